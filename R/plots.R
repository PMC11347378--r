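#' Plot methods for screen results
#'
#' `autoplot.score_table()` draws the standard screen summary: with two
#' (or more) replicates, a replicate-vs-replicate scatter per context with
#' the depletion threshold marked; with one replicate, a per-gene dot
#' plot. `autoplot.celltrace()` draws the division-number histogram per
#' channel, and `autoplot.count_matrix()` the per-sample guide frequency
#' distribution (input-evenness view).
#'
#' @param object The result object.
#' @param threshold Depletion threshold drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.score_table <- function(object, threshold = -1, ...) {
  st <- as_tibble(object)
  key <- if ("guide_id" %in% names(st)) "guide_id" else "gene"
  reps <- sort(unique(st$replicate))
  if (length(reps) >= 2) {
    wide <- st |>
      filter(.data$replicate %in% reps[1:2]) |>
      select(dplyr::all_of(c(key, "gene", "context")), "replicate",
             "score") |>
      pivot_wider(names_from = "replicate", values_from = "score",
                  names_prefix = "rep_")
    ggplot(wide, aes(x = .data[[paste0("rep_", reps[1])]],
                     y = .data[[paste0("rep_", reps[2])]])) +
      geom_hline(yintercept = threshold, linetype = 2,
                 colour = "grey50") +
      geom_point(aes(colour = .data$gene), show.legend = FALSE) +
      geom_abline(slope = 1, intercept = 0, colour = "grey70") +
      facet_wrap(~context) +
      labs(x = paste("score, replicate", reps[1]),
           y = paste("score, replicate", reps[2])) +
      theme_bw()
  } else {
    ggplot(st, aes(x = .data[[key]], y = .data$score)) +
      geom_hline(yintercept = threshold, linetype = 2,
                 colour = "grey50") +
      geom_point() +
      facet_wrap(~context) +
      labs(x = NULL, y = "log2 score") +
      theme_bw() +
      ggplot2::theme(axis.text.x =
                       ggplot2::element_text(angle = 90, hjust = 1))
  }
}

#' @rdname autoplot.score_table
#' @export
autoplot.celltrace <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = factor(.data$division), y = .data$frequency)) +
    geom_col() +
    facet_wrap(~channel) +
    labs(x = "cell divisions", y = "fraction of cells") +
    theme_bw()
}

#' @rdname autoplot.score_table
#' @export
autoplot.count_matrix <- function(object, ...) {
  cm <- as_tibble(object) |>
    group_by(.data$sample_id) |>
    mutate(frequency = .data$count / sum(.data$count)) |>
    ungroup()
  ggplot(cm, aes(x = .data$guide_id, y = .data$frequency)) +
    geom_col() +
    facet_wrap(~sample_id) +
    labs(x = NULL, y = "guide frequency") +
    theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}
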