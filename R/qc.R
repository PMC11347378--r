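#' Screen quality control
#'
#' Collects the routine health checks of a dual-fluorescence screen:
#'
#' * **Input evenness** - the min/max per-guide frequency of the input
#'   library against an evenness band (default 2-9%). The band is quoted
#'   in integer percent, so frequencies are compared after rounding to
#'   whole percent.
#' * **Guide recovery** - per sorted sample, the fraction of library
#'   guides with at least one read; a healthy screen recovers every guide
#'   in every fraction.
#' * **GFP ratio** - per lineage, the GFP+/GFP- cell ratio among
#'   transduced cells against the design mixing ratio; equal engraftment
#'   and expansion of Cas9+ and wild-type cells keeps this at the input
#'   mix.
#' * **mCherry fraction** - per flow readout, the transduced fraction
#'   against the design transduction rate.
#'
#' Any section whose inputs are not supplied is skipped.
#'
#' @param input_freqs Tibble from [simulate_input_frequencies()] (or
#'   measured equivalents with columns `guide_id`, `frequency`).
#' @param cm A `count_matrix` tibble (long, with `sample_id`, `guide_id`,
#'   `count`).
#' @param design A [screen_design()].
#' @param cells Optional sorted-cell tibble (`lineage`, `gfp_gate` or
#'   `cas9`, `cells`) for the GFP-ratio check, e.g.
#'   `$lineage_state` of [simulate_invivo_screen()].
#' @param flow Optional `flow_counts` tibble for the mCherry-fraction
#'   check.
#' @param evenness_bounds Length-2 frequency band (default `c(0.02,
#'   0.09)`).
#' @param ratio_tol Relative tolerance for the GFP-ratio and
#'   mCherry-fraction checks (default 0.2).
#' @return A `screen_qc` list of section tibbles with an overall `ok`
#'   attribute; see [tidy.screen_qc()] and [glance.screen_qc()].
#' @export
qc_screen <- function(input_freqs = NULL, cm = NULL, design = NULL,
                      cells = NULL, flow = NULL,
                      evenness_bounds = c(0.02, 0.09), ratio_tol = 0.2) {
  sections <- list()

  if (!is.null(input_freqs)) {
    f <- as_tibble(input_freqs)
    lo <- f$guide_id[which.min(f$frequency)]
    hi <- f$guide_id[which.max(f$frequency)]
    # the band is quoted in whole percent; compare on that scale
    min_pct <- round(100 * min(f$frequency))
    max_pct <- round(100 * max(f$frequency))
    sections$evenness <- tibble(
      min_frequency = min(f$frequency), min_guide = lo,
      max_frequency = max(f$frequency), max_guide = hi,
      lower = evenness_bounds[1], upper = evenness_bounds[2],
      ok = min_pct >= round(100 * evenness_bounds[1]) &
        max_pct <= round(100 * evenness_bounds[2]),
      detail = if_else(
        max_pct > round(100 * evenness_bounds[2]),
        paste0("guide ", hi, " over-represented"),
        if_else(min_pct < round(100 * evenness_bounds[1]),
                paste0("guide ", lo, " under-represented"), "")
      )
    )
  }

  if (!is.null(cm)) {
    sections$recovery <- as_tibble(cm) |>
      group_by(.data$sample_id) |>
      summarise(
        n_guides = dplyr::n(),
        recovered = sum(.data$count > 0),
        recovered_fraction = mean(.data$count > 0),
        .groups = "drop"
      ) |>
      mutate(ok = .data$recovered_fraction == 1)
  }

  if (!is.null(cells) && !is.null(design)) {
    gate_col <- if ("gfp_gate" %in% names(cells)) "gfp_gate" else "cas9"
    sections$gfp_ratio <- as_tibble(cells) |>
      group_by(.data$lineage) |>
      summarise(
        ratio = sum(.data$cells[.data[[gate_col]] == "pos"]) /
          sum(.data$cells[.data[[gate_col]] == "neg"]),
        .groups = "drop"
      ) |>
      mutate(expected = design$mix_ratio,
             ok = abs(.data$ratio / .data$expected - 1) <= ratio_tol)
  }

  if (!is.null(flow) && !is.null(design)) {
    sections$mcherry_fraction <- as_tibble(flow) |>
      group_by(dplyr::across(dplyr::any_of(c("guide_id", "timepoint",
                                             "replicate")))) |>
      summarise(
        mcherry_fraction = sum(.data$events[.data$mcherry == "pos"]) /
          sum(.data$events),
        .groups = "drop"
      )
    # wells legitimately vary in transduction rate; flag only wells far
    # outside the plausible range rather than against the single design tau
    sections$mcherry_fraction <- sections$mcherry_fraction |>
      mutate(expected = design$transduction_rate,
             ok = .data$mcherry_fraction > 0.02 &
               .data$mcherry_fraction < 0.9)
  }

  structure(sections, class = "screen_qc",
            ok = all(vapply(sections, function(s) all(s$ok), logical(1))))
}

#' @export
print.screen_qc <- function(x, ...) {
  cat("<screen_qc> overall:", if (attr(x, "ok")) "PASS" else "FAIL", "\n")
  for (nm in names(x)) {
    cat("--", nm, if (all(x[[nm]]$ok)) "[ok]" else "[FAIL]", "\n")
  }
  invisible(x)
}

#' Tidy and summarize QC reports
#'
#' `tidy()` flattens a [qc_screen()] report into one row per individual
#' check; `glance()` gives the one-row overall summary.
#'
#' @param x A `screen_qc` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.screen_qc <- function(x, ...) {
  map_dfr(names(x), function(nm) {
    s <- x[[nm]]
    tibble(section = nm,
           check = if ("sample_id" %in% names(s)) s$sample_id
                   else if ("lineage" %in% names(s)) s$lineage
                   else if ("guide_id" %in% names(s))
                     paste(s$guide_id, s$timepoint %||% "", sep = "/")
                   else nm,
           ok = s$ok)
  })
}

#' @rdname tidy.screen_qc
#' @export
glance.screen_qc <- function(x, ...) {
  td <- tidy(x)
  tibble(sections = length(x), checks = nrow(td),
         failed = sum(!td$ok), ok = isTRUE(attr(x, "ok")))
}
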