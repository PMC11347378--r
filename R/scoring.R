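#' Survival/proliferation score from flow-cytometry gate counts
#'
#' The screen's flow readout: for each well, the GFP+ (Cas9+) fraction
#' among transduced (mCherry+) cells is compared with the GFP+ fraction
#' among untransduced (mCherry-) cells of the same well, and the score is
#' the log2 ratio of the two fractions. Because the untransduced cells of
#' the same well are the reference, the score is invariant to the well's
#' transduction efficiency and to overall culture growth; knockouts that
#' impair survival or proliferation deplete GFP+ cells specifically in the
#' mCherry+ gate and drive the score negative.
#'
#' The default `mode = "fraction"` is this within-gate fraction ratio. The
#' literal cell-count ratio mCherry+GFP+ / mCherry-GFP+ is available as
#' `mode = "raw"`; it is *not* transduction-invariant (a well at 60%
#' transduction scores ~log2(0.6/0.4) even for a neutral guide), which is
#' why the fraction form is the default. An optional anchor timepoint
#' subtracts each guide's early score (e.g. day 2, before knockout effects
#' manifest) from later timepoints.
#'
#' @param flow A `flow_counts` tibble in long gate format: columns
#'   `mcherry`, `gfp`, `events` plus identifying columns (`guide_id`,
#'   `gene`, `timepoint`, optionally `replicate`).
#' @param pseudocount Added to each gate count inside the fractions
#'   (default 0.5), keeping all scores finite.
#' @param mode `"fraction"` (default, internally controlled) or `"raw"`.
#' @param anchor_timepoint Optional timepoint label whose score is
#'   subtracted from every other timepoint within guide and replicate.
#' @return A `score_table` tibble: `guide_id`, `gene`, `context` (the
#'   timepoint), `replicate`, `score`.
#' @export
surpro_score <- function(flow, pseudocount = 0.5,
                         mode = c("fraction", "raw"),
                         anchor_timepoint = NULL) {
  mode <- match.arg(mode)
  flow <- as_tibble(flow)
  stopifnot(all(c("mcherry", "gfp", "events") %in% names(flow)))
  if (!"replicate" %in% names(flow)) flow$replicate <- 1L
  keys <- intersect(c("guide_id", "gene", "timepoint", "replicate"),
                    names(flow))

  wide <- flow |>
    mutate(gate = paste0("m", .data$mcherry, "_g", .data$gfp)) |>
    select(dplyr::all_of(keys), "gate", "events") |>
    pivot_wider(names_from = "gate", values_from = "events",
                values_fill = 0L)
  empty <- wide |>
    filter(.data$mpos_gpos + .data$mpos_gneg == 0 |
             .data$mneg_gpos + .data$mneg_gneg == 0)
  if (nrow(empty) > 0)
    abort(paste0("well(s) with an empty mCherry gate (no events); ",
                 "increase FACS analysis depth: ",
                 paste(utils::head(empty$guide_id, 5), collapse = ", ")),
          class = "dualscreen_data_error")

  a <- pseudocount
  out <- wide |>
    mutate(score = if (mode == "fraction") {
      fpos <- (.data$mpos_gpos + a) /
        (.data$mpos_gpos + .data$mpos_gneg + 2 * a)
      fneg <- (.data$mneg_gpos + a) /
        (.data$mneg_gpos + .data$mneg_gneg + 2 * a)
      log2(fpos / fneg)
    } else {
      log2((.data$mpos_gpos + a) / (.data$mneg_gpos + a))
    }) |>
    select(dplyr::all_of(keys), "score") |>
    rename(context = "timepoint")

  if (!is.null(anchor_timepoint)) {
    anchor <- out |>
      filter(.data$context == anchor_timepoint) |>
      select(-"context") |>
      rename(.anchor = "score")
    out <- out |>
      filter(.data$context != anchor_timepoint) |>
      left_join(anchor, by = setdiff(keys, "timepoint")) |>
      mutate(score = .data$score - .data$.anchor) |>
      select(-".anchor")
  }
  new_score_table(out)
}

new_score_table <- function(x) {
  x <- as_tibble(x)
  structure(x, class = c("score_table", setdiff(class(x), "score_table")))
}

#' sgRNA abundance score from sorted-fraction read counts
#'
#' The screen's sequencing readout: per guide and lineage, the log2 fold
#' change of CPM-normalized read counts in the sorted GFP+ (Cas9+)
#' fraction over the GFP- (wild-type) fraction. The wild-type cells carry
#' the same guides through the same transplantation bottleneck and
#' expansion, so guide-specific depletion in GFP+ cells isolates the
#' knockout effect.
#'
#' @param cm A CPM-normalized `count_matrix` tibble (see
#'   [normalize_cpm()]): columns `guide_id`, `gene`, `lineage`,
#'   `gfp_gate` (`"pos"/"neg"`), `cpm`, optionally `replicate` /
#'   `experiment`.
#' @return A `score_table` tibble: `guide_id`, `gene`, `context` (the
#'   lineage), `replicate`, `score`.
#' @export
abundance_score <- function(cm) {
  cm <- as_tibble(cm)
  stopifnot(all(c("guide_id", "lineage", "gfp_gate") %in% names(cm)))
  if (!"cpm" %in% names(cm))
    abort("run normalize_cpm() before abundance_score()")
  if (!"replicate" %in% names(cm)) cm$replicate <- 1L
  keys <- intersect(c("guide_id", "gene", "lineage", "replicate",
                      "experiment"), names(cm))
  wide <- cm |>
    select(dplyr::all_of(keys), "gfp_gate", "cpm") |>
    pivot_wider(names_from = "gfp_gate", values_from = "cpm")
  if (!all(c("pos", "neg") %in% names(wide)) || anyNA(wide$pos) ||
      anyNA(wide$neg))
    abort("GFP+ and GFP- samples are not matched guide-for-guide",
          class = "dualscreen_data_error")
  wide |>
    mutate(score = log2(.data$pos / .data$neg)) |>
    select(dplyr::all_of(keys), "score") |>
    rename(context = "lineage") |>
    new_score_table()
}

#' Aggregate per-guide scores to gene level
#'
#' Averages the scores of a gene's guides within each context and
#' replicate (mean by default; median available). Guides with missing
#' scores are dropped with a warning, and genes left with no scored guide
#' are omitted.
#'
#' @param st A `score_table` (from [surpro_score()] or
#'   [abundance_score()]).
#' @param method `"mean"` (default) or `"median"`.
#' @return A `score_table` tibble keyed by `gene`, `context`, `replicate`
#'   with `score` and `n_guides`.
#' @export
gene_score <- function(st, method = c("mean", "median")) {
  method <- match.arg(method)
  st <- as_tibble(st)
  if (anyNA(st$score)) {
    warn("dropping guide scores that are NA")
    st <- st |> filter(!is.na(.data$score))
  }
  agg <- if (method == "mean") mean else median
  st |>
    group_by(.data$gene, .data$context, .data$replicate) |>
    summarise(score = agg(.data$score), n_guides = dplyr::n(),
              .groups = "drop") |>
    new_score_table()
}

#' Call depletion (and optionally enrichment) hits
#'
#' A gene is a depleted hit in a context when its aggregated score falls
#' below the log2 threshold (default -1, i.e. at least a two-fold
#' GFP+-specific depletion) in *every* replicate; setting
#' `require_all_replicates = FALSE` instead thresholds the replicate-mean
#' score.
#'
#' @param gene_scores A gene-level `score_table` (see [gene_score()]).
#' @param threshold Depletion threshold in log2 units (default -1).
#' @param require_all_replicates Hit must pass in each replicate
#'   (default) rather than on the replicate mean.
#' @param enrichment Also report genes scoring above `-threshold` as
#'   enriched.
#' @return A `hit_table` tibble: `gene`, `context`, `score` (replicate
#'   mean), `n_replicates`, `threshold`, `hit`, `direction`.
#' @export
call_hits <- function(gene_scores, threshold = -1,
                      require_all_replicates = TRUE, enrichment = FALSE) {
  gs <- as_tibble(gene_scores)
  if (nrow(gs) == 0) abort("no gene scores supplied")
  out <- gs |>
    group_by(.data$gene, .data$context) |>
    summarise(
      dep_hit = if (require_all_replicates) all(.data$score < threshold)
                else mean(.data$score) < threshold,
      enr_hit = if (require_all_replicates) all(.data$score > -threshold)
                else mean(.data$score) > -threshold,
      score = mean(.data$score),
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(threshold = threshold,
           hit = .data$dep_hit | (enrichment & .data$enr_hit),
           direction = dplyr::case_when(
             .data$dep_hit ~ "depleted",
             enrichment & .data$enr_hit ~ "enriched",
             TRUE ~ "none"
           )) |>
    select("gene", "context", "score", "n_replicates", "threshold",
           "hit", "direction")
  structure(out, class = c("hit_table", class(out)))
}

#' Correlation of scores between two replicates
#'
#' Pearson correlation of matched guide (or gene) scores between
#' replicate pairs, the screen's reproducibility readout.
#'
#' @param st A `score_table` with a `replicate` column holding exactly
#'   two replicates, or more (all pairs are reported).
#' @return Tibble with `context`, `replicate_a`, `replicate_b`, `r`, `n`.
#' @export
replicate_correlation <- function(st) {
  st <- as_tibble(st)
  key <- if ("guide_id" %in% names(st)) "guide_id" else "gene"
  reps <- sort(unique(st$replicate))
  if (length(reps) < 2) abort("need at least two replicates")
  pairs <- utils::combn(reps, 2, simplify = FALSE)
  map_dfr(sort(unique(st$context)), function(ctx) {
    map_dfr(pairs, function(pr) {
      a <- st |> filter(.data$context == ctx, .data$replicate == pr[1])
      b <- st |> filter(.data$context == ctx, .data$replicate == pr[2])
      m <- inner_join(a |> select(dplyr::all_of(key), "score"),
                      b |> select(dplyr::all_of(key), "score"),
                      by = key, suffix = c("_a", "_b"))
      if (nrow(m) < 3)
        abort("fewer than 3 matched keys between replicates",
              class = "dualscreen_data_error")
      tibble(context = ctx, replicate_a = pr[1], replicate_b = pr[2],
             r = cor(m$score_a, m$score_b), n = nrow(m))
    })
  })
}
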