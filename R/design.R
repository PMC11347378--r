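#' Screen design parameters
#'
#' Bundles the experimental design constants of a dual-fluorescence screen:
#' how Cas9-GFP and wild-type cells are mixed, how efficiently wells are
#' transduced, how large wells and grafts are, how many divisions have
#' happened by each flow readout, and which output lineages are analyzed at
#' what expansion and sorting depth.
#'
#' `screen_design_invitro()` and `screen_design_invivo()` give the two
#' stock designs: culture wells read on day 2 (1 division) and day 7
#' (5 divisions) at a 1:1 Cas9+:Cas9- mix, versus transplantation at a 3:2
#' mix with a 5e4-cell transduced graft (3e4 Cas9+, 2e4 Cas9-) per mouse
#' and six sorted output lineages.
#'
#' @param mix_ratio Cas9+:Cas9- mixing ratio rho (1 means 1:1, 1.5 means
#'   3:2).
#' @param transduction_rate Fraction of cells transduced per well, in
#'   (0, 1).
#' @param cells_per_well Cells seeded per well.
#' @param graft_size Transduced cells transplanted per recipient (in vivo).
#' @param divisions_by_readout Named integer vector mapping readout labels
#'   to cumulative division numbers; must be non-decreasing in time.
#' @param lineages Tibble with columns `lineage`, `expansion` (fold
#'   expansion of the engrafted population by analysis) and `sort_depth`
#'   (cells sorted per GFP fraction).
#' @param facs_events Flow-cytometry events recorded per well analysis.
#' @return A `screen_design` list.
#' @export
screen_design <- function(mix_ratio = 1,
                          transduction_rate = 0.3,
                          cells_per_well = 2e4,
                          graft_size = 5e4,
                          divisions_by_readout = c(day2 = 1L, day7 = 5L),
                          lineages = NULL,
                          facs_events = 1e4) {
  stopifnot(mix_ratio > 0,
            transduction_rate > 0, transduction_rate < 1,
            cells_per_well >= 1, graft_size >= 1, facs_events >= 1)
  if (is.unsorted(divisions_by_readout))
    abort("divisions_by_readout must be non-decreasing over time")
  if (is.null(lineages))
    lineages <- tibble(lineage = "HSPC", expansion = 1e3, sort_depth = 1e4)
  # graft split follows the mixing ratio exactly (e.g. 3:2 -> 3e4 + 2e4)
  pos <- round(graft_size * mix_ratio / (1 + mix_ratio))
  structure(list(
    mix_ratio = mix_ratio,
    transduction_rate = transduction_rate,
    cells_per_well = cells_per_well,
    graft_size = graft_size,
    graft_split = c(cas9_pos = pos, cas9_neg = graft_size - pos),
    divisions_by_readout = divisions_by_readout,
    lineages = as_tibble(lineages),
    facs_events = facs_events
  ), class = "screen_design")
}

#' @rdname screen_design
#' @param ... Overrides passed on to [screen_design()].
#' @export
screen_design_invitro <- function(...) {
  args <- modifyList(list(
    mix_ratio = 1, transduction_rate = 0.3, cells_per_well = 2e4,
    divisions_by_readout = c(day2 = 1L, day7 = 5L), facs_events = 1e4
  ), list(...))
  do.call(screen_design, args)
}

#' @rdname screen_design
#' @export
screen_design_invivo <- function(...) {
  lin <- tibble(
    lineage = c("HSPC", "Gr1", "T", "B", "GCB", "B1a"),
    expansion = 1e3,
    sort_depth = 1e4
  )
  args <- modifyList(list(
    mix_ratio = 1.5, transduction_rate = 0.25, cells_per_well = 2e4,
    graft_size = 5e4, divisions_by_readout = c(week8 = 10L),
    lineages = lin, facs_events = 1e4
  ), list(...))
  do.call(screen_design, args)
}

#' @export
print.screen_design <- function(x, ...) {
  cat("<screen_design>\n",
      "  mix_ratio (Cas9+:Cas9-): ", x$mix_ratio, "\n",
      "  transduction_rate: ", x$transduction_rate, "\n",
      "  cells_per_well: ", x$cells_per_well, "\n",
      "  graft: ", x$graft_size, " (",
      x$graft_split[["cas9_pos"]], " Cas9+ / ",
      x$graft_split[["cas9_neg"]], " Cas9-)\n",
      "  readouts: ",
      paste(names(x$divisions_by_readout), x$divisions_by_readout,
            sep = "=", collapse = ", "), " divisions\n",
      "  lineages: ", paste(x$lineages$lineage, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Planted per-gene fitness effects for simulation
#'
#' The simulator's ground truth: per-gene Cas9 editing efficiency `e` (the
#' probability that a transduced Cas9+ cell is actually knocked out) and
#' per gene-by-lineage relative fitness `w` of edited cells. An edited
#' cell's expected surviving offspring per division is `2 w`: `w = 1` is
#' neutral, `w = 0.5` means no net growth, `w = 0` means extinction after
#' one division. Gene-lineage pairs not listed in `effects` default to
#' neutral.
#'
#' @param effects Data frame with columns `gene`, `lineage`
#'   (`"*"` applies to every context) and `fitness` (w >= 0). `NULL` means
#'   an all-neutral model.
#' @param editing Editing efficiency in `[0, 1]`; either a single default
#'   or a named per-gene vector (default 0.9, the measured knockout rate a
#'   few days post transduction).
#' @return A `fitness_model` list.
#' @export
#' @examples
#' fm <- fitness_model(
#'   tibble::tibble(gene = "Tfdp1", lineage = "*", fitness = 0.5)
#' )
#' fitness_of(fm, c("Tfdp1", "Rosa26"), "HSPC")
fitness_model <- function(effects = NULL, editing = 0.9) {
  if (is.null(effects))
    effects <- tibble(gene = character(), lineage = character(),
                      fitness = double())
  effects <- as_tibble(effects)
  stopifnot(all(c("gene", "lineage", "fitness") %in% names(effects)))
  if (any(effects$fitness < 0))
    abort("fitness w must be >= 0", class = "dualscreen_parameter_error")
  if (any(unlist(editing) < 0 | unlist(editing) > 1))
    abort("editing efficiency must lie in [0, 1]",
          class = "dualscreen_parameter_error")
  structure(list(effects = effects, editing = editing),
            class = "fitness_model")
}

#' @rdname fitness_model
#' @param fm A `fitness_model`.
#' @param gene Gene symbol(s).
#' @param lineage Single lineage/context label.
#' @export
fitness_of <- function(fm, gene, lineage) {
  eff <- fm$effects
  vapply(gene, function(g) {
    hit <- eff$fitness[eff$gene == g &
                         (eff$lineage == lineage | eff$lineage == "*")]
    if (length(hit)) hit[1] else 1
  }, numeric(1), USE.NAMES = FALSE)
}

#' @rdname fitness_model
#' @export
editing_of <- function(fm, gene) {
  e <- fm$editing
  if (is.null(names(e))) rep(unname(e[1]), length(gene))
  else {
    out <- unname(e[gene])
    out[is.na(out)] <- 0.9
    out
  }
}

#' Write or read the simulation truth fixture
#'
#' Every simulation can write its planted fitness effects alongside the
#' generated data, so that hit-calling can be checked against the ground
#' truth (parameter recovery). Format: TSV with columns `gene`, `lineage`,
#' `fitness`, `editing`.
#'
#' @param fm A [fitness_model()].
#' @param lib The library the simulation used (supplies the gene list).
#' @param path Output TSV path.
#' @param contexts Contexts to tabulate (default the wildcard `"*"`).
#' @return `write_truth_tsv()` returns `path` invisibly; `read_truth_tsv()`
#'   a tibble.
#' @export
write_truth_tsv <- function(fm, lib, path, contexts = "*") {
  genes <- unique(as_tibble(lib)$gene)
  truth <- expand_grid(gene = genes, lineage = contexts)
  truth$fitness <- vapply(seq_len(nrow(truth)), function(i)
    fitness_of(fm, truth$gene[i], truth$lineage[i]), numeric(1))
  truth$editing <- editing_of(fm, truth$gene)
  readr::write_tsv(truth, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  readr::read_tsv(path, col_types = "ccdd", progress = FALSE)
}
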