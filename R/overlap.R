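#' Build a top-percentile target gene set from binding scores
#'
#' Given per-gene binding scores (e.g. ChIP peak scores for a
#' transcription factor), returns the genes at or above the empirical
#' `q`-quantile, the conventional way of defining a factor's direct-target
#' set from a continuous binding ranking. The quantile is computed by the
#' nearest-rank method (quantile type 1) and ties at the cutoff are all
#' included, so set membership is stable under score rescaling.
#'
#' @param scores Data frame with columns `gene` and `score`, or a named
#'   numeric vector.
#' @param q Quantile in (0, 1); default 0.90 (the top decile).
#' @param name Name for the resulting set.
#' @return A `gene_set`: a character vector of gene symbols with
#'   attributes `name` and `cutoff`.
#' @export
#' @examples
#' percentile_target_set(
#'   tibble::tibble(gene = paste0("g", 1:10), score = 1:10), q = 0.9
#' )
percentile_target_set <- function(scores, q = 0.90, name = "targets") {
  if (is.numeric(scores) && !is.null(names(scores)))
    scores <- tibble(gene = names(scores), score = unname(scores))
  scores <- as_tibble(scores)
  stopifnot(all(c("gene", "score") %in% names(scores)))
  if (nrow(scores) == 0) abort("empty score map")
  if (!all(is.finite(scores$score))) abort("scores must be finite")
  if (q <= 0 || q >= 1) abort("q must lie in (0, 1)")
  # nearest-rank on the upper tail: the cutoff is the k-th largest score
  # with k = ceiling((1 - q) n), so unique scores give exactly k genes
  # and ties at the cutoff are all included
  k <- ceiling((1 - q) * nrow(scores))
  cutoff <- sort(scores$score, decreasing = TRUE)[k]
  gene_set(scores$gene[scores$score >= cutoff], name = name,
           cutoff = cutoff)
}

#' @rdname percentile_target_set
#' @param members Character vector of gene symbols (deduplicated).
#' @param cutoff Optional score cutoff recorded as an attribute.
#' @export
gene_set <- function(members, name = "set", cutoff = NULL) {
  structure(unique(as.character(members)), class = "gene_set",
            name = name, cutoff = cutoff)
}

#' @export
print.gene_set <- function(x, ...) {
  cat("# gene_set '", attr(x, "name"), "': ", length(x), " genes\n",
      sep = "")
  print(unclass(head(x, 10)))
  if (length(x) > 10) cat("...\n")
  invisible(x)
}

#' Hypergeometric overlap test between two gene sets
#'
#' Significance of the intersection of two gene sets drawn from a common
#' universe of `universe_size` genes, under the one-sided hypergeometric
#' (Fisher exact) upper tail: `p = P(X >= |A intersect B|)` for
#' `X ~ Hypergeometric(N, |B|, |A|)`. The universe must be supplied
#' explicitly (typically the number of expressed genes) because the
#' p-value depends strongly on it. Fold enrichment is the observed overlap
#' over its null expectation, `(|A∩B| / |A|) / (|B| / N)`.
#'
#' @param a,b `gene_set`s or character vectors.
#' @param universe_size Number of genes in the common universe `N`.
#' @return An `overlap_result` list; see [tidy.overlap_result()] and
#'   [glance.overlap_result()].
#' @export
overlap_test <- function(a, b, universe_size) {
  name_a <- attr(a, "name") %||% "A"
  name_b <- attr(b, "name") %||% "B"
  a <- unique(as.character(a)); b <- unique(as.character(b))
  n <- length(a); m <- length(b); N <- universe_size
  if (n > N || m > N)
    abort("set larger than the declared universe")
  k <- length(intersect(a, b))
  if (k > min(n, m)) abort("overlap exceeds the smaller set") # unreachable
  # upper tail including the observed overlap
  p <- phyper(k - 1, m, N - m, n, lower.tail = FALSE)
  structure(list(
    set_a = name_a, set_b = name_b,
    n_a = n, n_b = m, n_overlap = k, universe = N,
    p_value = p,
    fold_enrichment = if (n == 0 || m == 0) NA_real_
                      else (k / n) / (m / N),
    jaccard = if (length(union(a, b)) == 0) NA_real_
              else k / length(union(a, b)),
    overlap_genes = intersect(a, b)
  ), class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("<overlap_result> |A|=", x$n_a, " |B|=", x$n_b,
      " |A∩B|=", x$n_overlap, " N=", x$universe, "\n",
      "  hypergeometric upper-tail p = ", format(x$p_value, digits = 4),
      ", fold enrichment = ", format(x$fold_enrichment, digits = 4),
      ", Jaccard = ", format(x$jaccard, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Tidy and summarize overlap results
#'
#' `tidy()` returns the per-region membership counts; `glance()` the
#' one-row test summary.
#'
#' @param x An `overlap_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.overlap_result <- function(x, ...) {
  tibble(
    region = c("a_only", "b_only", "overlap"),
    count = c(x$n_a - x$n_overlap, x$n_b - x$n_overlap, x$n_overlap)
  )
}

#' @rdname tidy.overlap_result
#' @export
glance.overlap_result <- function(x, ...) {
  tibble(n_a = x$n_a, n_b = x$n_b, n_overlap = x$n_overlap,
         universe = x$universe, p_value = x$p_value,
         fold_enrichment = x$fold_enrichment, jaccard = x$jaccard)
}

#' Exact Venn region counts for two or three gene sets
#'
#' @param sets Named list of 2 or 3 `gene_set`s / character vectors.
#' @return Tibble with one row per Venn region: logical membership
#'   columns (one per set), `region` label and `count`. Region counts sum
#'   to the size of the union.
#' @export
multiway_venn <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || length(sets) > 3)
    abort("multiway_venn supports 2 or 3 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- paste0("set", seq_along(sets))
  sets <- map(sets, function(s) unique(as.character(s)))
  universe <- unique(unlist(sets))
  member <- map(sets, function(s) universe %in% s)
  grid <- expand_grid(!!!setNames(rep(list(c(TRUE, FALSE)),
                                      length(sets)), names(sets))) |>
    filter(dplyr::if_any(dplyr::everything()))
  grid$count <- vapply(seq_len(nrow(grid)), function(i) {
    inside <- rep(TRUE, length(universe))
    for (nm in names(sets)) {
      want <- grid[[nm]][i]
      inside <- inside & (member[[nm]] == want)
    }
    sum(inside)
  }, numeric(1))
  grid$region <- vapply(seq_len(nrow(grid)), function(i)
    paste(names(sets)[unlist(grid[i, names(sets)])], collapse = "&"),
    character(1))
  grid[, c(names(sets), "region", "count")]
}

#' Read and write gene lists
#'
#' Gene lists are one symbol per line; scored lists are two-column TSV
#' (`gene`, `score`) with a header.
#'
#' @param path File path.
#' @return `read_gene_list()` returns a character vector;
#'   `read_gene_scores()` a tibble with `gene` and `score`.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, encoding = "UTF-8"))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' @rdname read_gene_list
#' @export
read_gene_scores <- function(path) {
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  stopifnot(all(c("gene", "score") %in% names(out)))
  out
}
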