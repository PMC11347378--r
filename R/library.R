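#' Assemble an sgRNA library from per-gene guide specifications
#'
#' Builds the canonical guide catalog used by every downstream stage. Input
#' is tidy: one row per candidate spacer. The assembled library keeps exactly
#' `guides_per_gene` guides per gene (the screen design mixes a fixed number
#' of guides per gene so that gene-level aggregation is balanced), orders
#' entries canonically (gene alphabetical, then guide index) and assigns
#' stable guide ids of the form `sg<gene>-<i>`.
#'
#' @param gene_specs Data frame with columns `gene`, `role`
#'   (one of `"candidate"`, `"negative_control"`, `"positive_control"`) and
#'   `spacer` (20-nt uppercase DNA over ACGT); one row per spacer.
#' @param guides_per_gene Number of guides retained per gene (default 3).
#' @param name Library name stored as an attribute and echoed in output
#'   provenance.
#' @param ragged If `TRUE`, genes may carry fewer or more than
#'   `guides_per_gene` guides; the default is strict because balanced
#'   gene-level score aggregation assumes equal multiplicity.
#' @return An `sgrna_library`: a tibble with columns `guide_id`, `gene`,
#'   `spacer`, `role` and attributes `name` and `guides_per_gene`.
#' @export
#' @examples
#' specs <- tibble::tibble(
#'   gene = rep(c("Rosa26", "Tfdp1"), each = 3),
#'   role = rep(c("negative_control", "candidate"), each = 3),
#'   spacer = c("ACGTACGTACGTACGTACGT", "TTGCATTGCAGGGACCTTAC",
#'              "GATCGATCGATCGATCGATC", "CCGGAATTCCGGAATTCCGG",
#'              "TGCATGCATGCATGCATGCA", "AATTCCGGAATTGGCCAATT")
#' )
#' assemble_library(specs, guides_per_gene = 3, name = "demo")
assemble_library <- function(gene_specs, guides_per_gene = 3L,
                             name = "library", ragged = FALSE) {
  spec <- as_tibble(gene_specs)
  need <- c("gene", "role", "spacer")
  if (!all(need %in% names(spec)))
    abort(paste0("gene_specs must have columns ",
                 paste(need, collapse = ", ")))
  check_spacer_format(spec$spacer, where = spec$gene)

  dup <- spec |>
    dplyr::add_count(.data$spacer, name = ".n_spacer") |>
    filter(.data$.n_spacer > 1)
  if (nrow(dup) > 0) {
    offenders <- dup |>
      group_by(.data$spacer) |>
      summarise(genes = paste(unique(.data$gene), collapse = ", ")) |>
      mutate(msg = paste0(.data$spacer, " (", .data$genes, ")"))
    abort(c("duplicate spacer(s) shared across guides:", offenders$msg),
          class = "dualscreen_validation_error")
  }

  lib <- spec |>
    arrange(.data$gene) |>
    group_by(.data$gene) |>
    mutate(.idx = row_number()) |>
    ungroup()
  if (!ragged) {
    short <- lib |> count(.data$gene) |> filter(n < guides_per_gene)
    if (nrow(short) > 0)
      abort(paste0("gene(s) with fewer than ", guides_per_gene,
                   " spacers: ", paste(short$gene, collapse = ", ")))
    lib <- lib |> filter(.data$.idx <= guides_per_gene)
  }
  lib <- lib |>
    mutate(guide_id = paste0("sg", .data$gene, "-", .data$.idx)) |>
    select("guide_id", "gene", "spacer", "role")
  new_sgrna_library(lib, name = name, guides_per_gene = guides_per_gene)
}

new_sgrna_library <- function(x, name, guides_per_gene) {
  x <- as_tibble(x)
  structure(x,
            class = c("sgrna_library", class(x)),
            name = name,
            guides_per_gene = as.integer(guides_per_gene))
}

check_spacer_format <- function(spacers, where = NULL) {
  bad_len <- nchar(spacers) != 20L
  bad_chr <- grepl("[^ACGT]", spacers)
  if (any(bad_len | bad_chr)) {
    lab <- if (is.null(where)) seq_along(spacers) else where
    abort(c("malformed spacer(s): must be 20-nt uppercase ACGT",
            paste0(lab[bad_len | bad_chr], ": ",
                   spacers[bad_len | bad_chr])),
          class = "dualscreen_format_error")
  }
  invisible(TRUE)
}

#' Validate an sgRNA library
#'
#' Runs the full set of structural checks and returns a report rather than
#' raising: spacer length and alphabet, uniqueness of guide ids and spacers,
#' per-gene guide multiplicity, and presence of at least one
#' negative-control gene (required by the scoring stage, which needs a
#' neutral reference).
#'
#' @param lib A library data frame (columns `guide_id`, `gene`, `spacer`,
#'   `role`), typically from [assemble_library()] or [read_library_tsv()].
#' @return A `library_validation` tibble with one row per check
#'   (columns `check`, `ok`, `detail`) and attribute `ok` (all checks
#'   passed). `validation_ok()` extracts the flag.
#' @export
validate_library <- function(lib) {
  lib <- as_tibble(lib)
  gpg <- attr(lib, "guides_per_gene") %||% 3L
  checks <- list()
  add <- function(check, ok, detail = "") {
    checks[[length(checks) + 1]] <<- tibble(check = check, ok = ok,
                                            detail = detail)
  }

  bad_len <- lib$spacer[nchar(lib$spacer) != 20L]
  add("spacer_length", length(bad_len) == 0,
      if (length(bad_len)) paste(bad_len, collapse = ", ") else "")
  bad_chr <- lib$spacer[grepl("[^ACGT]", lib$spacer)]
  add("spacer_alphabet", length(bad_chr) == 0,
      if (length(bad_chr)) paste(bad_chr, collapse = ", ") else "")
  dup_id <- unique(lib$guide_id[duplicated(lib$guide_id)])
  add("guide_id_unique", length(dup_id) == 0, paste(dup_id, collapse = ", "))
  dup_sp <- unique(lib$spacer[duplicated(lib$spacer)])
  add("spacer_unique", length(dup_sp) == 0, paste(dup_sp, collapse = ", "))
  mult <- lib |> count(.data$gene) |> filter(n != gpg)
  add("per_gene_multiplicity", nrow(mult) == 0,
      if (nrow(mult)) paste0(mult$gene, " (", mult$n, ")", collapse = ", ")
      else "")
  add("no_negative_control", any(lib$role == "negative_control"),
      if (!any(lib$role == "negative_control"))
        "no negative_control gene present" else "")

  rep <- bind_rows(checks)
  structure(rep, class = c("library_validation", class(rep)),
            ok = all(rep$ok))
}

#' @rdname validate_library
#' @param report A `library_validation` object.
#' @export
validation_ok <- function(report) isTRUE(attr(report, "ok"))

#' Read and write sgRNA library TSV files
#'
#' The on-disk format is a plain UTF-8 tab-separated file with a header row
#' naming the columns `guide_id`, `gene`, `spacer`, `role` (any column
#' order; parsing is header-driven). Blank lines are skipped with a message.
#' `read_library_tsv(write_library_tsv(lib, path))` is the identity.
#'
#' @param path File path.
#' @param name Library name for the returned object; defaults to the file
#'   name without extension.
#' @return `read_library_tsv()` returns an `sgrna_library` tibble;
#'   `write_library_tsv()` returns `path` invisibly.
#' @export
read_library_tsv <- function(path, name = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  blank <- !nzchar(trimws(lines))
  if (any(blank)) {
    inform(paste0("skipped ", sum(blank), " blank line(s) in ", path))
    lines <- lines[!blank]
  }
  lines <- lines[!startsWith(lines, "#")]
  tab <- readr::read_tsv(I(paste(lines, collapse = "\n")),
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("guide_id", "gene", "spacer", "role")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    abort(paste0("library TSV missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "dualscreen_format_error")
  tab <- tab |> select(dplyr::all_of(need))
  check_spacer_format(tab$spacer, where = tab$guide_id)
  gpg <- tab |> count(.data$gene) |> pull(n)
  new_sgrna_library(
    tab,
    name = name %||% sub("\\.[^.]*$", "", basename(path)),
    guides_per_gene = if (length(unique(gpg)) == 1) gpg[1] else 3L
  )
}

#' @rdname read_library_tsv
#' @param lib An `sgrna_library` (or compatible data frame).
#' @export
write_library_tsv <- function(lib, path) {
  readr::write_tsv(as_tibble(lib)[, c("guide_id", "gene", "spacer", "role")],
                   path, progress = FALSE)
  invisible(path)
}

#' Generate mutually distant synthetic spacer sequences
#'
#' Deterministically generates `n` 20-nt spacers with pairwise Hamming
#' distance at least `min_dist` (default 3, so that single-mismatch barcode
#' rescue can never cross-assign reads between guides). Used to build the
#' packaged example libraries, whose true spacer sequences are not public.
#'
#' @param n Number of spacers.
#' @param seed Integer seed; the same seed always yields the same spacers.
#' @param min_dist Minimum pairwise Hamming distance.
#' @return Character vector of `n` spacers.
#' @export
synthetic_spacers <- function(n, seed = 104729L, min_dist = 3L) {
  with_stage_seed(seed, "synthetic_spacers", {
    out <- character(0)
    mat <- NULL # accepted spacers as an integer matrix, one row each
    tries <- 0
    while (length(out) < n) {
      tries <- tries + 1
      if (tries > 10000 * n) abort("could not generate spacers; lower n")
      cand <- sample(c("A", "C", "G", "T"), 20, replace = TRUE)
      ci <- match(cand, c("A", "C", "G", "T"))
      if (!is.null(mat) &&
          any(rowSums(mat != matrix(ci, nrow(mat), 20, byrow = TRUE)) <
              min_dist)) next
      out <- c(out, paste(cand, collapse = ""))
      mat <- rbind(mat, ci)
    }
    out
  })
}

#' Packaged example libraries (synthetic spacers)
#'
#' Two ready-made guide catalogs mirroring the screens the package models:
#' `example_invivo_library()` is the 15-gene transplantation screen library
#' (45 guides, 3 per gene) with lineage-specific positive controls
#' (HSPC: Gfi1, Uhrf1; B lineage: Ebf1, Pax5, Btk, Bcl6; T: Cd3e, Notch1;
#' granulocyte: Csf3r), negative controls Gfi1b and Rosa26, and the
#' candidates Tfdp1, Zfp114, Mllt3, Dach1. `example_invitro_library()` is a
#' 33-gene culture screen (99 guides) built around the strong depletion
#' genes Lmo2, Uhrf1, Tfdp1 and Zfp114, a Rosa26 negative control, and 28
#' neutral zinc-finger candidates. Spacer sequences are synthetic (the
#' original oligo sequences are not public) but deterministic, with
#' pairwise Hamming distance > 2.
#'
#' @return An `sgrna_library` tibble.
#' @export
example_invivo_library <- function() {
  genes <- c(
    Gfi1   = "positive_control", Uhrf1 = "positive_control",
    Ebf1   = "positive_control", Pax5  = "positive_control",
    Btk    = "positive_control", Bcl6  = "positive_control",
    Cd3e   = "positive_control", Notch1 = "positive_control",
    Csf3r  = "positive_control",
    Gfi1b  = "negative_control", Rosa26 = "negative_control",
    Tfdp1  = "candidate", Zfp114 = "candidate",
    Mllt3  = "candidate", Dach1  = "candidate"
  )
  build_example_library(genes, name = "invivo15", seed = 20021L)
}

#' @rdname example_invivo_library
#' @export
example_invitro_library <- function() {
  genes <- c(
    Rosa26 = "negative_control",
    Lmo2 = "positive_control", Uhrf1 = "positive_control",
    Tfdp1 = "candidate", Zfp114 = "candidate",
    setNames(rep("candidate", 28), sprintf("Zfp%03d", 1:28))
  )
  build_example_library(genes, name = "invitro33", seed = 48611L)
}

build_example_library <- function(genes, name, seed) {
  spacers <- synthetic_spacers(3L * length(genes), seed = seed)
  specs <- tibble(
    gene = rep(names(genes), each = 3),
    role = rep(unname(genes), each = 3),
    spacer = spacers
  )
  assemble_library(specs, guides_per_gene = 3L, name = name)
}

#' Expected lineage effects for the example in vivo library
#'
#' Maps each gene of [example_invivo_library()] to the output lineages where
#' its knockout is expected to deplete, the reference for
#' parameter-recovery checks. Negative-control genes map to no lineage.
#'
#' @return Tibble with columns `gene`, `role` and list-column `lineages`.
#' @export
example_gene_role_map <- function() {
  tibble(
    gene = c("Gfi1", "Uhrf1", "Ebf1", "Pax5", "Btk", "Bcl6", "Cd3e",
             "Notch1", "Csf3r", "Gfi1b", "Rosa26", "Tfdp1", "Zfp114",
             "Mllt3", "Dach1"),
    role = c(rep("positive_control", 9), rep("negative_control", 2),
             rep("candidate", 4)),
    lineages = list(
      c("HSPC", "Gr1"), c("HSPC", "Gr1"),
      c("B", "GCB", "B1a"), c("B", "GCB", "B1a"),
      c("B", "GCB", "B1a"), c("GCB"),
      c("T"), c("T"), c("Gr1"),
      character(0), character(0),
      c("HSPC", "Gr1", "T", "B", "GCB", "B1a"),
      character(0), character(0), character(0)
    )
  )
}

#' @export
print.sgrna_library <- function(x, ...) {
  cat("# sgRNA library '", attr(x, "name"), "': ",
      nrow(x), " guides, ", length(unique(x$gene)), " genes (",
      attr(x, "guides_per_gene"), " guides/gene)\n", sep = "")
  NextMethod()
}
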