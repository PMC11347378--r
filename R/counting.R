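#' Extract candidate spacers from amplicon reads
#'
#' Locates the 5' anchor of the layout within the allowed offset window
#' (tolerating up to `max_anchor_mismatch` substitutions; the earliest
#' acceptable offset wins) and returns the 20-mer that follows. Reads where
#' the anchor is not found, or that are too short to contain a full spacer
#' after it, yield `NA`.
#'
#' @param reads Character vector of read sequences.
#' @param layout A [read_layout()].
#' @return Character vector of 20-mers, `NA` where extraction failed.
#' @export
extract_spacer <- function(reads, layout) {
  m <- nchar(layout$anchor5)
  sl <- layout$spacer_len
  out <- rep(NA_character_, length(reads))
  remaining <- seq_along(reads)
  for (off in layout$anchor_search_window) {
    if (!length(remaining)) break
    cand <- substr(reads[remaining], off + 1L, off + m)
    ok <- cand == layout$anchor5
    if (layout$max_anchor_mismatch > 0 && any(!ok)) {
      chk <- which(!ok & nchar(cand) == m)
      if (length(chk)) {
        a_raw <- charToRaw(layout$anchor5)
        mm <- vapply(cand[chk], function(s)
          sum(charToRaw(s) != a_raw), integer(1), USE.NAMES = FALSE)
        ok[chk] <- mm <= layout$max_anchor_mismatch
      }
    }
    hit <- remaining[ok]
    sp <- substr(reads[hit], off + m + 1L, off + m + sl)
    full <- nchar(sp) == sl
    out[hit[full]] <- sp[full]
    remaining <- c(remaining[!ok], hit[!full])
  }
  out
}

#' Assign extracted spacers to library guides
#'
#' Exact matches win. A non-exact spacer is rescued if exactly one library
#' spacer lies within Hamming distance `max_mismatch`; two or more
#' equidistant nearest neighbours make it ambiguous, none within range
#' leaves it unassigned. With a library whose pairwise spacer distances
#' exceed `2 * max_mismatch`, rescue can never cross-assign reads.
#'
#' @param spacers Character vector of candidate 20-mers (`NA` allowed).
#' @param lib The library.
#' @param max_mismatch Maximum Hamming distance for rescue (default 1).
#' @return Tibble with columns `spacer`, `guide_id` (`NA` unless
#'   assigned) and `status` (`assigned_exact`, `assigned_mm`, `ambiguous`,
#'   `unassigned`).
#' @export
assign_spacer <- function(spacers, lib, max_mismatch = 1L) {
  lib_tb <- as_tibble(lib)
  idx <- match(spacers, lib_tb$spacer)
  status <- ifelse(is.na(spacers), NA_character_,
                   ifelse(is.na(idx), "unassigned", "assigned_exact"))
  guide <- lib_tb$guide_id[idx]

  todo <- which(!is.na(spacers) & is.na(idx))
  if (length(todo) && max_mismatch > 0) {
    lib_raw <- lapply(lib_tb$spacer, charToRaw)
    uniq <- unique(spacers[todo])
    res <- lapply(uniq, function(s) {
      if (nchar(s) != 20L) return(list(status = "unassigned",
                                       guide = NA_character_))
      s_raw <- charToRaw(s)
      d <- vapply(lib_raw, function(l) sum(l != s_raw), integer(1))
      near <- which(d <= max_mismatch & d == min(d))
      if (length(near) == 1)
        list(status = "assigned_mm", guide = lib_tb$guide_id[near])
      else if (length(near) >= 2)
        list(status = "ambiguous", guide = NA_character_)
      else list(status = "unassigned", guide = NA_character_)
    })
    names(res) <- uniq
    status[todo] <- vapply(res[spacers[todo]], `[[`, "", "status")
    guide[todo] <- vapply(res[spacers[todo]], `[[`, "", "guide")
  }
  tibble(spacer = spacers, guide_id = guide, status = status)
}

read_fastq_sequences <- function(path) {
  # light structural validation so malformed records are reported by index
  lines <- readLines(path)
  if (length(lines) %% 4 != 0)
    abort(paste0("malformed FASTQ ", path, ": truncated record ",
                 floor(length(lines) / 4) + 1),
          class = "dualscreen_data_error")
  if (length(lines) == 0) return(character(0))
  heads <- lines[seq(1, length(lines), by = 4)]
  seps <- lines[seq(3, length(lines), by = 4)]
  bad <- which(!startsWith(heads, "@") | !startsWith(seps, "+"))
  if (length(bad))
    abort(paste0("malformed FASTQ ", path, ": record ", bad[1]),
          class = "dualscreen_data_error")
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Count sgRNA barcodes from amplicon FASTQ files
#'
#' Runs [extract_spacer()] and [assign_spacer()] over every read of every
#' sample and tabulates assigned reads per guide. Ambiguous and unassigned
#' reads are excluded from the count matrix but accounted for in the
#' mapping statistics, whose categories partition the anchor-found reads
#' exactly.
#'
#' @param sample_sheet Data frame with columns `file` (FASTQ path) and
#'   `sample_id`, plus any metadata columns to carry through (typically
#'   `experiment`, `lineage`, `gfp_gate`, `replicate`).
#' @param lib The library.
#' @param layout A [read_layout()].
#' @param max_mismatch Hamming rescue distance for [assign_spacer()].
#' @return List with `counts` (a `count_matrix` tibble: sample metadata +
#'   `guide_id`, `gene`, `count`, `total_reads`, canonical guide order)
#'   and `stats` (a `mapping_stats` tibble: `reads_total`, `anchor_found`,
#'   `assigned_exact`, `assigned_mm`, `ambiguous`, `unassigned` per
#'   sample).
#' @export
count_fastq <- function(sample_sheet, lib, layout = read_layout(),
                        max_mismatch = 1L) {
  sheet <- as_tibble(sample_sheet)
  stopifnot(all(c("file", "sample_id") %in% names(sheet)))
  lib_tb <- as_tibble(lib)
  meta_cols <- setdiff(names(sheet), "file")

  per_sample <- map(seq_len(nrow(sheet)), function(i) {
    reads <- read_fastq_sequences(sheet$file[i])
    sp <- extract_spacer(reads, layout)
    asg <- assign_spacer(sp, lib_tb, max_mismatch = max_mismatch)
    counts <- setNames(rep(0L, nrow(lib_tb)), lib_tb$guide_id)
    tab <- table(asg$guide_id[!is.na(asg$guide_id)])
    counts[names(tab)] <- as.integer(tab)
    stats <- tibble(
      reads_total = length(reads),
      anchor_found = sum(!is.na(sp)),
      assigned_exact = sum(asg$status == "assigned_exact", na.rm = TRUE),
      assigned_mm = sum(asg$status == "assigned_mm", na.rm = TRUE),
      ambiguous = sum(asg$status == "ambiguous", na.rm = TRUE),
      unassigned = sum(asg$status == "unassigned", na.rm = TRUE)
    )
    list(counts = counts, stats = stats)
  })

  counts <- map_dfr(seq_len(nrow(sheet)), function(i)
    bind_cols(sheet[rep(i, nrow(lib_tb)), meta_cols],
              tibble(guide_id = lib_tb$guide_id, gene = lib_tb$gene,
                     count = unname(per_sample[[i]]$counts),
                     total_reads = per_sample[[i]]$stats$reads_total)))
  stats <- map_dfr(seq_len(nrow(sheet)), function(i)
    bind_cols(sheet[i, meta_cols], per_sample[[i]]$stats))
  list(
    counts = structure(counts, class = c("count_matrix", class(counts))),
    stats = structure(stats, class = c("mapping_stats", class(stats)))
  )
}

#' Normalize a count matrix to counts per million
#'
#' Per sample, each guide's reads (plus a pseudocount) are divided by the
#' sample's pseudocounted total and scaled to one million, so every
#' sample's CPM column sums to 1e6 regardless of sequencing depth. The
#' pseudocount keeps downstream log ratios finite for dropout guides.
#'
#' @param cm A `count_matrix` tibble (long format with `sample_id`,
#'   `guide_id`, `count`).
#' @param pseudocount Added to every count before normalization
#'   (default 0.5).
#' @return The input with an added `cpm` column.
#' @export
normalize_cpm <- function(cm, pseudocount = 0.5) {
  cm <- as_tibble(cm)
  stopifnot(all(c("sample_id", "guide_id", "count") %in% names(cm)))
  bad <- cm |>
    group_by(.data$sample_id) |>
    summarise(tot = sum(.data$count + pseudocount), .groups = "drop") |>
    filter(.data$tot <= 0)
  if (nrow(bad))
    abort(paste0("sample(s) with zero total counts: ",
                 paste(bad$sample_id, collapse = ", "),
                 " - inspect mapping statistics / screen QC"),
          class = "dualscreen_data_error")
  out <- cm |>
    group_by(.data$sample_id) |>
    mutate(cpm = (.data$count + pseudocount) /
             sum(.data$count + pseudocount) * 1e6) |>
    ungroup()
  structure(out, class = c("count_matrix", class(out)))
}

#' Read and write count matrix TSV files
#'
#' Plain TSV in long format, with provenance header lines prefixed `#`
#' (written by the pipeline stages) skipped on read.
#'
#' @param cm A `count_matrix` tibble.
#' @param path File path.
#' @param header Optional character vector of provenance lines (written
#'   prefixed with `"# "`).
#' @return `write_count_tsv()` returns `path` invisibly;
#'   `read_count_tsv()` a `count_matrix` tibble.
#' @export
write_count_tsv <- function(cm, path, header = NULL) {
  body <- strsplit(readr::format_tsv(as_tibble(cm)), "\n",
                   fixed = TRUE)[[1]]
  head <- if (is.null(header)) character(0) else paste0("# ", header)
  writeLines(c(head, body), path)
  invisible(path)
}

#' @rdname write_count_tsv
#' @export
read_count_tsv <- function(path) {
  out <- readr::read_tsv(path, comment = "#", progress = FALSE,
                         show_col_types = FALSE)
  structure(as_tibble(out), class = c("count_matrix", class(out)))
}
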