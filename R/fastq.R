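#' Amplicon read layout
#'
#' Describes where the 20-nt spacer sits inside a sequencing read: a fixed
#' 5' anchor (the vector sequence immediately upstream of the spacer, e.g.
#' the U6 promoter tail), the spacer slot, and a fixed 3' anchor (the start
#' of the sgRNA scaffold). The defaults are the standard lentiviral
#' U6-sgRNA cassette sequences; real amplicon designs set their own.
#'
#' @param anchor5,anchor3 DNA strings flanking the spacer.
#' @param spacer_len Spacer length (fixed at 20).
#' @param read_length Total read length; reads are padded/truncated to it.
#' @param max_anchor_mismatch Substitutions tolerated when locating
#'   `anchor5`.
#' @param anchor_search_window Offsets (0-based) at which the anchor may
#'   start.
#' @return A `read_layout` list.
#' @export
read_layout <- function(anchor5 = "TTGTGGAAAGGACGAAACACCG",
                        anchor3 = "GTTTTAGAGCTAGAAATAGCAAG",
                        spacer_len = 20L,
                        read_length = 75L,
                        max_anchor_mismatch = 1L,
                        anchor_search_window = 0:3) {
  stopifnot(nzchar(anchor5), nzchar(anchor3), spacer_len == 20L)
  if (read_length < nchar(anchor5) + spacer_len)
    abort("read_length shorter than anchor5 + spacer",
          class = "dualscreen_layout_error")
  structure(list(anchor5 = anchor5, anchor3 = anchor3,
                 spacer_len = as.integer(spacer_len),
                 read_length = as.integer(read_length),
                 max_anchor_mismatch = as.integer(max_anchor_mismatch),
                 anchor_search_window = as.integer(anchor_search_window)),
            class = "read_layout")
}

#' Write simulated amplicon reads to FASTQ
#'
#' Emits one FASTQ record per read: `anchor5 + spacer + anchor3`, padded
#' with the constant downstream sequence base `A` to the layout read
#' length, with independent per-base substitution errors at `error_rate`
#' and constant Phred quality 37. Together with [count_fastq()] this gives
#' a lossless round trip at zero error rate, the end-to-end check of the
#' counting stage.
#'
#' @param count_row Tibble with columns `guide_id` and `count` (reads to
#'   emit per guide).
#' @param lib The library supplying each guide's spacer.
#' @param layout A [read_layout()].
#' @param path Output FASTQ path (plain text, 4-line records, Phred+33).
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(count_row, lib, layout, path, error_rate = 0,
                        seed = 1L) {
  stopifnot(inherits(layout, "read_layout"),
            error_rate >= 0, error_rate < 1)
  lib_tb <- as_tibble(lib)
  row <- as_tibble(count_row)
  spacers <- lib_tb$spacer[match(row$guide_id, lib_tb$guide_id)]
  if (anyNA(spacers)) abort("count_row contains guides not in the library")

  reads <- rep(paste0(layout$anchor5, spacers, layout$anchor3),
               times = row$count)
  names <- sprintf("read%06d:%s", seq_along(reads),
                   rep(row$guide_id, times = row$count))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(reads) == 0) return(invisible(path))

  L <- layout$read_length
  reads <- substr(paste0(reads, strrep("A", L)), 1, L)
  if (error_rate > 0) {
    reads <- with_stage_seed(seed, "fastq_errors", {
      mat <- matrix(unlist(strsplit(reads, "")), nrow = length(reads),
                    byrow = TRUE)
      hit <- matrix(runif(length(mat)) < error_rate, nrow = nrow(mat))
      if (any(hit)) {
        # substitute with one of the three other bases, uniformly
        alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
        pick <- ceiling(runif(sum(hit)) * 3)
        mat[hit] <- substr(alt[mat[hit]], pick, pick)
      }
      apply(mat, 1, paste, collapse = "")
    })
  }
  qual <- strrep("F", L) # Phred 37
  writeLines(paste0("@", names, "\n", reads, "\n+\n", qual), con)
  invisible(path)
}
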