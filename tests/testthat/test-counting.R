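lib6 <- function() tiny_library(n_genes = 2, seed = 53)

test_that("spacer extraction honors anchors, mismatches and length guards", {
  layout <- read_layout()
  lib <- lib6()
  sp <- lib$spacer[1]
  exact <- paste0(layout$anchor5, sp, layout$anchor3)
  expect_equal(extract_spacer(exact, layout), sp)

  # one substitution inside the anchor is tolerated
  mm <- exact
  substr(mm, 3, 3) <- if (substr(mm, 3, 3) == "A") "C" else "A"
  expect_equal(extract_spacer(mm, layout), sp)

  # a shifted anchor within the search window still resolves
  shifted <- paste0("GG", exact)
  expect_equal(extract_spacer(shifted, layout), sp)

  # too short to hold anchor + spacer
  expect_true(is.na(extract_spacer(substr(exact, 1, 30), layout)))
  # anchor absent
  expect_true(is.na(extract_spacer(strrep("T", 75), layout)))
})

test_that("spacer assignment is exact-first with single-mismatch rescue and tie rejection", {
  lib <- lib6()
  res <- assign_spacer(lib$spacer[2], lib)
  expect_equal(res$guide_id, lib$guide_id[2])
  expect_equal(res$status, "assigned_exact")

  # Hamming-1 neighbour of exactly one spacer: brute-force scan confirms
  # uniqueness, then rescue must find it
  mut <- lib$spacer[2]
  substr(mut, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mut, 10, 10))[1]
  d <- vapply(lib$spacer, function(s)
    sum(charToRaw(s) != charToRaw(mut)), integer(1))
  expect_equal(sum(d <= 1), 1L)
  res <- assign_spacer(mut, lib)
  expect_equal(res$guide_id, lib$guide_id[2])
  expect_equal(res$status, "assigned_mm")

  # equidistant between two library spacers -> ambiguous
  amb_lib <- tibble::as_tibble(lib)
  amb_lib$spacer[1] <- lib$spacer[2]
  substr(amb_lib$spacer[1], 1, 1) <- setdiff(c("A", "C", "G", "T"),
                                             substr(lib$spacer[2], 1,
                                                    1))[1]
  probe <- lib$spacer[2]
  substr(probe, 1, 1) <- setdiff(c("A", "C", "G", "T"),
                                 c(substr(lib$spacer[2], 1, 1),
                                   substr(amb_lib$spacer[1], 1, 1)))[1]
  res <- assign_spacer(probe, amb_lib)
  expect_equal(res$status, "ambiguous")

  # far from everything -> unassigned
  res <- assign_spacer(strrep("A", 20), lib)
  expect_equal(res$status, "unassigned")
})

test_that("counting round-trips simulator FASTQ exactly at zero error rate", {
  lib <- lib6()
  layout <- read_layout()
  for (seed in 1:3) {
    set.seed(seed)
    truth <- tibble::tibble(guide_id = lib$guide_id,
                            count = rpois(nrow(lib), 200))
    path <- withr::local_tempfile(fileext = ".fastq")
    write_fastq(truth, lib, layout, path, error_rate = 0, seed = seed)
    sheet <- tibble::tibble(file = path, sample_id = "s1")
    res <- count_fastq(sheet, lib, layout)
    expect_identical(
      res$counts$count[match(truth$guide_id, res$counts$guide_id)],
      as.integer(truth$count))
    expect_equal(res$stats$assigned_exact, sum(truth$count))
  }
})

test_that("mapping statistics partition anchor-found reads and match the error model", {
  lib <- lib6()
  layout <- read_layout()
  n <- 4000
  truth <- tibble::tibble(guide_id = lib$guide_id[1], count = n)
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(truth, lib, layout, path, error_rate = 0.01, seed = 8)
  res <- count_fastq(tibble::tibble(file = path, sample_id = "s1"),
                     lib, layout)
  st <- res$stats
  expect_equal(st$assigned_exact + st$assigned_mm + st$ambiguous +
                 st$unassigned, st$anchor_found)
  expect_lte(st$anchor_found, st$reads_total)

  # assignable fraction ~ P(anchor within 1 mm) * P(spacer within 1 mm)
  p1 <- function(L) 0.99^L + L * 0.01 * 0.99^(L - 1)
  expected <- p1(nchar(layout$anchor5)) * p1(20)
  got <- (st$assigned_exact + st$assigned_mm) / st$reads_total
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(got - expected), 4 * se)
})

test_that("empty and malformed FASTQ inputs are handled explicitly", {
  lib <- lib6()
  path <- withr::local_tempfile(fileext = ".fastq")
  writeLines(character(0), path)
  res <- count_fastq(tibble::tibble(file = path, sample_id = "s1"),
                     lib, read_layout())
  expect_true(all(res$counts$count == 0))
  expect_equal(res$stats$reads_total, 0L)

  writeLines(c("@r1", "ACGT", "+"), path) # truncated record
  err <- expect_error(
    count_fastq(tibble::tibble(file = path, sample_id = "s1"),
                lib, read_layout()),
    class = "dualscreen_data_error")
  expect_match(conditionMessage(err), basename(path), fixed = TRUE)

  writeLines(c("r1", "ACGT", "+", "FFFF"), path) # header lacks @
  err <- expect_error(
    count_fastq(tibble::tibble(file = path, sample_id = "s1"),
                lib, read_layout()),
    class = "dualscreen_data_error")
  expect_match(conditionMessage(err), "record 1")
})

test_that("CPM normalization matches hand arithmetic and sums to a million", {
  cm <- count_fixture(c(10, 30, 60), c(1, 1, 1))
  out <- normalize_cpm(cm, pseudocount = 0)
  pos <- dplyr::filter(out, gfp_gate == "pos")
  expect_equal(pos$cpm, c(1e5, 3e5, 6e5))

  # symmetric pseudocount on an all-zero pair of guides
  cm2 <- count_fixture(c(0, 0), c(5, 5))
  out2 <- normalize_cpm(cm2, pseudocount = 0.5)
  expect_equal(dplyr::filter(out2, gfp_gate == "pos")$cpm, c(5e5, 5e5))

  # rows always sum to 1e6
  set.seed(1)
  cm3 <- count_fixture(rpois(20, 100), rpois(20, 100))
  sums <- normalize_cpm(cm3) |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(s = sum(cpm))
  expect_equal(sums$s, rep(1e6, 2))

  # an all-zero sample without pseudocount is a QC error
  expect_error(normalize_cpm(count_fixture(c(0, 0), c(5, 5)),
                             pseudocount = 0),
               class = "dualscreen_data_error")
})

test_that("count matrix TSV round trip preserves counts and skips provenance", {
  cm <- count_fixture(c(3, 9), c(4, 4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_tsv(cm, path, header = c("tool x", "seed 1"))
  expect_true(startsWith(readLines(path, n = 1), "#"))
  back <- read_count_tsv(path)
  expect_equal(back$count, cm$count)
  expect_equal(back$sample_id, cm$sample_id)
})
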