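test_that("input library frequencies behave like a symmetric Dirichlet", {
  lib <- example_invivo_library()

  # near-infinite concentration collapses to the uniform 1/45
  f <- simulate_input_frequencies(lib, concentration = 1e6, seed = 1)
  expect_equal(sum(f$frequency), 1)
  expect_true(all(abs(f$frequency - 1 / 45) < 0.002))

  # single-guide library is forced to frequency 1
  solo <- assemble_library(
    tibble::tibble(gene = "G", role = "negative_control",
                   spacer = synthetic_spacers(3, seed = 2)),
    guides_per_gene = 3)[1, ]
  expect_equal(simulate_input_frequencies(solo, seed = 1)$frequency, 1)

  # at the default concentration the marginal Beta(150, 6600) keeps every
  # guide below 9% in each of 20 seeded draws
  maxes <- vapply(1:20, function(s)
    max(simulate_input_frequencies(lib, concentration = 150,
                                   seed = s)$frequency), numeric(1))
  expect_true(all(maxes <= 0.09))

  expect_error(simulate_input_frequencies(lib[0, ], seed = 1), "empty")
})

test_that("well simulation matches the closed-form expected GFP+ fraction", {
  lib <- tiny_library()
  design <- screen_design_invitro()
  fm <- fitness_model(tibble::tibble(gene = "Gene1", lineage = "*",
                                     fitness = 0.5), editing = 0.9)
  # expectation: edited grow (2w)^5 = 1, unedited 2^5 = 32, so the GFP+
  # fraction within mCherry+ is (0.9 + 0.1*32) / (0.9 + 0.1*32 + 32)
  expected <- 4.1 / 36.1
  fracs <- vapply(1:1000, function(s) {
    fc <- simulate_well(lib, design, fm, "sgGene1-1",
                        timepoints = "day7", seed = s)
    w <- tidyr::pivot_wider(fc, names_from = c("mcherry", "gfp"),
                            values_from = "events")
    w$pos_pos / (w$pos_pos + w$pos_neg)
  }, numeric(1))
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - expected), 3 * se + 1e-4)
})

test_that("a neutral guide leaves the GFP+ fraction at the mix ratio in both gates", {
  lib <- tiny_library()
  design <- screen_design_invitro()
  fm <- fitness_model()
  fr <- purrr::map_dfr(1:50, function(s) {
    fc <- simulate_well(lib, design, fm, "sgNeg1-1",
                        timepoints = "day7", seed = s)
    w <- tidyr::pivot_wider(fc, names_from = c("mcherry", "gfp"),
                            values_from = "events")
    tibble::tibble(in_mpos = w$pos_pos / (w$pos_pos + w$pos_neg),
                   in_mneg = w$neg_pos / (w$neg_pos + w$neg_neg))
  })
  expect_lt(abs(mean(fr$in_mpos) - 0.5), 0.01)
  expect_lt(abs(mean(fr$in_mneg) - 0.5), 0.01)
})

test_that("lethal editing empties the edited compartment", {
  lib <- tiny_library()
  design <- screen_design_invitro()
  fm <- fitness_model(tibble::tibble(gene = "Gene1", lineage = "*",
                                     fitness = 0), editing = 1)
  fc <- simulate_well(lib, design, fm, "sgGene1-1",
                      timepoints = "day7", seed = 1)
  w <- tidyr::pivot_wider(fc, names_from = c("mcherry", "gfp"),
                          values_from = "events")
  # all transduced Cas9+ cells edited and extinct
  expect_lt(w$pos_pos / (w$pos_pos + w$pos_neg), 0.005)
  expect_error(
    simulate_well(lib, design,
                  fitness_model(tibble::tibble(gene = "Gene1",
                                               lineage = "*",
                                               fitness = -1)),
                  "sgGene1-1", seed = 1),
    class = "dualscreen_parameter_error")
})

test_that("simulation output is bit-identical under the same seed", {
  lib <- tiny_library()
  design <- screen_design_invitro()
  fm <- fitness_model()
  a <- simulate_invitro_screen(lib, design, fm, replicates = 2, seed = 9)
  b <- simulate_invitro_screen(lib, design, fm, replicates = 2, seed = 9)
  expect_identical(a, b)
  c <- simulate_invitro_screen(lib, design, fm, replicates = 2, seed = 10)
  expect_false(identical(a$events, c$events))
  expect_identical(dim(a), dim(c))

  # small design so the 12-well tiny library can fill three grafts
  dsmall <- screen_design_invivo(graft_size = 5e3)
  s1 <- simulate_invivo_screen(lib, dsmall, fm, seed = 4)
  s2 <- simulate_invivo_screen(lib, dsmall, fm, seed = 4)
  expect_identical(s1$sorted, s2$sorted)
})

test_that("every transplantation partition conserves cells", {
  lib <- example_invivo_library()
  design <- screen_design_invivo()
  fm <- fitness_model()
  scr <- simulate_invivo_screen(lib, design, fm, n_mice = 3, seed = 11)

  # graft drawn without replacement: per category never exceeds the pool
  pool_m <- dplyr::filter(scr$pool, mcherry == "pos")
  expect_true(all(scr$graft$cells <= pool_m$cells))
  expect_equal(sum(scr$graft$cells), 3 * design$graft_size)
  split <- tapply(scr$graft$cells, scr$graft$cas9, sum)
  expect_equal(as.vector(split[c("pos", "neg")]),
               as.vector(3 * design$graft_split[c("cas9_pos",
                                                  "cas9_neg")]))

  # sorting draws at most the design depth, from available cells only
  per_gate <- scr$sorted |>
    dplyr::group_by(lineage, gfp_gate) |>
    dplyr::summarise(n = sum(cells), .groups = "drop")
  expect_true(all(per_gate$n == design$lineages$sort_depth[1]))
  joined <- dplyr::inner_join(
    scr$sorted,
    dplyr::rename(scr$lineage_state, avail = cells),
    by = c("lineage", "guide_id", "gene", "edited",
           "gfp_gate" = "cas9"))
  expect_true(all(joined$cells <= joined$avail))
})

test_that("drawing the whole urn returns the urn", {
  counts <- c(10L, 0L, 25L, 3L)
  expect_identical(dualscreen:::rmvhyper(counts, sum(counts)), counts)
  expect_error(dualscreen:::rmvhyper(counts, sum(counts) + 1), "pool")
})

test_that("a gene lethal only in T cells vanishes from sorted GFP+ T cells alone", {
  lib <- example_invivo_library()
  design <- screen_design_invivo()
  fm <- fitness_model(tibble::tibble(gene = "Cd3e", lineage = "T",
                                     fitness = 0), editing = 1)
  scr <- simulate_invivo_screen(lib, design, fm, seed = 21)
  cd3e <- scr$sorted |> dplyr::filter(gene == "Cd3e") |>
    dplyr::group_by(lineage, gfp_gate) |>
    dplyr::summarise(cells = sum(cells), .groups = "drop")
  get <- function(l, g)
    cd3e$cells[cd3e$lineage == l & cd3e$gfp_gate == g]
  expect_equal(get("T", "pos"), 0)
  expect_gt(get("T", "neg"), 0)
  expect_gt(get("B", "pos"), 0)
})

test_that("graft larger than the pool is rejected", {
  lib <- tiny_library()
  design <- screen_design_invivo(graft_size = 1e7)
  expect_error(simulate_invivo_screen(lib, design, fitness_model(),
                                      seed = 1),
               "graft")
})
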