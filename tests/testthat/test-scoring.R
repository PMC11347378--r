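test_that("survival/proliferation score matches hand arithmetic", {
  # equal GFP+ fractions in both gates -> 0
  expect_equal(surpro_score(flow_fixture(300, 300, 700, 700))$score, 0)

  # without pseudocount: log2((100/1000) / (500/1000))
  s <- surpro_score(flow_fixture(100, 900, 500, 500), pseudocount = 0)
  expect_equal(s$score, log2(0.1 / 0.5), tolerance = 1e-12)
  expect_equal(s$score, -2.321928, tolerance = 1e-6)

  # an empty GFP+ gate stays finite through the pseudocount:
  # log2((0.5/1001) / (500.5/1001)) = -log2(1001)
  s <- surpro_score(flow_fixture(0, 1000, 500, 500), pseudocount = 0.5)
  expect_equal(s$score, log2(0.5 / 500.5), tolerance = 1e-12)
  expect_equal(s$score, -9.967226, tolerance = 1e-6)

  # a fully empty mCherry gate is a data error (FACS depth)
  expect_error(surpro_score(flow_fixture(10, 10, 0, 0)),
               class = "dualscreen_data_error")
})

test_that("the fraction-ratio score is invariant to transduction efficiency", {
  # same GFP composition inside each gate, transduction from 20% to 60%
  scores <- vapply(seq(0.2, 0.6, by = 0.1), function(tau) {
    n <- 1e4
    surpro_score(flow_fixture(round(n * tau * 0.3),
                              round(n * tau * 0.7),
                              round(n * (1 - tau) * 0.5),
                              round(n * (1 - tau) * 0.5)),
                 pseudocount = 0)$score
  }, numeric(1))
  expect_equal(scores, rep(scores[1], length(scores)), tolerance = 1e-12)

  # the literal raw-count ratio is *not* invariant (why it is non-default)
  raw <- vapply(c(0.2, 0.6), function(tau) {
    n <- 1e4
    surpro_score(flow_fixture(round(n * tau * 0.5),
                              round(n * tau * 0.5),
                              round(n * (1 - tau) * 0.5),
                              round(n * (1 - tau) * 0.5)),
                 mode = "raw", pseudocount = 0)$score
  }, numeric(1))
  expect_gt(abs(raw[2] - raw[1]), 1)
})

test_that("scores are antisymmetric under swapping the GFP roles", {
  # mirrored gate compositions (f+ = 1 - f-): the GFP swap maps the
  # fraction ratio onto its reciprocal exactly
  fc <- flow_fixture(300, 700, 700, 300)
  swapped <- dplyr::mutate(fc, gfp = ifelse(gfp == "pos", "neg", "pos"))
  expect_equal(surpro_score(swapped)$score, -surpro_score(fc)$score,
               tolerance = 1e-12)
  # and the sign always flips
  fc2 <- flow_fixture(321, 679, 512, 488)
  sw2 <- dplyr::mutate(fc2, gfp = ifelse(gfp == "pos", "neg", "pos"))
  expect_lt(surpro_score(fc2)$score, 0)
  expect_gt(surpro_score(sw2)$score, 0)

  set.seed(5)
  cm <- normalize_cpm(count_fixture(rpois(10, 200), rpois(10, 200)))
  sw <- dplyr::mutate(cm, gfp_gate = ifelse(gfp_gate == "pos", "neg",
                                            "pos"))
  expect_equal(abundance_score(sw)$score, -abundance_score(cm)$score,
               tolerance = 1e-12)
})

test_that("day-2 anchoring subtracts each guide's early score", {
  fc <- dplyr::bind_rows(
    flow_fixture(450, 550, 500, 500, timepoint = "day2"),
    flow_fixture(100, 900, 500, 500, timepoint = "day7"))
  plain <- surpro_score(fc, pseudocount = 0)
  anchored <- surpro_score(fc, pseudocount = 0,
                           anchor_timepoint = "day2")
  expect_equal(anchored$score,
               plain$score[plain$context == "day7"] -
                 plain$score[plain$context == "day2"],
               tolerance = 1e-12)
  expect_false("day2" %in% anchored$context)
})

test_that("abundance score is the log2 CPM ratio with exact pseudocount arithmetic", {
  cm <- count_fixture(c(200, 500), c(800, 500)) |>
    dplyr::mutate(cpm = count) # values already on a common scale
  st <- abundance_score(cm)
  expect_equal(st$score[1], -2)

  # identical fractions -> all zeros
  cm0 <- normalize_cpm(count_fixture(c(5, 10), c(5, 10)))
  expect_equal(abundance_score(cm0)$score, c(0, 0))

  # dropout guide: plug-in CPM formula oracle at alpha = 0.5
  pos_counts <- c(0, rep(22727, 44))
  neg_counts <- c(1000, rep(22704, 44))
  cm1 <- normalize_cpm(count_fixture(pos_counts, neg_counts),
                       pseudocount = 0.5)
  expected <- log2(((0 + 0.5) / sum(pos_counts + 0.5)) /
                     ((1000 + 0.5) / sum(neg_counts + 0.5)))
  expect_equal(abundance_score(cm1)$score[1], expected,
               tolerance = 1e-12)
  expect_true(is.finite(expected) && expected < -5)

  # mismatched gates are rejected
  broken <- normalize_cpm(count_fixture(c(1, 2), c(3, 4)))
  broken <- broken[-1, ]
  expect_error(abundance_score(broken),
               class = "dualscreen_data_error")
})

test_that("gene aggregation averages guides with a median option", {
  st <- tibble::tibble(
    guide_id = paste0("sg", 1:3), gene = "G", context = "day7",
    replicate = 1L, score = c(-2, -1.5, -1))
  expect_equal(gene_score(st)$score, -1.5)
  st$score <- c(-3, -1, 0)
  expect_equal(gene_score(st, method = "median")$score, -1)
  solo <- st[1, ]
  expect_equal(gene_score(solo)$score, -3)
})

test_that("hit calling follows the replicate rule and is monotone in the threshold", {
  gs <- tibble::tibble(gene = rep(c("A", "B"), each = 2),
                       context = "day7", replicate = rep(1:2, 2),
                       score = c(-2.1, -1.8, -1.2, -0.4))
  hits <- call_hits(gs, threshold = -1)
  expect_true(hits$hit[hits$gene == "A"])
  expect_false(hits$hit[hits$gene == "B"])

  # replicate-mean mode can rescue B? mean(-1.2, -0.4) = -0.8 -> still no
  hits_mean <- call_hits(gs, threshold = -1,
                         require_all_replicates = FALSE)
  expect_false(hits_mean$hit[hits_mean$gene == "B"])

  # lowering the threshold never adds hits
  set.seed(2)
  gs2 <- tibble::tibble(gene = paste0("g", 1:50), context = "x",
                        replicate = 1L, score = rnorm(50, -1, 1))
  prev <- rep(TRUE, 50)
  for (thr in c(-0.5, -1, -1.5, -2, -3)) {
    cur <- call_hits(gs2, threshold = thr)$hit
    expect_true(all(!cur | prev)) # cur subset of prev
    prev <- cur
  }
})

test_that("replicate correlation matches the covariance-formula oracle", {
  st <- tibble::tibble(
    guide_id = rep(paste0("sg", 1:20), 2),
    gene = rep(paste0("g", 1:20), 2),
    context = "day7",
    replicate = rep(1:2, each = 20),
    score = c(rnorm(20, 0, 0.2), rnorm(20, 0, 0.2)))
  st$score[c(1, 21)] <- c(-3, -2.9) # one strongly depleted guide

  rc <- replicate_correlation(st)
  a <- st$score[1:20]; b <- st$score[21:40]
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(rc$r, oracle, tolerance = 1e-12)
  expect_equal(rc$n, 20L)

  ident <- dplyr::mutate(st, score = rep(a, 2))
  expect_equal(replicate_correlation(ident)$r, 1)
  negated <- dplyr::mutate(st, score = c(a, -a))
  expect_equal(replicate_correlation(negated)$r, -1)

  expect_error(replicate_correlation(st[c(1, 2, 21, 22), ]),
               class = "dualscreen_data_error")
})

test_that("neutral screens score near zero with a sub-1% false hit rate", {
  lib <- tiny_library(n_genes = 3)
  design <- screen_design_invitro()
  fm <- fitness_model()
  genes <- purrr::map_dfr(1:200, function(s) {
    fc <- simulate_well(lib, design, fm, "sgGene1-1",
                        timepoints = "day7", seed = 1000 + s)
    surpro_score(fc)
  })
  se <- sd(genes$score) / sqrt(nrow(genes))
  expect_lt(abs(mean(genes$score)), 3 * se + 0.01)
  expect_lt(mean(genes$score < -1), 0.01)
})

test_that("scores decrease monotonically with fitness", {
  lib <- tiny_library()
  design <- screen_design_invitro()
  means <- vapply(c(1, 0.8, 0.6, 0.4, 0.2, 0), function(w) {
    fm <- fitness_model(tibble::tibble(gene = "Gene1", lineage = "*",
                                       fitness = w))
    mean(vapply(1:40, function(s)
      surpro_score(simulate_well(lib, design, fm, "sgGene1-1",
                                 timepoints = "day7",
                                 seed = s))$score, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0.05))
  # at w = 0 only the ~10% unedited escapers remain in the GFP+ gate:
  # expected score log2((3.2/35.2)/0.5) ~ -2.46
  expect_lt(means[length(means)], means[1] - 2)
})
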