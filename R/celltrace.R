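#' Simulate a division-tracking dye assay
#'
#' Models the cell-trace dye-dilution experiment: labeled Cas9+ cells are
#' transduced with one guide (mCherry+) or remain untransduced (mCherry-),
#' and the number of completed divisions per cell is read off the dye
#' intensity at days 2 or 4. Unimpaired cells divide on a fixed schedule
#' (one division per `division_interval` days, so they reach division 5 by
#' day 4 at the default) with a small integer jitter between founders.
#' Edited cells follow a progressive-arrest model: the g-th division
#' succeeds with probability `w^(g-1)`, so neutral genes (`w = 1`) divide
#' like controls while a gene with `w = 0.5` leaves most cells arrested at
#' divisions 1-2. Histograms report the fate of the labeled founder
#' cohort: each founder contributes one count at the division number its
#' lineage reached, truncated at division 8 (dye resolution limit).
#' Counting founders rather than descendants avoids the `2^d` weighting
#' under which the few unedited escaper lineages would dominate the
#' transduced channel.
#'
#' @param fitness A [fitness_model()].
#' @param gene Targeted gene (looked up in context `"*"`).
#' @param days Assay day (0, 2 or 4 supported).
#' @param n_founders Labeled founder cells per channel.
#' @param division_interval Days per division for unimpaired cells
#'   (default 0.8).
#' @param transduction_rate Probability a founder is transduced
#'   (mCherry+).
#' @param seed Integer seed.
#' @return A `celltrace` tibble: `channel` (`"mcherry_pos"` /
#'   `"mcherry_neg"`), `division` (0-8), `cells`, `frequency` (within
#'   channel).
#' @export
simulate_celltrace <- function(fitness, gene, days, n_founders = 2000,
                               division_interval = 0.8,
                               transduction_rate = 0.5, seed = 1L) {
  stopifnot(days >= 0, n_founders >= 1, division_interval > 0)
  w <- fitness_of(fitness, gene, "*")
  e <- editing_of(fitness, gene)

  draw_channel <- function(n, edited_prob) {
    # founder-specific attempted divisions: schedule plus integer jitter
    jitter <- if (days > 0) rnorm(n, 0, 0.4) else numeric(n)
    M <- pmin(8L, pmax(0L, round(days / division_interval + jitter)))
    edited <- runif(n) < edited_prob
    d <- M
    if (any(edited) && w < 1) {
      d[edited] <- vapply(M[edited], function(m) {
        g <- 0L
        while (g < m && runif(1) < w^g) g <- g + 1L
        g
      }, integer(1))
    }
    tibble(division = 0:8,
           cells = vapply(0:8, function(k) sum(d == k), numeric(1)))
  }
  n_pos <- round(n_founders * transduction_rate)
  # the untransduced channel is seeded independently of the targeted gene:
  # it contains no guide, so its divisions cannot depend on the knockout
  pos <- with_stage_seed(seed, paste0("celltrace/", gene, "/day", days),
                         draw_channel(n_pos, edited_prob = e)) |>
    mutate(channel = "mcherry_pos")
  neg <- with_stage_seed(seed, paste0("celltrace_control/day", days),
                         draw_channel(n_founders - n_pos,
                                      edited_prob = 0)) |>
    mutate(channel = "mcherry_neg")
  out <- bind_rows(pos, neg) |>
    group_by(.data$channel) |>
    mutate(frequency = .data$cells / sum(.data$cells)) |>
    ungroup() |>
    select("channel", "division", "cells", "frequency")
  structure(out, class = c("celltrace", class(out)))
}
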