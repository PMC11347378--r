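#' Simulate the per-guide composition of the input library
#'
#' Draws the relative representation of each guide in the pooled input from
#' a symmetric Dirichlet distribution. The concentration parameter controls
#' evenness: large values approach the uniform 1/n distribution, small
#' values produce jackpot guides. The default (150 per guide) reproduces a
#' "relatively equal" input in which every guide lands near 1/45 with the
#' few-percent spread seen in practice.
#'
#' @param lib An sgRNA library.
#' @param concentration Per-guide Dirichlet concentration (> 0).
#' @param seed Integer seed.
#' @return Tibble with columns `guide_id`, `gene`, `frequency`
#'   (summing to 1).
#' @export
simulate_input_frequencies <- function(lib, concentration = 150, seed = 1L) {
  lib <- as_tibble(lib)
  if (nrow(lib) == 0) abort("library is empty")
  stopifnot(concentration > 0)
  g <- with_stage_seed(seed, "input_frequencies",
                       rgamma(nrow(lib), shape = concentration, rate = 1))
  if (all(g == 0)) g <- rep(1, length(g)) # numerically degenerate draw
  tibble(guide_id = lib$guide_id, gene = lib$gene, frequency = g / sum(g))
}

# initial composition of one well immediately after transduction:
# cells_per_well cells split over mCherry x GFP gates (transduction and Cas9
# status independent), transduced Cas9+ cells further split edited/unedited
# with the gene's editing efficiency. Returns integer counts.
well_initial_state <- function(design, e_gene, tau = NULL) {
  p9 <- design$mix_ratio / (1 + design$mix_ratio)
  tau <- tau %||% design$transduction_rate
  probs <- c(
    mpos_gpos = tau * p9,
    mpos_gneg = tau * (1 - p9),
    mneg_gpos = (1 - tau) * p9,
    mneg_gneg = (1 - tau) * (1 - p9)
  )
  n <- drop(rmultinom(1, design$cells_per_well, probs))
  edited <- rbinom(1, n[["mpos_gpos"]], e_gene)
  c(
    mpos_gpos_edited = edited,
    mpos_gpos_unedited = n[["mpos_gpos"]] - edited,
    mpos_gneg = n[["mpos_gneg"]],
    mneg_gpos = n[["mneg_gpos"]],
    mneg_gneg = n[["mneg_gneg"]]
  )
}

# expected growth factor after D divisions: neutral cells double every
# division, edited cells leave 2w surviving offspring per division.
growth_factor <- function(D, w = 1) (2 * w)^D

#' Simulate one arrayed screen well through its flow-cytometry readouts
#'
#' Models a single 96-well culture: Cas9-GFP and wild-type cells mixed at
#' the design ratio, transduced with one guide (mCherry), the transduced
#' Cas9+ cells edited with probability `e`, then grown. Neutral cells
#' multiply by `2^D` over `D` divisions and edited cells by `(2w)^D`
#' (Poisson noise around the branching-process expectation), after which a
#' fixed number of FACS events is sampled multinomially from the four
#' mCherry-by-GFP gates.
#'
#' @param lib An sgRNA library containing `guide_id`.
#' @param design A [screen_design()].
#' @param fitness A [fitness_model()]; fitness is looked up in context
#'   `context`.
#' @param guide_id Guide transduced into this well.
#' @param timepoints Which readouts of `design$divisions_by_readout` to
#'   report (default all).
#' @param context Fitness context label (default `"*"`, i.e. the global
#'   effect).
#' @param tau Optional per-well transduction rate overriding the design
#'   value (wells vary in practice; the score is built to be invariant to
#'   this).
#' @param seed Integer seed.
#' @return A `flow_counts` tibble in long gate format: columns `guide_id`,
#'   `gene`, `timepoint`, `mcherry` (`"pos"/"neg"`), `gfp` (`"pos"/"neg"`),
#'   `events`. Events per timepoint sum to `design$facs_events`.
#' @export
simulate_well <- function(lib, design, fitness, guide_id,
                          timepoints = NULL, context = "*",
                          tau = NULL, seed = 1L) {
  lib <- as_tibble(lib)
  row <- lib[lib$guide_id == guide_id, ]
  if (nrow(row) != 1) abort(paste0("guide not in library: ", guide_id))
  gene <- row$gene
  w <- fitness_of(fitness, gene, context)
  if (w < 0) abort("fitness w must be >= 0",
                   class = "dualscreen_parameter_error")
  e <- editing_of(fitness, gene)
  timepoints <- timepoints %||% names(design$divisions_by_readout)

  with_stage_seed(seed, paste0("well/", guide_id), {
    n0 <- well_initial_state(design, e, tau = tau)
    out <- map_dfr(timepoints, function(tp) {
      D <- design$divisions_by_readout[[tp]]
      fac <- c(growth_factor(D, w), growth_factor(D), growth_factor(D),
               growth_factor(D), growth_factor(D))
      nt <- rpois(5, n0 * fac)
      gates <- c(
        mpos_gpos = nt[1] + nt[2], # edited + unedited transduced Cas9+
        mpos_gneg = nt[3],
        mneg_gpos = nt[4],
        mneg_gneg = nt[5]
      )
      if (sum(gates) == 0) abort("well went extinct; no cells to analyze")
      ev <- drop(rmultinom(1, design$facs_events, gates / sum(gates)))
      tibble(
        guide_id = guide_id, gene = gene, timepoint = tp,
        mcherry = c("pos", "pos", "neg", "neg"),
        gfp = c("pos", "neg", "pos", "neg"),
        events = ev
      )
    })
    structure(out, class = c("flow_counts", class(out)))
  })
}

#' Simulate a full arrayed in vitro screen (one well per guide)
#'
#' Convenience wrapper running [simulate_well()] for every guide in the
#' library across replicates, with per-well transduction rates drawn
#' uniformly from `tau_range` (wells differ in infection efficiency; the
#' survival/proliferation score is internally controlled against this).
#' A truth fixture of the planted fitness effects can be written alongside.
#'
#' @inheritParams simulate_well
#' @param replicates Number of independent experiments.
#' @param tau_range Range of per-well transduction rates.
#' @param truth_path Optional path for the planted-truth TSV.
#' @return A `flow_counts` tibble with an extra `replicate` column.
#' @export
simulate_invitro_screen <- function(lib, design, fitness, replicates = 2,
                                    tau_range = c(0.2, 0.6), seed = 1L,
                                    truth_path = NULL) {
  lib_tb <- as_tibble(lib)
  out <- map_dfr(seq_len(replicates), function(r) {
    taus <- with_stage_seed(seed, paste0("tau/rep", r),
                            runif(nrow(lib_tb), tau_range[1], tau_range[2]))
    map_dfr(seq_len(nrow(lib_tb)), function(i) {
      simulate_well(lib_tb, design, fitness, lib_tb$guide_id[i],
                    tau = taus[i],
                    seed = child_seed(seed, paste0("rep", r))) |>
        mutate(replicate = r)
    })
  })
  if (!is.null(truth_path)) write_truth_tsv(fitness, lib_tb, truth_path)
  structure(out, class = c("flow_counts", class(out)))
}

# draw k balls without replacement from urn counts (multivariate
# hypergeometric), sequentially category by category.
rmvhyper <- function(counts, k) {
  total <- sum(counts)
  if (k > total) abort("cannot draw more cells than the pool contains")
  out <- integer(length(counts))
  rem_total <- total
  rem_k <- k
  for (i in seq_along(counts)) {
    if (rem_k == 0) break
    if (i == length(counts)) { out[i] <- rem_k; break }
    out[i] <- rhyper(1, counts[i], rem_total - counts[i], rem_k)
    rem_total <- rem_total - counts[i]
    rem_k <- rem_k - out[i]
  }
  out
}

#' Simulate the transplantation screen end to end
#'
#' Runs the pooled in vivo arm stage by stage: (1) one transduced well per
#' guide is simulated and all wells are pooled; (2) each recipient's graft
#' (`design$graft_split`, e.g. 3e4 Cas9+ and 2e4 Cas9- transduced cells) is
#' drawn from the pooled mCherry+ cells *without replacement* (a
#' multivariate hypergeometric bottleneck over guide-by-editing
#' categories); (3) each lineage expands by its design fold with the
#' planted gene-by-lineage fitness applied per division to edited cells
#' (Poisson noise around the branching expectation); recipients are pooled
#' at analysis; (4) each lineage's mCherry+ cells are sorted into GFP+ and
#' GFP- fractions of the design sort depth, again without replacement.
#' Cell counts are conserved at every partition.
#'
#' @inheritParams simulate_well
#' @param n_mice Recipients per experiment (pooled at analysis).
#' @param truth_path Optional path for the planted-truth TSV.
#' @return An `invivo_screen` list with tibbles `pool` (post-transduction
#'   pooled wells), `graft` (cells engrafted per category), `lineage_state`
#'   (expanded cells per lineage, guide, Cas9 status and editing status)
#'   and `sorted` (cells per sorted GFP fraction), plus `input_frequencies`.
#' @export
simulate_invivo_screen <- function(lib, design, fitness, n_mice = 3,
                                   seed = 1L, truth_path = NULL) {
  lib_tb <- as_tibble(lib)
  n_g <- nrow(lib_tb)

  # stage 1: transduce one well per guide, at input-library representation,
  # and pool. Well sizes are scaled by the input frequency draw so the pool
  # carries the slightly uneven guide representation of a real input.
  freqs <- simulate_input_frequencies(lib_tb, seed = seed)
  pool <- with_stage_seed(seed, "wells", {
    map_dfr(seq_len(n_g), function(i) {
      n0 <- well_initial_state(design, editing_of(fitness, lib_tb$gene[i]))
      # rescale the well to the drawn input share of this guide
      scale <- freqs$frequency[i] * n_g
      n0 <- rpois(length(n0), n0 * scale)
      tibble(
        guide_id = lib_tb$guide_id[i], gene = lib_tb$gene[i],
        cas9 = c("pos", "pos", "neg", "pos", "neg"),
        mcherry = c("pos", "pos", "pos", "neg", "neg"),
        edited = c(TRUE, FALSE, FALSE, FALSE, FALSE),
        cells = as.integer(n0)
      )
    })
  })

  # stage 2: per-recipient graft, drawn without replacement from the
  # pooled mCherry+ cells, split across Cas9 arms per the design ratio
  candidates <- pool |> filter(.data$mcherry == "pos")
  graft <- with_stage_seed(seed, "graft", {
    remaining <- candidates$cells
    drawn <- integer(length(remaining))
    for (m in seq_len(n_mice)) {
      for (arm in c("pos", "neg")) {
        idx <- which(candidates$cas9 == arm)
        k <- design$graft_split[[paste0("cas9_", arm)]]
        if (k > sum(remaining[idx]))
          abort("graft larger than the available pooled cells")
        d <- rmvhyper(remaining[idx], k)
        drawn[idx] <- drawn[idx] + d
        remaining[idx] <- remaining[idx] - d
      }
    }
    candidates |> mutate(cells = drawn)
  })

  # stage 3: lineage expansion with per-division fitness on edited cells
  lineage_state <- with_stage_seed(seed, "expansion", {
    map_dfr(seq_len(nrow(design$lineages)), function(li) {
      lin <- design$lineages$lineage[li]
      E <- design$lineages$expansion[li]
      D <- log2(E)
      w <- fitness_of(fitness, graft$gene, lin)
      fac <- ifelse(graft$edited, growth_factor(D, w), E)
      graft |>
        mutate(lineage = lin,
               cells = rpois(dplyr::n(), .data$cells * fac)) |>
        select("lineage", "guide_id", "gene", "cas9", "edited", "cells")
    })
  })

  # stage 4: sort mCherry+ cells of each lineage into GFP fractions
  sorted <- with_stage_seed(seed, "sort", {
    map_dfr(seq_len(nrow(design$lineages)), function(li) {
      lin <- design$lineages$lineage[li]
      depth <- design$lineages$sort_depth[li]
      map_dfr(c(pos = "pos", neg = "neg"), function(gate) {
        fr <- lineage_state |>
          filter(.data$lineage == lin, .data$cas9 == gate)
        k <- min(depth, sum(fr$cells))
        fr |>
          mutate(cells = rmvhyper(fr$cells, k), gfp_gate = gate) |>
          select("lineage", "gfp_gate", "guide_id", "gene", "edited",
                 "cells")
      })
    })
  })

  if (!is.null(truth_path))
    write_truth_tsv(fitness, lib_tb, truth_path,
                    contexts = design$lineages$lineage)
  structure(list(pool = pool, graft = graft,
                 lineage_state = lineage_state, sorted = sorted,
                 input_frequencies = freqs, design = design),
            class = "invivo_screen")
}

#' Simulate amplicon sequencing of sorted cell fractions
#'
#' Converts sorted cell counts into sgRNA read counts per sample. Reads are
#' drawn Dirichlet-multinomial: the expected read share of a guide equals
#' its cell frequency in the sorted fraction, and `pcr_rho` sets the PCR /
#' library-prep overdispersion (per-sample Dirichlet concentration
#' `1 / pcr_rho`; `pcr_rho = 0` is a pure multinomial).
#'
#' @param sorted Tibble of sorted fractions with columns `lineage`,
#'   `gfp_gate`, `guide_id`, `cells` (e.g. `$sorted` of an
#'   [simulate_invivo_screen()] result; editing status is collapsed —
#'   sequencing sees only the integrated guide barcode).
#' @param lib The library (fixes canonical guide order).
#' @param depth Reads per sample.
#' @param pcr_rho Overdispersion parameter (>= 0).
#' @param seed Integer seed.
#' @return A `count_matrix` tibble: `sample_id`, `lineage`, `gfp_gate`,
#'   `guide_id`, `gene`, `count`, `total_reads`, in canonical library
#'   order within each sample.
#' @export
simulate_sequencing <- function(sorted, lib, depth = 1e6, pcr_rho = 0.001,
                                seed = 1L) {
  stopifnot(depth >= 1, pcr_rho >= 0)
  lib_tb <- as_tibble(lib)
  cells <- sorted |>
    group_by(.data$lineage, .data$gfp_gate, .data$guide_id) |>
    summarise(cells = sum(.data$cells), .groups = "drop")
  samples <- cells |> distinct(.data$lineage, .data$gfp_gate)
  out <- map_dfr(seq_len(nrow(samples)), function(si) {
    lin <- samples$lineage[si]; gate <- samples$gfp_gate[si]
    v <- cells |> filter(.data$lineage == lin, .data$gfp_gate == gate)
    n <- setNames(rep(0, nrow(lib_tb)), lib_tb$guide_id)
    n[v$guide_id] <- v$cells
    sid <- paste0(lin, "_GFP", gate)
    counts <- with_stage_seed(seed, paste0("sequencing/", sid), {
      if (sum(n) == 0) {
        warn(paste0("sorted sample ", sid,
                    " contains no cells; emitting an all-zero row"))
        rep(0L, length(n))
      } else {
        p <- n / sum(n)
        if (pcr_rho > 0) {
          g <- rgamma(length(p), shape = p / pcr_rho, rate = 1)
          p <- if (sum(g) > 0) g / sum(g) else p
        }
        drop(rmultinom(1, depth, p))
      }
    })
    tibble(sample_id = sid, lineage = lin, gfp_gate = gate,
           guide_id = lib_tb$guide_id, gene = lib_tb$gene,
           count = as.integer(counts), total_reads = as.integer(depth))
  })
  structure(out, class = c("count_matrix", class(out)))
}
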