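---
title: "The dualscreen model: internally controlled CRISPR depletion screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dualscreen model: internally controlled CRISPR depletion screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(dualscreen)
library(dplyr)
```

## The experimental design being modeled

Pooled CRISPR dropout screens read gene essentiality from the depletion of
guide RNAs over time. The design implemented here adds an *internal
wild-type control*: Cas9-GFP cells and wild-type (GFP^-^) cells are mixed at
a fixed ratio, and each sgRNA lentivirus (marked by mCherry) infects both
populations alike. Only transduced Cas9^+^ cells are edited; transduced
wild-type cells carry the same guide through the same culture or the same
recipient mouse without a knockout phenotype. Every well and every sorted
fraction therefore ships its own control, cancelling well-to-well
differences in transduction efficiency, culture growth, engraftment and
sampling depth.

Two readouts quantify depletion:

* **Survival/proliferation (sur/pro) score** (flow cytometry, arrayed
  wells). Let $f^+$ be the GFP^+^ fraction among mCherry^+^ (transduced)
  cells and $f^-$ the GFP^+^ fraction among mCherry^-^ (untransduced) cells
  of the same well. The score is
  $$S = \log_2\!\frac{f^+}{f^-},$$
  with a pseudocount $\alpha$ (default 0.5) added to each gate count so $S$
  is always finite. A knockout that impairs survival or proliferation
  removes GFP^+^ cells specifically from the mCherry^+^ gate and drives
  $S$ below zero.

* **Abundance score** (amplicon sequencing, pooled transplantation). Per
  output lineage, mCherry^+^GFP^+^ and mCherry^+^GFP^-^ cells are sorted,
  their integrated sgRNA barcodes amplified and sequenced, counts
  CPM-normalized per library, and
  $$A_s = \log_2\!\frac{\mathrm{CPM}^+_s}{\mathrm{CPM}^-_s}$$
  computed per guide $s$.

Genes are aggregated as the mean of their (three) guides and called
*depleted hits* below a log2 threshold of $-1$ (two-fold depletion) in
every replicate.

### Why the fraction ratio, not the literal cell-count ratio

The flow readout is sometimes described as the log2 fold change of
mCherry^+^GFP^+^ over mCherry^-^GFP^+^ *cells*. Taken literally as a count
ratio, that statistic inherits the well's transduction rate: at 60%
transduction a neutral guide would score $\log_2(0.6/0.4) \approx 0.58$,
at 20% it would score $-2$. Wells are infected at 20-60% efficiency, yet
early-timepoint scores are reported near zero for every guide — which is
only consistent with the *within-gate fraction* ratio above, the form that
is exactly invariant to the mCherry^+^ fraction. `surpro_score()` therefore
defaults to the fraction ratio (`mode = "fraction"`); the literal count
ratio stays available as `mode = "raw"`, and an optional
`anchor_timepoint` subtracts each guide's early score if a
day-2-referenced score is wanted. Note one consequence of this choice: the
abundance score is exactly antisymmetric under swapping the GFP^+^/GFP^-^
roles, while the fraction-ratio sur/pro score flips sign but is exactly
antisymmetric only for mirrored gate compositions ($f^+ = 1 - f^-$).

## The generative simulator

Real screens of this design are not publicly deposited, so the package
carries a stage-by-stage generative model of the whole experiment. It is
first-class, tested code — the statistical structure of the study, not a
convenience fixture — and every analysis stage can be exercised against
its planted ground truth.

**Stages** (each stage draws from a child seed derived from one root seed
and the stage name, so any stage reproduces in isolation):

1. **Input library**: per-guide frequencies drawn from a symmetric
   Dirichlet. The default concentration of 150 per guide keeps 45 guides
   near the uniform 2.2% with a realistic few-percent spread.
2. **Wells and transduction**: each well seeds `cells_per_well` (2×10^4)
   cells, Cas9^+^ at the design mix (1:1 in culture, 3:2 for
   transplantation), transduced at rate $\tau$ (0.3 in culture, kept
   below 0.3 in vivo so a transduced cell carries a single integration).
   Transduced Cas9^+^ cells are edited with probability $e$ (default 0.9,
   the knockout efficiency measured a few days post transduction);
   editing is applied before the first division, absorbing the editing
   delay into $e$.
3. **Growth**: over $D$ divisions, unimpaired cells multiply by $2^D$ and
   edited cells by $(2w)^D$, where $w$ is the planted per-division
   relative fitness ($w = 1$ neutral, $w = 0.5$ no net growth, $w = 0$
   extinction). Counts are drawn Poisson around the branching-process
   expectation — the desk-scale approximation to a per-cell branching
   simulation, accurate at the 10^4^-10^6^ cell counts involved. Culture
   readouts use day 2 = 1 division and day 7 = 5 divisions.
4. **Flow analysis**: 10^4^ FACS events sampled multinomially from the
   four mCherry×GFP gates.
5. **Transplantation bottleneck** (in vivo arm): wells are pooled and
   each recipient's graft — 5×10^4 transduced cells split 3×10^4
   Cas9^+^ / 2×10^4 Cas9^-^, following the 3:2 mix — is drawn *without
   replacement* (multivariate hypergeometric over guide×editing
   categories). Cell counts are conserved at every partition.
6. **Lineage expansion**: eight weeks of repopulation are modeled as a
   per-lineage fold expansion $E_l$ (default 10^3) rather than calendar
   time, since only relative guide composition enters the scores; the
   per-division fitness acts through $D_l = \log_2 E_l$ effective
   divisions. The number of in vivo divisions is not observable at this
   resolution, so $E_l$ is a free design parameter.
7. **Sorting and sequencing**: per lineage, mCherry^+^ cells are sorted
   into GFP fractions of fixed depth (again hypergeometric), and reads
   are drawn Dirichlet-multinomial with concentration $1/\rho_{PCR}$
   (default $\rho_{PCR} = 0.001$; 0 gives a pure multinomial), modeling
   PCR/library overdispersion. `write_fastq()` can emit the reads as
   anchored amplicons for end-to-end tests of the counting stage.
8. **Division-tracking dye assay**: `simulate_celltrace()` models dye
   dilution with unimpaired cells dividing every 0.8 days (division 5 by
   day 4) and edited cells under *progressive arrest*: the $g$-th
   division succeeds with probability $w^{g-1}$, so $w = 1$ tracks the
   control schedule while $w = 0.5$ strands most knockouts at divisions
   1-2. Histograms count labeled founder lineages rather than
   descendants, so a handful of unedited escaper lineages (the
   $1 - e \approx 10\%$) cannot dominate the transduced channel by
   sheer cell number.

### Worked expectation used throughout the tests

For $e = 0.9$, $w = 0.5$, $D = 5$ and a 1:1 mix, edited cells hold at
$(2 \cdot 0.5)^5 = 1$ while everything else grows $2^5 = 32$-fold, so the
expected GFP^+^ fraction among transduced cells is
$(0.9 + 0.1 \cdot 32)/(0.9 + 0.1 \cdot 32 + 32) = 4.1/36.1 \approx 0.114$
against $f^- = 0.5$, giving $S \approx \log_2(0.114/0.5) = -2.14$ — a
clear call against the $-1$ threshold:

```{r}
lib <- example_invitro_library()
fm <- fitness_model(tibble(gene = "Tfdp1", lineage = "*", fitness = 0.5),
                    editing = 0.9)
scores <- vapply(1:20, function(s)
  surpro_score(simulate_well(lib, screen_design_invitro(), fm,
                             "sgTfdp1-1", timepoints = "day7",
                             seed = s))$score, numeric(1))
mean(scores)
```

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `mix_ratio` | 1 (culture), 1.5 (transplant) | Cas9^+^:Cas9^-^ | design mixing ratios (1:1, 3:2) |
| `transduction_rate` | 0.3 / 0.25 | fraction | 20-60% in culture; <0.3 in vivo for single integration |
| `cells_per_well` | 2×10^4 | cells | plating density |
| `graft_size` | 5×10^4 | transduced cells/recipient | transplant dose; split 3:2 |
| `divisions_by_readout` | day2=1, day7=5 | divisions | culture readout schedule |
| `expansion` ($E_l$) | 10^3 | fold | stands in for eight weeks of repopulation |
| `sort_depth` | 10^4 | cells/fraction | sorted cells per GFP gate |
| `facs_events` | 10^4 | events | flow analysis depth |
| `editing` ($e$) | 0.9 | probability | measured knockout efficiency |
| `concentration` | 150 | per guide | input-library evenness |
| `pcr_rho` | 0.001 | — | sequencing overdispersion |
| `pseudocount` ($\alpha$) | 0.5 | counts | finite log ratios |
| `threshold` | −1 | log2 | two-fold depletion hit cutoff |
| `q` | 0.90 | quantile | top-decile target sets |

## Numerical and statistical choices

* **Pseudocount** $\alpha = 0.5$ is applied wherever a log ratio is
  formed (gate fractions, CPM), so all scores are finite by construction;
  it is configurable and recorded in output provenance.
* **Evenness band**: input QC checks the min/max guide frequency against
  a 2-9% band. The band is quoted in whole percent, so the comparison is
  made on the rounded integer-percent scale (a 45-guide library centered
  on 1/45 ≈ 2.2% legitimately has minima of ~1.7%, which report as 2%).
* **Percentile target sets** use nearest-rank on the upper tail: the
  cutoff is the $\lceil (1-q) n \rceil$-th largest score and ties at the
  cutoff are all included — set membership is stable under monotone score
  transformations, which interpolating quantiles cannot guarantee.
* **Overlap significance** is the one-sided hypergeometric (Fisher
  exact) upper tail, the field standard for Venn significance; the
  universe size must be supplied explicitly because $p$ depends strongly
  on it. The test suite checks the implementation against exhaustive
  enumeration of all $\binom{20}{4}$ draws on a 20-gene universe.
* **Hamming-1 barcode rescue**: reads are assigned to a guide when
  exactly one library spacer is within one mismatch; equidistant ties are
  dropped as ambiguous. Packaged libraries are generated with pairwise
  spacer distance ≥ 3 so rescue can never cross-assign.
* **Hit replicate rule**: a gene must clear the threshold in every
  replicate (consistent with highlighting genes reproducible across two
  independent experiments); a replicate-mean mode is available.
* **Gene aggregation** is the mean of the three guides (median
  available); how replicates were combined in published heatmaps is not
  stated, so both per-replicate and replicate-mean views are kept.
* **Seeding**: one root seed; each stochastic stage derives a child seed
  from the root and the stage name (a small string hash), so identical
  configurations are bit-reproducible and stages re-run in isolation.

## What the simulator does and does not emulate

The generator reproduces the *statistical structure* of the screen:
mixing, transduction, editing efficiency, fitness-dependent growth, the
transplantation bottleneck, sorting depths, input unevenness, and
counting noise with PCR overdispersion. Tests passing on simulated
screens therefore demonstrate that the scoring pipeline recovers planted
truths through these noise sources at the design's coverage.

They do not demonstrate robustness to what the generator leaves out:
guide-specific cutting efficiency differences, off-target effects,
multi-integration events (infection is assumed below the single-copy
regime), clonal drift and niche effects during repopulation, homing and
engraftment kinetics, apoptosis as a channel distinct from net fitness
(cell death is absorbed into $w$), index hopping or adapter artifacts in
sequencing, and real FACS gating noise. The packaged libraries carry
synthetic spacer sequences (the original oligos are not public), so
sequence-level results exercise the counting machinery, not the actual
reagents.

## Problem sizes

The test suite and the acceptance script run at the design's own scale —
45-guide (15-gene) and 99-guide (33-gene) libraries, 2×10^4-cell wells,
5×10^4-cell grafts, 10^4-event flow analyses, 10^5-10^6-read samples —
with 20-seed Monte Carlo repeats for stochastic checks and up to
1000-seed repeats where a closed-form expectation is verified to three
standard errors. A full run of everything completes in about a minute on
one core.

## Limitations

Hit calling is a fixed fold-change threshold, not a statistical test; no
p-values, FDR, copy-number correction or rank aggregation are provided
(by design — the readout is internally controlled and the libraries are
small). The expansion factor $E_l$ compresses weeks of hematopoiesis into
one effective parameter; recovering *absolute* fitness from in vivo
scores is therefore out of reach, only the ordering and threshold calls
are meaningful. The overlap module computes set statistics on
user-supplied lists; it does not fetch or parse external binding or
expression databases.
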