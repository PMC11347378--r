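#' Derive a reproducible child seed for a named simulation stage
#'
#' All stochastic stages of the simulator draw their randomness from a child
#' seed derived deterministically from one root seed and the stage name, so
#' any stage can be re-run in isolation and still reproduce its output
#' bit-for-bit. The derivation is a small string hash (djb2 over the stage
#' label, folded with the root seed); it is stable across platforms and
#' always returns a positive integer below 2^31 - 1.
#'
#' @param seed Integer root seed.
#' @param stage Character scalar naming the stage (e.g. `"graft"`,
#'   `"sequencing/HSPC/pos"`).
#' @return A single integer seed.
#' @export
#' @examples
#' child_seed(1, "graft")
#' child_seed(1, "graft") == child_seed(1L, "graft")
child_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1, is.finite(seed), is.character(stage),
            length(stage) == 1, nzchar(stage))
  m <- 2147483629 # largest prime < 2^31, keeps arithmetic exact in doubles
  h <- 5381
  for (c in utf8ToInt(stage)) h <- (h * 33 + c) %% m
  as.integer((h + (as.double(seed) %% m) * 7919) %% m + 1)
}

# run `expr` under a local RNG state seeded from (seed, stage); restores the
# caller's RNG afterwards so simulator calls never perturb user code.
with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(child_seed(seed, stage))
  expr
}
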