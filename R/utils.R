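#' Round half away from zero
#'
#' Printed tables round 0.005 up, unlike R's banker's rounding; all table
#' arithmetic in this package uses this rule.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Deterministic per-subject seed substreams derived from a master seed, so
# that subsetting a cohort never reshuffles the remaining subjects. Seeds
# are drawn (with replacement, one RNG draw each) from a master-seeded
# stream: the first k seeds are identical for any cohort size >= k, and
# the scrambling avoids the correlated-initialisation artefacts of
# arithmetic seed progressions.
subject_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master)
  sample.int(2147483646L, n, replace = TRUE)
}
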