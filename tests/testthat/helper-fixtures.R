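# Shared fixtures, built once per test run.

random_generator <- function(seed = NULL, max_rate = 1) {
  if (!is.null(seed)) set.seed(seed)
  q <- stats::runif(4, 0, max_rate)
  Q <- matrix(0, 3, 3)
  Q[1, 2] <- q[1]; Q[1, 3] <- q[2]; Q[2, 1] <- q[3]; Q[2, 3] <- q[4]
  diag(Q) <- -rowSums(Q)
  Q
}

# expm via high-accuracy integration of the Kolmogorov forward equations
ode_pmatrix <- function(Q, t) {
  deriv <- function(s, y, parms) list(as.numeric(matrix(y, 3) %*% Q))
  out <- deSolve::lsoda(as.numeric(diag(3)), c(0, t), deriv, NULL,
                        rtol = 1e-12, atol = 1e-12)
  matrix(out[2, -1], 3)
}

# small observed cohort used by several msm tests
small_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- cohort_config(n_subjects = 400, seed = 301,
                           entry_age_mean = 76, entry_age_sd = 7,
                           entry_age_max = 95)
      tp <- default_truth("childhood")
      paths <- simulate_paths(tp, cfg)
      panel <- observe_panel(paths, cfg)
      attr(panel, "ses_spec") <- "childhood"
      panel <- apply_inclusion_criteria(panel)
      attr(panel, "ses_spec") <- "childhood"
      cache <<- list(panel = panel, truth = tp, config = cfg,
                     paths = paths)
    }
    cache
  }
})

# intercepts-only parameter set: all four intensities 0.1
flat_params <- function(rate = 0.1) {
  transition_params(rep(log(rate), 4), rep(0, 4), spec = "none")
}
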