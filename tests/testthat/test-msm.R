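test_that("inclusion criteria drop young entrants, single waves, missing data", {
  raw <- data.frame(
    subject = c(1, 1, 2, 3, 3, 4, 4, 5),
    age = c(70, 73, 71, 64.9, 68, 72, NA, 80),
    state = c(1, 2, 1, 1, 2, 1, 1, 1),
    exact = FALSE)
  out <- apply_inclusion_criteria(raw)
  log <- attr(out, "exclusion_log")
  expect_equal(sort(unique(out$subject)), 1)  # 2: single wave; 3: under 65
  expect_equal(log[["under_65"]], 1L)
  expect_gte(log[["single_wave"]], 2L)        # subjects 2, 5, and 4 (after NA)
  expect_equal(log[["missing"]], 1L)

  clean <- data.frame(subject = rep(1:3, each = 2),
                      age = c(70, 72, 66, 69, 80, 83),
                      state = c(1, 1, 1, 2, 2, 3), exact = FALSE)
  out2 <- apply_inclusion_criteria(clean)
  expect_equal(nrow(out2), 6L)
  expect_true(all(attr(out2, "exclusion_log") == 0L))
})

test_that("likelihood contributions follow their definitions", {
  tp <- flat_params(0.1)
  Q <- build_intensity_matrix(tp, 65)
  P1 <- pmatrix_const(Q, 1)
  # living -> living
  pan <- data.frame(subject = 1, age = c(65, 66), state = c(1, 1),
                    exact = FALSE, gender = 0, ses = 0)
  expect_equal(negative_log_likelihood(pan, tp), -log(P1[1, 1]),
               tolerance = 1e-12)
  # exact death: survive in some living state, then die instantaneously
  pand <- data.frame(subject = 1, age = c(65, 66), state = c(1, 3),
                     exact = c(FALSE, TRUE), gender = 0, ses = 0)
  expect_equal(negative_log_likelihood(pand, tp),
               -log(P1[1, 1] * Q[1, 3] + P1[1, 2] * Q[2, 3]),
               tolerance = 1e-12)
  # interval-censored death uses the plain transition probability
  panc <- data.frame(subject = 1, age = c(65, 66), state = c(1, 3),
                     exact = FALSE, gender = 0, ses = 0)
  expect_equal(negative_log_likelihood(panc, tp), -log(P1[1, 3]),
               tolerance = 1e-12)
})

test_that("likelihood agrees with a forward-equation ODE oracle", {
  sm <- small_panel()
  panel <- sm$panel[sm$panel$subject %in% unique(sm$panel$subject)[1:40], ]
  attr(panel, "ses_spec") <- "childhood"
  tp <- sm$truth
  # oracle: integrate the Kolmogorov equations substep by substep
  iv <- frailmslt:::panel_intervals(panel, tp)
  ll <- 0
  for (i in seq_along(iv$age1)) {
    g <- iv$X[i, "gender"]; s <- c(0, 1, 2)[iv$X[i, "sesMedium"] +
                                              2 * iv$X[i, "sesHigh"] + 1]
    P <- diag(3)
    age <- iv$age1[i]; left <- iv$dt[i]
    while (left > 1e-9) {
      step <- min(0.1, left)
      P <- P %*% ode_pmatrix(build_intensity_matrix(tp, age, g, s), step)
      age <- age + step; left <- left - step
    }
    pr <- if (iv$s2[i] != 3) {
      P[iv$s1[i], iv$s2[i]]
    } else if (iv$exact[i]) {
      # death intensity at the final substep's left endpoint
      nf <- floor(iv$dt[i] / 0.1 + 1e-9)
      rem <- iv$dt[i] - nf * 0.1
      la <- iv$age1[i] + (if (rem > 1e-9) nf else nf - 1) * 0.1
      qq <- transition_rates(tp, la, g, s)
      P[iv$s1[i], 1] * qq[, "q13"] + P[iv$s1[i], 2] * qq[, "q23"]
    } else P[iv$s1[i], 3]
    ll <- ll - as.numeric(log(pr))
  }
  expect_equal(negative_log_likelihood(panel, tp), ll, tolerance = 1e-8)
})

test_that("likelihood is invariant to subject order and dataset splits", {
  sm <- small_panel()
  panel <- sm$panel
  tp <- sm$truth
  base <- negative_log_likelihood(panel, tp)
  shuf <- panel[sample(nrow(panel)), ]
  attr(shuf, "ses_spec") <- "childhood"
  expect_equal(negative_log_likelihood(shuf, tp), base, tolerance = 1e-10)
  ids <- unique(panel$subject)
  half <- panel$subject %in% ids[1:(length(ids) %/% 2)]
  p1 <- panel[half, ]; p2 <- panel[!half, ]
  attr(p1, "ses_spec") <- attr(p2, "ses_spec") <- "childhood"
  expect_equal(negative_log_likelihood(p1, tp) +
                 negative_log_likelihood(p2, tp), base, tolerance = 1e-10)
})

test_that("inadmissible parameters give +Inf, not an error", {
  pan <- data.frame(subject = 1, age = c(65, 66), state = c(1, 2),
                    exact = FALSE, gender = 0, ses = 0)
  tp0 <- transition_params(rep(-Inf, 4), rep(0, 4), spec = "none")
  expect_identical(negative_log_likelihood(pan, tp0), Inf)
})

test_that("fitting recovers parameters and is robust to the starting point", {
  sm <- small_panel()
  panel <- sm$panel
  fitA <- fit_msm(panel, spec = "none", gender_mode = "pooled")
  truth_init <- transition_params(
    unclass(sm$truth)[, 1], unclass(sm$truth)[, 2],
    unclass(sm$truth)[, 3], spec = "none")
  fitB <- fit_msm(panel, spec = "none", gender_mode = "pooled",
                  init = truth_init)
  expect_true(fitA$converged)
  expect_true(fitB$converged)
  expect_lt(abs(fitA$logLik - fitB$logLik), 1e-4)
  se <- msm_se(fitA)
  expect_true(all(is.finite(se)) && all(se > 0))
  expect_true(all(eigen(fitA$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-8))
  # intercepts and slopes in the right neighbourhood of the truth
  z <- (unclass(fitA$params)[, 1:2] - unclass(truth_init)[, 1:2]) /
    se[, 1:2]
  expect_lt(max(abs(z)), 4)
})

test_that("degenerate all-robust data drives exit intensities to the bound", {
  pan <- data.frame(subject = rep(1:40, each = 3),
                    age = rep(c(65, 67, 69), 40) +
                      rep(seq(0, 3.9, by = 0.1), each = 3),
                    state = 1, exact = FALSE, gender = 0, ses = 0)
  fit <- suppressWarnings(fit_msm(pan, spec = "none",
                                  gender_mode = "pooled"))
  expect_true(fit$boundary)
  expect_false(fit$converged)
  # exit intensities driven to numerically-zero territory
  expect_lte(unclass(fit$params)["1-2", "intercept"], -10)
  expect_lte(unclass(fit$params)["1-3", "intercept"], -10)
})

test_that("stratified fitting returns one fit per gender without a gender column", {
  sm <- small_panel()
  fit <- fit_msm(sm$panel, spec = "childhood", gender_mode = "stratify",
                 max_iter = 200)
  expect_s3_class(fit, "msm_fit_strata")
  expect_named(fit, c("female", "male"))
  expect_false("gender" %in% colnames(fit$male$params))
  expect_equal(attr(fit, "spec"), "childhood")
})
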