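test_that("annual matrices: identity for the null model, absorbing death", {
  tp0 <- transition_params(rep(-Inf, 4), rep(0, 4), spec = "none")
  expect_equal(annual_transition_matrix(tp0, 80), diag(3),
               ignore_attr = TRUE)
  P <- annual_transition_matrix(default_truth("childhood"), 80,
                                gender = 1, ses = 1)
  expect_equal(unname(P[3, ]), c(0, 0, 1))
  expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  expect_error(annual_transition_matrix(tp0, 130), "input error")
})

test_that("constant intensities collapse the substep product to one expm", {
  tp <- flat_params(0.15)
  Q <- build_intensity_matrix(tp, 70)
  expect_lt(max(abs(annual_transition_matrix(tp, 70) -
                      pmatrix_const(Q, 1))), 1e-10)
})

test_that("transition curves are monotone under signed age slopes", {
  tp <- default_truth("childhood")
  for (g in 0:1) for (s in 0:2) {
    cv <- transition_curves(tp, gender = g, ses = s, ages = 65:95)
    expect_true(all(diff(cv$p12) >= 0))
    expect_true(all(diff(cv$p13) >= 0))
    expect_true(all(diff(cv$p23) >= 0))
    expect_true(all(diff(cv$p21) <= 0))
  }
  tp0 <- transition_params(rep(-Inf, 4), rep(0, 4), spec = "none")
  cv0 <- transition_curves(tp0, ages = 65:70)
  expect_true(all(cv0$p12 == 0))
})

test_that("a protective incidence coefficient lowers the curve pointwise", {
  tp <- default_truth("childhood")
  lo <- transition_curves(tp, gender = 1, ses = 0, ages = 65:95)
  hi <- transition_curves(tp, gender = 1, ses = 2, ages = 65:95)
  expect_true(all(hi$p12 < lo$p12))
})

test_that("occupancy grids are proper distributions with monotone mortality", {
  tp <- default_truth("childhood")
  occ <- state_occupancy(tp, 65, gender = 1, ses = 0)
  expect_equal(occ$age[1], 65)
  expect_equal(occ$age[nrow(occ)], 130)
  expect_lt(max(abs(occ$p1 + occ$p2 + occ$p3 - 1)), 1e-10)
  expect_true(all(diff(occ$p3) >= -1e-12))
  # zero-mortality model: no one dies, the living states partition mass
  tpnm <- transition_params(c(log(0.3), -Inf, log(0.2), -Inf), rep(0, 4),
                            spec = "none")
  occ0 <- state_occupancy(tpnm, 70)
  expect_lt(max(occ0$p3), 1e-12)
  expect_lt(max(abs(occ0$p1 + occ0$p2 - 1)), 1e-12)
})

test_that("life expectancy matches the single-state closed form with first-order step error", {
  mu <- 0.1
  tp <- transition_params(c(-Inf, log(mu), -Inf, -Inf), rep(0, 4),
                          spec = "none")
  truth <- (1 - exp(-mu * 65)) / mu
  le1 <- life_expectancies(tp, 65, h = 0.1)
  expect_lt(abs(le1$total - truth), 0.06)
  le2 <- life_expectancies(tp, 65, h = 0.05)
  expect_lt(abs(le2$total - truth), abs(le1$total - truth))
  expect_lt(abs(le2$total - truth), 0.6 * abs(le1$total - truth))
  # zero-mortality model spends all remaining years alive
  tp0 <- transition_params(rep(-Inf, 4), rep(0, 4), spec = "none")
  expect_equal(life_expectancies(tp0, 70)$total, 60)
})

test_that("robust + frailty = total exactly; proportions behave", {
  tp <- default_truth("trajectory")
  for (s in c(1, 5, 9)) for (a in c(65, 75, 90)) {
    le <- life_expectancies(tp, a, gender = 0, ses = s)
    expect_identical(le$total, le$robust + le$frailty)
    expect_equal(le$prop_robust + le$prop_frailty, 100)
  }
  # near-immediate death: the left-endpoint rule floors total LE at one
  # grid step from the living start
  tpd <- transition_params(c(-Inf, 20, -Inf, 20), rep(0, 4), spec = "none")
  led <- life_expectancies(tpd, 65)
  expect_lt(led$total, 0.11)
  expect_equal(led$prop_robust, 100)
  # total LE non-increasing in index age under positive mortality
  tp1 <- default_truth("childhood")
  les <- vapply(c(65, 70, 75, 80, 90, 100), function(a)
    life_expectancies(tp1, a, gender = 1, ses = 0)$total, numeric(1))
  expect_true(all(diff(les) < 0))
})

test_that("uniformly protective mortality coefficients never decrease total LE", {
  base <- default_truth("childhood")
  prot <- unclass(base)
  prot[c("1-3", "2-3"), "intercept"] <- prot[c("1-3", "2-3"),
                                             "intercept"] - 0.3
  prot <- transition_params(prot[, "intercept"], prot[, "age65"],
                            prot[, "gender"],
                            prot[, c("sesMedium", "sesHigh")],
                            spec = "childhood")
  for (a in c(65, 75, 85)) {
    expect_gte(life_expectancies(prot, a, 1, 0)$total,
               life_expectancies(base, a, 1, 0)$total)
  }
})

test_that("grid refinement: halving h moves LE by less than the h=0.1 error", {
  mu <- 0.08
  tp <- transition_params(c(-Inf, log(mu), -Inf, -Inf), rep(0, 4),
                          spec = "none")
  truth <- (1 - exp(-mu * 65)) / mu
  e1 <- abs(life_expectancies(tp, 65, h = 0.1)$total - truth)
  d12 <- abs(life_expectancies(tp, 65, h = 0.05)$total -
               life_expectancies(tp, 65, h = 0.1)$total)
  expect_lt(d12, e1)
})

test_that("bootstrap intervals are seed-reproducible and collapse with zero covariance", {
  sm <- small_panel()
  fit <- fit_msm(sm$panel, spec = "none", gender_mode = "pooled")
  b1 <- bootstrap_ci(fit, 65, gender = 1, ses = 0, B = 40, seed = 9)
  b2 <- bootstrap_ci(fit, 65, gender = 1, ses = 0, B = 40, seed = 9)
  expect_identical(b1$ci, b2$ci)
  expect_true(all(b1$ci[1, 1:3] <= b1$ci[2, 1:3]))
  fit0 <- fit
  fit0$vcov <- matrix(0, nrow(fit$vcov), ncol(fit$vcov))
  b0 <- bootstrap_ci(fit0, 65, gender = 1, ses = 0, B = 10, seed = 1)
  expect_lt(max(b0$ci[2, ] - b0$ci[1, ]), 1e-12)
  fitbad <- fit
  fitbad$vcov[1, 1] <- -1
  expect_error(bootstrap_ci(fitbad, 65, B = 5, seed = 1), "refit")
})

test_that("marginal initial distributions reflect frailty prevalence at entry", {
  sm <- small_panel()
  ini70 <- marginal_init(sm$panel, 70)
  ini95 <- marginal_init(sm$panel, 95)
  expect_equal(sum(ini70), 1)
  expect_gt(ini95[2], ini70[2])  # older entrants more often frail
})

test_that("the LE table covers every profile with printed-style proportions", {
  sm <- small_panel()
  fit <- fit_msm(sm$panel, spec = "childhood", gender_mode = "stratify",
                 max_iter = 200)
  tab <- le_table(fit, ages = 65, B = 0)
  expect_equal(nrow(tab), 6L)  # 2 genders x 3 categories
  expect_setequal(tab$label, c("low", "medium", "high"))
  expect_equal(tab$prop_robust + tab$prop_frailty, rep(100, 6),
               tolerance = 0.011)
  expect_equal(tab$total_le, tab$robust_le + tab$frailty_le,
               tolerance = 1e-10)
})
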