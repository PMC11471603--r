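# Extract a transition_params object and a covariate profile row from
# either a fitted model or raw parameters.
resolve_params <- function(object) {
  if (inherits(object, "msm_fit")) object$params
  else if (inherits(object, "transition_params")) object
  else stop("need an 'msm_fit' or 'transition_params' object")
}

# One-step living-block probabilities over each substep of a grid for a
# fixed profile: returns list of vectors P11, P12, P21, P22 with one entry
# per substep [grid[k], grid[k] + len[k]).
grid_steps <- function(params, gender, ses, grid, len) {
  q <- transition_rates(params, grid, gender, ses)
  expm_living(q[, "q12"], q[, "q13"], q[, "q21"], q[, "q23"], len)
}

#' Annual transition probability matrix at a given age
#'
#' Computes `P(age -> age + 1)` as the product of ten 0.1-year
#' matrix-exponential substeps with the intensities re-evaluated at each
#' substep's left endpoint, so annual probabilities share the life table's
#' age discretisation. The dead row is (0, 0, 1).
#'
#' @param object an `msm_fit` or a [transition_params()] object.
#' @param age index age, in `[65, 129]`.
#' @param gender 0 female, 1 male (ignored by gender-stratified fits).
#' @param ses SES category (0:2) or trajectory code (1:9) per the spec.
#' @param h substep length in years.
#' @return 3x3 stochastic matrix.
#' @export
annual_transition_matrix <- function(object, age, gender = 0, ses = 0,
                                     h = 0.1) {
  if (length(age) != 1L || age < 65 || age > 129)
    stop("input error: age must lie in [65, 129]")
  params <- resolve_params(object)
  ns <- round(1 / h)
  grid <- age + (seq_len(ns) - 1L) * h
  st <- grid_steps(params, gender, ses, grid, rep(h, ns))
  A <- c(1, 0, 0, 1)  # P11 P12 P21 P22
  for (k in seq_len(ns)) {
    A <- c(A[1] * st$P11[k] + A[2] * st$P21[k],
           A[1] * st$P12[k] + A[2] * st$P22[k],
           A[3] * st$P11[k] + A[4] * st$P21[k],
           A[3] * st$P12[k] + A[4] * st$P22[k])
  }
  P <- matrix(c(A[1], A[2], max(1 - A[1] - A[2], 0),
                A[3], A[4], max(1 - A[3] - A[4], 0),
                0, 0, 1), 3, byrow = TRUE, dimnames = list(1:3, 1:3))
  P
}

#' Annual transition-probability curves across ages
#'
#' Extracts the four annual transition probabilities (robust->frailty,
#' frailty->robust, robust->dead, frailty->dead) over a range of index
#' ages for one covariate profile, in the shape used for the published
#' transition-probability figures.
#'
#' @inheritParams annual_transition_matrix
#' @param ages integer-ish vector of index ages within `[65, 129]`.
#' @return data frame: age, p12, p21, p13, p23.
#' @export
transition_curves <- function(object, gender = 0, ses = 0, ages = 65:95,
                              h = 0.1) {
  rows <- lapply(ages, function(a) {
    P <- annual_transition_matrix(object, a, gender, ses, h)
    data.frame(age = a, p12 = P[1, 2], p21 = P[2, 1],
               p13 = P[1, 3], p23 = P[2, 3])
  })
  do.call(rbind, rows)
}

#' State occupancy probabilities on a 0.1-year grid
#'
#' Propagates an initial distribution over the living states from the
#' index age to the assumed maximum age of 130 by
#' `pi(x + h) = pi(x) %*% expm(Q(x) h)` with `h = 0.1` by default.
#'
#' @inheritParams annual_transition_matrix
#' @param index_age starting age, `[65, 130)`.
#' @param init length-2 distribution over (robust, frailty) at the index
#'   age; must sum to 1.
#' @return data frame of class `occupancy_grid`: age, p1, p2, p3 (rows sum
#'   to 1; p3 non-decreasing).
#' @export
state_occupancy <- function(object, index_age, gender = 0, ses = 0,
                            init = c(1, 0), h = 0.1) {
  stopifnot(index_age >= 65, index_age < MAX_AGE,
            abs(sum(init) - 1) < 1e-8, all(init >= 0))
  params <- resolve_params(object)
  grid <- seq(index_age, MAX_AGE, by = h)
  n <- length(grid)
  st <- grid_steps(params, gender, ses, grid[-n], rep(h, n - 1L))
  p1 <- numeric(n); p2 <- numeric(n)
  p1[1] <- init[1]; p2[1] <- init[2]
  for (k in seq_len(n - 1L)) {
    p1[k + 1L] <- p1[k] * st$P11[k] + p2[k] * st$P21[k]
    p2[k + 1L] <- p1[k] * st$P12[k] + p2[k] * st$P22[k]
  }
  out <- data.frame(age = grid, p1 = p1, p2 = p2,
                    p3 = pmax(1 - p1 - p2, 0))
  class(out) <- c("occupancy_grid", "data.frame")
  out
}

#' Total, robust and frailty life expectancy at an index age
#'
#' Integrates the state occupancy probabilities over age with the
#' left-endpoint rectangle ("step") rule on the 0.1-year grid (the
#' published default; a trapezoid rule is available behind `method`).
#' Robust LE + frailty LE = total LE exactly by construction.
#'
#' @inheritParams state_occupancy
#' @param method `"step"` (left endpoint) or `"trapezoid"`.
#' @return list of class `le_estimate`: total, robust, frailty (years),
#'   prop_robust, prop_frailty (percent, `NA` when total is 0), plus the
#'   index age and profile.
#' @export
life_expectancies <- function(object, index_age, gender = 0, ses = 0,
                              init = c(1, 0), h = 0.1,
                              method = c("step", "trapezoid")) {
  method <- match.arg(method)
  occ <- state_occupancy(object, index_age, gender, ses, init, h)
  n <- nrow(occ)
  w <- rep(h, n)
  if (method == "step") {
    w[n] <- 0                      # left endpoints only
  } else {
    w[c(1, n)] <- h / 2
  }
  robust <- sum(occ$p1 * w)
  frailty <- sum(occ$p2 * w)
  total <- robust + frailty
  pr <- if (total > 0) 100 * robust / total else NA_real_
  structure(list(total = total, robust = robust, frailty = frailty,
                 prop_robust = pr,
                 prop_frailty = if (total > 0) 100 - pr else NA_real_,
                 index_age = index_age, gender = gender, ses = ses,
                 method = method, h = h),
            class = "le_estimate")
}

#' @export
print.le_estimate <- function(x, ...) {
  cat(sprintf(
    "LE at age %g (gender %d, ses %s): total %.2f = robust %.2f + frailty %.2f (%.2f%% robust)\n",
    x$index_age, x$gender, as.character(x$ses), x$total, x$robust,
    x$frailty, x$prop_robust))
  invisible(x)
}

#' Logistic-in-age frailty prevalence at entry, for marginal LE
#'
#' Fits `P(state = frailty | alive)` against age on the living records of
#' one covariate profile (falling back to the whole panel when the profile
#' has fewer than 50 living records), and returns the implied initial
#' distribution over (robust, frailty) at an index age. Used when life
#' expectancy is reported marginally over initial states rather than
#' conditional on starting robust.
#'
#' @param panel analysis panel (subject, age, state, gender, ses).
#' @param index_age age at which the initial distribution is evaluated.
#' @inheritParams annual_transition_matrix
#' @return length-2 numeric `c(robust, frailty)`.
#' @export
marginal_init <- function(panel, index_age, gender = NULL, ses = NULL) {
  liv <- panel[panel$state %in% 1:2, , drop = FALSE]
  sub <- liv
  if (!is.null(gender)) sub <- sub[sub$gender == gender, , drop = FALSE]
  if (!is.null(ses)) sub <- sub[sub$ses == ses, , drop = FALSE]
  if (nrow(sub) < 50L) sub <- liv
  fit <- stats::glm(I(state == 2L) ~ I(age - 65), family = stats::binomial,
                    data = sub)
  p <- stats::predict(fit, newdata = data.frame(age = index_age),
                      type = "response")
  c(1 - p, p)
}

#' Parametric-bootstrap confidence intervals for life expectancies
#'
#' Draws `B` parameter vectors from the multivariate normal centred at the
#' estimates with the fitted covariance, recomputes the life expectancies
#' for each draw, and reports percentile 2.5/97.5% bounds.
#'
#' @param fit an `msm_fit` with a valid covariance matrix.
#' @inheritParams life_expectancies
#' @param B number of bootstrap draws (default 500).
#' @param seed integer seed; fixed seed gives identical intervals.
#' @return list: `est` (the point [life_expectancies()]), `ci` (2 x 5
#'   matrix of bounds for total, robust, frailty, prop_robust,
#'   prop_frailty) and `draws` (B x 5 matrix).
#' @export
bootstrap_ci <- function(fit, index_age, gender = 0, ses = 0,
                         init = c(1, 0), B = 500, seed = 1, h = 0.1,
                         method = "step") {
  stopifnot(inherits(fit, "msm_fit"), B >= 2)
  vc <- fit$vcov
  if (any(!is.finite(vc)))
    stop("non-finite covariance; refit the model before bootstrapping")
  ev <- eigen(vc, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("covariance is not positive semi-definite; refit the model")
  set.seed(seed)
  theta <- params_to_vector(fit$params)
  draws_theta <- MASS::mvrnorm(B, mu = theta, Sigma = vc, tol = 1e-6)
  cols <- c("total", "robust", "frailty", "prop_robust", "prop_frailty")
  draws <- matrix(NA_real_, B, 5, dimnames = list(NULL, cols))
  for (b in seq_len(B)) {
    pb <- vector_to_params(draws_theta[b, ], fit$params)
    le <- life_expectancies(pb, index_age, gender, ses, init, h, method)
    draws[b, ] <- c(le$total, le$robust, le$frailty, le$prop_robust,
                    le$prop_frailty)
  }
  est <- life_expectancies(fit, index_age, gender, ses, init, h, method)
  ci <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)
  list(est = est, ci = ci, draws = draws)
}

#' Life-expectancy table across covariate profiles
#'
#' Builds the published-table shape: one row per gender x index age x SES
#' category (or trajectory), with total/robust/frailty LE, bootstrap 95%
#' confidence intervals and robust/frailty proportions (percent, rounded
#' half-up to two decimals as printed).
#'
#' @param fit an `msm_fit` (pooled, with gender column) or
#'   `msm_fit_strata` (gender-stratified).
#' @param ages index ages (default 65 and 75).
#' @param B bootstrap draws per row; 0 skips intervals.
#' @param seed master seed for the bootstrap.
#' @param init length-2 initial distribution over living states, or the
#'   string `"marginal"` to weight initial states by the logistic-in-age
#'   prevalence model fitted to `panel`.
#' @param panel required when `init = "marginal"`.
#' @inheritParams life_expectancies
#' @return data frame of class `le_table`.
#' @export
le_table <- function(fit, ages = c(65, 75), B = 500, seed = 1,
                     init = c(1, 0), panel = NULL, h = 0.1,
                     method = "step") {
  strata <- inherits(fit, "msm_fit_strata")
  spec <- if (strata) attr(fit, "spec") else fit$spec
  ses_vals <- switch(spec, childhood = 0:2, trajectory = 1:9, none = 0)
  ses_labs <- switch(spec,
                     childhood = c("low", "medium", "high"),
                     trajectory = trajectory_label(1:9),
                     none = "all")
  marginal <- identical(init, "marginal")
  if (marginal && is.null(panel))
    stop("init = \"marginal\" needs the analysis panel")
  rows <- list()
  k <- 0L
  for (g in 0:1) {
    f <- if (strata) fit[[c("female", "male")[g + 1L]]] else fit
    for (a in ages) for (i in seq_along(ses_vals)) {
      s <- ses_vals[i]
      ini <- if (marginal) marginal_init(panel, a, g, s) else init
      k <- k + 1L
      if (B >= 2) {
        bs <- bootstrap_ci(f, a, g, s, ini, B = B,
                           seed = seed + 1000L * k, h = h, method = method)
        est <- bs$est; ci <- bs$ci
      } else {
        est <- life_expectancies(f, a, g, s, ini, h, method)
        ci <- matrix(NA_real_, 2, 5)
      }
      rows[[k]] <- data.frame(
        gender = c("female", "male")[g + 1L], age = a,
        ses = s, label = ses_labs[i],
        total_le = est$total, total_lo = ci[1, 1], total_hi = ci[2, 1],
        robust_le = est$robust, robust_lo = ci[1, 2], robust_hi = ci[2, 2],
        frailty_le = est$frailty, frailty_lo = ci[1, 3],
        frailty_hi = ci[2, 3],
        prop_robust = round_half_up(est$prop_robust, 2),
        prop_frailty = round_half_up(est$prop_frailty, 2))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "spec") <- spec
  class(out) <- c("le_table", "data.frame")
  out
}
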