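#' Apply the cohort inclusion criteria to a raw state panel
#'
#' Drops records with missing age or state, subjects whose first observed
#' age is below 65, and subjects left with fewer than two usable records
#' (single-wave respondents). An exclusion log reports counts per rule.
#'
#' @param panel data frame with columns subject, age, state (1/2/3), exact.
#' @return the filtered panel with an `exclusion_log` attribute
#'   (`missing`, `under_65`, `single_wave` counts of dropped subjects or
#'   records).
#' @export
apply_inclusion_criteria <- function(panel) {
  log <- c(missing = 0L, under_65 = 0L, single_wave = 0L)
  ok <- !is.na(panel$age) & !is.na(panel$state)
  log["missing"] <- sum(!ok)
  panel <- panel[ok, , drop = FALSE]
  panel <- panel[order(panel$subject, panel$age), , drop = FALSE]
  first_age <- tapply(panel$age, panel$subject, min)
  young <- names(first_age)[first_age < 65]
  log["under_65"] <- length(young)
  panel <- panel[!(as.character(panel$subject) %in% young), , drop = FALSE]
  nrec <- table(panel$subject)
  single <- names(nrec)[nrec < 2]
  log["single_wave"] <- length(single)
  panel <- panel[!(as.character(panel$subject) %in% single), , drop = FALSE]
  rownames(panel) <- NULL
  attr(panel, "exclusion_log") <- log
  panel
}

# Covariate design matrix for the columns a transition_params object
# expects beyond intercept/age65.
panel_design <- function(panel, params) {
  cols <- setdiff(colnames(params), c("intercept", "age65"))
  n <- nrow(panel)
  X <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  spec <- attr(params, "spec")
  if ("gender" %in% cols) X[, "gender"] <- panel$gender
  if (spec == "childhood") {
    X[, "sesMedium"] <- as.numeric(panel$ses == 1)
    X[, "sesHigh"] <- as.numeric(panel$ses == 2)
  } else if (spec == "trajectory") {
    for (j in 2:9) X[, paste0("traj", j)] <- as.numeric(panel$ses == j)
  }
  X
}

# Consecutive-record observation intervals, precomputed once per dataset.
panel_intervals <- function(panel, params) {
  panel <- panel[order(panel$subject, panel$age), , drop = FALSE]
  idx <- seq_len(nrow(panel) - 1L)
  same <- panel$subject[idx] == panel$subject[idx + 1L]
  from <- idx[same]
  to <- from + 1L
  if (any(panel$age[to] <= panel$age[from]))
    stop("ages must be strictly increasing within subject")
  if (any(panel$state[from] == 3L))
    stop("observations after death in panel")
  list(age1 = panel$age[from],
       dt = panel$age[to] - panel$age[from],
       s1 = panel$state[from],
       s2 = panel$state[to],
       exact = panel$exact[to],
       X = panel_design(panel[from, , drop = FALSE], params))
}

nll_from_intervals <- function(iv, params, h = 0.1,
                               age_update = c("substep", "interval")) {
  age_update <- match.arg(age_update)
  off <- rate_offsets(params, iv$X)
  slopes <- unclass(params)[, "age65"]
  if (anyNA(off) || any(off == Inf)) return(Inf)
  P <- if (age_update == "substep") {
    living_product(off, slopes, iv$age1, iv$dt, h)
  } else {
    a <- exp(off[, 1] + slopes[1] * (iv$age1 - 65))
    b <- exp(off[, 2] + slopes[2] * (iv$age1 - 65))
    cc <- exp(off[, 3] + slopes[3] * (iv$age1 - 65))
    d <- exp(off[, 4] + slopes[4] * (iv$age1 - 65))
    s <- expm_living(a, b, cc, d, iv$dt)
    c(s, list(last_age = iv$age1))
  }
  from1 <- iv$s1 == 1L
  p11 <- ifelse(from1, P$P11, P$P21)
  p12 <- ifelse(from1, P$P12, P$P22)
  pr <- numeric(length(iv$age1))
  liv <- iv$s2 != 3L
  pr[liv] <- ifelse(iv$s2[liv] == 1L, p11[liv], p12[liv])
  dead <- !liv
  if (any(dead)) {
    ex <- dead & iv$exact
    cen <- dead & !iv$exact
    if (any(ex)) {
      q13 <- exp(off[ex, 2] + slopes[2] * (P$last_age[ex] - 65))
      q23 <- exp(off[ex, 4] + slopes[4] * (P$last_age[ex] - 65))
      pr[ex] <- p11[ex] * q13 + p12[ex] * q23
    }
    if (any(cen)) pr[cen] <- pmax(1 - p11[cen] - p12[cen], 0)
  }
  if (any(!is.finite(pr)) || any(pr <= 0)) return(Inf)
  -sum(log(pr))
}

#' Negative log-likelihood of a panel under given transition parameters
#'
#' The likelihood is the standard panel-data Markov likelihood: for each
#' pair of consecutive records of a subject, a living destination state
#' contributes the interval transition probability; an exactly dated death
#' contributes the probability of surviving the interval in some living
#' state times that state's instantaneous death intensity at the death age
#' (the unobserved pre-death state is summed out). Intensities are held
#' piecewise-constant on a 0.1-year age lattice within each interval by
#' default (`age_update = "substep"`); `"interval"` instead freezes
#' covariate age at the interval's left endpoint.
#'
#' A parameter set giving a zero-probability observation returns `+Inf`
#' rather than raising, so optimizers can recover.
#'
#' @param panel a panel data frame (subject, age, state, exact, gender,
#'   ses) already passing [apply_inclusion_criteria()].
#' @param params a [transition_params()] object.
#' @param h lattice step in years.
#' @param age_update `"substep"` or `"interval"`.
#' @return the negative log-likelihood (scalar, possibly `Inf`).
#' @export
negative_log_likelihood <- function(panel, params, h = 0.1,
                                    age_update = c("substep", "interval")) {
  iv <- panel_intervals(panel, params)
  nll_from_intervals(iv, params, h, match.arg(age_update))
}

#' Fit the three-state model to interval-censored panel data
#'
#' Maximum-likelihood estimation by bounded quasi-Newton (L-BFGS-B) with
#' parameter scaling; intercepts are bounded at +/- 20 on the log scale to
#' avoid overflow, other coefficients at +/- 5. The covariance matrix is
#' the inverse of the finite-difference observed information at the
#' optimum. Because published results are reported per gender, the default
#' stratifies the fit by gender (no gender column in either stratum);
#' `gender_mode = "pooled"` fits one model with a gender main effect.
#'
#' @param panel panel data frame including `gender` and `ses` columns and
#'   an inclusion-filtered structure (>= 2 records per subject).
#' @param spec covariate specification, `"childhood"` (2 dummies) or
#'   `"trajectory"` (8 dummies); defaults to the panel's `ses_spec`
#'   attribute.
#' @param gender_mode `"stratify"` or `"pooled"`.
#' @param init optional [transition_params()] starting values.
#' @param h,age_update see [negative_log_likelihood()].
#' @param max_iter optimizer iteration cap.
#' @return an object of class `msm_fit` (or `msm_fit_strata`, a list of
#'   two `msm_fit`s, when stratified): parameter estimates, covariance,
#'   log-likelihood, convergence/boundary flags and interval transition
#'   counts.
#' @export
fit_msm <- function(panel, spec = attr(panel, "ses_spec"),
                    gender_mode = c("stratify", "pooled"), init = NULL,
                    h = 0.1, age_update = c("substep", "interval"),
                    max_iter = 500) {
  gender_mode <- match.arg(gender_mode)
  age_update <- match.arg(age_update)
  if (is.null(spec)) spec <- "none"
  if (gender_mode == "stratify") {
    fits <- lapply(c(female = 0, male = 1), function(g) {
      sub <- panel[panel$gender == g, , drop = FALSE]
      attr(sub, "ses_spec") <- spec
      fit_msm(sub, spec = spec, gender_mode = "pooled", init = init,
              h = h, age_update = age_update, max_iter = max_iter)
    })
    # stratified fits carry no gender column: rebuild without it
    return(structure(fits, class = "msm_fit_strata", spec = spec))
  }
  stratified <- length(unique(panel$gender)) == 1L
  if (is.null(init)) {
    init <- transition_params(
      intercepts = log(c(0.2, 0.05, 0.2, 0.1)),
      age_slopes = rep(0, 4),
      gender_coefs = if (stratified) NULL else rep(0, 4),
      ses_coefs = if (spec == "none") NULL else
        matrix(0, 4, length(ses_dummy_names(spec))),
      spec = spec)
  }
  iv <- panel_intervals(panel, init)

  # Precondition: standardise the covariate columns (age, gender, dummies)
  # inside the optimisation, so the quasi-Newton search is not crippled by
  # the strong intercept/age-slope collinearity. theta = A %*% gamma where
  # per transition beta_j = gamma_j / s_j and
  # beta_0 = gamma_0 - sum_j c_j gamma_j / s_j.
  p <- unclass(init)
  ncov <- ncol(p) - 1L
  agemid <- iv$age1 + iv$dt / 2 - 65
  cvals <- c(mean(agemid),
             if (ncov > 1L) colMeans(iv$X) else NULL)
  svals <- c(max(stats::sd(agemid), 1), rep(1, ncov - 1L))
  Ablk <- diag(1 / c(1, svals))
  Ablk[1, -1] <- -cvals / svals
  A <- kronecker(Ablk, diag(4))  # theta ordered column-major: 4 per column
  Ainv <- solve(A)
  cache <- new.env(parent = emptyenv())
  evalpt <- function(gamma) {
    key <- paste(gamma, collapse = ",")
    if (!identical(cache$key, key)) {
      res <- nll_and_grad(iv, vector_to_params(drop(A %*% gamma), init),
                          h, age_update)
      cache$key <- key
      cache$nll <- if (is.finite(res$nll)) res$nll else 1e10
      cache$grad <- drop(t(A) %*% res$grad)
    }
    cache
  }
  fn <- function(gamma) evalpt(gamma)$nll
  gr <- function(gamma) evalpt(gamma)$grad
  gamma0 <- drop(Ainv %*% params_to_vector(init))
  is_int <- as.numeric(col(p) == 1L)
  lower <- ifelse(is_int == 1, -20, -5 * rep(c(1, svals), each = 4))
  upper <- -lower
  gamma0 <- pmin(pmax(gamma0, lower + 1e-8), upper - 1e-8)
  opt <- stats::optim(gamma0, fn, gr, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = max_iter, factr = 1e5,
                                     pgtol = 1e-8))
  theta_hat <- drop(A %*% opt$par)
  est <- vector_to_params(theta_hat, init)
  hess <- try(stats::optimHess(opt$par, fn, gr), silent = TRUE)
  vc <- NULL
  vcov_ok <- FALSE
  if (!inherits(hess, "try-error") && all(is.finite(hess))) {
    vcg <- try(solve(hess), silent = TRUE)
    if (!inherits(vcg, "try-error") &&
        all(is.finite(vcg)) && all(diag(vcg) > -1e-8)) {
      vcov_ok <- TRUE
      vc <- A %*% ((vcg + t(vcg)) / 2) %*% t(A)
    }
  }
  if (!vcov_ok) {
    vc <- if (!inherits(hess, "try-error") && all(is.finite(hess))) {
      A %*% MASS::ginv(hess) %*% t(A)
    } else matrix(NA_real_, length(gamma0), length(gamma0))
    vc <- (vc + t(vc)) / 2
  }
  at_bound <- any(abs(opt$par - lower) < 1e-6 | abs(opt$par - upper) < 1e-6)
  grad <- gr(opt$par)
  counts <- table(factor(iv$s1, 1:2), factor(iv$s2, 1:3))
  dimnames(counts) <- list(from = c("robust", "frailty"),
                           to = c("robust", "frailty", "dead"))
  structure(list(params = est, vcov = vc, logLik = -opt$value,
                 converged = opt$convergence == 0 && !at_bound,
                 boundary = at_bound, vcov_ok = vcov_ok,
                 grad_norm = max(abs(grad)),
                 counts = counts, spec = spec,
                 stratified = stratified, h = h, age_update = age_update,
                 n_subjects = length(unique(panel$subject)),
                 n_intervals = length(iv$age1),
                 optim_convergence = opt$convergence),
            class = "msm_fit")
}

#' @export
print.msm_fit <- function(x, ...) {
  cat("Three-state panel Markov model fit (spec: ", x$spec,
      if (x$stratified) ", gender-stratified stratum" else ", pooled",
      ")\n", sep = "")
  cat("  subjects:", x$n_subjects, " intervals:", x$n_intervals,
      " logLik:", format(x$logLik, digits = 8), "\n")
  cat("  converged:", x$converged,
      if (x$boundary) " (parameter at bound)" else "", "\n")
  se <- matrix(sqrt(pmax(diag(x$vcov), 0)), 4)
  est <- unclass(x$params)
  out <- matrix(sprintf("%.3f (%.3f)", est, se), 4,
                dimnames = dimnames(est))
  print(out, quote = FALSE)
  invisible(x)
}

#' Standard errors of the fitted coefficients
#' @param fit an `msm_fit`.
#' @return matrix shaped like the parameter matrix.
#' @export
msm_se <- function(fit) {
  m <- unclass(fit$params)
  se <- matrix(sqrt(pmax(diag(fit$vcov), 0)), nrow(m), ncol(m),
               dimnames = dimnames(m))
  se
}
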