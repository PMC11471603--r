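#' Transition parameter sets for the three-state frailty model
#'
#' The model has three states: 1 = robust (frailty index <= 0.10),
#' 2 = frailty (FI > 0.10), 3 = dead (absorbing). Four instantaneous
#' transitions are allowed (1->2, 1->3, 2->1, 2->3); each carries a
#' log-linear intensity
#' \deqn{q_{rs}(age, x) = \exp\{\beta_0 + \beta_a (age - 65) + \beta_g g +
#'   \sum_k \beta_k x_k\}}
#' where `g` is gender (male = 1, female = 0) and `x_k` are dummy
#' indicators for the socioeconomic category (childhood SES medium/high
#' against low) or life-course trajectory (codes 2..9 against low-low).
#'
#' A `transition_params` object is a numeric matrix with one row per
#' allowed transition (`"1-2"`, `"1-3"`, `"2-1"`, `"2-3"`) and columns
#' `intercept`, `age65`, optionally `gender`, and the SES dummy columns
#' implied by `spec`.
#'
#' @param intercepts named or ordered numeric length-4 vector of log
#'   intensities at the reference profile (age 65, female, reference SES),
#'   in transition order 1-2, 1-3, 2-1, 2-3.
#' @param age_slopes numeric length-4, per-year log-intensity slopes.
#' @param gender_coefs numeric length-4 or `NULL` to omit the gender column
#'   (used for gender-stratified fits).
#' @param ses_coefs numeric matrix (4 x number of dummies) or `NULL`; column
#'   count must match `spec` (2 for `"childhood"`, 8 for `"trajectory"`).
#' @param spec one of `"none"`, `"childhood"`, `"trajectory"`.
#' @return a `transition_params` matrix.
#' @seealso [default_truth()] for the calibrated simulator defaults,
#'   [build_intensity_matrix()] for the resulting generator.
#' @export
transition_params <- function(intercepts, age_slopes,
                              gender_coefs = NULL, ses_coefs = NULL,
                              spec = c("none", "childhood", "trajectory")) {
  spec <- match.arg(spec)
  stopifnot(length(intercepts) == 4L, length(age_slopes) == 4L)
  dummies <- ses_dummy_names(spec)
  if (spec == "none") {
    if (!is.null(ses_coefs)) stop("ses_coefs given but spec is 'none'")
    ses_coefs <- matrix(numeric(0), nrow = 4L, ncol = 0L)
  } else {
    if (is.null(ses_coefs)) stop("spec '", spec, "' requires ses_coefs")
    ses_coefs <- as.matrix(ses_coefs)
    if (nrow(ses_coefs) != 4L || ncol(ses_coefs) != length(dummies))
      stop("ses_coefs must be 4 x ", length(dummies), " for spec '", spec, "'")
  }
  cols <- c("intercept", "age65",
            if (!is.null(gender_coefs)) "gender", dummies)
  m <- cbind(intercept = as.numeric(intercepts),
             age65 = as.numeric(age_slopes))
  if (!is.null(gender_coefs)) {
    stopifnot(length(gender_coefs) == 4L)
    m <- cbind(m, gender = as.numeric(gender_coefs))
  }
  if (ncol(ses_coefs) > 0L) {
    colnames(ses_coefs) <- dummies
    m <- cbind(m, ses_coefs)
  }
  rownames(m) <- transition_names()
  colnames(m) <- cols
  # -Inf intercept switches a transition off (zero intensity at all ages)
  if (any(is.na(m)) || any(m[, -1] %in% c(Inf, -Inf)) ||
      any(m[, 1] == Inf))
    stop("transition parameters must be finite (intercepts may be -Inf)")
  structure(m, spec = spec, class = c("transition_params", "matrix"))
}

transition_names <- function() c("1-2", "1-3", "2-1", "2-3")

ses_dummy_names <- function(spec) {
  switch(spec,
         none = character(0),
         childhood = c("sesMedium", "sesHigh"),
         trajectory = paste0("traj", 2:9))
}

#' @export
print.transition_params <- function(x, ...) {
  cat("Log-linear transition intensity parameters (spec: ",
      attr(x, "spec"), ")\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Dummy encoding of an SES value under a covariate specification
#'
#' @param spec `"none"`, `"childhood"` or `"trajectory"`.
#' @param value childhood category in 0:2 (0 low, 1 medium, 2 high) or
#'   trajectory code in 1:9 (1 = low-low reference, ... 9 = high-high).
#' @return named 0/1 vector of the spec's dummy columns.
#' @export
ses_dummies <- function(spec, value) {
  nm <- ses_dummy_names(spec)
  out <- stats::setNames(numeric(length(nm)), nm)
  if (spec == "childhood") {
    if (!value %in% 0:2) stop("childhood SES category must be 0, 1 or 2")
    if (value == 1) out["sesMedium"] <- 1
    if (value == 2) out["sesHigh"] <- 1
  } else if (spec == "trajectory") {
    if (!value %in% 1:9) stop("trajectory code must be in 1..9")
    if (value > 1) out[paste0("traj", value)] <- 1
  } else if (length(value) && !is.na(value) && !identical(value, 0)) {
    # spec "none": no SES columns; any value is ignored
  }
  out
}

# Row of the non-age covariate design (matching params columns after
# intercept/age65) for one profile.
profile_row <- function(params, gender, ses) {
  spec <- attr(params, "spec")
  cols <- colnames(params)
  x <- numeric(0)
  if ("gender" %in% cols) x <- c(gender = as.numeric(gender))
  c(x, ses_dummies(spec, ses))
}

# Per-observation rate offsets: o[i, t] = intercept_t + x_i . beta_t,
# excluding the age term. X is the covariate matrix with columns matching
# params columns 3..p (possibly zero columns).
rate_offsets <- function(params, X) {
  p <- unclass(params)
  covcols <- setdiff(colnames(p), c("intercept", "age65"))
  n <- if (is.null(nrow(X))) 1L else nrow(X)
  off <- matrix(rep(p[, "intercept"], each = n), nrow = n,
                dimnames = list(NULL, rownames(p)))
  if (length(covcols)) {
    X <- as.matrix(X)[, covcols, drop = FALSE]
    off <- off + X %*% t(p[, covcols, drop = FALSE])
  }
  off
}

#' Transition intensities for one covariate profile across ages
#'
#' @param params a [transition_params()] object.
#' @param age numeric vector of ages in years.
#' @param gender 0 (female) or 1 (male); ignored if the parameters carry no
#'   gender column (stratified fits).
#' @param ses SES category (0:2) or trajectory code (1:9) per the spec.
#' @return matrix `length(age)` x 4 with columns `q12, q13, q21, q23`.
#' @export
transition_rates <- function(params, age, gender = 0, ses = 0) {
  x <- profile_row(params, gender, ses)
  off <- rate_offsets(params, matrix(x, nrow = 1,
                                     dimnames = list(NULL, names(x))))
  sl <- unclass(params)[, "age65"]
  out <- exp(outer(age - 65, sl, `*`) + matrix(off, nrow = length(age),
                                               ncol = 4L, byrow = TRUE))
  colnames(out) <- c("q12", "q13", "q21", "q23")
  out
}

#' Generator matrix of the three-state model at one age and profile
#'
#' Builds the 3x3 transition intensity matrix Q: off-diagonals are the four
#' allowed log-linear intensities, diagonals make rows sum to zero, and the
#' dead row is identically zero.
#'
#' @inheritParams transition_rates
#' @param age a single age in years, in `[65, 130]`.
#' @return 3x3 numeric matrix.
#' @export
build_intensity_matrix <- function(params, age, gender = 0, ses = 0) {
  stopifnot(length(age) == 1L)
  if (age < 65 || age > 130) stop("age must lie in [65, 130]")
  q <- transition_rates(params, age, gender, ses)[1L, ]
  if (!all(is.finite(q))) stop("non-finite transition intensity")
  Q <- matrix(0, 3, 3, dimnames = list(1:3, 1:3))
  Q[1, 2] <- q[["q12"]]; Q[1, 3] <- q[["q13"]]
  Q[2, 1] <- q[["q21"]]; Q[2, 3] <- q[["q23"]]
  diag(Q) <- -rowSums(Q)
  Q
}

# Flatten/unflatten for the optimizer.
params_to_vector <- function(params) as.numeric(unclass(params))

vector_to_params <- function(theta, template) {
  out <- template
  out[] <- theta
  out
}
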