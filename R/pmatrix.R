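# Transition probabilities of the three-state generator.
#
# Because death is absorbing, exp(Q t) is determined by the exponential of
# the 2x2 living-state block
#     M = [ -(a+b)   a   ]        a = q12, b = q13,
#         [   c    -(c+d)]        c = q21, d = q23,
# whose eigenvalues are always real (the discriminant is
# (m11 - m22)^2 + 4ac >= 0), so a closed spectral form is safe. All kernels
# below are vectorised over (a, b, c, d, t) so the panel likelihood can
# evaluate thousands of observation intervals in a handful of vector ops.

# Living-block entries of exp(M t); returns list(P11, P12, P21, P22).
# Overflow-safe: both eigenvalues are <= 0, so exp(lambda t) <= 1.
expm_living <- function(a, b, c, d, t) {
  m11 <- -(a + b)
  m22 <- -(c + d)
  tr <- m11 + m22
  dif <- m11 - m22
  disc <- sqrt(dif * dif + 4 * a * c)
  e1 <- exp((tr + disc) / 2 * t)
  e2 <- exp((tr - disc) / 2 * t)
  # exp(Mt) = ((e1+e2)/2) I + w (M - (tr/2) I); near-defective case
  # (disc*t ~ 0) via the limit w -> t exp(tr t / 2)
  small <- disc * t < 1e-7
  w <- (e1 - e2) / ifelse(disc == 0, 1, disc)
  if (any(small)) {
    Emid <- exp(tr * t / 2)
    w <- ifelse(small, (if (length(t) == 1L) rep(t, length(w)) else t) *
                  Emid, w)
    half <- ifelse(small, Emid, (e1 + e2) / 2)
  } else half <- (e1 + e2) / 2
  hd <- w * dif / 2
  list(P11 = pmax(half + hd, 0), P12 = pmax(w * a, 0),
       P21 = pmax(w * c, 0), P22 = pmax(half - hd, 0))
}

#' Transition probability matrix over an interval of constant intensities
#'
#' Computes `P(t) = expm(Q t)` for the three-state generator with constant
#' intensities, via the closed-form exponential of the 2x2 living block.
#'
#' @param Q 3x3 generator matrix (see [build_intensity_matrix()]).
#' @param t elapsed time in years (scalar, >= 0).
#' @return 3x3 stochastic matrix.
#' @export
pmatrix_const <- function(Q, t) {
  stopifnot(t >= 0, all(dim(Q) == c(3L, 3L)))
  p <- expm_living(Q[1, 2], Q[1, 3], Q[2, 1], Q[2, 3], t)
  P <- matrix(c(p$P11, p$P12, 1 - p$P11 - p$P12,
                p$P21, p$P22, 1 - p$P21 - p$P22,
                0, 0, 1), nrow = 3, byrow = TRUE,
              dimnames = list(1:3, 1:3))
  P[, 3] <- pmax(P[, 3], 0)
  P
}

# Age-inhomogeneous product of living-block steps.
#
# For n observation intervals starting at ages `age1` with lengths `dt`,
# accumulates prod_k expm(M(a_k) h) over a left-endpoint piecewise-constant
# lattice of step `h` (plus a final partial step for the remainder).
# Because ages advance by exactly h per full substep, each intensity
# updates by the scalar factor exp(slope * h); the only per-row exp calls
# are the initial rates and the two eigenvalue exponentials inside
# expm_living. Intervals are processed sorted by step count so the active
# set is always a prefix.
#
# `off` is the n x 4 matrix of non-age log-intensity offsets (from
# rate_offsets()), `slopes` the per-transition age slopes. Returns the
# accumulated living-block entries plus `last_age`, the left endpoint of
# the final substep (where an exact-death intensity is evaluated), in the
# original row order.
living_product <- function(off, slopes, age1, dt, h = 0.1) {
  n <- length(age1)
  nfull <- floor(dt / h + 1e-9)
  rem <- pmax(dt - nfull * h, 0)
  rem[rem < 1e-9] <- 0
  ord <- order(nfull, decreasing = TRUE)
  nfull_s <- nfull[ord]
  rem_s <- rem[ord]
  age_s <- age1[ord]
  # clamp so extreme optimizer probes cannot overflow to Inf/NaN
  a <- pmin(exp(off[ord, 1] + slopes[1] * (age_s - 65)), 1e10)
  b <- pmin(exp(off[ord, 2] + slopes[2] * (age_s - 65)), 1e10)
  cc <- pmin(exp(off[ord, 3] + slopes[3] * (age_s - 65)), 1e10)
  d <- pmin(exp(off[ord, 4] + slopes[4] * (age_s - 65)), 1e10)
  fac <- exp(slopes * h)
  A11 <- rep(1, n); A12 <- numeric(n)
  A21 <- numeric(n); A22 <- rep(1, n)
  kmax <- if (n) nfull_s[1] else 0L
  k <- 0L
  while (k < kmax) {
    m <- sum(nfull_s > k)          # active prefix
    i <- seq_len(m)
    s <- expm_living(a[i], b[i], cc[i], d[i], h)
    n11 <- A11[i] * s$P11 + A12[i] * s$P21
    n12 <- A11[i] * s$P12 + A12[i] * s$P22
    n21 <- A21[i] * s$P11 + A22[i] * s$P21
    n22 <- A21[i] * s$P12 + A22[i] * s$P22
    A11[i] <- n11; A12[i] <- n12; A21[i] <- n21; A22[i] <- n22
    a[i] <- a[i] * fac[1]; b[i] <- b[i] * fac[2]
    cc[i] <- cc[i] * fac[3]; d[i] <- d[i] * fac[4]
    k <- k + 1L
  }
  last_age <- age_s + pmax(nfull_s - 1L, 0L) * h
  i <- which(rem_s > 0)
  if (length(i)) {
    s <- expm_living(a[i], b[i], cc[i], d[i], rem_s[i])
    n11 <- A11[i] * s$P11 + A12[i] * s$P21
    n12 <- A11[i] * s$P12 + A12[i] * s$P22
    n21 <- A21[i] * s$P11 + A22[i] * s$P21
    n22 <- A21[i] * s$P12 + A22[i] * s$P22
    A11[i] <- n11; A12[i] <- n12; A21[i] <- n21; A22[i] <- n22
    last_age[i] <- age_s[i] + nfull_s[i] * h
  }
  inv <- integer(n)
  inv[ord] <- seq_len(n)
  list(P11 = A11[inv], P12 = A12[inv], P21 = A21[inv], P22 = A22[inv],
       last_age = last_age[inv])
}
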