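# Analytic score of the panel likelihood.
#
# Each interval's living-block probability is a product of closed-form
# 2x2 exponentials S_k over lattice substeps. Every model parameter
# enters S_k only through the four rates (log-linearly), so
#   dP/dtheta_j = sum_k L_{k-1} [x_j(k) G_t(k)] R_{k+1},
# where G_t(k) = rate_t * dS_k/drate_t, t is the parameter's transition,
# and x_j(k) is its design value (1, gender, dummy, or age_k - 65 for the
# slope). A forward pass stores prefixes L and step rates; a backward
# pass maintains suffixes R and accumulates, per transition,
#   U_t = sum_k L G_t R   and   V_t = sum_k (age_k - 65) L G_t R,
# from which all coefficient derivatives follow by scaling with the
# interval's covariates. Cost is a small multiple of the likelihood
# itself, independent of the number of parameters.

# Derivatives of the living-block exponential entries with respect to the
# four rates, times the rates (log-scale derivatives). `tau` is the step
# length (scalar or vector). Returns list over transitions 1-2,1-3,2-1,2-3
# of 4-entry lists (d11, d12, d21, d22).
expm_living_lograte_grad <- function(a, b, c, d, tau) {
  u <- -(a + b + c + d) / 2
  dl <- (-a - b + c + d) / 2          # delta
  v <- sqrt(dl * dl + a * c)
  vs <- pmax(v, 1e-12)
  e1 <- exp((u + v) * tau)
  e2 <- exp((u - v) * tau)
  half <- (e1 + e2) / 2
  w <- (e1 - e2) / (2 * vs)
  small <- v * tau < 1e-7
  if (any(small)) {
    Emid <- exp(u * tau)
    w <- ifelse(small, tau * Emid, w)
  }
  one <- function(ddl, dac2) {
    du <- -0.5
    dv <- (dl * ddl + dac2) / vs
    de1 <- e1 * tau * (du + dv)
    de2 <- e2 * tau * (du - dv)
    dhalf <- (de1 + de2) / 2
    dw <- (de1 - de2) / (2 * vs) - w * dv / vs
    list(dhalf = dhalf, dw = dw, ddl = ddl)
  }
  ga <- one(-0.5, c / 2)
  gb <- one(-0.5, 0)
  gc <- one(0.5, a / 2)
  gd <- one(0.5, 0)
  pack <- function(g, isa, isc) {
    d11 <- g$dhalf + g$dw * dl + w * g$ddl
    d22 <- g$dhalf - g$dw * dl - w * g$ddl
    d12 <- g$dw * a + if (isa) w else 0
    d21 <- g$dw * c + if (isc) w else 0
    list(d11 = d11, d12 = d12, d21 = d21, d22 = d22)
  }
  scale4 <- function(p, r) lapply(p, function(z) z * r)
  list(`1-2` = scale4(pack(ga, TRUE, FALSE), a),
       `1-3` = scale4(pack(gb, FALSE, FALSE), b),
       `2-1` = scale4(pack(gc, FALSE, TRUE), c),
       `2-3` = scale4(pack(gd, FALSE, FALSE), d))
}

mm2 <- function(x11, x12, x21, x22, y11, y12, y21, y22) {
  list(x11 * y11 + x12 * y21, x11 * y12 + x12 * y22,
       x21 * y11 + x22 * y21, x21 * y12 + x22 * y22)
}

# Likelihood and analytic score for precomputed intervals. Returns
# list(nll, grad) with grad in the parameter-vector (column-major) order,
# or nll = Inf and a zero gradient for inadmissible parameters.
nll_and_grad <- function(iv, params, h = 0.1,
                         age_update = c("substep", "interval")) {
  age_update <- match.arg(age_update)
  off <- rate_offsets(params, iv$X)
  slopes <- unclass(params)[, "age65"]
  npar <- length(params_to_vector(params))
  if (anyNA(off) || any(off == Inf))
    return(list(nll = Inf, grad = numeric(npar)))
  n <- length(iv$age1)

  if (age_update == "interval") {
    nfull <- integer(n)
    rem <- iv$dt
  } else {
    nfull <- floor(iv$dt / h + 1e-9)
    rem <- pmax(iv$dt - nfull * h, 0)
    rem[rem < 1e-9] <- 0
  }
  ord <- order(nfull, decreasing = TRUE)
  nfull_s <- nfull[ord]; rem_s <- rem[ord]; age_s <- iv$age1[ord]
  a <- pmin(exp(off[ord, 1] + slopes[1] * (age_s - 65)), 1e10)
  b <- pmin(exp(off[ord, 2] + slopes[2] * (age_s - 65)), 1e10)
  cc <- pmin(exp(off[ord, 3] + slopes[3] * (age_s - 65)), 1e10)
  d <- pmin(exp(off[ord, 4] + slopes[4] * (age_s - 65)), 1e10)
  fac <- exp(slopes * h)
  kmax <- if (n) nfull_s[1] else 0L
  mk <- if (kmax > 0) vapply(seq_len(kmax), function(k) sum(nfull_s >= k),
                             integer(1)) else integer(0)

  A11 <- rep(1, n); A12 <- numeric(n); A21 <- numeric(n); A22 <- rep(1, n)
  Lst <- vector("list", kmax)   # prefix before step k
  Rate <- vector("list", kmax)  # rates at step k
  for (k in seq_len(kmax)) {
    i <- seq_len(mk[k])
    Lst[[k]] <- list(A11[i], A12[i], A21[i], A22[i])
    Rate[[k]] <- list(a[i], b[i], cc[i], d[i])
    s <- expm_living(a[i], b[i], cc[i], d[i], h)
    nw <- mm2(A11[i], A12[i], A21[i], A22[i], s$P11, s$P12, s$P21, s$P22)
    A11[i] <- nw[[1]]; A12[i] <- nw[[2]]; A21[i] <- nw[[3]]; A22[i] <- nw[[4]]
    a[i] <- a[i] * fac[1]; b[i] <- b[i] * fac[2]
    cc[i] <- cc[i] * fac[3]; d[i] <- d[i] * fac[4]
  }
  # partial step (rates now at age1 + nfull*h)
  has_rem <- rem_s > 0
  Sp <- list(P11 = rep(1, n), P12 = numeric(n),
             P21 = numeric(n), P22 = rep(1, n))
  if (any(has_rem)) {
    i <- which(has_rem)
    s <- expm_living(a[i], b[i], cc[i], d[i], rem_s[i])
    Sp$P11[i] <- s$P11; Sp$P12[i] <- s$P12
    Sp$P21[i] <- s$P21; Sp$P22[i] <- s$P22
  }
  Lfull <- list(A11, A12, A21, A22)
  fin <- mm2(A11, A12, A21, A22, Sp$P11, Sp$P12, Sp$P21, Sp$P22)
  P11 <- fin[[1]]; P12 <- fin[[2]]; P21 <- fin[[3]]; P22 <- fin[[4]]
  last_age <- age_s + ifelse(has_rem, nfull_s * h,
                             pmax(nfull_s - 1L, 0L) * h)

  # backward pass: U_t, V_t accumulators (entries x transitions), and the
  # suffix product R
  U <- lapply(1:4, function(t) list(numeric(n), numeric(n),
                                    numeric(n), numeric(n)))
  V <- lapply(1:4, function(t) list(numeric(n), numeric(n),
                                    numeric(n), numeric(n)))
  R11 <- rep(1, n); R12 <- numeric(n); R21 <- numeric(n); R22 <- rep(1, n)
  add_contrib <- function(idx, L, G, R11i, R12i, R21i, R22i, xage) {
    for (t in 1:4) {
      g <- G[[t]]
      lg <- mm2(L[[1]], L[[2]], L[[3]], L[[4]],
                g$d11, g$d12, g$d21, g$d22)
      hgt <- mm2(lg[[1]], lg[[2]], lg[[3]], lg[[4]],
                 R11i, R12i, R21i, R22i)
      for (e in 1:4) {
        U[[t]][[e]][idx] <<- U[[t]][[e]][idx] + hgt[[e]]
        V[[t]][[e]][idx] <<- V[[t]][[e]][idx] + xage * hgt[[e]]
      }
    }
  }
  if (any(has_rem)) {
    i <- which(has_rem)
    G <- expm_living_lograte_grad(a[i], b[i], cc[i], d[i], rem_s[i])
    add_contrib(i, lapply(Lfull, `[`, i), G,
                R11[i], R12[i], R21[i], R22[i],
                age_s[i] + nfull_s[i] * h - 65)
    R11[i] <- Sp$P11[i]; R12[i] <- Sp$P12[i]
    R21[i] <- Sp$P21[i]; R22[i] <- Sp$P22[i]
  }
  for (k in rev(seq_len(kmax))) {
    i <- seq_len(mk[k])
    r <- Rate[[k]]
    G <- expm_living_lograte_grad(r[[1]], r[[2]], r[[3]], r[[4]], h)
    add_contrib(i, Lst[[k]], G, R11[i], R12[i], R21[i], R22[i],
                age_s[i] + (k - 1L) * h - 65)
    s <- expm_living(r[[1]], r[[2]], r[[3]], r[[4]], h)
    nw <- mm2(s$P11, s$P12, s$P21, s$P22, R11[i], R12[i], R21[i], R22[i])
    R11[i] <- nw[[1]]; R12[i] <- nw[[2]]; R21[i] <- nw[[3]]; R22[i] <- nw[[4]]
  }

  # contribution weights dpr/dP and direct exact-death terms
  s1 <- iv$s1[ord]; s2 <- iv$s2[ord]; exact <- iv$exact[ord]
  from1 <- s1 == 1L
  w11 <- numeric(n); w12 <- numeric(n); w21 <- numeric(n); w22 <- numeric(n)
  pr <- numeric(n)
  liv1 <- s2 == 1L; liv2 <- s2 == 2L
  pr[liv1 & from1] <- P11[liv1 & from1]; w11[liv1 & from1] <- 1
  pr[liv2 & from1] <- P12[liv2 & from1]; w12[liv2 & from1] <- 1
  pr[liv1 & !from1] <- P21[liv1 & !from1]; w21[liv1 & !from1] <- 1
  pr[liv2 & !from1] <- P22[liv2 & !from1]; w22[liv2 & !from1] <- 1
  dead <- s2 == 3L
  q13 <- q23 <- numeric(n)
  ex <- dead & exact
  if (any(ex)) {
    q13[ex] <- exp(off[ord, 2][ex] + slopes[2] * (last_age[ex] - 65))
    q23[ex] <- exp(off[ord, 4][ex] + slopes[4] * (last_age[ex] - 65))
    i <- ex & from1
    pr[i] <- P11[i] * q13[i] + P12[i] * q23[i]
    w11[i] <- q13[i]; w12[i] <- q23[i]
    i <- ex & !from1
    pr[i] <- P21[i] * q13[i] + P22[i] * q23[i]
    w21[i] <- q13[i]; w22[i] <- q23[i]
  }
  cen <- dead & !exact
  if (any(cen)) {
    i <- cen & from1
    pr[i] <- pmax(1 - P11[i] - P12[i], 0)
    w11[i] <- -1; w12[i] <- -1
    i <- cen & !from1
    pr[i] <- pmax(1 - P21[i] - P22[i], 0)
    w21[i] <- -1; w22[i] <- -1
  }
  if (any(!is.finite(pr)) || any(pr <= 0))
    return(list(nll = Inf, grad = numeric(npar)))
  nll <- -sum(log(pr))

  invpr <- 1 / pr
  # per-transition derivative of pr for a constant unit log-rate bump
  # (base) and for an (age - 65)-weighted bump (slope part)
  base <- matrix(0, n, 4)
  slp <- matrix(0, n, 4)
  for (t in 1:4) {
    base[, t] <- w11 * U[[t]][[1]] + w12 * U[[t]][[2]] +
      w21 * U[[t]][[3]] + w22 * U[[t]][[4]]
    slp[, t] <- w11 * V[[t]][[1]] + w12 * V[[t]][[2]] +
      w21 * V[[t]][[3]] + w22 * V[[t]][[4]]
  }
  # direct dependence of the exact-death intensity factor
  if (any(ex)) {
    i1 <- ex & from1; i2 <- ex & !from1
    d13 <- numeric(n); d23 <- numeric(n)
    d13[i1] <- P11[i1] * q13[i1]; d23[i1] <- P12[i1] * q23[i1]
    d13[i2] <- P21[i2] * q13[i2]; d23[i2] <- P22[i2] * q23[i2]
    base[, 2] <- base[, 2] + d13
    base[, 4] <- base[, 4] + d23
    slp[, 2] <- slp[, 2] + d13 * (last_age - 65)
    slp[, 4] <- slp[, 4] + d23 * (last_age - 65)
  }
  X <- iv$X[ord, , drop = FALSE]
  p <- unclass(params)
  grad <- matrix(0, 4, ncol(p), dimnames = dimnames(p))
  for (t in 1:4) {
    gb <- invpr * base[, t]
    grad[t, "intercept"] <- -sum(gb)
    grad[t, "age65"] <- -sum(invpr * slp[, t])
    for (cn in colnames(X)) grad[t, cn] <- -sum(gb * X[, cn])
  }
  list(nll = nll, grad = as.numeric(grad))
}
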