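#' Calibrated default ground-truth dynamics for the cohort simulator
#'
#' Returns a [transition_params()] set whose intensities were calibrated
#' once so that the simulated cohort behaves like a Chinese oldest-old
#' longitudinal survey: the annual robust-to-frailty probability for
#' low-SES men rises from roughly 23% at 65 to roughly 51% at 95, the
#' frailty-to-robust recovery probability falls from about 20% to about 2%,
#' women have higher frailty incidence but lower mortality than men, and
#' total male life expectancy at 65 is around 14.3 years. Higher SES is
#' protective on incidence and mortality and favourable to recovery.
#'
#' @param spec `"childhood"` (two SES dummies: medium, high against low) or
#'   `"trajectory"` (eight dummies for codes 2..9 against low-low; effects
#'   are additive in the childhood and adulthood category levels, with the
#'   childhood component roughly 2.5 times the adult one).
#' @return a `transition_params` object including gender coefficients.
#' @export
default_truth <- function(spec = c("childhood", "trajectory")) {
  spec <- match.arg(spec)
  # reference profile: female, lowest SES, age 65
  intercepts <- c(`1-2` = -1.0713, `1-3` = -4.7133,
                  `2-1` = -1.7141, `2-3` = -3.5869)
  age_slopes <- c(0.0527, 0.0800, -0.0746, 0.0800)
  gender_coefs <- c(-0.12, 0.26, 0.20, 0.20)  # male = 1
  # per-level effects (childhood level, adult level) on each transition
  child_eff <- c(`1-2` = -0.095, `1-3` = -0.110, `2-1` = 0.050,
                 `2-3` = -0.055)
  adult_eff <- child_eff / 2.5
  if (spec == "childhood") {
    ses <- cbind(sesMedium = child_eff, sesHigh = 2 * child_eff)
  } else {
    codes <- 2:9
    child <- (codes - 1) %/% 3
    adult <- (codes - 1) %% 3
    ses <- outer(child_eff, child) + outer(adult_eff, adult)
    colnames(ses) <- paste0("traj", codes)
  }
  transition_params(intercepts, age_slopes, gender_coefs, ses, spec = spec)
}

#' Cohort design configuration for the simulator
#'
#' Defaults emulate the design of a multi-wave longitudinal ageing survey:
#' staggered enrolment across seven waves, follow-up visits about three
#' years apart with +/- half a year of jitter, entry ages 65 and above with
#' an oldest-old-heavy age distribution, and a female majority. The default
#' SES distribution matches the published childhood SES prevalence
#' (67.7 / 20.7 / 11.6%); for trajectory cohorts the published nine-way
#' distribution is used.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param enrollment_waves calendar offsets (years) of the enrolment waves.
#' @param wave_spacing years between follow-up visits.
#' @param wave_jitter half-width (years) of the uniform jitter on spacing.
#' @param entry_age_mean,entry_age_sd,entry_age_min,entry_age_max truncated
#'   normal entry-age distribution (minimum must be >= 65).
#' @param entry_age_dist `"truncnorm"` (default) or `"uniform"` over
#'   `[entry_age_min, entry_age_max]`.
#' @param gender_mix proportion male.
#' @param ses_spec `"childhood"` or `"trajectory"`.
#' @param ses_distribution probabilities over the 3 childhood categories or
#'   the 9 trajectory codes; must sum to 1.
#' @param entry_state `"prevalence"` (logistic-in-age frailty prevalence at
#'   entry, so older entrants are more often frail), `"robust"`, or
#'   `"frailty"`.
#' @param prevalence_coefs intercept and age slope (per year over 65) of the
#'   entry-state logistic model.
#' @param deficit_missing_rate,ses_missing_rate item-level missingness
#'   proportions in `[0, 1)`.
#' @param follow_up_years length of the observation window after the first
#'   enrolment wave.
#' @param seed master integer seed; per-subject substreams are derived from
#'   it, so subsetting a cohort does not reshuffle other subjects.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 2000,
                          enrollment_waves = c(0, 2, 4, 7, 10, 13, 16),
                          wave_spacing = 3,
                          wave_jitter = 0.5,
                          entry_age_mean = 87,
                          entry_age_sd = 11,
                          entry_age_min = 65,
                          entry_age_max = 115,
                          entry_age_dist = c("truncnorm", "uniform"),
                          gender_mix = 0.412,
                          ses_spec = c("childhood", "trajectory"),
                          ses_distribution = NULL,
                          entry_state = c("prevalence", "robust", "frailty"),
                          prevalence_coefs = c(-1.3, 0.075),
                          deficit_missing_rate = 0.03,
                          ses_missing_rate = 0.02,
                          follow_up_years = 20,
                          seed = 1) {
  ses_spec <- match.arg(ses_spec)
  entry_state <- match.arg(entry_state)
  entry_age_dist <- match.arg(entry_age_dist)
  if (is.null(ses_distribution)) {
    ses_distribution <- if (ses_spec == "childhood") {
      c(0.677, 0.207, 0.116)
    } else {
      c(0.416, 0.205, 0.056, 0.088, 0.082, 0.036, 0.016, 0.048, 0.052) /
        0.999  # published nine-way proportions, renormalised
    }
  }
  k <- if (ses_spec == "childhood") 3L else 9L
  if (length(ses_distribution) != k)
    stop("ses_distribution must have length ", k, " for spec '",
         ses_spec, "'")
  if (abs(sum(ses_distribution) - 1) > 1e-12)
    stop("configuration error: ses_distribution must sum to 1")
  if (n_subjects < 1) stop("configuration error: n_subjects must be >= 1")
  for (r in c(deficit_missing_rate, ses_missing_rate))
    if (r < 0 || r >= 1)
      stop("configuration error: missingness rates must lie in [0, 1)")
  if (entry_age_min < 65) stop("configuration error: entry ages must be >= 65")
  if (entry_age_max > 125) stop("configuration error: entry_age_max > 125")
  structure(list(n_subjects = as.integer(n_subjects),
                 enrollment_waves = enrollment_waves,
                 wave_spacing = wave_spacing, wave_jitter = wave_jitter,
                 entry_age_mean = entry_age_mean, entry_age_sd = entry_age_sd,
                 entry_age_min = entry_age_min, entry_age_max = entry_age_max,
                 entry_age_dist = entry_age_dist,
                 gender_mix = gender_mix, ses_spec = ses_spec,
                 ses_distribution = ses_distribution,
                 entry_state = entry_state,
                 prevalence_coefs = prevalence_coefs,
                 deficit_missing_rate = deficit_missing_rate,
                 ses_missing_rate = ses_missing_rate,
                 follow_up_years = follow_up_years,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

MAX_AGE <- 130
SIM_H <- 0.1

# Lattice of substep left endpoints shared by simulation, likelihood and
# life table: 65.0, 65.1, ..., 129.9.
age_lattice <- function(h = SIM_H) seq(65, MAX_AGE - h, by = h)

# Per-profile intensity lattice: list of four vectors over age_lattice().
profile_rate_lattice <- function(truth, gender, ses, h = SIM_H) {
  q <- transition_rates(truth, age_lattice(h), gender, ses)
  list(a = q[, "q12"], b = q[, "q13"], c = q[, "q21"], d = q[, "q23"])
}

#' Simulate latent health-state paths for a cohort
#'
#' Forward-simulates the three-state process by competing-risks sampling
#' from age-inhomogeneous intensities held piecewise-constant on a 0.1-year
#' age lattice (the same discretisation the life-table integration uses).
#' Entry ages are rounded to the lattice. Paths are truncated at age 130.
#' Each subject consumes an independent seed substream derived from the
#' master seed.
#'
#' @param truth a [transition_params()] object (see [default_truth()]).
#' @param config a [cohort_config()].
#' @return an object of class `cohort_paths`: list with `subjects`
#'   (id, enroll_time, entry_age, gender, ses, entry_state, death_age),
#'   `jumps` (subject, age, state entered), and the config.
#' @export
simulate_paths <- function(truth, config) {
  stopifnot(inherits(truth, "transition_params"),
            inherits(config, "cohort_config"))
  if (attr(truth, "spec") != config$ses_spec)
    stop("truth spec and config ses_spec disagree")
  n <- config$n_subjects
  h <- SIM_H
  grid <- age_lattice(h)
  ng <- length(grid)

  # rate lattices for every gender x SES combination that can occur
  ses_vals <- if (config$ses_spec == "childhood") 0:2 else 1:9
  lat <- list()
  for (g in 0:1) for (s in ses_vals)
    lat[[paste(g, s)]] <- profile_rate_lattice(truth, g, s, h)

  subjects <- data.frame(id = seq_len(n), enroll_time = NA_real_,
                         entry_age = NA_real_, gender = NA_integer_,
                         ses = NA_integer_, entry_state = NA_integer_,
                         death_age = NA_real_)
  jumps <- vector("list", n)

  seeds <- subject_seeds(config$seed, n)
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    et <- sample(config$enrollment_waves, 1L)
    if (identical(config$entry_age_dist, "uniform")) {
      ea <- stats::runif(1, config$entry_age_min, config$entry_age_max)
    } else {
      ea <- Inf
      while (ea < config$entry_age_min || ea > config$entry_age_max)
        ea <- stats::rnorm(1, config$entry_age_mean, config$entry_age_sd)
    }
    ea <- round((ea - 65) / h) * h + 65
    ea <- min(ea, MAX_AGE - h)
    g <- stats::rbinom(1, 1, config$gender_mix)
    s <- if (config$ses_spec == "childhood") {
      sample(0:2, 1L, prob = config$ses_distribution)
    } else sample(1:9, 1L, prob = config$ses_distribution)
    st <- switch(config$entry_state,
                 robust = 1L, frailty = 2L,
                 prevalence = {
                   p <- stats::plogis(config$prevalence_coefs[1] +
                                        config$prevalence_coefs[2] * (ea - 65))
                   1L + stats::rbinom(1, 1, p)
                 })
    rl <- lat[[paste(g, s)]]
    path <- simulate_one_path(rl, st, ea, grid, h)
    subjects$enroll_time[i] <- et
    subjects$entry_age[i] <- ea
    subjects$gender[i] <- g
    subjects$ses[i] <- s
    subjects$entry_state[i] <- st
    subjects$death_age[i] <- path$death_age
    if (nrow(path$jumps))
      jumps[[i]] <- cbind(subject = i, path$jumps)
  }
  jumps <- if (any(!vapply(jumps, is.null, TRUE))) {
    do.call(rbind, jumps[!vapply(jumps, is.null, TRUE)])
  } else data.frame(subject = integer(0), age = numeric(0),
                    state = integer(0))
  structure(list(subjects = subjects, jumps = jumps, config = config,
                 truth = truth, h = h),
            class = "cohort_paths")
}

# Exact sojourn sampling under lattice-piecewise-constant intensities:
# draw a unit exponential, invert the cumulative hazard over the lattice.
simulate_one_path <- function(rl, state, entry_age, grid, h) {
  jump_age <- numeric(0)
  jump_state <- integer(0)
  age <- entry_age
  death_age <- NA_real_
  repeat {
    pos <- min(max(1L, floor((age - 65) / h + 1e-9) + 1L), length(grid))
    if (state == 1L) {
      ex <- rl$a[pos:length(grid)] + rl$b[pos:length(grid)]
    } else {
      ex <- rl$c[pos:length(grid)] + rl$d[pos:length(grid)]
    }
    len <- rep(h, length(ex))
    len[1] <- grid[pos] + h - age
    ch <- cumsum(ex * len)
    E <- stats::rexp(1)
    if (E >= ch[length(ch)]) break  # survives in this state to age 130
    j <- which(ch >= E)[1]
    prev <- if (j == 1L) 0 else ch[j - 1L]
    seg_start <- if (j == 1L) age else grid[pos + j - 1L]
    t_jump <- seg_start + (E - prev) / ex[j]
    k <- pos + j - 1L
    u <- stats::runif(1)
    if (state == 1L) {
      new_state <- if (u < rl$a[k] / (rl$a[k] + rl$b[k])) 2L else 3L
    } else {
      new_state <- if (u < rl$c[k] / (rl$c[k] + rl$d[k])) 1L else 3L
    }
    jump_age <- c(jump_age, t_jump)
    jump_state <- c(jump_state, new_state)
    if (new_state == 3L) {
      death_age <- t_jump
      break
    }
    state <- new_state
    age <- t_jump
  }
  list(jumps = data.frame(age = jump_age, state = jump_state),
       death_age = death_age)
}

# Latent state of one subject at given ages (vectorised over age).
state_at <- function(paths, subject, age) {
  sub <- paths$subjects[paths$subjects$id == subject, ]
  jj <- paths$jumps[paths$jumps$subject == subject, , drop = FALSE]
  vapply(age, function(a) {
    if (!is.na(sub$death_age) && a >= sub$death_age) return(3L)
    before <- jj[jj$age <= a, , drop = FALSE]
    if (nrow(before) == 0L) sub$entry_state else before$state[nrow(before)]
  }, integer(1))
}

#' Observe latent paths at survey waves (interval censoring)
#'
#' Converts latent paths into wave-based panel observations: living states
#' are recorded only at wave ages; death is recorded at its exact age with
#' an `exact` flag; subjects alive past their last wave inside the
#' follow-up window are right-censored at that wave. Transition ages of
#' living-state jumps are not exposed.
#'
#' @param paths a `cohort_paths` object from [simulate_paths()].
#' @param config the same [cohort_config()] used for simulation.
#' @return a `data.frame` panel (subject, age, state, exact, gender, ses)
#'   with attribute `ses_spec`.
#' @export
observe_panel <- function(paths, config = paths$config) {
  set.seed(config$seed + 100003L)
  end_time <- max(config$enrollment_waves) + config$follow_up_years
  recs <- vector("list", nrow(paths$subjects))
  for (i in seq_len(nrow(paths$subjects))) {
    sub <- paths$subjects[i, ]
    t <- sub$enroll_time
    wave_ages <- sub$entry_age
    while (TRUE) {
      t <- t + config$wave_spacing +
        stats::runif(1, -config$wave_jitter, config$wave_jitter)
      if (t > end_time) break
      wave_ages <- c(wave_ages, sub$entry_age + (t - sub$enroll_time))
    }
    dead <- !is.na(sub$death_age)
    live_ages <- if (dead) wave_ages[wave_ages < sub$death_age] else wave_ages
    st <- state_at(paths, sub$id, live_ages)
    out <- data.frame(subject = sub$id, age = live_ages, state = st,
                      exact = FALSE)
    # death observed only if it falls inside the follow-up window
    if (dead && sub$death_age <= sub$entry_age + (end_time - sub$enroll_time))
      out <- rbind(out, data.frame(subject = sub$id, age = sub$death_age,
                                   state = 3L, exact = TRUE))
    if (nrow(out)) {
      out$gender <- sub$gender
      out$ses <- sub$ses
      recs[[i]] <- out
    }
  }
  panel <- do.call(rbind, recs)
  rownames(panel) <- NULL
  attr(panel, "ses_spec") <- config$ses_spec
  panel
}

#' Emit deficit and SES indicator data consistent with the latent cohort
#'
#' For every living panel record, draws 38 binary health deficits whose
#' count reproduces a frailty index consistent with the latent state
#' (FI <= 0.10 when robust, > 0.10 when frail). For every subject, draws
#' 4 childhood and 6 adult binary SES indicators whose totals fall in the
#' score bin of the subject's assigned category, then injects MCAR
#' missingness at the configured rates. With zero injected missingness,
#' round-tripping through [compute_fi()]/[classify_state()] and
#' [score_and_categorize()] recovers the latent state and categories
#' exactly.
#'
#' @param paths a `cohort_paths` object.
#' @param panel the panel from [observe_panel()].
#' @param config the matching [cohort_config()].
#' @return list with `deficits` (subject, age, d01..d38), `ses` (subject,
#'   4 childhood + 6 adult indicator columns), and `latent` (the true
#'   states and categories, for validation).
#' @export
sample_deficits_and_ses <- function(paths, panel, config = paths$config) {
  set.seed(config$seed + 200003L)
  living <- panel[panel$state != 3L, , drop = FALSE]
  n <- nrow(living)

  # deficit counts: robust -> 0..3 of 38 (FI <= 0.079), frail -> >= 4
  robust <- living$state == 1L
  count <- integer(n)
  count[robust] <- sample(0:3, sum(robust), replace = TRUE,
                          prob = c(0.25, 0.35, 0.25, 0.15))
  p_extra <- stats::plogis(-2.1 + 0.02 * (living$age[!robust] - 65))
  count[!robust] <- 4L + stats::rbinom(sum(!robust), 34L, p_extra)
  def <- matrix(0L, n, 38L,
                dimnames = list(NULL, sprintf("d%02d", 1:38)))
  for (r in seq_len(n))
    if (count[r] > 0L) def[r, sample.int(38L, count[r])] <- 1L
  if (config$deficit_missing_rate > 0) {
    mask <- matrix(stats::runif(n * 38L) < config$deficit_missing_rate, n)
    def[mask] <- NA_integer_
  }
  deficits <- cbind(living[, c("subject", "age")], as.data.frame(def))

  # SES indicators per subject
  subs <- paths$subjects
  m <- nrow(subs)
  if (config$ses_spec == "trajectory") {
    child_cat <- (subs$ses - 1L) %/% 3L
    adult_cat <- (subs$ses - 1L) %% 3L
  } else {
    child_cat <- subs$ses
    # upward-leaning conditional adult category given childhood
    cond <- rbind(c(0.60, 0.30, 0.10),
                  c(0.30, 0.50, 0.20),
                  c(0.15, 0.40, 0.45))
    adult_cat <- vapply(child_cat, function(cc)
      sample(0:2, 1L, prob = cond[cc + 1L, ]), integer(1))
  }
  child_total <- ifelse(child_cat == 0L, 0L,
                 ifelse(child_cat == 1L, 1L,
                        sample(2:4, m, replace = TRUE,
                               prob = c(0.5, 0.3, 0.2))))
  adult_total <- ifelse(adult_cat == 0L,
                        stats::rbinom(m, 1L, 0.4),
                 ifelse(adult_cat == 1L,
                        2L + stats::rbinom(m, 1L, 0.4),
                        4L + stats::rbinom(m, 2L, 0.35)))
  child_ind <- indicator_patterns(child_total, 4L)
  adult_ind <- indicator_patterns(adult_total, 6L)
  colnames(child_ind) <- c("birth_type", "hunger_free", "father_occupation",
                           "medical_care")
  colnames(adult_ind) <- c("residence", "education", "occupation", "pension",
                           "financial_sufficiency", "medical_care_at_60")
  ses <- data.frame(subject = subs$id, child_ind, adult_ind)
  if (config$ses_missing_rate > 0) {
    for (cl in colnames(ses)[-1]) {
      mask <- stats::runif(m) < config$ses_missing_rate
      ses[[cl]][mask] <- NA_integer_
    }
  }
  latent <- data.frame(subject = living$subject, age = living$age,
                       state = living$state)
  latent_subjects <- data.frame(subject = subs$id, child_cat = child_cat,
                                adult_cat = adult_cat,
                                trajectory = 3L * child_cat + adult_cat + 1L)
  list(deficits = deficits, ses = ses, latent = latent,
       latent_subjects = latent_subjects)
}

#' Lattice years-in-state from simulated paths
#'
#' Accumulates each path's time in the robust and frailty states with the
#' same left-endpoint 0.1-year rule the life table uses (a path counts
#' `h` years in state `s` for every lattice age it occupies `s` at), so
#' Monte-Carlo means are directly comparable to [life_expectancies()].
#'
#' @param paths a `cohort_paths` object.
#' @param index_age lattice origin; subjects are assumed to enter at it.
#' @param h lattice step.
#' @return data frame: subject, robust, frailty, total (years).
#' @export
path_years_in_state <- function(paths, index_age = 65, h = 0.1) {
  npts <- function(x, y)  # lattice points of index_age + k h in [x, y)
    max(ceiling((y - index_age) / h - 1e-9), 0) -
    max(ceiling((x - index_age) / h - 1e-9), 0)
  subs <- paths$subjects
  out <- matrix(0, nrow(subs), 2)
  jumps <- split(paths$jumps, paths$jumps$subject)
  for (i in seq_len(nrow(subs))) {
    jj <- jumps[[as.character(subs$id[i])]]
    starts <- c(subs$entry_age[i], jj$age)
    states <- c(subs$entry_state[i], jj$state)
    ends <- c(jj$age, MAX_AGE)
    for (k in seq_along(starts)) {
      if (states[k] == 3L) break
      out[i, states[k]] <- out[i, states[k]] +
        h * npts(starts[k], min(ends[k], MAX_AGE))
    }
  }
  data.frame(subject = subs$id, robust = out[, 1], frailty = out[, 2],
             total = out[, 1] + out[, 2])
}

# Mostly-Guttman indicator patterns: given a total t of k indicators, the
# first t indicators in a fixed "difficulty" order are set with probability
# 0.8, otherwise a random subset of size t; this induces strong inter-item
# correlation, as in real SES batteries.
indicator_patterns <- function(total, k) {
  m <- length(total)
  out <- matrix(0L, m, k)
  guttman <- stats::runif(m) < 0.8
  for (i in seq_len(m)) {
    t <- total[i]
    if (t == 0L) next
    idx <- if (guttman[i]) seq_len(min(t, k)) else sample.int(k, min(t, k))
    out[i, idx] <- 1L
  }
  out
}
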