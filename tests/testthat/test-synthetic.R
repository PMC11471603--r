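test_that("configuration validation catches bad inputs", {
  expect_error(cohort_config(ses_distribution = c(0.5, 0.4, 0.2)),
               "sum to 1")
  expect_error(cohort_config(n_subjects = 0), "n_subjects")
  expect_error(cohort_config(deficit_missing_rate = 1), "rates")
  expect_error(cohort_config(entry_age_min = 60), ">= 65")
  expect_error(simulate_paths(default_truth("trajectory"),
                              cohort_config(ses_spec = "childhood")),
               "disagree")
})

test_that("paths obey the state structure: no resurrection, no self-jumps", {
  sm <- small_panel()
  jumps <- sm$paths$jumps
  subs <- sm$paths$subjects
  # death is absorbing: any death jump is the subject's last
  for (s in unique(jumps$subject)) {
    jj <- jumps[jumps$subject == s, ]
    expect_true(all(diff(jj$age) > 0))
    if (any(jj$state == 3L))
      expect_equal(which(jj$state == 3L), nrow(jj))
    # self-jumps impossible: consecutive states alternate or end in death
    st <- c(subs$entry_state[subs$id == s], jj$state)
    expect_true(all(diff(st) != 0))
  }
  expect_true(all(jumps$state %in% c(1L, 2L, 3L)))
})

test_that("waiting time to frailty matches the exponential closed form", {
  # pure 1->2 process at 0.2/yr: P(frail by 70 | robust at 65) = 1-e^{-1}
  cfg <- cohort_config(n_subjects = 10000, seed = 17,
                       entry_age_mean = 65, entry_age_sd = 0,
                       entry_age_max = 66, entry_state = "robust",
                       ses_spec = "childhood",
                       ses_distribution = c(1, 0, 0))
  tp <- transition_params(c(log(0.2), -Inf, -Inf, -Inf), rep(0, 4),
                          gender_coefs = rep(0, 4),
                          ses_coefs = matrix(0, 4, 2), spec = "childhood")
  paths <- simulate_paths(tp, cfg)
  frail_by_70 <- vapply(paths$subjects$id, function(id) {
    jj <- paths$jumps[paths$jumps$subject == id, ]
    any(jj$state == 2L & jj$age <= 70)
  }, logical(1))
  p_hat <- mean(frail_by_70)
  p_true <- 1 - exp(-1)
  se <- sqrt(p_true * (1 - p_true) / length(frail_by_70))
  expect_lt(abs(p_hat - p_true), 3 * se)
})

test_that("zero intensities give jump-free paths; fixed seed reproduces; subsets are stable", {
  tp0 <- transition_params(rep(-Inf, 4), rep(0, 4),
                           gender_coefs = rep(0, 4),
                           ses_coefs = matrix(0, 4, 2),
                           spec = "childhood")
  cfg <- cohort_config(n_subjects = 100, seed = 31)
  p0 <- simulate_paths(tp0, cfg)
  expect_equal(nrow(p0$jumps), 0L)
  expect_true(all(is.na(p0$subjects$death_age)))

  tp <- default_truth("childhood")
  p1 <- simulate_paths(tp, cfg)
  p2 <- simulate_paths(tp, cfg)
  expect_identical(p1$jumps, p2$jumps)
  expect_identical(p1$subjects, p2$subjects)
  # per-subject substreams: shrinking the cohort leaves the rest untouched
  cfg50 <- cohort_config(n_subjects = 50, seed = 31)
  p50 <- simulate_paths(tp, cfg50)
  expect_identical(p50$subjects, p1$subjects[1:50, ])
  expect_equal(p50$jumps, p1$jumps[p1$jumps$subject <= 50, ],
               ignore_attr = TRUE)
})

test_that("panel observation censors living jumps and dates deaths exactly", {
  # hand-built path: robust at 65, frail at 66.4; waves land at 65 and 68
  mk_paths <- function(death_age) {
    cfg <- cohort_config(n_subjects = 1, wave_spacing = 3, wave_jitter = 0,
                         enrollment_waves = 0, follow_up_years = 3.5,
                         seed = 1)
    subjects <- data.frame(id = 1L, enroll_time = 0, entry_age = 65,
                           gender = 1L, ses = 0L, entry_state = 1L,
                           death_age = death_age)
    jumps <- if (is.na(death_age)) {
      data.frame(subject = 1L, age = 66.4, state = 2L)
    } else {
      data.frame(subject = 1L, age = death_age, state = 3L)
    }
    structure(list(subjects = subjects, jumps = jumps, config = cfg,
                   h = 0.1), class = "cohort_paths")
  }
  p <- mk_paths(NA)
  obs <- observe_panel(p, p$config)
  expect_equal(obs$age, c(65, 68))
  expect_equal(obs$state, c(1L, 2L))
  expect_false(any(obs$exact))
  expect_false(66.4 %in% obs$age)

  pd <- mk_paths(67.2)
  obsd <- observe_panel(pd, pd$config)
  expect_equal(obsd$age, c(65, 67.2))
  expect_equal(obsd$state, c(1L, 3L))
  expect_equal(obsd$exact, c(FALSE, TRUE))
})

test_that("deficit emission respects the FI cut and injects a reproducible mask", {
  cfg <- cohort_config(n_subjects = 120, seed = 61,
                       deficit_missing_rate = 0.05)
  tp <- default_truth("childhood")
  paths <- simulate_paths(tp, cfg)
  panel <- observe_panel(paths, cfg)
  em1 <- sample_deficits_and_ses(paths, panel, cfg)
  em2 <- sample_deficits_and_ses(paths, panel, cfg)
  expect_identical(em1$deficits, em2$deficits)  # same seed, same mask
  def <- as.matrix(em1$deficits[, -(1:2)])
  expect_equal(ncol(def), 38L)
  miss_rate <- mean(is.na(def))
  expect_lt(abs(miss_rate - 0.05), 0.01)
  # with missing cells ignored, counts still match the latent state
  counts <- rowSums(def == 1, na.rm = TRUE)
  frail <- em1$latent$state == 2L
  expect_true(all(counts[!frail] <= 3))
})

test_that("annual transition fractions match expm-based probabilities", {
  tp <- default_truth("childhood")
  cfg <- cohort_config(n_subjects = 4000, seed = 23,
                       entry_age_mean = 70, entry_age_sd = 4,
                       entry_age_max = 80, entry_state = "prevalence",
                       gender_mix = 1, ses_distribution = c(1, 0, 0))
  paths <- simulate_paths(tp, cfg)
  # latent state of every subject at integer ages 70..75
  for (a in c(70, 73)) {
    s_now <- vapply(paths$subjects$id, function(id)
      frailmslt:::state_at(paths, id, a), integer(1))
    s_next <- vapply(paths$subjects$id, function(id)
      frailmslt:::state_at(paths, id, a + 1), integer(1))
    entered <- paths$subjects$entry_age <= a
    P <- annual_transition_matrix(tp, a, gender = 1, ses = 0)
    for (s in 1:2) {
      at_risk <- entered & s_now == s
      n <- sum(at_risk)
      for (s2 in 1:3) {
        p_hat <- mean(s_next[at_risk] == s2)
        p_true <- P[s, s2]
        se <- sqrt(max(p_true * (1 - p_true), 1e-10) / n)
        expect_lt(abs(p_hat - p_true), 3 * se + 1e-8)
      }
    }
  }
})
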