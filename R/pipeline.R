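#' Run the full synthetic-cohort analysis pipeline
#'
#' Chains every stage end to end on a simulated cohort: path simulation,
#' wave observation, deficit/SES emission, frailty-index state coding,
#' chained-equations SES imputation and categorisation, inclusion
#' filtering, gender-stratified model fitting, transition curves, and the
#' life-expectancy table with bootstrap intervals, plus the baseline
#' trajectory distribution and mobility summary.
#'
#' @param config a [cohort_config()].
#' @param truth ground-truth dynamics; defaults to the calibrated
#'   [default_truth()] for the config's SES spec.
#' @param ages index ages for the LE table.
#' @param B bootstrap draws per LE-table row (0 to skip intervals).
#' @param m_impute imputations for the SES chained equations.
#' @param curve_ages ages for the transition-probability curves.
#' @param out_dir if non-NULL, [render_reports()] is called on the result.
#' @return list: panel, fit, le (table), curves, baseline, mobility,
#'   exclusion log, config.
#' @export
run_pipeline <- function(config, truth = default_truth(config$ses_spec),
                         ages = c(65, 75), B = 200, m_impute = 20,
                         curve_ages = 65:95, out_dir = NULL) {
  paths <- simulate_paths(truth, config)
  obs <- observe_panel(paths, config)
  emitted <- sample_deficits_and_ses(paths, obs, config)

  deaths <- obs[obs$state == 3L, c("subject", "age")]
  names(deaths) <- c("subject", "death_age")
  states <- build_state_series(emitted$deficits, deaths)

  cats <- ses_categorize(emitted$ses, m = m_impute, seed = config$seed)
  covar <- if (config$ses_spec == "childhood") "child_cat" else "trajectory"
  subj_info <- merge(paths$subjects[, c("id", "gender")],
                     cats[, c("subject", covar)],
                     by.x = "id", by.y = "subject")
  names(subj_info) <- c("subject", "gender", "ses")

  panel <- merge(states, subj_info, by = "subject")
  panel <- panel[order(panel$subject, panel$age), ]
  attr(panel, "ses_spec") <- config$ses_spec
  panel <- apply_inclusion_criteria(panel)
  attr(panel, "ses_spec") <- config$ses_spec

  fit <- fit_msm(panel, spec = config$ses_spec, gender_mode = "stratify")

  le <- le_table(fit, ages = ages, B = B, seed = config$seed)

  ses_vals <- if (config$ses_spec == "childhood") 0:2 else 1:9
  curves <- do.call(rbind, lapply(c("female", "male"), function(g) {
    gi <- as.integer(g == "male")
    f <- fit[[g]]
    do.call(rbind, lapply(ses_vals, function(s)
      cbind(gender = g, ses = s,
            transition_curves(f, gi, s, ages = curve_ages))))
  }))

  traj_pct <- 100 * tabulate(cats$trajectory, 9L) / nrow(cats)
  baseline <- data.frame(code = 1:9, label = trajectory_label(1:9),
                         pct = round_half_up(traj_pct, 1))
  mobility <- mobility_summary(traj_pct)

  result <- list(panel = panel, fit = fit, le = le, curves = curves,
                 baseline = baseline, mobility = mobility,
                 exclusions = attr(panel, "exclusion_log"),
                 state_exclusions = attr(states, "exclusion_log"),
                 categories = cats, config = config)
  if (!is.null(out_dir)) render_reports(result, out_dir)
  result
}
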