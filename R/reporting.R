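#' Robust life-expectancy proportion
#'
#' The share of remaining life expected in the robust state,
#' `100 * robust / total`, rounded half-up to two decimals as printed in
#' the life-expectancy tables.
#'
#' @param total_le total LE in years (> 0).
#' @param robust_le robust LE in years, `0 <= robust_le <= total_le`.
#' @return percentage, or `NA` when total is not positive.
#' @examples
#' le_proportion(14.34, 4.74)  # 33.05
#' @export
le_proportion <- function(total_le, robust_le) {
  out <- rep(NA_real_, length(total_le))
  ok <- !is.na(total_le) & total_le > 0
  if (any(robust_le[ok] < 0 | robust_le[ok] > total_le[ok] + 1e-9))
    stop("robust LE must lie in [0, total LE]")
  out[ok] <- round_half_up(100 * robust_le[ok] / total_le[ok], 2)
  out
}

#' Pairwise contrasts and category averages of a life-expectancy table
#'
#' Computes, within each gender x index-age block, all pairwise
#' differences in the robust-LE proportion between SES categories, and the
#' unweighted means of the total/robust/frailty LE across categories. All
#' arithmetic is on the printed rounding (two decimals), matching how the
#' published between-category gaps and category averages are quoted.
#'
#' @param tab a data frame with columns `gender`, `age`, `label`,
#'   `total_le`, `robust_le`, `frailty_le` and optionally `prop_robust`
#'   (recomputed via [le_proportion()] when absent), e.g. an [le_table()]
#'   or a printed reference table.
#' @return list with `differences` (gender, age, a, b, diff =
#'   prop_robust[a] - prop_robust[b]) and `averages` (gender, age, mean
#'   total/robust/frailty LE, rounded to two decimals).
#' @export
group_contrasts <- function(tab) {
  if (is.null(tab$prop_robust))
    tab$prop_robust <- le_proportion(tab$total_le, tab$robust_le)
  blocks <- unique(tab[, c("gender", "age")])
  diffs <- list(); avgs <- list()
  for (r in seq_len(nrow(blocks))) {
    b <- tab[tab$gender == blocks$gender[r] & tab$age == blocks$age[r], ]
    if (anyDuplicated(b$label))
      stop("input error: duplicated category in a gender/age block")
    cmb <- utils::combn(nrow(b), 2)
    diffs[[r]] <- data.frame(
      gender = blocks$gender[r], age = blocks$age[r],
      a = b$label[cmb[2, ]], b = b$label[cmb[1, ]],
      diff = round_half_up(b$prop_robust[cmb[2, ]] -
                             b$prop_robust[cmb[1, ]], 2))
    avgs[[r]] <- data.frame(
      gender = blocks$gender[r], age = blocks$age[r],
      total_le = round_half_up(mean(b$total_le), 2),
      robust_le = round_half_up(mean(b$robust_le), 2),
      frailty_le = round_half_up(mean(b$frailty_le), 2))
  }
  list(differences = do.call(rbind, diffs),
       averages = do.call(rbind, avgs))
}

#' Published reference tables bundled with the package
#'
#' Transcriptions of the published summary tables, used as inputs to the
#' derived-arithmetic checks (proportions, differences, category
#' averages, mobility sums): the childhood-SES and trajectory
#' life-expectancy tables (point estimates and printed proportions) and
#' the nine-way baseline trajectory distribution.
#'
#' @param which `"childhood_le"`, `"trajectory_le"` or
#'   `"trajectory_distribution"`.
#' @return a data frame.
#' @export
printed_table <- function(which = c("childhood_le", "trajectory_le",
                                    "trajectory_distribution")) {
  which <- match.arg(which)
  f <- system.file("extdata", paste0("printed_", which, ".csv"),
                   package = "frailmslt", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

md_table <- function(df) {
  fmt <- vapply(df, function(cl)
    if (is.numeric(cl)) format(round_half_up(cl, 2), trim = TRUE)
    else as.character(cl), character(nrow(df)))
  if (is.null(dim(fmt))) fmt <- matrix(fmt, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(fmt, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                           " |"))
  c(header, sep, body)
}

#' Write the report bundle for a pipeline run
#'
#' Emits CSV and Markdown life-expectancy tables, a baseline distribution
#' table, tidy transition-curve CSVs with one PNG panel figure per
#' transition (male and female side by side), and a JSON run manifest
#' (seed, configuration, package version). Outputs are a pure function of
#' the inputs, so a rerun with the same seed and configuration reproduces
#' the CSVs byte for byte.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
render_reports <- function(result, dir) {
  for (nm in c("le", "curves", "baseline"))
    if (is.null(result[[nm]]))
      stop("missing upstream artifact '", nm,
           "': run the pipeline stage that produces it first")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(result$le, "le_table.csv")
  writeLines(md_table(result$le), file.path(dir, "le_table.md"))
  wr(result$baseline, "baseline_distribution.csv")
  wr(result$curves, "transition_curves.csv")
  trans <- c(p12 = "robust to frailty", p21 = "frailty to robust",
             p13 = "robust to dead", p23 = "frailty to dead")
  for (tr in names(trans)) {
    p <- file.path(dir, paste0("curve_", tr, ".png"))
    grDevices::png(p, width = 900, height = 450)
    graphics::par(mfrow = c(1, 2))
    for (g in c("male", "female")) {
      sub <- result$curves[result$curves$gender == g, ]
      cats <- sort(unique(sub$ses))
      graphics::matplot(
        x = matrix(sub$age, ncol = length(cats)),
        y = matrix(sub[[tr]], ncol = length(cats)), type = "l", lty = 1,
        xlab = "age", ylab = "annual probability",
        main = paste0(trans[tr], " (", g, ")"))
      graphics::legend("topleft", legend = cats, col = seq_along(cats),
                       lty = 1, cex = 0.8, title = "SES")
    }
    grDevices::dev.off()
    paths <- c(paths, p)
  }
  manifest <- list(seed = result$config$seed,
                   ses_spec = result$config$ses_spec,
                   n_subjects = result$config$n_subjects,
                   package_version =
                     as.character(utils::packageVersion("frailmslt")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, file.path(dir, "manifest.json"))
  invisible(paths)
}
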