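#' Chained-equations imputation of binary SES indicators
#'
#' Fills missing cells of a block of binary indicators by multiple
#' imputation with chained logistic regressions, using only the other
#' indicators of the same block as predictors. Each of the `m` imputations
#' initialises missing cells from the observed marginal distribution, runs
#' `cycles` update sweeps (fit a logistic conditional on the currently
#' completed other columns, then redraw the missing cells as Bernoulli from
#' the predicted probabilities), and records the final draws. Each missing
#' cell is then replaced by the mean of its `m` draws, rounded to the
#' nearest whole number and converted to 0 or 1.
#'
#' @param indicators data frame of 0/1/NA columns forming one index block
#'   (e.g. the four childhood indicators, or the six adult ones).
#' @param m number of imputations (default 100).
#' @param seed integer seed.
#' @param cycles chained-update sweeps per imputation.
#' @return the completed data frame (no missing cells).
#' @export
impute_chained <- function(indicators, m = 100, seed = 1, cycles = 10) {
  stopifnot(m >= 1)
  x <- as.matrix(indicators)
  storage.mode(x) <- "double"
  bad <- x[!is.na(x)]
  if (length(bad) && any(!bad %in% c(0, 1)))
    stop("indicators must be 0/1 or missing")
  miss <- is.na(x)
  if (!any(miss)) return(as.data.frame(indicators))
  if (any(colSums(!miss) == 0L))
    stop("imputation error: a column is entirely missing")
  set.seed(seed)
  acc <- matrix(0, nrow(x), ncol(x))
  target_cols <- which(colSums(miss) > 0L)
  for (imp in seq_len(m)) {
    cur <- x
    for (j in seq_len(ncol(x))) {
      mj <- miss[, j]
      if (any(mj)) {
        p <- mean(x[!mj, j])
        cur[mj, j] <- stats::rbinom(sum(mj), 1L, p)
      }
    }
    for (cy in seq_len(cycles)) {
      for (j in target_cols) {
        mj <- miss[, j]
        X <- cbind(1, cur[, -j, drop = FALSE])
        fit <- tryCatch(
          suppressWarnings(stats::glm.fit(X[!mj, , drop = FALSE], x[!mj, j],
                                          family = stats::binomial())),
          error = function(e) NULL)
        p <- if (is.null(fit) || any(!is.finite(fit$coefficients))) {
          rep(mean(x[!mj, j]), sum(mj))
        } else {
          co <- fit$coefficients
          co[is.na(co)] <- 0
          stats::plogis(drop(X[mj, , drop = FALSE] %*% co))
        }
        cur[mj, j] <- stats::rbinom(sum(mj), 1L, p)
      }
    }
    acc <- acc + cur
  }
  mean_draws <- acc / m
  out <- as.data.frame(indicators)
  for (j in seq_along(out)) {
    mj <- miss[, j]
    if (any(mj)) {
      v <- as.numeric(round_half_up(mean_draws[mj, j], 0) >= 1)
      if (is.integer(out[[j]])) v <- as.integer(v)
      out[[j]][mj] <- v
    }
  }
  out
}

#' Default score-to-category schemes for the SES indices
#'
#' Childhood totals (0-4) are split by equal-width bins with the top two
#' merged: `{0}` low, `{1}` medium, `{2,3,4}` high. Adult totals (0-6) use
#' range terciles: `{0,1}` low, `{2,3}` medium, `{4,5,6}` high. Both maps
#' are monotone and surjective onto `{0, 1, 2}`.
#'
#' @return list with elements `childhood` (length 5, totals 0:4) and
#'   `adulthood` (length 7, totals 0:6) giving the category per total.
#' @export
default_scheme <- function() {
  list(childhood = c(0L, 1L, 2L, 2L, 2L),
       adulthood = c(0L, 0L, 1L, 1L, 2L, 2L, 2L))
}

#' Score an indicator block and map the total to a category
#'
#' @param indicators completed (no missing) 0/1 indicator data frame: 4
#'   columns for childhood, 6 for adulthood.
#' @param which `"childhood"` or `"adulthood"`.
#' @param scheme a scheme list as from [default_scheme()].
#' @return integer categories in `{0, 1, 2}` (0 low, 1 medium, 2 high).
#' @export
score_and_categorize <- function(indicators,
                                 which = c("childhood", "adulthood"),
                                 scheme = default_scheme()) {
  which <- match.arg(which)
  x <- as.matrix(indicators)
  if (anyNA(x))
    stop("precondition error: impute missing indicators first")
  k <- if (which == "childhood") 4L else 6L
  if (ncol(x) != k)
    stop(which, " block must have ", k, " indicator columns")
  map <- scheme[[which]]
  if (is.unsorted(map) || !setequal(unique(map), 0:2))
    stop("scheme must be monotone and surjective onto {0,1,2}")
  total <- rowSums(x)
  as.integer(map[total + 1L])
}

#' Life-course SES trajectory code
#'
#' Combines the childhood and adulthood categories into the nine-way
#' trajectory code: `3 * childhood + adulthood + 1`, so low-low = 1,
#' low-medium = 2, ..., high-high = 9.
#'
#' @param child_cat,adult_cat integer categories in `{0, 1, 2}`.
#' @return integer codes in 1..9.
#' @export
life_course_trajectory <- function(child_cat, adult_cat) {
  if (any(!child_cat %in% 0:2) || any(!adult_cat %in% 0:2))
    stop("input error: categories must be 0, 1 or 2")
  as.integer(3L * child_cat + adult_cat + 1L)
}

#' Trajectory code labels
#' @param code integer codes 1..9.
#' @return labels like `"low-medium"`.
#' @export
trajectory_label <- function(code) {
  lv <- c("low", "medium", "high")
  paste(lv[(code - 1L) %/% 3L + 1L], lv[(code - 1L) %% 3L + 1L], sep = "-")
}

#' Social-mobility and accumulation summaries of a trajectory distribution
#'
#' @param pct named or ordered numeric length-9 vector of percentages for
#'   trajectory codes 1..9 (must sum to 100 within rounding slack).
#' @return list with `upward` (codes 2, 3, 6), `downward` (4, 7, 8),
#'   `stable_low` (1), `stable_medium` (5), `stable_high` (9), and
#'   `accumulation` (percentages for accumulation scores 0..4, where the
#'   score is childhood category + adulthood category).
#' @export
mobility_summary <- function(pct) {
  stopifnot(length(pct) == 9L)
  if (abs(sum(pct) - 100) > 0.5)
    stop("trajectory percentages must sum to 100 (within rounding)")
  pct <- as.numeric(pct)
  child <- (1:9 - 1L) %/% 3L
  adult <- (1:9 - 1L) %% 3L
  score <- child + adult
  acc <- vapply(0:4, function(s) sum(pct[score == s]), numeric(1))
  names(acc) <- paste0("score", 0:4)
  list(upward = sum(pct[c(2, 3, 6)]),
       downward = sum(pct[c(4, 7, 8)]),
       stable_low = pct[1], stable_medium = pct[5], stable_high = pct[9],
       accumulation = acc)
}

#' Impute and categorise a full SES indicator table
#'
#' Convenience wrapper: imputes the childhood block (using only childhood
#' indicators) and the adult block (only adult indicators) separately, then
#' scores, categorises and derives the trajectory code per subject.
#'
#' @param ses data frame with a `subject` column, the 4 childhood columns
#'   and the 6 adult columns (in that order).
#' @inheritParams impute_chained
#' @param scheme categorisation scheme, see [default_scheme()].
#' @return data frame: subject, child_cat, adult_cat, trajectory.
#' @export
ses_categorize <- function(ses, m = 100, seed = 1, cycles = 10,
                           scheme = default_scheme()) {
  child <- impute_chained(ses[, 2:5], m = m, seed = seed, cycles = cycles)
  adult <- impute_chained(ses[, 6:11], m = m, seed = seed + 1L,
                          cycles = cycles)
  cc <- score_and_categorize(child, "childhood", scheme)
  ac <- score_and_categorize(adult, "adulthood", scheme)
  data.frame(subject = ses$subject, child_cat = cc, adult_cat = ac,
             trajectory = life_course_trajectory(cc, ac))
}
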