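#' Deficit-accumulation frailty index
#'
#' Computes the frailty index (FI) from 38 health deficits, each scored in
#' `[0, 1]` or missing. Missing deficits are excluded from both numerator
#' and denominator; when strictly more than 30% of the 38 deficits are
#' missing the FI is flagged incomplete (11 of 38 missing still computes,
#' 12 of 38 is incomplete).
#'
#' @param deficits a numeric vector of length 38, or a matrix/data frame
#'   with 38 columns (one row per record); values in `[0, 1]` or `NA`.
#' @return a `data.frame` with columns `fi` (NA when incomplete),
#'   `n_observed`, `n_total` (38) and `incomplete`.
#' @examples
#' compute_fi(rep(0, 38))$fi                        # 0
#' compute_fi(c(rep(1, 6), rep(0, 24), rep(NA, 8)))$fi  # 6/30 = 0.2
#' @export
compute_fi <- function(deficits) {
  if (is.null(dim(deficits))) deficits <- matrix(deficits, nrow = 1L)
  deficits <- as.matrix(deficits)
  if (ncol(deficits) != 38L)
    stop("input error: a deficit vector must have exactly 38 items")
  vals <- suppressWarnings(apply(deficits, 2, as.numeric))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
  bad <- vals[!is.na(vals)]
  if (any(bad < 0 | bad > 1))
    stop("input error: deficit values must lie in [0, 1]")
  n_obs <- rowSums(!is.na(vals))
  incomplete <- (38L - n_obs) / 38 > 0.30
  fi <- ifelse(n_obs > 0, rowSums(vals, na.rm = TRUE) / n_obs, NA_real_)
  fi[incomplete] <- NA_real_
  data.frame(fi = fi, n_observed = n_obs, n_total = 38L,
             incomplete = incomplete)
}

#' Code a record into robust / frailty / dead
#'
#' Death dominates; otherwise FI <= 0.10 codes robust (1) and FI > 0.10
#' codes frailty (2). An incomplete FI on a living record yields `NA` and
#' marks the record for exclusion (the missing-FI exclusion rule).
#'
#' @param fi frailty index value(s) in `[0, 1]`, `NA` when incomplete.
#' @param died logical, `TRUE` for a record at a verified death age.
#' @return integer state code(s) in `{1, 2, 3}`, or `NA` for living records
#'   with incomplete FI.
#' @export
classify_state <- function(fi, died = FALSE) {
  n <- max(length(fi), length(died))
  fi <- rep_len(fi, n)
  died <- rep_len(died, n)
  out <- ifelse(died, 3L, ifelse(is.na(fi), NA_integer_,
                                 ifelse(fi <= 0.10, 1L, 2L)))
  as.integer(out)
}

#' Build the state panel from a deficit panel and death records
#'
#' Computes the FI for every subject-wave, codes living states, appends one
#' exact-death record per deceased subject at the verified death age, and
#' drops (and logs) records whose FI is incomplete.
#'
#' @param deficit_panel data frame with columns `subject`, `age` and 38
#'   deficit columns (any names; all non-id columns are taken as deficits).
#' @param deaths data frame with columns `subject`, `death_age`, or `NULL`.
#' @return a panel `data.frame` (subject, age, state, exact) with an
#'   `exclusion_log` attribute counting dropped incomplete records.
#' @export
build_state_series <- function(deficit_panel, deaths = NULL) {
  idcols <- intersect(c("subject", "age"), names(deficit_panel))
  if (length(idcols) != 2L)
    stop("deficit_panel needs 'subject' and 'age' columns")
  defcols <- setdiff(names(deficit_panel), idcols)
  fi <- compute_fi(deficit_panel[, defcols])
  state <- classify_state(fi$fi)
  panel <- data.frame(subject = deficit_panel$subject,
                      age = deficit_panel$age,
                      state = state, exact = FALSE, fi = fi$fi)
  dropped <- sum(is.na(state))
  panel <- panel[!is.na(panel$state), , drop = FALSE]
  if (!is.null(deaths) && nrow(deaths)) {
    deaths <- deaths[!is.na(deaths$death_age), , drop = FALSE]
    last_age <- tapply(panel$age, panel$subject, max)
    la <- last_age[as.character(deaths$subject)]
    bad <- !is.na(la) & deaths$death_age < la
    if (any(bad))
      stop("data-consistency error: death age earlier than last interview ",
           "for subject(s) ", paste(deaths$subject[bad], collapse = ", "))
    panel <- rbind(panel,
                   data.frame(subject = deaths$subject,
                              age = deaths$death_age, state = 3L,
                              exact = TRUE, fi = NA_real_))
  }
  panel <- panel[order(panel$subject, panel$age), , drop = FALSE]
  rownames(panel) <- NULL
  attr(panel, "exclusion_log") <- c(incomplete_fi = dropped)
  panel
}
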