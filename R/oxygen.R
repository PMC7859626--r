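# Effective FiO2, cumulative oxygen utilization, and respiratory outcome
# labels (BPD by birth-weight/36-week criterion, BPD by room-air challenge,
# PRD from caregiver surveys).

.oxygen <- new.env(parent = emptyenv())

# Weight x flow grid of cannula dilution fractions, bilinearly interpolated.
# The shipped table is a synthetic stand-in derived from a simple inspiratory
# flow model (see the file header and the package vignette); the published
# bedside conversion charts are not redistributable here.
fio2_table <- function() {
  if (is.null(.oxygen$table)) {
    path <- system.file("extdata", "synthetic_effective_fio2_table.tsv",
                        package = "preemiexpr", mustWork = TRUE)
    .oxygen$table <- read.delim(path)
  }
  .oxygen$table
}

interp1 <- function(grid, x) {
  # clamp-and-interpolate helper on a sorted grid; returns index weights
  x <- min(max(x, grid[1]), grid[length(grid)])
  hi <- findInterval(x, grid, rightmost.closed = TRUE) + 1L
  hi <- min(max(hi, 2L), length(grid))
  lo <- hi - 1L
  w <- (x - grid[lo]) / (grid[hi] - grid[lo])
  list(lo = lo, hi = hi, w = w)
}

cannula_fraction <- function(weight_g, flow_lpm) {
  tab <- fio2_table()
  ws <- sort(unique(tab$weight_g))
  fs <- sort(unique(tab$flow_lpm))
  grid <- matrix(NA_real_, length(ws), length(fs))
  grid[cbind(match(tab$weight_g, ws), match(tab$flow_lpm, fs))] <- tab$cannula_fraction
  vapply(seq_along(weight_g), function(i) {
    if (flow_lpm[i] <= 0) return(0)
    # below the smallest tabulated flow, interpolate linearly toward 0 at
    # zero flow (no flow delivers room air)
    if (flow_lpm[i] < fs[1]) {
      iw <- interp1(ws, weight_g[i])
      f_min <- (1 - iw$w) * grid[iw$lo, 1] + iw$w * grid[iw$hi, 1]
      return(f_min * flow_lpm[i] / fs[1])
    }
    iw <- interp1(ws, weight_g[i])
    jf <- interp1(fs, flow_lpm[i])
    f_lo <- (1 - jf$w) * grid[iw$lo, jf$lo] + jf$w * grid[iw$lo, jf$hi]
    f_hi <- (1 - jf$w) * grid[iw$hi, jf$lo] + jf$w * grid[iw$hi, jf$hi]
    (1 - iw$w) * f_lo + iw$w * f_hi
  }, numeric(1))
}

#' Effective FiO2 with low-flow nasal cannula correction
#'
#' For `low_flow_cannula` support the nominal FiO2 is diluted by entrained
#' room air: effective = 0.21 + (FiO2 - 0.21) * c(weight, flow), where the
#' dilution fraction c comes from the shipped weight-by-flow conversion
#' table (bilinear interpolation). All other support modes pass through
#' unchanged. Results are clipped to \[0.21, 1\].
#'
#' @param fio2 nominal FiO2 fraction(s) in \[0.21, 1\].
#' @param support_mode one of `"vent"`, `"cpap"`, `"high_flow"`,
#'   `"low_flow_cannula"`, `"room_air"` (vectorized).
#' @param flow_lpm cannula flow in L/min (must be >= 0).
#' @param weight_g body weight in grams (used only for cannula dilution).
#' @return effective FiO2 fraction(s) in \[0.21, 1\].
#' @export
effective_fio2 <- function(fio2, support_mode, flow_lpm = 0, weight_g = 1500) {
  n <- max(length(fio2), length(support_mode), length(flow_lpm), length(weight_g))
  fio2 <- rep_len(fio2, n); support_mode <- rep_len(support_mode, n)
  flow_lpm <- rep_len(flow_lpm, n); weight_g <- rep_len(weight_g, n)
  if (any(flow_lpm < 0)) stop("cannula flow must be non-negative")
  if (any(fio2 < 0.21 - 1e-9 | fio2 > 1 + 1e-9)) stop("FiO2 must be a fraction in [0.21, 1]")
  out <- fio2
  lf <- support_mode == "low_flow_cannula"
  if (any(lf)) {
    frac <- cannula_fraction(weight_g[lf], flow_lpm[lf])
    out[lf] <- 0.21 + (fio2[lf] - 0.21) * frac
  }
  out[support_mode == "room_air"] <- 0.21
  pmin(pmax(out, 0.21), 1)
}

#' Construct an oxygen trace
#'
#' @param subject_id subject identifier.
#' @param days data.frame with 1-based strictly increasing `day`, `fio2`
#'   (fraction), `support_mode`, `flow_lpm`, `pressure_cmH2O`.
#' @param birth_weight_g birth weight in grams.
#' @return object of class `oxygen_trace`.
#' @export
oxygen_trace <- function(subject_id, days, birth_weight_g) {
  stopifnot(is.data.frame(days),
            all(c("day", "fio2", "support_mode", "flow_lpm") %in% names(days)))
  if (is.null(days$pressure_cmH2O)) days$pressure_cmH2O <- 0
  if (any(diff(days$day) <= 0) || days$day[1] < 1) {
    stop("trace days must be strictly increasing, starting at day >= 1")
  }
  if (any(days$fio2 > 1 + 1e-9)) stop("FiO2 must be recorded as a fraction, not percent")
  structure(list(subject_id = subject_id, days = days,
                 birth_weight_g = birth_weight_g),
            class = "oxygen_trace")
}

# Daily effective FiO2 vector for days 1..through_day with the gap policy:
# missing days carry the last observation forward for up to `locf_max` days,
# beyond which room air (0.21) is assumed with a warning.
daily_effective_fio2 <- function(trace, through_day, locf_max = 2) {
  stopifnot(inherits(trace, "oxygen_trace"))
  d <- trace$days
  if (nrow(d) == 0) stop("oxygen trace has no recorded days")
  eff_rec <- effective_fio2(d$fio2, d$support_mode, d$flow_lpm, trace$birth_weight_g)
  eff <- rep(NA_real_, through_day)
  eff[d$day[d$day <= through_day]] <- eff_rec[d$day <= through_day]
  if (anyNA(eff)) {
    gap_run <- 0
    imputed_ra <- FALSE
    last <- 0.21
    for (i in seq_len(through_day)) {
      if (is.na(eff[i])) {
        gap_run <- gap_run + 1
        if (gap_run <= locf_max && i > 1 && !is.na(last)) {
          eff[i] <- last
        } else {
          eff[i] <- 0.21
          imputed_ra <- TRUE
        }
      } else {
        gap_run <- 0
        last <- eff[i]
      }
    }
    if (imputed_ra) warning("missing flowsheet days beyond carry-forward window treated as room air")
  }
  eff
}

#' Cumulative oxygen utilization (oxygen AUC)
#'
#' Default convention: the sum over days 1..`through_day` of the daily noon
#' effective FiO2 excess over room air, i.e. area above 0.21 in
#' FiO2-excess x days. The integrand is a swappable strategy so a
#' pressure-weighted variant can be slotted in; the default ignores support
#' pressure.
#'
#' @param trace an [oxygen_trace()].
#' @param through_day last postnatal day included (typically 14 or 28).
#' @param convention either `"daily_excess"` or a function mapping the
#'   vector of daily effective FiO2 values to a single exposure value.
#' @return non-negative oxygen AUC in FiO2-excess x days.
#' @export
oxygen_auc <- function(trace, through_day = 14, convention = "daily_excess") {
  eff <- daily_effective_fio2(trace, through_day)
  if (is.function(convention)) return(convention(eff))
  switch(convention,
    daily_excess = sum(eff - 0.21),
    stop("unknown oxygen AUC convention: ", convention)
  )
}

#' BPD label by the birth-weight / 36-week criterion
#'
#' BPD is "yes" iff birth weight < 1500 g and supplemental oxygen is
#' required at 36 weeks postmenstrual age; infants at or above 1500 g are
#' "not-applicable".
#'
#' @param support_at_36wk_pma logical: supplemental oxygen at 36 weeks PMA.
#' @param birth_weight_g birth weight in grams.
#' @return `"yes"`, `"no"`, or `"not-applicable"` (vectorized).
#' @export
label_bpd_shennan <- function(support_at_36wk_pma, birth_weight_g) {
  n <- max(length(support_at_36wk_pma), length(birth_weight_g))
  s <- rep_len(as.logical(support_at_36wk_pma), n)
  bw <- rep_len(birth_weight_g, n)
  out <- ifelse(bw >= 1500, "not-applicable", ifelse(s, "yes", "no"))
  out
}

#' BPD label by the physiologic room-air-challenge criterion
#'
#' Eligibility requires at least 28 days (not necessarily consecutive) with
#' effective FiO2 above 0.21. An eligible infant is "yes" on a failed
#' room-air challenge, "no" on a pass; ineligible infants are "no";
#' an eligible infant without a challenge result is "not-assessed".
#'
#' @param trace an [oxygen_trace()] covering the days to assess.
#' @param rac_result `"pass"`, `"fail"`, or `"not-done"`.
#' @param min_days qualifying-day threshold (default 28).
#' @return `"yes"`, `"no"`, or `"not-assessed"`.
#' @export
label_bpd_rac <- function(trace, rac_result, min_days = 28) {
  stopifnot(inherits(trace, "oxygen_trace"))
  d <- trace$days
  eff <- effective_fio2(d$fio2, d$support_mode, d$flow_lpm, trace$birth_weight_g)
  qualifying <- sum(eff > 0.21 + 1e-9)
  eligible <- qualifying >= min_days
  if (!eligible) return("no")
  switch(rac_result,
    fail = "yes",
    pass = "no",
    "not-assessed"
  )
}

#' PRD label from caregiver post-discharge surveys
#'
#' Surveys at 3, 6, 9, and 12 months corrected age each assess four
#' morbidity domains (respiratory hospitalization, home support,
#' respiratory medication, cough/wheeze without a cold). PRD is "yes" when
#' at least two surveys each have at least one positive domain; "no" when
#' enough completed negative surveys exist to rule a second positive out;
#' "missing" otherwise.
#'
#' @param surveys 4-column logical matrix (one row per survey, one column
#'   per domain). A row of all-`NA` is a missed survey; a row is positive if
#'   any domain is `TRUE`, negative if all four are `FALSE`, and otherwise
#'   indeterminate (treated as missing).
#' @return `"yes"`, `"no"`, or `"missing"`.
#' @export
label_prd <- function(surveys) {
  surveys <- as.matrix(surveys)
  stopifnot(ncol(surveys) == 4, nrow(surveys) <= 4)
  status <- apply(surveys, 1L, function(r) {
    if (any(r %in% TRUE)) "positive"
    else if (all(!is.na(r)) && all(!r)) "negative"
    else "missing"
  })
  n_pos <- sum(status == "positive")
  n_missing <- sum(status == "missing") + (4 - nrow(surveys))
  if (n_pos >= 2) "yes"
  else if (n_pos + n_missing >= 2) "missing"   # a second positive is still possible
  else "no"
}

#' Outcome labels and oxygen metrics for one subject
#'
#' Convenience wrapper computing `oxygen_auc14`, `oxygen_auc28`, and the
#' three outcome labels from a trace plus assessments.
#'
#' @inheritParams oxygen_auc
#' @param support_at_36wk_pma logical oxygen requirement at 36 weeks PMA.
#' @param rac_result room-air-challenge result.
#' @param surveys caregiver survey matrix for [label_prd()], or `NULL`.
#' @return list of class `outcome_labels`.
#' @export
outcome_labels <- function(trace, support_at_36wk_pma = NA,
                           rac_result = "not-done", surveys = NULL) {
  auc14 <- oxygen_auc(trace, 14)
  auc28 <- oxygen_auc(trace, min(28, max(trace$days$day)))
  structure(list(
    subject_id = trace$subject_id,
    oxygen_auc14 = auc14,
    oxygen_auc28 = auc28,
    bpd_shennan = if (is.na(support_at_36wk_pma)) NA_character_ else
      label_bpd_shennan(support_at_36wk_pma, trace$birth_weight_g),
    bpd_rac = label_bpd_rac(trace, rac_result),
    prd = if (is.null(surveys)) NA_character_ else label_prd(surveys)
  ), class = "outcome_labels")
}

#' Read a flowsheet TSV into a list of oxygen traces
#'
#' Expected columns: subject_id, day, fio2, support_mode, flow_lpm,
#' pressure_cmH2O. Birth weights come from the metadata table.
#'
#' @param path flowsheet TSV.
#' @param birth_weights named vector of birth weights (grams) by subject_id.
#' @return named list of [oxygen_trace()] objects.
#' @export
read_flowsheet <- function(path, birth_weights) {
  fs <- read.delim(path, stringsAsFactors = FALSE)
  split_fs <- split(fs, fs$subject_id)
  lapply(split_fs, function(d) {
    d <- d[order(d$day), ]
    oxygen_trace(d$subject_id[1], d[, setdiff(names(d), "subject_id")],
                 birth_weight_g = unname(birth_weights[d$subject_id[1]]))
  })
}
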