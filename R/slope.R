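# Longitudinal DELFI-TF dynamics: per-patient slope with eligibility windows
# around progression, and cohort dichotomization at the median slope.

parse_date <- function(x) {
  d <- as.Date(x)
  if (anyNA(d)) delfi_error("dates must be ISO-8601 (YYYY-MM-DD)", "delfi_parse_error")
  d
}

#' Eligibility of a longitudinal series for slope analysis
#'
#' A patient is eligible when at least three samples were drawn strictly
#' before the progression date and at least one sample lies in the analysis
#' window: the 120 days up to progression for the PFS analysis, extended to
#' 60 days after progression for the OS analysis.
#'
#' @param dates draw dates (ISO strings or Date).
#' @param progression_date progression date, or `NA` (ineligible).
#' @param analysis `"PFS"` or `"OS"`.
#' @return logical scalar with attribute `reason` when ineligible.
#' @export
slope_eligibility <- function(dates, progression_date, analysis = c("PFS", "OS")) {
  analysis <- match.arg(analysis)
  if (is.na(progression_date))
    return(structure(FALSE, reason = "no progression date"))
  dates <- parse_date(dates)
  prog <- parse_date(progression_date)
  n_pre <- sum(dates < prog)
  if (n_pre < 3L)
    return(structure(FALSE, reason = sprintf("only %d samples before progression", n_pre)))
  win_lo <- prog - 120
  win_hi <- if (analysis == "OS") prog + 60 else prog
  if (!any(dates >= win_lo & dates <= win_hi))
    return(structure(FALSE, reason = "no sample in the progression window"))
  TRUE
}

#' DELFI-TF slope for one patient
#'
#' Ordinary least-squares slope of DELFI-TF (percentage points) on elapsed
#' days since the first post-treatment draw (T1), using draws from T1 through
#' progression (PFS) or through progression + 60 days (OS).
#'
#' @param dates,delfi_tf the patient's draw dates and scores (percent).
#' @param t1_date first post-treatment draw date.
#' @param progression_date progression date (or `NA`).
#' @param analysis `"PFS"` or `"OS"`.
#' @return list with `slope` (percentage points per day, `NA` when
#'   undefined), `n_points`, `eligible`, `reason`.
#' @export
delfi_tf_slope <- function(dates, delfi_tf, t1_date, progression_date,
                           analysis = c("PFS", "OS")) {
  analysis <- match.arg(analysis)
  eligible <- slope_eligibility(dates, progression_date, analysis)
  dates <- parse_date(dates)
  t1 <- parse_date(t1_date)
  hi <- if (is.na(progression_date)) as.Date(Inf, origin = "1970-01-01") else {
    p <- parse_date(progression_date)
    if (analysis == "OS") p + 60 else p
  }
  inc <- dates >= t1 & dates <= hi
  x <- as.numeric(dates[inc] - t1)
  y <- delfi_tf[inc]
  if (length(x) < 2L || diff(range(x)) == 0) {
    return(list(slope = NA_real_, n_points = length(x),
                eligible = isTRUE(eligible),
                reason = attr(eligible, "reason") %||% "fewer than 2 included points"))
  }
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  list(slope = slope, n_points = length(x), eligible = isTRUE(eligible),
       reason = attr(eligible, "reason"))
}

#' Compute slopes for a cohort and dichotomize at the median
#'
#' Joins per-sample DELFI-TF scores with clinical metadata, derives T1 as the
#' earliest draw strictly after treatment start, computes each patient's
#' slope, and flags eligible patients as above or below the median slope
#' across eligible patients (a slope exactly at the median is "below").
#'
#' @param scores tibble/data.frame with `patient_id`, `date`, `delfi_tf`.
#' @param clinical tibble/data.frame with `patient_id`, `treatment_start`,
#'   `progression_date` (NA allowed).
#' @param analysis `"PFS"` or `"OS"`.
#' @return tibble `patient_id analysis slope n_points eligible above_median`.
#' @export
delfi_slopes <- function(scores, clinical, analysis = c("PFS", "OS")) {
  analysis <- match.arg(analysis)
  rows <- lapply(seq_len(nrow(clinical)), function(i) {
    p <- clinical$patient_id[i]
    s <- scores[scores$patient_id == p, ]
    s <- s[order(as.Date(s$date)), ]
    post <- as.Date(s$date) > parse_date(clinical$treatment_start[i])
    if (!any(post)) {
      return(tibble::tibble(patient_id = p, analysis = analysis,
                            slope = NA_real_, n_points = 0L, eligible = FALSE,
                            above_median = NA))
    }
    t1 <- min(as.Date(s$date)[post])
    r <- delfi_tf_slope(s$date, s$delfi_tf, t1,
                        clinical$progression_date[i], analysis)
    tibble::tibble(patient_id = p, analysis = analysis, slope = r$slope,
                   n_points = r$n_points,
                   eligible = r$eligible && is.finite(r$slope),
                   above_median = NA)
  })
  dichotomize_slopes(do.call(rbind, rows))
}

#' Dichotomize slopes at the eligible-patient median
#'
#' Sets `above_median` to `TRUE` for eligible slopes strictly greater than
#' the median over eligible patients and `FALSE` otherwise (ties at the
#' median go below). Ineligible rows keep `NA`.
#'
#' @param slopes tibble with `slope` and `eligible` columns.
#' @return the tibble with `above_median` filled in.
#' @export
dichotomize_slopes <- function(slopes) {
  el <- slopes$eligible & is.finite(slopes$slope)
  if (sum(el) >= 2L) {
    med <- median(slopes$slope[el])
    slopes$above_median <- ifelse(el, slopes$slope > med, NA)
  }
  slopes
}
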