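#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function under right censoring
#' (computed via [survival::survfit()]; ties are handled with deaths
#' preceding censorings at the same time, the product-limit convention).
#'
#' @param times Non-negative follow-up times in days.
#' @param events Logical (or 0/1) event indicators, `TRUE` = death.
#' @return A data frame of class `km_curve` with columns `day`, `n_risk`,
#'   `n_event`, `survival`.
#' @seealso [km_survival_at()]
#' @export
#' @examples
#' km <- km_estimate(c(1, 2, 3), c(TRUE, FALSE, TRUE))
#' km_survival_at(km, 3)
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("empty survival input", call. = FALSE)
  if (length(events) != length(times)) {
    stop("times and events must have equal length", call. = FALSE)
  }
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  fit <- survival::survfit(
    survival::Surv(times, as.integer(as.logical(events))) ~ 1
  )
  structure(
    data.frame(day = fit$time, n_risk = fit$n.risk,
               n_event = fit$n.event, survival = fit$surv),
    class = c("km_curve", "data.frame")
  )
}

#' @rdname km_estimate
#' @param curve A `km_curve`.
#' @param day Day (vectorized) at which to evaluate the step function;
#'   `S(0) = 1`.
#' @export
km_survival_at <- function(curve, day) {
  vapply(day, function(d) {
    i <- which(curve$day <= d)
    if (length(i) == 0) 1 else curve$survival[max(i)]
  }, numeric(1))
}

#' Kaplan-Meier mortality of a generated arm
#'
#' Convenience wrapper: deaths are events, survivors are censored at their
#' censor day, and mortality is `1 - S(day)`.
#'
#' @param cohort A cohort data frame (one arm or subset thereof).
#' @param day Evaluation day (default 365).
#' @return Mortality fraction in \[0, 1\].
#' @export
km_mortality <- function(cohort, day = 365) {
  dead <- !is.na(cohort$death_day)
  times <- ifelse(dead, cohort$death_day, cohort$censor_day)
  1 - km_survival_at(km_estimate(times, dead), day)
}

#' Area under the utility curve (quality-adjusted days)
#'
#' Trapezoidal integral of the interpolated utility trajectory from day 0
#' to `min(death_day, horizon)`. Utility is linearly interpolated between
#' interview points, carried forward after the last point, and steps to 0
#' at death. Before the first point the default is to carry the first
#' observed value back to day 0 (`hospital_phase = "carry_back"`); the
#' alternative convention treats utility as 0 until the first completed
#' interview (`hospital_phase = "zero"`).
#'
#' @param days Strictly increasing interview days.
#' @param utilities Utility values on \[0, 1\], one per day.
#' @param death_day Day of death, or `NA` if alive through the horizon.
#' @param horizon Integration horizon in days (default 365).
#' @param hospital_phase `"carry_back"` or `"zero"`: convention for the
#'   interval before the first interview.
#' @return Quality-adjusted days in \[0, min(death_day, horizon)\].
#' @export
#' @examples
#' utility_auc(c(61, 365), c(0.4, 0.6)) # 61*0.4 + 304*0.5 = 176.4
utility_auc <- function(days, utilities, death_day = NA_real_,
                        horizon = 365,
                        hospital_phase = c("carry_back", "zero")) {
  hospital_phase <- match.arg(hospital_phase)
  H <- min(if (is.na(death_day)) Inf else death_day, horizon)
  if (H <= 0) return(0)
  if (length(days) == 0) {
    stop("no utility points; impute a trajectory upstream", call. = FALSE)
  }
  if (length(days) != length(utilities)) {
    stop("days and utilities must have equal length", call. = FALSE)
  }
  if (is.unsorted(days, strictly = TRUE)) {
    stop("interview days must be strictly increasing", call. = FALSE)
  }
  if (any(utilities < 0 | utilities > 1)) {
    stop("utilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(days > H)) {
    stop("utility point recorded after death or beyond the horizon",
         call. = FALSE)
  }
  x <- c(0, days)
  y <- c(utilities[1], utilities)
  if (max(days) < H) { # carry-forward to the horizon (or death)
    x <- c(x, H)
    y <- c(y, utilities[length(utilities)])
  }
  auc <- sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
  if (hospital_phase == "zero") auc <- auc - days[1] * utilities[1]
  auc
}

#' One-year quality-adjusted survival per patient
#'
#' Computes each patient's quality-adjusted days over the first year as the
#' area under the utility curve, and one-year life years as
#' `min(death_day, 365) / 365`. Patients alive past day 0 with no completed
#' interview receive the arm-wave median trajectory (the imputation count
#' is attached as attribute `n_imputed`); missing intermediate interviews
#' are bridged by the linear interpolation inherent in the trapezoid.
#'
#' @param cohort A cohort data frame with wide utility columns `u_day*`.
#' @param interview_days Interview wave days matching the `u_day*` columns.
#' @param hospital_phase Convention before the first interview, see
#'   [utility_auc()].
#' @return The cohort with `qa_days_one_year` and `life_years_one_year`
#'   columns appended; attribute `n_imputed` counts patients whose whole
#'   trajectory was imputed.
#' @export
one_year_effect <- function(cohort, interview_days = c(61, 183, 274, 365),
                            hospital_phase = c("carry_back", "zero")) {
  hospital_phase <- match.arg(hospital_phase)
  ucols <- paste0("u_day", interview_days)
  if (!all(ucols %in% names(cohort))) {
    stop("cohort lacks utility columns: ",
         paste(setdiff(ucols, names(cohort)), collapse = ", "), call. = FALSE)
  }
  umat <- as.matrix(cohort[, ucols])
  # arm-wave medians of observed utilities, used for whole-trajectory
  # imputation of interview-less patients
  arm_medians <- lapply(split(seq_len(nrow(cohort)), cohort$arm), function(i) {
    m <- apply(umat[i, , drop = FALSE], 2, stats::median, na.rm = TRUE)
    m[!is.finite(m)] <- 0.5 # no observations at all for a wave
    m
  })
  n_imputed <- 0L
  qa <- numeric(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    death <- cohort$death_day[i]
    H <- min(if (is.na(death)) Inf else death, 365)
    if (H <= 0) { qa[i] <- 0; next }
    obs <- which(!is.na(umat[i, ]))
    if (length(obs) > 0) {
      qa[i] <- utility_auc(interview_days[obs], umat[i, obs],
                           death_day = death,
                           hospital_phase = hospital_phase)
    } else {
      n_imputed <- n_imputed + 1L
      med <- arm_medians[[cohort$arm[i]]]
      eligible <- which(interview_days <= H &
                          (is.na(death) | interview_days < death))
      if (length(eligible) > 0) {
        qa[i] <- utility_auc(interview_days[eligible], med[eligible],
                             death_day = death,
                             hospital_phase = hospital_phase)
      } else {
        # died before the first wave: carry the first-wave median back
        qa[i] <- if (hospital_phase == "carry_back") H * med[1] else 0
      }
    }
  }
  cohort$qa_days_one_year <- qa
  cohort$life_years_one_year <-
    pmin(ifelse(is.na(cohort$death_day), 365, cohort$death_day), 365) / 365
  attr(cohort, "n_imputed") <- n_imputed
  cohort
}
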