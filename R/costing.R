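#' Unit-cost weights for post-discharge resource use
#'
#' The unit-cost schema used to price post-discharge resource use, in 2010
#' US dollars. Home oxygen is priced as a fixed first-day set-up charge plus
#' a daily rate thereafter; re-hospitalization days are priced as a base
#' daily rate plus additive increments for ICU days and ventilated days
#' (encoded as the differences 2600 - 1500 = 1100 and 2800 - 2600 = 200, so
#' a single ICU + ventilated day costs $2800); lost work is valued at a
#' median daily income.
#'
#' @param home_oxygen_first_day,home_oxygen_other_days Home oxygen set-up
#'   charge ($) and daily rate thereafter ($/day).
#' @param home_help Home help, $/day.
#' @param rehab Rehabilitation, $/day.
#' @param snf_vent Skilled nursing facility with ventilation, $/day.
#' @param ed_visit Emergency-department visit, $/visit.
#' @param dr_visit Physician visit, $/visit.
#' @param rehosp_base Re-hospitalization base rate, $/day.
#' @param rehosp_icu_increment Additional cost of an ICU day over a ward
#'   day, $/day.
#' @param rehosp_vent_increment Additional cost of a ventilated day over an
#'   ICU day, $/day.
#' @param medications Medications, $/day.
#' @param lost_work Lost work, $/day.
#' @return A list of class `cost_weights`.
#' @export
#' @examples
#' w <- cost_weights()
#' rehospitalization_cost(10, 3, 2, w)
cost_weights <- function(home_oxygen_first_day = 600,
                         home_oxygen_other_days = 6.50,
                         home_help = 100,
                         rehab = 800,
                         snf_vent = 1500,
                         ed_visit = 800,
                         dr_visit = 200,
                         rehosp_base = 1500,
                         rehosp_icu_increment = 2600 - 1500,
                         rehosp_vent_increment = 2800 - 2600,
                         medications = 10,
                         lost_work = 200) {
  w <- list(
    home_oxygen_first_day = home_oxygen_first_day,
    home_oxygen_other_days = home_oxygen_other_days,
    home_help = home_help, rehab = rehab, snf_vent = snf_vent,
    ed_visit = ed_visit, dr_visit = dr_visit,
    rehosp_base = rehosp_base,
    rehosp_icu_increment = rehosp_icu_increment,
    rehosp_vent_increment = rehosp_vent_increment,
    medications = medications, lost_work = lost_work
  )
  if (any(unlist(w) < 0)) stop("cost weights must be >= 0", call. = FALSE)
  structure(w, class = "cost_weights")
}

#' Hospital cost from department charges and cost-to-charge ratios
#'
#' Converts billed hospital charges to estimated economic costs by applying
#' department-specific cost-to-charge ratios, with an optional
#' whole-hospital fallback ratio for departments missing from the ratio
#' map.
#'
#' @param department_charges Named numeric vector, charges ($) by
#'   department. May be empty.
#' @param cost_to_charge Named numeric vector of ratios by department.
#' @param fallback Optional single ratio for departments without one.
#' @return Total estimated cost, a single non-negative number.
#' @export
#' @examples
#' hospital_cost(c(ICU = 100000), c(ICU = 0.5))
hospital_cost <- function(department_charges, cost_to_charge,
                          fallback = NULL) {
  if (length(department_charges) == 0) return(0)
  if (any(department_charges < 0)) stop("charges must be >= 0", call. = FALSE)
  depts <- names(department_charges)
  ratio <- cost_to_charge[depts]
  missing <- depts[is.na(ratio)]
  if (length(missing) > 0) {
    if (is.null(fallback)) {
      stop("no cost-to-charge ratio for department(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    ratio[is.na(ratio)] <- fallback
  }
  sum(department_charges * ratio)
}

#' Re-hospitalization cost
#'
#' Prices re-hospitalization days as
#' `total_days * base + icu_days * icu_increment + vent_days * vent_increment`,
#' i.e. ICU and ventilated days add increments on top of the base daily
#' rate rather than replacing it.
#'
#' @param total_days,icu_days,vent_days Non-negative day counts;
#'   `icu_days <= total_days` and `vent_days <= total_days`.
#' @param weights A [cost_weights()].
#' @return Cost in dollars (vectorized over the day counts).
#' @export
rehospitalization_cost <- function(total_days, icu_days, vent_days,
                                   weights = cost_weights()) {
  if (any(total_days < 0) || any(icu_days < 0) || any(vent_days < 0)) {
    stop("day counts must be >= 0", call. = FALSE)
  }
  if (any(icu_days > total_days) || any(vent_days > total_days)) {
    stop("ICU and ventilated days cannot exceed total re-hospitalization days",
         call. = FALSE)
  }
  total_days * weights$rehosp_base +
    icu_days * weights$rehosp_icu_increment +
    vent_days * weights$rehosp_vent_increment
}

#' Home oxygen cost
#'
#' A fixed first-day set-up charge plus a daily rate for each subsequent
#' day: zero days cost nothing, one day costs the set-up charge.
#'
#' @param days Non-negative day count (vectorized).
#' @param weights A [cost_weights()].
#' @return Cost in dollars.
#' @export
home_oxygen_cost <- function(days, weights = cost_weights()) {
  if (any(days < 0)) stop("days must be >= 0", call. = FALSE)
  ifelse(days == 0, 0,
         weights$home_oxygen_first_day +
           weights$home_oxygen_other_days * (days - 1))
}

#' Post-discharge costs by category
#'
#' Applies the unit-cost weights to each resource-use category; home oxygen
#' and re-hospitalization use their dedicated formulas. Lost wages are
#' reported separately from the direct medical categories.
#'
#' @param resources A data frame (or one-row list) with the resource-use
#'   columns of [generate_cohort()].
#' @param weights A [cost_weights()].
#' @return A data frame with one cost column per category (dollars):
#'   `cost_home_oxygen`, `cost_home_help`, `cost_rehab`, `cost_snf_vent`,
#'   `cost_rehosp`, `cost_ed`, `cost_dr`, `cost_medications`, and
#'   `cost_lost_wages`.
#' @export
post_discharge_cost <- function(resources, weights = cost_weights()) {
  r <- as.data.frame(resources)
  data.frame(
    cost_home_oxygen = home_oxygen_cost(r$home_oxygen_days, weights),
    cost_home_help = r$home_help_days * weights$home_help,
    cost_rehab = r$rehab_days * weights$rehab,
    cost_snf_vent = r$snf_vent_days * weights$snf_vent,
    cost_rehosp = rehospitalization_cost(r$rehosp_total_days,
                                         r$rehosp_icu_days,
                                         r$rehosp_vent_days, weights),
    cost_ed = r$ed_visits * weights$ed_visit,
    cost_dr = r$dr_visits * weights$dr_visit,
    cost_medications = r$medication_days * weights$medications,
    cost_lost_wages = r$lost_work_days * weights$lost_work
  )
}

direct_cost_columns <- c(
  "cost_home_oxygen", "cost_home_help", "cost_rehab", "cost_snf_vent",
  "cost_rehosp", "cost_ed", "cost_dr", "cost_medications"
)

#' Per-patient one-year cost stream
#'
#' Appends the per-category post-discharge costs, hospital cost and lost
#' wages to the cohort and forms the one-year total
#' `cost_total_one_year = hospital + post-discharge direct + lost wages`
#' (2010 dollars).
#'
#' @param cohort A cohort data frame from [generate_cohort()] (or the same
#'   schema loaded from CSV).
#' @param weights A [cost_weights()].
#' @return The cohort with cost columns appended.
#' @export
cost_stream <- function(cohort, weights = cost_weights()) {
  pd <- post_discharge_cost(cohort, weights)
  out <- cbind(cohort, pd)
  out$cost_hospital <- cohort$hospital_cost
  out$cost_total_one_year <- out$cost_hospital +
    rowSums(pd[, direct_cost_columns, drop = FALSE]) + pd$cost_lost_wages
  out
}

#' Express an amount in 2010 dollars
#'
#' Multiplies an amount by the consumer-price-index factor of its calendar
#' year relative to 2010. The factor table is user-editable CSV (columns
#' `year`, `factor_to_2010`, with factor 1 for 2010); an approximate
#' default is bundled at
#' `system.file("extdata", "cpi_to_2010.csv", package = "trialcea")`.
#'
#' @param amount Dollar amount in `year` dollars (vectorized).
#' @param year Calendar year (vectorized or scalar).
#' @param cpi A CPI table data frame, e.g. from [read_cpi_table()].
#' @return Amount in 2010 dollars.
#' @export
index_to_2010 <- function(amount, year, cpi = read_cpi_table()) {
  idx <- match(year, cpi$year)
  if (any(is.na(idx))) {
    stop("year(s) missing from CPI table: ",
         paste(unique(year[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  amount * cpi$factor_to_2010[idx]
}

#' @rdname index_to_2010
#' @param path CSV path; defaults to the bundled table.
#' @export
read_cpi_table <- function(path = system.file("extdata", "cpi_to_2010.csv",
                                              package = "trialcea")) {
  cpi <- utils::read.csv(path)
  stopifnot(all(c("year", "factor_to_2010") %in% names(cpi)))
  if (2010 %in% cpi$year &&
      abs(cpi$factor_to_2010[cpi$year == 2010] - 1) > 1e-9) {
    stop("CPI factor for 2010 must equal 1", call. = FALSE)
  }
  cpi
}
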