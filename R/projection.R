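#' Build a synthetic life table
#'
#' A small Gompertz-derived remaining-life-expectancy table keyed by age
#' band, sex and race/ethnicity, bundled so the lifetime projection is
#' testable without external downloads. The mortality hazard is
#' `mu(x) = a * exp(b x)` with proportional sex and race multipliers;
#' remaining life expectancy at age `x` is the numerically integrated
#' survival curve. The table is synthetic: users with access to official
#' period life tables should supply them in the same CSV schema (columns
#' `age`, `sex`, `race`, `expectancy_years`).
#'
#' @param ages Age bands (years).
#' @param a,b Gompertz level and slope of the baseline (male, white)
#'   hazard.
#' @param sex_mult Named multipliers on `a` by sex.
#' @param race_mult Named multipliers on `a` by race/ethnicity; must
#'   include `other`, the fallback category.
#' @return A data frame with columns `age`, `sex`, `race`,
#'   `expectancy_years`.
#' @export
#' @examples
#' lt <- make_synthetic_life_table()
#' remaining_life_expectancy(51, "F", "white", lt)
make_synthetic_life_table <- function(ages = seq(0, 100, by = 5),
                                      a = 6.7e-5, b = 0.09,
                                      sex_mult = c(M = 1.3, F = 0.85),
                                      race_mult = c(white = 1.0, black = 1.25,
                                                    hispanic = 0.9,
                                                    other = 1.0)) {
  stopifnot("other" %in% names(race_mult))
  tgrid <- seq(0, 120, by = 0.1)
  le_at <- function(x, a_g) {
    s <- exp(-(a_g / b) * (exp(b * (x + tgrid)) - exp(b * x)))
    sum((s[-1] + s[-length(s)]) / 2) * 0.1
  }
  grid <- expand.grid(age = ages, sex = names(sex_mult),
                      race = names(race_mult), stringsAsFactors = FALSE)
  grid$expectancy_years <- mapply(function(age, sex, race) {
    round(le_at(age, a * sex_mult[[sex]] * race_mult[[race]]), 2)
  }, grid$age, grid$sex, grid$race)
  grid[order(grid$sex, grid$race, grid$age), c("age", "sex", "race",
                                               "expectancy_years")]
}

#' Read a life table from CSV
#'
#' @param path CSV with columns `age`, `sex`, `race`, `expectancy_years`;
#'   defaults to the bundled synthetic table.
#' @return A life-table data frame.
#' @export
read_life_table <- function(path = system.file("extdata",
                                               "life_table_synthetic.csv",
                                               package = "trialcea")) {
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("age", "sex", "race", "expectancy_years") %in% names(lt)))
  if (any(lt$expectancy_years < 0)) {
    stop("life expectancies must be >= 0", call. = FALSE)
  }
  lt
}

#' Remaining life expectancy lookup
#'
#' Nearest-age-band lookup of remaining life expectancy by sex and
#' race/ethnicity. Ages beyond the oldest band are clamped to it with a
#' warning; races absent from the table fall back to the `other` category.
#'
#' @param age,sex,race Vectors (recycled to the longest).
#' @param table A life-table data frame, see [read_life_table()].
#' @return Remaining life expectancy in years.
#' @export
remaining_life_expectancy <- function(age, sex, race,
                                      table = read_life_table()) {
  n <- max(length(age), length(sex), length(race))
  age <- rep_len(age, n); sex <- rep_len(sex, n); race <- rep_len(race, n)
  bands <- sort(unique(table$age))
  if (any(age > max(bands))) {
    warning("age(s) beyond the oldest life-table band; clamped", call. = FALSE)
  }
  race_known <- race %in% unique(table$race)
  race[!race_known] <- "other"
  band <- bands[vapply(pmin(age, max(bands)), function(x) {
    which.min(abs(bands - x))
  }, integer(1))]
  key <- paste(band, sex, race)
  idx <- match(key, paste(table$age, table$sex, table$race))
  if (any(is.na(idx))) {
    stop("life-table lookup failed for: ",
         paste(unique(key[is.na(idx)]), collapse = "; "), call. = FALSE)
  }
  table$expectancy_years[idx]
}

#' Reference-case projection parameters
#'
#' The base-case lifetime extrapolation: survivors at one year accrue a
#' constant utility (default 0.6) and a constant annual healthcare cost
#' over their life-table remaining life expectancy, both discounted
#' annually (default 3%/year). The annual post-year-one cost is a required
#' user input; the default $5,000/year is an illustrative placeholder, not
#' an empirical estimate. The life-expectancy multiplier supports
#' sensitivity analyses on expected survival.
#'
#' @param utility_beyond_one_year Utility on \[0, 1\] assigned beyond one
#'   year.
#' @param annual_cost_beyond_one_year $/year (2010 dollars) beyond one
#'   year.
#' @param discount_rate Annual discount rate for costs and effects
#'   (fraction/year, >= 0).
#' @param life_expectancy_multiplier Positive scalar on the life-table
#'   remaining life expectancy.
#' @return A list of class `reference_case_params`.
#' @export
reference_case_params <- function(utility_beyond_one_year = 0.6,
                                  annual_cost_beyond_one_year = 5000,
                                  discount_rate = 0.03,
                                  life_expectancy_multiplier = 1.0) {
  assert_prob(utility_beyond_one_year, "utility beyond one year")
  if (discount_rate < 0) stop("discount rate must be >= 0", call. = FALSE)
  if (life_expectancy_multiplier <= 0) {
    stop("life-expectancy multiplier must be > 0", call. = FALSE)
  }
  if (annual_cost_beyond_one_year < 0) {
    stop("annual cost must be >= 0", call. = FALSE)
  }
  structure(
    list(utility_beyond_one_year = utility_beyond_one_year,
         annual_cost_beyond_one_year = annual_cost_beyond_one_year,
         discount_rate = discount_rate,
         life_expectancy_multiplier = life_expectancy_multiplier),
    class = "reference_case_params"
  )
}

#' Present value of a constant annual stream
#'
#' End-of-year discounting: the amount accrued in projected year `t` is
#' divided by `(1 + rate)^t`; a fractional final year accrues
#' `frac * amount / (1 + rate)^ceiling(years)`. With rate 0 this reduces
#' exactly to `amount * years`.
#'
#' @param annual_amount Amount accrued per year (any unit).
#' @param years Non-negative duration in years (vectorized).
#' @param rate Annual discount rate (fraction/year, >= 0).
#' @return Present value in the unit of `annual_amount`.
#' @export
#' @examples
#' discounted_annuity(0.6, 10, 0.03) # 0.6 * (1 - 1.03^-10) / 0.03
discounted_annuity <- function(annual_amount, years, rate) {
  if (any(years < 0)) stop("duration must be >= 0", call. = FALSE)
  if (rate < 0) stop("rate must be >= 0", call. = FALSE)
  if (rate == 0) return(annual_amount * years)
  full <- floor(years)
  frac <- years - full
  af <- (1 - (1 + rate)^(-full)) / rate
  annual_amount * af + frac * annual_amount * (1 + rate)^(-ceiling(years))
}

#' Lifetime projection of costs and QALYs
#'
#' Fills the lifetime components of the per-patient streams. Decedents
#' within the first year keep their one-year values. Survivors at day 365
#' accrue, over `multiplier * LE(age + 1, sex, race)` years, the
#' reference-case utility and annual cost as discounted annuities:
#' `lifetime_qalys = qa_days/365 + PV(utility)` and
#' `lifetime_cost = cost_total_one_year + PV(annual cost)`.
#'
#' @param cohort A cohort with `cost_total_one_year` and
#'   `qa_days_one_year` columns (see [cost_stream()], [one_year_effect()]).
#' @param params A [reference_case_params()].
#' @param life_table A life-table data frame.
#' @return The cohort with `remaining_le`, `lifetime_qalys` and
#'   `lifetime_cost` (dollars) appended.
#' @export
project_cohort <- function(cohort, params = reference_case_params(),
                           life_table = read_life_table()) {
  needed <- c("cost_total_one_year", "qa_days_one_year")
  if (!all(needed %in% names(cohort))) {
    stop("run cost_stream() and one_year_effect() first", call. = FALSE)
  }
  survivor <- is.na(cohort$death_day)
  le <- rep(0, nrow(cohort))
  if (any(survivor)) {
    le[survivor] <- params$life_expectancy_multiplier *
      remaining_life_expectancy(cohort$age[survivor] + 1,
                                cohort$sex[survivor],
                                cohort$race[survivor], life_table)
  }
  cohort$remaining_le <- le
  cohort$lifetime_qalys <- cohort$qa_days_one_year / 365 +
    discounted_annuity(params$utility_beyond_one_year, le,
                       params$discount_rate)
  cohort$lifetime_cost <- cohort$cost_total_one_year +
    discounted_annuity(params$annual_cost_beyond_one_year, le,
                       params$discount_rate)
  cohort
}
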