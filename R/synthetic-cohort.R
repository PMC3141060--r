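#' Solve two-piece exponential hazards from two survival anchors
#'
#' A minimal survival model identified by exactly two Kaplan-Meier anchors:
#' a constant hazard up to day 60 and a second constant hazard from day 60
#' to day 365. The hazards satisfy `exp(-60 * h1) = s60` and
#' `exp(-60 * h1 - 305 * h2) = s365`.
#'
#' @param s60 Survival probability at day 60, in (0, 1\].
#' @param s365 Survival probability at day 365, `0 < s365 <= s60`.
#' @return Named numeric vector `c(hazard1, hazard2)` in events/day.
#' @export
#' @examples
#' solve_piecewise_hazards(0.738, 0.644)
#' solve_piecewise_hazards(1, 1) # zero-hazard case
solve_piecewise_hazards <- function(s60, s365) {
  if (!is.finite(s60) || !is.finite(s365) || s60 <= 0 || s365 <= 0 ||
      s60 > 1 || s365 > 1) {
    stop("survival anchors must lie in (0, 1]", call. = FALSE)
  }
  if (s365 > s60 + 1e-12) {
    stop(sprintf(
      "inconsistent anchors: S(365) = %.4f exceeds S(60) = %.4f",
      s365, s60
    ), call. = FALSE)
  }
  h1 <- -log(s60) / 60
  h2 <- max(0, (log(s60) - log(s365)) / 305)
  c(hazard1 = h1, hazard2 = h2)
}

# inverse-CDF draw from the two-piece exponential; returns Inf when the
# patient survives past day 365 (administrative censoring handles it)
draw_twopiece_survival <- function(n, s60, s365) {
  hz <- solve_piecewise_hazards(s60, s365)
  u <- stats::runif(n)
  t <- rep(Inf, n)
  early <- u >= s60            # death in (0, 60]
  late <- u < s60 & u >= s365  # death in (60, 365]
  if (any(early)) t[early] <- -log(u[early]) / hz[["hazard1"]]
  if (any(late)) {
    t[late] <- 60 + (-log(u[late]) - 60 * hz[["hazard1"]]) / hz[["hazard2"]]
  }
  t
}

# positive-part resource draw: log-normal for day totals, shifted negative
# binomial for counts (both guaranteed >= 1)
draw_positive <- function(n, family, mean, sd) {
  if (n == 0) return(numeric(0))
  if (family == "lognormal") {
    p <- lnorm_pars(mean, sd)
    pmax(1, round(stats::rlnorm(n, p$meanlog, p$sdlog)))
  } else if (family == "negbin") {
    mu <- max(mean - 1, 0.1)
    v <- sd^2
    if (v > mu) {
      size <- mu^2 / (v - mu)
      1 + stats::rnbinom(n, mu = mu, size = size)
    } else {
      1 + stats::rpois(n, mu)
    }
  } else {
    stop("unknown positive-part family: ", family, call. = FALSE)
  }
}

#' Generate a synthetic two-arm cohort
#'
#' Draws one patient-level cohort with the statistical structure a
#' trial-based economic evaluation assumes: per-arm survival from a
#' two-piece exponential solved from the configured day-60/day-365 anchors
#' (administrative censoring at day 365), log-normal hospital costs matched
#' by moments, baseline covariates (age, sex, race, APACHE III, fluid
#' strategy, tidal volume, delay to protocol, diagnosis), interview
#' utilities on \[0, 1\] generated only for patients alive at each wave and
#' thinned by the per-wave completion probabilities, and post-discharge
#' resource-use counts as prevalence Bernoulli times a heavy-tailed
#' positive part. All randomness flows from `config$seed`, so identical
#' configurations reproduce identical cohorts.
#'
#' @param config A [cohort_config()].
#' @return A data frame, one row per patient: identifiers and covariates,
#'   `death_day` (NA if alive through follow-up), `censor_day`,
#'   `discharge_day`, `discharged_alive`, `hospital_cost` (2010 dollars),
#'   wide utility columns `u_day61, ...` with matching `proxy_day*` flags,
#'   and resource-use counts (`home_oxygen_days`, `home_help_days`,
#'   `rehab_days`, `snf_vent_days`, `rehosp_total_days`, `rehosp_icu_days`,
#'   `rehosp_vent_days`, `ed_visits`, `dr_visits`, `medication_days`,
#'   `lost_work_days`).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_per_arm = 30))
#' nrow(cohort)
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  withr::with_seed(config$seed, {
    arms <- lapply(config$arms, function(arm) generate_arm(config, arm))
    cohort <- do.call(rbind, arms)
  })
  rownames(cohort) <- NULL
  cohort
}

generate_arm <- function(config, arm) {
  n <- config$n_per_arm
  anch <- config$mortality_anchors[[arm]]

  t_death <- draw_twopiece_survival(n, anch[["s60"]], anch[["s365"]])
  death_day <- ifelse(t_death <= 365, round(t_death, 1), NA_real_)
  censor_day <- ifelse(is.na(death_day), 365, NA_real_)

  age <- round(pmin(90, pmax(18, stats::rnorm(n, 50, 16))))
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.47, 0.53))
  race <- sample(c("white", "black", "hispanic", "other"), n,
                 replace = TRUE, prob = c(0.68, 0.20, 0.09, 0.03))
  apache3 <- round(pmax(10, stats::rnorm(n, 94, 31)))
  fluid_strategy <- sample(c("liberal", "conservative"), n, replace = TRUE)
  tidal_volume <- round(pmax(3, stats::rnorm(n, 7.15, 1.55)), 1)
  delay_to_protocol <- round(pmax(0.5, stats::rnorm(n, 24, 14)), 1)
  diagnosis <- sample(c("pneumonia", "sepsis", "aspiration", "trauma", "other"),
                      n, replace = TRUE, prob = c(0.46, 0.22, 0.16, 0.07, 0.09))

  los_p <- lnorm_pars(config$los_mean[[arm]], config$los_sd[[arm]])
  los <- pmax(1, round(stats::rlnorm(n, los_p$meanlog, los_p$sdlog), 1))
  discharged_alive <- is.na(death_day) | death_day > los
  discharge_day <- ifelse(discharged_alive, los, death_day)

  cost_p <- lnorm_pars(config$hospital_cost_mean[[arm]] * 1000,
                       config$hospital_cost_sd[[arm]] * 1000)
  hospital_cost <- round(stats::rlnorm(n, cost_p$meanlog, cost_p$sdlog), 2)

  # utilities: logit-normal around the wave median (median preserved under
  # the monotone logistic transform), patient random effect + wave noise
  meds <- config$utility_medians[[arm]]
  waves <- config$interview_days
  b <- stats::rnorm(n, 0, config$utility_patient_sd)
  u_mat <- matrix(NA_real_, n, length(waves))
  proxy_mat <- matrix(NA, n, length(waves))
  for (j in seq_along(waves)) {
    alive <- is.na(death_day) | death_day > waves[j]
    done <- alive & stats::runif(n) < config$interview_completion_probs[j]
    val <- stats::plogis(stats::qlogis(meds[j]) + b +
                           stats::rnorm(n, 0, config$utility_wave_sd))
    u_mat[done, j] <- round(val[done], 3)
    proxy_mat[done, j] <- stats::runif(sum(done)) < config$proxy_prob
  }
  colnames(u_mat) <- paste0("u_day", waves)
  colnames(proxy_mat) <- paste0("proxy_day", waves)

  # post-discharge resource use: survivors only, prevalence Bernoulli times
  # a positive part; medication counts become medication-days at 30 d each
  rp <- config$resource_use_params[config$resource_use_params$arm == arm, ]
  res <- list(
    home_oxygen_days = numeric(n), home_help_days = numeric(n),
    rehab_days = numeric(n), snf_vent_days = numeric(n),
    rehosp_total_days = numeric(n), rehosp_icu_days = numeric(n),
    rehosp_vent_days = numeric(n), ed_visits = numeric(n),
    dr_visits = numeric(n), medication_days = numeric(n),
    lost_work_days = numeric(n)
  )
  for (k in seq_len(nrow(rp))) {
    cat_k <- rp$category[k]
    users <- discharged_alive & stats::runif(n) < rp$prevalence[k]
    draw <- draw_positive(sum(users), rp$family[k], rp$mean[k], rp$sd[k])
    if (cat_k == "medications") {
      res$medication_days[users] <- draw * 30
    } else {
      res[[cat_k]][users] <- draw
    }
  }
  # ICU and ventilated fractions of re-hospitalization days (not reported;
  # Beta-fraction splits keep the nesting invariants by construction)
  has_rehosp <- res$rehosp_total_days > 0
  if (any(has_rehosp)) {
    tot <- res$rehosp_total_days[has_rehosp]
    icu <- round(tot * stats::rbeta(sum(has_rehosp), 1.5, 3.5))
    vent <- round(icu * stats::rbeta(sum(has_rehosp), 1, 3))
    res$rehosp_icu_days[has_rehosp] <- icu
    res$rehosp_vent_days[has_rehosp] <- vent
  }
  lw <- config$lost_work
  lw_users <- discharged_alive & stats::runif(n) < lw$prevalence
  res$lost_work_days[lw_users] <-
    pmin(365, draw_positive(sum(lw_users), "lognormal", lw$mean, lw$sd))

  out <- data.frame(
    id = paste0(arm, "-", seq_len(n)),
    arm = arm, age = age, sex = sex, race = race, apache3 = apache3,
    fluid_strategy = fluid_strategy, tidal_volume = tidal_volume,
    delay_to_protocol = delay_to_protocol, diagnosis = diagnosis,
    death_day = death_day, censor_day = censor_day,
    discharge_day = discharge_day, discharged_alive = discharged_alive,
    hospital_cost = hospital_cost,
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(u_mat), as.data.frame(proxy_mat),
        as.data.frame(res))
}

#' Write / read a cohort as CSV
#'
#' One row per patient, utilities wide (`u_day61`, `u_day183`, ...), the
#' layout produced by [generate_cohort()].
#'
#' @param cohort A cohort data frame.
#' @param path File path.
#' @return `read_cohort()` returns the cohort data frame;
#'   `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
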