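#' Default subgroup specifications
#'
#' The prespecified strata of the subgroup analysis: age (<45, 45-64,
#' >64), sex, race/ethnicity, fluid strategy, APACHE III score (cut at 90,
#' ties to the lower stratum), tidal volume (cut at 6.9 mL/kg, ties low),
#' delay from diagnosis to protocol initiation (cut at 21.5 h, ties low),
#' and diagnosis (sepsis / pneumonia / aspiration, overlapping
#' selections, not a partition).
#'
#' @return A named list of predicate functions over the cohort data frame.
#' @export
subgroup_specs <- function() {
  list(
    "all" = function(d) rep(TRUE, nrow(d)),
    "age <45" = function(d) d$age < 45,
    "age 45-64" = function(d) d$age >= 45 & d$age <= 64,
    "age >64" = function(d) d$age > 64,
    "female" = function(d) d$sex == "F",
    "male" = function(d) d$sex == "M",
    "white" = function(d) d$race == "white",
    "black" = function(d) d$race == "black",
    "hispanic" = function(d) d$race == "hispanic",
    "fluid liberal" = function(d) d$fluid_strategy == "liberal",
    "fluid conservative" = function(d) d$fluid_strategy == "conservative",
    "APACHE III >90" = function(d) d$apache3 > 90,
    "APACHE III <=90" = function(d) d$apache3 <= 90,
    "tidal volume >6.9" = function(d) d$tidal_volume > 6.9,
    "tidal volume <=6.9" = function(d) d$tidal_volume <= 6.9,
    "delay >21.5h" = function(d) d$delay_to_protocol > 21.5,
    "delay <=21.5h" = function(d) d$delay_to_protocol <= 21.5,
    "sepsis" = function(d) d$diagnosis == "sepsis",
    "pneumonia" = function(d) d$diagnosis == "pneumonia",
    "aspiration" = function(d) d$diagnosis == "aspiration"
  )
}

#' Subgroup analyses
#'
#' Runs a full bootstrap PSA within each subgroup of a projected cohort
#' and tabulates the incremental estimates, the probability that the
#' intervention is inferior (more costly and less effective) and the
#' probability that it is acceptable at a willingness-to-pay threshold.
#' Subgroups empty in either arm are skipped with a warning.
#'
#' @param cohort A projected cohort (see [project_cohort()]).
#' @param specs Named list of predicate functions, see [subgroup_specs()].
#' @param n_trials,seed PSA settings (the same seed is used for every
#'   subgroup, so the identity subgroup reproduces the all-cohort run).
#' @param wtp_k Willingness-to-pay threshold in $k/QALY for the
#'   acceptability column (default 50).
#' @param arms `c(intervention, comparator)`.
#' @return A data frame: `subgroup`, `n`, `inc_cost_k`, `inc_qaly`,
#'   `pct_inferior`, `pct_below_wtp`.
#' @export
run_subgroups <- function(cohort, specs = subgroup_specs(),
                          n_trials = 1000, seed = 20110721, wtp_k = 50,
                          arms = c("PAC", "CVC")) {
  rows <- lapply(names(specs), function(nm) {
    sel <- specs[[nm]](cohort)
    sub <- cohort[sel, , drop = FALSE]
    if (!all(vapply(arms, function(a) any(sub$arm == a), logical(1)))) {
      warning("subgroup '", nm, "' empty in at least one arm; skipped",
              call. = FALSE)
      return(NULL)
    }
    cloud <- psa_bootstrap(sub, n_trials = n_trials, seed = seed, arms = arms)
    data.frame(
      subgroup = nm, n = nrow(sub),
      inc_cost_k = mean(cloud$delta_cost_k),
      inc_qaly = mean(cloud$delta_effect_qaly),
      pct_inferior = 100 * quadrant_probs(cloud)$dominated,
      pct_below_wtp = 100 * mean(wtp_k * cloud$delta_effect_qaly -
                                   cloud$delta_cost_k >= 0)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default one-way sensitivity scenarios
#'
#' The built-in one-way scenarios: halved life expectancy, post-year-one
#' utility scaled by 0.75 and 1.25, discount rate raised to 5%, annual
#' post-year-one cost halved and doubled, and physician-visit cost halved
#' and doubled (the closest implementable surrogate for varying physician
#' reimbursements).
#'
#' @return A named list; each scenario has `params` (multiplicative or
#'   absolute overrides on [reference_case_params()] fields) and `weights`
#'   (multipliers on [cost_weights()] fields).
#' @export
default_scenarios <- function() {
  list(
    "reference" = list(params = list(), weights = list()),
    "life expectancy x0.5" = list(
      params = list(life_expectancy_multiplier = 0.5), weights = list()
    ),
    "utility beyond 1y x0.75" = list(
      params = list(utility_scale = 0.75), weights = list()
    ),
    "utility beyond 1y x1.25" = list(
      params = list(utility_scale = 1.25), weights = list()
    ),
    "discount rate 5%" = list(
      params = list(discount_rate = 0.05), weights = list()
    ),
    "annual cost x0.5" = list(
      params = list(annual_cost_scale = 0.5), weights = list()
    ),
    "annual cost x2" = list(
      params = list(annual_cost_scale = 2), weights = list()
    ),
    "physician visits x0.5" = list(params = list(),
                                   weights = list(dr_visit = 0.5)),
    "physician visits x2" = list(params = list(),
                                 weights = list(dr_visit = 2))
  )
}

apply_scenario <- function(scenario, params, weights) {
  p <- unclass(params)
  ov <- scenario$params
  if (!is.null(ov$life_expectancy_multiplier)) {
    p$life_expectancy_multiplier <- ov$life_expectancy_multiplier
  }
  if (!is.null(ov$discount_rate)) p$discount_rate <- ov$discount_rate
  if (!is.null(ov$utility_scale)) {
    p$utility_beyond_one_year <-
      min(1, p$utility_beyond_one_year * ov$utility_scale)
  }
  if (!is.null(ov$annual_cost_scale)) {
    p$annual_cost_beyond_one_year <-
      p$annual_cost_beyond_one_year * ov$annual_cost_scale
  }
  w <- unclass(weights)
  for (nm in names(scenario$weights)) {
    if (!nm %in% names(w)) {
      stop("scenario overrides unknown cost weight: ", nm, call. = FALSE)
    }
    w[[nm]] <- w[[nm]] * scenario$weights[[nm]]
  }
  list(params = do.call(reference_case_params, p),
       weights = do.call(cost_weights, w))
}

#' One-way sensitivity analyses
#'
#' Re-runs costing, projection and the bootstrap PSA of a cohort under
#' each scenario's parameter overrides (same seed throughout) and reports
#' incremental cost and QALYs with percent changes against the reference
#' scenario.
#'
#' @param cohort A cohort with one-year effects computed (output of
#'   [one_year_effect()]); costs and projection are recomputed per
#'   scenario.
#' @param scenarios A scenario list, see [default_scenarios()]. A
#'   `"reference"` entry is required (added if missing).
#' @param weights Baseline [cost_weights()].
#' @param params Baseline [reference_case_params()].
#' @param life_table Life table for the projection.
#' @param n_trials,seed PSA settings.
#' @param arms `c(intervention, comparator)`.
#' @return A data frame: `scenario`, `inc_cost_k`, `inc_qaly`,
#'   `pct_change_cost`, `pct_change_qaly` (changes relative to the
#'   reference scenario; 0 for the reference itself).
#' @export
run_sensitivity <- function(cohort, scenarios = default_scenarios(),
                            weights = cost_weights(),
                            params = reference_case_params(),
                            life_table = read_life_table(),
                            n_trials = 1000, seed = 20110721,
                            arms = c("PAC", "CVC")) {
  if (!"reference" %in% names(scenarios)) {
    scenarios <- c(list(reference = list(params = list(), weights = list())),
                   scenarios)
  }
  rows <- lapply(names(scenarios), function(nm) {
    sc <- apply_scenario(scenarios[[nm]], params, weights)
    streams <- project_cohort(cost_stream(cohort, sc$weights),
                              params = sc$params, life_table = life_table)
    cloud <- psa_bootstrap(streams, n_trials = n_trials, seed = seed,
                           arms = arms)
    data.frame(scenario = nm,
               inc_cost_k = mean(cloud$delta_cost_k),
               inc_qaly = mean(cloud$delta_effect_qaly))
  })
  out <- do.call(rbind, rows)
  ref <- out[out$scenario == "reference", ]
  pct <- function(x, x0) if (abs(x0) < 1e-12) NA_real_ else 100 * (x - x0) / abs(x0)
  out$pct_change_cost <- vapply(out$inc_cost_k, pct, numeric(1),
                                x0 = ref$inc_cost_k)
  out$pct_change_qaly <- vapply(out$inc_qaly, pct, numeric(1),
                                x0 = ref$inc_qaly)
  rownames(out) <- NULL
  out
}
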