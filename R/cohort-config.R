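#' Configuration for the synthetic two-arm cohort generator
#'
#' Bundles every tunable of [generate_cohort()]. The defaults emulate a
#' two-arm critical-care trial of hemodynamic monitoring (pulmonary artery
#' catheter, `PAC`, versus central venous catheter, `CVC`) in acute lung
#' injury: roughly 300 patients per arm, two-month mortality near 26%/25%
#' and one-year mortality near 36%/32%, heavy right-tailed hospital costs
#' (mean near $97k/$89k with SDs near the means), utility trajectories that
#' start around 0.5 at two months and plateau by nine months, and
#' post-discharge resource-use with the prevalence/positive-part structure
#' typical of ALI survivors.
#'
#' @param n_per_arm Patients per arm (>= 1).
#' @param mortality_anchors Named list (one element per arm) of
#'   `c(s60 = , s365 = )` survival probabilities at day 60 and day 365.
#'   Within each arm `s365 <= s60` must hold.
#' @param hospital_cost_mean,hospital_cost_sd Named numeric vectors (per
#'   arm), hospital cost moments in thousands of 2010 dollars.
#' @param los_mean,los_sd Named numeric vectors (per arm), hospital
#'   length-of-stay moments in days.
#' @param utility_medians Named list (per arm) of interview-wave utility
#'   medians on \[0, 1\], one per interview wave.
#' @param utility_patient_sd,utility_wave_sd Logit-scale SDs of the
#'   patient-level random effect and the per-wave noise.
#' @param interview_days Days of the utility interviews. The defaults place
#'   the 2/6/9/12-month interviews at days 61, 183, 274 and 365
#'   (30.4375 days/month).
#' @param interview_completion_probs Per-wave probability that a living
#'   patient completes the interview.
#' @param proxy_prob Probability that a completed interview is answered by a
#'   proxy (carried as a flag, not used in computation).
#' @param resource_use_params Data frame of post-discharge resource-use
#'   generators, columns `category`, `arm`, `prevalence`, `mean`, `sd`,
#'   `family` (`"lognormal"` for day totals, `"negbin"` for counts). See
#'   [default_resource_params()].
#' @param lost_work List `prevalence`, `mean`, `sd` for lost work days among
#'   survivors (applied to both arms).
#' @param seed Integer seed; all randomness in [generate_cohort()] flows
#'   from it.
#'
#' @return A list of class `cohort_config`.
#' @seealso [generate_cohort()], [default_resource_params()]
#' @export
#' @examples
#' cfg <- cohort_config(n_per_arm = 50)
#' cohort <- generate_cohort(cfg)
#' table(cohort$arm)
cohort_config <- function(n_per_arm = 300,
                          mortality_anchors = list(
                            PAC = c(s60 = 0.738, s365 = 0.644),
                            CVC = c(s60 = 0.749, s365 = 0.681)
                          ),
                          hospital_cost_mean = c(PAC = 96.8, CVC = 89.2),
                          hospital_cost_sd = c(PAC = 86.8, CVC = 74.5),
                          los_mean = c(PAC = 24.4, CVC = 23.8),
                          los_sd = c(PAC = 19.2, CVC = 19.8),
                          utility_medians = list(
                            PAC = c(0.47, 0.55, 0.61, 0.61),
                            CVC = c(0.51, 0.60, 0.66, 0.66)
                          ),
                          utility_patient_sd = 0.6,
                          utility_wave_sd = 0.7,
                          interview_days = c(61, 183, 274, 365),
                          interview_completion_probs = c(0.75, 0.75, 0.80, 0.80),
                          proxy_prob = 0.25,
                          resource_use_params = default_resource_params(),
                          lost_work = list(prevalence = 0.40, mean = 90, sd = 80),
                          seed = 20110721) {
  cfg <- structure(
    list(
      n_per_arm = n_per_arm,
      arms = names(mortality_anchors),
      mortality_anchors = mortality_anchors,
      hospital_cost_mean = hospital_cost_mean,
      hospital_cost_sd = hospital_cost_sd,
      los_mean = los_mean,
      los_sd = los_sd,
      utility_medians = utility_medians,
      utility_patient_sd = utility_patient_sd,
      utility_wave_sd = utility_wave_sd,
      interview_days = interview_days,
      interview_completion_probs = interview_completion_probs,
      proxy_prob = proxy_prob,
      resource_use_params = resource_use_params,
      lost_work = lost_work,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
}

#' Validate a cohort configuration
#'
#' Checks the structural invariants of a [cohort_config()]: probabilities in
#' \[0, 1\], per-arm survival anchors ordered (`s365 <= s60`), at least one
#' patient per arm, non-negative SDs.
#'
#' @param config A `cohort_config` object.
#' @return `config`, invisibly usable, after validation (errors otherwise).
#' @export
validate_cohort_config <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_per_arm < 1) stop("n_per_arm must be >= 1", call. = FALSE)
  if (length(config$arms) < 2) stop("need at least two arms", call. = FALSE)
  for (arm in config$arms) {
    a <- config$mortality_anchors[[arm]]
    assert_prob(a, paste0("mortality anchors (", arm, ")"))
    if (a[["s365"]] > a[["s60"]] + 1e-12) {
      stop(sprintf(
        "inconsistent anchors for arm %s: day-365 survival (%.3f) exceeds day-60 survival (%.3f)",
        arm, a[["s365"]], a[["s60"]]
      ), call. = FALSE)
    }
    if (config$hospital_cost_sd[[arm]] < 0 || config$los_sd[[arm]] < 0) {
      stop("cost and length-of-stay SDs must be >= 0", call. = FALSE)
    }
    assert_prob(config$utility_medians[[arm]], paste0("utility medians (", arm, ")"))
    if (length(config$utility_medians[[arm]]) != length(config$interview_days)) {
      stop("one utility median per interview wave is required", call. = FALSE)
    }
  }
  assert_prob(config$interview_completion_probs, "interview completion probabilities")
  assert_prob(config$proxy_prob, "proxy probability")
  assert_prob(config$resource_use_params$prevalence, "resource-use prevalences")
  assert_prob(config$lost_work$prevalence, "lost-work prevalence")
  if (any(config$resource_use_params$sd < 0)) {
    stop("resource-use SDs must be >= 0", call. = FALSE)
  }
  config
}

#' Default post-discharge resource-use generator parameters
#'
#' Per-arm prevalence (fraction of survivors with any use) and positive-part
#' moments for each post-discharge resource category: home oxygen days,
#' total re-hospitalization days, rehabilitation days, emergency-department
#' visits, physician visits and medication counts. Day totals use a
#' log-normal positive part, counts a shifted negative binomial; both are
#' heavy right-tailed, as the reported SDs exceed the means. Medication
#' counts are converted to medication-days (30 days per reported
#' medication) by the generator. Home-help and ventilated
#' skilled-nursing-facility days are carried in the schema with zero use.
#'
#' @return A data frame with columns `category`, `arm`, `prevalence`,
#'   `mean`, `sd`, `family`.
#' @export
default_resource_params <- function() {
  rbind(
    data.frame(
      category = c("home_oxygen_days", "rehosp_total_days", "rehab_days",
                   "ed_visits", "dr_visits", "medications"),
      arm = "PAC",
      prevalence = c(0.314, 0.481, 0.343, 0.586, 0.967, 0.881),
      mean = c(90.4, 20.2, 72.9, 4.3, 20.3, 18.6),
      sd = c(109.4, 28.5, 94.3, 4.5, 22.0, 15.9),
      family = c("lognormal", "lognormal", "lognormal",
                 "negbin", "negbin", "negbin")
    ),
    data.frame(
      category = c("home_oxygen_days", "rehosp_total_days", "rehab_days",
                   "ed_visits", "dr_visits", "medications"),
      arm = "CVC",
      prevalence = c(0.292, 0.425, 0.292, 0.532, 0.982, 0.918),
      mean = c(86.8, 17.7, 54.0, 3.1, 19.4, 17.7),
      sd = c(108.7, 23.0, 68.4, 3.1, 30.6, 15.9),
      family = c("lognormal", "lognormal", "lognormal",
                 "negbin", "negbin", "negbin")
    )
  )
}
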