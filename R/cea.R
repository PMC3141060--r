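#' Winsorize at the 95th percentile
#'
#' Replaces values above the empirical 95th percentile of the input by that
#' percentile, leaving all other values unchanged. Used to damp the
#' influence of extreme per-patient cost outliers before averaging.
#'
#' @param values Non-empty numeric vector.
#' @param probs Percentile level (default 0.95).
#' @return Vector of the same length; its maximum equals the percentile.
#' @export
#' @examples
#' winsorize_p95(1:100)
winsorize_p95 <- function(values, probs = 0.95) {
  if (length(values) == 0 || all(is.na(values))) {
    stop("cannot winsorize an empty vector", call. = FALSE)
  }
  cap <- stats::quantile(values, probs, na.rm = TRUE, names = FALSE)
  pmin(values, cap)
}

#' Incremental difference between strategies
#'
#' Difference of comparable quantities, intervention minus comparator
#' (e.g. PAC minus CVC), the numerator/denominator convention of the
#' incremental cost-effectiveness ratio.
#'
#' @param intervention,comparator Numeric (vectorized).
#' @return `intervention - comparator`.
#' @export
#' @examples
#' incremental(191.1, 176.7)
incremental <- function(intervention, comparator) {
  intervention - comparator
}

new_psa_cloud <- function(delta_cost_k, delta_effect_qaly, seed = NA_integer_,
                          arm_means = NULL) {
  structure(
    data.frame(trial = seq_along(delta_cost_k),
               delta_cost_k = delta_cost_k,
               delta_effect_qaly = delta_effect_qaly),
    class = c("psa_cloud", "data.frame"),
    seed = seed, arm_means = arm_means
  )
}

#' Bootstrap probabilistic sensitivity analysis
#'
#' Nonparametric patient-level bootstrap within arm: each simulated trial
#' resamples patients with replacement to the original arm sizes and
#' recomputes the per-arm mean lifetime cost (winsorized at the 95th
#' percentile within the resample, costs only) and mean lifetime QALYs.
#' The cloud collects the per-trial incremental pairs, intervention minus
#' comparator, with costs in thousands of dollars.
#'
#' @param cohort A projected cohort (columns `arm`, `lifetime_cost` in
#'   dollars, `lifetime_qalys`).
#' @param n_trials Number of simulated trials (default 5000).
#' @param seed Integer seed; identical seeds give identical clouds.
#' @param arms Length-2 character vector `c(intervention, comparator)`.
#' @param winsorize_costs Winsorize per-patient costs within each resample
#'   (default TRUE).
#' @return A data frame of class `psa_cloud` with columns `trial`,
#'   `delta_cost_k`, `delta_effect_qaly`; attribute `arm_means` holds the
#'   per-arm mean of the per-trial means.
#' @export
psa_bootstrap <- function(cohort, n_trials = 5000, seed = 20110721,
                          arms = c("PAC", "CVC"), winsorize_costs = TRUE) {
  for (arm in arms) {
    if (!any(cohort$arm == arm)) {
      stop("arm has no patients: ", arm, call. = FALSE)
    }
  }
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  arm_rows <- lapply(arms, function(a) which(cohort$arm == a))
  names(arm_rows) <- arms
  withr::with_seed(as.integer(seed), {
    per_arm <- lapply(arms, function(a) {
      rows <- arm_rows[[a]]
      n <- length(rows)
      cost <- cohort$lifetime_cost[rows] / 1000
      qaly <- cohort$lifetime_qalys[rows]
      means <- matrix(NA_real_, n_trials, 2,
                      dimnames = list(NULL, c("cost_k", "qaly")))
      for (b in seq_len(n_trials)) {
        idx <- sample.int(n, n, replace = TRUE)
        ck <- cost[idx]
        if (winsorize_costs) ck <- winsorize_p95(ck)
        means[b, ] <- c(mean(ck), mean(qaly[idx]))
      }
      means
    })
  })
  names(per_arm) <- arms
  cloud <- new_psa_cloud(
    per_arm[[1]][, "cost_k"] - per_arm[[2]][, "cost_k"],
    per_arm[[1]][, "qaly"] - per_arm[[2]][, "qaly"],
    seed = as.integer(seed),
    arm_means = lapply(per_arm, colMeans)
  )
  cloud
}

#' Parametric probabilistic sensitivity analysis
#'
#' Draws each arm's mean lifetime cost and mean lifetime QALYs from normal
#' distributions parameterized by supplied means and SDs (the sampling
#' distributions of the arm means), optionally with a within-arm
#' cost-effect correlation, and forms the per-trial incremental pairs.
#' Useful to reconstruct published summary-level analyses when patient
#' data are unavailable.
#'
#' @param arm_moments A list with one element per arm (intervention first),
#'   each a list/vector with `cost_mean`, `cost_sd` (thousand $),
#'   `qaly_mean`, `qaly_sd`.
#' @param n_trials Number of simulated trials.
#' @param seed Integer seed.
#' @param rho Within-arm correlation between cost and effect draws
#'   (default 0, independent normals).
#' @return A `psa_cloud`.
#' @export
#' @examples
#' cloud <- psa_parametric(list(
#'   PAC = c(cost_mean = 191.1, cost_sd = 8.5, qaly_mean = 4.54, qaly_sd = 0.21),
#'   CVC = c(cost_mean = 176.7, cost_sd = 7.1, qaly_mean = 4.83, qaly_sd = 0.21)
#' ), n_trials = 1000, seed = 1)
psa_parametric <- function(arm_moments, n_trials = 5000, seed = 20110721,
                           rho = 0) {
  stopifnot(length(arm_moments) == 2, abs(rho) <= 1)
  withr::with_seed(as.integer(seed), {
    draws <- lapply(arm_moments, function(m) {
      m <- as.list(m)
      z1 <- stats::rnorm(n_trials)
      z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n_trials)
      list(cost = m$cost_mean + m$cost_sd * z1,
           qaly = m$qaly_mean + m$qaly_sd * z2)
    })
  })
  new_psa_cloud(draws[[1]]$cost - draws[[2]]$cost,
                draws[[1]]$qaly - draws[[2]]$qaly,
                seed = as.integer(seed))
}

#' Cost-effectiveness plane quadrant probabilities
#'
#' Fractions of simulated trials in each quadrant of the incremental
#' cost-effectiveness plane. `dominated` is more costly and less effective
#' (`delta_cost > 0` and `delta_effect < 0`); `dominant` is its closed
#' complement corner (`delta_cost <= 0`, `delta_effect >= 0`);
#' `tradeoff_ne` and `tradeoff_sw` are the remaining quadrants. The four
#' regions partition the plane, so the trial counts (attached as attribute
#' `counts`, with `n_trials`) sum to the number of trials exactly.
#'
#' @param cloud A `psa_cloud`.
#' @return Named list of four probabilities, with attributes `counts` and
#'   `n_trials`.
#' @export
quadrant_probs <- function(cloud) {
  dc <- cloud$delta_cost_k; de <- cloud$delta_effect_qaly
  n <- length(dc)
  if (n == 0) stop("empty PSA cloud", call. = FALSE)
  counts <- c(
    dominated = sum(dc > 0 & de < 0),
    dominant = sum(dc <= 0 & de >= 0),
    tradeoff_ne = sum(dc > 0 & de >= 0),
    tradeoff_sw = sum(dc <= 0 & de < 0)
  )
  structure(as.list(counts / n), counts = counts, n_trials = n)
}

#' Probability of exceeding willingness-to-pay thresholds
#'
#' For each threshold `lambda` ($k/QALY), the fraction of trials whose net
#' monetary benefit `lambda * delta_effect - delta_cost` is negative, i.e.
#' trials in which the intervention is worse than the threshold allows.
#' Dominated trials have negative net benefit at every threshold, so they
#' always count as exceeding.
#'
#' @param cloud A `psa_cloud`.
#' @param thresholds Willingness-to-pay values in $k/QALY.
#' @return Named numeric vector of probabilities.
#' @export
threshold_exceedance_probs <- function(cloud, thresholds = c(50, 100)) {
  if (nrow(cloud) == 0) stop("empty PSA cloud", call. = FALSE)
  vapply(thresholds, function(lam) {
    mean(lam * cloud$delta_effect_qaly - cloud$delta_cost_k < 0)
  }, numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(paste0("wtp_", thresholds, "k"))
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay `lambda` the acceptance probability is the
#' fraction of trials with non-negative net monetary benefit,
#' `lambda * delta_effect - delta_cost >= 0`. At `lambda = 0` this is
#' `P(delta_cost <= 0)`; as `lambda` grows it approaches the fraction of
#' effect-positive trials (plus effect-neutral, cost-saving ones), attached
#' as attribute `limit_inf`.
#'
#' @param cloud A `psa_cloud`.
#' @param wtp_grid Willingness-to-pay grid in $k/QALY (default 0 to 1000
#'   by 10).
#' @return A data frame of class `cea_curve` with columns `wtp_k`,
#'   `probability`.
#' @export
ceac <- function(cloud, wtp_grid = seq(0, 1000, by = 10)) {
  if (length(wtp_grid) == 0) stop("empty willingness-to-pay grid", call. = FALSE)
  de <- cloud$delta_effect_qaly; dc <- cloud$delta_cost_k
  prob <- vapply(wtp_grid, function(lam) mean(lam * de - dc >= 0), numeric(1))
  structure(
    data.frame(wtp_k = wtp_grid, probability = prob),
    class = c("cea_curve", "data.frame"),
    limit_inf = mean(de > 0 | (de == 0 & dc <= 0))
  )
}

#' Point estimate and classification of the incremental result
#'
#' Means of the PSA cloud with the cost-effectiveness classification:
#' `dominated` (more costly, less effective), `dominant` (no more costly,
#' no less effective) or `tradeoff`. An ICER (`delta_cost / delta_effect`,
#' $k/QALY) is reported only for tradeoffs — a ratio is not informative
#' for dominated or dominant strategies.
#'
#' @param cloud A `psa_cloud`.
#' @return A list of class `icer_result`: `mean_delta_cost_k`,
#'   `mean_delta_effect_qaly`, `classification`, and `icer_k_per_qaly`
#'   (`NA` unless tradeoff).
#' @export
icer_result <- function(cloud) {
  dc <- mean(cloud$delta_cost_k)
  de <- mean(cloud$delta_effect_qaly)
  classification <- if (dc > 0 && de < 0) {
    "dominated"
  } else if (dc <= 0 && de >= 0) {
    "dominant"
  } else {
    "tradeoff"
  }
  structure(
    list(mean_delta_cost_k = dc, mean_delta_effect_qaly = de,
         classification = classification,
         icer_k_per_qaly = if (classification == "tradeoff") dc / de
                           else NA_real_),
    class = "icer_result"
  )
}

#' Confidence ellipse of the incremental cloud
#'
#' The `level` confidence ellipse of the bivariate (incremental effect,
#' incremental cost) distribution, from the cloud's mean and covariance at
#' the chi-square(2 df) quantile. For bivariate-normal clouds the fraction
#' of points inside converges to `level`.
#'
#' @param cloud A `psa_cloud` with at least 3 trials and non-degenerate
#'   covariance.
#' @param level Coverage level in \[0, 1) (default 0.95); level 0 gives a
#'   degenerate point at the mean.
#' @return A list of class `ce_ellipse`: `center` (effect, cost), `radii`
#'   (semi-axis lengths, major first), `angle` (radians of the major axis
#'   from the effect axis), `cov`, `level`.
#' @seealso [ellipse_points()], [in_ellipse()]
#' @export
confidence_ellipse <- function(cloud, level = 0.95) {
  if (nrow(cloud) < 3) stop("need at least 3 trials", call. = FALSE)
  xy <- cbind(effect = cloud$delta_effect_qaly, cost = cloud$delta_cost_k)
  S <- stats::cov(xy)
  if (!is.finite(det(S)) || det(S) <= 1e-12 * prod(diag(S) + 1e-300)) {
    stop("degenerate covariance: the cloud has no two-dimensional spread",
         call. = FALSE)
  }
  e <- eigen(S, symmetric = TRUE)
  q <- stats::qchisq(level, df = 2)
  structure(
    list(center = colMeans(xy),
         radii = sqrt(pmax(e$values, 0) * q),
         angle = atan2(e$vectors[2, 1], e$vectors[1, 1]),
         cov = S, level = level),
    class = "ce_ellipse"
  )
}

#' @rdname confidence_ellipse
#' @param ellipse A `ce_ellipse`.
#' @param n Number of polygon points.
#' @export
ellipse_points <- function(ellipse, n = 200) {
  theta <- seq(0, 2 * pi, length.out = n)
  R <- matrix(c(cos(ellipse$angle), sin(ellipse$angle),
                -sin(ellipse$angle), cos(ellipse$angle)), 2, 2)
  pts <- R %*% rbind(ellipse$radii[1] * cos(theta),
                     ellipse$radii[2] * sin(theta))
  data.frame(effect = ellipse$center[1] + pts[1, ],
             cost = ellipse$center[2] + pts[2, ])
}

#' @rdname confidence_ellipse
#' @param effect,cost Point coordinates (vectorized).
#' @export
in_ellipse <- function(ellipse, effect, cost) {
  xy <- cbind(effect - ellipse$center[1], cost - ellipse$center[2])
  d2 <- rowSums((xy %*% solve(ellipse$cov)) * xy)
  d2 <= stats::qchisq(ellipse$level, df = 2)
}
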