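#' Compute all per-patient streams
#'
#' Convenience wrapper chaining [cost_stream()], [one_year_effect()] and
#' [project_cohort()] on a raw cohort.
#'
#' @param cohort A cohort data frame from [generate_cohort()] or
#'   [read_cohort()].
#' @param weights A [cost_weights()].
#' @param params A [reference_case_params()].
#' @param life_table A life-table data frame.
#' @param interview_days,hospital_phase Passed to [one_year_effect()].
#' @return The cohort with cost, effect and lifetime columns appended;
#'   attribute `n_imputed` carries the utility-imputation count.
#' @export
compute_patient_streams <- function(cohort, weights = cost_weights(),
                                    params = reference_case_params(),
                                    life_table = read_life_table(),
                                    interview_days = c(61, 183, 274, 365),
                                    hospital_phase = "carry_back") {
  out <- one_year_effect(cost_stream(cohort, weights),
                         interview_days = interview_days,
                         hospital_phase = hospital_phase)
  n_imputed <- attr(out, "n_imputed")
  out <- project_cohort(out, params = params, life_table = life_table)
  attr(out, "n_imputed") <- n_imputed
  out
}

#' Run configuration for the reference case
#'
#' @param cohort_config A [cohort_config()] (the cohort is generated), or
#'   `NULL` with `cohort_path` pointing at a cohort CSV.
#' @param cohort_path Optional CSV path of an existing cohort.
#' @param weights,params,life_table Pipeline inputs.
#' @param n_trials,seed PSA settings (default 5000 trials).
#' @param wtp_grid Willingness-to-pay grid in $k/QALY for the CEAC.
#' @param run_subgroups,run_sensitivity Whether to run the subgroup and
#'   one-way sensitivity stages.
#' @param out_dir Output directory for the written artifacts.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort_config = trialcea::cohort_config(),
                       cohort_path = NULL,
                       weights = cost_weights(),
                       params = reference_case_params(),
                       life_table = read_life_table(),
                       n_trials = 5000, seed = 20110721,
                       wtp_grid = seq(0, 1000, by = 10),
                       run_subgroups = FALSE, run_sensitivity = FALSE,
                       out_dir = tempfile("trialcea-run-")) {
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  if (!is.null(cohort_path) && !file.exists(cohort_path)) {
    stop("cohort file not found: ", cohort_path, call. = FALSE)
  }
  structure(
    list(cohort_config = cohort_config, cohort_path = cohort_path,
         weights = weights, params = params, life_table = life_table,
         n_trials = as.integer(n_trials), seed = as.integer(seed),
         wtp_grid = wtp_grid, run_subgroups = run_subgroups,
         run_sensitivity = run_sensitivity, out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full reference case
#'
#' Wires the whole pipeline: cohort (generated or loaded), per-patient
#' cost/effect/lifetime streams, bootstrap PSA, point estimate and
#' classification, CEAC, 95% confidence ellipse, and optionally subgroup
#' and one-way sensitivity tables. All artifacts are written to
#' `config$out_dir` as CSV/JSON along with a run manifest (seed, settings,
#' package version, imputation and winsorization accounting); re-running
#' the same configuration reproduces the outputs exactly.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with elements `cohort`, `streams`, `cloud`,
#'   `icer`, `quadrants`, `thresholds`, `ceac`, `ellipse`, and (when
#'   enabled) `subgroups`, `sensitivity`, plus `out_dir`.
#' @export
run_reference_case <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- if (!is.null(config$cohort_path)) {
    read_cohort(config$cohort_path)
  } else {
    generate_cohort(config$cohort_config)
  }
  interview_days <- config$cohort_config$interview_days %||%
    c(61, 183, 274, 365)

  streams <- compute_patient_streams(
    cohort, weights = config$weights, params = config$params,
    life_table = config$life_table, interview_days = interview_days
  )
  cloud <- psa_bootstrap(streams, n_trials = config$n_trials,
                         seed = config$seed)
  icer <- icer_result(cloud)
  quads <- quadrant_probs(cloud)
  thresh <- threshold_exceedance_probs(cloud)
  curve <- ceac(cloud, config$wtp_grid)
  ellipse <- confidence_ellipse(cloud)

  out <- list(cohort = cohort, streams = streams, cloud = cloud,
              icer = icer, quadrants = quads, thresholds = thresh,
              ceac = curve, ellipse = ellipse, out_dir = config$out_dir)

  if (isTRUE(config$run_subgroups)) {
    out$subgroups <- run_subgroups(streams, n_trials = config$n_trials,
                                   seed = config$seed)
  }
  if (isTRUE(config$run_sensitivity)) {
    base <- one_year_effect(cohort, interview_days = interview_days)
    out$sensitivity <- run_sensitivity(
      base, weights = config$weights, params = config$params,
      life_table = config$life_table, n_trials = config$n_trials,
      seed = config$seed
    )
  }

  write_run_artifacts(out, config)
  invisible(out)
}

write_run_artifacts <- function(out, config) {
  d <- config$out_dir
  write_cohort(out$streams, file.path(d, "patient_streams.csv"))
  utils::write.csv(as.data.frame(out$cloud), file.path(d, "psa_cloud.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(out$ceac), file.path(d, "ceac.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(
      icer = unclass(out$icer), quadrants = out$quadrants,
      threshold_exceedance = as.list(out$thresholds),
      ellipse = list(center = as.list(out$ellipse$center),
                     radii = out$ellipse$radii,
                     angle = out$ellipse$angle, level = out$ellipse$level)
    ),
    file.path(d, "results.json"), auto_unbox = TRUE, digits = NA
  )
  if (!is.null(out$subgroups)) {
    utils::write.csv(out$subgroups, file.path(d, "subgroups.csv"),
                     row.names = FALSE)
  }
  if (!is.null(out$sensitivity)) {
    utils::write.csv(out$sensitivity, file.path(d, "sensitivity.csv"),
                     row.names = FALSE)
  }
  manifest <- list(
    package = "trialcea",
    version = as.character(utils::packageVersion("trialcea")),
    r_version = R.version.string,
    seed = config$seed, n_trials = config$n_trials,
    n_patients = nrow(out$streams),
    n_imputed_utility_trajectories = attr(out$streams, "n_imputed"),
    params = unclass(config$params),
    weights = unclass(config$weights)
  )
  jsonlite::write_json(manifest, file.path(d, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(d)
}

#' Cost-effectiveness plane plot
#'
#' Scatter of the PSA cloud on the incremental cost-effectiveness plane
#' with the confidence ellipse and optional willingness-to-pay rays.
#'
#' @param cloud A `psa_cloud`.
#' @param ellipse Optional `ce_ellipse` to overlay.
#' @param wtp_k Willingness-to-pay slopes ($k/QALY) drawn as reference
#'   lines through the origin.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(cloud, ellipse = NULL, wtp_k = c(50, 100)) {
  p <- ggplot2::ggplot(as.data.frame(cloud),
                       ggplot2::aes(.data$delta_effect_qaly,
                                    .data$delta_cost_k)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Incremental effect (QALYs)",
                  y = "Incremental cost ($k)") +
    ggplot2::theme_minimal()
  for (lam in wtp_k) {
    p <- p + ggplot2::geom_abline(slope = lam, intercept = 0,
                                  linetype = "dashed", colour = "grey50")
  }
  if (!is.null(ellipse)) {
    p <- p + ggplot2::geom_path(
      data = ellipse_points(ellipse),
      ggplot2::aes(.data$effect, .data$cost), colour = "red"
    )
  }
  p
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param curve A `cea_curve` from [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve) {
  ggplot2::ggplot(as.data.frame(curve),
                  ggplot2::aes(.data$wtp_k, .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Willingness-to-pay ($k/QALY)",
                  y = "Probability cost-effective") +
    ggplot2::theme_minimal()
}
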