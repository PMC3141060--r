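# Independent oracles used across the suite. Each is deliberately written
# from the definition (enumeration, fine grids, closed forms), not by
# calling the implementation under test.

# hand product-limit estimator: S(t) at each distinct death time, with
# deaths preceding censorings at tied times
km_hand <- function(times, events) {
  death_times <- sort(unique(times[events]))
  if (length(death_times) == 0) {
    return(data.frame(day = numeric(0), survival = numeric(0)))
  }
  s <- 1
  out <- data.frame(day = death_times, survival = NA_real_)
  for (k in seq_along(death_times)) {
    t <- death_times[k]
    n_risk <- sum(times >= t)
    d <- sum(times == t & events)
    s <- s * (1 - d / n_risk)
    out$survival[k] <- s
  }
  out
}

km_hand_at <- function(times, events, day) {
  h <- km_hand(times, events)
  i <- which(h$day <= day)
  if (length(i) == 0) 1 else h$survival[max(i)]
}

# fine-grid midpoint Riemann sum of the interpolated utility trajectory
riemann_auc <- function(days, utilities, death_day = NA, horizon = 365,
                        hospital_phase = "carry_back", step = 0.01) {
  H <- min(if (is.na(death_day)) Inf else death_day, horizon)
  if (H <= 0) return(0)
  u_at <- function(t) {
    if (t < days[1]) {
      return(if (hospital_phase == "carry_back") utilities[1] else 0)
    }
    if (t >= days[length(days)]) return(utilities[length(utilities)])
    stats::approx(days, utilities, xout = t)$y
  }
  mids <- seq(step / 2, H - step / 2, by = step)
  sum(vapply(mids, u_at, numeric(1))) * step +
    # fractional last cell if H is not a multiple of step
    (H - step * length(mids)) * u_at(H - (H - step * length(mids)) / 2)
}

# closed-form / loop annuity oracle with end-of-year discounting
annuity_loop <- function(amount, years, rate) {
  full <- floor(years)
  v <- 0
  for (t in seq_len(full)) v <- v + amount / (1 + rate)^t
  v + (years - full) * amount / (1 + rate)^ceiling(years)
}

# a small cohort with all downstream columns, shared by several tests
make_test_streams <- function(n_per_arm = 120, seed = 42) {
  cfg <- cohort_config(n_per_arm = n_per_arm, seed = seed)
  compute_patient_streams(generate_cohort(cfg))
}

table5_arm_moments <- list(
  PAC = c(cost_mean = 191.1, cost_sd = 8.5, qaly_mean = 4.54, qaly_sd = 0.21),
  CVC = c(cost_mean = 176.7, cost_sd = 7.1, qaly_mean = 4.83, qaly_sd = 0.21)
)
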