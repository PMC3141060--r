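test_that("winsorization caps at the empirical 95th percentile", {
  x <- 1:100
  w <- winsorize_p95(x)
  p95 <- quantile(x, 0.95, names = FALSE)
  expect_equal(max(w), p95)
  expect_true(all(w[x <= p95] == x[x <= p95]))
  expect_true(all(w[x > p95] == p95))
  # constant vectors unchanged; mean never increases
  expect_equal(winsorize_p95(rep(7, 10)), rep(7, 10))
  withr::with_seed(4, {
    for (i in 1:10) {
      y <- rlnorm(50, 10, 1.5)
      expect_lte(mean(winsorize_p95(y)), mean(y))
    }
  })
  expect_error(winsorize_p95(numeric(0)), "empty")
})

test_that("incremental is intervention minus comparator", {
  expect_equal(incremental(191.1, 176.7), 14.4)
  expect_equal(incremental(5, 5), 0)
  expect_equal(incremental(c(1, 2), c(3, 1)), c(-2, 1))
})

test_that("quadrant probabilities partition the plane exactly", {
  cloud <- psa_parametric(table5_arm_moments, n_trials = 2000, seed = 12)
  q <- quadrant_probs(cloud)
  expect_identical(sum(attr(q, "counts")), attr(q, "n_trials"))
  expect_equal(q$dominated + q$dominant + q$tradeoff_ne + q$tradeoff_sw, 1,
               tolerance = 1e-12)
  # degenerate single-corner clouds
  all_dom <- trialcea:::new_psa_cloud(rep(1, 10), rep(-1, 10))
  expect_equal(quadrant_probs(all_dom)$dominated, 1)
  expect_equal(unname(threshold_exceedance_probs(all_dom, c(0, 50, 1e6))),
               c(1, 1, 1))
  # symmetric zero-mean independent cloud sits near 1/4 per quadrant
  sym <- psa_parametric(list(
    A = c(cost_mean = 0, cost_sd = 1, qaly_mean = 0, qaly_sd = 1),
    B = c(cost_mean = 0, cost_sd = 1, qaly_mean = 0, qaly_sd = 1)
  ), n_trials = 20000, seed = 5)
  expect_lt(abs(quadrant_probs(sym)$dominated - 0.25), 0.01)
})

test_that("parametric PSA matches the product-of-normals oracle", {
  cloud <- psa_parametric(table5_arm_moments, n_trials = 20000, seed = 8)
  # independence oracle: P(dC > 0) * P(dE < 0)
  z_cost <- (191.1 - 176.7) / sqrt(8.5^2 + 7.1^2)
  z_eff <- (4.83 - 4.54) / sqrt(0.21^2 + 0.21^2)
  p_oracle <- pnorm(z_cost) * pnorm(z_eff)
  se <- sqrt(p_oracle * (1 - p_oracle) / 20000)
  expect_lt(abs(quadrant_probs(cloud)$dominated - p_oracle), 4 * se)
  # means recover the configured incremental point estimate
  expect_lt(abs(mean(cloud$delta_cost_k) - 14.4), 0.3)
  expect_lt(abs(mean(cloud$delta_effect_qaly) - (-0.29)), 0.01)
})

test_that("CEAC limits match their definitions exactly", {
  cloud <- psa_parametric(table5_arm_moments, n_trials = 3000, seed = 77)
  curve <- ceac(cloud, wtp_grid = c(0, 50, 100, 1e9))
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
  expect_identical(curve$probability[1], mean(cloud$delta_cost_k <= 0))
  de <- cloud$delta_effect_qaly; dc <- cloud$delta_cost_k
  limit <- mean(de > 0 | (de == 0 & dc <= 0))
  expect_identical(attr(curve, "limit_inf"), limit)
  expect_equal(curve$probability[4], limit) # plateau reached numerically
  # dominant cloud is always acceptable
  dom <- trialcea:::new_psa_cloud(rep(-1, 5), rep(1, 5))
  expect_true(all(ceac(dom, c(0, 10, 1000))$probability == 1))
  # CEAC + threshold exceedance are complementary at every threshold
  lam <- c(0, 30, 50, 200)
  expect_equal(unname(threshold_exceedance_probs(cloud, lam)),
               1 - ceac(cloud, lam)$probability)
})

test_that("ICER is reported only for tradeoffs", {
  dominated <- trialcea:::new_psa_cloud(rep(2, 5), rep(-1, 5))
  r <- icer_result(dominated)
  expect_equal(r$classification, "dominated")
  expect_true(is.na(r$icer_k_per_qaly))
  tradeoff <- trialcea:::new_psa_cloud(rep(50, 5), rep(1, 5))
  r2 <- icer_result(tradeoff)
  expect_equal(r2$classification, "tradeoff")
  expect_equal(r2$icer_k_per_qaly, 50)
  dominant <- trialcea:::new_psa_cloud(rep(-3, 5), rep(0.5, 5))
  expect_equal(icer_result(dominant)$classification, "dominant")
})

test_that("confidence ellipse covers the nominal level and rotates", {
  n <- 50000
  withr::with_seed(101, {
    cloud <- trialcea:::new_psa_cloud(rnorm(n), rnorm(n))
  })
  ell <- confidence_ellipse(cloud, level = 0.95)
  coverage <- mean(in_ellipse(ell, cloud$delta_effect_qaly,
                              cloud$delta_cost_k))
  expect_lt(abs(coverage - 0.95), 0.005)
  # level 0 degenerates to a point at the mean
  ell0 <- confidence_ellipse(cloud, level = 0)
  expect_equal(unname(ell0$radii), c(0, 0))
  # rotation equivariance of the major axis:
  # effect' = cos*e - sin*c, cost' = sin*e + cos*c
  withr::with_seed(202, {
    cost0 <- rnorm(5000, sd = 3); eff0 <- rnorm(5000, sd = 1)
  })
  theta <- pi / 6
  base <- trialcea:::new_psa_cloud(cost0, eff0)
  rot <- trialcea:::new_psa_cloud(
    sin(theta) * eff0 + cos(theta) * cost0,
    cos(theta) * eff0 - sin(theta) * cost0
  )
  a1 <- confidence_ellipse(base)$angle
  a2 <- confidence_ellipse(rot)$angle
  diff_ang <- (a2 - a1 - theta) %% pi
  expect_lt(min(diff_ang, pi - diff_ang), 0.05)
  # degenerate cloud rejected
  flat <- trialcea:::new_psa_cloud(1:10, rep(0.5, 10))
  expect_error(confidence_ellipse(flat), "degenerate")
})

test_that("bootstrap PSA is deterministic and consistent", {
  st <- make_test_streams(n_per_arm = 60, seed = 1)
  c1 <- psa_bootstrap(st, n_trials = 200, seed = 9)
  c2 <- psa_bootstrap(st, n_trials = 200, seed = 9)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  c3 <- psa_bootstrap(st, n_trials = 200, seed = 10)
  expect_false(identical(c1$delta_cost_k, c3$delta_cost_k))

  # single-patient arms: every trial returns those patients' values
  one <- st[c(which(st$arm == "PAC")[1], which(st$arm == "CVC")[1]), ]
  cl_one <- psa_bootstrap(one, n_trials = 50, seed = 3)
  expect_equal(unique(round(cl_one$delta_cost_k, 9)),
               round((one$lifetime_cost[1] - one$lifetime_cost[2]) / 1000, 9))

  # mean of bootstrap incremental cost converges to the winsorized
  # cohort incremental within 3 bootstrap SEs
  big <- psa_bootstrap(st, n_trials = 2000, seed = 123)
  wmean <- function(a) mean(winsorize_p95(st$lifetime_cost[st$arm == a] / 1000))
  point <- wmean("PAC") - wmean("CVC")
  # the bootstrap SE of the incremental estimate is the cloud SD
  expect_lt(abs(mean(big$delta_cost_k) - point), 3 * sd(big$delta_cost_k))

  expect_error(psa_bootstrap(st[st$arm == "PAC", ], n_trials = 10, seed = 1),
               "no patients")
})
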