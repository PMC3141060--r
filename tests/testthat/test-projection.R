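test_that("discounted annuity matches its closed form and loop oracle", {
  # closed form: 0.6 * (1 - 1.03^-10) / 0.03
  expect_equal(discounted_annuity(0.6, 10, 0.03), 0.6 * 8.530203,
               tolerance = 1e-6)
  expect_equal(discounted_annuity(0.6, 10, 0), 6.0)
  expect_equal(discounted_annuity(123, 0, 0.07), 0)
  withr::with_seed(9, {
    for (i in 1:20) {
      amount <- runif(1, 0.1, 5000)
      years <- runif(1, 0, 60)
      rate <- sample(c(0, 0.01, 0.03, 0.05, 0.1), 1)
      expect_equal(discounted_annuity(amount, years, rate),
                   annuity_loop(amount, years, rate), tolerance = 1e-10)
    }
  })
  expect_error(discounted_annuity(1, -1, 0.03), ">= 0")
})

test_that("rate 0 reproduces undiscounted sums; higher rates shrink value", {
  yrs <- c(0.5, 1, 7.3, 25)
  expect_equal(discounted_annuity(2, yrs, 0), 2 * yrs)
  v3 <- discounted_annuity(1, yrs, 0.03)
  v5 <- discounted_annuity(1, yrs, 0.05)
  expect_true(all(v5 < v3))
  expect_true(all(v3 < 1 * yrs))
})

test_that("life-table lookup is exact on rows, clamps, and falls back", {
  lt <- read_life_table()
  # identity lookup of a bundled row
  row <- lt[lt$age == 50 & lt$sex == "M" & lt$race == "white", ]
  expect_equal(remaining_life_expectancy(50, "M", "white", lt),
               row$expectancy_years)
  # ages beyond the oldest band clamp to it, with a warning
  oldest <- lt[lt$age == max(lt$age) & lt$sex == "F" & lt$race == "white", ]
  expect_warning(
    le <- remaining_life_expectancy(130, "F", "white", lt),
    "clamped"
  )
  expect_equal(le, oldest$expectancy_years)
  # unknown race maps to the declared fallback category
  expect_equal(remaining_life_expectancy(40, "M", "martian", lt),
               remaining_life_expectancy(40, "M", "other", lt))
  # exhaustive monotonicity scan: LE non-increasing in age within strata
  for (s in unique(lt$sex)) {
    for (r in unique(lt$race)) {
      le_by_age <- lt$expectancy_years[lt$sex == s & lt$race == r][
        order(lt$age[lt$sex == s & lt$race == r])]
      expect_true(all(diff(le_by_age) <= 0))
    }
  }
})

test_that("projection keeps decedents at one-year values and adds a tail", {
  st <- make_test_streams(n_per_arm = 100, seed = 77)
  dead <- !is.na(st$death_day)
  expect_equal(st$lifetime_qalys[dead], st$qa_days_one_year[dead] / 365)
  expect_equal(st$lifetime_cost[dead], st$cost_total_one_year[dead])
  surv <- !dead
  expect_true(all(st$lifetime_qalys[surv] >=
                    st$qa_days_one_year[surv] / 365))
  expect_true(all(st$lifetime_cost[surv] >= st$cost_total_one_year[surv]))
})

test_that("survivor projection equals the annuity arithmetic", {
  lt <- read_life_table()
  co <- generate_cohort(cohort_config(n_per_arm = 40, seed = 15))
  eff <- one_year_effect(cost_stream(co))
  p <- reference_case_params()
  proj <- project_cohort(eff, p, lt)
  i <- which(is.na(proj$death_day))[1]
  le <- remaining_life_expectancy(proj$age[i] + 1, proj$sex[i],
                                  proj$race[i], lt)
  expect_equal(proj$lifetime_qalys[i],
               proj$qa_days_one_year[i] / 365 +
                 discounted_annuity(0.6, le, 0.03))
  expect_equal(proj$lifetime_cost[i],
               proj$cost_total_one_year[i] +
                 discounted_annuity(5000, le, 0.03))
  # a survivor with LE 10 gains the canonical 5.118 discounted QALYs
  expect_equal(discounted_annuity(0.6, 10, 0.03), 5.118122, tolerance = 1e-6)
})

test_that("halving the life-expectancy multiplier shrinks both tails", {
  co <- generate_cohort(cohort_config(n_per_arm = 80, seed = 30))
  eff <- one_year_effect(cost_stream(co))
  full <- project_cohort(eff, reference_case_params(), read_life_table())
  half <- project_cohort(
    eff, reference_case_params(life_expectancy_multiplier = 0.5),
    read_life_table()
  )
  surv <- is.na(co$death_day)
  expect_true(all(half$lifetime_qalys[surv] < full$lifetime_qalys[surv]))
  expect_true(all(half$lifetime_cost[surv] < full$lifetime_cost[surv]))
  expect_equal(half$lifetime_cost[!surv], full$lifetime_cost[!surv])
})

test_that("parameter validation rejects impossible reference cases", {
  expect_error(reference_case_params(utility_beyond_one_year = 1.2),
               "\\[0, 1\\]")
  expect_error(reference_case_params(discount_rate = -0.01), ">= 0")
  expect_error(reference_case_params(life_expectancy_multiplier = 0), "> 0")
})
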