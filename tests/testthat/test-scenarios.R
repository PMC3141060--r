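test_that("identity subgroup reproduces the all-cohort PSA exactly", {
  st <- make_test_streams(n_per_arm = 50, seed = 6)
  tab <- run_subgroups(st, specs = list("all" = function(d) rep(TRUE, nrow(d))),
                       n_trials = 150, seed = 17)
  cloud <- psa_bootstrap(st, n_trials = 150, seed = 17)
  expect_equal(tab$inc_cost_k, mean(cloud$delta_cost_k))
  expect_equal(tab$inc_qaly, mean(cloud$delta_effect_qaly))
  expect_equal(tab$n, nrow(st))
})

test_that("partition subgroups cover the cohort without overlap", {
  st <- make_test_streams(n_per_arm = 80, seed = 13)
  specs <- subgroup_specs()
  age_sets <- lapply(c("age <45", "age 45-64", "age >64"),
                     function(nm) which(specs[[nm]](st)))
  expect_equal(sort(unlist(age_sets)), seq_len(nrow(st)))
  expect_equal(sum(lengths(age_sets)), nrow(st))
  for (pair in list(c("APACHE III >90", "APACHE III <=90"),
                    c("tidal volume >6.9", "tidal volume <=6.9"),
                    c("delay >21.5h", "delay <=21.5h"),
                    c("female", "male"))) {
    a <- specs[[pair[1]]](st); b <- specs[[pair[2]]](st)
    expect_true(all(xor(a, b)))
  }
})

test_that("empty-in-one-arm subgroups are skipped with a warning", {
  st <- make_test_streams(n_per_arm = 30, seed = 44)
  st$age[st$arm == "PAC"] <- 50 # nobody <45 in the PAC arm
  expect_warning(
    tab <- run_subgroups(st, specs = list("age <45" = function(d) d$age < 45,
                                          "all" = function(d) rep(TRUE, nrow(d))),
                         n_trials = 50, seed = 2),
    "skipped"
  )
  expect_equal(tab$subgroup, "all")
})

test_that("a planted subgroup cost effect is recovered in direction", {
  st <- make_test_streams(n_per_arm = 150, seed = 55)
  st2 <- st
  bump <- st2$arm == "PAC" & st2$fluid_strategy == "liberal"
  st2$lifetime_cost[bump] <- st2$lifetime_cost[bump] + 60000
  tab <- run_subgroups(
    st2,
    specs = list("fluid liberal" = function(d) d$fluid_strategy == "liberal",
                 "fluid conservative" = function(d) d$fluid_strategy == "conservative"),
    n_trials = 300, seed = 31
  )
  ref <- run_subgroups(
    st,
    specs = list("fluid liberal" = function(d) d$fluid_strategy == "liberal"),
    n_trials = 300, seed = 31
  )
  lib <- tab[tab$subgroup == "fluid liberal", ]
  expect_gt(lib$inc_cost_k, ref$inc_cost_k + 40)
})

test_that("the no-override scenario changes nothing", {
  co <- generate_cohort(cohort_config(n_per_arm = 60, seed = 23))
  base <- one_year_effect(co)
  tab <- run_sensitivity(
    base,
    scenarios = list(reference = list(params = list(), weights = list()),
                     noop = list(params = list(), weights = list())),
    n_trials = 100, seed = 7
  )
  ref <- tab[tab$scenario == "reference", ]
  noop <- tab[tab$scenario == "noop", ]
  expect_identical(noop$inc_cost_k, ref$inc_cost_k)
  expect_identical(noop$inc_qaly, ref$inc_qaly)
  expect_equal(noop$pct_change_cost, 0)
  expect_equal(noop$pct_change_qaly, 0)
})

test_that("one-way scenarios move the increments in the expected direction", {
  # make the CVC arm clearly longer-lived so the projected tail favours it
  cfg <- cohort_config(
    n_per_arm = 150, seed = 61,
    mortality_anchors = list(PAC = c(s60 = 0.70, s365 = 0.58),
                             CVC = c(s60 = 0.80, s365 = 0.74))
  )
  base <- one_year_effect(generate_cohort(cfg))
  tab <- run_sensitivity(base, n_trials = 250, seed = 19)
  get <- function(nm, col) tab[tab$scenario == nm, col]
  ref_q <- get("reference", "inc_qaly")
  expect_lt(ref_q, 0) # CVC longer-lived: PAC loses QALYs

  # discounting at 5% compresses the projected tail: |dQALY| shrinks
  expect_lt(abs(get("discount rate 5%", "inc_qaly")), abs(ref_q))
  # richer post-year-one utility widens the QALY gap
  expect_gt(abs(get("utility beyond 1y x1.25", "inc_qaly")), abs(ref_q))
  expect_lt(abs(get("utility beyond 1y x0.75", "inc_qaly")), abs(ref_q))
  # the annual post-year-one cost accrues mostly to the longer-lived CVC
  # survivors, so halving it raises incremental cost and doubling lowers it
  ref_c <- get("reference", "inc_cost_k")
  expect_gt(get("annual cost x0.5", "inc_cost_k"), ref_c)
  expect_lt(get("annual cost x2", "inc_cost_k"), ref_c)
})
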