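test_that("simulation is seed-deterministic and demands a seed", {
  d <- design_binding_j2(2)
  s1 <- simulate_trials(d, n_reps = 2e4, seed = 99)
  s2 <- simulate_trials(d, n_reps = 2e4, seed = 99)
  expect_identical(s1, s2)
  s3 <- simulate_trials(d, n_reps = 2e4, seed = 100)
  expect_false(identical(s1[c("pwer", "fwer", "lob_stop_freq")],
                         s3[c("pwer", "fwer", "lob_stop_freq")]))
  expect_error(simulate_trials(d, n_reps = 10), "seed")
})

test_that("Monte-Carlo standard errors follow the binomial formula", {
  d <- design_binding_j2(1)
  s <- simulate_trials(d, n_reps = 5e4, seed = 5)
  expect_equal(s$mc_se[["pwer"]],
               sqrt(s$pwer * (1 - s$pwer) / s$n_reps), tolerance = 1e-12)
  expect_equal(s$mc_se[["fwer"]],
               sqrt(s$fwer * (1 - s$fwer) / s$n_reps), tolerance = 1e-12)
})

test_that("empirical rates agree with analytic integration within Monte-Carlo error", {
  n <- 2e5
  configs <- list(
    list(d = design_binding_j2(1), hyp = "global_null", field = "pwer",
         ref = function(d, b) pwer(d, b)),
    list(d = design_binding_j2(1), hyp = "global_alternative",
         field = "per_pair_power",
         ref = function(d, b) pwer(d, b, hypothesis = "alternative")),
    list(d = design_binding_j3(2), hyp = "global_null", field = "fwer",
         ref = function(d, b) fwer(d, b)),
    list(d = design_ineqd(K = 3, J = 2), hyp = "global_null", field = "fwer",
         ref = function(d, b) fwer(d, b)))
  for (i in seq_along(configs)) {
    cf <- configs[[i]]
    b <- boundary_set(cf$d)
    s <- simulate_trials(cf$d, b, n_reps = n, seed = 123 + i, hypothesis = cf$hyp)
    ref <- cf$ref(cf$d, b)
    se <- sqrt(ref * (1 - ref) / n)
    expect_lt(abs(s[[cf$field]] - ref), 4 * se,
              label = sprintf("config %d: |%.4f - %.4f|", i, s[[cf$field]], ref))
  }
})

test_that("power measures from simulation respect the ordering", {
  d <- design_binding_j2(3)
  s <- simulate_trials(d, n_reps = 5e4, seed = 21,
                       hypothesis = "global_alternative")
  expect_lte(s$all_pair_power, s$per_pair_power)
  expect_lte(s$per_pair_power, s$any_pair_power)
})

test_that("stopping frequencies are proper and efficacy bounds are exercised", {
  d <- design_binding_j3(2)
  b <- boundary_set(d, efficacy_rule("custom", p = c(0.01, 0.05)))
  s <- simulate_trials(d, b, n_reps = 5e4, seed = 8,
                       hypothesis = "global_alternative")
  per_comp <- colSums(s$lob_stop_freq) + colSums(s$eff_stop_freq)
  expect_true(all(per_comp <= 1 + 1e-12))
  expect_true(all(colSums(s$eff_stop_freq) > 0))  # liberal bounds do stop arms
})

test_that("simultaneous stopping leaves the FWER unchanged but trims the PWER", {
  base <- design_binding_j3(4)
  b <- boundary_set(base, efficacy_rule("custom", p = c(0.01, 0.05)))
  sim <- base; sim$stopping_rule <- "simultaneous"
  n <- 2e5
  s_sep <- simulate_trials(base, b, n_reps = n, seed = 77)
  s_sim <- simulate_trials(sim, b, n_reps = n, seed = 77)
  se <- sqrt(s_sep$fwer * (1 - s_sep$fwer) / n)
  expect_lt(abs(s_sep$fwer - s_sim$fwer), 3 * se)
  expect_lte(s_sim$pwer, s_sep$pwer + 2 * s_sep$mc_se[["pwer"]])
})

test_that("the study grid reports inflation in the published table format", {
  g <- replicate_study_grid(n_comparisons = c(1, 2), stages = 2,
                            outcomes = "different",
                            rule = efficacy_rule("haybittle_peto"))
  expect_equal(nrow(g), 2)
  expect_named(g, c("comparisons", "stages", "outcomes", "fwer_no_eb",
                    "fwer_eb", "inflation", "percentage", "per_pair_no_eb",
                    "per_pair_eb", "any_pair_no_eb", "any_pair_eb",
                    "all_pair_no_eb", "all_pair_eb"))
  expect_equal(g$inflation, g$fwer_eb - g$fwer_no_eb, tolerance = 1e-12)
  expect_equal(g$percentage, round(100 * g$inflation / g$fwer_no_eb))
  expect_true(all(g$inflation >= -1e-8))  # efficacy looks never reduce the FWER
  # single-cell grid
  g1 <- replicate_study_grid(1, 2, "same", efficacy_rule("none"))
  expect_equal(nrow(g1), 1)
})
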