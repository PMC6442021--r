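test_that("binding two- and three-stage error rates match the Markov grid oracle", {
  d2 <- design_binding_j2()
  t2 <- d2$info_fractions
  l2 <- qnorm(1 - d2$alpha)
  expect_near(pwer(d2), markov_exceed_prob(l2, t2), 1e-5)
  expect_near(pwer(d2, hypothesis = "alternative"),
              markov_exceed_prob(l2, t2, mean = noncentrality(d2)), 1e-5)

  d3 <- design_binding_j3()
  t3 <- d3$info_fractions
  l3 <- qnorm(1 - d3$alpha)
  expect_near(pwer(d3), markov_exceed_prob(l3, t3), 1e-5)
  expect_near(pwer(d3, hypothesis = "alternative"),
              markov_exceed_prob(l3, t3, mean = noncentrality(d3)), 1e-5)

  # with an interim efficacy bound, crossing events add to the error
  b <- boundary_set(d2, efficacy_rule("custom", p = 0.01))
  e1 <- qnorm(1 - 0.01)
  oracle <- markov_exceed_prob(c(e1, -Inf), t2) +
    markov_box_prob(c(l2[1], l2[2]), c(e1, Inf), t2)
  expect_near(pwer(d2, b), oracle, 1e-5)
})

test_that("degenerate designs recover closed forms", {
  d1 <- mams_design(1, alpha = 0.025, omega = 0.90)
  expect_near(pwer(d1), 0.025, 1e-9)
  expect_near(fwer(d1), 0.025, 1e-9)

  # independent comparisons: FWER = 1 - (1 - alpha)^K
  expect_equal(max_fwer_dunnett(4, 0, 0.025), 1 - 0.975^4, tolerance = 1e-12)
  expect_near(max_fwer_dunnett(1, 0.5, 0.025), 0.025, 1e-9)
  expect_equal(max_fwer_dunnett(3, 1, 0.025), 0.025)  # perfectly correlated
})

test_that("the non-binding maximum PWER with no efficacy looks is alpha_J", {
  for (J in 2:4) {
    ladder <- tail(c(0.5, 0.25, 0.1, 0.025), J)
    d <- mams_design(1, alpha = ladder)
    expect_near(pwer(d, max_variant = TRUE), 0.025, 1e-8)
  }
})

test_that("Dunnett-type maximum FWER agrees with a shared-control simulation", {
  val <- max_fwer_dunnett(5, 0.5, 0.025)
  mc <- dunnett_mc(5, 0.5, qnorm(0.975), n = 2e6, seed = 3)
  se <- sqrt(val * (1 - val) / 2e6)
  expect_lt(abs(val - mc), 4 * se)
  # increasing in K, decreasing in rho
  ks <- sapply(1:5, max_fwer_dunnett, rho = 0.5, alpha_final = 0.025)
  expect_true(all(diff(ks) > 0))
  rs <- sapply(c(0.1, 0.3, 0.5, 0.7), max_fwer_dunnett, K = 3, alpha_final = 0.025)
  expect_true(all(diff(rs) < 0))
})

test_that("familywise error reduces to pairwise at K = 1 and obeys union bounds", {
  d <- design_binding_j2()
  expect_near(fwer(d), pwer(d), 1e-7)
  for (K in c(2, 5)) {
    dK <- design_binding_j2(K)
    p1 <- pwer(dK); pK <- fwer(dK)
    expect_gte(pK, p1 - 1e-7)
    expect_lte(pK, K * p1 + 1e-7)
  }
})

test_that("binding multi-arm FWER matches an inclusion-exclusion cross-check", {
  d <- design_binding_j2(2)
  # P(at least one error) = 2 PWER - P(both err); both-error from the
  # explicit shared-control construction
  p1 <- markov_exceed_prob(qnorm(1 - d$alpha), d$info_fractions)
  set.seed(19)
  n <- 4e5
  t1 <- d$info_fractions[1]
  U1 <- rnorm(n); U2 <- rnorm(n)                      # control increments
  both <- {
    e11 <- rnorm(n); e12 <- rnorm(n); e21 <- rnorm(n); e22 <- rnorm(n)
    z11 <- sqrt(0.5) * U1 + sqrt(0.5) * e11           # comparison 1, stage 1
    z21 <- sqrt(0.5) * U1 + sqrt(0.5) * e21
    z12 <- sqrt(t1) * z11 + sqrt(1 - t1) * (sqrt(0.5) * U2 + sqrt(0.5) * e12)
    z22 <- sqrt(t1) * z21 + sqrt(1 - t1) * (sqrt(0.5) * U2 + sqrt(0.5) * e22)
    l <- qnorm(1 - d$alpha)
    mean(z11 > l[1] & z12 > l[2] & z21 > l[1] & z22 > l[2])
  }
  est <- 2 * p1 - both
  se <- sqrt(both * (1 - both) / n)
  expect_lt(abs(fwer(d) - est), 4 * se)
})

test_that("power measures are ordered and coincide for a single comparison", {
  d1 <- design_binding_j2(1)
  pm1 <- power_measures(d1)
  expect_lt(diff(range(pm1)), 1e-9)

  for (d in list(design_binding_j2(3), design_binding_j3(2),
                 design_ineqd(K = 3, J = 2))) {
    pm <- power_measures(d)
    expect_lte(pm[["all_pair"]], pm[["per_pair"]] + 1e-7)
    expect_lte(pm[["per_pair"]], pm[["any_pair"]] + 1e-7)
  }
})

test_that("error rates are monotone in the interim efficacy thresholds", {
  d <- design_binding_j3(2)
  thresholds <- c(5e-4, 2e-3, 5e-3, 1e-2)
  pw <- fw <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    b <- boundary_set(d, efficacy_rule("custom",
                                       p = c(5e-4, thresholds[i])))
    pw[i] <- pwer(d, b)
    fw[i] <- fwer(d, b)
  }
  expect_true(all(diff(pw) > -1e-8))
  expect_true(all(diff(fw) > -1e-8))
})

test_that("non-binding maxima dominate binding error rates", {
  d <- design_binding_j3(2)
  b <- boundary_set(d, efficacy_rule("haybittle_peto"))
  expect_gt(pwer(d, b, max_variant = TRUE), pwer(d, b))
  expect_gt(fwer(d, b, max_variant = TRUE), fwer(d, b))
  # Bonferroni sandwich for the non-binding maximum
  mx <- pwer(d, b, max_variant = TRUE)
  expect_gte(mx, 0.025 - 1e-8)
  expect_lte(mx, 0.025 + 2 * 5e-4 + 1e-8)
})

test_that("the full report carries consistent fields", {
  d <- design_ineqd(K = 2, J = 2)
  rep <- error_rate_report(d)
  expect_s3_class(rep, "mams_error_report")
  expect_near(rep$pwer, 0.025, 1e-8)   # non-binding maximum
  expect_near(rep$per_pair_power, 0.90, 1e-6)
  expect_true(rep$max_variant)
  probs <- unlist(rep[c("pwer", "fwer", "per_pair_power", "any_pair_power",
                        "all_pair_power")])
  expect_true(all(probs >= 0 & probs <= 1))
})
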