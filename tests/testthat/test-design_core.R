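test_that("design validation accepts conventional specifications", {
  st <- mams_design(5, alpha = c(0.5, 0.25, 0.1, 0.025),
                    omega = c(0.95, 0.95, 0.95, 0.90), allocation = 0.5,
                    intermediate = outcome_spec("FFS", "intermediate", hr_alt = 0.75))
  expect_s3_class(st, "mams_design")
  expect_identical(st$n_comparisons, 5L)
  expect_false(st$binding)  # intermediate outcome => non-binding default

  single <- mams_design(1, alpha = 0.025, omega = 0.90)
  expect_equal(single$info_fractions, 1)
  expect_true(single$binding)
})

test_that("design validation rejects inconsistent specifications", {
  expect_error(mams_design(1, alpha = c(0.1, 0.2)), "decreasing")
  expect_error(mams_design(0, alpha = 0.025), "n_comparisons")
  expect_error(mams_design(1, alpha = c(0.1, 0.025), omega = 0.9), "per stage")
  expect_error(mams_design(1, alpha = c(0.1, 0.025),
                           control_events = c(400, 300)), "nondecreasing")
  expect_error(mams_design(1, alpha = c(0.1, 0.025),
                           d_info_fractions = c(0.5, 0.9)), "last entry 1")
  expect_error(outcome_spec("D", "definitive", hr_alt = 1.1), "smaller")
})

test_that("information fractions follow the quantile-ratio formula", {
  t2 <- information_fractions(c(0.1, 0.025), c(0.95, 0.90))
  eta <- qnorm(c(0.90, 0.975)) + qnorm(c(0.95, 0.90))
  expect_equal(t2, (eta / eta[2])^2, tolerance = 1e-12)
  expect_equal(t2, c(0.8150, 1), tolerance = 1e-4)
  expect_equal(information_fractions(c(0.25, 0.1, 0.025), c(0.95, 0.95, 0.90)),
               c(0.5120, 0.8150, 1), tolerance = 1e-4)
  expect_equal(information_fractions(0.025, 0.90), 1)
})

test_that("an explicit event schedule overrides the formula", {
  d <- design_binding_j2()
  expect_equal(d$info_fractions, c(334, 403) / 403)
})

test_that("required events match the Schoenfeld formula and a brute-force search", {
  expect_equal(required_events(0.025, 0.90, 0.75, 1),
               list(total = 508L, control = 254L))
  expect_equal(required_events(0.025, 0.90, 0.75, 0.5),
               list(total = 572L, control = 381L))
  expect_error(required_events(0.025, 0.90, 1, 1), "unbounded")

  # smallest integer event count whose normal-approximation power >= omega
  brute <- function(alpha, omega, hr, A) {
    e <- 10L
    repeat {
      pow <- pnorm(abs(log(hr)) * sqrt(e * A) / (1 + A) - qnorm(1 - alpha))
      if (pow >= omega) return(e)
      e <- e + 1L
    }
  }
  cases <- expand.grid(alpha = c(0.025, 0.1), omega = c(0.8, 0.95),
                       hr = c(0.6, 0.8), A = c(0.5, 1))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    expect_equal(required_events(cs$alpha, cs$omega, cs$hr, cs$A)$total,
                 brute(cs$alpha, cs$omega, cs$hr, cs$A),
                 info = paste(unlist(cs), collapse = "/"))
  }
})

test_that("noncentrality obeys the stagewise calibration identity", {
  d <- design_binding_j3()
  eta <- noncentrality(d)
  expect_equal(eta[2], 1.28155 + 1.64485, tolerance = 1e-4)
  # marginal stage-j power at the lack-of-benefit threshold is exactly omega_j
  expect_equal(pnorm(eta - qnorm(1 - d$alpha)), d$omega, tolerance = 1e-12)
  expect_equal(noncentrality(d, hypothesis = "null"), rep(0, 3))
})

test_that("information fractions are scale invariant", {
  # same quantile sums, different allocation / hazard ratios: identical timing
  a <- c(0.3, 0.1, 0.025); w <- c(0.9, 0.95, 0.85)
  t1 <- information_fractions(a, w)
  d1 <- mams_design(2, alpha = a, omega = w, allocation = 0.5)
  d2 <- mams_design(4, alpha = a, omega = w, allocation = 1,
                    definitive = outcome_spec("D", "definitive", hr_alt = 0.6))
  expect_equal(d1$info_fractions, t1)
  expect_equal(d2$info_fractions, t1)
})
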