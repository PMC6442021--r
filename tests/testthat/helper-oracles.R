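# Absolute-tolerance comparison (testthat's tolerance is relative, which is
# too strict for probabilities printed to 4 decimals).
expect_near <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol)
}

# Independent oracles used to check the multivariate-normal integration.
#
# Cumulative stagewise statistics at information fractions t form a Markov
# chain (independent increments): Z_j | Z_{j-1} = u is normal with mean
# mu_j + r (u - mu_{j-1}) and sd sqrt(1 - r^2), r = sqrt(t_{j-1}/t_j).
# Propagating the (sub-)density over a fine grid gives box probabilities
# without any multivariate-normal CDF code.
markov_box_prob <- function(lower, upper, t, mean = rep(0, length(t)),
                            n_cells = 2000) {
  J <- length(t)
  stage_grid <- function(j) {
    a <- max(lower[j], mean[j] - 9)
    b <- min(upper[j], mean[j] + 9)
    if (b <= a) return(NULL)
    edges <- seq(a, b, length.out = n_cells + 1)
    list(mid = (edges[-1] + edges[-(n_cells + 1)]) / 2, dz = edges[2] - edges[1])
  }
  g <- stage_grid(1)
  if (is.null(g)) return(0)
  dens <- dnorm(g$mid, mean = mean[1])
  if (J > 1) {
    for (j in 2:J) {
      r <- sqrt(t[j - 1] / t[j])
      s <- sqrt(1 - r^2)
      gj <- stage_grid(j)
      if (is.null(gj)) return(0)
      cond_mean <- mean[j] + r * (g$mid - mean[j - 1])  # given Z_{j-1}
      kern <- outer(gj$mid, cond_mean, function(znew, m) dnorm(znew, m, s))
      dens <- as.vector(kern %*% dens) * g$dz
      g <- gj
    }
  }
  sum(dens) * g$dz
}

markov_exceed_prob <- function(lower, t, mean = rep(0, length(t)))
  markov_box_prob(lower, rep(Inf, length(t)), t, mean)

# P(Z1 > a, Z2 > b) for bivariate normal, by 1-D conditioning quadrature.
cond_biv_exceed <- function(a, b, rho, mu = c(0, 0)) {
  integrate(function(u)
    dnorm(u, mu[1]) * pnorm((b - mu[2] - rho * (u - mu[1])) / sqrt(1 - rho^2),
                            lower.tail = FALSE),
    a, Inf, rel.tol = 1e-10)$value
}

# Monte-Carlo Dunnett familywise error with explicit shared-control
# construction: Z_k = sqrt(rho) U + sqrt(1 - rho) e_k.
dunnett_mc <- function(K, rho, z_final, n = 2e6, seed = 7) {
  set.seed(seed)
  U <- rnorm(n)
  any_cross <- rep(FALSE, n)
  for (k in seq_len(K)) {
    Zk <- sqrt(rho) * U + sqrt(1 - rho) * rnorm(n)
    any_cross <- any_cross | (Zk > z_final)
  }
  mean(any_cross)
}

# The STAMPEDE control-arm event schedule; trailing subsets give the
# conventional two- and three-stage designs used throughout the tests.
stampede_events <- c(113, 216, 334, 403)

design_binding_j2 <- function(K = 1)
  mams_design(K, alpha = c(0.1, 0.025), omega = c(0.95, 0.90),
              control_events = tail(stampede_events, 2))

design_binding_j3 <- function(K = 1)
  mams_design(K, alpha = c(0.25, 0.1, 0.025), omega = c(0.95, 0.95, 0.90),
              control_events = tail(stampede_events, 3))

design_ineqd <- function(K = 2, J = 2, allocation = 1, ...) {
  ladder <- c(0.5, 0.25, 0.1, 0.025)
  mams_design(K, alpha = tail(ladder, J), allocation = allocation,
              intermediate = outcome_spec("FFS", "intermediate", hr_alt = 0.70),
              ...)
}
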