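# Analytic pairwise/familywise error rates and the three power measures by
# multivariate-normal integration.
#
# Every stagewise decision event of a single comparison is a rectangle in
# its statistic vector: a type I error at stage j means continuing through
# stages < j (above the lack-of-benefit bound, below the efficacy bound) and
# crossing the efficacy bound at j (or the final threshold at stage J).
# The per-comparison error event is a disjoint union of such boxes, and so
# is its complement (stopping without an error).  Joint probabilities over
# K exchangeable comparisons are sums over box assignments, reduced to
# multisets by symmetry under the global null/alternative.

# Deterministic quadrature for low dimension, quasi-Monte-Carlo CDF above,
# with a fixed internal seed so that 4-decimal table values are reproducible.
.pmvn <- function(lower, upper, mean = NULL, sigma) {
  if (any(lower == Inf) || any(upper == -Inf) || any(upper <= lower)) return(0)
  keep <- is.finite(lower) | is.finite(upper)
  if (!any(keep)) return(1)
  lower <- lower[keep]
  upper <- upper[keep]
  mean <- if (is.null(mean)) rep(0, sum(keep)) else mean[keep]
  sigma <- sigma[keep, keep, drop = FALSE]
  d <- length(lower)
  if (d == 1L)
    return(stats::pnorm(upper, mean, sqrt(sigma[1, 1])) -
             stats::pnorm(lower, mean, sqrt(sigma[1, 1])))
  if (d <= 3L) {   # Miwa quadrature is deterministic; +/-40 sd is exhaustive
    lower <- pmax(lower, -40)
    upper <- pmin(upper, 40)
    alg <- mvtnorm::Miwa(steps = 512)
  } else {
    alg <- mvtnorm::GenzBretz(abseps = 1e-7, maxpts = 25000 * d)
  }
  .with_fixed_rng(
    as.numeric(mvtnorm::pmvnorm(lower = lower, upper = upper, mean = mean,
                                sigma = sigma, algorithm = alg)))
}

.with_fixed_rng <- function(expr, seed = 20190116L) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

# Per-comparison decision boxes over the statistic layout.
# what = "error": boxes whose disjoint union is the type I error /
#   detection event; "no_error": boxes whose union is its complement.
# Non-binding (or the max variant) removes all lack-of-benefit constraints.
.decision_boxes <- function(design, bounds, layout, what = c("error", "no_error"),
                            binding = design$binding) {
  what <- match.arg(what)
  J <- design$n_stages
  M <- nrow(layout)
  final_z <- p_to_z(attr(bounds, "alpha_final"))
  lob_z <- bounds$lob_z
  eff_z <- bounds$eff_z

  continue_constraints <- function(j) {   # stages strictly before j
    lo <- rep(-Inf, M); up <- rep(Inf, M)
    for (r in seq_len(M)) {
      if (layout$stage[r] >= j) next
      if (layout$tests_lob[r] && binding) lo[r] <- lob_z[layout$stage[r]]
      if (layout$tests_eff[r]) up[r] <- eff_z[layout$stage[r]]
    }
    list(lo = lo, up = up)
  }
  boxes <- list()
  for (j in seq_len(J)) {
    cc <- continue_constraints(j)
    if (what == "error") {
      if (j < J) {
        r <- which(layout$tests_eff & layout$stage == j)
        if (length(r) == 0L) next             # no efficacy look at this stage
        cc$lo[r] <- eff_z[j]
      } else {
        r <- which(layout$is_final)
        cc$lo[r] <- final_z
      }
      boxes[[length(boxes) + 1L]] <- cc
    } else {
      if (j < J) {
        if (!binding) next                    # arms are never dropped
        r <- which(layout$tests_lob & layout$stage == j)
        if (length(r) == 0L) next
        re <- which(layout$tests_eff & layout$stage == j)
        if (length(re)) cc$up[re] <- pmin(cc$up[re], eff_z[j])
        # lack-of-benefit stop; when I = D the same statistic carries both
        # tests and z <= l_j is the tighter of the two constraints
        cc$up[r] <- pmin(cc$up[r], lob_z[j])
      } else {
        r <- which(layout$is_final)
        cc$up[r] <- final_z
      }
      boxes[[length(boxes) + 1L]] <- cc
    }
  }
  boxes
}

# Stagewise mean shifts of the layout statistics under a hypothesis.
.layout_means <- function(design, layout, hypothesis = c("null", "alternative")) {
  hypothesis <- match.arg(hypothesis)
  if (hypothesis == "null") return(rep(0, nrow(layout)))
  eta <- noncentrality(design)
  J <- design$n_stages
  mu <- numeric(nrow(layout))
  for (r in seq_len(nrow(layout))) {
    if (layout$is_final[r]) {
      mu[r] <- eta[J]
    } else if (!.uses_intermediate(design) || layout$outcome[r] == "I") {
      mu[r] <- eta[layout$stage[r]]             # stagewise calibration
    } else {
      mu[r] <- eta[J] * sqrt(layout$fraction[r]) # D interim: Brownian scaling
    }
  }
  mu
}

# All multisets of size K over `n` box types: matrix of counts, one row per
# multiset, with the multinomial assignment weight attached.
.multisets <- function(n, K) {
  comp <- function(total, slots) {
    if (slots == 1L) return(matrix(total, 1L, 1L))
    do.call(rbind, lapply(0:total, function(i)
      cbind(i, comp(total - i, slots - 1L))))
  }
  m <- comp(K, n)
  w <- apply(m, 1L, function(r) factorial(K) / prod(factorial(r)))
  list(counts = m, weights = w)
}

# P(every comparison's statistic vector falls in its assigned box), summed
# over all assignments of the given boxes to the K exchangeable comparisons.
.joint_event_prob <- function(boxes, corr, mean_one) {
  K <- corr$n_comparisons
  M <- nrow(corr$layout)
  if (length(boxes) == 0L) return(0)
  ms <- .multisets(length(boxes), K)
  mu <- rep(mean_one, K)
  total <- 0
  for (i in seq_len(nrow(ms$counts))) {
    lo <- up <- numeric(0)
    for (b in seq_along(boxes)) {
      cnt <- ms$counts[i, b]
      if (cnt == 0L) next
      lo <- c(lo, rep(boxes[[b]]$lo, cnt))
      up <- c(up, rep(boxes[[b]]$up, cnt))
    }
    total <- total + ms$weights[i] * .pmvn(lo, up, mu, corr$full)
  }
  total
}

#' Pairwise type I error rate / per-pair detection probability
#'
#' The probability that a single comparison crosses an efficacy bound at an
#' interim look or the final threshold at stage J while still eligible,
#' summed over the disjoint stagewise crossing events.  Under the null this
#' is the PWER; under the alternative it is the per-pair power.  The
#' non-binding maximum (`max_variant`) removes the lack-of-benefit bounds;
#' with no efficacy looks it equals the final-stage significance level
#' exactly.
#'
#' @param design A `mams_design`.
#' @param bounds A [boundary_set()]; default no efficacy rule.
#' @param hypothesis `"null"` or `"alternative"`.
#' @param max_variant Replace lack-of-benefit bounds by minus infinity;
#'   defaults to `!design$binding`.
#' @return A probability.
#' @export
pwer <- function(design, bounds = boundary_set(design),
                 hypothesis = c("null", "alternative"),
                 max_variant = !design$binding) {
  hypothesis <- match.arg(hypothesis)
  stopifnot(inherits(design, "mams_design"))
  layout <- .stat_layout(design, bounds)
  boxes <- .decision_boxes(design, bounds, layout, "error",
                           binding = design$binding && !max_variant)
  within <- .within_correlation(layout, design$rho_id)
  mu <- .layout_means(design, layout, hypothesis)
  sum(vapply(boxes, function(b) .pmvn(b$lo, b$up, mu, within), numeric(1)))
}

#' Familywise type I error rate
#'
#' Probability that at least one comparison makes a type I error under the
#' global null, accounting for the shared-control and information-time
#' correlation.  Computed as one minus the probability that every comparison
#' stops without an error, by (J K)-dimensional integration; with
#' non-binding bounds and no interim efficacy looks the computation reduces
#' to the classical single-stage Dunnett conditioning integral.  Under the
#' global null the FWER is the same for separate and simultaneous stopping,
#' so the stopping rule does not enter.
#'
#' @inheritParams pwer
#' @return A probability.
#' @export
fwer <- function(design, bounds = boundary_set(design),
                 max_variant = !design$binding) {
  stopifnot(inherits(design, "mams_design"))
  K <- design$n_comparisons
  if (K == 1L) return(pwer(design, bounds, "null", max_variant))
  if (max_variant && !.has_interim_efficacy(bounds)) {
    return(max_fwer_dunnett(K, between_comparison_rho(design$allocation),
                            attr(bounds, "alpha_final")))
  }
  corr <- joint_correlation(design, bounds)
  layout <- corr$layout
  boxes <- .decision_boxes(design, bounds, layout, "no_error",
                           binding = design$binding && !max_variant)
  mu <- .layout_means(design, layout, "null")
  1 - .joint_event_prob(boxes, corr, mu)
}

#' Maximum FWER of a Dunnett-type comparison set
#'
#' With non-binding lack-of-benefit bounds and no interim efficacy looks,
#' only the K equicorrelated final-stage statistics matter, and the maximum
#' FWER is the classical Dunnett probability
#' \deqn{1 - \int \phi(u)\, \Phi\!\left(\frac{z_{1-\alpha_J} - \sqrt{\rho}\,u}{\sqrt{1-\rho}}\right)^{K} du.}
#'
#' @param K Number of comparisons.
#' @param rho Between-comparison correlation in \[0, 1\].
#' @param alpha_final Final-stage one-sided significance level.
#' @return A probability; increases in K, decreases in rho, equals
#'   `alpha_final` at K = 1 or rho = 1.
#' @examples
#' max_fwer_dunnett(2, 0.5, 0.025)   # 0.0455
#' @export
max_fwer_dunnett <- function(K, rho, alpha_final) {
  stopifnot(K >= 1, rho >= 0, rho <= 1, alpha_final > 0, alpha_final < 1)
  if (rho >= 1 - 1e-12) return(alpha_final)  # perfectly correlated comparisons
  zb <- stats::qnorm(1 - alpha_final)
  if (rho == 0) return(1 - (1 - alpha_final)^K)
  val <- stats::integrate(function(u)
    stats::dnorm(u) * stats::pnorm((zb - sqrt(rho) * u) / sqrt(1 - rho))^K,
    -Inf, Inf, rel.tol = 1e-10)$value
  1 - val
}

#' Per-pair, any-pair and all-pair power
#'
#' Under the global alternative (all research arms effective at their target
#' hazard ratios), per-pair power is the probability of detecting the effect
#' in one particular arm, any-pair power the probability of detecting at
#' least one, and all-pair power the probability of detecting every one.  An
#' early efficacy crossing counts as a detection.  The three coincide for a
#' single comparison.
#'
#' @inheritParams pwer
#' @return Named numeric vector `per_pair`, `any_pair`, `all_pair`.
#' @export
power_measures <- function(design, bounds = boundary_set(design),
                           max_variant = !design$binding) {
  stopifnot(inherits(design, "mams_design"))
  per <- pwer(design, bounds, "alternative", max_variant)
  K <- design$n_comparisons
  if (K == 1L)
    return(c(per_pair = per, any_pair = per, all_pair = per))
  corr <- joint_correlation(design, bounds)
  layout <- corr$layout
  binding_eff <- design$binding && !max_variant
  err_boxes <- .decision_boxes(design, bounds, layout, "error", binding_eff)
  ne_boxes <- .decision_boxes(design, bounds, layout, "no_error", binding_eff)
  mu <- .layout_means(design, layout, "alternative")
  all_pair <- .joint_event_prob(err_boxes, corr, mu)
  any_pair <- 1 - .joint_event_prob(ne_boxes, corr, mu)
  c(per_pair = per, any_pair = any_pair, all_pair = all_pair)
}

#' Full analytic operating-characteristics report
#'
#' @inheritParams pwer
#' @param rule An [efficacy_rule()] used to build the boundary set.
#' @return An object of class `mams_error_report` with fields `pwer`,
#'   `fwer`, `per_pair_power`, `any_pair_power`, `all_pair_power`, `method`,
#'   `tolerance`, `binding`, `max_variant`.
#' @examples
#' d <- mams_design(2, alpha = c(0.1, 0.025))
#' error_rate_report(d)
#' @export
error_rate_report <- function(design, rule = efficacy_rule("none"),
                              max_variant = !design$binding) {
  bounds <- boundary_set(design, rule)
  pw <- power_measures(design, bounds, max_variant)
  rep <- list(pwer = pwer(design, bounds, "null", max_variant),
              fwer = fwer(design, bounds, max_variant),
              per_pair_power = unname(pw["per_pair"]),
              any_pair_power = unname(pw["any_pair"]),
              all_pair_power = unname(pw["all_pair"]),
              method = "integration",
              tolerance = 1e-6,
              binding = design$binding && !max_variant,
              max_variant = max_variant)
  structure(rep, class = "mams_error_report")
}

#' @export
print.mams_error_report <- function(x, ...) {
  cat(sprintf("Operating characteristics (%s%s)\n", x$method,
              if (isTRUE(x$max_variant)) ", non-binding maximum" else ""))
  cat(sprintf("  PWER:            %.4f\n", x$pwer))
  cat(sprintf("  FWER:            %.4f\n", x$fwer))
  cat(sprintf("  per-pair power:  %.4f\n", x$per_pair_power))
  cat(sprintf("  any-pair power:  %.4f\n", x$any_pair_power))
  cat(sprintf("  all-pair power:  %.4f\n", x$all_pair_power))
  invisible(x)
}
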