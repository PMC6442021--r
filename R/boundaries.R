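# Stagewise lack-of-benefit and efficacy thresholds under the
# Haybittle-Peto, O'Brien-Fleming-type spending, or custom rules.

#' Convert a one-sided p-value threshold to the benefit-z scale
#'
#' All statistics are oriented so that larger z indicates more benefit
#' (HR < 1); a one-sided threshold p maps to the z-scale threshold
#' \eqn{z_{1-p}}.
#'
#' @param p One-sided p-value(s) in (0, 1).
#' @return Benefit-z threshold(s).
#' @export
p_to_z <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("'p' must lie in (0, 1)", call. = FALSE)
  stats::qnorm(1 - p)
}

#' @rdname p_to_z
#' @param z Benefit-z threshold(s).
#' @export
z_to_p <- function(z) stats::pnorm(z, lower.tail = FALSE)

#' Describe an efficacy stopping rule
#'
#' @param kind One of `"none"`, `"haybittle_peto"`, `"obf_spending"`,
#'   `"custom"`.
#' @param p For `"custom"`: per-stage one-sided efficacy p-thresholds of
#'   length J - 1 (padded with the final-stage significance level) or J
#'   (last entry must equal it).  For `"haybittle_peto"`: the interim
#'   threshold, default 0.0005.
#' @param alpha_total For `"obf_spending"`: total one-sided alpha to spend;
#'   defaults to the design's final-stage significance level.
#' @param method For `"obf_spending"`: `"recursion"` solves the exact
#'   group-sequential boundary so the cumulative crossing probability equals
#'   the spent alpha at each look; `"nominal"` uses the cumulative spending
#'   function values directly as stagewise nominal p-value thresholds (the
#'   simpler, slightly liberal convention).
#' @return An object of class `mams_efficacy_rule`.
#' @export
efficacy_rule <- function(kind = c("none", "haybittle_peto", "obf_spending", "custom"),
                          p = NULL, alpha_total = NULL,
                          method = c("recursion", "nominal")) {
  kind <- match.arg(kind)
  method <- match.arg(method)
  if (kind == "custom" && (is.null(p) || length(p) == 0L)) kind <- "none"
  if (kind == "haybittle_peto" && is.null(p)) p <- 5e-4
  if (!is.null(p) && any(p <= 0 | p >= 1))
    stop("efficacy p-thresholds must lie in (0, 1)", call. = FALSE)
  structure(list(kind = kind, p = p, alpha_total = alpha_total, method = method),
            class = "mams_efficacy_rule")
}

#' Haybittle-Peto efficacy boundary
#'
#' A constant, very stringent one-sided p-value threshold (default 0.0005)
#' at every interim look, with the final analysis at the design's
#' final-stage significance level.
#'
#' @param J Number of stages (>= 1).
#' @param alpha_final Final-stage one-sided significance level.
#' @param p_interim Interim threshold, default 0.0005.
#' @return Numeric vector of stagewise one-sided efficacy p-thresholds.
#' @examples
#' haybittle_peto_bounds(3, 0.025)   # 0.0005 0.0005 0.0250
#' @export
haybittle_peto_bounds <- function(J, alpha_final, p_interim = 5e-4) {
  stopifnot(J >= 1, alpha_final > 0, alpha_final < 1)
  if (alpha_final < p_interim)
    warning("final-stage level is more stringent than the interim ",
            "efficacy threshold; interim bounds are laxer than the final test")
  c(rep(p_interim, J - 1L), alpha_final)
}

#' One-sided O'Brien-Fleming-type alpha-spending function
#'
#' Cumulative spend at information time t:
#' \eqn{f(t) = 2\,(1 - \Phi(z_{1-\alpha/2}/\sqrt{t}))}, the Lan-DeMets
#' approximation to the O'Brien-Fleming boundary, with `f(1) = alpha`.
#'
#' @param t Information fractions in (0, 1].
#' @param alpha_total Total one-sided alpha to spend.
#' @return Cumulative alpha spent at each `t`.
#' @export
obf_spending <- function(t, alpha_total) {
  if (any(t <= 0)) stop("information fractions must be positive", call. = FALSE)
  2 * (1 - stats::pnorm(stats::qnorm(1 - alpha_total / 2) / sqrt(t)))
}

#' Stagewise efficacy bounds from O'Brien-Fleming-type spending
#'
#' With `method = "recursion"` the stagewise z-bounds are solved
#' sequentially so that the joint probability of having crossed by look j
#' equals the cumulative spend \eqn{f(t_j)}, using the independent-increments
#' cross-stage correlation \eqn{\sqrt{t_i/t_j}}; the total crossing
#' probability is then exactly `alpha_total`.  With `method = "nominal"` the
#' cumulative spend values are used directly as stagewise nominal p-value
#' thresholds.
#'
#' @param info_fractions Increasing information fractions, last entry 1.
#' @param alpha_total Total one-sided alpha to spend.
#' @param method `"recursion"` (default) or `"nominal"`.
#' @return Numeric vector of stagewise one-sided efficacy p-thresholds.
#' @export
obf_spending_bounds <- function(info_fractions, alpha_total,
                                method = c("recursion", "nominal")) {
  method <- match.arg(method)
  t <- info_fractions
  J <- length(t)
  if (t[1] <= 0) stop("information fractions must be positive", call. = FALSE)
  if (J > 1L && any(diff(t) <= 0))
    stop("information fractions must be strictly increasing", call. = FALSE)
  if (abs(t[J] - 1) > 1e-12)
    stop("the final information fraction must be 1", call. = FALSE)
  spend <- obf_spending(t, alpha_total)
  if (method == "nominal" || J == 1L) return(spend)
  u <- numeric(J)
  u[1] <- stats::qnorm(1 - spend[1])
  corr <- stage_correlation(t)
  for (j in 2:J) {
    target <- 1 - spend[j]                      # P(no crossing through look j)
    f <- function(uj)
      .pmvn(lower = rep(-Inf, j), upper = c(u[1:(j - 1)], uj),
            sigma = corr[1:j, 1:j, drop = FALSE]) - target
    u[j] <- stats::uniroot(f, interval = c(-1, 40), extendInt = "upX",
                           tol = 1e-10)$root
  }
  z_to_p(u)
}

#' Custom efficacy boundary
#'
#' @param p Per-stage one-sided efficacy p-thresholds, length J - 1 (padded
#'   with `alpha_final`) or J (last entry must equal `alpha_final`).
#' @param alpha_final Final-stage one-sided significance level.
#' @param J Number of stages.
#' @return Numeric vector of length J.
#' @export
custom_bounds <- function(p, alpha_final, J) {
  if (is.null(p) || length(p) == 0L) return(NULL)
  if (any(p <= 0 | p >= 1))
    stop("efficacy p-thresholds must lie in (0, 1)", call. = FALSE)
  if (length(p) == J - 1L) {
    p <- c(p, alpha_final)
  } else if (length(p) == J) {
    if (abs(p[J] - alpha_final) > 1e-12)
      stop("the final custom efficacy threshold must equal the final-stage ",
           "significance level", call. = FALSE)
  } else {
    stop("custom efficacy p-vector must have length J - 1 or J", call. = FALSE)
  }
  p
}

#' Construct the per-stage boundary set of a design
#'
#' Combines the design's lack-of-benefit thresholds with the efficacy
#' thresholds of a stopping rule, on both the one-sided p-scale and the
#' benefit-z scale.  For an I != D design with an active efficacy rule, the
#' efficacy bounds apply to the definitive outcome at *its* information
#' fractions (`d_info_fractions`), which must then be present in the design.
#'
#' @param design A `mams_design`.
#' @param rule An [efficacy_rule()]; default none.
#' @return An object of class `mams_bounds`: a data frame with one row per
#'   stage (`stage`, `outcome`, `lob_p`, `lob_z`, `eff_p`, `eff_z`,
#'   `info_fraction`, `eff_info_fraction`), plus the rule as an attribute.
#' @examples
#' d <- mams_design(1, alpha = c(0.25, 0.1, 0.025))
#' boundary_set(d, efficacy_rule("haybittle_peto"))
#' @export
boundary_set <- function(design, rule = efficacy_rule("none")) {
  stopifnot(inherits(design, "mams_design"), inherits(rule, "mams_efficacy_rule"))
  J <- design$n_stages
  alpha_J <- design$alpha[J]
  t <- design$info_fractions
  active <- rule$kind != "none" && J > 1L

  # information fractions at which efficacy looks are made (D-outcome scale)
  s <- if (.uses_intermediate(design)) design$d_info_fractions else t
  if (active && .uses_intermediate(design) && is.null(s))
    stop("'d_info_fractions' are required for an I != D design with an ",
         "active efficacy rule", call. = FALSE)
  if (!active && is.null(s)) s <- t

  eff_p <- rep(NA_real_, J)
  eff_p[J] <- alpha_J
  if (active) {
    eff_p <- switch(rule$kind,
      haybittle_peto = haybittle_peto_bounds(J, alpha_J, rule$p),
      obf_spending = {
        a_tot <- if (is.null(rule$alpha_total)) alpha_J else rule$alpha_total
        b <- obf_spending_bounds(s, a_tot, rule$method)
        b[J] <- alpha_J   # the final analysis is always the design's own test
        b
      },
      custom = custom_bounds(rule$p, alpha_J, J))
    if (any(eff_p[-J] > design$alpha[-J]))
      stop("efficacy thresholds must be at least as stringent as the ",
           "lack-of-benefit levels at every interim stage", call. = FALSE)
  }

  lob_outcome <- if (.uses_intermediate(design)) design$intermediate$name
                 else design$definitive$name
  out <- data.frame(
    stage = seq_len(J),
    outcome = c(rep(lob_outcome, J - 1L), design$definitive$name),
    lob_p = design$alpha,
    lob_z = p_to_z(design$alpha),
    eff_p = eff_p,
    eff_z = ifelse(is.na(eff_p), NA_real_, stats::qnorm(1 - eff_p)),
    info_fraction = t,
    eff_info_fraction = if (is.null(s)) t else s)
  structure(out, rule = rule, alpha_final = alpha_J, class = c("mams_bounds", "data.frame"))
}

# Is an interim efficacy look made at any stage?
.has_interim_efficacy <- function(bounds) {
  J <- nrow(bounds)
  J > 1L && any(!is.na(bounds$eff_p[-J]))
}

#' @export
print.mams_bounds <- function(x, ...) {
  rule <- attr(x, "rule")
  cat(sprintf("Stagewise boundaries (efficacy rule: %s)\n", rule$kind))
  df <- as.data.frame(x)
  df[c("lob_p", "eff_p")] <- lapply(df[c("lob_p", "eff_p")], round, 4)
  df[c("lob_z", "eff_z")] <- lapply(df[c("lob_z", "eff_z")], round, 4)
  df[c("info_fraction", "eff_info_fraction")] <-
    lapply(df[c("info_fraction", "eff_info_fraction")], round, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
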