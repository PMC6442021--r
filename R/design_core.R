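# Design definition and completion: stagewise significance/power parameters,
# allocation, event schedule, information fractions and noncentralities.

#' Specify an outcome measure
#'
#' An outcome is characterised by its role in the design (interim
#' lack-of-benefit assessment on the intermediate outcome, efficacy claims on
#' the definitive outcome) and its hazard ratios under the null and the
#' target alternative.
#'
#' @param name Label, e.g. `"OS"` or `"FFS"`.
#' @param role `"definitive"` or `"intermediate"`.
#' @param hr_null Hazard ratio under the null hypothesis (dimensionless,
#'   positive; 1 in the usual no-effect null).
#' @param hr_alt Target hazard ratio under the alternative; must indicate
#'   benefit, i.e. `hr_alt < hr_null`.
#' @return An object of class `mams_outcome`.
#' @examples
#' outcome_spec("OS", "definitive", hr_alt = 0.75)
#' @export
outcome_spec <- function(name, role = c("definitive", "intermediate"),
                         hr_null = 1, hr_alt) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(hr_null) || hr_null <= 0)
    stop("'hr_null' must be a positive hazard ratio", call. = FALSE)
  if (!is.numeric(hr_alt) || hr_alt <= 0)
    stop("'hr_alt' must be a positive hazard ratio", call. = FALSE)
  if (hr_alt >= hr_null)
    stop("'hr_alt' must be smaller than 'hr_null' (benefit direction, HR < 1)",
         call. = FALSE)
  structure(list(name = name, role = role, hr_null = hr_null, hr_alt = hr_alt),
            class = "mams_outcome")
}

#' Define a multi-arm multi-stage design
#'
#' Describes a K-comparison, J-stage design: one-sided stagewise
#' lack-of-benefit significance levels `alpha` (strictly decreasing), the
#' stagewise powers `omega`, the research:control allocation ratio, the
#' outcome measures, and the stopping conventions.  Interim lack-of-benefit
#' assessments are made on the intermediate outcome (or the definitive
#' outcome when the two coincide); efficacy claims, and hence type I errors,
#' are made on the definitive outcome only.
#'
#' Information fractions at which the interim analyses occur default to the
#' quantile-ratio formula
#' \deqn{t_j = (z_{1-\alpha_j} + z_{1-\omega_j})^2 / (z_{1-\alpha_J} + z_{1-\omega_J})^2,}
#' which is scale invariant (independent of the target hazard ratio and the
#' allocation ratio).  An explicit per-stage control-arm event schedule, when
#' supplied, overrides the formula: `t_j = control_events[j] / control_events[J]`.
#'
#' @param n_comparisons Number of research-arm comparisons K (>= 1) sharing
#'   one control arm.
#' @param alpha One-sided stagewise lack-of-benefit significance levels,
#'   length J, strictly decreasing, each in (0, 1).  The last entry is the
#'   final-stage significance level used for the efficacy claim.
#' @param omega Stagewise powers, length J, each in (0, 1).  Defaults to 0.95
#'   at interim stages and `final_power` at stage J.
#' @param allocation Allocation ratio A = research:control (per comparison);
#'   positive, at most 1 in typical designs.
#' @param definitive [outcome_spec()] for the definitive outcome.
#' @param intermediate Optional [outcome_spec()] for the intermediate
#'   outcome; `NULL` means interim assessment uses the definitive outcome
#'   (an I = D design).
#' @param final_power Power used for the final stage when `omega` is omitted.
#' @param binding Are lack-of-benefit boundaries binding?  Defaults to
#'   `TRUE` for I = D designs and `FALSE` when an intermediate outcome is
#'   used (where maximum error rates under non-binding bounds are reported).
#' @param stopping_rule `"separate"` (trial continues with remaining arms
#'   after an efficacy stop; the default) or `"simultaneous"` (the whole
#'   trial stops at the first efficacy crossing).
#' @param rho_id Correlation in \[0, 1\] between the estimated treatment
#'   effects on the intermediate and definitive outcomes.  Required only
#'   when simulating or integrating a *binding* I != D design; maximum
#'   (non-binding) error rates do not depend on it.
#' @param control_events Optional control-arm event counts triggering each
#'   stage (length J, nondecreasing); overrides the information-fraction
#'   formula.
#' @param d_info_fractions Optional definitive-outcome information fractions
#'   at each stage (length J, increasing, last entry 1).  Required for an
#'   I != D design with an active efficacy rule, because interim efficacy
#'   looks are made on the definitive outcome at *its* information times.
#' @return A validated object of class `mams_design`.
#' @examples
#' # two-arm two-stage design, interim lack-of-benefit at alpha = 0.1
#' mams_design(1, alpha = c(0.1, 0.025), omega = c(0.95, 0.90))
#' @export
mams_design <- function(n_comparisons,
                        alpha,
                        omega = NULL,
                        allocation = 1,
                        definitive = outcome_spec("D", "definitive", hr_alt = 0.75),
                        intermediate = NULL,
                        final_power = 0.90,
                        binding = NULL,
                        stopping_rule = c("separate", "simultaneous"),
                        rho_id = NULL,
                        control_events = NULL,
                        d_info_fractions = NULL) {
  stopping_rule <- match.arg(stopping_rule)
  J <- length(alpha)
  if (is.null(omega))
    omega <- c(rep(0.95, max(J - 1L, 0L)), final_power)
  same_outcome <- is.null(intermediate)
  if (is.null(binding)) binding <- same_outcome
  design <- structure(
    list(n_comparisons = as.integer(n_comparisons),
         n_stages = J,
         alpha = as.numeric(alpha),
         omega = as.numeric(omega),
         allocation = allocation,
         definitive = definitive,
         intermediate = intermediate,
         binding = binding,
         stopping_rule = stopping_rule,
         rho_id = rho_id,
         control_events = control_events,
         d_info_fractions = d_info_fractions,
         info_fractions = NULL),
    class = "mams_design")
  validate_design(design)
}

#' Validate a design and resolve derived quantities
#'
#' Checks all invariants (monotone boundaries, allocation, event schedule,
#' information fractions) and fills in the resolved interim information
#' fractions.  Called by [mams_design()]; exported so that configurations
#' assembled by hand or read from file can be re-checked.
#'
#' @param design An object of class `mams_design`.
#' @return The validated design with `info_fractions` resolved.
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "mams_design"))
  K <- design$n_comparisons
  J <- design$n_stages
  alpha <- design$alpha
  omega <- design$omega
  if (is.na(K) || K < 1L) stop("'n_comparisons' must be >= 1", call. = FALSE)
  if (J < 1L) stop("at least one stage is required", call. = FALSE)
  if (any(alpha <= 0 | alpha >= 1))
    stop("stagewise significance levels must lie in (0, 1)", call. = FALSE)
  if (J > 1L && any(diff(alpha) >= 0))
    stop("stagewise significance levels must be strictly decreasing ",
         "(liberal early, stringent late)", call. = FALSE)
  if (length(omega) != J)
    stop("'omega' must have one entry per stage", call. = FALSE)
  if (any(omega <= 0 | omega >= 1))
    stop("stagewise powers must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(design$allocation) || design$allocation <= 0)
    stop("'allocation' must be a positive ratio", call. = FALSE)
  if (!inherits(design$definitive, "mams_outcome") ||
      design$definitive$role != "definitive")
    stop("'definitive' must be an outcome_spec with role 'definitive'",
         call. = FALSE)
  if (!is.null(design$intermediate)) {
    if (!inherits(design$intermediate, "mams_outcome") ||
        design$intermediate$role != "intermediate")
      stop("'intermediate' must be an outcome_spec with role 'intermediate'",
           call. = FALSE)
  }
  if (!is.null(design$rho_id) &&
      (design$rho_id < 0 || design$rho_id > 1))
    stop("'rho_id' must lie in [0, 1]", call. = FALSE)

  if (!is.null(design$control_events)) {
    ce <- design$control_events
    if (length(ce) != J)
      stop("'control_events' must have one entry per stage", call. = FALSE)
    if (any(diff(ce) < 0))
      stop("'control_events' must be nondecreasing across stages", call. = FALSE)
    if (any(ce <= 0)) stop("'control_events' must be positive", call. = FALSE)
    design$info_fractions <- ce / ce[J]
  } else {
    design$info_fractions <- information_fractions(alpha, omega)
  }
  t <- design$info_fractions
  if (J > 1L && any(diff(t) <= 0))
    stop("interim information fractions are non-monotone; ",
         "the (alpha, omega) sequence describes an inconsistent design",
         call. = FALSE)

  if (!is.null(design$d_info_fractions)) {
    s <- design$d_info_fractions
    if (length(s) != J || abs(s[J] - 1) > 1e-12)
      stop("'d_info_fractions' must have length J with last entry 1",
           call. = FALSE)
    if (any(diff(s) <= 0) || s[1] <= 0)
      stop("'d_info_fractions' must be strictly increasing and positive",
           call. = FALSE)
  }
  design
}

#' Information fractions from the stagewise design parameters
#'
#' The timing of interim analyses in the time-to-event MAMS framework is
#' driven by the control-arm event count required for each stagewise test,
#' which is proportional to \eqn{(z_{1-\alpha_j} + z_{1-\omega_j})^2}.  The
#' information fraction of stage j is therefore the ratio of that quantity
#' to its final-stage value, independent of the absolute event scale, the
#' target hazard ratio and the allocation ratio.
#'
#' @param alpha Stagewise one-sided significance levels in (0, 1).
#' @param omega Stagewise powers in (0, 1), same length.
#' @return Numeric vector of information fractions; the last entry is 1.
#' @examples
#' information_fractions(c(0.1, 0.025), c(0.95, 0.90))   # 0.8150, 1
#' @export
information_fractions <- function(alpha, omega) {
  stopifnot(length(alpha) == length(omega))
  if (any(alpha <= 0 | alpha >= 1) || any(omega <= 0 | omega >= 1))
    stop("'alpha' and 'omega' entries must lie in (0, 1)", call. = FALSE)
  eta <- stats::qnorm(1 - alpha) + stats::qnorm(omega)
  (eta / eta[length(eta)])^2
}

#' Required number of events for a stagewise comparison
#'
#' Schoenfeld-type event count for a one-sided level-`alpha` log-rank
#' comparison with power `omega` against hazard ratio `hr_alt` under
#' research:control allocation `A`:
#' \deqn{E = \frac{(1+A)^2}{A} \cdot \frac{(z_{1-\alpha} + z_{1-\omega})^2}{(\log hr)^2},}
#' rounded up, with control-arm share 1/(1+A).
#'
#' @param alpha One-sided significance level in (0, 1).
#' @param omega Power in (0, 1).
#' @param hr_alt Target hazard ratio (not 1).
#' @param allocation Allocation ratio A > 0 (research:control).
#' @return A list with integer components `total` and `control`.
#' @examples
#' required_events(0.025, 0.90, 0.75, 1)    # total 508, control 254
#' @export
required_events <- function(alpha, omega, hr_alt, allocation = 1) {
  stopifnot(alpha > 0, alpha < 1, omega > 0, omega < 1, allocation > 0)
  if (hr_alt == 1)
    stop("'hr_alt' = 1 demands an unbounded number of events", call. = FALSE)
  A <- allocation
  e_total <- (1 + A)^2 / A *
    (stats::qnorm(1 - alpha) + stats::qnorm(omega))^2 / log(hr_alt)^2
  list(total = as.integer(ceiling(e_total)),
       control = as.integer(ceiling(e_total / (1 + A))))
}

#' Noncentrality (mean shift) of the stagewise benefit-z statistic
#'
#' All statistics are oriented so that larger z means more benefit (HR < 1).
#' By the design calibration, the stage-j statistic on the outcome tested for
#' lack-of-benefit has mean \eqn{\eta_j = z_{1-\alpha_j} + z_{1-\omega_j}}
#' under the target alternative, so that its marginal stagewise power is
#' exactly \eqn{\omega_j}.  Under the null the shift is 0.
#'
#' @param design A `mams_design`.
#' @param stage Optional stage index; by default all stages.
#' @param hypothesis `"alternative"` (default) or `"null"`.
#' @return Numeric vector of stagewise mean shifts.
#' @export
noncentrality <- function(design, stage = NULL,
                          hypothesis = c("alternative", "null")) {
  hypothesis <- match.arg(hypothesis)
  stopifnot(inherits(design, "mams_design"))
  eta <- stats::qnorm(1 - design$alpha) + stats::qnorm(design$omega)
  if (hypothesis == "null") eta <- rep(0, design$n_stages)
  if (!is.null(stage)) eta <- eta[stage]
  eta
}

# Stages 1..J-1 tested on the intermediate outcome?
.uses_intermediate <- function(design) !is.null(design$intermediate)

#' @export
print.mams_design <- function(x, ...) {
  io <- if (.uses_intermediate(x)) {
    sprintf("%s (interim) / %s (final)", x$intermediate$name, x$definitive$name)
  } else {
    sprintf("%s throughout (I = D)", x$definitive$name)
  }
  cat(sprintf("MAMS design: %d comparison%s, %d stage%s\n",
              x$n_comparisons, if (x$n_comparisons > 1) "s" else "",
              x$n_stages, if (x$n_stages > 1) "s" else ""))
  cat(sprintf("  outcomes:            %s\n", io))
  cat(sprintf("  allocation (R:C):    %g\n", x$allocation))
  cat(sprintf("  alpha (one-sided):   %s\n", paste(format(x$alpha), collapse = ", ")))
  cat(sprintf("  omega:               %s\n", paste(format(x$omega), collapse = ", ")))
  cat(sprintf("  info fractions:      %s%s\n",
              paste(format(round(x$info_fractions, 4)), collapse = ", "),
              if (is.null(x$control_events)) "" else "  (from event schedule)"))
  cat(sprintf("  lack-of-benefit:     %s\n",
              if (x$binding) "binding" else "non-binding"))
  cat(sprintf("  stopping rule:       %s\n", x$stopping_rule))
  invisible(x)
}
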