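# Search for the final-stage significance level that strongly controls the
# maximum FWER at a prespecified level.

#' Solve for the final-stage significance level controlling the maximum FWER
#'
#' The maximum FWER of a design is computed assuming non-binding
#' lack-of-benefit boundaries (all research arms pass all interim stages);
#' controlling that maximum controls the FWER under any configuration of
#' true effects on the intermediate or definitive outcomes.  This search
#' adjusts the final-stage one-sided significance level by linear
#' interpolation (regula falsi on a bracketing interval), re-deriving any
#' efficacy bounds that depend on it at each step — the Haybittle-Peto
#' interim threshold stays fixed, an O'Brien-Fleming-type rule re-spends the
#' candidate level, custom interim thresholds stay fixed — until the maximum
#' FWER matches the target.  The control-arm event consequences at the
#' design's final-stage power are reported alongside.
#'
#' @param design A `mams_design`.
#' @param rule An [efficacy_rule()]; default none.
#' @param target_fwer Target familywise error rate (one-sided), in (0, 1).
#' @param tol Convergence tolerance on |max FWER - target|, default 1e-5.
#' @param max_iter Iteration cap, default 50.
#' @return An object of class `mams_control`: `alpha_final_adjusted`,
#'   `achieved_fwer`, `iterations`, `events_original`, `events_adjusted`,
#'   `incremental_events` (control-arm final-stage events), plus the
#'   unadjusted maximum FWER.
#' @examples
#' icon5 <- mams_design(4, alpha = c(0.064, 0.025), omega = c(0.95, 0.98),
#'                      intermediate = outcome_spec("PFS", "intermediate", hr_alt = 0.75))
#' solve_alpha_final(icon5, target_fwer = 0.025)   # alpha_J = 0.0073
#' @export
solve_alpha_final <- function(design, rule = efficacy_rule("none"),
                              target_fwer = 0.025, tol = 1e-5, max_iter = 50L) {
  stopifnot(inherits(design, "mams_design"),
            target_fwer > 0, target_fwer < 1)
  J <- design$n_stages
  alpha_orig <- design$alpha[J]

  max_fwer_at <- function(a) {
    d <- design
    d$alpha[J] <- a
    # keep the lack-of-benefit ladder formally decreasing; interim levels do
    # not enter the non-binding maximum
    if (J > 1L) d$alpha[-J] <- pmax(d$alpha[-J], a * 2)
    d <- validate_design(d)
    fwer(d, boundary_set(d, rule), max_variant = TRUE)
  }

  unadjusted <- max_fwer_at(alpha_orig)
  # interim efficacy spend puts a floor on the achievable maximum FWER;
  # probing the alpha_J -> 0 limit intentionally inverts the usual
  # interim/final stringency, so that advisory warning is silenced here
  floor_fwer <- suppressWarnings(max_fwer_at(1e-9))
  if (floor_fwer > target_fwer - tol)
    stop(sprintf(paste0("target %.4g is infeasible: interim efficacy looks ",
                        "alone spend %.4g of familywise error"),
                 target_fwer, floor_fwer), call. = FALSE)

  lo <- 1e-9; f_lo <- floor_fwer - target_fwer
  hi <- target_fwer; f_hi <- max_fwer_at(hi) - target_fwer
  iter <- 0L
  while (f_hi < 0) {           # bracket expansion (f increasing in alpha)
    hi <- min(hi * 2, 0.999); f_hi <- max_fwer_at(hi) - target_fwer
    iter <- iter + 1L
    if (iter > 20L) stop("failed to bracket the target FWER", call. = FALSE)
  }
  a <- hi; f_a <- f_hi
  repeat {
    iter <- iter + 1L
    a <- lo - f_lo * (hi - lo) / (f_hi - f_lo)   # linear interpolation
    f_a <- max_fwer_at(a) - target_fwer
    if (abs(f_a) <= tol || iter >= max_iter) break
    if (f_a > 0) { hi <- a; f_hi <- f_a } else { lo <- a; f_lo <- f_a }
  }
  if (abs(f_a) > tol)
    warning(sprintf("search stopped after %d iterations at |error| = %.2g",
                    iter, abs(f_a)))

  omega_J <- design$omega[J]
  hr <- design$definitive$hr_alt
  ev0 <- required_events(alpha_orig, omega_J, hr, design$allocation)
  ev1 <- required_events(a, omega_J, hr, design$allocation)
  structure(list(alpha_final_original = alpha_orig,
                 alpha_final_adjusted = a,
                 achieved_fwer = f_a + target_fwer,
                 target_fwer = target_fwer,
                 unadjusted_max_fwer = unadjusted,
                 iterations = iter,
                 rule = rule$kind,
                 events_original = ev0$control,
                 events_adjusted = ev1$control,
                 incremental_events = ev1$control - ev0$control),
            class = "mams_control")
}

#' @export
print.mams_control <- function(x, ...) {
  cat("FWER control search\n")
  cat(sprintf("  efficacy rule:            %s\n", x$rule))
  cat(sprintf("  unadjusted max FWER:      %.4f (at alpha_J = %.4g)\n",
              x$unadjusted_max_fwer, x$alpha_final_original))
  cat(sprintf("  target FWER:              %.4f\n", x$target_fwer))
  cat(sprintf("  adjusted alpha_J:         %.4f  (%d iterations)\n",
              x$alpha_final_adjusted, x$iterations))
  cat(sprintf("  achieved max FWER:        %.5f\n", x$achieved_fwer))
  cat(sprintf("  control-arm events:       %d -> %d (+%d)\n",
              x$events_original, x$events_adjusted, x$incremental_events))
  invisible(x)
}
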