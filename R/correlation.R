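# Joint correlation of all stagewise test statistics across comparisons and
# outcomes.  Two sources of correlation: the shared control arm (Dunnett
# structure, A/(1+A)) and the independent-increments information-time
# structure within an outcome (sqrt(t_i/t_j)), attenuated by rho_ID across
# outcomes.

#' Between-comparison correlation induced by the shared control arm
#'
#' Two comparisons against a common control arm with research:control
#' allocation A share the control-arm estimate, giving correlation
#' \eqn{\rho = A/(1+A)} between their treatment-effect statistics at a
#' common stage and outcome (0.5 at equal allocation, the classical Dunnett
#' value).
#'
#' @param allocation Allocation ratio A > 0.
#' @return Correlation in (0, 1).
#' @export
between_comparison_rho <- function(allocation) {
  stopifnot(allocation > 0)
  allocation / (1 + allocation)
}

#' Cross-stage correlation matrix of cumulative test statistics
#'
#' Under the independent-increments (Brownian motion) structure of
#' cumulative score statistics, statistics at information fractions t_i <=
#' t_j have correlation \eqn{\sqrt{t_i/t_j}}.
#'
#' @param t Increasing, positive information fractions.
#' @return J x J correlation matrix.
#' @export
stage_correlation <- function(t) {
  if (any(t <= 0)) stop("information fractions must be positive", call. = FALSE)
  if (length(t) > 1L && any(diff(t) <= 0))
    stop("information fractions must be strictly increasing", call. = FALSE)
  outer(sqrt(t), sqrt(t), function(a, b) pmin(a, b) / pmax(a, b))
}

# Coordinate layout of the per-comparison statistic vector.
#
# One row per statistic entering the stagewise decisions of a single
# comparison: columns stage, outcome ("I"/"D"), fraction (information time
# on that outcome's scale), tests_lob, tests_eff, is_final.
#
# I = D designs use one statistic per stage.  I != D designs use the
# intermediate-outcome statistics for interim lack-of-benefit (included when
# the design is binding or rho_id is supplied), definitive-outcome
# statistics at interim efficacy looks, and the final definitive statistic.
.stat_layout <- function(design, bounds) {
  J <- design$n_stages
  interim_eff <- .has_interim_efficacy(bounds)
  if (!.uses_intermediate(design)) {
    t <- design$info_fractions
    return(data.frame(
      stage = seq_len(J), outcome = "D", fraction = t,
      tests_lob = seq_len(J) < J,
      tests_eff = interim_eff & seq_len(J) < J & !is.na(bounds$eff_p),
      is_final = seq_len(J) == J))
  }
  lay <- data.frame(stage = J, outcome = "D", fraction = 1,
                    tests_lob = FALSE, tests_eff = FALSE, is_final = TRUE)
  if (interim_eff) {
    jj <- which(!is.na(bounds$eff_p) & seq_len(J) < J)
    s <- bounds$eff_info_fraction
    lay <- rbind(data.frame(stage = jj, outcome = "D", fraction = s[jj],
                            tests_lob = FALSE, tests_eff = TRUE,
                            is_final = FALSE), lay)
  }
  include_I <- J > 1L && (design$binding || !is.null(design$rho_id))
  if (include_I) {
    jj <- seq_len(J - 1L)
    lay <- rbind(data.frame(stage = jj, outcome = "I",
                            fraction = design$info_fractions[jj],
                            tests_lob = TRUE, tests_eff = FALSE,
                            is_final = FALSE), lay)
  }
  o <- order(lay$stage, lay$outcome)  # I before D within a stage
  lay[o, , drop = FALSE]
}

# Within-comparison correlation over a layout: sqrt(f_i/f_j) within an
# outcome, times rho_id across outcomes.
.within_correlation <- function(layout, rho_id) {
  M <- nrow(layout)
  f <- layout$fraction
  base <- outer(sqrt(f), sqrt(f), function(a, b) pmin(a, b) / pmax(a, b))
  cross <- outer(layout$outcome, layout$outcome, "!=")
  if (any(cross)) {
    if (is.null(rho_id))
      stop("'rho_id' is required to correlate intermediate- and ",
           "definitive-outcome statistics", call. = FALSE)
    base[cross] <- base[cross] * rho_id
  }
  diag(base) <- 1
  base
}

#' Joint correlation model of all stagewise statistics
#'
#' Builds the full (K*M) x (K*M) correlation matrix over all statistics
#' entering the design's decisions: within a comparison the
#' independent-increments entry \eqn{\sqrt{t_i/t_j}} (times `rho_id` across
#' outcomes); across comparisons the same entry multiplied by the shared
#' control-arm correlation \eqn{A/(1+A)}.
#'
#' @param design A `mams_design`.
#' @param bounds A [boundary_set()]; defaults to no efficacy rule.
#' @return An object of class `mams_corr`: list with the per-comparison
#'   statistic `layout`, `within` (M x M), `rho_between`, and the `full`
#'   (K*M) x (K*M) matrix (checked positive semi-definite).
#' @export
joint_correlation <- function(design, bounds = boundary_set(design)) {
  stopifnot(inherits(design, "mams_design"))
  layout <- .stat_layout(design, bounds)
  within <- .within_correlation(layout, design$rho_id)
  rho <- between_comparison_rho(design$allocation)
  K <- design$n_comparisons
  M <- nrow(layout)
  full <- matrix(0, K * M, K * M)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    blk <- if (i == j) within else rho * within
    full[(M * (i - 1) + 1):(M * i), (M * (j - 1) + 1):(M * j)] <- blk
  }
  diag(full) <- 1
  ev <- eigen(full, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("joint correlation matrix is not positive semi-definite ",
         sprintf("(smallest eigenvalue %.3g)", min(ev)), call. = FALSE)
  structure(list(layout = layout, within = within, rho_between = rho,
                 full = full, n_comparisons = K),
            class = "mams_corr")
}

#' @export
print.mams_corr <- function(x, ...) {
  cat(sprintf("Joint correlation model: %d comparison(s) x %d statistic(s)\n",
              x$n_comparisons, nrow(x$layout)))
  cat(sprintf("  between-comparison rho (shared control): %.4f\n", x$rho_between))
  cat("  per-comparison layout:\n")
  print(x$layout, row.names = FALSE)
  invisible(x)
}
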