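# Monte-Carlo engine: stagewise multivariate-normal test statistics for K
# comparisons, stagewise decisions, empirical operating characteristics.

#' Simulate trial replicates at the test-statistic level
#'
#' Draws the joint (K x M)-dimensional normal statistic vector of the design
#' (model correlation from [joint_correlation()], hypothesis-dependent
#' means), applies the stagewise decisions — drop for lack-of-benefit when
#' binding, stop a comparison for efficacy when it crosses an interim bound,
#' stop the whole trial at the first efficacy crossing under the
#' simultaneous rule — and tabulates the empirical error rates, the three
#' power measures and the per-stage stopping frequencies.  Under non-binding
#' bounds, lack-of-benefit crossings are recorded but do not stop a
#' comparison, so the non-binding maxima are estimated directly.
#'
#' @param design A `mams_design`.
#' @param bounds A [boundary_set()]; default no efficacy rule.
#' @param n_reps Number of simulated trials.
#' @param seed RNG seed (required, for reproducibility).
#' @param hypothesis `"global_null"` or `"global_alternative"`.
#' @return An object of class `mams_sim`: empirical `pwer`, `fwer`,
#'   `per_pair_power`/`any_pair_power`/`all_pair_power` (under the
#'   alternative), Monte-Carlo standard errors, per-stage lack-of-benefit
#'   and efficacy stopping frequencies per comparison, `n_reps` and `seed`.
#' @examples
#' d <- mams_design(2, alpha = c(0.1, 0.025))
#' simulate_trials(d, n_reps = 1e4, seed = 1)
#' @export
simulate_trials <- function(design, bounds = boundary_set(design),
                            n_reps = 1e6, seed,
                            hypothesis = c("global_null", "global_alternative")) {
  hypothesis <- match.arg(hypothesis)
  stopifnot(inherits(design, "mams_design"), n_reps >= 1)
  if (missing(seed) || is.null(seed))
    stop("a 'seed' is required: simulation results must be reproducible",
         call. = FALSE)
  corr <- joint_correlation(design, bounds)
  layout <- corr$layout
  K <- design$n_comparisons
  J <- design$n_stages
  M <- nrow(layout)
  mu_one <- .layout_means(design, layout,
                          if (hypothesis == "global_null") "null" else "alternative")
  mu <- rep(mu_one, K)
  R <- chol(corr$full + diag(1e-12, K * M))
  final_z <- p_to_z(attr(bounds, "alpha_final"))
  simultaneous <- design$stopping_rule == "simultaneous"

  # per-stage column indices within one comparison's layout
  lob_col <- vapply(seq_len(J), function(j) {
    r <- which(layout$tests_lob & layout$stage == j)
    if (length(r)) r else NA_integer_
  }, integer(1))
  eff_col <- vapply(seq_len(J), function(j) {
    r <- which(layout$tests_eff & layout$stage == j)
    if (length(r)) r else NA_integer_
  }, integer(1))
  fin_col <- which(layout$is_final)

  err_n <- numeric(K)                # per-comparison error/detection counts
  any_n <- all_n <- 0
  lob_stop <- matrix(0, J, K)        # lack-of-benefit crossings by stage
  eff_stop <- matrix(0, J, K)        # efficacy crossings by stage

  n_done <- 0
  chunk <- min(n_reps, 250000L)
  set.seed(seed)
  while (n_done < n_reps) {
    n <- min(chunk, n_reps - n_done)
    X <- matrix(stats::rnorm(n * K * M), n, K * M) %*% R
    X <- sweep(X, 2L, mu, "+")

    cross_stage <- matrix(J + 1L, n, K)   # first interim efficacy crossing
    err <- matrix(FALSE, n, K)
    active <- matrix(TRUE, n, K)
    for (j in seq_len(J - 1L)) {
      for (k in seq_len(K)) {
        off <- (k - 1L) * M
        cross <- logical(n)
        if (!is.na(eff_col[j])) {
          cross <- active[, k] & X[, off + eff_col[j]] >= bounds$eff_z[j]
          newc <- cross & cross_stage[, k] > J
          cross_stage[newc, k] <- j
          eff_stop[j, k] <- eff_stop[j, k] + sum(cross)
          err[, k] <- err[, k] | cross
        }
        if (!is.na(lob_col[j])) {
          drop <- active[, k] & !cross & X[, off + lob_col[j]] <= bounds$lob_z[j]
          lob_stop[j, k] <- lob_stop[j, k] + sum(drop)
          if (design$binding) active[, k] <- active[, k] & !cross & !drop
          else active[, k] <- active[, k] & !cross
        } else {
          active[, k] <- active[, k] & !cross
        }
      }
    }
    for (k in seq_len(K)) {
      off <- (k - 1L) * M
      fin <- active[, k] & X[, off + fin_col] > final_z
      err[, k] <- err[, k] | fin
    }
    if (simultaneous) {
      # errors/detections only count up to the first efficacy crossing
      first <- apply(cross_stage, 1L, min)
      for (k in seq_len(K)) {
        late_interim <- cross_stage[, k] > first & cross_stage[, k] <= J
        reached_final <- cross_stage[, k] > J & first <= J
        err[late_interim | reached_final, k] <- FALSE
      }
    }
    err_n <- err_n + colSums(err)
    any_n <- any_n + sum(rowSums(err) > 0)
    all_n <- all_n + sum(rowSums(err) == K)
    n_done <- n_done + n
  }

  p_pair <- err_n / n_reps
  p_any <- any_n / n_reps
  p_all <- all_n / n_reps
  mc_se <- function(p) sqrt(p * (1 - p) / n_reps)
  res <- list(n_reps = n_reps, seed = seed, hypothesis = hypothesis,
              lob_stop_freq = lob_stop / n_reps,
              eff_stop_freq = eff_stop / n_reps)
  if (hypothesis == "global_null") {
    res$pwer <- mean(p_pair)
    res$fwer <- p_any
    res$mc_se <- c(pwer = mc_se(res$pwer), fwer = mc_se(res$fwer))
  } else {
    res$per_pair_power <- mean(p_pair)
    res$any_pair_power <- p_any
    res$all_pair_power <- p_all
    res$mc_se <- c(per_pair_power = mc_se(res$per_pair_power),
                   any_pair_power = mc_se(res$any_pair_power),
                   all_pair_power = mc_se(res$all_pair_power))
  }
  structure(res, class = "mams_sim")
}

#' @export
print.mams_sim <- function(x, ...) {
  cat(sprintf("Simulated operating characteristics (%s, %s replicates, seed %s)\n",
              x$hypothesis, format(x$n_reps, big.mark = ","), x$seed))
  show <- intersect(c("pwer", "fwer", "per_pair_power", "any_pair_power",
                      "all_pair_power"), names(x))
  for (nm in show)
    cat(sprintf("  %-16s %.4f  (MC SE %.5f)\n", paste0(nm, ":"), x[[nm]],
                x$mc_se[[nm]]))
  invisible(x)
}

#' Operating characteristics over a grid of design configurations
#'
#' Evaluates each configuration with and without the efficacy rule and
#' reports the familywise error rate, its inflation (absolute difference
#' and rounded percentage) and the three power measures, in the long format
#' of the usual summary tables.
#'
#' @param n_comparisons Vector of K values.
#' @param stages Vector of J values (2, 3 or 4 use the conventional
#'   lack-of-benefit ladders 0.5, 0.25, 0.1, 0.025 truncated to the last J
#'   entries).
#' @param outcomes `"same"` (I = D, binding) or `"different"` (I != D,
#'   non-binding maxima).
#' @param rule An [efficacy_rule()] applied in the "with EB" column.
#' @param allocation Allocation ratio.
#' @param d_info_fractions_ratio For I != D designs with an efficacy rule:
#'   definitive-outcome information at each interim look as a fraction of
#'   the intermediate-outcome information fraction (default 0.5, emulating
#'   slower accrual of definitive events).
#' @param method `"integration"` (default) or `"simulation"`.
#' @param n_reps,seed Used when `method = "simulation"`.
#' @return A data frame, one row per configuration.
#' @export
replicate_study_grid <- function(n_comparisons = 1:5, stages = 2:4,
                                 outcomes = c("same", "different"),
                                 rule = efficacy_rule("haybittle_peto"),
                                 allocation = 1,
                                 d_info_fractions_ratio = 0.5,
                                 method = c("integration", "simulation"),
                                 n_reps = 1e5, seed = 1L) {
  outcomes <- match.arg(outcomes)
  method <- match.arg(method)
  ladder <- c(0.5, 0.25, 0.1, 0.025)
  rows <- list()
  for (J in stages) {
    stopifnot(J >= 2, J <= 4)
    alpha <- utils::tail(ladder, J)
    for (K in n_comparisons) {
      inter <- if (outcomes == "different")
        outcome_spec("I", "intermediate", hr_alt = 0.70) else NULL
      t <- information_fractions(alpha, c(rep(0.95, J - 1), 0.90))
      s <- if (outcomes == "different")
        c(pmin(t[-J] * d_info_fractions_ratio, 1), 1) else NULL
      d <- mams_design(K, alpha = alpha, allocation = allocation,
                       intermediate = inter, d_info_fractions = s)
      evaluate <- function(b) {
        if (method == "integration") {
          pw <- power_measures(d, b)
          c(fwer = fwer(d, b), pw)
        } else {
          s0 <- simulate_trials(d, b, n_reps, seed, "global_null")
          s1 <- simulate_trials(d, b, n_reps, seed + 1L, "global_alternative")
          c(fwer = s0$fwer, per_pair = s1$per_pair_power,
            any_pair = s1$any_pair_power, all_pair = s1$all_pair_power)
        }
      }
      no_eb <- evaluate(boundary_set(d, efficacy_rule("none")))
      with_eb <- evaluate(boundary_set(d, rule))
      infl <- with_eb[["fwer"]] - no_eb[["fwer"]]
      rows[[length(rows) + 1L]] <- data.frame(
        comparisons = K, stages = J, outcomes = outcomes,
        fwer_no_eb = no_eb[["fwer"]], fwer_eb = with_eb[["fwer"]],
        inflation = infl,
        percentage = round(100 * infl / no_eb[["fwer"]]),
        per_pair_no_eb = no_eb[["per_pair"]], per_pair_eb = with_eb[["per_pair"]],
        any_pair_no_eb = no_eb[["any_pair"]], any_pair_eb = with_eb[["any_pair"]],
        all_pair_no_eb = no_eb[["all_pair"]], all_pair_eb = with_eb[["all_pair"]])
    }
  }
  do.call(rbind, rows)
}
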