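---
title: "Error rates and power of MAMS designs with efficacy stopping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error rates and power of MAMS designs with efficacy stopping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mamsoc)
```

## The design and its statistical model

A multi-arm multi-stage (MAMS) trial compares K research arms against one
shared control arm over J stages.  Stages 1 to J−1 test each comparison for
*lack of benefit* at one-sided levels α₁ > … > α_{J−1}: an arm continues
only if it rejects "no benefit" at the stage's level, i.e. if its benefit-z
statistic exceeds z(1−α_j).  The final stage tests efficacy at α_J.  In
time-to-event settings the interim tests usually use an intermediate
outcome I (earlier, correlated with the definitive outcome D, possibly a
composite containing it); efficacy claims — and therefore type I errors —
are only ever made on D.  Optionally, a stringent efficacy boundary αE_j on
D permits stopping an arm early for overwhelming benefit.

All computations in this package are on standardised cumulative score
statistics, taken as multivariate normal with unit variances.  This is the
asymptotic model under which such designs are constructed, and it fixes the
entire joint law with three ingredients:

* **Information fractions.**  Stage j's test needs a number of events
  proportional to (z(1−α_j) + z(1−ω_j))², where ω_j is the stagewise power;
  the information fraction t_j is that quantity relative to stage J.  This
  quantile-ratio default is scale invariant — it does not depend on the
  target hazard ratio, the allocation ratio or the absolute event counts.
  When a design's actual event schedule is known it should be supplied
  (`control_events=`), because practical schedules are rounded and
  software-adjusted and override the formula; `mams_design()` then uses
  t_j = e_j/e_J.  Cumulative statistics at fractions t_i ≤ t_j have
  correlation √(t_i/t_j) (independent increments).

* **Shared control arm.**  Two comparisons at the same stage and outcome
  correlate at ρ = A/(1+A) for research:control allocation A (0.5 at equal
  allocation — the classical Dunnett structure).  Cross-comparison,
  cross-stage entries factor as ρ·√(t_i/t_j), which is exact for normal
  increments sharing control information proportionally.

* **Intermediate vs definitive outcome.**  Statistics on I and D correlate
  through the treatment-effect correlation ρ_ID, supplied as a design input
  (it depends on the outcome definitions and censoring patterns and is not
  derivable from the design parameters alone).  Maximum (non-binding) error
  rates do not involve ρ_ID at all, because they remove the interim
  lack-of-benefit constraints and type I errors live entirely on D; this is
  why `rho_id` is only required for *binding* I ≠ D computations.

Under the target alternative, the stage-j statistic on the interim-tested
outcome has mean η_j = z(1−α_j) + z(1−ω_j) — the calibration that makes the
marginal stagewise power exactly ω_j.  For D-statistics at interim looks of
an I ≠ D design no stagewise calibration exists, and the mean follows
Brownian scaling, η_J·√(s_j) at D-information fraction s_j.

## Error rates

The pairwise error rate (PWER) sums the disjoint stagewise crossing events:
continue through stages before j (above the lack-of-benefit bound, below
the efficacy bound), then cross the efficacy bound at j (or the final
threshold at stage J).  Each term is a box probability of a multivariate
normal vector; `pwer()` evaluates them directly.  The familywise error rate
(FWER) is one minus the probability that *every* comparison stops without
an error.  Because the complement of a comparison's error event is itself a
disjoint union of stagewise boxes, the joint probability is a sum of
(J·K)-dimensional box probabilities over assignments of stop-stages to
comparisons; exchangeability under the global null reduces the sum to
multisets with multinomial weights.  With non-binding bounds and no interim
efficacy looks only the K equicorrelated final statistics matter and
`fwer()` uses the classical one-dimensional Dunnett conditioning integral
instead.

Two regimes matter in practice:

* **Binding** lack-of-benefit bounds: arms that fail an interim really
  stop.  This is the *actual* error rate, and it is below α_J because the
  interim hurdles absorb error probability.
* **Non-binding maximum**: every arm is assumed to pass every interim
  (bounds replaced by −∞).  With no efficacy looks the maximum PWER is α_J
  exactly; efficacy looks add the interim crossing probability.  Strong
  control of the FWER is control of this maximum.

Under the global null the FWER is identical for separate stopping (trial
continues after an efficacy stop) and simultaneous stopping (whole trial
stops): an error after the first crossing cannot create a *first* error.
The simulator exposes both rules and the suite asserts the equality; the
PWER decreases marginally under simultaneous stopping because later
errors in the same replicate are never made.

## Efficacy boundaries

* **Haybittle–Peto**: constant one-sided p = 0.0005 at every interim, the
  design's own test at stage J.  Unaffected by analysis timing, which is
  why it is the default rule.
* **O'Brien–Fleming-type spending**: cumulative spend
  f(t) = 2(1 − Φ(z(1−α/2)/√t)), the Lan–DeMets approximation.  Two
  conventions are implemented.  `method = "recursion"` (default) solves the
  stagewise z-bounds sequentially so the joint crossing probability through
  look j equals f(t_j) exactly — spending is conserved and the total type I
  error of the boundary alone is exactly α.  `method = "nominal"` uses
  f(t_j) directly as the stagewise nominal threshold; it is simpler,
  slightly liberal, and is the convention behind some published boundary
  tables, so it is kept for comparability.  In both cases the stage-J
  analysis remains the design's own α_J test.
* **Custom**: any per-stage p-vector, padded with α_J; entries laxer than
  the lack-of-benefit level are rejected.

For I ≠ D designs the efficacy looks are taken at the *definitive*
outcome's information fractions (`d_info_fractions`), not at the interim
outcome's.  Early looks typically carry very little D-information, which is
why a spending rule then allocates almost nothing to them and inflates
nothing, while a constant Haybittle–Peto threshold spends a little at every
look.

## Controlling the FWER

`solve_alpha_final()` finds the α_J whose *maximum* FWER equals a target,
by regula-falsi linear interpolation on a bracketing interval (the maximum
FWER is continuous and increasing in α_J; convergence tolerance 1e-5 on the
FWER by default, typically 3–4 iterations).  Efficacy boundaries are
re-derived at each candidate: the Haybittle–Peto interim threshold is held
fixed (only the final level moves), a spending rule re-spends the candidate
total, custom interim thresholds stay fixed.  A target below the error
spent by the interim efficacy bounds alone is reported as infeasible.  The
event cost of the adjustment is computed from the Schoenfeld-type formula
E = ((1+A)²/A)·(z(1−α)+z(1−ω))²/(log hr)², rounded up, control share
1/(1+A).  Published event schedules are not exactly reproducible from this
(or any single printed) formula — production software applies its own
adjustments — so explicit event counts in a configuration always take
precedence over derived ones, and derived counts should be read as the
formula's answer, not the trial's.

## Numerical choices

* Quadrature: deterministic Miwa quadrature (512 grid points) up to
  dimension 3; Genz–Bretz quasi-Monte-Carlo above (absolute tolerance 1e-7,
  fixed internal scrambling seed so that reported 4-decimal values are
  reproducible run to run).  Coordinates unconstrained on both sides are
  dropped before integration.
* The Dunnett maximum uses a 1-D conditioning integral at relative
  tolerance 1e-10; ρ = 1 and ρ = 0 take their closed-form limits.
* The spending recursion solves each stagewise bound with `uniroot` at
  tolerance 1e-10; a look with (numerically) zero spend gets an infinite
  bound and contributes nothing.
* Degenerate inputs: J = 1 collapses every quantity to the single test at
  α_J; K = 1 makes the three power measures identical and FWER = PWER.

## The simulator, and what the tests do and do not show

`simulate_trials()` draws the (K·M)-dimensional statistic vector from the
model correlation (Cholesky factorisation, 250k-replicate chunks) and
applies the stagewise decisions literally, including non-binding
bookkeeping and both stopping rules.  It emulates exactly the asymptotic
normal model: no patient-level survival times, no staggered accrual, no
misspecified proportional hazards, no estimation noise in the information
fractions.  Agreement between simulator and integration (asserted
throughout the test suite at 3–4 Monte-Carlo standard errors) therefore
validates the *implementation* of the model, not the normal approximation
itself in small samples.  Default problem sizes in the tests are 2×10⁵
replicates for agreement checks and 10⁶ for the headline five-comparison
FWER, which puts Monte-Carlo standard errors near 3×10⁻⁴; studies wanting
published-table precision should use several million replicates.

The bundled study-grid defaults mirror the conventional simulation
conditions for such designs: lack-of-benefit ladders (0.5, 0.25, 0.1,
0.025) truncated to the last J stages, interim power 0.95, final power
0.90, final-stage α_J = 0.025 one-sided, allocation ratio 1, intermediate
outcome hazard ratio 0.70 and definitive 0.75 under the alternative.  For
I ≠ D grids with efficacy looks, the definitive outcome's interim
information is taken as half the intermediate outcome's fraction — chosen
once to emulate the roughly 2:1 lag between failure-type and survival
events seen in practice — and is exposed as a parameter, since real designs
should supply their own expected D-event schedule.

## Known limitations

* Logrank statistics are treated as exactly normal with independent
  increments; small-sample and heavy-censoring deviations are out of scope.
* ρ_ID is an input, not derived from an event-overlap model of composite
  outcomes.
* Only the final-stage level is searched when controlling the FWER; the
  whole boundary sequence is never re-optimised.
* Pocock-type efficacy boundaries, futility spending functions and
  two-sided testing are not implemented.
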