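# mamsoc

Operating characteristics of multi-arm multi-stage (MAMS) trial designs
with efficacy stopping boundaries.

## The problem

A MAMS trial with time-to-event outcomes randomises patients between one
control arm and K research arms and assesses each pairwise comparison at
J - 1 interim analyses before a final analysis.  Interim looks test for
*lack of benefit* on an intermediate outcome I (for example failure-free
survival) at liberal one-sided levels α₁ > α₂ > … > α_J, dropping arms that
fail to show activity; the final analysis tests the definitive outcome D
(for example overall survival) at α_J.  On top of this, a data monitoring
committee may want a formal rule for stopping an arm early for
*overwhelming efficacy* on D — a Haybittle–Peto threshold (one-sided
p = 0.0005 at every interim), an O'Brien–Fleming-type alpha-spending
boundary, or a custom per-stage p-vector.

Two questions then matter to the trial statistician:

1. **What are the error rates and power of the whole design?**  The
   stagewise test statistics are correlated — across stages through the
   accruing information (corr √(t_i/t_j) at information fractions t_i < t_j)
   and across comparisons through the shared control arm
   (corr ρ = A/(1+A) at allocation ratio A) — so the pairwise error rate
   (PWER), familywise error rate (FWER) and the per-/any-/all-pair powers
   are probabilities of a correlated multivariate-normal vector crossing the
   stagewise boundaries.  With lack-of-benefit bounds l₁…l_J and efficacy
   bounds b₁…b_J (benefit-z scale: large z = benefit), the pairwise error
   rate of a binding design is

   PWER = P(Z₁ ≥ b₁) + P(l₁ < Z₁ < b₁, Z₂ ≥ b₂) + …
        + P(l₁ < Z₁ < b₁, …, l_{J-1} < Z_{J-1} < b_{J-1}, Z_J ≥ z_{1-α_J}),

   and the FWER is the probability that *any* of the K exchangeable
   comparisons makes such an error under the global null.  The package
   evaluates these by deterministic quadrature (dimension ≤ 3) or
   quasi-Monte-Carlo multivariate-normal integration, and cross-checks them
   with a statistic-level Monte-Carlo simulator.

2. **How do you keep strong control of the FWER?**  Non-binding
   lack-of-benefit bounds give the *maximum* FWER (every arm passes every
   interim); `solve_alpha_final()` searches, by linear interpolation, for
   the final-stage significance level α_J whose maximum FWER equals a
   prespecified target, re-deriving the efficacy boundary at each candidate
   level, and reports the control-arm event cost of the adjustment.

## Worked example

A three-stage design with an intermediate outcome, Haybittle–Peto efficacy
looks on the definitive outcome (which, at interim analyses, has accrued
only 15% and 45% of its final information):

```r
library(mamsoc)
d <- mams_design(3, alpha = c(0.25, 0.1, 0.025),
                 intermediate = outcome_spec("FFS", "intermediate", hr_alt = 0.70),
                 d_info_fractions = c(0.15, 0.45, 1))
boundary_set(d, efficacy_rule("haybittle_peto"))
#> Stagewise boundaries (efficacy rule: haybittle_peto)
#>  stage outcome lob_p  lob_z  eff_p  eff_z info_fraction eff_info_fraction
#>      1     FFS 0.250 0.6745 0.0005 3.2905         0.512              0.15
#>      2     FFS 0.100 1.2816 0.0005 3.2905         0.815              0.45
#>      3       D 0.025 1.9600 0.0250 1.9600         1.000              1.00

error_rate_report(d, efficacy_rule("haybittle_peto"))
#> Operating characteristics (integration, non-binding maximum)
#>   PWER:            0.0255
#>   FWER:            0.0640
#>   per-pair power:  0.9003
#>   any-pair power:  0.9845
#>   all-pair power:  0.7822
```

The interim efficacy looks inflate the maximum PWER from α_J = 0.025 to
0.0255; with three comparisons the maximum FWER is 6.4%.  To control it at
2.5% one-sided:

```r
solve_alpha_final(d, efficacy_rule("haybittle_peto"), target_fwer = 0.025)
#> FWER control search
#>   efficacy rule:            haybittle_peto
#>   unadjusted max FWER:      0.0640 (at alpha_J = 0.025)
#>   target FWER:              0.0250
#>   adjusted alpha_J:         0.0087  (3 iterations)
#>   achieved max FWER:        0.02500
#>   control-arm events:       254 -> 324 (+70)
```

The final-stage level must drop to 0.0087, which costs 70 additional
control-arm events to retain the designed 90% power.

Every analytic number can be checked empirically:

```r
simulate_trials(d, boundary_set(d, efficacy_rule("haybittle_peto")),
                n_reps = 1e6, seed = 1)
```

Designs can also be read from JSON configurations (two published examples
ship in `inst/extdata/`) and driven from the shell via
`inst/cli/mams.R` with subcommands `design`, `simulate`, `control-fwer`
and `replicate-study`.

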