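# wishplan

Wish-list driven automated multi-criteria IMRT planning, at desk scale.

Automated treatment planning systems for intensity-modulated radiotherapy
replace the manual trial-and-error tuning of optimization objectives and
beam angles with a fixed, prioritized *wish-list*: hard constraints plus
objectives minimized one at a time in priority order, each stage inserting
a bound so later stages cannot undo earlier gains, with beam-angle
selection integrated into the same optimization. The optimized plan's
dose-volume histograms (DVHs) are then handed to a second, template-driven
optimizer that produces the final deliverable plan. `wishplan` implements
this whole chain for locally advanced non-small cell lung cancer (LA-NSCLC)
geometry on seeded synthetic thorax phantoms, so the method's mechanics —
lexicographic priority protection, Goal/Sufficient semantics, greedy
integrated beam-angle optimization (BAO), DVH-faithful handover, and the
plan-comparison statistics — can be studied, tested and reproduced without
patient data. It is a research laboratory for the *method*, not a clinical
system.

## The method in brief

For fluence `x >= 0` and a dose influence matrix `D` (Gy per unit
fluence), each wish-list stage solves a convex program

    minimize f_k(D x)   subject to hard caps and all inserted bounds,

where `f_k` is a structure mean, a structure maximum, or the logarithmic
tumor control probability of the target,

    LTCP = (1/m) * sum_j exp(-alpha * (d_j - 0.95 * D_p)),

which equals 1 at a uniform 95%-of-prescription dose and punishes cold
spots exponentially (`alpha` = 0.85/Gy at 60 Gy, 0.8/Gy at 66/70 Gy).
Round 1 walks priorities 1..13, inserting the Goal value as a constraint
when achieved, otherwise the achieved value with 3% relaxation; round 2
re-minimizes every objective without a Sufficient value to the fullest
extent. Beam angles are chosen greedily from a laterality-dependent
candidate arc (140–40° right-sided, 320–220° left-sided, 5° spacing, 53
candidates), each candidate scored by running the full two-round
optimization. The handover stage converts OAR DVHs into line objectives
sampled every 0.7 Gy, adds fixed target/maximum points and a normal-tissue
objective, and re-optimizes a plan from the template alone.

Stage problems are solved by the package's own log-barrier interior-point
method (C++/Armadillo); no external optimization library is used in the
planning path. See the methods vignette
(`vignettes/methods.Rmd`) for every model, parameter and numerical choice.

## Worked example

```r
library(wishplan)

ph  <- generate_phantom(phantom_config(grid = c(48, 48), spacing_mm = 5), seed = 17)
wl  <- build_wishlist(ph$prescription_Gy)
inf <- compute_influence(ph, template_angles(ph$laterality))
plan <- lexicographic_solve(inf, wl, ph)
plan$stage_log[1:4, c("round", "priority", "structure", "type",
                      "achieved", "bound_inserted", "bound_type")]
#>   round priority structure type    achieved bound_inserted bound_type
#> 1     1        1       PTV LTCP  0.08368665         0.1200       goal
#> 2     1        2     lungs Mean 13.37336519        19.0000       goal
#> 3     1        4 shell_1cm  Max 64.87854837        66.8249    relaxed
#> 4     1        5 shell_7cm  Max 13.86055564        42.9000       goal

check_clinical_constraints(normalize_plan(plan, ph), ph)
#>     structure metric direction limit achieved pass
#>           PTV  V_95%         > 98.00   100.00 TRUE
#>         lungs  V_5Gy         < 65.00    40.64 TRUE
#>         lungs V_20Gy         < 35.00    21.91 TRUE
#>         lungs D_mean         < 20.00    13.67 TRUE
#>         heart V_30Gy         < 40.00     6.02 TRUE
#>     esophagus D_mean         < 34.00     2.74 TRUE
#>  spinal_canal  D_max         < 50.00    10.23 TRUE
#>          body  D_max         < 70.62    67.44 TRUE
#> overall: PASS
```

Reading this: priority 1 drove the target LTCP down to 0.084 — better
than the 0.12 goal, so the *goal* (not the tighter achieved value) is
inserted as the bound, deliberately leaving headroom for the
lung/heart/esophagus stages below it; the priority-4 conformity shell
missed its 59.4 Gy goal (64.9 Gy achieved), so its achieved value with 3%
relaxation became the bound instead. After normalization to a 66 Gy PTV
median, the plan passes the full clinical constraint audit.

The whole pipeline (phantom → BAO → FMO → audits → template handover →
surrogate final plan, all artifacts on disk) is one call:

```r
res <- run_pipeline(run_config(seed = 4))
list.files(res$output_dir)
```

A thin command-line driver is installed at `inst/scripts/wishplan`
(`wishplan plan --seed 4 --beams 4,6,8 --out run/`).

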