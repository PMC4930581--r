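# mamsio

Operating characteristics of multi-arm multi-stage (MAMS) clinical trial
designs in which interim analyses use an **intermediate** time-to-event
outcome *I* (e.g. failure-free survival) and the final analysis uses the
**definitive** outcome *D* (e.g. overall survival).

The package is for trial statisticians designing or auditing such trials.
It answers three questions:

1. **What are the design's error rates?** Under the joint null the pairwise
   type I error rate (PWER) of one arm is the lower-orthant probability
   `α = Φ_J(z_{α_1}, …, z_{α_J}; R)`, where `α_j` are the one-sided
   stagewise levels and `R` is the between-stage correlation of the
   treatment-effect estimates, `R[j,j'] = sqrt(e_j/e_j')` for nested
   control-arm event counts `e_j`. Overall pairwise power substitutes the
   stagewise powers `ω_j`.
2. **How bad can they get?** An arm effective on *I* but null on *D* passes
   interims too easily; in the limit the PWER plateaus at the final-stage
   level `α_J`, and the familywise error rate (FWER) across `K` arms peaks
   at the single-stage Dunnett probability
   `FWER_max = 1 − Φ_K(z_{1−α_J}, …, z_{1−α_J}; C)`, with between-arm
   correlation `C[k,k'] = A/(A+1)` induced by the shared control under
   allocation ratio `A`.
3. **How do you control them?** Strong control at level `α*` needs only the
   final-stage level: set `α_J = α*` for the PWER, or search `α_J` (grid of
   step 1e-4, or equicoordinate-quantile root finding) so that the Dunnett
   maximum meets an FWER target, then re-size the final stage.

Both analytic computation (deterministic multivariate-normal quadrature)
and Monte-Carlo simulation of the correlated stagewise z-statistics are
provided and agree by construction; the simulator additionally evaluates
arbitrary per-arm effect scenarios and effect sweeps.

## Worked example

The six-arm four-stage prostate-cancer design shipped as
`inst/extdata/stampede.yaml` (failure-free survival at three interims,
overall survival at the final stage, A = 0.5, target hazard ratio 0.75):

```r
library(mamsio)
d <- read_mams_config(system.file("extdata", "stampede.yaml", package = "mamsio"))
summary(d)
#> MAMS design: 5 experimental arms, 4 stages, allocation ratio A = 0.5
#>
#>  stage outcome target_hr  alpha  omega control_events
#>      1       I     0.750 0.5000 0.9500            113
#>      2       I     0.750 0.2500 0.9500            216
#>      3       I     0.750 0.1000 0.9500            334
#>      4       D     0.750 0.0250 0.9000            403
#>
#> Overall pairwise type I error rate (joint null): 0.0213
#> Overall pairwise power:                          0.8552
#> Maximum pairwise error rate (strong sense):      0.0250
#> Maximum familywise error rate (strong sense):    0.1031
```

The joint-null PWER (0.0213) is what a naive calculation would report; the
strong-control maxima are the numbers that matter: any single arm's error
rate can reach the final-stage level 0.025, and with five arms the
familywise rate can reach 0.103. Controlling the FWER at one-sided 2.5 %
requires tightening the final stage:

```r
find_alpha_J_for_fwer(d, target_fwer = 0.025)
#> [1] 0.0054
#> attr(,"achieved_fwer")
#> [1] 0.02476568
redesign_final_stage(d, 0.0054)$control_events
#> [1] 113 216 334 563
```

i.e. final-stage level 0.0054 and roughly 40 % more definitive-outcome
control-arm events. Simulation confirms the plateau — with every arm
certain to pass the interims but null on *D*, each arm rejects at ~0.025
and at least one of the five rejects at ~0.103:

```r
sim <- estimate_error_rates(d, effect_scenario(d, theta_I = -Inf, theta_D = 0),
                            n_reps = 1e5, seed = 1)
sim
#> MAMS simulation (100000 replicates, seed 1)
#>  arm  reject    pwer power
#>    1 0.02523 0.02523    NA
#>    2 0.02483 0.02483    NA
#>    3 0.02568 0.02568    NA
#>    4 0.02590 0.02590    NA
#>    5 0.02458 0.02458    NA
#> FWER (null-true arms): 0.1040 (MC se 9.65e-04)
```

See the vignette (`vignettes/mams-error-rates.Rmd`) for the model, the
correlation conventions and their limitations.

## Command line

A thin CLI over the same functions is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "mams.R", package = "mamsio"))')
Rscript "$CLI" report   --config design.yaml --out reports/
Rscript "$CLI" control  --config design.yaml --target-fwer 0.025
Rscript "$CLI" sweep    --config design.yaml --grid "0,-0.105,-0.223,-Inf" --seed 7
Rscript "$CLI" simulate --config design.yaml --theta-i "-Inf" --theta-d 0 --seed 7
```

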