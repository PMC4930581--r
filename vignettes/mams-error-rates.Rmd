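---
title: "Type I error rates of multi-arm multi-stage designs with intermediate outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Type I error rates of multi-arm multi-stage designs with intermediate outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mamsio)
```

## The design

A multi-arm multi-stage (MAMS) trial compares $K$ experimental arms against
a shared control over at most $J$ stages. The first $J-1$ analyses are
interim looks on an *intermediate* outcome $I$ (for example failure-free
survival) that is observed earlier than the *definitive* outcome $D$ of the
final analysis (for example overall survival). At the end of stage $j$ —
triggered when the control arm has accumulated $e_j$ events — recruitment
stops to every experimental arm whose observed effect on $I$ is not
significant at the one-sided stagewise level $\alpha_j$; surviving arms are
compared to control on $D$ at the final level $\alpha_J$. Effects are log
hazard ratios $\theta$, with negative values denoting benefit, so an arm
passes stage $j$ when its z-statistic falls below
$z_{\alpha_j} = \Phi^{-1}(\alpha_j)$.

A false-positive conclusion can only be drawn at the final stage (the
interim outcome is never the basis of an efficacy claim), which is what
makes the error-rate structure of these designs distinctive.

`mams_design()` holds the static design; all evaluation functions take it
as their first argument:

```{r design}
stampede <- mams_design(
  n_stages = 4, n_arms = 5, allocation_ratio = 0.5,
  alpha = c(0.500, 0.250, 0.100, 0.025),
  omega = c(0.95, 0.95, 0.95, 0.90),
  control_events = c(113, 216, 334, 403),
  target_effect_I = log(0.75), target_effect_D = log(0.75)
)
stampede
```

This is the original design of a six-arm four-stage prostate-cancer trial
that used failure-free survival at three interim looks and overall survival
at the final analysis, with one patient allocated to each experimental arm
for every two control patients ($A = 0.5$).

## Correlation of the stagewise statistics

Two sources of correlation drive every calculation in the package.

**Between stages.** Analyses at stages $j \le j'$ use nested event sets, so
the treatment-effect estimates correlate as
$R_{jj'} = \sqrt{e_j / e_{j'}}$. The package applies this convention across
the $I \to D$ transition as well, treating the definitive-outcome events of
the final stage as the continuation of the same accumulating-information
process. This is a modelling choice, discussed under *Limitations* below.

**Between arms.** All comparisons share one control group. Under allocation
ratio $A$ the induced correlation between any two arms' estimates at the
same stage is $A/(A+1)$.

The joint correlation of all $JK$ stagewise statistics factorises over the
two: the entry for (arm $k$, stage $j$) against (arm $k'$, stage $j'$) is
$C_{kk'} R_{jj'}$. This product rule follows from the shared-control
accumulating-information normal model, and the test suite verifies it
against a brute-force simulation of control and experimental score
increments at the event level.

```{r corr}
round(between_stage_corr(stampede), 3)
between_arm_corr(5, 0.5)[1, 2]
```

## Pairwise error rate and power

Under the joint null on both outcomes, the probability that one arm passes
every interim and is significant at the final stage is the lower-orthant
probability

$$\alpha = \Phi_J(z_{\alpha_1}, \dots, z_{\alpha_J};\, R),$$

and the overall pairwise power replaces the $z_{\alpha_j}$ with
$z_{\omega_j}$. Both are computed by deterministic quadrature
(`mvtnorm`'s Miwa algorithm, absolute tolerance $10^{-6}$; coordinates tied
by perfect correlation are collapsed first, so equal event counts are
handled exactly).

```{r eq1}
pairwise_error(stampede)
pairwise_power(stampede)
```

The power formula presumes the design's event counts were calibrated so
that stage $j$ has power $\omega_j$ at the target effect; the same
(null-design) event counts, and hence the same $R$, are used for error and
power. When the event counts are exactly Schoenfeld-calibrated the formula
is exact, which is how the test suite cross-validates it against
simulation.

## Why the nominal PWER is not the maximum

The orthant probability above assumes the arm is null on *both* outcomes.
An arm can be genuinely effective on the intermediate outcome yet null on
the definitive one — rejecting it at the final stage is still a type I
error, but its chance of surviving to that point is higher. In the limit
$\theta_I \to -\infty$ every interim is passed with certainty, the interim
stages are redundant, and the pairwise error rate reaches its maximum: the
final-stage level $\alpha_J$.

```{r pwer-scenario}
pwer_under_scenario(stampede, theta_I = 0)       # joint null
pwer_under_scenario(stampede, theta_I = log(0.8))
pwer_under_scenario(stampede, theta_I = -Inf)    # the plateau
```

The approach to the plateau is fast: even modest intermediate-outcome
effects push the PWER most of the way to $\alpha_J$. Strong control of the
pairwise rate therefore amounts to choosing $\alpha_J$ equal to the desired
maximum (`find_alpha_J_for_pwer()`), and with the maximum controlled this
way the interim boundaries can be treated as non-binding: letting an arm
continue past a failed interim cannot push the error rate above $\alpha_J$.

## Familywise error rate

With several arms, the probability of at least one false rejection — the
familywise error rate — exceeds the pairwise rate. It is maximised when
*all* arms are certain to pass the interims but null on $D$; the design
then collapses to a single-stage many-to-one comparison and the maximum is
the Dunnett probability

$$\mathrm{FWER}_{\max} = 1 - \Phi_K(z_{1-\alpha_J}, \dots, z_{1-\alpha_J};\, C),$$

with $C$ the equicorrelated between-arm matrix.

```{r fwer}
max_fwer(stampede)
```

To control it in the strong sense, `find_alpha_J_for_fwer()` searches the
final-stage level. The default grid method scans candidate levels from the
Bonferroni bound $\mathrm{target}/K$ to the target in steps of $10^{-4}$
and returns the largest level whose maximum FWER does not exceed the
target; a level whose achieved FWER ties with the target at the grid's own
precision (within $5 \times 10^{-5}$, half a unit in the fourth decimal
place) counts as meeting it, since finer distinctions are below the
resolution at which such searches are reported. The quantile method solves
the equicoordinate equation by root finding and rounds down to four
decimals; the two agree to within one grid step.

```{r search}
find_alpha_J_for_fwer(stampede, target_fwer = 0.025)
find_alpha_J_for_fwer(stampede, target_fwer = 0.05)
```

Tightening $\alpha_4$ from 0.025 to these levels enlarges the final stage;
`redesign_final_stage()` rescales the final-stage event requirement by the
squared ratio of normal-quantile sums:

```{r redesign}
redesign_final_stage(stampede, 0.0054)$control_events
redesign_final_stage(stampede, 0.0113)$control_events
```

## Simulation

`estimate_error_rates()` implements statistic-level simulation: replicates
of all $JK$ z-statistics are drawn from the joint normal with the
correlation above and mean shifts $\mu_{jk} = (\theta_{jk} -
\theta_j^0)/SE_j$, where $SE_j = \sqrt{(1+A)/(A e_j)}$ is the asymptotic
standard error of a log-HR estimate with $e_j$ control-arm events. The
stopping rule is then applied replicate by replicate. No patient-level
event times are generated; the multivariate-normal working model for the
stagewise estimates *is* the model under which the analytic results hold,
so simulation and quadrature must agree, and the test suite requires
agreement within three Monte-Carlo standard errors throughout.

Infinite intermediate effects are sentinels, not numbers fed to
arithmetic: $\theta_{Ik} = -\infty$ fixes the arm's interim statistics at
certain passage, the limiting configuration that maximises the error
rates.

```{r sim}
sim <- estimate_error_rates(stampede,
                            effect_scenario(stampede, theta_I = -Inf, theta_D = 0),
                            n_reps = 1e5, seed = 1)
sim
```

`scenario_sweep()` traces the inflation of the error rates as the
underlying intermediate-outcome effect strengthens, reusing one seed across
grid points so that comparisons along the grid are coupled rather than
masked by independent Monte-Carlo noise:

```{r sweep}
two_stage <- mams_design(2, 2, 1, alpha = c(0.5, 0.025),
                         omega = c(0.95, 0.90), control_events = c(72, 200),
                         target_effect_I = log(0.75), target_effect_D = log(0.75))
scenario_sweep(two_stage, c(0, log(0.9), log(0.8), -Inf),
               n_reps = 1e5, seed = 1)
```

## Parameters and defaults

* `alpha`, `omega` — one-sided stagewise levels and powers; the published
  guideline pattern (lenient early levels, 0.025 at the final stage) is
  typical.
* `control_events` — cumulative control-arm events at each analysis. These
  are *inputs*: the package's own `control_events_for_stage()` is a
  Schoenfeld-type approximation,
  $e_C = \lceil (z_{1-\alpha_j}+z_{\omega_j})^2 (1+A)/(A\theta^2) \rceil$,
  which runs a few percent below the counts produced by the dedicated
  design software used for the published examples (381 vs 403 for the
  final-stage parameters above). Because every error-rate computation takes
  event counts as given, this approximation never propagates into them.
* `n_reps` — default 250{,}000, giving a Monte-Carlo standard error of
  about $5 \times 10^{-4}$ on probabilities near 0.025; worked examples and
  tests in this package use $10^5$–$10^6$ depending on the precision the
  comparison needs.
* `seed` — required for every stochastic routine; identical inputs and seed
  give bit-identical results.
* Degenerate inputs: tied event counts (perfect correlation) are collapsed
  before quadrature; a non-positive-semi-definite joint matrix is an error
  naming the offending eigenvalue rather than a silent repair; `-Inf`/
  `+Inf` effects on $I$ are handled as certain pass/fail.

## What the simulation model does and does not capture

The generator draws the stagewise *statistics*, not patients. It therefore
embodies exactly the asymptotic normal working model — nested-information
between-stage correlation, shared-control between-arm correlation, mean
shifts $\theta/SE_j$ — and none of the finite-sample features of a real
trial: censoring patterns, staggered accrual, non-proportional hazards,
event-rate misspecification, or analyses triggered at event counts other
than those planned. Agreement between the analytic and simulated rates
validates the implementation of the model, not the model's fit to any
particular trial.

## Limitations

* **The cross-outcome correlation is a convention.** Correlating the
  interim ($I$-based) and final ($D$-based) statistics as
  $\sqrt{e_j/e_J}$ treats the two outcomes as one accumulating information
  stream. A full treatment would use the definitive-outcome information
  accrued at each interim and the within-patient association between the
  two outcomes — quantities that are design-specific and not part of this
  package's inputs. For the six-arm worked example the published
  design-level error rate (0.013) and power (0.83) were produced with such
  information; under the nested-events convention on the published event
  counts this package computes 0.0213 and 0.8552. The two bracket the
  convention choice: with the cross-outcome correlation set to zero the
  same inputs give 0.0020 and 0.809. Quantities that do not depend on the
  convention — the maximum PWER ($\alpha_J$), the maximum FWER and the
  final-stage levels that control it — are unaffected, and those are the
  quantities the strong-control methodology turns on.
* **Identical outcomes with binding boundaries.** When $I = D$ and the
  interim rules are strictly enforced, every stagewise level contributes to
  the maximum error rates and control requires a joint search over
  $(\alpha_1, \dots, \alpha_J)$; the relevant functions refuse rather than
  return something misleading. With non-binding boundaries the $I \ne D$
  machinery applies unchanged.
* **Event counts are approximate.** The sample-size module is a
  closed-form companion, not a replacement for dedicated design software;
  its outputs are documented as approximations wherever they appear.
* **Problem sizes.** The deterministic quadrature is exercised up to the
  dimensions that arise in practice (stages and arms in the single
  digits); the simulator's memory use grows with `n_reps` times $JK$.
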