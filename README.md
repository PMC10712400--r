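# bmimarkov

Markov-chain modelling of long-term adult weight-status change.

## The problem

Cross-sectional health surveys such as NHANES ask adults for their current
weight and their recalled weight ten years earlier. Each respondent thus
contributes one observed decade-scale transition between CDC BMI categories
(underweight < 18.5, normal 18.5–<25, overweight 25–<30, obese ≥ 30 kg/m²;
with underweight usually merged into a "normal/underweight" state because it
is so thin). `bmimarkov` turns a cohort of such paired records into a
discrete-time Markov model of population weight status:

1. **Estimation.** The survey-weighted transition matrix
   `P̂[i,j] = Σ w·1{past=i, now=j} / Σ w·1{past=i}`, with the survey
   sampling weights `w` adjusting for selection probability and
   nonresponse, and the survey-weighted category prevalences `π̂`.
2. **Projection.** Decade-by-decade forecasts `π(t+1) = π(t) P̂` under
   time-homogeneity (default horizon: 10 decades), and the stationary
   distribution `π* = π*P̂` — the chain's long-run category mix — computed by
   power iteration and cross-checked against the direct linear-system
   solution.
3. **Uncertainty.** Percentile confidence bands from bootstrap resampling
   of individuals: each replicate re-estimates the matrix and the initial
   prevalences and re-projects the whole trajectory, so the compounding of
   estimation error across repeated projections (a 5% per-step error
   compounds to `1.05¹⁰ − 1 ≈ 62.9%` after ten steps) is captured by
   construction. Sex- and race-stratified runs are built in.
4. **Descriptives.** A characteristics table stratified by weight
   loss vs gain/maintenance (Welch t-tests, chi-square tests), the paired
   t-test for decade weight change, and weight-change histogram data.

Because the underlying survey microdata must be downloaded separately, the
package ships a seeded synthetic-cohort generator that emulates the cohort's
published structure — demographic strata, a configurable true transition
matrix (`state_mode`), or a Normal(3.27, 14.97²) kg decade weight-change
distribution (`weight_mode`), with positive lognormal survey weights — so
the entire pipeline is testable and demonstrable offline. It is intended for
epidemiologists and biostatisticians studying obesity dynamics, and as a
reference implementation of the bootstrap-banded Markov projection method.

## Worked example

```r
library(bmimarkov)

cfg     <- cohort_config(n = 6146, seed = 42)   # state_mode defaults
cohort  <- generate_cohort(cfg)
derived <- derive_cohort(cohort)                # BMI, categories, change

tm <- estimate_transition_matrix(derived)
tm
#> <transition_matrix> scheme3 (rows = origin, cols = destination)
#>                 normal_or_under overweight  obese
#> normal_or_under          0.5710     0.3277 0.1013
#> overweight               0.1583     0.5087 0.3330
#> obese                    0.0308     0.1892 0.7800
```

The generator's true matrix has rows (0.58, 0.32, 0.10), (0.16, 0.49,
0.35), (0.03, 0.19, 0.78); the weighted estimate recovers every cell to
about one percentage point at n = 6146. Projecting the survey-time
prevalences forward and asking for the long-run mix:

```r
traj <- project(tm, initial_distribution(derived), horizon = 10)
dplyr::filter(traj, decade == 10)
#>   decade state            prob
#> 1     10 normal_or_under 0.153
#> 2     10 overweight      0.309
#> 3     10 obese           0.537

stationary_distribution(tm)
#>   state            prob
#> 1 normal_or_under 0.153
#> 2 overweight      0.309
#> 3 obese           0.538
```

After ten decades the trajectory has essentially reached the stationary
distribution: with this transition structure, about 54% of the population
ends up obese regardless of today's mix. Bootstrap bands quantify how sure
the data allow us to be about that figure:

```r
bands <- bootstrap_projection(derived, B = 1000, seed = 7, horizon = 10)
dplyr::filter(bands, decade == 10)
#>   state           decade point lower upper
#> 1 normal_or_under     10 0.153 0.135 0.173
#> 2 overweight          10 0.309 0.290 0.330
#> 3 obese               10 0.537 0.509 0.567

autoplot(bands)   # ggplot of the banded trajectories
```

`run_report()` executes every stage and writes CSV/JSON tables, the exact
configuration, and a log to one directory; `inst/cli/bmimarkov.R` exposes
the same stages as shell subcommands (`generate`, `derive`, `estimate`,
`project`, `stationary`, `bootstrap`, `report`).

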