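---
title: "Modelling decade-scale weight-status change with survey-weighted Markov chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling decade-scale weight-status change with survey-weighted Markov chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmimarkov)
```

## The model

Each survey respondent reports a current weight and a recalled weight ten
years earlier; with a (constant) height these become two BMI values and two
CDC weight categories, i.e. one observed decade-scale transition per person.
`bmimarkov` treats the population's category mix as a discrete-time Markov
chain with a one-decade time step:

* **States.** Either the four CDC categories (`scheme4`) or, by default,
  three states with underweight merged into normal (`scheme3`). The merge
  exists because underweight adults are rare (on the order of 1% of a
  typical adult cohort), which makes a dedicated underweight transition row
  extremely data-sparse. Category intervals are half-open:
  `[0, 18.5)`, `[18.5, 25)`, `[25, 30)`, `[30, ∞)`. Prose definitions of
  the cutoffs are ambiguous exactly at the boundaries; the half-open
  convention matches CDC usage, and for continuous BMI the boundary set has
  measure zero, so the choice cannot matter for real data.
* **Transition matrix.** Rows are origin states, columns destinations, and
  prevalence vectors are row vectors multiplied on the left
  (`pi_next <- pi %*% P`). This convention is stated everywhere it is used
  because transposition is the classic Markov-implementation bug.
  Estimation is a survey-weighted tally:
  \[
  \hat P_{ij} = \frac{\sum_r w_r\,\mathbf 1\{\text{past}_r = i,\ \text{now}_r = j\}}
                     {\sum_r w_r\,\mathbf 1\{\text{past}_r = i\}},
  \]
  where \(w_r\) is the record's survey sampling weight (adjusting for
  selection probability and nonresponse). Both \(\hat P\) and the
  prevalence estimates are invariant to rescaling all weights by a positive
  constant, which the tests check to machine precision.
* **Time-homogeneity.** One matrix is applied at every decade step. This
  ignores age- and period-structure in weight change — a 30-year-old's
  decade is not an 80-year-old's — and is the model's strongest assumption.
  Mortality is not modelled; no state is absorbing.

## Projection anchor

Projections start from the *current* (survey-time) category prevalences by
default — the question being "where does the population go from here" — and
`anchor = "past"` is available for anchoring at the recalled decade-ago
states instead. The choice is a flag rather than a hard-coded decision
because the recalled-state prevalences a decade ago are genuinely a second
defensible anchor, and reproducibility demands that either be expressible.

## Stationary distribution

`stationary_distribution()` runs power iteration from the uniform vector to
an L1 tolerance of 1e-12 (cap 10,000 iterations) and then cross-checks the
result against the direct solution of the linear system \(\pi P = \pi,\
\sum_i \pi_i = 1\); disagreement beyond 1e-8 is an error, never a silent
answer. Power iteration alone is not enough: a period-2 chain started at
its (uniform) stationary vector "converges" instantly while having no
limiting distribution at all, and a reducible chain has many fixed points.
A second power iteration from a deliberately asymmetric start therefore
backs up the first — oscillation there exposes periodicity, and convergence
to a different fixed point exposes reducibility; both abort with a message
naming the issue.

## Bootstrap bands

Attaching a confidence interval to each matrix cell separately understates
the uncertainty of a projection, because per-step error compounds
multiplicatively: a relative error of \(e\) per step grows to
\((1+e)^{t}-1\) after \(t\) steps (5% per decade is already 62.9% after
ten; see `compounding_error()`). The bands here instead resample whole
chains:

* **Resampling unit** is the individual record, drawn uniformly with
  replacement, carrying its survey weight into re-estimation ("bootstrap
  the rows, keep the weights"). The survey's complex design (strata, PSUs)
  is *not* honoured by the resampling — a Rao–Wu style survey bootstrap is
  an explicit non-goal — so the bands reflect sampling-of-individuals
  uncertainty only.
* Each replicate re-estimates the matrix *and* the initial distribution and
  re-projects the full trajectory; bands are the empirical
  \(\alpha/2\) and \(1-\alpha/2\) percentiles per (state, decade). Plain
  percentile intervals are used, not BCa: they are simple, seed-stable, and
  make no bias-correction claim. A consequence worth knowing: the
  percentile method does not guarantee `lower ≤ point ≤ upper`, and the
  package deliberately does not assert it.
* A replicate in which an origin state that the full cohort does occupy
  receives no resampled records is redrawn (count recorded; a warning names
  the sparsest state when more than 10% of replicates needed redrawing).
  Redrawing, rather than patching the row, keeps every replicate a valid
  chain. Origin states empty in the *full* cohort get an identity
  (self-loop) row once, with a warning, so degenerate cohorts still yield
  well-defined zero-width bands.
* The default is B = 10,000 replicates. The test suite uses B = 500 (and
  B = 200 for the band-width-shrinkage property) purely as a problem-size
  choice; percentile endpoints at those sizes are accurate to well under a
  percentage point for these smooth functionals.
* Stratified runs derive per-stratum seeds deterministically from the
  shared seed (stratum *i* in sorted label order uses
  `seed + (i − 1)·100003`), so a single-stratum run reproduces the
  unstratified run exactly.
* Point estimates and band *distributions* are invariant to record order;
  the specific replicate draws are not, since resampling consumes indices
  from the seeded stream. The tests pin down the invariance of the point
  trajectory under row permutation.

## The synthetic-cohort generator

The generator exists so that every downstream stage has a ground truth. It
emulates a cohort of 6,146 US adults: sex mix 49/51, race mix
White/Hispanic/Black/Asian/Other = 2252/1257/1636/739/262 out of 6,146
(exact count proportions), ages truncated-normal 58.4 (12.9) on [18, 100],
heights truncated-normal by sex (1.75 m / 1.62 m, SD 0.07), and lognormal
survey weights (sdlog 0.5) normalized to mean 1 — positive and right-skewed
like real design weights, without claiming the real weight construction.

Two modes are deliberately separate, because no single mechanism can match
both of the published calibration targets at once:

* **`state_mode`** draws each record's past category from configurable
  marginals (default: the merged current-state prevalences 34/22/43,
  renormalized — the survey never prints the decade-ago marginals, so this
  is a documented default, not a claim) and the current category from the
  matching row of a configurable true matrix (default rows
  0.58/0.32/0.10, 0.16/0.49/0.35, 0.03/0.19/0.78). A BMI value is then
  drawn from a truncated normal centred in the category's interval
  (underweight over [15, 18.5), merged normal/underweight over [16, 25),
  obese capped at 60 to stay physiologic) and converted to weight through
  the record's height. Derived categories therefore equal the generating
  categories by construction, making parameter recovery exactly testable.
* **`weight_mode`** draws a past weight from a sex-specific truncated
  normal (85/75 kg, SD 20, upper bound 170 kg) and adds a
  Normal(3.27, 14.97²) kg decade change. The past-weight floor rises with
  height (`max(55, 10·h² + 42)` kg) so that even far-left-tail change
  draws almost never push current BMI below 10; the rare draw that still
  does (≈1 in 10⁴) is redrawn. The realized change distribution is thus the
  configured normal conditioned on a physiologic current BMI — within about
  1e-4 total variation of the unconditional normal, a truncation small
  enough that the empirical mean and SD recover the configured values
  within 3 standard errors at n = 10⁵.

Height is constant within an individual across the decade: BMI change is
weight-driven, matching a design in which only the two weights are
recorded. What the generator does **not** emulate: recall bias in
self-reported past weight, the survey's stratified multistage design (so
design-effect-correct variance estimation cannot be tested against it),
laboratory variables, within-person correlation of weight with height
beyond the floor above, and any age- or race-dependence of weight change.
Passing recovery tests on this generator therefore demonstrates correctness
of the estimators under the stated sampling model — not robustness to the
messiness of real recalled weights.

## Numerical and policy choices

* BMI exactly 25 is overweight; exactly 30 is obese (half-open intervals).
* A weight change of exactly 0 kg is classed `GAINED_OR_MAINTAINED`.
* Adults-only inclusion (age ≥ 18) is an ingestion filter with per-reason
  exclusion tallies; no upper age cut, no outlier rule for implausible
  recalled weights (deliberately: no such rule is published, so none is
  invented).
* Empty transition rows: error by default, naming the state; an explicit
  `self_loop` policy substitutes an identity row with a warning and
  `row_mass = 0` as the flag. The 4-state scheme is supported but its
  underweight row is expected to be data-sparse; the 3-state merge is the
  default for exactly that reason.
* Descriptive tests are unweighted (they describe the raw cohort); Welch's
  unequal-variance t-test is the default with the pooled test behind a
  flag; chi-square tests drop the continuity correction. p-values print to
  3 significant figures, `"<0.001"` below.
* Cohort CSVs round-trip doubles exactly: written at 17 significant digits
  and parsed through base R's correctly rounded `strtod`.
* One published inconsistency is resolved in favour of arithmetic: the
  overweight row's first entry (0.16) is read as the transition into the
  *merged* normal/underweight state, since the three-state chain has no
  separate underweight destination.

## Problem sizes in the test suite

Recovery checks run at n = 6,146 (the cohort's size) and n = 10⁵
(consistency); the coverage experiment uses 200 outer replications of
n = 6,146 cohorts with B = 500 bootstrap replicates over decades 0–3 and
expects 90–99% empirical coverage of the 95% bands; the stationary-solver
equivalence check runs 1,000 random 3×3 and 4×4 chains. These sizes are the
package's chosen demonstration scale; all are configurable at the function
level.

## Limitations

Time-homogeneity and the two-time-point design are the dominant caveats:
the model extrapolates one observed decade transition structure a century
forward, with no age structure, no cohort effects, no mortality, and recall
error folded silently into the "past" state. The bands quantify sampling
uncertainty under that model — not structural uncertainty about the model
itself.
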