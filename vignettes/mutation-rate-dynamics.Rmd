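---
title: "Models and methods behind mutevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mutevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutevol)
```

`mutevol` implements the estimator chain used to study how mutation rates
themselves evolve while a microbial population adapts to severe stress:
fluctuation-assay mutation-rate estimation, Gompertz growth kinetics,
competition fitness, death-rate estimation, and the lineage/trajectory
accounting that ties them together. This vignette explains each model, its
assumptions, the tunable parameters, and the numerical and design choices
made where more than one defensible option existed. It states no empirical
claims beyond what the package's own test suite and `scripts/acceptance.R`
compute.

## Fluctuation assays and the Lea–Coulson model

A fluctuation assay grows many small parallel cultures from mutant-free
inocula and scores, in each, the number of mutants resistant to a selective
agent. Because a mutation arising early founds a large resistant clone, the
mutant count is heavy-tailed ("jackpots"). Under the Lea–Coulson model —
deterministic exponential growth of the population, Poisson-distributed
mutational events with intensity proportional to the number of divisions,
stochastic (Yule) growth of each mutant clone, no mutant fitness cost and
no phenotypic delay — the count distribution for expected events per
culture $m$ has the probability recursion

$$p_0 = e^{-m}, \qquad
  p_n = \frac{m}{n}\sum_{i=0}^{n-1}\frac{p_i}{n-i+1}.$$

`ld_pmf()` implements this recursion (in C++; the likelihood is evaluated
repeatedly with the distribution truncated at the largest observed count,
often in the thousands). Equivalently the distribution is compound Poisson
with clone-size law $P(k) = 1/(k(k+1))$; the test suite uses that second
construction as an independent oracle.

`mss_mle()` maximizes the resulting likelihood over $\log m$ with a
derivative-free 1-D search on the bracket $[10^{-6}, \max(\text{count})]$,
tolerance $10^{-6}$ on $\log m$. The likelihood is unimodal in $m$, so a
bracketed scalar search is robust without derivatives; the estimate is 0
exactly when no culture contains a mutant, and an estimate pinned at the
upper bracket raises a warning carrying the bracket. Counts above a
ceiling (default $10^4$) are capped with a warning: jackpot plates are
effectively uncountable and the truncated likelihood would otherwise cost
quadratic time in the largest count.

The mutation rate is $\hat m / \bar N_t$ with $\bar N_t$ the mean of the
plated calibration counts; no per-culture $N_t$ correction is applied,
mirroring the protocol in which a handful of calibration cultures
represent all parallel cultures. Rescaling to other units (per bp, per
$10^7$ generations) is deliberately a user-supplied factor, because the
extrapolation from a reporter locus to the genome depends on the assay's
target size.

**Confidence intervals.** The default is Stewart's log-normal
approximation, $\sigma_{\ln m} = 1.225\, m^{-0.315}/\sqrt{C}$ for $C$
cultures — the behaviour of the widely used fluctuation-analysis
calculators, and accurate enough here that simulated 95% intervals at
$C = 1000$ cover the truth in at least 90% of seeded replicates across
$m \in \{0.1, 1, 5\}$ (checked in the acceptance suite). A
profile-likelihood interval (chi-square cutoff) is available via
`ci_95(method = "profile")` for small or irregular experiments.

**Comparing rates.** Two estimates are compared with a two-sided Student's
t-test on per-biological-replicate $\hat m$ values — the replicate-level
"number of mutational events" — plus the fold change of rates. This
presumes the strains were assayed at equal cell density;
`density_equality()` checks that precondition with a one-way ANOVA and
Tukey post-hoc on the calibration counts, and `compare_rates()` flags a
failure. The t-test-on-$\hat m$ convention is an interpretation of common
calculator practice, not a uniquely defined statistic; it is the only
replicate-level quantity comparable across strains at equal density.

## Gompertz growth kinetics

Growth curves are fitted on $\log_{10}$ optical density with the modified
Gompertz form

$$y(x) = y_0 + y_M\exp\!\left[-\exp\!\left(\frac{e\,\mathrm{SGR}}{y_M}
  (LT - x) + 1\right)\right],$$

whose parameters are directly interpretable: $y_0$ baseline, $y_M$ total
rise, SGR the maximum slope (h⁻¹ in log10 units), and $LT$ the time where
the inflection tangent meets the baseline. Two exact identities follow —
the maximum of $dy/dx$ equals SGR, and that tangent hits $y = y_0$ at
$x = LT$ — and both are enforced as property tests on random parameter
draws. The constant is $e = \exp(1)$; quoting it rounded to 2.718, as
protocol write-ups usually do, shifts the identities at the $10^{-4}$
level. Doubling time is $\log_{10}(2)/\mathrm{SGR}$.

Fitting is Levenberg–Marquardt with box constraints
($\mathrm{SGR}, y_M \in (0, 10]$, $LT \in [0, t_{\max}]$), via
`minpack.lm`. Start values come from the data (minimum, range, steepest
finite-difference slope, tangent intercept), which makes convergence
robust across the realistic parameter range. OD readings are floored at
$10^{-3}$ before the log so blank wells stay finite; curves whose log10
range is below 0.05, or that only decline, are reported as failed fits
with a reason rather than as errors, so batch tabulation
(`growth_summary()`) degrades gracefully. Parameter intervals come from
the linearized covariance at the optimum — adequate for well-conditioned
plate-reader fits and much cheaper than a bootstrap.

## Competition fitness

With two strains distinguished by a fluorescent marker, the focal
fraction $A$ before and after $n$ rounds of competition gives the
per-round odds-ratio fitness

$$W = \left[\frac{A_{end}(1-A_{start})}{(1-A_{end})A_{start}}\right]^{1/n}.$$

This reading — $W = 1$ at no change, $W > 1$ when the focal strain gains —
composes multiplicatively over rounds and inverts in closed form:
`rounds_to_fixation()` returns
$n = \ln[\mathrm{odds}(A_{target})/\mathrm{odds}(A_{start})]/\ln W$, and
the round trip is exact to machine precision. The reciprocal convention is
exposed as an option. A 48-h competition cycle counts as one selection
round by default; whether "rounds" should be cycles or generations is a
convention, and the choice is configurable.

Marker loss is modelled as
$\text{observed} = \text{true}\times(1-f_{loss})$: a known fraction of
truly marked cells scores negative, so the correction divides by
$1-f_{loss}$ (clipping at 1 with a warning). Boundary fractions from zero
counts are handled with an optional Haldane-style 0.5-event pseudocount;
the odds ratio is undefined at 0 and 1, so the error message points there.

`theoretical_competition()` competes two *fitted growth models* in silico:
each strain multiplies its inoculum by its model's rise above baseline,
$10^{\,y(t)-y_0}$, over one cycle, with no interaction between strains.
The baseline-anchored normalization matters: the Gompertz double
exponential is already 6.6% of its rise at $t = 0$, so normalizing by the
model value *at* zero instead of $y_0$ would penalize a zero-lag strain
and invert the expected lag ordering. Comparing the theoretical number of
rounds to fixation with the observed one (`fixation_consistency()`) flags
ratios well above 1 as consistent with direct effects of mutations
accumulated during the sweep — an annotation, not a test.

## Mortality

Viable counts rise, plateau, and then fall as cells die in stationary
phase. The decline is modelled as one-phase exponential decay
$y = (y_{max}-y_{min})e^{-kx} + y_{min}$ with $k$ the death-rate constant.
The decline segment is chosen by a deterministic, testable rule: the
maximal suffix starting at the global CFU maximum, earliest index on ties;
at least 4 points are required. The fit runs on the linear CFU scale, as
the model is written (log-scale residuals would weight the tail
differently); time is re-origined to the segment start; $y_{min}$ is
fitted freely with a floor at 0 by default, or can be fixed
(`fix_ymin`) when the floor is known. Replicate $k$ values are compared
with pairwise two-tailed t-tests, or one-way ANOVA with Tukey correction
across more than two groups; dead-cell fractions from live-dead staining
are compared with a two-sided t-test.

## Lineage accounting and trajectory analyses

Generations per transfer cycle are $\log_2(\mathrm{CFU}_e/\mathrm{CFU}_i)$
and sum over cycles; the effective size of a serial-transfer population is
$N_e = gN_0$ with $N_0$ the founders per passage. These are exact
arithmetic, kept as functions so the accounting is explicit and testable.

Because stress tolerance moves on a discrete grid (0.5-point steps,
0.25-point at and above 7.5%), the association between consecutive changes
in tolerance and in mutation rate is measured with Spearman rank
correlation: average ranks for ties (implemented explicitly and checked
against `stats::cor`), permutation p-values (default $10^4$ seeded
permutations) below 20 delta pairs, and the t approximation above. Rate
deltas are taken on the rate scale by default with a log-scale option; the
rank correlation is invariant to any strictly monotone transform, so the
choice affects only the delta definition, not the statistic's logic.
`group_association()` dichotomizes lines into above/not-above wild-type
mutation rate and rank-correlates that binary code against endpoint
tolerance. Spectrum tallies classify substitutions as transitions versus
transversions and indels as frameshift or in-frame by length mod 3, with
everything else (multi-base same-length changes, ambiguous bases) counted
as unclassified so totals are conserved; no homopolymer-context
normalization is attempted.

## Synthetic data: what it emulates and what it does not

Each generator reproduces the sampling structure of its assay with known
truth and a mandatory seed (same seed, same bytes):

* `simulate_fluctuation()` draws Lea–Coulson counts either by inverse CDF
  from `ld_pmf()` (tail mass beyond the cap assigned to the cap, flagged)
  or by forward generation-wise simulation: binomial mutations among each
  generation's divisions, mutation times spread within the generation with
  density matching exponential growth, and Yule (geometric) clone
  expansion. The two modes agree in distribution; a forward variant with
  *deterministic* clone doubling was rejected because synchronous doubling
  quantizes clone sizes to powers of two and measurably distorts the pmf.
* `simulate_growth()` evaluates the Gompertz curve on a 15-minute grid and
  applies mean-one lognormal OD noise (default CV 2%).
* `simulate_competition()` propagates the focal fraction by the odds
  update and draws cytometry events binomially (default $10^5$ events), with
  optional fluorescence loss.
* `simulate_decay()` evaluates the decay curve (default 30 points over
  90 h) under lognormal count noise (default CV 10%), optionally with a
  rising phase prepended to exercise segment selection.
* `simulate_trajectory()` couples discrete tolerance steps to
  multiplicative rate jumps (default 4-fold) and lets rates decay
  geometrically (default 0.75 per cycle) on plateaus, with estimation
  noise scaled to the Stewart interval width at 30 cultures.

Defaults mirror the assay regimes the pipeline targets: $\ge 30$ parallel
cultures and final densities near $2\times10^8$ per culture, $m$ of order
0.1–10, $W$ in 1–4, $k$ in 0.01–1 h⁻¹. The generators deliberately omit
several features of real data — plating efficiency below 1, phenotypic
delay, differential mutant fitness, plate-reader drift and evaporation,
cytometry gating artefacts, biphasic death — so passing recovery tests
demonstrates correctness of the estimators under their own model
assumptions, not robustness to every violation a wet-lab dataset may
carry.

## Problem sizes and reproducibility

The recovery statistics computed by the test suite and
`scripts/acceptance.R` use sizes chosen to make sampling error small
relative to the tolerances they check: 200 seeds of 1000-culture
experiments for MLE recovery and interval coverage, 100 seeds for Gompertz
and decay recovery, 25–200 seeded replicates for the competition and
calibration checks, 50–100 seeds for trajectory correlations. Every
stochastic function takes an explicit seed, and `run_pipeline()` writes a
manifest so a whole synthetic study is pinned by one integer.

## Known limitations

Plating-efficiency and partial-plating corrections, phenotypic-delay and
differential-mutant-fitness variants of the fluctuation model, alternative
growth laws (logistic, Baranyi), frequency-dependent selection, and
mechanistic death models are out of scope. The Stewart interval is an
approximation whose constants were calibrated for moderate $m$; for very
small experiments the profile-likelihood option is the safer choice.
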