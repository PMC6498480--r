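---
title: "Measurement variability and the reproducibility of RECIST response rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement variability and the reproducibility of RECIST response rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In solid-tumor oncology trials, treatment response is categorized from the
percent change of the tumor burden — the sum of target-lesion diameters —
between a baseline and a post-treatment CT scan: complete response (CR) at
−100%, partial response (PR) at −30% or less, progression (PD) at +20% or
more, stable disease (SD) in between. The objective response rate (ORR, the
percentage of patients reaching CR or PR) and the progression rate inherit
the measurement variability of the underlying diameter readings: re-imaging
the same burden can change its measured size by several percent, and two
readers can disagree substantially more. A patient whose burden shrank by
31% on the first reading has a real chance of being recorded as SD if the
trial were re-read.

`recistvar` quantifies that vulnerability. Given (i) a repeated-readings
dataset from which the measurement-error distribution can be estimated and
(ii) a trial's lesion table, it produces the distribution of ORRs (and
progression rates) one would expect **if the same trial data were reassessed**
by the same or a different reader, summarized by the median and the 95%
central range (2.5th–97.5th percentiles). This central range measures
reproducibility against measurement variability; it is conceptually distinct
from the confidence interval of the observed ORR, which measures sampling
uncertainty.

## The measurement-error model

Diameter readings are modelled on the square-root scale, which stabilises
the size-dependency of measurement error: larger lesions carry larger
absolute errors, approximately in proportion to the square root of their
size. The candidate transforms (identity, square root, cube root, log) can
be compared through Bland–Altman limits of agreement: `bland_altman()`
computes limits `mean ± 1.96·sd` of transformed differences, and
`loa_original_scale()` maps a transformed-scale limit `L` back to an
original-scale difference at a pair mean `m` through the exact
difference-of-powers identity

$$D(m, L) = \left(m^{1/n} + L/2\right)^n - \left(m^{1/n} - L/2\right)^n,$$

which assumes the two transformed measurements straddle $m^{1/n}$
symmetrically and reduces to $2\sqrt{m}\,L$ for the square root — the
fan-shaped limits that motivate the transform. The identity is applied to
each limit separately rather than recentring on the mean difference; for
mean differences near zero (the case here) the two conventions coincide.

For a dataset in which lesion $i$ is read by reader $j$ in session $k$, the
(baseline, post) pair of square-root diameters decomposes as

$$z_{ijk} = \mu + \alpha_i + \beta_j + \gamma_{ij} + \varepsilon_{ijk},$$

with the lesion effect $\alpha$, reader effect $\beta$, lesion-by-reader
interaction $\gamma$ and residual $\varepsilon$ each a mean-zero bivariate
normal over the two phases, giving four 2×2 covariance matrices
(`variance_components`). The residual covariance is the **intra-reader**
error (one reader re-reading the same lesion); the **inter-reader** error
combines reader, interaction and half the residual covariance:
$\Sigma_\beta + \Sigma_\gamma + \Sigma_\varepsilon/2$. Patients are not a
separate level of the hierarchy: patient-to-patient variation is part of
lesion-to-lesion variation and does not alter the error components of
interest. Sessions carry no systematic effect and are treated as
exchangeable replicates. Long-axis (solid lesion) and short-axis (lymph
node) data are fitted separately; trial evaluation uses the short axis for
lymph nodes throughout.

Before fitting, `trim_outliers()` removes, per phase, the 5% of records
with the largest absolute standardized residuals under the univariate
version of the same model — gross errors from misperceived lesion
boundaries rather than ordinary measurement noise. The removal unit is a
single measurement record, with `floor(fraction · n)` records removed per
phase in a single pass (the trimming is not iterated), and the other-phase
partner of a removed record is dropped too so that the bivariate fit sees
complete pairs.

### Fitting routes

* **REML (default).** Three univariate `lme4` fits — baseline, post, and
  their sum — per axis; each cross-covariance is recovered from
  $\mathrm{Cov}(b,p) = (\mathrm{Var}(b{+}p) - \mathrm{Var}(b) -
  \mathrm{Var}(p))/2$ and the resulting 2×2 matrix is clamped onto the
  positive-semidefinite cone. Deterministic, seconds-fast, and treated
  downstream as a single posterior draw.
* **MCMC.** The full Bayesian bivariate fit in JAGS with weakly
  informative priors: half-normal(1) on each component SD — diffuse on the
  $\sqrt{\text{mm}}$ scale, where values run from roughly 0.05 (error SDs)
  to 12 (the largest diameters) — and a uniform(−1, 1) prior on each 2×2
  correlation, the two-dimensional case of the standard uniform-over-
  correlation-matrices family. Defaults: 4 chains, 1,000 adaptation/burn-in
  and 1,000 retained iterations each; split-chain R̂ is reported per scalar
  parameter and values above 1.1 attach a warning without failing the fit.

The package's probability tables take the posterior seriously when it is
available (each table iteration uses a fresh posterior draw) but the
posterior of the error components is tight and leptokurtic in practice, so
the single-draw REML route gives practically identical tables; that is the
configuration exercised most heavily in the test-suite.

## Reassessment simulation

For a scenario — a burden composition (up to 5 lesions, at most 2 lymph
nodes), a first-reading percent change $c$, a reader mode, and for
single-lesion burdens a baseline size — `sample_burden_set()` builds 100
artificial burdens:

* single-lesion burdens use the fixed baseline (reference grids 10–150 mm
  long axis, 10–80 mm short axis, 1 mm steps);
* multi-lesion baselines are drawn from the empirical log-normal
  LN(3.55, 0.53²) truncated to the measurable range (≥ 10 mm; 10–80 mm on
  the short axis, where the same shape is used as a documented default in
  the absence of a separate short-axis estimate);
* per-lesion changes $c_x$ are Normal($c$, $v$) with $v = 0.17$ (long axis)
  or $0.10$ (short axis), then shifted by a common size-weighted amount so
  that $\sum_x c_x Y_{b_x} = c \sum_x Y_{b_x}$ holds exactly. Changes are
  floored at −1 (a lesion cannot lose more than its whole size); when the
  floor binds, the deficit is redistributed over the unfloored lesions, so
  the restriction still holds exactly. The shift mechanism preserves the
  spread of the draws; the restriction itself does not dictate a mechanism,
  so this choice is documented here.

`perturb_burden()` creates the hypothetical second assessment: per lesion,
a correlated (baseline, post) error pair from the intra- or inter-reader
covariance is added on the square-root scale and the result squared,
$Y' = (\sqrt{Y} + \epsilon)^2$. Perturbed square roots below zero are
clamped at zero before squaring — squaring a negative root would silently
turn "measured smaller than nothing" into a positive size. Errors are
independent across the lesions of a burden (cross-lesion error correlation
is not identified by the reading design), each lesion using the error model
of its own axis.

`estimate_probabilities()` reports the proportions of perturbed burdens
whose second-assessment percent change is ≤ −0.3 (response) or ≥ +0.2
(progression); a perturbed baseline burden of exactly zero is redrawn with
a logged count. `build_probability_table()` repeats this 100 times per
scenario, each repetition under a fresh posterior draw, and stores the
median probabilities. When the posterior holds fewer draws than requested
iterations (the REML single-draw case) the iteration count is capped at
the number of draws rather than refusing to run: medians over duplicated
draws would only add Monte Carlo noise.

The resulting probability curves are sigmoid in $c$: response probability
near 1 for $c$ well below −30%, near 0 well above, with a transition whose
steepness grows with baseline size (percent-change error shrinks roughly as
$2\epsilon/\sqrt{Y_b}$). At $c = -1$ (complete disappearance) the response
probability is essentially 1: measurement variability cannot undo a vanished
lesion.

## Trial evaluation and validation

`evaluate_trial()` implements the evaluation algorithm: each patient's
burden summary is matched to a table entry ($c$ rounded to the nearest
0.01 and clamped to $[-1, 1]$; single-lesion baselines to the nearest
1 mm grid point, clamped to the grid range; multi-lesion burdens matched by
composition only — the burden size itself is not part of the multi-lesion
index, a deliberate roughness inherited from the scenario design), giving a
response probability $p_i$ and progression probability $q_i$. One simulated
trial repetition draws independent Bernoulli events per patient; patients
with definitive progression (unequivocal radiologic progression, symptomatic
progression, or death) contribute progression = 1 and response = 0 with
certainty and sit in both denominators. Repeating 1,000 times yields the
simulated rate distributions; the 95% central range uses linear
interpolation between order statistics (`quantile` type 7), the most common
convention, fixed here for bit-reproducibility. Response and progression
events are drawn independently within a repetition; this choice affects no
marginal rate summary, only joint ones, which the package does not report.

Two validation procedures mirror how the approach is checked against a
re-read dataset:

* `burden_second_reading_ranges()` + `coverage_of_second_readings()`:
  per burden and phase, the 95% central range of 1,000 simulated second
  readings is compared with an actual (or synthetically generated) second
  reading; calibration shows as coverage near 95%.
* `bootstrap_orr_coverage()`: patient-level resampling with replacement;
  per resample the simulated ORR central range from the first readings is
  checked against the observed second-reading ORR of the same resample.

`run_simulation_study()` packages the reproducibility experiments: trials
of 50 single-lesion solid burdens are generated under configurable baseline
sizes and percent-change distributions, and the observed ORR with its exact
Clopper–Pearson 95% CI (chosen over asymptotic intervals for its behaviour
at ORR near 0 or 100%) is contrasted with the reassessed median and central
range. The characteristic pattern: small baselines with changes piled near
the −30% cutoff give wide central ranges (poor reproducibility); large
baselines with changes far from the cutoff give narrow ranges that coincide
with the CI.

## Synthetic data and what the tests show

`generate_readings()` builds repeated readings additively on the
square-root scale from known components and squares them — the exact model
the fitter assumes — with a default design of 249 lesions × 6 readers × 2
sessions × 2 phases. `generate_trial()` builds single-lesion solid trials
(baselines LN(3.55, 0.53²) truncated at 10 mm or fixed; percent changes
normal on the percent scale). When a known true ORR is requested, changes
are drawn from the mixture of the two truncated components of the change
distribution (below vs above −30%) weighted so the expected observed ORR
equals the target exactly, preserving the component shapes — calibration by
construction rather than by rejection. `generate_second_readings()` re-reads
a trial through the same square-root perturbation used everywhere else.

The package's reference variance components
(`default_variance_components()`) are stated on the $\sqrt{\text{mm}}$
scale: lesion SD 1.6 (dominant, true size variation), reader and
interaction SDs 0.08, residual SD 0.10, with positive baseline–post
correlations (0.95 lesion, 0.8 reader, 0.5 interaction, 0.3 residual).
They were chosen once so that a single re-measurement of a typical burden
moves its size by less than about 10% — for a 30 mm lesion the inter-reader
size-change SD is about 5%, putting ~95% of re-reads inside ±10% — the
magnitude reported for repeat imaging of single-tumor burdens. The
short-axis set is proportionally tighter.

Because the generators implement the model's own assumptions, passing tests
demonstrate internal consistency — correct decomposition, calibrated
intervals, exact Poisson-binomial behaviour of the trial simulation — not
that real CT readings follow a square-root-scale additive normal model.
Features of real data the generators do not emulate: reader-specific
systematic bias profiles, lesion-morphology effects (irregular borders,
conglomeration), non-normal heavy-tailed gross errors (these appear only as
the planted outliers used to test trimming), and correlation of errors
across lesions of the same patient.

Problem sizes in the test-suite are chosen for desk-scale runtimes: variance
recovery uses 200 lesions × 6 readers × 2 sessions (10 replicate datasets,
REML route), coverage checks use 200 burdens × 1,000 simulated re-reads,
the study runner 2 × 20 replicate trials of 50 patients, and the MCMC
route is exercised at 15 lesions × 3 readers with short chains. Full-scale
MCMC fits (4 × 2,000 iterations on ~6,000 records) are minutes-scale, not
part of the default suite.

## Numerical choices and limitations

* Percentiles: `quantile` type 7 everywhere a central range is formed.
* Estimated 2×2 covariances are clamped onto the PSD cone (non-negative
  diagonals, off-diagonal bounded by the geometric mean) before use.
* The trimming fraction applies per phase via `floor`; ties in
  standardized residuals are broken by order of appearance.
* `c > 1` (growth beyond +100%) is clamped to +1 during lookup with a
  warning; designation there is PD with probability ≈ 1, so the
  approximation is benign.
* Degenerate designs fail loudly: one reader (intra-only fit suggested),
  fewer than 2 lesions, empty scenario grids, compositions absent from a
  probability table (the error lists the available compositions).
* Multi-lesion probability tables are indexed by composition and percent
  change only, not by burden size — a rough treatment of multi-lesion
  baselines that mirrors the scenario design and is flagged as such.
* The model targets two time points (baseline, one post-treatment
  assessment); best-overall-response logic across multiple time points,
  RECIST new-lesion/non-target progression rules beyond the definitive
  progression flag, and confirmation scans are out of scope.
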