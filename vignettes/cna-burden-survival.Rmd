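---
title: "Copy-number burden scores, cutoff selection, and survival stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number burden scores, cutoff selection, and survival stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnasurv)
```

## The problem

Tumors accumulate somatic copy-number alterations (CNAs), and the overall
CNA burden of a tumor has been proposed as a biomarker of benefit from
immune checkpoint blockade (ICB), complementary to tumor mutational burden
(TMB). Two burden summaries are in routine use. The **fraction of genome
altered** (FGA) is length-weighted over segments:

$$\mathrm{FGA}(x) =
  \frac{\sum \mathrm{length}\{|\log_2 R| \ge x\}}
       {\sum \mathrm{length}(\text{all measured segments})},$$

where $R$ is the segment-level copy ratio and $x$ the CNA-calling cutoff.
The **aneuploidy score** (AS) counts chromosome arms instead of base pairs:
an arm is called gained (lost) when the gain (loss) category covers a
dominant fraction of its measured length, and

$$\mathrm{AS}(x) = \frac{\#\mathrm{GAIN} + \#\mathrm{LOSS}}
                        {\#\text{evaluable arms}}.$$

Both are monotone non-increasing in $x$, and the choice of $x$ — 0.1 and
0.2 are both common in the literature — changes which patients are labelled
CNA-high and hence the apparent prognostic value of the score. `cnasurv`
implements the scoring, two data-driven ways of choosing $x$, and the
downstream survival stratification, plus a synthetic-cohort generator that
makes every step testable against known truth.

## Scoring model and its parameters

Segments are read from SEG files (1-based inclusive coordinates; lengths
are always `end - start + 1`). Overlapping segments within a
sample-chromosome are rejected outright rather than merged, because any
overlap corrupts length-weighted scores silently.

Arm-level calls use the convention of the established arm-calling tool for
targeted panels:

* **Arms**: the 39 autosomal arms (22 autosomes × 2 arms minus the five
  acrocentric p arms 13p, 14p, 15p, 21p, 22p). The bundled table derives
  p/q boundaries from the hg19 centromere gaps. Sex chromosomes are kept in
  the segment table but excluded from scoring by default.
* **Categories**: gain when $\log_2 R \ge x$, loss when $\log_2 R \le -x$,
  neutral otherwise. Segments spanning the centromere contribute their
  within-arm portion to each arm separately.
* **`min_arm_coverage` = 0.5**: an arm with less than half its length
  measured is `NOT_EVALUABLE` and leaves the AS denominator. Counting
  unmeasured arms as unaltered would bias AS downward on panels with uneven
  arm coverage.
* **`arm_call_fraction` = 0.7**: an evaluable arm is called for a category
  only when that category covers at least 70% of the measured length;
  otherwise it is `NO_CALL` (evaluable, counted in the denominator, not
  altered).

The FGA boundary is `>=` by default. The two conventions (`>=` vs `>`)
circulate side by side in the literature, sometimes within one paper's
prose versus its formula; they differ only for samples with a segment mean
exactly at the cutoff, so the rule is a configurable argument
(`boundary`), not a hidden constant.

## Choosing the cutoff

### Elbow point (Kneedle)

The cohort-mean score-versus-cutoff curve (grid 0.01–0.50, step 0.01)
falls steeply while the cutoff climbs through measurement noise — every
extra hundredth of $\log_2 R$ removes a swath of false calls — and
flattens once only true events remain. The knee of that curve is a natural
cutoff. `find_elbow()` implements the Kneedle procedure for a decreasing
curve: min-max normalise both axes, flip the curve to increasing, form the
difference from the unit diagonal, and take the first local maximum of the
difference curve confirmed by the sensitivity criterion (the difference
must drop `sensitivity` × the mean grid step below the maximum before the
next candidate). Numerical choices:

* **Sensitivity 1, offline mode** — the defaults of the reference
  implementation of the method; nothing in our use case motivates
  deviating.
* **Snapped to the grid** — the elbow is reported as a grid point, not
  interpolated, because downstream CNA calling is grid-based.
* **Degenerate inputs** — a straight line has an identically-zero
  difference curve and raises a no-knee error (so does any curve whose
  difference never clears the sensitivity threshold); a non-monotone curve
  is a validation error, since per-sample score curves are non-increasing
  by construction.
* The elbow is invariant to adding a constant to the curve or rescaling it
  by a positive factor (min-max normalisation); the tests assert this.

`bootstrap_elbow()` resamples *samples* with replacement (1000 replicates
by default), recomputes the mean curve and its elbow per replicate, and
reports the percentile 2.5%/97.5% interval. Percentile rather than BCa:
the estimand lives on a coarse grid, where BCa's acceleration correction
buys nothing. Replicates with no knee are dropped and counted; more than
50% no-knee replicates raises an unstable-elbow error rather than
reporting a meaningless interval.

### Gaussian-mixture boundary

As a parametric alternative, `gmm_cutoff()` fits a two-component
unequal-variance Gaussian mixture to the per-segment $|\log_2 R|$ values
of a cohort (segment-level and unweighted by length — the simplest reading
where finer detail is unspecified) and returns the equal-posterior
decision boundary between the component means, solved by `uniroot` on the
log posterior odds. The EM fit itself is delegated to mclust; the boundary
is computed here. Degeneracy handling goes beyond vanishing weights
(< 0.01) and indistinct means (< 1e-3 apart): a single-component fit
preferred by BIC also raises a degenerate-mixture error, because a
two-state "neutral versus altered" reading of a unimodal sample is
meaningless — this is what catches data drawn from one Gaussian, which can
otherwise yield a well-separated but spurious two-component fit. The
estimator has a known pathology on burden data, which the test suite
reproduces on a constructed cohort: when a subset of high-purity tumors
pushes the altered component's mean high, the mixture boundary lands well
above the elbow point and zeroes out AS for a large share of the
low-purity samples whose attenuated events all fall below it, while the
elbow cutoff keeps them.

## Survival stratification

Binarization is always **within cancer type**: a sample is score-high when
its value strictly exceeds the type-specific empirical percentile (ties go
to low, so a constant score yields no high group), TMB-high in the top 20%
(80th percentile). Cox models are partial-likelihood fits with Efron tie
handling via the survival package; ICB drug class enters as indicator
contrasts against a fixed reference (`PD-1/PD-L1` when present).
Pan-cancer fits are unstratified by default — binarization is already
type-specific — with `stratify_by_type = TRUE` available where a shared
baseline hazard is implausible.

`search_binarization()` scans candidate percentiles (default 20th–80th by
tens; the displayed 10th–90th family of some analyses is a config choice
away) and picks the candidate with the highest multivariable hazard ratio
among those whose Wald P survives Bonferroni correction *over the number
of candidates*. When none survives, the result is an explicit
"none chosen" state, not a silent best guess. Leave-one-out refits are a
stability diagnostic (`loo = TRUE`; the spread of hazard ratios when any
single patient is dropped) and never part of the selection — selection on
the full-cohort fit is the only aggregation that is well defined, and the
diagnostic is opt-in because it costs one model fit per patient per
candidate.

Supporting analyses: `compare_hrs_paired()` (two-sided Wilcoxon
signed-rank on per-cancer-type hazard ratios, zeros dropped per the
standard convention, plus the difference of mean HRs),
`power_sample_size()` (Schoenfeld's events formula
$d = (z_{1-\alpha/2}+z_{\mathrm{power}})^2 / [p(1-p)\ln^2 \mathrm{HR}]$,
total $n = \lceil d/\psi \rceil$ with $\psi$ the overall event
probability), and `mutation_frequency_diff()` (per-gene 2×2 chi-squared
without continuity correction, Bonferroni over testable genes; genes with
no mutations are flagged untestable rather than dropped silently).

## What the synthetic cohorts emulate

`simulate_segments()` draws, per sample, a tumor purity
$\rho \sim \mathrm{Beta}(4,4)$ (median ≈ 0.5, the realistic range of
clinical specimens) and a true copy state per arm (event probability 0.15;
gains CN = 3, losses CN = 1), emits each arm as 1–3 segments, injects
occasional ~3 Mb focal events (capped at a quarter of the arm so a focal
event can never overturn an arm-level call), and observes

$$\log_2 R = \log_2\!\frac{\rho \cdot CN + (1-\rho)\cdot 2}{2}
  + \varepsilon,\qquad \varepsilon \sim N(0, \sigma),$$

clamped to ±3. This mixing formula is the mechanism by which low purity
drags real log2 ratios toward 0 and silently converts CNA-high tumors into
CNA-low calls at a fixed cutoff: a single-copy gain is detectable at
cutoff 0.2 only when $\rho \gtrsim 0.30$. The default noise
$\sigma = 0.1$ was chosen so that cohort elbow points land in the
0.14–0.22 range reported for targeted-panel ICB cohorts; with it, the
elbow of a default cohort sits just above the noise floor, which is
exactly the structure the elbow method exists to find.

`simulate_survival()` generates exponential event times with rate
$\lambda_0 \exp(\beta_s \cdot \text{score-high} + \beta_t \cdot
\text{TMB-high} + \beta_d)$ — defaults $\lambda_0 = \ln 2 / 15$ per month
(15-month baseline median), $\beta_s = \ln 1.35$ (harmful high CNA
burden), $\beta_t = \ln 0.6$ (protective high TMB under ICB), small drug
class effects — under uniform administrative censoring on 0–60 months.
Exponential rather than Weibull baseline: the downstream models are
semi-parametric, so any proportional-hazards generator is adequate and the
exponential has closed-form truth. `make_knee_cohort()` is a separate,
fully controlled construction for elbow tests: a piecewise-linear template
(90% of the drop before the knee) per-sample rescaled, shifted and
noised — transformations under which the Kneedle elbow is invariant — so
the construction knee is the provable truth.

What the generator does **not** emulate: probe-level panel design and
segmentation artifacts, correlated co-occurrence of specific arm events,
subclonal (fractional) copy states, ploidy shifts (whole-genome doubling),
and any dependence of TMB or drug class on the copy-number state. Passing
tests therefore demonstrate that the pipeline's estimators recover known
structure of this form — not that any particular clinical cohort carries
that structure.

## Problem sizes and tolerances in the test suite

The suite exercises: exact closed-form scoring on hand-built fixtures;
agreement of the arm caller with committed golden files (computed by an
independent brute-force oracle, labelled synthetic); monotonicity of
AS/FGA over the full grid for 100 simulated samples; elbow recovery at
construction knees 0.14/0.20/0.22 (n = 200, 1000 bootstrap replicates,
point estimate within one grid step) with confidence-interval coverage
≥ 90% over 100 regenerated cohorts; the mixture boundary within ±0.02 of
its analytic value at n = 10,000; Cox interval coverage ≥ 90% over 200
replicates at n = 2000 with approximately uniform null P values;
recovery of a constructed 60th-percentile effect in the majority of 50
searches at n = 1600 with ≥ 88% "none chosen" under the null; the
four-group median-survival ordering at n = 3000; Schoenfeld sample sizes
against an independent power computation (66 at HR 2, balanced groups,
full events); and ≤ 1 Bonferroni hit among 500 null genes. These sizes
keep the whole suite at a few minutes on one core while leaving each
stochastic assertion several standard errors of slack; grid-valued
estimates always carry one grid step (0.01) of tolerance for
discretisation.

## Known limitations

* Arm calls are hard labels; no per-arm uncertainty is propagated into AS.
* The elbow is cohort-level; per-sample cutoffs (and purity/ploidy-aware
  recalling generally) are out of scope — where purity and ploidy are
  known, dedicated callers should replace the fixed-cutoff scoring
  upstream of this package.
* The mixture cutoff ignores segment length; a length-weighted variant
  would need a weighted EM and is not provided.
* `search_binarization()` inherits the usual caveat of threshold
  optimisation: the chosen percentile is optimistic in-sample, and the
  leave-one-out spread is a diagnostic, not a correction.
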