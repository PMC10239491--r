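# cnasurv

Tumor copy-number burden scoring and immunotherapy survival stratification.

Somatic copy-number alterations (CNAs) are a candidate biomarker of response
to immune checkpoint blockade (ICB). Two cohort-level summaries dominate the
literature: the **aneuploidy score** (AS), the fraction of chromosome arms
carrying an arm-level CNA, and the **fraction of genome altered** (FGA), the
length-weighted fraction of the measured genome in altered segments,

```
FGA = sum(seg_length[ |log2 ratio| >= x ]) / sum(seg_length)
AS  = (# GAIN arms + # LOSS arms) / (# evaluable arms)
```

Both depend on the CNA-calling cutoff `x` on the absolute log2 copy ratio,
and that choice materially changes their power to stratify survival.
`cnasurv` implements the full analysis path for clinical-genomics analysts
working from segmented copy-number (SEG) files:

- **Scoring** — FGA and arm-level AS at any cutoff, with the 0.7
  dominant-category / 0.5 minimum-coverage arm-calling convention over the
  39 autosomal arms (hg19 table bundled), and score-versus-cutoff sweeps
  over a 0.01–0.50 grid.
- **Cutoff selection** — the Kneedle elbow point of the cohort-mean
  score-versus-cutoff curve with 1000-replicate bootstrap confidence
  intervals, and a two-component Gaussian-mixture decision boundary as the
  parametric alternative.
- **Survival stratification** — within-cancer-type binarization of TMB (top
  20%) and CNA scores, multivariable Cox proportional-hazards models
  (score + TMB + ICB drug class), a binarization-percentile search
  (20th–80th, Bonferroni-corrected, with a leave-one-out stability
  diagnostic), Kaplan–Meier four-group analysis, paired Wilcoxon comparison
  of per-cancer-type hazard ratios, Schoenfeld power/sample-size analysis,
  and differential gene-mutation-frequency tests.
- **Synthetic cohorts** — a generator with fully known ground truth
  (purity-attenuated log2 ratios via `log2((rho*CN + (1-rho)*2)/2)`, arm and
  focal events, log-normal TMB, exponential proportional-hazards survival),
  so every step is testable without access to clinical cohorts.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` for fitted objects, `autoplot()` for each result type.

## Worked example

```r
library(cnasurv)

# a synthetic 3-type ICB cohort (1200 patients) with known truth
cohort <- simulate_cohort(sim_config(n_samples = 400), seed = 7)

# score-versus-cutoff sweep and a cancer-type-specific elbow point
sweep <- score_sweep(cohort$segments)
mel <- cohort$clinical$sample_id[cohort$clinical$cancer_type == "melanoma"]
bootstrap_elbow(dplyr::filter(sweep, sample_id %in% mel),
                score = "as", n_bootstrap = 1000, seed = 7)
#> # A tibble: 1 × 8
#>   score_kind elbow_point ci_low ci_high n_bootstrap n_noknee n_samples  seed
#>   <chr>            <dbl>  <dbl>   <dbl>       <dbl>    <int>     <int> <dbl>
#> 1 AS                0.16   0.15    0.16        1000        0       400     7

# score at a cutoff above the elbow (clear of the noise floor), binarize,
# and fit the multivariable model
scores <- compute_scores(cohort$segments, cutoff = 0.2)
binned <- bin_cohort(cohort$clinical, scores, score_col = "as_score",
                     score_percentile = 60)
fit <- fit_cox(binned)
tidy(fit)
#> # A tibble: 4 × 7
#>   term             estimate    hr std.error conf.low conf.high  p.value
#>   <chr>               <dbl> <dbl>     <dbl>    <dbl>     <dbl>    <dbl>
#> 1 score_highTRUE     0.215  1.24     0.0749    1.07      1.44  0.00412
#> 2 tmb_highTRUE      -0.352  0.703    0.0967    0.582     0.850 0.000269
#> 3 drug_classCombo   -0.0181 0.982    0.0884    0.826     1.17  0.838
#> 4 drug_classCTLA-4   0.233  1.26     0.0987    1.04      1.53  0.0182
```

The elbow sits just above the generator's per-segment noise scale
(sd 0.1), where false arm-level calls die out. The fitted effects carry
the constructed signs and magnitudes: score-high HR 1.24 (construction
1.35, attenuated by measurement noise in the score), protective high-TMB
HR 0.70 (construction 0.6), CTLA-4 HR 1.26 (construction 1.1).

Four-group stratification:

```r
km <- km_compare(binned)          # TMB-{H,L} x Score-{H,L}
glance(km)
#> # A tibble: 4 × 4
#>   group             n n_events median
#>   <chr>         <dbl>    <dbl>  <dbl>
#> 1 TMB-H/Score-L   153       73   26.1
#> 2 TMB-H/Score-H    87       57   16.3
#> 3 TMB-L/Score-L   621      400   15.0
#> 4 TMB-L/Score-H   339      234   13.1
autoplot(km)                      # Kaplan-Meier step curves
```

Median survival reproduces the constructed ordering: high TMB is
protective, a high CNA score deleterious within each TMB stratum.

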