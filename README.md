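# biradsvar

Observer variability in categorical BI-RADS ultrasound features and its
effect on a Bayes computer-aided diagnosis (CAD) of solid breast masses.

## The problem

The six BI-RADS ultrasound descriptors of a solid breast mass — shape,
orientation, margin, lesion boundary, echo pattern, posterior acoustic
features — are coded with considerable intra-observer variability: reading
the same images months apart, the same radiologist agrees with themselves
anywhere from slightly (κ ≈ 0.2) to almost perfectly (κ ≈ 0.95), and the
pooled agreement declines as the interval grows. A CAD system that turns the
coded features into a probability of malignancy inherits that variability.
This package implements the full analysis showing that a naive-Bayes
classifier, **retrained on each reading round's own feature codes** and
evaluated by leave-one-out cross-validation, keeps its diagnostic
performance stable despite the feature drift.

The core statistic is the Bayes probability of malignancy

P(M | F) = P(M) ∏ᵢ P(Fᵢ | M) / [ P(M) ∏ᵢ P(Fᵢ | M) + P(B) ∏ᵢ P(Fᵢ | B) ],

with count-ratio priors, additively smoothed class-conditional category
probabilities, and (optionally) a class-conditional normal density of
patient age as one extra factor. Around it sit:

* a synthetic-cohort generator (264 masses, 85 malignant / 179 benign,
  per-class ages 58.8 ± 12.1 / 48.0 ± 14.5 years, exact histology-subtype
  mix) with a keep-or-resample observer-noise model whose expected Cohen's
  kappa is analytic (κ = f against truth, κ = fₐf_b between rounds);
* per-feature and pooled Cohen's kappa with Landis–Koch labels;
* empirical ROC area (Mann–Whitney) with DeLong SE/CI, paired DeLong tests
  between reading rounds, and ICC(A,1) of the repeated probability
  estimates.

Intended users: biostatisticians and CAD researchers studying how rating
noise propagates through retrained classifiers, and anyone needing tested R
implementations of pooled kappa, DeLong machinery, or ANOVA-based ICC with
F-based confidence limits.

## Worked example

```r
library(biradsvar)

cfg <- experiment_config(master_seed = 20260101)  # default 264-lesion study
rep <- run_experiment(cfg)

rep$kappa_table[rep$kappa_table$feature == "overall", c(2, 4, 6)]
#>   kappa_obs1_vs_obs2 kappa_obs2_vs_obs3 kappa_obs1_vs_obs3
#> 7             0.7731             0.6622             0.5786

rep$performance[, c("variant", "observation", "auc", "se")]
#>       variant observation       auc         se
#>      features        obs1 0.7658232 0.03200700
#>      features        obs2 0.7662175 0.03096967
#>      features        obs3 0.7639172 0.03131912
#>  features_age        obs1 0.8316135 0.02614440
#>  features_age        obs2 0.8322708 0.02496926
#>  features_age        obs3 0.8247125 0.02644553

rep$comparisons[rep$comparisons$variant == "features", ]
#>    variant obs_a obs_b    delta_auc   p_value
#> 1 features  obs1  obs2 0.0003943477 0.9847344
#> 2 features  obs1  obs3 0.0019060138 0.9239976
#> 3 features  obs2  obs3 0.0023003615 0.9120174

rep$icc[, c("variant", "icc", "ci_low", "ci_high")]
#>        variant       icc    ci_low   ci_high
#> 1     features 0.8691187 0.8423298 0.8924670
#> 2 features_age 0.9104233 0.8914253 0.9267931
```

Reading: the pooled agreement between rounds falls from substantial (0.77)
to moderate (0.58) as the interval grows, yet the area under the ROC curve
moves by at most ~0.002 between rounds (p ≥ 0.91), the posteriors correlate
at ICC ≈ 0.87 across rounds, and adding the age term lifts A_z from ~0.77
to ~0.83. That is the robustness-under-retraining finding in one run.

## The analysis workflow

The numbered drivers under `analysis/` run the study end to end and write
tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_cohort.R` | cohort + three reading rounds → `results/data/` |
| `02_agreement.R` | per-feature and overall kappa table |
| `03_bayes_cad.R` | leave-one-out posteriors per round, ± age |
| `04_performance.R` | A_z ± SE, paired DeLong tests, ICC |
| `05_replication.R` | 50-replicate Monte-Carlo summary |

Each stage reads only the previous stage's files, so every reported number
can be recomputed from stored intermediates. `vignettes/` contains the
methods write-up: model assumptions, the noise model and its kappa algebra,
calibration of the shipped defaults, and known limitations.

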