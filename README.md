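# metabodisc

Discriminant and Bayesian analysis of two-group untargeted metabolomics
peak-intensity tables, built for studies that ask which gut (or other)
metabolites distinguish two animal populations — e.g. lines divergently
selected for the environmental variance of a production trait, where the
low-variance line is treated as the resilient group. The package takes a
samples × metabolites table of positive peak areas (with below-detection
missingness and a per-metabolite acquisition-method label), and answers two
complementary questions:

* **Which metabolite panel best classifies the two populations?**
  A from-scratch PLS-DA with iterative variable selection.
* **Which individual metabolites differ credibly in abundance?**
  A per-metabolite Bayesian two-group comparison with an FDR-style rule.

A synthetic-data generator with known ground truth makes every stage testable
without any real dataset.

## Methods in brief

**Compositional preprocessing.** Metabolites with more than 20 % missing
values in either population are removed; remaining missing entries are
imputed as half the minimum observed intensity of the metabolite's
acquisition method. Because peak areas are compositional, the table is mapped
to unconstrained space with the additive log-ratio transform

```
ALR(j | ref) = log(x_j / x_ref) = log(x_j) − log(x_ref),
```

using the metabolite with the lowest coefficient of variation as the
reference (p metabolites give p − 1 log-ratios). A Procrustes correlation
against the centered log-ratio geometry reports how well the ALR choice
preserves the sample configuration. Columns are then autoscaled to mean 0,
SD 1, so downstream effects are in units of each metabolite's SD.

**PLS-DA.** NIPALS PLS2 against a centered two-column class indicator;
samples are classified by Mahalanobis distance to the class centroids in
score space (pooled within-class score covariance). The number of components
minimizes the balanced error rate (BER — the unweighted mean of the
per-class misclassification rates) under stratified fourfold
cross-validation repeated 100 times. Variables with a variable importance in
projection

```
VIP_j = sqrt( p · Σ_a SS_a (w_ja / ‖w_a‖)² / Σ_a SS_a )
```

below 1 are dropped and the model is re-tuned, iterating until the
cross-validated BER stops improving; the final model is validated with a
confusion matrix (fourfold CV × 10,000 by default) and a permuted-confusion
matrix, whose true-positive percentage should sit at the 50 % chance level
for balanced classes.

**Bayesian relevance.** Per metabolite, the model `y_ij = µ_i + e_ij` with
flat priors is Gibbs-sampled (4 chains × 50,000 iterations, lag 10, burn-in
1,000 by default); the pooled posterior of `D = µ_H − µ_L` yields the
posterior mean difference (in SD units), `P0` (the probability that the
difference has the sign of its posterior mean), the 95 % highest-posterior-
density interval, and the posterior error probability `PEP = (1 − P0)/0.5`.
Metabolites are flagged relevant where the cumulative PEP — the running mean
of ascending-sorted PEPs, a q-value analogue — is at most 0.05. The overlap
between the Bayes-relevant set and the PLS-selected panel is reported.

## Worked example

```r
library(metabodisc)
cfg <- sim_config(seed = 1)        # 13 + 13 samples, 200 metabolites,
d   <- generate_dataset(cfg)       # 10 of them shifted by 2 SD
tab <- inject_missingness(d$table, cfg)
tab
#> peak_table: 26 samples x 200 metabolites (4 methods)
#>   populations: H=13 L=13; missing entries: 520 (10.0%)

prep <- preprocess(tab)
#> filter_missing: removed 38 of 200 metabolites (> 20% missing in a population)
prep$report$reference_id           # lowest-CV ALR reference
#> [1] "M009"
round(prep$report$procrustes_corr, 3)
#> [1] 0.978

sel <- plsda_select(prep$matrix, prep$matrix$population, repeats = 25, seed = 2)
sel$trace
#>   iteration n_vars ncomp         ber
#> 1         1    161     2 0.072307692
#> 2         2     48     2 0.001538462
#> 3         3     16     2 0.000000000
#> 4         4      6     1 0.001538462

val <- plsda_validate(sel$model, prep$matrix, prep$matrix$population,
                      repeats = 500, seed = 3)
val
#> confusion matrix (row %):
#>     H   L
#> H 100   0
#> L   0 100
#> accuracy 1.000, precision 1.000 (positive class: L, resilient)

bay <- run_bayes(prep$matrix,
                 gibbs_config(n_chains = 2, n_iter = 5000, burn_in = 500,
                              thin = 5, seed = 4))
head(bay[order(bay$pep), c("metabolite_id", "mean_diff", "p0",
                           "hpd95_low", "hpd95_high", "pep", "cum_pep")], 5)
#>     metabolite_id mean_diff p0  hpd95_low hpd95_high pep cum_pep
#> 63           M077  1.378273  1  0.7916739  1.9868571   0       0
#> 97           M115  1.418803  1  0.8716414  2.0133209   0       0
#> 120          M140  1.470342  1  0.9613988  2.0203667   0       0
#> 143          M174 -1.283443  1 -1.8702640 -0.6279856   0       0
#> 158          M194  1.307286  1  0.6844877  1.9210751   0       0

attr(overlap_report(bay, sel$model), "counts")
#> bayes   pls  both
#>    41    16    16
```

Reading the output: the 16-metabolite PLS-DA panel cross-validates to a
perfect confusion matrix on this synthetic dataset (its ten 2-SD planted
effects are strong); the Bayesian sweep flags 41 metabolites at cumulative
PEP ≤ 0.05, and the entire PLS panel is contained in the Bayes-relevant set.
The top rows of the Bayesian table show posterior mean differences of
1.3–1.5 SD with HPD95 intervals well away from 0 and PEP 0.
`run_all(run_config(...), out_dir)` executes the same sequence end to end
and writes every table, report and a provenance manifest to a run directory.

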