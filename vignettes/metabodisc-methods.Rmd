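---
title: "Methods: discriminant and Bayesian analysis of compositional metabolomics data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discriminant and Bayesian analysis of compositional metabolomics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind each stage of
`metabodisc`, the tunable parameters and their defaults, the numerical
choices, and the design decisions taken where the methodology was genuinely
open. The running setting is a two-group untargeted LC-MS experiment:
two populations of animals (labelled `L`, resilient / low environmental
variance, and `H`, non-resilient / high), a samples × metabolites table of
positive peak areas, left-censored missingness, and each metabolite
quantified by one of a small number of UPLC-MS/MS methods.

## The synthetic-data generator

No public dataset accompanies the design this package targets, so the
generator in `generate_dataset()` is first-class, tested code and defines
the study conditions under which the pipeline is validated.

Per metabolite $j$, log-intensities are Normal:
$\log x_{ij} \sim N(\mu_j + z_i \delta_j \sigma_j,\; \sigma_j^2)$, where
$z_i$ indicates membership of population H, $\mu_j \sim N(16, 1.5)$ and
$\sigma_j = 0.8\,u_j$ with $u_j \sim U(0.5, 1.5)$. Exponentiating gives
strictly positive, log-normal peak areas of realistic magnitude
($e^{16} \approx 9\times 10^6$). Effects are additive on the log scale —
the natural choice given that the whole downstream analysis operates on
log-ratios — and are stated in units of the metabolite's log-scale SD
($\delta_j$ = `effect_sd`), so a planted effect is directly comparable to
the SD-unit posterior differences the Bayesian stage reports. The spreads of
$\mu_j$ and $\sigma_j$ are fixed constants: they make the coefficient of
variation differ across metabolites, without which selecting an ALR
reference by lowest CV would be meaningless.

Defaults — 13 samples per population, 200 metabolites, 10 informative at
2 SD, 4 acquisition methods (round-robin assignment, as each metabolite
belongs to exactly one method but no assignment rule is implied by the
design), 10 % missingness — describe a typical small divergent-selection
experiment and are not tuned per analysis.

Missingness is left-censoring: `inject_missingness()` flags every entry
below the per-method quantile of the target rate. Censoring is deterministic
given the table (a threshold, not a per-entry coin flip) so that tests can
verify it against an exact counting oracle; the uncensored matrix is kept in
an attribute. Real below-detection missingness is plausibly stochastic near
the limit of detection; the deterministic form is the idealization
consistent with half-minimum imputation. The generator does **not** emulate
retention times, m/z, peak integration, heteroscedastic technical noise,
batch effects, or the total-sum closure of real compositions (only
positivity); conclusions from passing tests are therefore about the
statistical machinery, not about instrument artefacts.

## Preprocessing

**Missingness filter.** A metabolite is removed when its missing fraction
exceeds the threshold (default 20 %) in *at least one* population. The
alternative reading — only when both populations exceed it — would retain
metabolites that are essentially unobserved in one group; such a metabolite
cannot support a two-group contrast, and its imputed values would be pure
artefact, so the either-population rule is used.

**Half-minimum imputation.** Each missing entry of metabolite $j$ becomes
$0.5 \min$ over *all* observed intensities of $j$'s acquisition method
(method-wide, not per metabolite): detection limits are a property of the
acquisition method, and the method-wide minimum is the natural proxy for
that limit.

**ALR reference.** The reference is the metabolite with the lowest
coefficient of variation (SD/mean of raw post-imputation intensities),
computed across all samples rather than per population — the reference
should be stable overall, and computing CV within groups would bias the
choice toward group-dependent stability. Ties (exactly equal CVs) go to the
earlier column, for determinism. Natural logarithms are used throughout;
any other base would only rescale columns, which autoscaling absorbs.

**Procrustes isometry check.** The ALR transform is not an isometry: with a
noisy reference the transformed sample geometry can be distorted. The check
computes principal coordinates of the ALR matrix and of the centered
log-ratio (CLR) transform — the isometric reference geometry — and reports
their symmetric Procrustes correlation $\sqrt{1 - m^2}$ (vegan's
superimposition). On synthetic tables at default settings the value is
typically ≈ 0.95–0.98. It is reported, with a warning below 0.95
(configurable), never a hard failure: there is no principled universal
cutoff, and the number is most useful as provenance.

**Autoscaling** centers each ALR column and divides by its sample SD
($n-1$ denominator), storing means and SDs so the transform round-trips
exactly. After this step a between-group difference of $d$ on a column is a
difference of $d$ SD units, which is what both downstream stages report.

No sample-exclusion rule is implemented: the pipeline analyses whatever
samples it is given.

## PLS-DA

`plsda_fit()` implements NIPALS PLS2. The response is a two-column one-hot
class indicator, column-centered — the standard discriminant coding, and
the one the field's reference implementation (mixOmics) uses; the test
suite verifies score-for-score and VIP-for-VIP agreement with it to
machine precision on a fixture. X is centered inside `fit` on the training
rows (important under cross-validation, where the global autoscaling is not
training-only); it is not re-scaled there, since the input is already
autoscaled. Components are extracted with the usual weight/score/loading
iteration and rank-one deflation; the first weight vector equals the
dominant left singular vector of $X^\top Y$, which the tests assert. If
deflation exhausts the numerical rank, the model simply carries fewer
components.

**Classification** is by Mahalanobis distance from a sample's score vector
to each class centroid, using the pooled within-class covariance of the
training scores with a ridge of $10^{-8} I$ for invertibility. The pooled
estimator is the natural choice under the equal-covariance working
assumption of the two-group model; with one component it collapses to
nearest-centroid on the scalar score.

**Tuning.** The component count (grid $1..\min(10, n-2, p)$) minimizes the
balanced error rate, BER — the unweighted mean of per-class
misclassification rates — under stratified fourfold cross-validation
repeated 100 times (per repeat, out-of-fold predictions are pooled and one
BER computed; repeats are averaged). Folds are stratified because with 13
samples per class, unstratified fourfold splits can produce training sets
missing a class entirely; a degenerate draw is redrawn and logged. Ties in
BER go to fewer components.

**Variable selection.** Iterate: tune, fit, compute VIP, drop all variables
with VIP < 1, stop when no variable is below 1, when fewer than two
variables would remain, or when the cross-validated BER of an iteration is
worse than its predecessor's; return the iteration with the lowest BER
(ties to fewer variables). "Until the lowest BER is achieved" does not by
itself define a stopping time, so the loop keeps the argmin over its trace —
the weakest stopping rule consistent with that goal; since mean VIP² is
exactly 1, some variable falls below 1 whenever VIPs are not all equal, so
the variable count strictly decreases and termination is guaranteed. VIP is
computed from the full-data fit of each iteration (not CV-averaged), the
simpler and more common convention.

**Validation.** The final model is assessed by aggregating out-of-fold
predictions over repeated stratified fourfold CV (default 10,000 repeats)
into a confusion matrix of class-wise percentages, with accuracy and
precision taking the resilient class L as the true positive. The
permuted-confusion matrix repeats this with labels randomized per repeat;
for balanced classes its true-positive percentage has a 50 % chance level,
and this calibration is one of the two quantities
`scripts/acceptance.R` recomputes. Repeat counts are configuration: the
protocol values (100 tuning / 10,000 validation) are defaults, and the test
suite runs 8–1,000 depending on the check, sizes chosen so the full suite
completes in a few minutes.

## Bayesian two-group relevance

Per metabolite (one autoscaled ALR column $y$), the model is
$y_{ij} = \mu_i + e_{ij}$, $e \sim N(0, \sigma^2)$, with improper flat
priors on the group means and the reference (Jeffreys) prior
$p(\sigma^2) \propto 1/\sigma^2$. The Gibbs sampler alternates
$\mu_i \mid \sigma^2 \sim N(\bar y_i, \sigma^2/n_i)$ with the scaled
inverse-chi-square conditional
$\sigma^2 \mid \mu \sim \text{Inv-Gamma}(n/2, \text{SSE}(\mu)/2)$. Under
this prior the pooled posterior of $D = \mu_H - \mu_L$ is exactly the
classical two-sample flat-prior posterior: a location-scale t with
$n_1+n_2-2$ degrees of freedom, location $\bar y_H - \bar y_L$ and scale
$s_p\sqrt{1/n_1 + 1/n_2}$ — the closed form the test suite uses as an
independent oracle. A uniform prior on $\sigma^2$ itself was the other
candidate reading of "flat priors for all unknowns"; it shifts the degrees
of freedom to $n-4$ and has no closed-form pedigree as a reference
posterior, so the Jeffreys form was chosen. The inner loop is compiled
(Rcpp) but draws from R's RNG stream, so results are reproducible with
`set.seed` semantics; per-metabolite runs are seeded `seed + column index`
so each metabolite's chain is reproducible in isolation.

Defaults follow the protocol: 4 chains × 50,000 iterations, burn-in 1,000,
lag 10 — 4,900 kept draws per chain, 19,600 pooled. Tests and the
acceptance script use 2 chains × 5,000 (burn-in 500, lag 5; 1,800 pooled
draws), which is ample for a two-parameter conjugate model whose chains mix
in a handful of iterations; no convergence diagnostics beyond the
multi-chain design are computed.

Summaries per metabolite: posterior mean of $D$ (in SD units, because the
input is autoscaled); $P_0 = \max\{P(D>0), P(D<0)\}\in[0.5,1]$; the 95 %
HPD interval by a deterministic narrowest-window scan over the sorted
draws; and the posterior error probability $\text{PEP} = (1-P_0)/0.5$.

**The cumulative-PEP rule, and its calibration.** Metabolites are sorted by
ascending PEP; the cumulative PEP at rank $k$ is the mean of the $k$
smallest PEPs (ties share their group's largest value), and metabolites
with cumulative PEP ≤ 0.05 are flagged relevant — the q-value-style rule
of averaging local error probabilities over an accepted set. One property
deserves an honest statement. For a truly null metabolite in this model,
$P_0$ is the posterior CDF evaluated at the observed t statistic, so
$P_0 \sim U(0.5, 1)$ and $\text{PEP} \sim U(0, 1)$ — it does *not*
concentrate near 1 the way a mixture-model local false-discovery rate
would. The running mean of the $k$ smallest of $m$ uniform PEPs is about
$k/2m$, so the rule admits nulls well beyond the nominal 5 %: the package's
own acceptance run measures the realized false-discovery proportion on
mixed null/signal simulations at roughly 44 % (and even a fully null table
yields flags on the order of a tenth of its metabolites). The rule is
implemented exactly as defined because it is the method under study; users
who need frequentist FDR control should treat the flags as a ranking, or
apply a standard p-value-based procedure to $2(1-P_0)$ themselves.

The realized SD-unit threshold that the rule induces (e.g. "relevant
metabolites differ by more than ~0.67 SD") is a data-dependent consequence
of the PEP distribution, not a rule; nothing is hard-coded.

## Pipeline, determinism, and problem sizes

`run_all()` sequences simulate → preprocess → select → validate → permute →
Bayes → overlap, writing TSV tables, JSON reports, and a manifest (stage
seeds and wall times). A single global seed fans out to per-stage seeds by
fixed offsets, and runs are byte-identical given the same configuration and
seed (the manifest's wall times excepted). The overlap report is the set
intersection of the Bayes-relevant and PLS-selected metabolite panels.

Problem sizes used in the shipped tests were chosen as a deliberate
trade-off between statistical resolution and a test suite that runs in
minutes: 26 × 200 tables for end-to-end checks, 100–200 replicates for
Monte-Carlo properties (SMD recovery, HPD coverage), 1,000 label
permutations for the chance-level check, and 12–50 replicates of the
300-metabolite mixed simulation for the FDR measurement.

## Known limitations

* The generator draws independent metabolites; real peak tables have strong
  correlation structure, which affects PLS-DA selection stability more than
  any marginal analysis. Enrichment results on synthetic data are therefore
  optimistic.
* Half-minimum imputation and the either-population filter are the
  implemented conventions; no alternative imputations (kNN, random forest)
  or CLR/ILR analysis branches are provided beyond the Procrustes check.
* The Bayesian model has a single line effect — no covariates, no
  hierarchical shrinkage across metabolites.
* Only two classes are supported; there is no sparse or orthogonal PLS
  variant.
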