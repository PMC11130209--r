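---
title: "Pathway-cluster survival signatures: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-cluster survival signatures: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psilc)
```

## The problem

Invasive lobular carcinoma (ILC) is a histologically distinct breast cancer
subtype with poorer long-term outcome than the common no-special-type
carcinomas, yet most clinically deployed expression signatures were not
designed around its biology. This package implements a discovery–validation
workflow for building pathway-centric prognostic and predictive models of
ILC transcriptomes, together with a synthetic-cohort generator so that every
stage can be exercised and verified without access to controlled patient
data.

The workflow has five stages:

1. **Dysregulated genes.** Tumour and matched normal log2 expression are
   compared twice: a moderated two-group test of mean differences
   (differential expression) and an F-test of variance differences
   (differential variability). The union of the two significant lists is
   the dysregulated-gene resource.
2. **Clusters of pathways (CPs).** Dysregulated genes are mapped to pathway
   gene sets by hypergeometric over-representation. Because curated pathway
   databases are heavily nested, enriched pathways are collapsed by
   hierarchical clustering on the overlap-coefficient distance, with the
   number of clusters chosen from the average silhouette curve. Each
   resulting CP is the gene union of its member pathways; genes mapping to
   no enriched pathway form a leftover CP. A non-redundant variant assigns
   each multi-CP gene to the CP where it has the highest relevance
   (fraction of CP co-members with absolute Spearman correlation above a
   threshold).
3. **Per-CP risk models.** Within a CP, genes univariably associated with
   outcome in the discovery cohort (Cox proportional hazards on per-gene
   z-scores, Wald p < 0.05) are retained; a patient's CP score is the
   coefficient-weighted sum of their z-scores. Risk groups use
   discovery-derived cut-offs only: the median for two groups, the 33rd
   and 66th percentiles for three.
4. **The multivariable signature (PSILC).** A random survival forest over
   all non-redundant CP scores, tuned by sweeping tree count, node size and
   mtry; candidates are ranked by out-of-bag (OOB) error and the Cox
   coefficient of their predicted score on an internal validation third.
5. **Contextual synthetic lethality.** Cell lines are scored with the
   fitted signature and split at the discovery cut-off; CRISPR gene-effect
   profiles are screened for genes whose knockout is selectively
   deleterious in the high-score group, with commonly essential genes
   flagged and excluded.

## The models and their assumptions

### Differential expression and variance

The default differential-expression test is a pooled-variance two-group
t-test with empirical-Bayes moderation: gene-wise pooled variances
$s_g^2$ (df $d = n_1 + n_2 - 2$) are shrunk towards a common prior
$s_0^2$ with prior df $d_0$,

$$\tilde{s}_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},$$

and the moderated t-statistic is referred to a t distribution with
$d + d_0$ df. The prior is fitted by matching the mean and excess variance
of $\log s_g^2$ to a scaled inverse chi-square (digamma/trigamma moment
identities); when the observed spread of log-variances does not exceed its
sampling noise the prior df is infinite and all genes share the pooled
common variance. A plain Welch t-test is available via
`method = "welch"`. Significance uses both a fold-change floor
(|log2 FC| > 1) and an FDR bound (BH q < 0.001), applied within the
analysis.

The variance test is the conventional two-sided F ratio on
$s^2_\mathrm{tumour}/s^2_\mathrm{normal}$; the published selection is
directional, so the significant set additionally requires the tumour SD to
exceed both the normal SD and an absolute floor of 0.5 log2 units, with a
very stringent FDR bound (q < 1e-15) reflecting how heavy-tailed variance
statistics are at cohort scale. Which variance test the upstream tooling
used is not fully specified in the literature this follows; the F-test is
the standard choice and the directional filters dominate the outcome.

### Pathway clustering

Similarity between pathways is the overlap coefficient
$|A \cap B| / \min(|A|, |B|)$, which (unlike Jaccard) equals 1 whenever one
set contains the other — exactly the nesting structure that motivates
collapsing. Clustering uses average linkage on $1 - \mathrm{overlap}$;
the linkage is configurable because the source method does not pin it down
(the ward reference in the original work concerns a results heatmap, not
this step). "Maximising both silhouette and the number of clusters" is made
precise as: among all k whose average silhouette is within a tolerance
(default 0.01) of the maximum, take the largest k. Singleton clusters get
silhouette 0, the usual convention.

### Relevance-based deredundancy

For a gene in several CPs, relevance in CP $c$ is
$R = (\#\text{co-members with } |\rho_\mathrm{Spearman}| > 0.3) / |c|$,
with the gene itself excluded from both numerator and denominator (a gene
cannot vouch for itself; excluding it from the denominator keeps $R \le 1$
exact). Correlations are computed on the discovery cohort only — the
assignment is part of the discovered model, so validation data must not
influence it. Ties in $R$ prefer the larger correlated count, then the
smaller CP id: deterministic and free of size bias.

### Cox models and risk groups

All proportional-hazards fits use Efron tie handling. Monotone-likelihood
separation (all early events on one side of a covariate) makes the partial
likelihood increase without bound; such fits are flagged and the
coefficient capped at |beta| = 10 so toy data cannot produce divergent
estimates. The score of a sample is strictly linear in its z-profile, so
risk-group cut-offs transfer across cohorts as long as each cohort is
z-scored internally. The boundary rule places the cut-off value itself in
the lower group, which keeps the discovery median split balanced for any
odd or even cohort size. Validation cohorts are standardized internally
(rather than reusing discovery means/SDs): this mirrors the practice of
applying a discovery model to independently processed validation sets and
makes the workflow robust to platform-level location shifts; reusing
discovery moments is possible by standardizing externally before calling
the scorers. Selected genes missing from a validation cohort contribute 0
(mean imputation on the z scale), with a coverage warning.

Prognostic evaluation pools risk groups across validation cohorts, as the
combined-validation design requires; if a pooled group has no events the
Wald hazard ratio is meaningless and a log-rank p-value is reported
instead. Adjusted models use the standard clinical covariates: age
dichotomised at 55 years, T-stage as factors, nodal status dichotomous,
tumour purity continuous. Proportional hazards are checked with the
Schoenfeld zero-slope test (global p attached to the fit). The
treatment-interaction model is `group * chemo` plus covariates; stratified
within-group treatment effects are suppressed whenever a group-by-arm cell
is empty or a stratum has fewer than two events.

### The survival forest

The aggregate signature is a random survival forest (log-rank splitting)
over CP scores, with ensemble mortality — the sum of the cumulative hazard
function over the event-time grid — as the continuous risk score. Any
monotone transform of this score would serve equally, because the
risk-group cut-offs are derived on the same scale. The sweep covers
ntrees 501–1001 (step 100), nodesize 10–15 and mtry 5–10: 216 candidates.
"Lowest OOB error and highest coefficient" is resolved as: sort candidates
by OOB error (1 − OOB concordance), keep the best decile (at least one),
and pick the candidate whose predicted score has the largest Cox
coefficient on the held-out internal-validation third. The 66/33 split is
stratified by event indicator, which stabilises small synthetic cohorts;
OOB error is computed on the 66% training portion, where out-of-bag
observations exist. Everything is deterministic given the seed: the split,
each forest, and hence the selected model and its cut-offs.

### The gene-effect screen

Gene-effect (GE) scores are knockout fitness effects: more negative means
stronger dependency, with −1 the median of known essentials. The
selectivity filter requires mean GE < −0.5 in the high group,
mean GE > −0.75 in the low group, and high mean below low mean — all
strict, as displayed in the source criteria. The one-sided Welch test
(high < low) is computed only when both groups have at least three lines;
an undefined p propagates as missing, never as 1. Essentiality (full-panel
median GE < −1) is annotated post hoc and excluded from the significant
list by default — an essential gene is not a useful selective target — with
a flag to retain them. "ERBB2 altered" means amplified or mutant. The
universe for the Fisher overlap of the two analyses (with and without
ERBB2-altered lines) is the set of genes evaluable in both, since no
universe is stated in the source.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, not
the raw technology. Normal samples are per-gene Gaussians on the log2
scale (gene means ~ N(7, 1.5), within-group SD 0.5 — a typical spread for
log2 microarray or log-CPM data); tumours add planted log2 fold-changes
and planted SD inflation. Survival follows exponential proportional
hazards: the linear predictor is the sum of planted per-gene coefficients
times within-cohort z-scores, events arrive at rate
$h_0 e^{\eta}$ (default $h_0$ = 0.08/year), censoring is independent
exponential (0.04/year) with an administrative cut at 10 years of
follow-up — the simplest law under which the downstream Cox fits are
correctly specified. Validation cohorts receive gene-wise additive mean
shifts (SD 0.3 log2 units) emulating the platform differences that
per-cohort standardization absorbs. The planted high-risk truth label is
$\eta$ above its cohort median, matching the median-dichotomisation
convention; a planted treatment interaction multiplies the hazard of
treated high-risk samples by $e^{\delta}$. Seeds are explicit arguments
everywhere and the generator restores the caller's RNG state.

What the generator does **not** emulate: probe structure, count noise,
normalization artefacts, correlated gene modules beyond the planted
pathway effects, informative censoring, or FFPE degradation. Passing tests
therefore demonstrate that the estimators recover the structure they
assume, at realistic sizes — not that any particular real cohort satisfies
those assumptions.

## Numerical choices and degenerate inputs

* Sample SDs use the n − 1 denominator throughout.
* Constant genes cannot be z-scored and are dropped with a warning;
  constant covariates are an error in Cox fits.
* An event exactly at the truncation horizon stays an event; only strictly
  later follow-up is administratively censored.
* The zero-count filter removes rows whose zero fraction is strictly
  greater than the threshold (exactly 75% zeros is retained).
* A score exactly at a cut-off goes to the lower group (two-group mode) or
  to intermediate (at q66 in three-group mode).
* Zero-variance genes are skipped (flagged) by the variance test rather
  than producing infinite F statistics; zero-variance Welch comparisons
  resolve by the direction of the mean difference.
* Identical pathways make the overlap distance matrix all-zero; clustering
  refuses such input rather than returning an arbitrary tree.

## Problem sizes used in the checks

The package's verification suite and `scripts/acceptance.R` run the whole
workflow at sizes chosen to be statistically meaningful yet quick on a
single CPU: end-to-end recovery uses 2000 genes, 25 pathways, a discovery
cohort of 150 tumours and three validation cohorts of 100, over 10 seeds;
differential-expression operating characteristics use 20 null replicates
of 2000 genes at 75/group; forest calibration uses 500 samples and 10 CP
features with a reduced sweep (the full 216-candidate grid is enumerated
and checked separately — the calibration properties do not depend on the
grid's extent); interaction recovery uses cohorts of 600 over 25 seeds,
with 100 null seeds for calibration. These are the package's own choices
of simulation size; all of them can be scaled up by the user through
`sim_config()` and the function arguments.

## Known limitations

* The per-CP score is the node-only variant (beta-weighted sum of selected
  genes' z-scores); network-edge-weighted variants are not implemented.
* No competing risks, cure fractions or time-varying coefficients.
* The generator's genes are independent within a cohort apart from planted
  effects, so relevance-based deredundancy on synthetic data mostly
  exercises the tie-breaking path unless correlations are planted
  explicitly.
* Count-based differential expression (negative binomial models) is out of
  scope; inputs are assumed to be approximately Gaussian on the log2
  scale.
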