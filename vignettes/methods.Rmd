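---
title: "Statistical methods for T21 immune-dysregulation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for T21 immune-dysregulation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t21immune)
```

## Scope and data model

`t21immune` implements the statistical machinery used to characterize
immune dysregulation in trisomy 21 (T21, Down syndrome) cohorts and to
evaluate immunomodulatory treatment trials: autoantibody positivity calling
from bead-array reactivities, composite interferon (IFN) and cytokine
scores against a euploid (D21) reference, mixed-model differential
abundance of plasma inflammatory markers, beta regression of immune-cell
cluster frequencies, and paired nonparametric endpoint evaluation over a
four-visit trial time course (baseline, weeks 2, 8, 16).

Upstream signal processing is out of scope by design: mass-cytometry
clustering, RNA-seq quantification and differential expression, and
immunoassay standard-curve fitting are consumed as input tables
(cluster-by-sample proportions, a gene-level differential-expression table,
and analyte-by-well concentrations respectively). The package therefore
ships a seeded synthetic-cohort generator that emulates the *statistical*
structure of each modality, so every stage is exercised end to end without
restricted participant data.

## Statistical primitives

All screens are built on a small set of exactly testable primitives.

* **Fisher's exact test** (`fisher_exact`): two-sided p-value by summing
  hypergeometric probabilities no larger than the observed table's
  (relative slack `1e-7` for floating-point ties). The reported effect is
  the sample odds ratio $ad/bc$; when a cell is zero the Haldane–Anscombe
  +0.5 correction keeps it finite. Two-sided tests are used throughout the
  package — sidedness is never varied per result, which is the
  conservative convention when both enrichment and depletion are reported.
* **Benjamini–Hochberg** (`benjamini_hochberg`): the step-up rule
  $q_{(i)} = \min_{j \ge i} m\, p_{(j)}/j$ capped at 1. Missing p-values
  are excluded from the family size $m$ and returned missing; this is why
  the adjustment is implemented here rather than delegated.
* **Mann–Whitney U** (`mann_whitney_u`): exact when $n_x n_y \le 400$ with
  no ties, otherwise a normal approximation with tie and continuity
  corrections. The unpaired effect summary is the difference of group
  medians.
* **Wilcoxon signed-rank** (`wilcoxon_signed_rank`): zero differences are
  dropped (the common signed-rank convention, flagged in the result);
  exact for $n \le 25$ untied absolute differences, otherwise midranks
  with the corrected normal approximation. The paired effect summary (MD)
  is the median of paired differences.
* **Quantiles** are fixed package-wide to linear interpolation (index
  $p\,(n-1)$, type 7), so the **extreme-outlier rule** — strictly more
  than $3\times$IQR below Q1 or above Q3 — is reproducible. The rule is
  strict at the fence and is invariant under positive affine transforms.

Each primitive is validated against an independent brute-force oracle
(full hypergeometric enumeration, the definitional step-up formula,
enumeration of group assignments and of $2^n$ sign vectors).

## Autoantibody pipeline

Reactivities are cleaned by a bead-count filter, then normalized per
sample in raw median-absolute-deviation units:
$\text{score} = (\text{MFI} - \text{median}_{\text{sample}})/
\text{MAD}_{\text{sample}}$. The raw MAD (no 1.4826 consistency constant)
is used deliberately so scores match this formula literally; samples with
zero MAD cannot be scaled and are excluded with an error record.
Positivity is a strict threshold at the 90th percentile of the euploid
control scores per antigen; controls are scored against their own
threshold, so about 10% of controls are positive by construction. The
over-representation screen excludes antigens with positive calls in fewer
than 18 samples — "detected" is interpreted as "called positive", the
only sample-level detection notion available — and both the percentile
and the detection threshold are exposed as parameters. Phenotype
associations require at least 5 cases and are BH-corrected within
phenotype across antigens (the family choice is recorded in the output).
Clinical assay rules are included as written: the anti-TPO index
$(S - N)/(P - N)$ with a 95th-percentile healthy-reference threshold,
and the ANA OD ratio rule (positive iff ratio $\ge 2.1$).

## Inflammatory markers

Preprocessing follows the plate conventions of multiplex immunoassays:
below-range wells are imputed with the per-plate, per-analyte minimum of
in-range calculated concentrations (above-range with the maximum),
duplicate wells are averaged per sample, and analytes with more than 10%
out-of-range wells are flagged but retained (removal is a configuration
choice, not the default). The operation is idempotent.

Differential abundance fits, per analyte,
`log2(concentration) ~ group + age + sex + (1 | source)` via
`lmerTest::lmer` (restricted maximum likelihood, Satterthwaite df); with a
single source level the model collapses to ordinary least squares and the
fallback is recorded. The group coefficient is the log2 fold-change;
BH correction runs across analytes at a 10% FDR.

For visualization and scoring, `adjust_covariates` removes
nuisance-covariate contributions estimated by a single multi-response
least-squares fit with *centered* covariate columns, preserving the
intercept and the kept (karyotype) effect. The **cytokine score** is the
sum of z-scores of TNF-α, IL-6, CRP and IP-10 on the log2, adjusted
scale — standardized against the euploid reference for cohort-context
comparisons, or within the pooled sample set ("self" mode) for trial
across-visit comparisons. Whether trial z-scores should pool visits or
standardize per visit is not externally constrained; pooling is
implemented (and recorded) because per-visit standardization would erase
the very treatment effect the endpoint measures.

## IFN transcriptional score

`select_isgs` is a pure filter on a candidate ISG list against a
differential-expression table: keep genes with $q < 0.1$ and fold-change
$\ge 1.5$ in T21 versus D21, excluding chromosome-21 genes (IFNAR2, MX1,
MX2 in the canonical candidate set), ordered by fold-change. The identity
of the resulting 16-gene set is data, never hard-coded. The IFN score is
the sum of gene-wise z-scores of log2(FPKM + 1) — the pseudocount is
configurable and needed because upstream quantification can produce
zeros — optionally covariate-adjusted, standardized against the euploid
reference or in self mode.

The trial ISG-response analysis computes, per gene and on-drug visit, the
arithmetic mean over participants of paired log2 expression ratios
against baseline (mean rather than median is the default, exposed as a
parameter), then tests the per-gene fold-change distribution against zero.
A one-sample U-test against a fixed null value reduces to the one-sample
signed-rank location test, which is what is implemented; q-values are BH
across visits.

## Cluster frequencies

Because no beta-regression package is part of this stack, the model is
fitted directly: maximum likelihood for a beta-distributed outcome with
logit mean link and a single constant precision $\phi$ per cluster
(`betareg_fit`), with analytic score functions, BFGS optimization started
from the least-squares fit of logit proportions, up to five jittered
restarts, and Wald inference from the observed information. Proportions
exactly at 0 or 1 have zero beta likelihood; the standard squeeze
$y' = (y(n-1) + 0.5)/n$ is applied when needed (toggleable; with the
squeeze disabled boundary values are an error). The reported
"fold-change" is the exponentiated group coefficient — by construction an
odds ratio of proportions; the field's label is kept, with this caveat.
Per cluster, extreme outliers are excluded per karyotype before fitting;
BH runs across clusters within one analysis level (clusters are analyzed
marginally, without a sum-to-one constraint, because each cluster is
modelled separately).

An independent cross-check against `glmmTMB`'s beta family, parameter
recovery at logit-effect 0.8 and precision 50, and the monotone decrease
of estimation error over $n \in \{50, 200, 800\}$ are part of the test
suite.

## Trial endpoints

Endpoints are composite scores (or single analytes/titers) compared
against baseline per visit with the exact paired signed-rank test; the MD
convention is the median of paired differences for paired tests and the
difference of group medians for unpaired comparisons, stated in the
output. BH runs across the three on-drug visits within an endpoint.
Visit-level immune-trigger annotations (vaccination, infection before a
blood draw) never silently delete data: every endpoint is reported both
including and excluding flagged visits. Titer trajectories are summarized
against an upper limit of normal (ULN) with strict thresholds: a baseline
exactly at the ULN is not "above", and crossing below requires a
baseline-positive participant.

## Synthetic-data generator

The generator is first-class, tested code. Its models are the simplest
ones consistent with each analysis's assumptions: Gaussian noise on the
log2 scale for marker concentrations and expression (matching the
analysis scale), multiplicative per-sample background times per-antigen
lognormal baseline with Bernoulli reactivity spikes for the bead array,
and beta draws with logit-linear means for cluster proportions. Duplicate
wells (two per sample, independent technical noise) exercise the
averaging rule; a configurable fraction of wells is flagged out of range
to exercise imputation; trial visits are fixed to B/W2/W8/W16 and receive
a multiplicative treatment effect, with optional immune-trigger
excursions that push a visit above baseline.

No quantitative generative model is available from the study itself, so
all effect sizes are configurable stand-ins fixed once at realistic
values: the bundled run (`run_pipeline`, `default_effects`) uses a cohort
of 120 T21 / 60 D21 (the autoantigen-arm sample sizes, the one modality
with both group sizes fully specified) and a 10-participant trial; ten of
54 analytes elevated by 0.5–1.5 log2 units; sixteen ISGs induced 1.5–2.5
fold; one antigen with a 9-fold spike-odds multiplier against base odds
1:9; cluster logit shifts of −0.7 and +0.5; batch SD 0.25 log2 units; a
30% treatment reduction; and a 5% per-visit trigger probability. The
generator deliberately omits realistic cross-modality covariance and
event-level single-cell structure, so passing tests demonstrate
correctness of the statistical machinery under its stated assumptions —
not robustness to the correlation structure of real cohorts.

## Numerical and validation choices

Seeds are explicit everywhere; generators save and restore the caller's
RNG state. Validation problem sizes were chosen to make the full suite
and the reproducibility report complete in a few minutes on one CPU:
20-seed operating-characteristic batteries (sensitivity ≥ 0.9 and
observed FDR ≤ 0.15 for the marker screen at n = 200/100; ≥ 90%
detection and first-rank rate for a 9-fold-enriched antigen at
n = 300/150; type-I rate within [0.03, 0.07] over ~1,000 null mixed-model
fits), exhaustive Fisher enumeration for all tables with row margins
≤ 15, and 1,000 random BH vectors. `run_pipeline` with the same seed is
bit-identical across runs, which the suite asserts at the file level.

Known limitations: the beta-regression implementation covers the constant-
precision, logit-link model only (no variable-precision regression); the
mixed model assumes a single random intercept for source; and composite
scores assume every component is present and non-degenerate in the
reference — all error explicitly rather than degrade silently.
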