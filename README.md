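# t21immune

Statistical toolkit for analyzing immune dysregulation in Down syndrome
(trisomy 21, T21) cohort studies and treatment trials. It is aimed at
biostatisticians and computational immunologists working with the typical
multi-modal readouts of such studies: autoantigen bead-array reactivities,
multiplex plasma inflammatory-marker panels, whole-blood transcriptomes,
mass-cytometry cluster frequencies, and four-visit trial time courses
(baseline, weeks 2/8/16).

## What it computes

* **Autoantibody positivity and screens.** Per-sample MAD normalization of
  bead-array MFI, `score = (MFI − median_sample) / MAD_sample` (raw MAD,
  no consistency constant); positivity strictly above the 90th percentile
  of euploid (D21) control scores per antigen; Fisher's-exact
  over-representation of positivity in T21 vs D21 (antigens positive in
  < 18 samples excluded) and autoantibody–phenotype associations (≥ 5
  cases), both Benjamini–Hochberg corrected at q < 0.1; per-sample
  autoantibody burden; anti-TPO index and ANA ratio rules.
* **Inflammatory markers.** Plate-level preprocessing (out-of-range
  imputation by per-plate min/max, duplicate-well averaging, >10%
  out-of-range flagging); per-karyotype 3×IQR extreme-outlier exclusion;
  differential abundance via `log2(conc) ~ group + age + sex +
  (1 | source)` mixed models; covariate adjustment; the composite
  **cytokine score** = Σ z-scores of TNF-α, IL-6, CRP, IP-10.
* **IFN transcriptional score.** ISG selection (q < 0.1, fold-change
  ≥ 1.5, chromosome-21 genes excluded) and the per-sample sum of gene-wise
  z-scores against the euploid reference; trial ISG-response analysis of
  paired log2 fold-changes versus baseline.
* **Cluster frequencies.** Maximum-likelihood beta regression (logit mean
  link, constant precision) of cell-cluster proportions on karyotype +
  age + sex, with fold-changes as exponentiated coefficients and BH
  correction across clusters.
* **Trial endpoints.** Exact paired Wilcoxon signed-rank tests of each
  on-drug visit versus baseline with median differences (MD), BH across
  visits within an endpoint, cohort-context Mann–Whitney comparisons on a
  shared reference scale, titer trajectories against an upper limit of
  normal, and dual reporting with/without immune-trigger-flagged visits.
* **Exact primitives** (Fisher, BH, Mann–Whitney U, signed-rank, type-7
  quantiles, 3×IQR outlier masks) implemented with explicit exact/
  asymptotic branch rules and validated against brute-force enumeration.
* **A seeded synthetic-cohort generator** for every modality, so the whole
  pipeline runs and is tested without access to restricted participant
  data.

## Worked example

```r
library(t21immune)
run <- run_pipeline(seed = 1)   # synthetic cohort (120 T21 / 60 D21) + trial

# cohort IFN score separation (euploid-referenced, Mann-Whitney)
k <- run$participants$karyotype
mann_whitney_u(run$ifn_scores$score[k == "T21"],
               run$ifn_scores$score[k == "D21"])
#> Mann-Whitney U test (asymptotic)
#>   statistic = 11868   p = 8.985e-28   effect = 29.99

# top of the autoantibody over-representation screen
head(run$overrepresentation, 1)
#>   antigen odds_ratio      p_value      q_value n_tested n_positive significant
#>     AG001   9.769697 2.313175e-08 1.110324e-06      175         68        TRUE

# trial cytokine-score endpoints (paired Wilcoxon vs baseline, BH over visits)
subset(run$endpoints, endpoint == "cytokine_score" & variant == "all_visits")
#>   visit n_pairs median_difference     q_value
#>      W2      10         -3.161492 0.002929688
#>      W8      10         -2.897404 0.083984375
#>     W16      10         -3.243349 0.002929688
```

The IFN effect (median difference ≈ 30 score units, i.e. ~16 genes each
shifted by roughly +2 reference SDs in this configuration) reflects the
generator's injected ISG fold-changes; the enriched antigen `AG001`
(spike-odds multiplier 9) tops the screen at OR ≈ 9.8; and the simulated
30% treatment reduction is detected at every on-drug visit (the W8
q-value is weakened by an immune-trigger excursion in one participant —
the `triggers_excluded` variant of the same table shows all three visits
at q < 0.004).

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/t21immune-pipeline.R --seed 1 --outdir run1
```

which writes the simulated inputs (`participants.csv`, `mfi.csv`,
`markers.csv`, `expression.csv`, `frequencies.csv`, `trial.csv`), a
provenance JSON, and all result tables under `run1/results/`.

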