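# Bundled end-to-end synthetic run: generate one cohort plus a trial time
# course and push them through every analysis stage. Serves as the worked
# example, the reproducibility check, and the input to the acceptance
# script.

#' Default effect sizes for the bundled synthetic run
#'
#' A single moderate, realistic configuration used by [run_pipeline()]:
#' ten of the 54 panel analytes elevated in T21 by 0.5-1.5 log2 units
#' (the four cytokine-score components among them), a mild age trend on
#' CRP, sixteen ISGs induced 1.5-2.5 fold, one antigen with a 9-fold
#' spike-odds enrichment, one depleted and one expanded cell cluster, and
#' a 30% multiplicative treatment reduction.
#'
#' @return An [effect_spec()].
#' @export
default_effects <- function() {
  elevated <- stats::setNames(seq(0.5, 1.5, length.out = 10),
                              default_analyte_names(10))
  isgs <- stats::setNames(seq(1.5, 2.5, length.out = 16),
                          sprintf("ISG%02d", 1:16))
  effect_spec(
    elevated_analytes = elevated,
    age_slopes = c("CRP" = 0.01),
    batch_sd = 0.25,
    isg_fold_changes = isgs,
    enriched_antigens = c("AG001" = 9),
    cluster_logit_shifts = c("C01" = -0.7, "C02" = 0.5),
    treatment_effect = 0.7
  )
}

#' Run the full synthetic cohort + trial analysis pipeline
#'
#' Generates a synthetic cohort (participants, autoantigen reactivities,
#' marker panel, ISG expression, cluster frequencies) and a trial time
#' course, then runs every analysis stage: autoantibody positivity and
#' over-representation, marker preprocessing and differential abundance,
#' cytokine and IFN scores against the euploid reference, beta-regression
#' differential cluster frequency, and the trial endpoint battery. With
#' `outdir` set, inputs, results and a provenance record are written as
#' CSV/JSON. The run is fully determined by `seed`.
#'
#' @param seed Integer master seed.
#' @param outdir Output directory, or `NULL` to skip writing.
#' @param n_t21,n_d21 Cohort group sizes.
#' @param n_trial Trial participants.
#' @param effects An [effect_spec()]; defaults to [default_effects()].
#' @param n_analytes,n_antigens,n_clusters Modality sizes.
#' @param trigger_prob Per-visit immune-trigger probability in the trial.
#' @return Invisibly, a list with all inputs and results.
#' @export
run_pipeline <- function(seed = 1, outdir = NULL,
                         n_t21 = 120, n_d21 = 60, n_trial = 10,
                         effects = default_effects(),
                         n_analytes = 54, n_antigens = 100,
                         n_clusters = 20, trigger_prob = 0.05) {
  spec <- cohort_spec(n_t21, n_d21, seed = seed)
  participants <- simulate_participants(spec)
  d21_ids <- participants$participant_id[participants$karyotype == "D21"]

  reactivity <- simulate_autoantigen_mfi(participants, effects,
                                         n_antigens = n_antigens,
                                         seed = seed + 101)
  panel <- simulate_marker_panel(participants, effects,
                                 n_analytes = n_analytes, seed = seed + 102)
  annotation <- default_gene_annotation()
  expression <- simulate_isg_expression(participants, effects, annotation,
                                        seed = seed + 103)
  de <- simulate_de_results(effects, annotation, seed = seed + 104)
  freqs <- simulate_cluster_frequencies(participants, effects,
                                        n_clusters = n_clusters,
                                        seed = seed + 105)
  trial <- simulate_trial_timecourse(n_trial, effects,
                                     trigger_prob = trigger_prob,
                                     seed = seed + 106)

  # -- autoantibody stage
  filtered <- qc_filter(reactivity)
  scores <- mad_transform(filtered)
  calls <- call_positivity(scores, intersect(d21_ids,
                                             colnames(scores$mad_scores)))
  overrep <- test_overrepresentation(calls, participants)
  hits <- overrep$antigen[overrep$significant]
  burden <- positivity_burden(calls,
                              if (length(hits)) hits else rownames(calls$calls))

  # -- marker stage
  prep <- preprocess_panel(panel)
  log2_conc <- log2(prep$concentrations)
  clean <- exclude_outliers_per_group(log2_conc, participants)
  da <- differential_abundance(clean, participants, log2_transform = FALSE)
  adjusted <- adjust_covariates(clean, participants)
  cyt <- cytokine_score(adjusted$values,
                        reference = intersect(d21_ids, colnames(clean)))

  # -- IFN stage
  isgs <- select_isgs(annotation$gene[annotation$is_isg], de)
  ifn <- ifn_score(expression, isgs, reference = d21_ids,
                   participants = participants,
                   adjust = c("age", "sex", "source"))

  # -- cytometry stage
  cluster_da <- cluster_differential_frequency(freqs, participants)

  # -- trial stage
  trial_cyt <- trial_composite_scores(trial, "marker")
  trial_ifn <- trial_composite_scores(trial, "expression")
  ep_cyt <- trial_endpoint_summary(
    stats::setNames(trial_cyt, sub("^score$", "value", names(trial_cyt))),
    endpoint = "cytokine_score")
  ep_ifn <- trial_endpoint_summary(
    stats::setNames(trial_ifn, sub("^score$", "value", names(trial_ifn))),
    endpoint = "ifn_score")
  isg_resp <- isg_response_analysis(trial)
  titers <- titer_trend(trial)

  out <- list(seed = seed, spec = spec, effects = effects,
              participants = participants, reactivity = reactivity,
              panel = panel, expression = expression, de = de,
              freqs = freqs, trial = trial,
              calls = calls, overrepresentation = overrep, burden = burden,
              differential_abundance = da, cytokine_scores = cyt,
              isg_set = isgs, ifn_scores = ifn,
              cluster_differential = cluster_da,
              trial_cytokine_scores = trial_cyt,
              trial_ifn_scores = trial_ifn,
              endpoints = rbind(ep_cyt, ep_ifn),
              isg_response = isg_resp, titer_trends = titers)

  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  invisible(out)
}

#' Write pipeline inputs and results to disk
#'
#' Emits the simulated input tables (`participants.csv`, `mfi.csv`,
#' `markers.csv`, `expression.csv`, `frequencies.csv`, `trial.csv`), a
#' provenance JSON echoing the generating parameters, and the analysis
#' result tables under `results/`.
#'
#' @param run A list returned by [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the output directory.
#' @export
write_pipeline_outputs <- function(run, outdir) {
  dir.create(file.path(outdir, "results"), recursive = TRUE,
             showWarnings = FALSE)
  wcsv <- function(x, f, rn = FALSE)
    utils::write.csv(x, file.path(outdir, f), row.names = rn)
  wcsv(run$participants, "participants.csv")
  wcsv(as.data.frame(run$reactivity$mfi), "mfi.csv", rn = TRUE)
  wcsv(as.data.frame(run$panel$concentrations), "markers.csv", rn = TRUE)
  wcsv(as.data.frame(run$expression), "expression.csv", rn = TRUE)
  wcsv(as.data.frame(run$freqs), "frequencies.csv", rn = TRUE)
  wcsv(run$trial, "trial.csv")
  jsonlite::write_json(
    list(seed = run$seed,
         cohort = unclass(run$spec),
         effects = lapply(unclass(run$effects), function(x)
           if (is.numeric(x) && !is.null(names(x))) as.list(x) else x)),
    file.path(outdir, "provenance.json"), auto_unbox = TRUE, digits = NA)

  wcsv(run$overrepresentation, "results/associations.csv")
  wcsv(data.frame(antigen = names(run$calls$thresholds),
                  threshold = run$calls$thresholds),
       "results/thresholds.csv")
  wcsv(run$burden$bands, "results/burden.csv")
  wcsv(run$differential_abundance, "results/marker_da.csv")
  wcsv(data.frame(sample = names(run$cytokine_scores$score),
                  cytokine_score = run$cytokine_scores$score),
       "results/cytokine_scores.csv")
  wcsv(data.frame(sample = names(run$ifn_scores$score),
                  ifn_score = run$ifn_scores$score),
       "results/ifn_scores.csv")
  wcsv(run$cluster_differential, "results/cluster_da.csv")
  wcsv(run$endpoints, "results/endpoint_summaries.csv")
  wcsv(run$isg_response$tests, "results/isg_response_tests.csv")
  wcsv(run$titer_trends, "results/titer_trends.csv")
  invisible(outdir)
}
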