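# Simulation-based operating characteristics of the analysis stages:
# sensitivity/FDR of the marker differential-abundance screen, type-I
# calibration, beta-regression parameter recovery, the autoantibody
# end-to-end screen, and trial endpoint power. Used by the validation
# suite and the reproducibility report.

#' Operating characteristics of the marker differential-abundance screen
#'
#' Simulates panels in which a subset of analytes is elevated in T21 by
#' log2 shifts spanning `delta_range`, runs the full preprocessing +
#' mixed-model pipeline, and averages sensitivity and observed false
#' discovery rate at `q < q_threshold` over seeds.
#'
#' @param n_seeds Number of simulated cohorts.
#' @param n_t21,n_d21 Group sizes.
#' @param n_analytes Panel size.
#' @param n_elevated Number of truly elevated analytes.
#' @param delta_range Range of injected log2 shifts.
#' @param q_threshold Significance threshold.
#' @param seed Master seed.
#' @return List: `sensitivity`, `fdr` (both averaged over seeds).
#' @export
oc_marker_da <- function(n_seeds = 20, n_t21 = 200, n_d21 = 100,
                         n_analytes = 54, n_elevated = 10,
                         delta_range = c(0.5, 1.5), q_threshold = 0.1,
                         seed = 1) {
  elevated <- default_analyte_names(n_elevated)
  eff <- effect_spec(elevated_analytes = stats::setNames(
    seq(delta_range[1], delta_range[2], length.out = n_elevated), elevated))
  sens <- fdr <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    sd_s <- seed + 7919L * s
    p <- simulate_participants(cohort_spec(n_t21, n_d21, seed = sd_s))
    panel <- simulate_marker_panel(p, eff, n_analytes = n_analytes,
                                   seed = sd_s + 1L)
    vals <- preprocess_panel(panel)$concentrations
    clean <- exclude_outliers_per_group(log2(vals), p)
    da <- differential_abundance(clean, p, log2_transform = FALSE,
                                 q_threshold = q_threshold)
    sig <- da$analyte[da$significant]
    tp <- sum(sig %in% elevated)
    sens[s] <- tp / n_elevated
    fdr[s] <- if (length(sig)) (length(sig) - tp) / length(sig) else 0
  }
  list(sensitivity = mean(sens), fdr = mean(fdr))
}

#' Type-I error calibration of the differential-abundance model
#'
#' Fits the mixed model to panels simulated under the global null and
#' reports the per-test rejection rate at `p < alpha`.
#'
#' @param n_fits Approximate total number of analyte fits.
#' @param n_t21,n_d21 Group sizes.
#' @param n_analytes Analytes per simulated panel.
#' @param alpha Nominal level.
#' @param seed Master seed.
#' @return List: `type1_rate`, `n_fits` actually performed.
#' @export
oc_marker_da_null <- function(n_fits = 1000, n_t21 = 100, n_d21 = 50,
                              n_analytes = 54, alpha = 0.05, seed = 1) {
  n_seeds <- ceiling(n_fits / n_analytes)
  ps <- numeric(0)
  for (s in seq_len(n_seeds)) {
    sd_s <- seed + 104729L * s
    p <- simulate_participants(cohort_spec(n_t21, n_d21, seed = sd_s))
    panel <- simulate_marker_panel(p, effect_spec(),
                                   n_analytes = n_analytes,
                                   seed = sd_s + 1L,
                                   out_of_range_frac = 0)
    vals <- preprocess_panel(panel)$concentrations
    da <- differential_abundance(vals, p)
    ps <- c(ps, da$p_value)
  }
  ps <- ps[!is.na(ps)]
  list(type1_rate = mean(ps < alpha), n_fits = length(ps))
}

#' Beta-regression parameter recovery
#'
#' Simulates beta-distributed proportions with logit mean
#' `intercept + effect * [group]` and the given precision, fits
#' [betareg_fit()], and reports the mean absolute error of the group
#' coefficient per sample size.
#'
#' @param n_values Sample sizes to evaluate.
#' @param n_seeds Replicates per sample size.
#' @param intercept,effect True logit-scale coefficients.
#' @param precision True beta precision.
#' @param seed Master seed.
#' @return Named numeric: mean absolute error per sample size.
#' @export
oc_betareg_recovery <- function(n_values = 300, n_seeds = 20,
                                intercept = -2, effect = 0.8,
                                precision = 50, seed = 1) {
  out <- vapply(n_values, function(n) {
    errs <- vapply(seq_len(n_seeds), function(s) {
      set.seed(seed + 31L * s + n)
      x <- cbind(1, stats::rbinom(n, 1, 0.5))
      mu <- stats::plogis(drop(x %*% c(intercept, effect)))
      y <- stats::rbeta(n, mu * precision, (1 - mu) * precision)
      betareg_fit(y, x)$coefficients$estimate[2] - effect
    }, numeric(1))
    mean(abs(errs))
  }, numeric(1))
  stats::setNames(out, n_values)
}

#' End-to-end operating characteristics of the autoantibody screen
#'
#' Simulates cohorts in which one antigen's reactivity-spike odds are
#' multiplied in T21 while all other antigens are null, runs QC, MAD
#' normalization, positivity calling and the over-representation screen,
#' and reports how often the enriched antigen is detected (q <
#' `q_threshold`), how often it has the smallest q, and the fraction of
#' null antigens called significant.
#'
#' @param n_seeds Number of simulated cohorts.
#' @param n_t21,n_d21 Group sizes.
#' @param n_null Number of null antigens alongside the enriched one.
#' @param multiplier Spike-odds multiplier for the enriched antigen.
#' @param q_threshold Significance threshold.
#' @param seed Master seed.
#' @return List: `frac_detected`, `frac_top`, `null_positive_rate`.
#' @export
oc_autoantibody_screen <- function(n_seeds = 20, n_t21 = 300, n_d21 = 150,
                                   n_null = 100, multiplier = 9,
                                   q_threshold = 0.1, seed = 1) {
  eff <- effect_spec(enriched_antigens = c(AG001 = multiplier))
  detected <- top <- logical(n_seeds)
  null_rate <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    sd_s <- seed + 5861L * s
    p <- simulate_participants(cohort_spec(n_t21, n_d21, seed = sd_s))
    r <- simulate_autoantigen_mfi(p, eff, n_antigens = n_null + 1,
                                  seed = sd_s + 1L)
    sc <- mad_transform(qc_filter(r))
    d21 <- intersect(p$participant_id[p$karyotype == "D21"],
                     colnames(sc$mad_scores))
    calls <- call_positivity(sc, d21)
    res <- test_overrepresentation(calls, p, q_threshold = q_threshold)
    hit <- res[res$antigen == "AG001", ]
    detected[s] <- nrow(hit) == 1 && hit$q_value < q_threshold
    top[s] <- nrow(hit) == 1 && hit$q_value <= min(res$q_value)
    nulls <- res[res$antigen != "AG001", ]
    null_rate[s] <- if (nrow(nulls)) mean(nulls$q_value < q_threshold) else 0
  }
  list(frac_detected = mean(detected), frac_top = mean(top),
       null_positive_rate = mean(null_rate))
}

#' Trial endpoint detection rate
#'
#' Simulates trial time courses with the given multiplicative treatment
#' effect on the cytokine-score components, evaluates the paired
#' endpoint battery, and reports the fraction of seeds in which every
#' on-drug visit reaches `q < q_threshold` and the overall fraction of
#' significant visits.
#'
#' @param n_seeds Number of simulated trials.
#' @param n_participants Trial size.
#' @param treatment_effect Multiplicative effect at on-drug visits
#'   (1 = null).
#' @param q_threshold Significance threshold.
#' @param seed Master seed.
#' @return List: `frac_all_visits`, `frac_visits_significant`.
#' @export
oc_trial_endpoints <- function(n_seeds = 20, n_participants = 10,
                               treatment_effect = 0.7, q_threshold = 0.1,
                               seed = 1) {
  all_visits <- logical(n_seeds)
  frac_sig <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    tr <- simulate_trial_timecourse(n_participants, effect_spec(),
                                    treatment_effect = treatment_effect,
                                    trigger_prob = 0,
                                    seed = seed + 613L * s,
                                    n_isg_genes = 4)
    v <- trial_composite_scores(tr, "marker")
    names(v)[names(v) == "score"] <- "value"
    summ <- trial_endpoint_summary(v, q_threshold = q_threshold)
    dec <- summ$significant & summ$median_difference < 0
    all_visits[s] <- all(if (treatment_effect < 1) dec else summ$significant)
    frac_sig[s] <- mean(summ$significant)
  }
  list(frac_all_visits = mean(all_visits),
       frac_visits_significant = mean(frac_sig))
}
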