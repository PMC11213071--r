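score_values <- function(trial, assay = "marker") {
  sc <- trial_composite_scores(trial, assay)
  names(sc)[names(sc) == "score"] <- "value"
  sc
}

test_that("paired_visit_test: null gives MD 0 / p 1; uniform drop is exact", {
  flat <- simulate_trial_timecourse(6, effect_spec(), treatment_effect = 1,
                                    trigger_prob = 0, seed = 101,
                                    n_isg_genes = 4, within_sd = 0)
  v <- score_values(flat)
  res <- paired_visit_test(v, "W2")
  expect_equal(res$median_difference, 0)
  expect_equal(res$p_value, 1)

  down <- simulate_trial_timecourse(10, effect_spec(),
                                    treatment_effect = 0.7,
                                    trigger_prob = 0, seed = 102,
                                    n_isg_genes = 4, within_sd = 0.05)
  v2 <- score_values(down)
  res2 <- paired_visit_test(v2, "W2")
  expect_equal(res2$n_pairs, 10)
  expect_equal(res2$p_value, 2 / 1024)   # all ten participants decreased
  expect_lt(res2$median_difference, 0)
  expect_equal(res2$direction, "decrease")
  expect_error(paired_visit_test(v2[v2$participant_id == "TR01", ], "W2"),
               "fewer than 2")
})

test_that("endpoint summary corrects across visits without lowering p", {
  down <- simulate_trial_timecourse(10, effect_spec(),
                                    treatment_effect = 0.7,
                                    trigger_prob = 0, seed = 103,
                                    n_isg_genes = 4, within_sd = 0.1)
  v <- score_values(down)
  summ <- trial_endpoint_summary(v, endpoint = "cytokine_score")
  expect_equal(nrow(summ), 3)
  expect_true(all(summ$q_value >= summ$p_value - 1e-15))
  expect_true(all(summ$variant == "all_visits"))
})

test_that("exclusion annotation reports both analysis variants", {
  tr <- simulate_trial_timecourse(10, effect_spec(), treatment_effect = 0.7,
                                  trigger_prob = 0, seed = 104,
                                  n_isg_genes = 4, within_sd = 0.05)
  # no flags: include/exclude identical
  v0 <- score_values(tr)
  s0 <- trial_endpoint_summary(v0)
  expect_true(all(s0$variant == "all_visits"))

  # flag one W8 visit and inject an excursion value there
  tr2 <- tr
  sel <- tr2$participant_id == "TR05" & tr2$visit == "W8"
  tr2$value[sel] <- tr2$value[sel] * 4
  tr2 <- exclusion_annotator(tr2, data.frame(participant_id = "TR05",
                                             visit = "W8"))
  v2 <- score_values(tr2)
  s2 <- trial_endpoint_summary(v2)
  expect_setequal(unique(s2$variant), c("all_visits", "triggers_excluded"))

  # the trigger-excluded analysis has less dispersed paired differences
  d_all <- with(merge(v2[v2$visit == "B", c("participant_id", "value")],
                      v2[v2$visit == "W8", c("participant_id", "value")],
                      by = "participant_id"), value.y - value.x)
  d_exc <- d_all[-5]
  expect_lt(var(d_exc), var(d_all))
  expect_error(exclusion_annotator(tr, data.frame(participant_id = "TR99",
                                                  visit = "W8")),
               "unknown")
})

test_that("titer trajectories against the ULN", {
  tr <- data.frame(
    participant_id = rep(c("A", "B", "C"), each = 3),
    visit = rep(c("B", "W8", "W16"), 3),
    assay = "titer", name = "anti-TPO",
    value = c(100, 80, 70,    # above ULN, decreasing, never crosses
              65, 55, 58,     # crosses below ULN
              59, 70, 40),    # baseline 59 is not above ULN 60
    trigger = FALSE, stringsAsFactors = FALSE)
  res <- titer_trend(tr, uln = 60)
  expect_equal(res$above_uln, c(TRUE, TRUE, FALSE))
  expect_equal(res$all_visits_decreased, c(TRUE, TRUE, FALSE))
  expect_equal(res$crossed_below_uln, c(FALSE, TRUE, FALSE))

  # missing visit: partial trajectory, annotated
  tr_miss <- tr[-2, ]
  res2 <- titer_trend(tr_miss, uln = 60)
  expect_equal(res2$n_visits_missing[res2$participant_id == "A"], 1)
  expect_error(titer_trend(tr[tr$visit != "B", ], uln = 60), "baseline")
})

test_that("cohort context comparison shares the reference scale", {
  p <- simulate_participants(cohort_spec(100, 100, seed = 105))
  ann <- default_gene_annotation()
  isg16 <- sprintf("ISG%02d", 1:16)
  fc <- 2^(0.75 * 0.5)
  eff <- effect_spec(isg_fold_changes = setNames(rep(fc, 16), isg16),
                     batch_sd = 0)
  expr <- simulate_isg_expression(p, eff, ann, seed = 106, age_slope = 0,
                                  sex_effect = 0)
  d21 <- p$participant_id[p$karyotype == "D21"]
  cohort_sc <- ifn_score(expr, isg16, reference = d21, pseudocount = 0)

  # trial samples standardized with the cohort reference
  trial_expr <- matrix(rlnorm(16 * 6, 4, 0.5), 16, 6,
                       dimnames = list(isg16, paste0("TR", 1:6)))
  trial_sc <- apply_score_reference(log2(trial_expr), cohort_sc)
  meta <- data.frame(sample_id = paste0("TR", 1:6),
                     visit = rep(c("B", "W2"), 3))
  res <- cohort_context_comparison(cohort_sc, p, trial_sc, meta)
  expect_lt(res$cohort_test$p_value, 0.001)
  expect_gt(res$cohort_test$effect, 0)    # T21 median above D21 median
  expect_equal(sort(as.character(res$visit_summary$visit)),
               sort(c("B", "W2")))

  # identical distributions: p near 1
  null_sc <- cohort_sc
  null_sc$score <- rep(cohort_sc$score[d21], 2)[seq_along(cohort_sc$score)]
  names(null_sc$score) <- names(cohort_sc$score)
  res0 <- cohort_context_comparison(null_sc, p, trial_sc, meta)
  expect_gt(res0$cohort_test$p_value, 0.5)

  # mismatched standardization references are an error
  other <- ifn_score(expr, isg16, reference = "self", pseudocount = 0)
  expect_error(cohort_context_comparison(cohort_sc, p, other, meta),
               "mismatched")
})

test_that("endpoint computations are bit-reproducible from the same seed", {
  r1 <- simulate_trial_timecourse(8, default_effects(), trigger_prob = 0.1,
                                  seed = 107, n_isg_genes = 10)
  r2 <- simulate_trial_timecourse(8, default_effects(), trigger_prob = 0.1,
                                  seed = 107, n_isg_genes = 10)
  expect_identical(r1, r2)
  expect_identical(trial_endpoint_summary(score_values(r1)),
                   trial_endpoint_summary(score_values(r2)))
})
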