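make_panel <- function(conc, status, sample_id, plate) {
  structure(list(concentrations = conc, status = status,
                 wells = data.frame(well_id = colnames(conc),
                                    sample_id = sample_id, plate = plate,
                                    stringsAsFactors = FALSE),
                 analyte_flags = setNames(rep(FALSE, nrow(conc)),
                                          rownames(conc)),
                 collapsed = FALSE),
            class = "marker_panel")
}

test_that("preprocess_panel imputes, averages duplicates, flags analytes", {
  conc <- matrix(c(100, 110, NA, 9, 5, 7), 1, 6,
                 dimnames = list("A1", paste0("W", 1:6)))
  status <- matrix(c("in_range", "in_range", "below_range", rep("in_range",
                                                                3)),
                   1, 6, dimnames = dimnames(conc))
  panel <- make_panel(conc, status,
                      sample_id = rep(c("S1", "S2", "S3"), each = 2),
                      plate = rep("PL1", 6))
  pp <- preprocess_panel(panel)
  expect_equal(unname(pp$concentrations["A1", "S1"]), 105)  # mean(100, 110)
  # below-range well imputed with the plate minimum (5), averaged with 9
  expect_equal(unname(pp$concentrations["A1", "S2"]), 7)
  # 1 of 6 wells out of range (17% > 10%): flagged
  expect_true(pp$analyte_flags["A1"])

  # idempotence
  pp2 <- preprocess_panel(pp)
  expect_equal(pp2$concentrations, pp$concentrations)
  expect_equal(pp2$analyte_flags, pp$analyte_flags)

  # 2 of 20 wells (10%) is not > 10%: unflagged
  conc2 <- matrix(rlnorm(20), 1, 20,
                  dimnames = list("A1", paste0("W", 1:20)))
  status2 <- matrix("in_range", 1, 20, dimnames = dimnames(conc2))
  status2[1, 1:2] <- "above_range"
  panel2 <- make_panel(conc2, status2, sample_id = paste0("S", 1:20),
                       plate = rep("PL1", 20))
  expect_false(preprocess_panel(panel2)$analyte_flags["A1"])
  # 3 of 20 (15%) is: flagged
  status2[1, 3] <- "above_range"
  panel3 <- make_panel(conc2, status2, sample_id = paste0("S", 1:20),
                       plate = rep("PL1", 20))
  expect_true(preprocess_panel(panel3)$analyte_flags["A1"])

  # no in-range value on a plate makes imputation impossible
  statusX <- matrix("below_range", 1, 6, dimnames = dimnames(conc))
  panelX <- make_panel(conc, statusX, rep(c("S1", "S2", "S3"), each = 2),
                       rep("PL1", 6))
  expect_error(preprocess_panel(panelX), "imputation impossible")
})

test_that("outliers are excluded within (analyte, group) strata only", {
  vals <- rbind(A1 = c(1:9, 100, 1:10))
  colnames(vals) <- paste0("S", 1:20)
  groups <- setNames(rep(c("T21", "D21"), each = 10), colnames(vals))
  out <- exclude_outliers_per_group(vals, groups)
  expect_true(is.na(out["A1", "S10"]))       # 100 in the T21 stratum
  expect_equal(sum(is.na(out)), 1)           # D21 untouched
  log <- attr(out, "exclusions")
  expect_equal(log$sample, "S10")
  expect_equal(log$group, "T21")

  tame <- rbind(A1 = rep(1:10, 2))
  colnames(tame) <- paste0("S", 1:20)
  out2 <- exclude_outliers_per_group(tame, groups)
  expect_false(anyNA(out2))
})

test_that("differential abundance recovers injected shifts; OLS collapse", {
  p <- simulate_participants(cohort_spec(200, 100, n_sources = 4, seed = 61))
  eff <- effect_spec(elevated_analytes = c("TNF-alpha" = 1))
  panel <- simulate_marker_panel(p, eff, n_analytes = 8, seed = 62,
                                 out_of_range_frac = 0)
  vals <- preprocess_panel(panel)$concentrations
  da <- differential_abundance(vals, p)
  hit <- da[da$analyte == "TNF-alpha", ]
  expect_equal(hit$model, "lmm")
  expect_lt(abs(hit$log2_fc - 1), 0.3)
  expect_true(hit$significant)

  # single source level collapses to ordinary least squares
  p1 <- p; p1$source <- "S1"
  da1 <- differential_abundance(vals, p1)
  expect_true(all(da1$model == "ols"))
  y <- log2(vals["TNF-alpha", ])
  ref <- lm(y ~ factor(karyotype, c("D21", "T21")) + age + factor(sex),
            data = p1)
  expect_equal(da1$log2_fc[da1$analyte == "TNF-alpha"],
               unname(coef(ref)[2]), tolerance = 1e-10)
})

test_that("adjust_covariates removes nuisance trends, keeps group effects", {
  p <- simulate_participants(cohort_spec(60, 60, seed = 63))
  vals <- matrix(rnorm(5 * 120), 5, 120,
                 dimnames = list(paste0("A", 1:5), p$participant_id))
  vals <- sweep(vals, 2, 0.05 * p$age, "+")          # age trend
  vals[, p$karyotype == "T21"] <- vals[, p$karyotype == "T21"] + 1

  adj <- adjust_covariates(vals, p, covariates = c("age", "sex", "source"))
  for (i in 1:5) {
    sl <- coef(lm(adj$values[i, ] ~ p$age))[2]
    expect_lt(abs(sl), 0.01)
  }
  # group difference survives adjustment
  gd <- rowMeans(adj$values[, p$karyotype == "T21"]) -
    rowMeans(adj$values[, p$karyotype == "D21"])
  expect_true(all(abs(gd - 1) < 0.45))

  # constant covariate leaves values unchanged
  p2 <- p; p2$source <- "S1"
  adj2 <- adjust_covariates(vals, p2, covariates = "source", keep = NULL)
  expect_equal(adj2$values, vals)
})

test_that("adjust_covariates matches limma::removeBatchEffect", {
  skip_if_not_installed("limma")
  p <- simulate_participants(cohort_spec(40, 40, seed = 64))
  vals <- matrix(rnorm(4 * 80), 4, 80,
                 dimnames = list(paste0("A", 1:4), p$participant_id))
  vals <- sweep(vals, 2, 0.08 * p$age, "+")
  mine <- adjust_covariates(vals, p, covariates = "age")$values
  design <- model.matrix(~ factor(p$karyotype, c("D21", "T21")))
  ref <- limma::removeBatchEffect(
    vals, covariates = scale(p$age, scale = FALSE), design = design)
  expect_equal(unname(mine), unname(ref), tolerance = 1e-8)
})

test_that("cytokine score is a reference-standardized sum of z-scores", {
  set.seed(65)
  comp <- c("TNF-alpha", "IL-6", "CRP", "IP-10")
  vals <- matrix(rnorm(4 * 30), 4, 30,
                 dimnames = list(comp, paste0("S", 1:30)))
  ref_ids <- paste0("S", 1:15)
  cs <- cytokine_score(vals, reference = ref_ids)
  expect_lt(abs(mean(cs$score[ref_ids])), 1e-9)

  # sample sitting at the reference mean scores 0; +1 SD per component -> 4
  at_mean <- cs$reference$mean
  plus1 <- at_mean + cs$reference$sd
  probe <- cbind(vals, M = at_mean, P = plus1)
  cs2 <- cytokine_score(probe, reference = ref_ids)
  expect_lt(abs(cs2$score["M"]), 1e-9)
  expect_lt(abs(cs2$score["P"] - 4), 1e-9)

  # per-analyte affine rescaling applied to samples and reference cancels
  resc <- vals * 3 + 2
  expect_equal(cytokine_score(resc, reference = ref_ids)$score, cs$score,
               tolerance = 1e-9)

  expect_error(cytokine_score(vals[1:3, ]), "absent")
  degenerate <- vals; degenerate["CRP", ref_ids] <- 5
  expect_error(cytokine_score(degenerate, reference = ref_ids),
               "degenerate")
})
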