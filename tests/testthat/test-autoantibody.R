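make_reactivity <- function(mfi, beads = NULL) {
  if (is.null(beads)) beads <- matrix(60, nrow(mfi), ncol(mfi),
                                      dimnames = dimnames(mfi))
  structure(list(mfi = mfi, bead_counts = beads,
                 antigen_meta = data.frame(antigen = rownames(mfi),
                                           protein = rownames(mfi))),
            class = "antigen_reactivity")
}

test_that("qc_filter masks low-bead reactions and drops sparse antigens", {
  mfi <- matrix(100, 4, 10,
                dimnames = list(paste0("AG", 1:4), paste0("S", 1:10)))
  beads <- matrix(60, 4, 10, dimnames = dimnames(mfi))

  # untouched at min_beads = 0
  r0 <- qc_filter(make_reactivity(mfi, beads), min_beads = 0)
  expect_identical(r0$mfi, mfi)

  # a single 3-bead reaction goes missing at min_beads = 20
  beads1 <- beads; beads1[2, 3] <- 3
  r1 <- qc_filter(make_reactivity(mfi, beads1), min_beads = 20)
  expect_true(is.na(r1$mfi[2, 3]))
  expect_equal(sum(is.na(r1$mfi)), 1)

  # antigen missing in 60% of samples is dropped at a 50% threshold
  beads2 <- beads; beads2[1, 1:6] <- 2
  r2 <- qc_filter(make_reactivity(mfi, beads2), min_beads = 20,
                  max_missing_frac = 0.5)
  expect_false("AG1" %in% rownames(r2$mfi))
  expect_equal(attr(r2, "qc_log")$antigens_dropped, "AG1")
  beads3 <- matrix(2, 4, 10)
  expect_error(qc_filter(make_reactivity(mfi, beads3), min_beads = 20),
               "all antigens")
})

test_that("mad_transform yields median-0 / MAD-1 samples, raw MAD units", {
  mfi <- matrix(c(10, 20, 30), 3, 1,
                dimnames = list(paste0("AG", 1:3), "S1"))
  sc <- mad_transform(make_reactivity(mfi))
  expect_equal(unname(sc$mad_scores[, 1]), c(-1, 0, 1))

  set.seed(31)
  big <- matrix(rlnorm(50 * 8), 50, 8,
                dimnames = list(paste0("AG", 1:50), paste0("S", 1:8)))
  sc2 <- mad_transform(big)
  med <- apply(sc2$mad_scores, 2, median)
  madv <- apply(sc2$mad_scores, 2, function(v) median(abs(v - median(v))))
  expect_true(all(abs(med) < 1e-9))
  expect_true(all(abs(madv - 1) < 1e-9))

  # per-sample positive affine rescaling leaves scores unchanged
  resc <- sweep(sweep(big, 2, runif(8, 0.5, 4), "*"), 2, runif(8, -5, 5), "+")
  expect_equal(mad_transform(resc)$mad_scores, sc2$mad_scores)

  const <- big; const[, 3] <- 7
  sc3 <- mad_transform(const)
  expect_equal(sc3$excluded_samples, "S3")
  expect_error(mad_transform(matrix(1, 5, 2)), "usable")
})

test_that("call_positivity thresholds at the control percentile", {
  scores <- structure(list(
    mad_scores = matrix(c(0:9, 8.2, 9), 1, 12,
                        dimnames = list("AG1", c(paste0("C", 1:10),
                                                 "T1", "T2"))),
    excluded_samples = character()), class = "reactivity_scores")
  calls <- call_positivity(scores, paste0("C", 1:10))
  expect_equal(unname(calls$thresholds["AG1"]), 8.1)
  expect_true(calls$calls["AG1", "T1"])   # 8.2 > 8.1
  expect_true(calls$calls["AG1", "T2"])
  # exactly one of the ten controls (score 9) exceeds its own threshold
  expect_equal(sum(calls$calls["AG1", paste0("C", 1:10)]), 1)
  expect_error(call_positivity(scores, paste0("C", 1:3)), "control")
})

test_that("clinical assay rules: anti-TPO index and ANA ratio", {
  expect_equal(tpo_index(10, 10, 110), 0)
  expect_equal(tpo_index(110, 10, 110), 1)
  expect_equal(tpo_index(60, 10, 110), 0.5)
  expect_error(tpo_index(5, 10, 10), "assay failure")

  healthy <- seq(0, 0.19, by = 0.01)  # 95th percentile = 0.1805
  pos <- tpo_positive(c(0.05, 0.2), healthy)
  expect_identical(as.logical(pos), c(FALSE, TRUE))

  expect_true(ana_call(2.1, 1))
  expect_false(ana_call(2.0999, 1))
  expect_false(ana_call(0, 1))
  expect_error(ana_call(1, 0), "assay failure")
})

test_that("over-representation excludes rarely detected antigens", {
  n_t <- 50; n_d <- 25
  samples <- c(paste0("T", 1:n_t), paste0("D", 1:n_d))
  groups <- setNames(rep(c("T21", "D21"), c(n_t, n_d)), samples)
  cm <- matrix(FALSE, 3, n_t + n_d,
               dimnames = list(c("rare", "enriched", "flat"), samples))
  cm["rare", 1:17] <- TRUE                       # 17 < 18: excluded
  cm["enriched", c(1:30, 51:53)] <- TRUE         # 30/50 vs 3/25
  cm["flat", c(1:20, 51:60)] <- TRUE             # 40% in both groups
  calls <- structure(list(calls = cm, thresholds = c(rare = 1, enriched = 1,
                                                     flat = 1),
                          reference_group = "controls"),
                     class = "positivity_calls")
  res <- test_overrepresentation(calls, groups, min_detected = 18)
  expect_false("rare" %in% res$antigen)
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  enr <- res[res$antigen == "enriched", ]
  expect_equal(enr$odds_ratio, (30 * 22) / (20 * 3))
  expect_equal(enr$p_value, oracle_fisher_p(30, 20, 3, 22),
               tolerance = 1e-10)
  flat <- res[res$antigen == "flat", ]
  expect_equal(flat$odds_ratio, 1)
  expect_warning(test_overrepresentation(calls, groups, min_detected = 999),
                 "detection filter")
})

test_that("positivity burden conserves counts and partitions samples", {
  cm <- matrix(c(TRUE, TRUE, FALSE,
                 TRUE, FALSE, FALSE,
                 FALSE, FALSE, FALSE), 3, 3, byrow = TRUE,
               dimnames = list(paste0("AG", 1:3), paste0("S", 1:3)))
  calls <- structure(list(calls = cm, thresholds = rep(1, 3),
                          reference_group = "controls"),
                     class = "positivity_calls")
  b <- positivity_burden(calls, band_breaks = c(0, 1))
  expect_equal(unname(b$counts), c(2, 1, 0))
  expect_equal(sum(b$counts), sum(cm))
  expect_equal(sum(b$bands$proportion), 1)
  expect_equal(b$bands$band, c("0", "1", "2+"))
  expect_equal(unname(b$counts["S3"]), 0)
  expect_error(positivity_burden(calls, "AGX"), "unknown antigen")
})

test_that("phenotype associations respect the minimum-case rule", {
  n <- 100
  ids <- paste0("S", seq_len(n))
  cm <- matrix(FALSE, 2, n, dimnames = list(c("AG1", "AG2"), ids))
  pheno <- data.frame(participant_id = ids,
                      tiny = c(rep(TRUE, 4), rep(FALSE, n - 4)),
                      cooccur = rep(c(TRUE, FALSE), each = n / 2))
  # antigen positive only in cases: 10 of 50 cases, 0 of 50 controls
  cm["AG1", 1:10] <- TRUE
  calls <- structure(list(calls = cm, thresholds = c(AG1 = 1, AG2 = 1),
                          reference_group = "controls"),
                     class = "positivity_calls")
  res <- test_phenotype_associations(calls, pheno, min_cases = 5)
  expect_false("tiny" %in% res$phenotype)      # 4 cases < 5: skipped
  ag1 <- res[res$phenotype == "cooccur" & res$antigen == "AG1", ]
  expect_equal(ag1$p_value, oracle_fisher_p(10, 40, 0, 50),
               tolerance = 1e-10)
  expect_equal(ag1$odds_ratio, (10.5 * 50.5) / (40.5 * 0.5))
  expect_true(all(res$q_value >= res$p_value - 1e-12))
})

test_that("positivity calls are invariant to per-sample affine MFI scaling", {
  p <- tiny_participants(20, 15, seed = 51)
  r <- simulate_autoantigen_mfi(p, effect_spec(), n_antigens = 30, seed = 52,
                                low_bead_frac = 0)
  sc <- mad_transform(r)
  ctl <- p$participant_id[p$karyotype == "D21"]
  c1 <- call_positivity(sc, ctl)
  r2 <- r
  r2$mfi <- sweep(sweep(r$mfi, 2, runif(ncol(r$mfi), 0.5, 3), "*"),
                  2, runif(ncol(r$mfi), 0, 50), "+")
  c2 <- call_positivity(mad_transform(r2), ctl)
  expect_identical(c1$calls, c2$calls)
})
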