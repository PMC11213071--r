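# Autoantibody pipeline: bead-array QC, per-sample MAD normalization,
# control-percentile positivity calling, over-representation and
# phenotype-association screens, and clinical assay rules (anti-TPO index,
# ANA ratio).

#' Bead-count quality filter for an antigen reactivity matrix
#'
#' Reactions with fewer than `min_beads` beads are set missing; antigens
#' and samples whose missing fraction then exceeds `max_missing_frac` are
#' dropped. The exclusion log is attached as attribute `"qc_log"`.
#'
#' @param reactivity An `antigen_reactivity` object
#'   (see [simulate_autoantigen_mfi()]) with `mfi` and `bead_counts`.
#' @param min_beads Minimum acceptable bead count (>= 0).
#' @param max_missing_frac Maximum tolerated fraction of missing reactions
#'   per antigen or sample.
#' @return The filtered `antigen_reactivity` object.
#' @export
qc_filter <- function(reactivity, min_beads = 20, max_missing_frac = 0.5) {
  stopifnot(inherits(reactivity, "antigen_reactivity"))
  if (min_beads < 0) stop("min_beads must be >= 0", call. = FALSE)
  mfi <- reactivity$mfi
  low <- reactivity$bead_counts < min_beads
  mfi[low] <- NA_real_

  antigen_miss <- rowMeans(is.na(mfi))
  keep_a <- antigen_miss <= max_missing_frac
  if (!any(keep_a))
    stop("all antigens fail the bead-count QC", call. = FALSE)
  sample_miss <- colMeans(is.na(mfi[keep_a, , drop = FALSE]))
  keep_s <- sample_miss <= max_missing_frac

  out <- reactivity
  out$mfi <- mfi[keep_a, keep_s, drop = FALSE]
  out$bead_counts <- reactivity$bead_counts[keep_a, keep_s, drop = FALSE]
  out$antigen_meta <- reactivity$antigen_meta[
    reactivity$antigen_meta$antigen %in% rownames(out$mfi), , drop = FALSE]
  attr(out, "qc_log") <- list(
    n_reactions_masked = sum(low),
    antigens_dropped = rownames(reactivity$mfi)[!keep_a],
    samples_dropped = colnames(reactivity$mfi)[!keep_s])
  out
}

#' Per-sample MAD transformation of reactivities
#'
#' Adjusts for sample-specific background by expressing each MFI value in
#' raw median-absolute-deviation units of its own sample:
#' `score = (MFI - median_sample(MFI)) / MAD_sample(MFI)`, where the MAD
#' is the raw median absolute deviation (no consistency constant), so the
#' scores match the normalization formula literally. Samples whose MAD is
#' zero cannot be scaled and are excluded with an error record.
#'
#' @param reactivity An `antigen_reactivity` object or a plain
#'   antigen x sample matrix.
#' @return A `reactivity_scores` object: `mad_scores` (antigen x sample)
#'   plus `excluded_samples`. Per retained sample the score median is 0
#'   and the score MAD is 1.
#' @export
mad_transform <- function(reactivity) {
  mfi <- if (inherits(reactivity, "antigen_reactivity")) reactivity$mfi
         else as.matrix(reactivity)
  med <- apply(mfi, 2, stats::median, na.rm = TRUE)
  mad_raw <- vapply(seq_len(ncol(mfi)), function(j)
    stats::median(abs(mfi[, j] - med[j]), na.rm = TRUE), numeric(1))
  n_vals <- colSums(!is.na(mfi))
  bad <- mad_raw == 0 | !is.finite(mad_raw) | n_vals < 3
  if (all(bad))
    stop("no sample has a usable (non-zero) MAD", call. = FALSE)
  scores <- sweep(mfi[, !bad, drop = FALSE], 2, med[!bad], "-")
  scores <- sweep(scores, 2, mad_raw[!bad], "/")
  structure(list(mad_scores = scores,
                 excluded_samples = colnames(mfi)[bad]),
            class = "reactivity_scores")
}

#' Call autoantibody positivity against a control-derived threshold
#'
#' Per antigen, the positivity threshold is the given percentile (linear
#' interpolation) of the MAD scores of the control (euploid) samples; a
#' sample is positive when its score is strictly above the threshold.
#' Control samples are scored against their own threshold like everyone
#' else, so by construction about 10% of controls are positive for each
#' antigen at the default 90th percentile.
#'
#' @param scores A `reactivity_scores` object from [mad_transform()].
#' @param control_ids Sample ids forming the reference (control) group.
#' @param percentile Threshold percentile of the control scores.
#' @param min_controls Minimum non-missing control scores per antigen;
#'   antigens below this are skipped with a warning.
#' @return A `positivity_calls` object: `calls` (antigen x sample
#'   logical), `thresholds` (named numeric, MAD units),
#'   `reference_group`.
#' @export
call_positivity <- function(scores, control_ids, percentile = 90,
                            min_controls = 5) {
  stopifnot(inherits(scores, "reactivity_scores"))
  s <- scores$mad_scores
  control_ids <- intersect(control_ids, colnames(s))
  if (length(control_ids) < min_controls)
    stop("fewer than ", min_controls, " control samples available",
         call. = FALSE)
  ctl <- s[, control_ids, drop = FALSE]
  n_ctl <- rowSums(!is.na(ctl))
  usable <- n_ctl >= min_controls
  if (!all(usable))
    warning(sum(!usable), " antigen(s) skipped: fewer than ", min_controls,
            " control values", call. = FALSE)
  thr <- apply(ctl[usable, , drop = FALSE], 1, stats::quantile,
               probs = percentile / 100, na.rm = TRUE, type = 7,
               names = FALSE)
  calls <- s[usable, , drop = FALSE] > thr
  structure(list(calls = calls,
                 thresholds = stats::setNames(thr, rownames(calls)),
                 reference_group = "controls", percentile = percentile),
            class = "positivity_calls")
}

#' Normalized anti-TPO index
#'
#' `(sample signal - negative control signal) /
#'  (positive control signal - negative control signal)`, so the negative
#' control maps to 0 and the positive control to 1.
#'
#' @param sample_signal Numeric assay signal(s).
#' @param negative_control,positive_control Control signals; the positive
#'   control must exceed the negative control.
#' @return Numeric index, same length as `sample_signal`.
#' @export
tpo_index <- function(sample_signal, negative_control, positive_control) {
  if (positive_control <= negative_control)
    stop("assay failure: positive control does not exceed negative control",
         call. = FALSE)
  (sample_signal - negative_control) /
    (positive_control - negative_control)
}

#' Anti-TPO positivity against a healthy-reference percentile
#'
#' The positivity threshold (upper limit of normal) is the given
#' percentile of healthy-control index values; samples strictly above it
#' are positive.
#'
#' @param indices Sample index values (from [tpo_index()]).
#' @param healthy_reference Index values of healthy control samples.
#' @param percentile Threshold percentile (default 95).
#' @return Logical vector of positivity calls, with the threshold as
#'   attribute `"threshold"`.
#' @export
tpo_positive <- function(indices, healthy_reference, percentile = 95) {
  thr <- stats::quantile(healthy_reference, percentile / 100, names = FALSE,
                         type = 7, na.rm = TRUE)
  structure(indices > thr, threshold = thr)
}

#' ANA positivity by OD ratio
#'
#' Positive when `sample OD / negative-control OD >= cutoff` (default
#' 2.1); strictly below is negative.
#'
#' @param sample_od Sample optical density (OD450).
#' @param negative_control_od Negative-control OD (> 0).
#' @param cutoff Ratio cutoff.
#' @return Logical vector.
#' @export
ana_call <- function(sample_od, negative_control_od, cutoff = 2.1) {
  if (negative_control_od <= 0)
    stop("assay failure: non-positive negative-control OD", call. = FALSE)
  (sample_od / negative_control_od) >= cutoff
}

#' Over-representation of autoantibody positivity between karyotype groups
#'
#' Per antigen, a 2x2 Fisher's exact test of positivity in cases versus
#' controls, excluding antigens with positive calls in fewer than
#' `min_detected` samples overall (rarely detected reactivities), with
#' Benjamini-Hochberg correction across tested antigens.
#'
#' @param calls A `positivity_calls` object.
#' @param groups Group label per sample: named character vector or a
#'   participant table with `participant_id` and `karyotype`.
#' @param case_level,control_level Labels of the case and control groups.
#' @param min_detected Minimum total positive calls for an antigen to be
#'   tested.
#' @param q_threshold Significance threshold on q.
#' @return Data frame: `antigen`, `odds_ratio`, `p_value`, `q_value`,
#'   `n_tested`, `n_positive`, `significant`.
#' @export
test_overrepresentation <- function(calls, groups, case_level = "T21",
                                    control_level = "D21",
                                    min_detected = 18, q_threshold = 0.1) {
  stopifnot(inherits(calls, "positivity_calls"))
  groups <- .group_lookup(groups)
  cm <- calls$calls
  g <- groups[colnames(cm)]
  case <- !is.na(g) & g == case_level
  ctrl <- !is.na(g) & g == control_level
  if (!any(case) || !any(ctrl))
    stop("both groups must be non-empty", call. = FALSE)

  n_pos <- rowSums(cm, na.rm = TRUE)
  tested <- n_pos >= min_detected
  if (!any(tested)) {
    warning("no antigen passes the detection filter", call. = FALSE)
    return(data.frame(antigen = character(), odds_ratio = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      n_tested = integer(), n_positive = integer(),
                      significant = logical()))
  }
  res <- lapply(rownames(cm)[tested], function(ag) {
    v <- cm[ag, ]
    a <- sum(v[case], na.rm = TRUE); b <- sum(!v[case], na.rm = TRUE)
    cc <- sum(v[ctrl], na.rm = TRUE); d <- sum(!v[ctrl], na.rm = TRUE)
    ft <- fisher_exact(a, b, cc, d)
    data.frame(antigen = ag, odds_ratio = ft$effect, p_value = ft$p_value,
               n_tested = a + b + cc + d, n_positive = a + cc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- benjamini_hochberg(out$p_value)
  out$significant <- out$q_value < q_threshold
  out[order(out$q_value, out$p_value),
      c("antigen", "odds_ratio", "p_value", "q_value", "n_tested",
        "n_positive", "significant")]
}

.group_lookup <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("participant_id", "karyotype") %in% names(groups)))
    stats::setNames(as.character(groups$karyotype), groups$participant_id)
  } else {
    if (is.null(names(groups)))
      stop("groups must be named by sample id", call. = FALSE)
    stats::setNames(as.character(groups), names(groups))
  }
}

#' Per-sample autoantibody burden
#'
#' Counts, per sample, positive calls within an antigen subset (typically
#' the antigens found over-represented in the case group) and summarizes
#' the cohort as banded proportions.
#'
#' @param calls A `positivity_calls` object.
#' @param antigen_subset Antigens to count over (default: all).
#' @param band_breaks Increasing non-negative integers; counts are banded
#'   as `0..b1`, `b1+1..b2`, ..., `> b_last`. The default
#'   `c(0, 5)` gives bands 0, 1-5 and 6+.
#' @return List with `counts` (named integer per sample) and `bands`
#'   (data frame of band label, n, proportion).
#' @export
positivity_burden <- function(calls, antigen_subset = NULL,
                              band_breaks = c(0, 5)) {
  stopifnot(inherits(calls, "positivity_calls"))
  cm <- calls$calls
  if (is.null(antigen_subset)) antigen_subset <- rownames(cm)
  if (length(antigen_subset) == 0)
    stop("antigen subset is empty", call. = FALSE)
  missing_ag <- setdiff(antigen_subset, rownames(cm))
  if (length(missing_ag))
    stop("unknown antigen(s): ", paste(missing_ag, collapse = ", "),
         call. = FALSE)
  counts <- colSums(cm[antigen_subset, , drop = FALSE], na.rm = TRUE)
  breaks <- c(-Inf, band_breaks, Inf)
  labels <- character(length(band_breaks) + 1)
  prev <- 0
  for (i in seq_along(band_breaks)) {
    labels[i] <- if (band_breaks[i] == prev) as.character(prev)
                 else paste0(prev, "-", band_breaks[i])
    prev <- band_breaks[i] + 1
  }
  labels[length(labels)] <- paste0(prev, "+")
  band <- cut(counts, breaks = breaks, labels = labels)
  tab <- table(band)
  list(counts = counts,
       bands = data.frame(band = names(tab), n = as.integer(tab),
                          proportion = as.numeric(tab) / sum(tab),
                          stringsAsFactors = FALSE))
}

#' Autoantibody-phenotype association screen
#'
#' Within a cohort (typically the case karyotype only), tests each
#' (antigen, phenotype) pair for over-representation of antigen
#' positivity in phenotype cases versus controls with Fisher's exact
#' test. Phenotypes with fewer than `min_cases` cases are skipped.
#' Benjamini-Hochberg correction is applied within each phenotype across
#' antigens (the multiple-testing family; recorded in the output
#' attribute `"bh_family"`).
#'
#' @param calls A `positivity_calls` object.
#' @param phenotypes Data frame: `participant_id` plus one logical column
#'   per phenotype flag (may contain `NA`).
#' @param min_cases Minimum number of cases for a phenotype to be tested.
#' @return Data frame: `phenotype`, `antigen`, `odds_ratio`, `p_value`,
#'   `q_value`, `n_cases`, `n_controls`.
#' @export
test_phenotype_associations <- function(calls, phenotypes, min_cases = 5) {
  stopifnot(inherits(calls, "positivity_calls"),
            "participant_id" %in% names(phenotypes))
  cm <- calls$calls
  flags <- setdiff(names(phenotypes), "participant_id")
  out <- list()
  for (ph in flags) {
    f <- stats::setNames(phenotypes[[ph]], phenotypes$participant_id)
    f <- f[intersect(names(f), colnames(cm))]
    f <- f[!is.na(f)]
    if (sum(f) < min_cases) next
    rows <- lapply(rownames(cm), function(ag) {
      v <- cm[ag, names(f)]
      a <- sum(v & f, na.rm = TRUE);  b <- sum(!v & f, na.rm = TRUE)
      cc <- sum(v & !f, na.rm = TRUE); d <- sum(!v & !f, na.rm = TRUE)
      ft <- fisher_exact(a, b, cc, d)
      data.frame(phenotype = ph, antigen = ag, odds_ratio = ft$effect,
                 p_value = ft$p_value, n_cases = a + b, n_controls = cc + d,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$q_value <- benjamini_hochberg(tab$p_value)
    out[[ph]] <- tab
  }
  if (length(out) == 0)
    return(structure(data.frame(phenotype = character(),
                                antigen = character(),
                                odds_ratio = numeric(), p_value = numeric(),
                                n_cases = integer(), n_controls = integer(),
                                q_value = numeric()),
                     bh_family = "within phenotype, across antigens"))
  structure(do.call(rbind, out),
            bh_family = "within phenotype, across antigens",
            row.names = NULL)
}
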