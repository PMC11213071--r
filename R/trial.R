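# Trial time-course endpoints: composite scores per visit, paired
# signed-rank tests versus baseline with BH correction across visits,
# placement of trial samples on the cohort reference scale, titer
# trajectories against an upper limit of normal, and visit-level exclusion
# annotation.

#' Composite scores for trial samples, pooled-visit standardization
#'
#' Builds the per-(participant, visit) composite score for a trial
#' modality: log2 values of the component features, z-scored against the
#' pooled trial samples across visits (`"self"` mode, the convention for
#' across-visit comparisons), summed over components.
#'
#' @param trial A `trial_table`.
#' @param assay `"marker"` or `"expression"`.
#' @param components Feature names summed into the score (default: all
#'   features of the modality).
#' @param pseudocount Added before log2.
#' @return Data frame: `participant_id`, `visit`, `score`, `trigger`.
#' @export
trial_composite_scores <- function(trial, assay = "marker",
                                   components = NULL, pseudocount = 0) {
  d <- trial[trial$assay == assay, , drop = FALSE]
  if (nrow(d) == 0) stop("no '", assay, "' records in trial", call. = FALSE)
  if (is.null(components)) components <- unique(d$name)
  d$col <- paste(d$participant_id, d$visit, sep = ".")
  cols <- unique(d$col)
  m <- matrix(NA_real_, length(components), length(cols),
              dimnames = list(components, cols))
  idx <- cbind(match(d$name, components), match(d$col, cols))
  ok <- !is.na(idx[, 1])
  m[idx[ok, , drop = FALSE]] <- d$value[ok]
  cs <- .composite_score(log2(m + pseudocount), components, "self", "self")
  info <- unique(d[, c("participant_id", "visit", "trigger", "col")])
  info <- info[match(cols, info$col), ]
  data.frame(participant_id = info$participant_id, visit = info$visit,
             score = unname(cs$score), trigger = info$trigger,
             stringsAsFactors = FALSE)
}

#' Paired visit-versus-baseline endpoint test
#'
#' Wilcoxon signed-rank test of an endpoint at one visit against
#' baseline, over participants with both measurements. The effect is the
#' median of paired differences (MD).
#'
#' @param values Data frame `participant_id`, `visit`, `value` (and
#'   optionally `trigger`).
#' @param visit Visit to compare against baseline.
#' @param baseline Baseline visit label.
#' @param exclude_flagged Drop (participant, visit) records with
#'   `trigger = TRUE` before pairing.
#' @return One-row data frame: `visit`, `n_pairs`, `median_difference`,
#'   `statistic`, `p_value`, `direction`.
#' @export
paired_visit_test <- function(values, visit, baseline = "B",
                              exclude_flagged = FALSE) {
  if (exclude_flagged && "trigger" %in% names(values))
    values <- values[!(values$trigger & values$visit == visit), ,
                     drop = FALSE]
  b <- values[values$visit == baseline, c("participant_id", "value")]
  v <- values[values$visit == visit, c("participant_id", "value")]
  mm <- merge(b, v, by = "participant_id", suffixes = c("_b", "_v"))
  if (nrow(mm) < 2)
    stop("fewer than 2 complete (baseline, ", visit, ") pairs",
         call. = FALSE)
  tt <- wilcoxon_signed_rank(mm$value_b, mm$value_v)
  data.frame(visit = visit, n_pairs = nrow(mm),
             median_difference = tt$effect, statistic = tt$statistic,
             p_value = tt$p_value,
             direction = c("decrease", "none",
                           "increase")[sign(tt$effect) + 2],
             stringsAsFactors = FALSE)
}

#' Endpoint summary across trial visits
#'
#' Runs [paired_visit_test()] at each on-drug visit and corrects the
#' p-values across visits within the endpoint (the multiple-testing
#' family for trial endpoints). When trigger annotations are present the
#' analysis is reported twice: including and excluding flagged visits.
#'
#' @param values Data frame `participant_id`, `visit`, `value`
#'   (optionally `trigger`).
#' @param visits On-drug visits.
#' @param endpoint Endpoint label carried into the output.
#' @param q_threshold Significance threshold on q.
#' @return Data frame with one row per visit (and per analysis variant
#'   when triggers exist): endpoint, variant, visit, n_pairs,
#'   median_difference, p_value, q_value, significant.
#' @export
trial_endpoint_summary <- function(values, visits = c("W2", "W8", "W16"),
                                   endpoint = "endpoint",
                                   q_threshold = 0.1) {
  run <- function(excl) {
    res <- do.call(rbind, lapply(visits, function(v)
      paired_visit_test(values, v, exclude_flagged = excl)))
    res$q_value <- benjamini_hochberg(res$p_value)
    res$significant <- res$q_value < q_threshold
    res$variant <- if (excl) "triggers_excluded" else "all_visits"
    res
  }
  out <- run(FALSE)
  if ("trigger" %in% names(values) && any(values$trigger, na.rm = TRUE))
    out <- rbind(out, run(TRUE))
  out$endpoint <- endpoint
  out[, c("endpoint", "variant", "visit", "n_pairs", "median_difference",
          "statistic", "p_value", "q_value", "significant")]
}

#' Standardize new samples against an existing score's reference
#'
#' Applies the per-feature reference mean/SD stored in a
#' `composite_score` to a new value matrix (same features, same scale),
#' placing the new samples on the same standardized scale.
#'
#' @param values Feature x sample matrix on the reference score's scale.
#' @param reference_score A `composite_score` whose reference statistics
#'   are reused.
#' @return A `composite_score` for the new samples.
#' @export
apply_score_reference <- function(values, reference_score) {
  stopifnot(inherits(reference_score, "composite_score"))
  comp <- reference_score$components
  absent <- setdiff(comp, rownames(values))
  if (length(absent))
    stop("component(s) absent from matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  ref <- reference_score$reference
  z <- sweep(sweep(values[comp, , drop = FALSE], 1, ref$mean, "-"),
             1, ref$sd, "/")
  structure(list(score = colSums(z), z = z, components = comp,
                 reference = ref),
            class = "composite_score")
}

#' Cohort-context comparison of trial scores
#'
#' Places cohort and trial composite scores side by side on the shared
#' euploid-reference scale: a Mann-Whitney U test of D21 versus T21
#' cohort scores (median difference = difference of group medians) plus
#' per-visit medians for the trial samples. Errors if the two score
#' series were standardized against different references.
#'
#' @param cohort_scores A `composite_score` for the cohort samples,
#'   standardized against the euploid reference.
#' @param cohort_groups Karyotype per cohort sample (named vector or
#'   participant table).
#' @param trial_scores A `composite_score` for trial samples on the same
#'   reference (see [apply_score_reference()]).
#' @param trial_meta Data frame `sample_id`, `visit` describing the trial
#'   score columns.
#' @param case_level,control_level Cohort group labels.
#' @return List with `cohort_test` (Mann-Whitney result, T21 vs D21) and
#'   `visit_summary` (per-visit n and median score).
#' @export
cohort_context_comparison <- function(cohort_scores, cohort_groups,
                                      trial_scores, trial_meta,
                                      case_level = "T21",
                                      control_level = "D21") {
  stopifnot(inherits(cohort_scores, "composite_score"),
            inherits(trial_scores, "composite_score"))
  if (!isTRUE(all.equal(cohort_scores$reference$mean,
                        trial_scores$reference$mean)) ||
      !isTRUE(all.equal(cohort_scores$reference$sd,
                        trial_scores$reference$sd)))
    stop("mismatched standardization references", call. = FALSE)
  g <- .group_lookup(cohort_groups)[names(cohort_scores$score)]
  x <- cohort_scores$score[!is.na(g) & g == case_level]
  y <- cohort_scores$score[!is.na(g) & g == control_level]
  tt <- mann_whitney_u(x, y)

  sc <- trial_scores$score[trial_meta$sample_id]
  vs <- stats::aggregate(list(median_score = sc),
                         by = list(visit = trial_meta$visit),
                         FUN = stats::median)
  vs$n <- as.integer(table(trial_meta$visit)[as.character(vs$visit)])
  list(cohort_test = tt, visit_summary = vs)
}

#' Autoantibody titer trajectories against an upper limit of normal
#'
#' Per participant: whether the baseline titer is strictly above the
#' upper limit of normal (ULN), the per-visit change from baseline,
#' whether every observed follow-up visit decreased relative to
#' baseline, and whether a baseline-positive participant crossed below
#' the ULN on treatment. Missing visits yield a partial trajectory with
#' the missing count annotated.
#'
#' @param trial A `trial_table`.
#' @param titer Name of the titer analyte.
#' @param uln Upper limit of normal, assay units.
#' @param visits Follow-up visits considered (default W8 and W16, the
#'   titer assessment points).
#' @return Data frame per participant: `baseline`, `above_uln`,
#'   `all_visits_decreased`, `crossed_below_uln`, `n_visits_missing`;
#'   per-visit changes as attribute `"changes"`.
#' @export
titer_trend <- function(trial, titer = "anti-TPO", uln = 60,
                        visits = c("W8", "W16")) {
  d <- trial[trial$assay == "titer" & trial$name == titer, , drop = FALSE]
  if (nrow(d) == 0) stop("no titer records for '", titer, "'", call. = FALSE)
  ids <- unique(d$participant_id)
  base <- d[d$visit == "B", ]
  if (!all(ids %in% base$participant_id))
    stop("baseline titers missing for: ",
         paste(setdiff(ids, base$participant_id), collapse = ", "),
         call. = FALSE)
  b <- stats::setNames(base$value, base$participant_id)

  changes <- list()
  rows <- lapply(ids, function(id) {
    vals <- vapply(visits, function(v) {
      x <- d$value[d$participant_id == id & d$visit == v]
      if (length(x)) x[1] else NA_real_
    }, numeric(1))
    changes[[id]] <<- data.frame(participant_id = id, visit = visits,
                                 value = vals, change = vals - b[id],
                                 stringsAsFactors = FALSE)
    obs <- vals[!is.na(vals)]
    data.frame(
      participant_id = id, baseline = unname(b[id]),
      above_uln = unname(b[id] > uln),
      all_visits_decreased = length(obs) > 0 && all(obs < b[id]),
      crossed_below_uln = unname(b[id] > uln) && any(obs < uln),
      n_visits_missing = sum(is.na(vals)),
      stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            changes = do.call(rbind, unname(changes)), uln = uln)
}

#' Annotate trial visits with exclusion flags
#'
#' Marks visit-level immune-trigger (or other exception) flags on a
#' trial table so downstream endpoint tests can be reported both with
#' and without the flagged visits. References to (participant, visit)
#' pairs absent from the table are an error.
#'
#' @param trial A `trial_table`.
#' @param annotations Data frame `participant_id`, `visit` (optionally
#'   `reason`).
#' @return The trial table with `trigger = TRUE` on annotated visits.
#' @export
exclusion_annotator <- function(trial, annotations) {
  stopifnot(all(c("participant_id", "visit") %in% names(annotations)))
  key <- paste(trial$participant_id, trial$visit)
  for (i in seq_len(nrow(annotations))) {
    k <- paste(annotations$participant_id[i], annotations$visit[i])
    hit <- key == k
    if (!any(hit))
      stop("unknown (participant, visit): ", k, call. = FALSE)
    trial$trigger[hit] <- TRUE
  }
  trial
}
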