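# Interferon transcriptional scores: ISG selection from a
# differential-expression table, the composite IFN score, and the trial
# ISG-response analysis.

#' Select interferon-stimulated genes for the IFN score
#'
#' Pure filter over a candidate ISG list against a differential-expression
#' result table: keep genes significantly changed (`q < q_max`) with
#' fold-change at least `fc_floor` in the case group, excluding genes on
#' `exclude_chrom` (on chromosome 21, trisomic dosage would confound the
#' score). Output is ordered by fold-change (descending) with the gene
#' name as tiebreak.
#'
#' @param candidates Character vector of candidate gene names.
#' @param de Differential-expression table with columns `gene`,
#'   `log2_fc`, `q_value`, `chromosome`.
#' @param fc_floor Minimum fold-change (linear scale).
#' @param q_max Significance threshold.
#' @param exclude_chrom Chromosome label to exclude.
#' @return An `isg_set`: list with `genes` (ordered) and `params`.
#' @export
select_isgs <- function(candidates, de, fc_floor = 1.5, q_max = 0.1,
                        exclude_chrom = "chr21") {
  stopifnot(all(c("gene", "log2_fc", "q_value", "chromosome") %in% names(de)))
  missing_genes <- setdiff(candidates, de$gene)
  if (length(missing_genes))
    stop("candidate(s) not annotated in the DE table: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  d <- de[match(candidates, de$gene), ]
  keep <- d$q_value < q_max & 2^d$log2_fc >= fc_floor &
    d$chromosome != exclude_chrom
  d <- d[keep, , drop = FALSE]
  if (nrow(d) == 0)
    stop("no candidate passes the selection rule; consider relaxing ",
         "fc_floor or q_max", call. = FALSE)
  d <- d[order(-d$log2_fc, d$gene), ]
  structure(list(genes = d$gene,
                 params = list(fc_floor = fc_floor, q_max = q_max,
                               exclude_chrom = exclude_chrom)),
            class = "isg_set")
}

#' Composite interferon (IFN) transcriptional score
#'
#' Sum of gene-wise z-scores over the selected ISG set. Expression is
#' log2-transformed with a pseudocount and optionally adjusted for
#' nuisance covariates (age, sex, batch) before standardization. In
#' reference mode z-scores use the mean and SD of the euploid reference
#' samples; in `"self"` mode standardization pools the provided samples
#' (trial across-visit comparisons).
#'
#' @param expression Gene x sample matrix of positive (FPKM-like) values.
#' @param isgs An `isg_set` from [select_isgs()], or a character vector
#'   of gene names.
#' @param reference Sample ids of the reference population, or `"self"`.
#' @param participants Participant table, required when `adjust` is
#'   non-empty.
#' @param adjust Nuisance covariates to remove before standardization
#'   (passed to [adjust_covariates()] with `keep = "karyotype"` when
#'   present, else `keep = NULL`).
#' @param pseudocount Added before log2 (expression pipelines upstream of
#'   this package produce zeros).
#' @return A `composite_score` (see [cytokine_score()]).
#' @export
ifn_score <- function(expression, isgs, reference = "self",
                      participants = NULL, adjust = character(0),
                      pseudocount = 1) {
  genes <- if (inherits(isgs, "isg_set")) isgs$genes else as.character(isgs)
  absent <- setdiff(genes, rownames(expression))
  if (length(absent))
    stop("ISG(s) absent from the expression matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  values <- log2(expression[genes, , drop = FALSE] + pseudocount)
  if (length(adjust)) {
    if (is.null(participants))
      stop("participants required for covariate adjustment", call. = FALSE)
    keep <- if ("karyotype" %in% names(participants)) "karyotype" else NULL
    values <- adjust_covariates(values, participants, covariates = adjust,
                                keep = keep)$values
  }
  .composite_score(values, genes, reference, "euploid controls")
}

#' ISG response to treatment across trial visits
#'
#' For every gene in the ISG universe and every on-drug visit, computes
#' the fold-change as the mean (or median) over participants of the
#' paired `log2(expression_visit / expression_baseline)`; then, per
#' visit, tests the location of the per-gene fold-changes against zero
#' with the one-sample signed-rank location test (the one-sample analog
#' of a U-test against zero change), with Benjamini-Hochberg correction
#' across visits. Participants lacking a baseline sample are excluded
#' with a warning.
#'
#' @param trial A `trial_table` (see [simulate_trial_timecourse()]) or
#'   equivalent long data frame with `participant_id`, `visit`, `assay`,
#'   `name`, `value`.
#' @param universe Genes analyzed (default: every gene in the
#'   expression modality).
#' @param visits On-drug visits to test.
#' @param aggregate `"mean"` or `"median"` over participants.
#' @return List with `fold_changes` (data frame `gene`, `visit`,
#'   `log2_fc`) and `tests` (per visit: statistic, `p_value`, `q_value`,
#'   `median_log2_fc`, `n_genes`).
#' @export
isg_response_analysis <- function(trial, universe = NULL,
                                  visits = c("W2", "W8", "W16"),
                                  aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  agg_fun <- if (aggregate == "mean") mean else stats::median
  expr <- trial[trial$assay == "expression", , drop = FALSE]
  if (nrow(expr) == 0) stop("no expression records in trial", call. = FALSE)
  if (is.null(universe)) universe <- unique(expr$name)
  absent <- setdiff(universe, expr$name)
  if (length(absent))
    stop("universe gene(s) missing from trial expression: ",
         paste(absent, collapse = ", "), call. = FALSE)
  expr <- expr[expr$name %in% universe, , drop = FALSE]

  has_baseline <- unique(expr$participant_id[expr$visit == "B"])
  dropped <- setdiff(unique(expr$participant_id), has_baseline)
  if (length(dropped)) {
    warning("participant(s) without baseline excluded: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    expr <- expr[expr$participant_id %in% has_baseline, , drop = FALSE]
  }

  base <- expr[expr$visit == "B", c("participant_id", "name", "value")]
  names(base)[3] <- "baseline"
  fc_rows <- list()
  tests <- list()
  for (v in visits) {
    ev <- expr[expr$visit == v, c("participant_id", "name", "value")]
    mm <- merge(ev, base, by = c("participant_id", "name"))
    mm$lfc <- log2(mm$value / mm$baseline)
    per_gene <- tapply(mm$lfc, mm$name, agg_fun)
    per_gene <- per_gene[universe[universe %in% names(per_gene)]]
    fc_rows[[v]] <- data.frame(gene = names(per_gene), visit = v,
                               log2_fc = as.numeric(per_gene),
                               stringsAsFactors = FALSE)
    tt <- wilcoxon_signed_rank(rep(0, length(per_gene)),
                               as.numeric(per_gene))
    tests[[v]] <- data.frame(visit = v, statistic = tt$statistic,
                             p_value = tt$p_value,
                             median_log2_fc = stats::median(per_gene),
                             n_genes = length(per_gene),
                             stringsAsFactors = FALSE)
  }
  tests <- do.call(rbind, tests)
  tests$q_value <- benjamini_hochberg(tests$p_value)
  list(fold_changes = do.call(rbind, fc_rows), tests = tests)
}
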