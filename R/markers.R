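# Multiplex immunoassay panel analysis: out-of-range imputation and
# duplicate-well averaging, per-group extreme-outlier exclusion, mixed-model
# differential abundance on the log2 scale, covariate adjustment for
# visualization/scoring, and the composite cytokine score.

#' Preprocess a multiplex marker panel
#'
#' Applies the standard plate-level cleanup: wells below the fit-curve
#' range are imputed with the per-plate, per-analyte minimum of in-range
#' calculated concentrations (above-range with the maximum); duplicate
#' wells are averaged per sample; and analytes with more than
#' `flag_fraction` of wells out of range are flagged (retained, not
#' dropped). The operation is idempotent.
#'
#' @param panel A `marker_panel` (see [simulate_marker_panel()]).
#' @param flag_fraction Out-of-range fraction above which an analyte is
#'   flagged.
#' @return A collapsed `marker_panel` with one column per sample:
#'   `concentrations` (analyte x sample), `analyte_flags`, and a
#'   `preprocess_log` attribute.
#' @export
preprocess_panel <- function(panel, flag_fraction = 0.10) {
  stopifnot(inherits(panel, "marker_panel"))
  conc <- panel$concentrations
  status <- panel$status
  wells <- panel$wells
  if (is.null(wells$plate)) stop("plate ids are required", call. = FALSE)

  oor_frac <- rowMeans(status != "in_range")
  flags <- panel$analyte_flags | (oor_frac > flag_fraction)

  # per-plate, per-analyte min/max imputation of out-of-range wells
  for (pl in unique(wells$plate)) {
    wcols <- which(wells$plate == pl)
    for (i in seq_len(nrow(conc))) {
      st <- status[i, wcols]
      if (all(st == "in_range")) next
      in_range <- conc[i, wcols][st == "in_range"]
      in_range <- in_range[!is.na(in_range)]
      if (length(in_range) == 0)
        stop("imputation impossible: no in-range values for analyte '",
             rownames(conc)[i], "' on plate '", pl, "'", call. = FALSE)
      conc[i, wcols[st == "below_range"]] <- min(in_range)
      conc[i, wcols[st == "above_range"]] <- max(in_range)
    }
  }

  # average duplicate wells per sample
  sample_ids <- unique(wells$sample_id)
  collapsed <- vapply(sample_ids, function(s) {
    rowMeans(conc[, wells$sample_id == s, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(conc)))
  collapsed <- matrix(collapsed, nrow = nrow(conc),
                      dimnames = list(rownames(conc), sample_ids))
  plate_of <- vapply(sample_ids, function(s)
    wells$plate[wells$sample_id == s][1], character(1))

  structure(list(
    concentrations = collapsed,
    status = matrix("in_range", nrow(collapsed), ncol(collapsed),
                    dimnames = dimnames(collapsed)),
    wells = data.frame(well_id = sample_ids, sample_id = sample_ids,
                       plate = unname(plate_of), stringsAsFactors = FALSE),
    analyte_flags = flags,
    collapsed = TRUE),
    class = "marker_panel",
    preprocess_log = list(out_of_range_fraction = oor_frac,
                          flagged = names(flags)[flags]))
}

#' Per-group extreme-outlier exclusion
#'
#' Within each (analyte/feature, group) stratum, values more than three
#' interquartile ranges beyond the quartiles
#' (see [extreme_outlier_mask()]) are set missing. The exclusion log is
#' attached as attribute `"exclusions"`.
#'
#' @param values Feature x sample numeric matrix.
#' @param groups Group label per sample (named vector or participant
#'   table with `participant_id`/`karyotype`).
#' @return The matrix with outliers set to `NA`.
#' @export
exclude_outliers_per_group <- function(values, groups) {
  groups <- .group_lookup(groups)
  g <- groups[colnames(values)]
  excl <- list()
  for (lev in unique(g[!is.na(g)])) {
    cols <- which(!is.na(g) & g == lev)
    for (i in seq_len(nrow(values))) {
      mask <- extreme_outlier_mask(values[i, cols])
      if (any(mask)) {
        excl[[length(excl) + 1]] <- data.frame(
          feature = rownames(values)[i], group = lev,
          sample = colnames(values)[cols[mask]],
          value = values[i, cols[mask]], stringsAsFactors = FALSE)
        values[i, cols[mask]] <- NA_real_
      }
    }
  }
  attr(values, "exclusions") <-
    if (length(excl)) do.call(rbind, excl)
    else data.frame(feature = character(), group = character(),
                    sample = character(), value = numeric())
  values
}

#' Differential abundance of markers by mixed-effects regression
#'
#' Per analyte, fits
#' `log2(concentration) ~ group + age + sex + (1 | source)` with the
#' group coefficient interpreted as a log2 fold-change, and corrects
#' p-values across analytes with Benjamini-Hochberg. When the data
#' contain a single source level the random intercept is dropped and an
#' ordinary least-squares fit is used (recorded in the `model` column).
#'
#' @param values Analyte x sample matrix of concentrations (or
#'   already-log2 values with `log2_transform = FALSE`).
#' @param participants Participant table (`participant_id`, `karyotype`,
#'   `age`, `sex`, `source`).
#' @param case_level,control_level Group labels; the coefficient is
#'   case minus control.
#' @param log2_transform Log2-transform `values` before fitting.
#' @param q_threshold Significance threshold on q.
#' @return Data frame: `analyte`, `log2_fc`, `p_value`, `q_value`,
#'   `n_used`, `model`, `significant`; analytes whose fit fails carry
#'   `NA` statistics and an error message in the `note` column.
#' @export
differential_abundance <- function(values, participants,
                                   case_level = "T21",
                                   control_level = "D21",
                                   log2_transform = TRUE,
                                   q_threshold = 0.1) {
  meta <- participants[match(colnames(values), participants$participant_id), ]
  if (anyNA(meta$participant_id))
    stop("samples missing from the participant table", call. = FALSE)
  keep <- meta$karyotype %in% c(case_level, control_level)
  values <- values[, keep, drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  grp <- factor(meta$karyotype, levels = c(control_level, case_level))
  multi_source <- length(unique(meta$source)) > 1

  rows <- lapply(seq_len(nrow(values)), function(i) {
    y <- if (log2_transform) log2(values[i, ]) else values[i, ]
    ok <- is.finite(y)
    d <- data.frame(y = y[ok], group = grp[ok], age = meta$age[ok],
                    sex = factor(meta$sex[ok]), source = meta$source[ok])
    if (sum(d$group == case_level) < 2 || sum(d$group == control_level) < 2)
      return(data.frame(analyte = rownames(values)[i], log2_fc = NA_real_,
                        p_value = NA_real_, n_used = nrow(d),
                        model = NA_character_,
                        note = "fewer than 2 samples per group",
                        stringsAsFactors = FALSE))
    fit_res <- tryCatch({
      if (multi_source && length(unique(d$source)) > 1) {
        # singular/convergence chatter is recorded, not propagated
        msgs <- character()
        fit <- withCallingHandlers(
          suppressMessages(
            lmerTest::lmer(y ~ group + age + sex + (1 | source), data = d)),
          warning = function(w) {
            msgs <<- c(msgs, conditionMessage(w))
            invokeRestart("muffleWarning")
          })
        co <- stats::coef(summary(fit))
        list(est = co[2, "Estimate"], p = co[2, "Pr(>|t|)"], model = "lmm",
             note = if (length(msgs)) paste(msgs, collapse = "; ") else NULL)
      } else {
        fit <- stats::lm(y ~ group + age + sex, data = d)
        co <- stats::coef(summary(fit))
        list(est = co[2, "Estimate"], p = co[2, "Pr(>|t|)"], model = "ols")
      }
    }, error = function(e) list(est = NA_real_, p = NA_real_,
                                model = NA_character_,
                                note = conditionMessage(e)))
    data.frame(analyte = rownames(values)[i], log2_fc = fit_res$est,
               p_value = fit_res$p, n_used = nrow(d),
               model = fit_res$model,
               note = if (is.null(fit_res$note)) "" else fit_res$note,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- benjamini_hochberg(out$p_value)
  out$significant <- !is.na(out$q_value) & out$q_value < q_threshold
  out[, c("analyte", "log2_fc", "p_value", "q_value", "n_used", "model",
          "significant", "note")]
}

#' Remove nuisance-covariate contributions from a value matrix
#'
#' Per feature, fits a linear model on the kept effect plus the nuisance
#' covariates and subtracts the estimated nuisance contributions
#' (computed from mean-centered covariate columns, so the grand level and
#' the kept effect are preserved). All features share one design, so the
#' fit is a single multi-response least-squares solve.
#'
#' @param values Feature x sample numeric matrix (typically log2 scale).
#' @param participants Participant table with the covariate columns.
#' @param covariates Nuisance covariate names to remove.
#' @param keep Column whose effect must be preserved (e.g. `karyotype`),
#'   or `NULL` to residualize on covariates only.
#' @return An `adjusted_matrix`: list with `values` (adjusted matrix) and
#'   `adjustment_record`.
#' @export
adjust_covariates <- function(values, participants,
                              covariates = c("age", "sex", "source"),
                              keep = "karyotype") {
  meta <- participants[match(colnames(values), participants$participant_id), ]
  if (anyNA(meta$participant_id))
    stop("samples missing from the participant table", call. = FALSE)
  miss <- setdiff(c(covariates, keep), names(meta))
  if (length(miss))
    stop("missing covariate column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  # expand nuisance covariates to a centered numeric design; covariates
  # without variation contribute nothing and are dropped up front
  dat <- meta[, c(covariates, keep), drop = FALSE]
  for (v in c(covariates, keep))
    if (is.character(dat[[v]])) dat[[v]] <- factor(dat[[v]])
  covariates <- covariates[vapply(covariates, function(v)
    length(unique(dat[[v]][!is.na(dat[[v]])])) > 1, logical(1))]
  if (length(covariates)) {
    nuis_terms <- stats::as.formula(paste("~",
                                          paste(covariates, collapse = "+")))
    x_nuis <- stats::model.matrix(nuis_terms, dat)[, -1, drop = FALSE]
    constant <- apply(x_nuis, 2, function(col) stats::var(col) == 0)
    x_nuis <- x_nuis[, !constant, drop = FALSE]
  } else {
    x_nuis <- matrix(numeric(0), nrow(dat), 0)
  }
  if (ncol(x_nuis) == 0) {
    return(structure(list(values = values,
                          adjustment_record = character(0)),
                     class = "adjusted_matrix"))
  }
  x_nuis_c <- scale(x_nuis, center = TRUE, scale = FALSE)
  x_keep <- if (!is.null(keep))
    stats::model.matrix(stats::as.formula(paste("~", keep)),
                        dat)[, -1, drop = FALSE] else NULL
  X <- cbind(`(Intercept)` = 1, x_keep, x_nuis_c)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    stop("collinear covariates in the adjustment design", call. = FALSE)

  # multi-response least squares; rows of `values` are responses
  beta <- qr.coef(qr_x, t(values))          # coef x feature
  nuis_idx <- seq.int(ncol(X) - ncol(x_nuis_c) + 1, ncol(X))
  fitted_nuis <- x_nuis_c %*% beta[nuis_idx, , drop = FALSE]
  adjusted <- values - t(fitted_nuis)
  structure(list(values = adjusted,
                 adjustment_record = colnames(x_nuis)),
            class = "adjusted_matrix")
}

# shared constructor for composite (sum-of-z) scores
.composite_score <- function(values, components, reference, ref_label) {
  absent <- setdiff(components, rownames(values))
  if (length(absent))
    stop("component(s) absent from matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  sub <- values[components, , drop = FALSE]
  if (identical(reference, "self")) {
    ref_ids <- colnames(sub)
    ref_label <- "self"
  } else {
    ref_ids <- intersect(reference, colnames(sub))
    if (length(ref_ids) < 2)
      stop("reference set must contain at least 2 samples present in the ",
           "matrix", call. = FALSE)
  }
  ref_mean <- rowMeans(sub[, ref_ids, drop = FALSE], na.rm = TRUE)
  ref_sd <- apply(sub[, ref_ids, drop = FALSE], 1, stats::sd, na.rm = TRUE)
  if (any(!is.finite(ref_sd)) || any(ref_sd == 0))
    stop("degenerate reference: zero or undefined SD for ",
         paste(components[!is.finite(ref_sd) | ref_sd == 0], collapse = ", "),
         call. = FALSE)
  z <- sweep(sweep(sub, 1, ref_mean, "-"), 1, ref_sd, "/")
  structure(list(score = colSums(z), z = z, components = components,
                 reference = list(label = ref_label, ids = ref_ids,
                                  mean = ref_mean, sd = ref_sd)),
            class = "composite_score")
}

#' Composite cytokine score
#'
#' Sum of per-analyte z-scores over the score components (by default
#' TNF-alpha, IL-6, CRP and IP-10) computed on log2, covariate-adjusted
#' concentrations. In reference mode the z-scores use the mean and SD of
#' the named reference samples (the euploid controls), so the reference
#' population has mean score 0; in `"self"` mode standardization is
#' within the provided sample set (used for trial across-visit
#' comparisons).
#'
#' @param values Analyte x sample matrix (log2, adjusted scale).
#' @param components Analytes summed into the score.
#' @param reference Sample ids of the reference population, or `"self"`.
#' @param ref_label Label recorded for a non-self reference.
#' @return A `composite_score`: `score` (named numeric per sample), the
#'   per-component `z` matrix, `components`, and `reference` statistics.
#' @export
cytokine_score <- function(values,
                           components = c("TNF-alpha", "IL-6", "CRP",
                                          "IP-10"),
                           reference = "self",
                           ref_label = "euploid controls") {
  .composite_score(values, components, reference, ref_label)
}
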