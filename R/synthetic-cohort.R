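# Seeded synthetic-data generators emulating the statistical structure of a
# T21/D21 immune-profiling cohort and a four-visit treatment trial: log2-scale
# Gaussian models for plasma markers and transcript abundance, multiplicative
# spike models for bead-array reactivities, beta-distributed cell-cluster
# frequencies, and multiplicative treatment effects with occasional
# immune-trigger excursions.

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Cohort design specification
#'
#' Parameters of a synthetic case-control cohort: group sizes, age range,
#' sex ratio, number of sample sources (recruitment/processing batches) and
#' the random seed. Sizes are parameters, not constants, so cohorts of any
#' scale can be generated.
#'
#' @param n_t21,n_d21 Positive participant counts for the trisomy-21 and
#'   euploid control groups.
#' @param age_range Length-2 numeric, years, `low < high`.
#' @param sex_ratio Probability that a participant is female, in `[0, 1]`.
#' @param n_sources Positive count of sample sources (batches).
#' @param seed Integer random seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_t21, n_d21, age_range = c(0.5, 57),
                        sex_ratio = 0.5, n_sources = 3, seed = 1) {
  if (n_t21 <= 0 || n_d21 <= 0 || n_sources <= 0)
    stop("counts must be positive", call. = FALSE)
  if (sex_ratio < 0 || sex_ratio > 1)
    stop("sex_ratio must be in [0, 1]", call. = FALSE)
  if (length(age_range) != 2 || age_range[1] >= age_range[2])
    stop("age_range must be (low, high) with low < high", call. = FALSE)
  structure(list(n_t21 = as.integer(n_t21), n_d21 = as.integer(n_d21),
                 age_range = as.numeric(age_range),
                 sex_ratio = sex_ratio, n_sources = as.integer(n_sources),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Effect-size specification for the synthetic generators
#'
#' Collects the group effects injected by the generators. All defaults are
#' null (no effect); named entries switch individual effects on.
#'
#' @param elevated_analytes Named numeric: per-analyte log2 shift added to
#'   T21 samples.
#' @param age_slopes Named numeric: per-analyte log2 units per year.
#' @param batch_sd Standard deviation (log2 units) of per-source offsets.
#' @param isg_fold_changes Named numeric > 0: per-gene expression
#'   fold-change applied to T21 samples.
#' @param enriched_antigens Named numeric > 0: per-antigen multiplier on
#'   the reactivity-spike odds in T21 samples.
#' @param cluster_logit_shifts Named numeric: per-cluster shift of the
#'   beta-mean on the logit scale for T21 samples.
#' @param treatment_effect Multiplicative change (> 0) applied to on-drug
#'   trial visits; 1 means no treatment effect.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(elevated_analytes = numeric(),
                        age_slopes = numeric(),
                        batch_sd = 0.25,
                        isg_fold_changes = numeric(),
                        enriched_antigens = numeric(),
                        cluster_logit_shifts = numeric(),
                        treatment_effect = 1) {
  if (length(isg_fold_changes) && any(isg_fold_changes <= 0))
    stop("fold-changes must be > 0", call. = FALSE)
  if (length(enriched_antigens) && any(enriched_antigens <= 0))
    stop("odds multipliers must be > 0", call. = FALSE)
  if (treatment_effect <= 0)
    stop("treatment_effect must be > 0", call. = FALSE)
  structure(list(elevated_analytes = elevated_analytes,
                 age_slopes = age_slopes, batch_sd = batch_sd,
                 isg_fold_changes = isg_fold_changes,
                 enriched_antigens = enriched_antigens,
                 cluster_logit_shifts = cluster_logit_shifts,
                 treatment_effect = treatment_effect),
            class = "effect_spec")
}

#' Simulate participant metadata
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with one row per participant: `participant_id`,
#'   `karyotype` ("T21"/"D21"), `age` (years), `sex` ("F"/"M"), `source`.
#' @export
simulate_participants <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_t21 + spec$n_d21
  with_seed(spec$seed, {
    data.frame(
      participant_id = sprintf("P%04d", seq_len(n)),
      karyotype = rep(c("T21", "D21"), c(spec$n_t21, spec$n_d21)),
      age = stats::runif(n, spec$age_range[1], spec$age_range[2]),
      sex = ifelse(stats::rbinom(n, 1, spec$sex_ratio) == 1, "F", "M"),
      source = sprintf("S%d", sample.int(spec$n_sources, n, replace = TRUE)),
      stringsAsFactors = FALSE
    )
  })
}

#' Default analyte names for a synthetic inflammatory-marker panel
#'
#' The first four names are the cytokine-score components; the remainder
#' are generic marker labels.
#' @param n_analytes Panel size (>= 1).
#' @return Character vector of analyte names.
#' @export
default_analyte_names <- function(n_analytes = 54) {
  core <- c("TNF-alpha", "IL-6", "CRP", "IP-10")
  if (n_analytes <= 4) return(core[seq_len(n_analytes)])
  c(core, sprintf("MRK%02d", seq.int(5, n_analytes)))
}

#' Simulate a multiplex immunoassay marker panel
#'
#' Per-sample log2 concentrations follow
#' `baseline + delta * [T21] + slope * age + source offset + N(0, noise_sd)`
#' and are exponentiated to pg/mL. Two duplicate wells per sample are
#' emitted with independent well-level noise; a configurable fraction of
#' wells is flagged below/above the fit-curve range (their concentrations
#' are unreliable and left missing for the preprocessing step to impute).
#'
#' @param participants Participant table from [simulate_participants()].
#' @param effects An [effect_spec()]; analyte names in
#'   `elevated_analytes`/`age_slopes` must exist in the panel.
#' @param n_analytes Number of analytes.
#' @param seed Integer seed.
#' @param noise_sd Between-sample biological noise SD, log2 units.
#' @param well_sd Technical duplicate-well noise SD, log2 units.
#' @param out_of_range_frac Fraction of wells flagged out of range.
#' @param plate_size Samples per plate (duplicates share a plate).
#' @param analyte_names Optional analyte names (length `n_analytes`).
#' @return A `marker_panel`: list with `concentrations` (analyte x well),
#'   `status` (analyte x well, in/below/above range), `wells` (well
#'   metadata: `well_id`, `sample_id`, `plate`), `analyte_flags`.
#' @export
simulate_marker_panel <- function(participants, effects, n_analytes = 54,
                                  seed = 1, noise_sd = 1, well_sd = 0.05,
                                  out_of_range_frac = 0.02, plate_size = 48,
                                  analyte_names = NULL) {
  if (nrow(participants) == 0) stop("participants is empty", call. = FALSE)
  if (is.null(analyte_names)) analyte_names <- default_analyte_names(n_analytes)
  stopifnot(length(analyte_names) == n_analytes)
  unknown <- setdiff(c(names(effects$elevated_analytes),
                       names(effects$age_slopes)), analyte_names)
  if (length(unknown))
    stop("unknown analyte(s) in effects: ", paste(unknown, collapse = ", "),
         call. = FALSE)

  n_s <- nrow(participants)
  t21 <- as.numeric(participants$karyotype == "T21")
  delta <- stats::setNames(rep(0, n_analytes), analyte_names)
  delta[names(effects$elevated_analytes)] <- effects$elevated_analytes
  slope <- stats::setNames(rep(0, n_analytes), analyte_names)
  slope[names(effects$age_slopes)] <- effects$age_slopes

  with_seed(seed, {
    baseline <- stats::runif(n_analytes, 2, 8)
    sources <- sort(unique(participants$source))
    src_off <- matrix(stats::rnorm(n_analytes * length(sources),
                                   sd = effects$batch_sd),
                      n_analytes, length(sources),
                      dimnames = list(analyte_names, sources))
    # latent per-sample log2 concentration
    log2_sample <- baseline +
      outer(delta, t21) +
      outer(slope, participants$age) +
      src_off[, participants$source, drop = FALSE] +
      matrix(stats::rnorm(n_analytes * n_s, sd = noise_sd), n_analytes, n_s)

    plate <- sprintf("PL%02d", (seq_len(n_s) - 1) %/% plate_size + 1)
    wells <- data.frame(
      well_id = sprintf("W%05d", seq_len(2 * n_s)),
      sample_id = rep(participants$participant_id, each = 2),
      plate = rep(plate, each = 2),
      stringsAsFactors = FALSE
    )
    log2_well <- log2_sample[, rep(seq_len(n_s), each = 2), drop = FALSE] +
      matrix(stats::rnorm(n_analytes * 2 * n_s, sd = well_sd),
             n_analytes, 2 * n_s)
    conc <- 2^log2_well
    dimnames(conc) <- list(analyte_names, wells$well_id)

    status <- matrix("in_range", n_analytes, 2 * n_s,
                     dimnames = dimnames(conc))
    if (out_of_range_frac > 0) {
      oor <- matrix(stats::runif(length(conc)) < out_of_range_frac,
                    n_analytes, 2 * n_s)
      med <- apply(conc, 1, stats::median)
      low <- conc < med
      status[oor & low] <- "below_range"
      status[oor & !low] <- "above_range"
      conc[oor] <- NA_real_
    }
    structure(list(concentrations = conc, status = status, wells = wells,
                   analyte_flags = stats::setNames(rep(FALSE, n_analytes),
                                                   analyte_names),
                   collapsed = FALSE),
              class = "marker_panel")
  })
}

#' Simulate an autoantigen bead-array reactivity matrix
#'
#' MFI = per-sample multiplicative background x per-antigen lognormal
#' baseline x lognormal noise. Each reaction independently receives a
#' reactivity spike (a multiplicative MFI excursion, the synthetic analog
#' of a true autoantibody) with base odds `base_odds`; for antigens named
#' in `effects$enriched_antigens` the spike odds in T21 samples are
#' multiplied by the stated factor. Bead counts are Poisson with a small
#' fraction of failed (low-bead) reactions.
#'
#' @param participants Participant table.
#' @param effects An [effect_spec()].
#' @param n_antigens Number of antigens (>= 2).
#' @param seed Integer seed.
#' @param base_odds Baseline spike odds (probability `o/(1+o)`).
#' @param spike_log2 Range (log2 units) of the spike multiplier.
#' @param mean_beads Mean bead count of a successful reaction.
#' @param low_bead_frac Fraction of reactions with failed bead counts.
#' @return An `antigen_reactivity` list: `mfi` and `bead_counts`
#'   (antigen x sample matrices), `antigen_meta` (antigen, protein).
#' @export
simulate_autoantigen_mfi <- function(participants, effects, n_antigens = 380,
                                     seed = 1, base_odds = 1 / 9,
                                     spike_log2 = c(3, 4.5),
                                     mean_beads = 60, low_bead_frac = 0.01) {
  if (nrow(participants) == 0) stop("participants is empty", call. = FALSE)
  if (n_antigens < 2) stop("need at least 2 antigens", call. = FALSE)
  antigens <- sprintf("AG%03d", seq_len(n_antigens))
  unknown <- setdiff(names(effects$enriched_antigens), antigens)
  if (length(unknown))
    stop("unknown antigen(s) in effects: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  n_s <- nrow(participants)
  t21 <- participants$karyotype == "T21"

  with_seed(seed, {
    bg <- exp(stats::rnorm(n_s, 0, 0.3))                    # sample background
    base <- exp(stats::rnorm(n_antigens, log(500), 0.6))    # antigen baseline
    noise <- matrix(exp(stats::rnorm(n_antigens * n_s, 0, 0.2)),
                    n_antigens, n_s)
    mfi <- outer(base, bg) * noise

    odds <- matrix(base_odds, n_antigens, n_s)
    if (length(effects$enriched_antigens)) {
      idx <- match(names(effects$enriched_antigens), antigens)
      odds[idx, t21] <- odds[idx, t21, drop = FALSE] *
        effects$enriched_antigens
    }
    spike <- matrix(stats::runif(n_antigens * n_s) < odds / (1 + odds),
                    n_antigens, n_s)
    mult <- 2^stats::runif(sum(spike), spike_log2[1], spike_log2[2])
    mfi[spike] <- mfi[spike] * mult

    beads <- matrix(stats::rpois(n_antigens * n_s, mean_beads),
                    n_antigens, n_s)
    fail <- matrix(stats::runif(n_antigens * n_s) < low_bead_frac,
                   n_antigens, n_s)
    beads[fail] <- stats::rpois(sum(fail), 5)
    dimnames(mfi) <- dimnames(beads) <-
      list(antigens, participants$participant_id)
    structure(list(mfi = mfi, bead_counts = beads,
                   antigen_meta = data.frame(
                     antigen = antigens,
                     protein = sprintf("PRT%03d", seq_len(n_antigens)),
                     stringsAsFactors = FALSE)),
              class = "antigen_reactivity")
  })
}

#' Default gene annotation for synthetic expression data
#'
#' Builds a gene table with a designated interferon-stimulated-gene (ISG)
#' block off chromosome 21, a chromosome-21 block (including the
#' chr21-encoded ISGs `IFNAR2`, `MX1`, `MX2` that the score-selection rule
#' must exclude), and background genes.
#'
#' @param n_genes Total number of genes.
#' @param n_isgs Number of designated non-chr21 ISGs.
#' @return Data frame with `gene`, `chromosome`, `is_isg`.
#' @export
default_gene_annotation <- function(n_genes = 160, n_isgs = 16) {
  stopifnot(n_genes >= n_isgs + 10)
  isg <- sprintf("ISG%02d", seq_len(n_isgs))
  chr21 <- c("IFNAR2", "MX1", "MX2")
  n_bg <- n_genes - n_isgs - length(chr21)
  bg <- sprintf("GENE%03d", seq_len(n_bg))
  data.frame(
    gene = c(isg, chr21, bg),
    chromosome = c(sample_free_chrom(n_isgs), rep("chr21", length(chr21)),
                   sample_free_chrom(n_bg)),
    is_isg = c(rep(TRUE, n_isgs), rep(TRUE, length(chr21)),
               rep(FALSE, n_bg)),
    stringsAsFactors = FALSE
  )
}

# deterministic non-chr21 chromosome labels (cycled, no RNG)
sample_free_chrom <- function(n) {
  pool <- paste0("chr", c(1:20, 22))
  pool[(seq_len(n) - 1) %% length(pool) + 1]
}

#' Simulate an expression matrix with ISG effects
#'
#' Per-gene log2 abundance = baseline + batch + age + sex effects +
#' Gaussian noise; genes named in `effects$isg_fold_changes` are
#' multiplied by their fold-change in T21 samples. Values are returned on
#' the positive FPKM-like scale.
#'
#' @param participants Participant table.
#' @param effects An [effect_spec()].
#' @param gene_annotation Data frame with `gene` and `chromosome`
#'   (see [default_gene_annotation()]).
#' @param seed Integer seed.
#' @param noise_sd Biological noise SD, log2 units.
#' @param age_slope,sex_effect Shared nuisance effects (log2 units/year,
#'   log2 units for female).
#' @return Gene x sample matrix of positive values, with the annotation
#'   attached as attribute `"annotation"`.
#' @export
simulate_isg_expression <- function(participants, effects, gene_annotation,
                                    seed = 1, noise_sd = 0.5,
                                    age_slope = 0.005, sex_effect = 0.1) {
  if (nrow(participants) == 0) stop("participants is empty", call. = FALSE)
  if (is.null(gene_annotation) || nrow(gene_annotation) == 0)
    stop("gene_annotation must be non-empty", call. = FALSE)
  if (!all(c("gene", "chromosome") %in% names(gene_annotation)))
    stop("gene_annotation needs 'gene' and 'chromosome' columns",
         call. = FALSE)
  genes <- gene_annotation$gene
  unknown <- setdiff(names(effects$isg_fold_changes), genes)
  if (length(unknown))
    stop("unknown gene(s) in effects: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  n_g <- length(genes); n_s <- nrow(participants)
  t21 <- as.numeric(participants$karyotype == "T21")
  log2fc <- stats::setNames(rep(0, n_g), genes)
  log2fc[names(effects$isg_fold_changes)] <- log2(effects$isg_fold_changes)

  with_seed(seed, {
    baseline <- stats::runif(n_g, 3, 9)
    sources <- sort(unique(participants$source))
    batch <- matrix(stats::rnorm(n_g * length(sources), sd = effects$batch_sd),
                    n_g, length(sources), dimnames = list(genes, sources))
    log2x <- baseline +
      outer(log2fc, t21) +
      batch[, participants$source, drop = FALSE] +
      matrix(rep(age_slope * participants$age, each = n_g), n_g, n_s) +
      matrix(rep(sex_effect * (participants$sex == "F"), each = n_g),
             n_g, n_s) +
      matrix(stats::rnorm(n_g * n_s, sd = noise_sd), n_g, n_s)
    x <- 2^log2x
    dimnames(x) <- list(genes, participants$participant_id)
    attr(x, "annotation") <- gene_annotation
    x
  })
}

#' Simulate a differential-expression result table consistent with the
#' injected fold-changes
#'
#' Stand-in for an upstream differential-expression analysis: genes with
#' an injected T21 fold-change get that fold-change (plus small noise) and
#' a significant q-value; null genes get near-zero fold-changes and
#' uniform q-values above 0.1.
#'
#' @param effects An [effect_spec()].
#' @param gene_annotation Gene annotation table.
#' @param seed Integer seed.
#' @return Data frame: `gene`, `log2_fc`, `q_value`, `chromosome`.
#' @export
simulate_de_results <- function(effects, gene_annotation, seed = 1) {
  genes <- gene_annotation$gene
  fc <- stats::setNames(rep(1, length(genes)), genes)
  fc[names(effects$isg_fold_changes)] <- effects$isg_fold_changes
  with_seed(seed, {
    lfc <- log2(fc) + stats::rnorm(length(genes), 0, 0.03)
    q <- ifelse(fc != 1, stats::runif(length(genes), 0, 0.05),
                stats::runif(length(genes), 0.15, 1))
    data.frame(gene = genes, log2_fc = lfc, q_value = q,
               chromosome = gene_annotation$chromosome,
               stringsAsFactors = FALSE)
  })
}

#' Simulate immune-cell cluster frequencies
#'
#' Each cluster's per-sample proportion is beta-distributed with logit
#' mean `base + shift * [T21] + age_logit_slope * age + sex term` and a
#' common precision. Rows need not sum to one: clusters are analyzed
#' marginally.
#'
#' @param participants Participant table.
#' @param effects An [effect_spec()]; `cluster_logit_shifts` names must
#'   exist among the cluster names.
#' @param n_clusters Number of clusters (>= 2).
#' @param seed Integer seed.
#' @param precision Beta precision parameter (phi > 0).
#' @param age_logit_slope,sex_logit_effect Nuisance effects on the logit
#'   scale.
#' @param cluster_names Optional cluster names (length `n_clusters`).
#' @return Cluster x sample matrix of proportions strictly in (0, 1).
#' @export
simulate_cluster_frequencies <- function(participants, effects,
                                         n_clusters = 20, seed = 1,
                                         precision = 50,
                                         age_logit_slope = 0,
                                         sex_logit_effect = 0,
                                         cluster_names = NULL) {
  if (n_clusters < 2) stop("need at least 2 clusters", call. = FALSE)
  if (is.null(cluster_names))
    cluster_names <- sprintf("C%02d", seq_len(n_clusters))
  stopifnot(length(cluster_names) == n_clusters)
  unknown <- setdiff(names(effects$cluster_logit_shifts), cluster_names)
  if (length(unknown))
    stop("unknown cluster(s) in effects: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  n_s <- nrow(participants)
  t21 <- as.numeric(participants$karyotype == "T21")
  shift <- stats::setNames(rep(0, n_clusters), cluster_names)
  shift[names(effects$cluster_logit_shifts)] <- effects$cluster_logit_shifts

  with_seed(seed, {
    base <- stats::qlogis(stats::runif(n_clusters, 0.02, 0.30))
    eta <- base + outer(shift, t21) +
      matrix(rep(age_logit_slope * participants$age +
                   sex_logit_effect * (participants$sex == "F"),
                 each = n_clusters), n_clusters, n_s)
    mu <- stats::plogis(eta)
    if (any(mu <= 0 | mu >= 1))
      stop("logit shifts push a cluster mean onto the (0,1) boundary",
           call. = FALSE)
    y <- matrix(stats::rbeta(n_clusters * n_s, mu * precision,
                             (1 - mu) * precision),
                n_clusters, n_s,
                dimnames = list(cluster_names, participants$participant_id))
    # guard against numerically degenerate draws at extreme precision
    eps <- .Machine$double.eps
    pmin(pmax(y, eps), 1 - eps)
  })
}

#' Simulate a four-visit trial time course
#'
#' Generates per-participant measurements at baseline (`B`) and weeks 2,
#' 8 and 16 (`W2`, `W8`, `W16`): marker concentrations (cytokine-score
#' components), ISG expression over a configurable gene universe, and an
#' anti-TPO-like titer. On-drug visits (W2-W16) are multiplied by
#' `treatment_effect`; with probability `trigger_prob` a visit receives an
#' immune-trigger excursion that reverses the treatment effect and pushes
#' values above baseline (emulating e.g. a vaccination or infection just
#' before a blood draw).
#'
#' @param n_participants Number of trial participants (>= 2).
#' @param baseline_from An [effect_spec()] supplying `treatment_effect`
#'   unless overridden.
#' @param treatment_effect Multiplicative change (> 0) at on-drug visits.
#' @param trigger_prob Per-visit probability of an immune-trigger
#'   excursion.
#' @param seed Integer seed.
#' @param n_isg_genes Size of the ISG universe carried in the expression
#'   modality.
#' @param marker_names Marker analytes measured at each visit.
#' @param within_sd Within-participant visit-to-visit noise SD, log2.
#' @param titer_uln Upper limit of normal for the synthetic titer (assay
#'   units); baselines straddle it.
#' @param excursion_log2 Size of a trigger excursion, log2 units.
#' @return A `trial_table` data frame: `participant_id`, `visit`,
#'   `assay` ("marker"/"expression"/"titer"), `name`, `value`, `trigger`.
#' @export
simulate_trial_timecourse <- function(n_participants = 10,
                                      baseline_from = effect_spec(),
                                      treatment_effect =
                                        baseline_from$treatment_effect,
                                      trigger_prob = 0, seed = 1,
                                      n_isg_genes = 136,
                                      marker_names = default_analyte_names(4),
                                      within_sd = 0.15,
                                      titer_uln = 60,
                                      excursion_log2 = 1) {
  if (n_participants < 2) stop("need at least 2 participants", call. = FALSE)
  if (treatment_effect <= 0)
    stop("treatment_effect must be > 0", call. = FALSE)
  visits <- c("B", "W2", "W8", "W16")
  ids <- sprintf("TR%02d", seq_len(n_participants))
  genes <- sprintf("ISGU%03d", seq_len(n_isg_genes))

  with_seed(seed, {
    # participant x feature baseline log2 values
    base_marker <- outer(stats::rnorm(n_participants, 0, 0.5),
                         rep(1, length(marker_names))) +
      matrix(rep(stats::runif(length(marker_names), 3, 7),
                 each = n_participants),
             n_participants, length(marker_names)) +
      matrix(stats::rnorm(n_participants * length(marker_names), 0, 0.5),
             n_participants, length(marker_names))
    base_expr <- matrix(rep(stats::runif(n_isg_genes, 3, 9),
                            each = n_participants),
                        n_participants, n_isg_genes) +
      matrix(stats::rnorm(n_participants * n_isg_genes, 0, 0.4),
             n_participants, n_isg_genes)
    # titers: ~70% of participants start above the ULN
    above <- stats::runif(n_participants) < 0.7
    base_titer <- ifelse(above,
                         titer_uln * 2^stats::runif(n_participants, 0.5, 2),
                         titer_uln * 2^stats::runif(n_participants, -2, -0.3))

    trigger <- matrix(FALSE, n_participants, length(visits),
                      dimnames = list(ids, visits))
    trigger[, -1] <- stats::runif(n_participants * 3) < trigger_prob

    rows <- vector("list", length(visits))
    for (vi in seq_along(visits)) {
      v <- visits[vi]
      on_drug <- v != "B"
      eff <- if (on_drug) log2(treatment_effect) else 0
      exc <- ifelse(trigger[, vi], excursion_log2 - eff, 0)
      mk <- base_marker + eff + exc +
        matrix(stats::rnorm(length(base_marker), 0, within_sd),
               n_participants, length(marker_names))
      ex <- base_expr + eff + exc +
        matrix(stats::rnorm(length(base_expr), 0, within_sd),
               n_participants, n_isg_genes)
      ti <- log2(base_titer) + eff + exc +
        stats::rnorm(n_participants, 0, within_sd)
      rows[[vi]] <- data.frame(
        participant_id = rep(ids, times = length(marker_names) +
                               n_isg_genes + 1),
        visit = v,
        assay = rep(c("marker", "expression", "titer"),
                    times = c(n_participants * length(marker_names),
                              n_participants * n_isg_genes, n_participants)),
        name = c(rep(marker_names, each = n_participants),
                 rep(genes, each = n_participants), rep("anti-TPO",
                                                        n_participants)),
        value = 2^c(mk, ex, ti),
        trigger = rep(trigger[, vi], times = length(marker_names) +
                        n_isg_genes + 1),
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    out$visit <- factor(out$visit, levels = visits)
    class(out) <- c("trial_table", "data.frame")
    out
  })
}
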