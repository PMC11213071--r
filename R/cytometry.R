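# Differential frequency analysis of immune-cell clusters: maximum-
# likelihood beta regression with a logit mean link and constant precision,
# per-group extreme-outlier exclusion, and logit-scale covariate adjustment
# for display.

# log-likelihood and analytic score of the beta regression model
.betareg_loglik <- function(theta, X, y) {
  p <- ncol(X)
  eta <- drop(X %*% theta[seq_len(p)])
  mu <- stats::plogis(eta)
  phi <- exp(theta[p + 1])
  sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

.betareg_score <- function(theta, X, y) {
  p <- ncol(X)
  eta <- drop(X %*% theta[seq_len(p)])
  mu <- stats::plogis(eta)
  phi <- exp(theta[p + 1])
  ystar <- stats::qlogis(y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  g_beta <- phi * drop(crossprod(X, (ystar - mustar) * mu * (1 - mu)))
  g_phi <- sum(mu * (ystar - mustar) + log(1 - y) -
                 digamma((1 - mu) * phi) + digamma(phi))
  c(g_beta, phi * g_phi)  # chain rule for log(phi)
}

#' Beta regression with logit link and constant precision
#'
#' Maximum-likelihood fit of a beta-distributed outcome in (0, 1) with
#' mean `mu = plogis(X %*% beta)` and a single precision parameter
#' `phi` (variance `mu (1 - mu) / (1 + phi)`). Standard errors and Wald
#' p-values come from the observed information at the optimum. Starting
#' values are the least-squares fit of `qlogis(y)` on the design; on
#' non-convergence up to five jittered restarts are attempted.
#'
#' Boundary values: proportions exactly 0 or 1 have zero beta likelihood.
#' With `squeeze = TRUE` the standard compression
#' `y' = (y (n - 1) + 0.5) / n` is applied when any boundary value is
#' present; with `squeeze = FALSE` boundary values are an error.
#'
#' @param y Numeric outcome vector, proportions.
#' @param X Design matrix (including an intercept column), full rank.
#' @param squeeze Apply the boundary compression if needed.
#' @param max_restarts Jittered restarts on non-convergence.
#' @return A `betareg_fit`: `coefficients` data frame (`term`,
#'   `estimate`, `se`, `z`, `p_value`), `precision` (phi), `loglik`,
#'   `converged`, `n`, `squeezed`.
#' @export
betareg_fit <- function(y, X, squeeze = TRUE, max_restarts = 5) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("y and X sizes differ", call. = FALSE)
  if (qr(X)$rank < ncol(X)) stop("design is rank deficient", call. = FALSE)
  squeezed <- FALSE
  if (any(y <= 0 | y >= 1)) {
    if (any(y < 0 | y > 1))
      stop("proportions must lie in [0, 1]", call. = FALSE)
    if (!squeeze)
      stop("boundary proportions present and squeeze is disabled",
           call. = FALSE)
    n <- length(y)
    y <- (y * (n - 1) + 0.5) / n
    squeezed <- TRUE
  }

  beta0 <- qr.coef(qr(X), stats::qlogis(y))
  mu0 <- stats::plogis(drop(X %*% beta0))
  s2 <- stats::var(y - mu0)
  phi0 <- max(mean(mu0 * (1 - mu0)) / max(s2, 1e-8) - 1, 1)
  start <- c(beta0, log(phi0))

  fit <- NULL
  for (attempt in 0:max_restarts) {
    st <- if (attempt == 0) start else
      start + stats::rnorm(length(start), 0, 0.2 * attempt)
    res <- try(stats::optim(st, fn = .betareg_loglik, gr = .betareg_score,
                            X = X, y = y, method = "BFGS",
                            control = list(fnscale = -1, maxit = 500)),
               silent = TRUE)
    if (!inherits(res, "try-error") && res$convergence == 0) {
      fit <- res
      break
    }
  }
  if (is.null(fit))
    stop("beta regression did not converge after restarts", call. = FALSE)

  H <- stats::optimHess(fit$par, fn = .betareg_loglik, gr = .betareg_score,
                        X = X, y = y)
  vcov <- try(solve(-H), silent = TRUE)
  p <- ncol(X)
  if (inherits(vcov, "try-error") || any(diag(vcov)[seq_len(p)] <= 0)) {
    se <- rep(NA_real_, p)
  } else {
    se <- sqrt(diag(vcov)[seq_len(p)])
  }
  est <- fit$par[seq_len(p)]
  z <- est / se
  terms <- colnames(X)
  if (is.null(terms)) terms <- paste0("x", seq_len(p))
  structure(list(
    coefficients = data.frame(term = terms, estimate = est, se = se, z = z,
                              p_value = 2 * stats::pnorm(-abs(z)),
                              stringsAsFactors = FALSE),
    precision = exp(fit$par[p + 1]),
    loglik = fit$value, converged = TRUE, n = length(y),
    squeezed = squeezed),
    class = "betareg_fit")
}

#' Differential cluster frequency by beta regression
#'
#' Per cluster: extreme outliers (3 x IQR beyond the quartiles) are
#' excluded per karyotype group, then a beta regression of the
#' proportion on group + age + sex (logit link) is fitted. The reported
#' fold-change is the exponentiated group coefficient (an odds ratio of
#' proportions, labelled fold-change by field convention). p-values are
#' Benjamini-Hochberg corrected across clusters.
#'
#' @param freqs Cluster x sample matrix of proportions in (0, 1).
#' @param participants Participant table.
#' @param case_level,control_level Group labels.
#' @param min_per_group Minimum usable samples per group; clusters below
#'   are skipped with a warning.
#' @param q_threshold Significance threshold on q.
#' @param squeeze Passed to [betareg_fit()].
#' @return Data frame: `cluster`, `coefficient` (logit scale),
#'   `fold_change`, `p_value`, `q_value`, `n_used`,
#'   `n_excluded_outliers`, `precision`, `significant`.
#' @export
cluster_differential_frequency <- function(freqs, participants,
                                           case_level = "T21",
                                           control_level = "D21",
                                           min_per_group = 10,
                                           q_threshold = 0.1,
                                           squeeze = TRUE) {
  meta <- participants[match(colnames(freqs), participants$participant_id), ]
  if (anyNA(meta$participant_id))
    stop("samples missing from the participant table", call. = FALSE)
  keep <- meta$karyotype %in% c(case_level, control_level)
  freqs <- freqs[, keep, drop = FALSE]
  meta <- meta[keep, , drop = FALSE]

  cleaned <- exclude_outliers_per_group(freqs, meta)
  n_excl <- rowSums(is.na(cleaned)) - rowSums(is.na(freqs))

  grp <- factor(meta$karyotype, levels = c(control_level, case_level))
  sexf <- factor(meta$sex)
  rows <- list()
  skipped <- character()
  for (i in seq_len(nrow(cleaned))) {
    y <- cleaned[i, ]
    ok <- !is.na(y)
    if (sum(ok & grp == case_level) < min_per_group ||
        sum(ok & grp == control_level) < min_per_group) {
      skipped <- c(skipped, rownames(cleaned)[i])
      next
    }
    X <- stats::model.matrix(~ grp + age + sex,
                             data.frame(grp = grp[ok], age = meta$age[ok],
                                        sex = sexf[ok]))
    fit <- tryCatch(betareg_fit(y[ok], X, squeeze = squeeze),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[length(rows) + 1]] <- data.frame(
        cluster = rownames(cleaned)[i], coefficient = NA_real_,
        fold_change = NA_real_, p_value = NA_real_, n_used = sum(ok),
        n_excluded_outliers = n_excl[i], precision = NA_real_,
        note = conditionMessage(fit), stringsAsFactors = FALSE)
      next
    }
    co <- fit$coefficients[2, ]
    rows[[length(rows) + 1]] <- data.frame(
      cluster = rownames(cleaned)[i], coefficient = co$estimate,
      fold_change = exp(co$estimate), p_value = co$p_value,
      n_used = sum(ok), n_excluded_outliers = n_excl[i],
      precision = fit$precision, note = "", stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("cluster(s) skipped (< ", min_per_group,
            " usable samples per group): ",
            paste(skipped, collapse = ", "), call. = FALSE)
  if (length(rows) == 0)
    return(data.frame(cluster = character(), coefficient = numeric(),
                      fold_change = numeric(), p_value = numeric(),
                      q_value = numeric(), n_used = integer(),
                      n_excluded_outliers = integer(),
                      precision = numeric(), significant = logical(),
                      note = character()))
  out <- do.call(rbind, rows)
  out$q_value <- benjamini_hochberg(out$p_value)
  out$significant <- !is.na(out$q_value) & out$q_value < q_threshold
  out[, c("cluster", "coefficient", "fold_change", "p_value", "q_value",
          "n_used", "n_excluded_outliers", "precision", "significant",
          "note")]
}

#' Age/sex-adjusted cluster frequencies for display
#'
#' Residualizes the logit-transformed proportions on the nuisance
#' covariates (preserving the karyotype effect) and back-transforms to
#' the proportion scale, so adjusted values remain in (0, 1).
#'
#' @param freqs Cluster x sample matrix of proportions in (0, 1).
#' @param participants Participant table.
#' @param covariates Covariates to remove.
#' @return Cluster x sample matrix of adjusted proportions.
#' @export
adjusted_frequencies_for_display <- function(freqs, participants,
                                             covariates = c("age", "sex")) {
  if (any(freqs <= 0 | freqs >= 1, na.rm = TRUE))
    stop("proportions must lie strictly in (0, 1)", call. = FALSE)
  lg <- stats::qlogis(freqs)
  keep <- if ("karyotype" %in% names(participants)) "karyotype" else NULL
  adj <- adjust_covariates(lg, participants, covariates = covariates,
                           keep = keep)
  stats::plogis(adj$values)
}
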