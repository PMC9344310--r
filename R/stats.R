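#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after least-squares
#' removal of the covariates (plus an intercept); the p-value comes from the
#' t distribution with `n - k - 2` degrees of freedom, `k` the number of
#' covariates. With no covariates this is the plain Pearson correlation.
#' A Spearman variant (ranks taken before residualisation) is available.
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates Numeric vector/matrix of covariates, or `NULL`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Tibble of class `partial_correlation`: `r`, `p_value`, `n`,
#'   `n_covariates`, `method`.
#' @export
partial_corr <- function(x, y, covariates = NULL,
                         method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  k <- 0L
  if (!is.null(covariates)) {
    z <- as.matrix(covariates)
    stopifnot(nrow(z) == n)
    k <- ncol(z)
    if (qr(cbind(1, z))$rank < k + 1L) {
      stop("covariates are rank-deficient", call. = FALSE)
    }
    vx <- stats::var(x); vy <- stats::var(y)
    x <- stats::residuals(stats::lm.fit(cbind(1, z), x))
    y <- stats::residuals(stats::lm.fit(cbind(1, z), y))
    # a variable explained exactly by the covariates has zero residual
    # variance: its partial correlation with anything is 0 by convention
    if (stats::var(x) < 1e-12 * max(vx, 1) ||
        stats::var(y) < 1e-12 * max(vy, 1)) {
      out <- tibble::tibble(r = 0, p_value = 1, n = n,
                            n_covariates = k, method = method)
      class(out) <- c("partial_correlation", class(out))
      return(out)
    }
  }
  if (n <= k + 3) stop("need n > n_covariates + 3", call. = FALSE)
  r <- stats::cor(x, y)
  df <- n - k - 2L
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df)
  out <- tibble::tibble(r = r, p_value = p, n = n,
                        n_covariates = k, method = method)
  class(out) <- c("partial_correlation", class(out))
  out
}

#' Linear model of self-similarity on age and scan interval
#'
#' Ordinary least squares of per-subject self-similarity on post-menstrual
#' age at the first scan and days between scans (with intercept), giving the
#' beta coefficient and two-sided p-value per term. Heavy collinearity of
#' the predictors is reported via the design's condition number but the fit
#' is still returned.
#'
#' @param self_sim Numeric vector of self-similarities, one per subject.
#' @param pma1 PMA at first scan (weeks).
#' @param days Days between scans.
#' @return A `fingerprint_glm` wrapping the `lm` fit; use [generics::tidy()]
#'   / [generics::glance()].
#' @export
glm_self_similarity <- function(self_sim, pma1, days) {
  stopifnot(length(self_sim) == length(pma1),
            length(self_sim) == length(days))
  if (length(self_sim) < 5) stop("need at least 5 subjects", call. = FALSE)
  df <- data.frame(self_sim = self_sim, pma1 = pma1, days = days)
  fit <- stats::lm(self_sim ~ pma1 + days, data = df)
  kappa_x <- kappa(stats::model.matrix(fit), exact = TRUE)
  if (kappa_x > 1e8) {
    warning("near-collinear design (condition number ",
            format(kappa_x, digits = 3), ")", call. = FALSE)
  }
  structure(list(fit = fit, n_obs = length(self_sim), model = "ols",
                 condition_number = kappa_x),
            class = "fingerprint_glm")
}

#' @exportS3Method generics::tidy
tidy.fingerprint_glm <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(co), estimate = unname(co[, 1]),
                 std_error = unname(co[, 2]), p_value = unname(co[, 4]))
}

#' @exportS3Method generics::glance
glance.fingerprint_glm <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r_squared = s$r.squared, sigma = s$sigma,
                 n_obs = x$n_obs, model = x$model)
}

#' @export
print.fingerprint_glm <- function(x, ...) {
  cat("<fingerprint_glm> n =", x$n_obs, "\n")
  print(tidy.fingerprint_glm(x))
  invisible(x)
}

#' Mixed-effects model of self-to-other-similarity on scan interval
#'
#' Stacks the off-diagonal entries of the similarity matrix (every subject's
#' timepoint-1 scan against every *other* subject's timepoint-2 scan) and
#' fits a linear mixed-effects model by REML with a random intercept per
#' timepoint-1 subject, accounting for the repeated measures within each
#' row. The cross-subject scan interval is
#' `(column subject's pma_scan2 - row subject's pma_scan1) * 7` days — the
#' only interval defined between different subjects' scans. Fixed effects
#' are the interval and, by default, PMA at the first scan
#' (`form = "days_plus_pma"`); `form = "days_only"` drops the age term.
#' P-values use Satterthwaite degrees of freedom.
#'
#' @param s A `similarity_matrix`.
#' @param panel A `cohort_panel` covering the matrix's subjects.
#' @param form `"days_plus_pma"` (default) or `"days_only"`.
#' @param include_self Include diagonal entries as well (default `FALSE`).
#' @return A `fingerprint_lme` wrapping the `lmerTest` fit; use
#'   [generics::tidy()] / [generics::glance()].
#' @export
lme_self_to_other <- function(s, panel, form = c("days_plus_pma", "days_only"),
                              include_self = FALSE) {
  form <- match.arg(form)
  v <- s$values
  ids <- s$subjects
  if (!all(ids %in% panel$subject_id)) {
    stop("panel does not cover all similarity-matrix subjects", call. = FALSE)
  }
  panel <- panel[match(ids, panel$subject_id), ]
  long <- tidyr::expand_grid(i = seq_along(ids), j = seq_along(ids)) |>
    dplyr::filter(include_self | .data$i != .data$j) |>
    dplyr::mutate(
      subject_tp1 = ids[.data$i],
      rho = v[cbind(.data$i, .data$j)],
      pma1 = panel$pma_scan1[.data$i],
      days = (panel$pma_scan2[.data$j] - panel$pma_scan1[.data$i]) * 7)

  fml <- if (form == "days_plus_pma") {
    rho ~ days + pma1 + (1 | subject_tp1)
  } else {
    rho ~ days + (1 | subject_tp1)
  }
  fit <- suppressMessages(lmerTest::lmer(fml, data = long, REML = TRUE))
  if (lme4::isSingular(fit, tol = 1e-5)) {
    warning("random-intercept variance estimated at (or near) zero",
            call. = FALSE)
  }
  structure(list(fit = fit, n_obs = nrow(long), model = "lme", form = form),
            class = "fingerprint_lme")
}

#' @exportS3Method generics::tidy
tidy.fingerprint_lme <- function(x, ...) {
  co <- stats::coef(summary(x$fit))
  tibble::tibble(term = rownames(co),
                 estimate = unname(co[, "Estimate"]),
                 std_error = unname(co[, "Std. Error"]),
                 p_value = unname(co[, "Pr(>|t|)"]))
}

#' @exportS3Method generics::glance
glance.fingerprint_lme <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  tibble::tibble(
    n_obs = x$n_obs, model = x$model, form = x$form,
    sd_intercept = vc$sdcor[vc$grp == "subject_tp1"],
    sd_residual = vc$sdcor[vc$grp == "Residual"])
}

#' @export
print.fingerprint_lme <- function(x, ...) {
  cat("<fingerprint_lme> n =", x$n_obs, "(", x$form, ")\n")
  print(tidy.fingerprint_lme(x))
  invisible(x)
}

#' Bonferroni correction
#'
#' Adjusts p-values for a family of `m` tests: `adjusted = min(1, p * m)`,
#' flagged significant below `alpha`. The default family size of 7 matches
#' the seven anatomical clusters tested per modality and predictor.
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @param m Family size (defaults to `max(7, length(p_values))`).
#' @param alpha Significance level (default 0.05).
#' @return Tibble with `p_value`, `p_adjusted`, `significant`.
#' @export
bonferroni <- function(p_values, m = max(7L, length(p_values)), alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (m < length(p_values)) {
    stop("family size m must be at least the number of p-values",
         call. = FALSE)
  }
  adj <- pmin(1, p_values * m)
  tibble::tibble(p_value = p_values, p_adjusted = adj,
                 significant = adj < alpha)
}

#' Motion association and low-motion subgroup
#'
#' Correlates per-subject mean framewise displacement (average of the two
#' scans' means) with functional self-similarity, and extracts the subgroup
#' whose mean FD stays below a threshold at *both* timepoints — the
#' low-motion subsample on which the association is expected to vanish if
#' it is motion-driven.
#'
#' @param self_sim Numeric vector of self-similarities (panel order).
#' @param panel A `cohort_panel` with `mean_fd_tp1` and `mean_fd_tp2`.
#' @param fd_threshold Threshold in mm (default 0.3).
#' @return List: `correlation` (a `partial_correlation` tibble),
#'   `per_timepoint` (tibble of per-scan correlations), `subgroup`
#'   (filtered panel), `subgroup_self_sim`.
#' @export
motion_analysis <- function(self_sim, panel, fd_threshold = 0.3) {
  if (anyNA(panel$mean_fd_tp1) || anyNA(panel$mean_fd_tp2)) {
    stop("panel is missing mean framewise displacement for some scans",
         call. = FALSE)
  }
  stopifnot(length(self_sim) == nrow(panel))
  mean_fd <- (panel$mean_fd_tp1 + panel$mean_fd_tp2) / 2
  corr <- partial_corr(mean_fd, self_sim)
  per_tp <- dplyr::bind_rows(
    dplyr::mutate(partial_corr(panel$mean_fd_tp1, self_sim), timepoint = 1L),
    dplyr::mutate(partial_corr(panel$mean_fd_tp2, self_sim), timepoint = 2L))
  keep <- panel$mean_fd_tp1 < fd_threshold & panel$mean_fd_tp2 < fd_threshold
  if (!any(keep)) {
    warning("no subjects below fd_threshold = ", fd_threshold, call. = FALSE)
  }
  list(correlation = corr, per_timepoint = per_tp,
       subgroup = panel[keep, ], subgroup_self_sim = self_sim[keep])
}
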