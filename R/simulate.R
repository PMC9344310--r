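#' Parameters for the synthetic paired-timepoint cohort
#'
#' Collects and validates the generator's tunable parameters. Defaults
#' emulate a preterm-to-term longitudinal cohort: first scans in the
#' preterm PMA range, second scans at term-equivalent age, 2300 BOLD samples
#' per scan, a strong structural fingerprint and a weak functional one with
#' age-dependent drift.
#'
#' @param n_subjects Number of subjects (each scanned at both timepoints).
#' @param n_nodes Atlas nodes (default 90).
#' @param backbone_density Probability an edge belongs to the shared group
#'   backbone (default 0.6).
#' @param alpha_sc Structural fingerprint strength, s.d. of the
#'   subject-specific additive component on log edge weights (default 0.5).
#' @param alpha_fc Functional fingerprint strength on factor loadings
#'   (default 0.08). Deliberately weak relative to the developmental drift,
#'   so the functional arm reproduces the low test-retest identifiability
#'   seen in developing cohorts.
#' @param gamma Developmental drift rate per week of post-menstrual age
#'   (default 0.05). Drives both the shared structural maturation gradient
#'   and the age-dependent reshaping of functional correlation structure.
#' @param sigma_sc Structural log-weight noise s.d. per scan (default 0.1).
#' @param n_latent Latent factors behind the functional correlation
#'   structure (default 10).
#' @param n_timepoints BOLD samples per scan (default 2300; must exceed
#'   `n_nodes` so partial correlation is well-posed).
#' @param psi Unique variance added to the factor covariance (default 0.5;
#'   must be positive so the correlation is positive-definite).
#' @param pma1_range,pma2_range PMA ranges (weeks) at scans 1 and 2
#'   (defaults c(29.3, 37.4) and c(38.4, 45)).
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A `synthetic_params` list.
#' @export
synthetic_params <- function(n_subjects,
                             n_nodes = 90L,
                             backbone_density = 0.6,
                             alpha_sc = 0.5,
                             alpha_fc = 0.08,
                             gamma = 0.05,
                             sigma_sc = 0.1,
                             n_latent = 10L,
                             n_timepoints = 2300L,
                             psi = 0.5,
                             pma1_range = c(29.3, 37.4),
                             pma2_range = c(38.4, 45.0),
                             seed = 1L) {
  p <- list(n_subjects = as.integer(n_subjects), n_nodes = as.integer(n_nodes),
            backbone_density = backbone_density, alpha_sc = alpha_sc,
            alpha_fc = alpha_fc, gamma = gamma, sigma_sc = sigma_sc,
            n_latent = as.integer(n_latent),
            n_timepoints = as.integer(n_timepoints), psi = psi,
            pma1_range = pma1_range, pma2_range = pma2_range,
            seed = as.integer(seed))
  stopifnot(p$n_subjects >= 1, p$n_nodes >= 3,
            p$backbone_density > 0, p$backbone_density <= 1,
            p$alpha_sc >= 0, p$alpha_fc >= 0, p$sigma_sc >= 0,
            p$n_latent >= 1, p$psi > 0,
            p$n_timepoints > p$n_nodes,
            diff(p$pma1_range) > 0, diff(p$pma2_range) > 0,
            p$pma2_range[1] > p$pma1_range[2])
  structure(p, class = "synthetic_params")
}

#' Simulate a paired-timepoint cohort
#'
#' Generative model, drawn in a fixed order under `set.seed(params$seed)` so
#' the same seed yields an identical cohort:
#'
#' 1. Panel: PMA at scans 1 and 2 uniform in their ranges; gestational age at
#'    birth = PMA1 minus Uniform(0.5, 4) weeks; sex alternating M/F.
#' 2. Group backbone: each of the n(n-1)/2 node pairs is a backbone edge
#'    independently with probability `backbone_density`; backbone edges carry
#'    a Normal(0, 1) baseline log-weight. Non-backbone edges stay 0 in every
#'    structural matrix.
#' 3. A shared developmental gradient D and, per subject, a fingerprint
#'    field F_i — both i.i.d. Normal(0, 1) per backbone edge.
#' 4. Structural connectome at a scan of age p (weeks):
#'    `log W = baseline + gamma * (p - 40) * D + alpha_sc * F_i +
#'    sigma_sc * noise`, exponentiated and symmetrised. The log-additive
#'    form keeps weights positive without clipping; the downstream Spearman
#'    similarity only sees edge ranks.
#' 5. Functional correlation via a factor model: loading matrix
#'    `L_i(p) = L_group + alpha_fc * L_i + gamma * (p - 40) * L_dev`
#'    (each an n_nodes x n_latent Normal(0, 1) draw; L_group and L_dev
#'    shared, L_i per subject); covariance `L L' + psi I` converted to a
#'    correlation matrix (positive-definite for any psi > 0). BOLD-like
#'    timeseries are `n_timepoints` independent multivariate-normal draws
#'    from it.
#'
#' @param params A [synthetic_params()].
#' @param modalities Which data to generate: subset of `c("sc", "fc")`.
#'   Structural draws precede functional ones, so the structural arm is
#'   identical whether or not timeseries are generated.
#' @return A `synthetic_cohort`: `panel` (cohort_panel tibble), `sc` and
#'   `ts` (lists `tp1` / `tp2` of per-subject connectomes / ROI-by-time
#'   matrices), `ground_truth` (fingerprint fields and loadings), `params`.
#' @export
simulate_cohort <- function(params, modalities = c("sc", "fc")) {
  stopifnot(inherits(params, "synthetic_params"))
  modalities <- match.arg(modalities, c("sc", "fc"), several.ok = TRUE)
  p <- params
  set.seed(p$seed)
  n <- p$n_subjects
  nn <- p$n_nodes

  pma1 <- stats::runif(n, p$pma1_range[1], p$pma1_range[2])
  pma2 <- stats::runif(n, p$pma2_range[1], p$pma2_range[2])
  ga <- pma1 - stats::runif(n, 0.5, 4)
  ids <- sprintf("sub-%03d", seq_len(n))
  panel <- as_cohort_panel(tibble::tibble(
    subject_id = ids,
    sex = rep(c("M", "F"), length.out = n),
    ga_birth = ga, pma_scan1 = pma1, pma_scan2 = pma2))

  ut <- upper.tri(matrix(0, nn, nn))
  m <- sum(ut)
  edge_on <- stats::runif(m) < p$backbone_density
  if (sum(edge_on) < 3) stop("backbone has fewer than 3 edges", call. = FALSE)
  base_logw <- stats::rnorm(m) * edge_on
  dev_grad <- stats::rnorm(m)
  fingerprints <- lapply(seq_len(n), function(i) stats::rnorm(m))

  build_sc <- function(i, tp, pma) {
    logw <- base_logw + p$gamma * (pma - 40) * dev_grad +
      p$alpha_sc * fingerprints[[i]] + p$sigma_sc * stats::rnorm(m)
    w <- matrix(0, nn, nn)
    w[ut] <- exp(logw) * edge_on
    w <- w + t(w)
    connectome(w, ids[i], tp, "structural")
  }
  sc <- NULL
  if ("sc" %in% modalities) {
    sc <- list(
      tp1 = lapply(seq_len(n), function(i) build_sc(i, 1L, pma1[i])),
      tp2 = lapply(seq_len(n), function(i) build_sc(i, 2L, pma2[i]))
    )
  }

  ts <- NULL
  loadings <- NULL
  if ("fc" %in% modalities) {
    l_group <- matrix(stats::rnorm(nn * p$n_latent), nn, p$n_latent)
    l_dev <- matrix(stats::rnorm(nn * p$n_latent), nn, p$n_latent)
    loadings <- lapply(seq_len(n), function(i) {
      matrix(stats::rnorm(nn * p$n_latent), nn, p$n_latent)
    })
    build_ts <- function(i, pma) {
      l <- l_group + p$alpha_fc * loadings[[i]] +
        p$gamma * (pma - 40) * l_dev
      sigma <- tcrossprod(l) + diag(p$psi, nn)
      corr <- stats::cov2cor(sigma)
      simulate_timeseries(corr, p$n_timepoints)
    }
    ts <- list(
      tp1 = lapply(seq_len(n), function(i) build_ts(i, pma1[i])),
      tp2 = lapply(seq_len(n), function(i) build_ts(i, pma2[i]))
    )
  }

  structure(list(panel = panel, sc = sc, ts = ts,
                 ground_truth = list(edge_on = edge_on,
                                     base_logw = base_logw,
                                     dev_grad = dev_grad,
                                     fingerprints = fingerprints,
                                     fc_loadings = loadings),
                 params = p),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d nodes (seed %d)\n",
              x$params$n_subjects, x$params$n_nodes, x$params$seed))
  invisible(x)
}

#' Draw a multivariate-normal timeseries with a given correlation
#'
#' Samples `n_timepoints` independent zero-mean multivariate-normal vectors
#' whose population correlation is `correlation`, via the Cholesky factor.
#' The sample correlation converges to the input as the number of samples
#' grows.
#'
#' @param correlation Symmetric positive-definite matrix with unit diagonal.
#' @param n_timepoints Number of samples (columns of the output).
#' @param seed Optional integer; when given, seeds the draw (otherwise the
#'   ambient RNG stream is used).
#' @return `n x n_timepoints` numeric matrix (nodes in rows).
#' @export
simulate_timeseries <- function(correlation, n_timepoints, seed = NULL) {
  n <- nrow(correlation)
  stopifnot(ncol(correlation) == n,
            max(abs(correlation - t(correlation))) < 1e-8,
            max(abs(diag(correlation) - 1)) < 1e-8)
  ch <- tryCatch(chol(correlation),
                 error = function(e) stop("correlation matrix is not positive-definite",
                                          call. = FALSE))
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(stats::rnorm(n_timepoints * n), n_timepoints, n)
  t(z %*% ch)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes the cohort table (`cohort.csv`), structural connectomes
#' (`sc_<subject>_tp<k>.csv`) and timeseries (`ts_<subject>_tp<k>.csv`,
#' ROI x time) into a directory, in the formats the readers accept.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(cohort$panel),
                   file.path(dir, "cohort.csv"), row.names = FALSE)
  for (tp in c(1L, 2L)) {
    key <- paste0("tp", tp)
    if (!is.null(cohort$sc)) {
      for (w in cohort$sc[[key]]) {
        write_connectome(w, file.path(dir, sprintf("sc_%s_tp%d.csv",
                                                   attr(w, "subject_id"), tp)))
      }
    }
    if (!is.null(cohort$ts)) {
      for (i in seq_along(cohort$ts[[key]])) {
        m <- cohort$ts[[key]][[i]]
        utils::write.table(m,
          file.path(dir, sprintf("ts_%s_tp%d.csv",
                                 cohort$panel$subject_id[i], tp)),
          sep = ",", row.names = FALSE, col.names = FALSE)
      }
    }
  }
  invisible(dir)
}
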