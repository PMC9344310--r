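#' Pearson functional connectivity
#'
#' Computes the Pearson correlation of the BOLD signal between every pair of
#' ROIs. Negative correlations are not considered and are set to zero after
#' the correlation is computed; the diagonal is zeroed. No scrubbing or
#' filtering is applied — preprocessing happens upstream.
#'
#' @param ts ROI-by-time numeric matrix (nodes in rows, samples in columns).
#' @param subject_id,timepoint Metadata carried onto the result.
#' @return A [connectome()] with modality `functional_pearson`.
#' @export
pearson_fc <- function(ts, subject_id = "unknown", timepoint = 1L) {
  check_timeseries(ts, min_t = 3L)
  r <- stats::cor(t(ts))
  r[r < 0] <- 0
  diag(r) <- 0
  connectome(r, subject_id, timepoint, "functional_pearson",
             node_labels = rownames(ts))
}

#' Partial-correlation functional connectivity
#'
#' Computes the partial correlation between every pair of ROIs controlling
#' for the signal in all remaining ROIs, via the precision matrix P of the
#' sample covariance: `pc(i,j) = -P[i,j] / sqrt(P[i,i] * P[j,j])`. Negative
#' partial correlations are set to zero afterwards.
#'
#' Requires more samples than nodes so the sample covariance is invertible;
#' an optional ridge term is available for near-singular covariances (off by
#' default, as typical acquisitions have T far above the node count).
#'
#' @inheritParams pearson_fc
#' @param ridge Non-negative ridge added to the covariance diagonal, as a
#'   fraction of its mean diagonal. Default 0.
#' @return A [connectome()] with modality `functional_partial`.
#' @export
partial_fc <- function(ts, subject_id = "unknown", timepoint = 1L, ridge = 0) {
  check_timeseries(ts, min_t = 3L)
  n <- nrow(ts)
  if (ncol(ts) <= n && ridge == 0) {
    stop("partial correlation needs more samples than ROIs (T = ", ncol(ts),
         ", n = ", n, "); supply longer timeseries or a ridge > 0",
         call. = FALSE)
  }
  s <- stats::cov(t(ts))
  if (ridge > 0) s <- s + diag(ridge * mean(diag(s)), n)
  p <- tryCatch(solve(s), error = function(e) {
    stop("sample covariance is singular; use T > n_nodes or ridge > 0",
         call. = FALSE)
  })
  d <- sqrt(diag(p))
  pc <- -p / tcrossprod(d)
  pc <- (pc + t(pc)) / 2  # kill numeric asymmetry from solve()
  pc[pc < 0] <- 0
  pc <- pmin(pc, 1)
  diag(pc) <- 0
  connectome(pc, subject_id, timepoint, "functional_partial",
             node_labels = rownames(ts))
}

check_timeseries <- function(ts, min_t) {
  if (!is.matrix(ts) || !is.numeric(ts)) {
    stop("timeseries must be a numeric ROI x time matrix", call. = FALSE)
  }
  if (ncol(ts) < min_t) {
    stop("timeseries needs at least ", min_t, " samples", call. = FALSE)
  }
  v <- apply(ts, 1, stats::var)
  if (any(v == 0)) {
    roi <- which(v == 0)
    lab <- if (!is.null(rownames(ts))) rownames(ts)[roi] else roi
    stop("constant signal in ROI ", paste(lab, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read an ROI-by-time timeseries matrix from a delimited file
#'
#' @param path Comma- or tab-delimited numeric matrix, ROIs in rows,
#'   samples in columns; optional leading label column is auto-detected.
#' @return Numeric matrix.
#' @export
read_timeseries <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, header = FALSE,
                          stringsAsFactors = FALSE)
  labels <- NULL
  if (is.character(df[[1]])) {
    labels <- df[[1]]
    df <- df[, -1, drop = FALSE]
  }
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  dimnames(m) <- if (is.null(labels)) NULL else list(labels, NULL)
  m
}
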