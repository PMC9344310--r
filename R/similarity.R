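#' Proportional network density mask
#'
#' Retains the top fraction of possible edges by weight: the
#' `ceil(density * n*(n-1)/2)` largest upper-triangle weights, with ties
#' broken deterministically by ascending (row, column) node-pair order.
#' Density is computed over all possible node pairs, not over nonzero
#' entries, so zero-weight edges can be retained when the requested density
#' exceeds the nonzero fraction (a message is emitted).
#'
#' @param w A [connectome()] or square symmetric matrix.
#' @param density Fraction of possible edges to retain, in (0, 1].
#' @return Symmetric logical matrix with `FALSE` diagonal.
#' @export
density_mask <- function(w, density) {
  if (!is.numeric(density) || length(density) != 1 ||
      density <= 0 || density > 1) {
    stop("density must be a single value in (0, 1]", call. = FALSE)
  }
  n <- nrow(w)
  ut <- upper.tri(w)
  vals <- w[ut]
  m <- length(vals)            # n(n-1)/2 possible edges
  k <- as.integer(ceiling(density * m))
  # upper.tri is column-major; recover (i, j) for the lexicographic tie-break
  ij <- which(ut, arr.ind = TRUE)
  ord <- order(-vals, ij[, 1], ij[, 2])
  keep <- ord[seq_len(k)]
  if (any(vals[keep] == 0)) {
    message("density ", density, " retains ", sum(vals[keep] == 0),
            " zero-weight edge(s)")
  }
  mask <- matrix(FALSE, n, n)
  sel <- ij[keep, , drop = FALSE]
  mask[sel] <- TRUE
  mask <- mask | t(mask)
  mask
}

#' Masked Spearman similarity between two connectomes
#'
#' Spearman rank correlation of the two matrices' upper-triangle edge
#' weights restricted to a common edge mask, so the same inter-regional
#' connections are compared. Ties receive average ranks. With `mask = NULL`
#' all upper-triangle pairs are used (the unthresholded variant).
#'
#' @param w1,w2 Connectomes with the same node count.
#' @param mask Symmetric logical mask from [density_mask()], or `NULL`.
#' @return Spearman rho (scalar).
#' @export
masked_spearman <- function(w1, w2, mask = NULL) {
  if (nrow(w1) != nrow(w2)) stop("node counts differ", call. = FALSE)
  ut <- upper.tri(w1)
  keep <- if (is.null(mask)) ut else ut & mask
  if (sum(keep) < 3) {
    stop("mask retains fewer than 3 edges", call. = FALSE)
  }
  stats::cor(w1[keep], w2[keep], method = "spearman")
}

#' Subject-by-subject similarity matrix between timepoints
#'
#' For every ordered pair (i, j), computes the masked Spearman similarity of
#' subject i's timepoint-1 connectome with subject j's timepoint-2
#' connectome. Under the default row mask convention the edge mask for the
#' whole of row i comes from thresholding subject i's timepoint-1 matrix at
#' the given density, so all entries within a row compare a fixed edge set —
#' commensurable with the row-wise match criterion and row-wise
#' normalisation. `union` / `intersection` instead combine the row and
#' column subjects' timepoint-1 masks, for sensitivity analysis.
#'
#' @param tp1,tp2 Lists of [connectome()]s in matched subject order (same
#'   subjects, same modality).
#' @param density Fraction in (0, 1], or `NULL` for no thresholding/masking.
#' @param mask_convention `"row"` (default), `"union"` or `"intersection"`.
#' @return A `similarity_matrix`: list with `values` (N x N Spearman rho,
#'   rows = timepoint-1 subjects, columns = timepoint-2 subjects, diagonal =
#'   self-similarity), `subjects`, `density`, `modality`, `mask_convention`.
#' @export
similarity_matrix <- function(tp1, tp2, density = 0.25,
                              mask_convention = c("row", "union", "intersection")) {
  mask_convention <- match.arg(mask_convention)
  ids1 <- vapply(tp1, attr, character(1), "subject_id")
  ids2 <- vapply(tp2, attr, character(1), "subject_id")
  if (!identical(ids1, ids2)) {
    stop("timepoint-1 and timepoint-2 subject lists do not match",
         call. = FALSE)
  }
  mods <- unique(c(vapply(tp1, attr, character(1), "modality"),
                   vapply(tp2, attr, character(1), "modality")))
  if (length(mods) != 1) stop("mixed modalities", call. = FALSE)
  n <- length(tp1)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)

  masks <- NULL
  if (!is.null(density)) {
    masks <- lapply(tp1, density_mask, density = density)
  }
  vals <- matrix(NA_real_, n, n, dimnames = list(ids1, ids1))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      mask <- if (is.null(masks)) NULL else switch(mask_convention,
        row          = masks[[i]],
        union        = masks[[i]] | masks[[j]],
        intersection = masks[[i]] & masks[[j]])
      vals[i, j] <- masked_spearman(tp1[[i]], tp2[[j]], mask)
    }
  }
  structure(list(values = vals, subjects = ids1,
                 density = density, modality = mods,
                 mask_convention = if (is.null(density)) NA_character_
                                   else mask_convention),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d x %d  %s  density %s\n",
              nrow(x$values), ncol(x$values), x$modality,
              if (is.null(x$density)) "none" else format(x$density)))
  invisible(x)
}

#' @export
as.data.frame.similarity_matrix <- function(x, ...) {
  as.data.frame(as_tibble.similarity_matrix(x))
}

#' Long-format view of a similarity matrix
#'
#' @param x A `similarity_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `subject_tp1`, `subject_tp2`, `rho`, `self`.
#' @exportS3Method tibble::as_tibble
as_tibble.similarity_matrix <- function(x, ...) {
  v <- x$values
  tibble::tibble(
    subject_tp1 = rep(rownames(v), times = ncol(v)),
    subject_tp2 = rep(colnames(v), each = nrow(v)),
    rho = as.vector(v)
  ) |>
    dplyr::mutate(self = .data$subject_tp1 == .data$subject_tp2)
}

#' Identifiability from a similarity matrix
#'
#' A subject is successfully matched when their self-similarity (diagonal
#' entry) is strictly higher than every self-to-other-similarity in their
#' row. Ties count as non-matches.
#'
#' @param s A `similarity_matrix` (or square numeric matrix).
#' @return An `identifiability` object: `n_matched`, `n_total`, `rate`,
#'   `matched` (logical per subject), `self_similarities`,
#'   `other_similarities`.
#' @export
identifiability <- function(s) {
  v <- if (inherits(s, "similarity_matrix")) s$values else s
  if (nrow(v) != ncol(v)) stop("similarity matrix must be square", call. = FALSE)
  n <- nrow(v)
  matched <- vapply(seq_len(n), function(i) {
    v[i, i] > max(v[i, -i])
  }, logical(1))
  names(matched) <- rownames(v)
  structure(list(
    n_matched = sum(matched),
    n_total = n,
    rate = sum(matched) / n,
    matched = matched,
    self_similarities = stats::setNames(diag(v), rownames(v)),
    other_similarities = v[row(v) != col(v)]
  ), class = "identifiability")
}

#' @export
print.identifiability <- function(x, ...) {
  cat(sprintf("identifiability: %d/%d matched (%.1f%%)\n",
              x$n_matched, x$n_total, 100 * x$rate))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.identifiability <- function(x, ...) {
  tibble::tibble(
    n_matched = x$n_matched, n_total = x$n_total, rate = x$rate,
    mean_self = mean(x$self_similarities),
    mean_other = mean(x$other_similarities)
  )
}

#' @exportS3Method generics::tidy
tidy.identifiability <- function(x, ...) {
  tibble::tibble(
    subject_id = names(x$matched),
    self_similarity = unname(x$self_similarities),
    matched = unname(x$matched)
  )
}

#' Row-max normalisation of a similarity matrix
#'
#' Divides each row by its own maximum, so a value of 1 marks the best match
#' for each timepoint-1 subject; the diagonal is 1 exactly when the subject
#' is successfully matched. Used for visualisation; identifiability is
#' unchanged.
#'
#' @param s A `similarity_matrix`.
#' @return A `similarity_matrix` with normalised values.
#' @export
row_max_normalize <- function(s) {
  v <- s$values
  mx <- apply(v, 1, max)
  if (any(mx <= 0)) stop("row maximum must be positive", call. = FALSE)
  s$values <- v / mx
  s
}

#' Row-wise z-scoring of a similarity matrix
#'
#' Standardises each row (one timepoint-1 subject's self- and
#' self-to-other-similarities) to mean 0 and sample standard deviation 1.
#' A strictly monotone per-row transform, so the row-wise match criterion is
#' preserved exactly. Global pooling (one mean/sd over the whole matrix) is
#' available as an alternative.
#'
#' @param s A `similarity_matrix`.
#' @param pooling `"row"` (default) or `"global"`.
#' @return A `similarity_matrix` with z-scored values.
#' @export
zscore_rows <- function(s, pooling = c("row", "global")) {
  pooling <- match.arg(pooling)
  v <- s$values
  if (pooling == "row") {
    if (ncol(v) < 3) stop("need at least 3 entries per row", call. = FALSE)
    sds <- apply(v, 1, stats::sd)
    if (any(sds == 0)) stop("zero-variance row", call. = FALSE)
    s$values <- (v - rowMeans(v)) / sds
  } else {
    if (stats::sd(v) == 0) stop("zero-variance matrix", call. = FALSE)
    s$values <- (v - mean(v)) / stats::sd(v)
  }
  s
}

#' Identifiability across a sweep of density thresholds
#'
#' Recomputes the similarity matrix and identifiability rate at each
#' requested network density and reports which densities attain the maximal
#' rate (typically a contiguous plateau).
#'
#' @inheritParams similarity_matrix
#' @param densities Numeric vector of densities in (0, 1].
#' @return Tibble with columns `density`, `rate`, `n_matched`, `n_total`,
#'   `is_max`; attribute `argmax` holds the maximal-rate densities.
#' @export
threshold_sweep <- function(tp1, tp2, densities = seq(0.05, 1, by = 0.05),
                            mask_convention = "row") {
  if (length(densities) == 0) stop("densities must be non-empty", call. = FALSE)
  rows <- purrr::map(densities, function(d) {
    idf <- identifiability(similarity_matrix(tp1, tp2, density = d,
                                             mask_convention = mask_convention))
    tibble::tibble(density = d, rate = idf$rate,
                   n_matched = idf$n_matched, n_total = idf$n_total)
  })
  out <- dplyr::bind_rows(rows)
  out$is_max <- out$rate == max(out$rate)
  attr(out, "argmax") <- out$density[out$is_max]
  out
}
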