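#' Weighted connectome matrix
#'
#' A `connectome` is a symmetric, non-negative, zero-diagonal weighted
#' adjacency matrix for one subject at one timepoint, tagged with the
#' connectivity modality. Structural weights are tractography-derived edge
#' strengths (any non-negative scale; downstream Spearman similarity is
#' invariant to monotone rescaling). Functional weights are correlations with
#' negatives set to zero, so they additionally lie in \[0, 1\].
#'
#' @param weights Square numeric matrix. Asymmetries up to `tol` are
#'   symmetrized by averaging; larger asymmetries are an error. Nonzero
#'   diagonal entries are zeroed (with a warning for structural matrices —
#'   functional inputs routinely carry a unit diagonal, which is dropped
#'   silently as the analysis never uses it).
#' @param subject_id Subject identifier.
#' @param timepoint Scan timepoint, `1` or `2`.
#' @param modality One of `"structural"`, `"functional_pearson"`,
#'   `"functional_partial"`.
#' @param node_labels Optional character vector of node names.
#' @param tol Maximum tolerated asymmetry (default `1e-10`).
#'
#' @return A `connectome` object: the validated matrix with `subject_id`,
#'   `timepoint` and `modality` attributes.
#' @export
#' @examples
#' w <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
#' connectome(w, "s01", 1, "structural")
connectome <- function(weights, subject_id, timepoint, modality,
                       node_labels = NULL, tol = 1e-10) {
  modality <- match.arg(modality,
                        c("structural", "functional_pearson", "functional_partial"))
  timepoint <- as.integer(timepoint)
  stopifnot(timepoint %in% c(1L, 2L))
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stop("`weights` must be a numeric matrix", call. = FALSE)
  }
  n <- nrow(weights)
  if (ncol(weights) != n) {
    stop("connectome matrix must be square, got ", n, "x", ncol(weights),
         call. = FALSE)
  }
  if (n < 2) stop("connectome needs at least 2 nodes", call. = FALSE)
  if (anyNA(weights)) stop("connectome weights contain NA", call. = FALSE)

  asym <- max(abs(weights - t(weights)))
  if (asym > tol) {
    stop("matrix asymmetry ", format(asym), " exceeds tolerance ", tol,
         call. = FALSE)
  }
  weights <- (weights + t(weights)) / 2

  off <- weights[row(weights) != col(weights)]
  if (any(off < 0)) {
    stop("negative weights are not allowed (", modality,
         "); functional negatives must be zeroed upstream", call. = FALSE)
  }
  if (modality != "structural" && any(off > 1 + 1e-12)) {
    stop("functional weights must lie in [0, 1]", call. = FALSE)
  }
  if (any(diag(weights) != 0)) {
    if (modality == "structural") {
      warning("nonzero diagonal zeroed for subject ", subject_id, call. = FALSE)
    }
    diag(weights) <- 0
  }

  if (!is.null(node_labels)) {
    stopifnot(length(node_labels) == n)
    dimnames(weights) <- list(node_labels, node_labels)
  }
  structure(weights,
            subject_id = as.character(subject_id),
            timepoint = timepoint,
            modality = modality,
            class = c("connectome", "matrix", "array"))
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %s  tp%d  %s  %d nodes\n",
              attr(x, "subject_id"), attr(x, "timepoint"),
              attr(x, "modality"), nrow(x)))
  invisible(x)
}

n_nodes <- function(w) nrow(w)

#' Read a connectome matrix from a delimited text file
#'
#' Accepts comma- or tab-delimited square numeric matrices, optionally with a
#' single header row of node labels (auto-detected: a first row that fails
#' numeric parsing is taken as labels).
#'
#' @param path Path to the matrix file.
#' @inheritParams connectome
#' @return A [connectome()].
#' @export
read_connectome <- function(path, subject_id, timepoint, modality) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty connectome file: ", path, call. = FALSE)
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","

  first <- strsplit(lines[[1]], sep, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  labels <- NULL
  if (has_header) {
    labels <- trimws(first)
    lines <- lines[-1]
  }
  rows <- lapply(lines, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(l, sep, fixed = TRUE)[[1]]))
    if (anyNA(v)) stop("non-numeric entry in ", path, call. = FALSE)
    v
  })
  ncols <- unique(vapply(rows, length, integer(1)))
  if (length(ncols) != 1 || ncols != length(rows)) {
    stop("connectome file is not a square matrix: ", path,
         " (", length(rows), " rows, columns ", paste(ncols, collapse = "/"),
         ")", call. = FALSE)
  }
  w <- do.call(rbind, rows)
  connectome(w, subject_id, timepoint, modality, node_labels = labels)
}

#' Write a connectome matrix to a delimited text file
#'
#' @param w A [connectome()] (or plain matrix).
#' @param path Output path; `.tsv` extension selects tab delimiting,
#'   anything else comma.
#' @param labels Write a header row of node labels when present.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(w, path, labels = !is.null(rownames(w))) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  con <- file(path, "w")
  on.exit(close(con))
  if (labels && !is.null(rownames(w))) {
    writeLines(paste(rownames(w), collapse = sep), con)
  }
  # full precision so write-then-read round-trips exactly
  apply(unclass(w), 1, function(r) {
    writeLines(paste(format(r, digits = 17, scientific = TRUE, trim = TRUE),
                     collapse = sep), con)
  })
  invisible(path)
}

#' Read a cohort metadata table
#'
#' Reads a delimited table with columns `subject_id`, `sex`, `ga_birth`,
#' `pma_scan1`, `pma_scan2` (weeks) and optionally `mean_fd_tp1`,
#' `mean_fd_tp2` (mm), validates it, and derives `days_between_scans`
#' as `(pma_scan2 - pma_scan1) * 7`.
#'
#' Rows violating the panel invariants (second scan not after the first,
#' gestational age at birth exceeding age at first scan, duplicated subject
#' id) are dropped with a named warning; the returned panel contains only
#' valid subjects.
#'
#' @param path Path to a comma- or tab-delimited table with a header.
#' @return A tibble of class `cohort_panel`, one row per subject.
#' @export
read_cohort_table <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  as_cohort_panel(df)
}

#' Build a validated cohort panel from a data frame
#'
#' @param df Data frame with the columns documented in [read_cohort_table()].
#' @return A `cohort_panel` tibble with `days_between_scans` derived.
#' @export
as_cohort_panel <- function(df) {
  required <- c("subject_id", "sex", "ga_birth", "pma_scan1", "pma_scan2")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("cohort table missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tb <- tibble::as_tibble(df)
  tb$subject_id <- as.character(tb$subject_id)
  tb$sex <- toupper(as.character(tb$sex))
  if (!all(tb$sex %in% c("M", "F"))) {
    stop("sex must be M or F", call. = FALSE)
  }
  for (col in c("mean_fd_tp1", "mean_fd_tp2")) {
    if (!col %in% names(tb)) tb[[col]] <- NA_real_
  }

  bad <- character(0)
  flag <- function(cond, reason) {
    ids <- tb$subject_id[cond]
    if (length(ids) > 0) {
      bad <<- union(bad, ids)
      warning("dropping subject(s) ", paste(ids, collapse = ", "),
              ": ", reason, call. = FALSE)
    }
  }
  flag(tb$pma_scan2 <= tb$pma_scan1, "pma_scan2 must exceed pma_scan1")
  flag(tb$ga_birth > tb$pma_scan1, "ga_birth exceeds pma_scan1")
  flag(duplicated(tb$subject_id) | duplicated(tb$subject_id, fromLast = TRUE),
       "duplicate subject_id")

  tb <- dplyr::filter(tb, !.data$subject_id %in% bad)
  tb <- dplyr::mutate(tb,
    days_between_scans = (.data$pma_scan2 - .data$pma_scan1) * 7)
  tb <- dplyr::select(tb, "subject_id", "sex", "ga_birth", "pma_scan1",
                      "pma_scan2", "days_between_scans",
                      "mean_fd_tp1", "mean_fd_tp2",
                      dplyr::everything())
  class(tb) <- c("cohort_panel", class(tb))
  tb
}
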