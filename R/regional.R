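#' Rerun the fingerprinting analysis within anatomical clusters
#'
#' For each cluster, restricts every subject's connectomes to the cluster's
#' internal node pairs and reruns the full similarity pipeline — density
#' mask (recomputed on the cluster's own pair count), masked Spearman
#' similarity, identification and row z-scores. "Regional" edges are the
#' within-cluster k x k pairs; the cluster-to-whole-brain variant (all rows
#' of the cluster's nodes) is available via `edge_scope = "to_all"` for
#' sensitivity analysis.
#'
#' @inheritParams similarity_matrix
#' @param clusters Named list of 0-based node index vectors
#'   (see [study_clusters()], [read_clusters()]).
#' @param edge_scope `"within"` (default) or `"to_all"`.
#' @return A `regional_result`: `summary` tibble (one row per cluster:
#'   `cluster`, `n_nodes`, `n_matched`, `n_total`, `rate`, `mean_self`,
#'   `mean_other`), plus per-cluster lists `similarity`, `identifiability`
#'   and `zscores`.
#' @export
regional_pipeline <- function(tp1, tp2, clusters, density = 0.25,
                              mask_convention = "row",
                              edge_scope = c("within", "to_all")) {
  edge_scope <- match.arg(edge_scope)
  nn <- nrow(tp1[[1]])
  sims <- list(); idfs <- list(); zs <- list()
  for (name in names(clusters)) {
    idx <- clusters[[name]]
    extract <- function(w) {
      if (edge_scope == "within") {
        cluster_submatrix(w, idx)
      } else {
        # zero out edges with both endpoints outside the cluster, keep size
        keep <- matrix(FALSE, nn, nn)
        keep[idx + 1L, ] <- TRUE
        keep[, idx + 1L] <- TRUE
        w2 <- unclass(w)
        w2[!keep] <- 0
        connectome(w2, attr(w, "subject_id"), attr(w, "timepoint"),
                   attr(w, "modality"))
      }
    }
    k <- length(idx)
    if (edge_scope == "within" && ceiling(density * k * (k - 1) / 2) < 3) {
      stop("cluster '", name, "' retains fewer than 3 edges at density ",
           density, call. = FALSE)
    }
    s <- similarity_matrix(lapply(tp1, extract), lapply(tp2, extract),
                           density = density,
                           mask_convention = mask_convention)
    sims[[name]] <- s
    idfs[[name]] <- identifiability(s)
    zs[[name]] <- zscore_rows(s)
  }
  summary <- purrr::imap(idfs, function(idf, name) {
    tibble::tibble(cluster = name, n_nodes = length(clusters[[name]]),
                   n_matched = idf$n_matched, n_total = idf$n_total,
                   rate = idf$rate,
                   mean_self = mean(idf$self_similarities),
                   mean_other = mean(idf$other_similarities))
  }) |> dplyr::bind_rows()
  structure(list(summary = summary, similarity = sims,
                 identifiability = idfs, zscores = zs,
                 density = density, edge_scope = edge_scope),
            class = "regional_result")
}

#' @export
print.regional_result <- function(x, ...) {
  cat("<regional_result> ", nrow(x$summary), " clusters, density ",
      format(x$density), "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.regional_result <- function(x, ...) x$summary
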