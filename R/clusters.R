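#' Anatomical cluster definitions
#'
#' Clusters group atlas nodes into larger anatomical areas; the regional
#' analysis reruns the whole fingerprinting pipeline within each cluster's
#' internal edges. A cluster set is a named list of integer vectors of
#' 0-based node indices, with an `atlas_size` attribute.
#'
#' @name clusters
NULL

STUDY_CLUSTER_SIZES <- c(central = 8L, frontal = 22L, limbic = 14L,
                         occipital = 14L, parietal = 10L, deep_grey = 8L,
                         temporal = 14L)

#' Default anatomical clusters for the 90-node AAL atlas
#'
#' Seven clusters over the standard 90-region AAL cortical + subcortical
#' parcellation: central (pre/postcentral gyri, paracentral lobules,
#' supplementary motor areas; 8 nodes), frontal (superior/middle/inferior and
#' orbitofrontal cortices, olfactory, rectus; 22), limbic (insula, cingulate,
#' hippocampus, parahippocampal, amygdala; 14), occipital (calcarine, cuneus,
#' lingual, occipital gyri, fusiform; 14), parietal (superior/inferior
#' parietal, supramarginal, angular, precuneus; 10), deep grey matter (basal
#' ganglia and thalami; 8) and temporal (Rolandic operculum, Heschl, temporal
#' gyri and poles; 14).
#'
#' @return Named list of 0-based node index vectors with attribute
#'   `atlas_size = 90`.
#' @export
study_clusters <- function() {
  # 1-based AAL-90 indices, converted to 0-based below
  cl <- list(
    central   = c(1, 2, 19, 20, 57, 58, 69, 70),
    frontal   = c(3:16, 21:28),
    limbic    = 29:42,
    occipital = 43:56,
    parietal  = 59:68,
    deep_grey = 71:78,
    temporal  = c(17, 18, 79:90)
  )
  cl <- lapply(cl, function(x) as.integer(x - 1L))
  validate_clusters(cl, atlas_size = 90L, study = TRUE)
}

validate_clusters <- function(clusters, atlas_size, study = FALSE) {
  stopifnot(is.list(clusters), length(clusters) > 0,
            !is.null(names(clusters)))
  clusters <- lapply(clusters, as.integer)
  all_idx <- unlist(clusters, use.names = FALSE)
  if (any(all_idx < 0) || any(all_idx >= atlas_size)) {
    stop("cluster node index out of range for atlas of size ", atlas_size,
         call. = FALSE)
  }
  if (anyDuplicated(all_idx)) {
    dup <- unique(all_idx[duplicated(all_idx)])
    stop("clusters overlap at node index ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  is_study <- study ||
    (atlas_size == 90L && setequal(names(clusters), names(STUDY_CLUSTER_SIZES)))
  if (is_study) {
    sizes <- vapply(clusters, length, integer(1))
    want <- STUDY_CLUSTER_SIZES[names(clusters)]
    if (!identical(unname(sizes), unname(want))) {
      stop("study cluster sizes must be ",
           paste(names(STUDY_CLUSTER_SIZES), STUDY_CLUSTER_SIZES,
                 sep = "=", collapse = ", "),
           call. = FALSE)
    }
    if (length(all_idx) != 90L) {
      stop("study clusters must cover all 90 atlas nodes", call. = FALSE)
    }
  }
  structure(clusters, atlas_size = as.integer(atlas_size))
}

#' Read cluster definitions from a JSON file
#'
#' The file maps cluster names to node index arrays and may carry two
#' reserved keys: `atlas_size` (number of atlas nodes; required) and
#' `index_base` (0 or 1; default 1, the common atlas convention). Indices
#' are converted to 0-based internally. When the file declares a 90-node
#' atlas with the seven study cluster names, the study size vector
#' (8, 22, 14, 14, 10, 8, 14), disjointness and full coverage are enforced.
#'
#' @param path Path to the JSON cluster file.
#' @return Named list of 0-based node index vectors (see [study_clusters()]).
#' @export
read_clusters <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(spec$atlas_size)) {
    stop("cluster file must declare atlas_size", call. = FALSE)
  }
  atlas_size <- as.integer(spec$atlas_size)
  index_base <- if (is.null(spec$index_base)) 1L else as.integer(spec$index_base)
  if (!index_base %in% c(0L, 1L)) stop("index_base must be 0 or 1", call. = FALSE)
  spec$atlas_size <- NULL
  spec$index_base <- NULL
  clusters <- lapply(spec, function(x) as.integer(x) - index_base)
  validate_clusters(clusters, atlas_size)
}

#' Write cluster definitions to a JSON file
#'
#' @param clusters Named list of 0-based node index vectors.
#' @param path Output path.
#' @param index_base Index base to write (default 1).
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path, index_base = 1L) {
  out <- lapply(clusters, function(x) as.integer(x) + as.integer(index_base))
  out$atlas_size <- attr(clusters, "atlas_size")
  out$index_base <- as.integer(index_base)
  jsonlite::write_json(out, path, auto_unbox = TRUE)
  invisible(path)
}

#' Extract the within-cluster submatrix of a connectome
#'
#' Restricts a connectome to the node pairs internal to one cluster,
#' preserving node order and subject metadata.
#'
#' @param w A [connectome()].
#' @param node_indices Integer vector of 0-based node indices.
#' @return A [connectome()] over the cluster's nodes.
#' @export
cluster_submatrix <- function(w, node_indices) {
  idx <- as.integer(node_indices) + 1L
  if (any(idx < 1L) || any(idx > nrow(w))) {
    stop("cluster index out of range for ", nrow(w), "-node connectome",
         call. = FALSE)
  }
  connectome(unclass(w)[idx, idx, drop = FALSE],
             subject_id = attr(w, "subject_id"),
             timepoint = attr(w, "timepoint"),
             modality = attr(w, "modality"))
}
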