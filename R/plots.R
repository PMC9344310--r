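#' Heatmap of a similarity matrix
#'
#' Tiles the subject-by-subject similarity matrix (timepoint-1 subjects in
#' rows, timepoint-2 in columns). On a row-max-normalised matrix a value of
#' 1 off the diagonal marks a failed identification.
#'
#' @param object A `similarity_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.similarity_matrix <- function(object, ...) {
  df <- as_tibble.similarity_matrix(object)
  df$subject_tp1 <- factor(df$subject_tp1, levels = rev(object$subjects))
  df$subject_tp2 <- factor(df$subject_tp2, levels = object$subjects)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subject_tp2,
                                   y = .data$subject_tp1,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "subject at timepoint 2", y = "subject at timepoint 1",
                  fill = "rho",
                  title = sprintf("%s similarity (density %s)",
                                  object$modality,
                                  if (is.null(object$density)) "none"
                                  else format(object$density))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Similarity against inter-scan interval
#'
#' Plots every similarity value against the interval between the row
#' subject's first scan and the column subject's second scan, marking
#' self-similarities. The age-dependence of self-to-other-similarity shows
#' up as a downward trend in the non-self points.
#'
#' @param s A `similarity_matrix`.
#' @param panel A `cohort_panel` covering its subjects.
#' @return A ggplot.
#' @export
plot_similarity_vs_interval <- function(s, panel) {
  panel <- panel[match(s$subjects, panel$subject_id), ]
  df <- as_tibble.similarity_matrix(s) |>
    dplyr::mutate(
      days = (panel$pma_scan2[match(.data$subject_tp2, panel$subject_id)] -
                panel$pma_scan1[match(.data$subject_tp1, panel$subject_id)]) * 7)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$days, y = .data$rho,
                                   shape = .data$self,
                                   colour = .data$self)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 8)) +
    ggplot2::labs(x = "days between scans", y = "Spearman rho",
                  shape = "self", colour = "self") +
    ggplot2::theme_minimal()
}

#' Identifiability across the density sweep
#'
#' @param sweep Tibble from [threshold_sweep()].
#' @return A ggplot.
#' @export
plot_threshold_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$density, y = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_max)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "network density", y = "identifiability rate",
                  colour = "maximal") +
    ggplot2::theme_minimal()
}
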