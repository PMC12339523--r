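# ggplot2 visualisations.

#' Plot a two-channel record
#'
#' Shows a time window of the pulse and ECG channels as stacked facets,
#' with ground-truth fiducials overlaid when available.
#'
#' @param object A `pf_record`.
#' @param window Time window in seconds (length 2).
#' @param fiducials Overlay ground-truth fiducials if present.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pf_record <- function(object, window = c(0, 5), fiducials = TRUE,
                               ...) {
  sig <- dplyr::filter(object$signal, .data$t >= window[1], .data$t <= window[2])
  long <- tidyr::pivot_longer(sig, c("ppw", "ecg"), names_to = "channel",
                              values_to = "value")
  long$channel <- factor(long$channel, levels = c("ppw", "ecg"),
                         labels = c("pressure pulse wave", "ECG"))
  p <- ggplot(long, aes(x = .data$t, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~channel, ncol = 1, scales = "free_y") +
    labs(x = "time (s)", y = NULL,
         title = sprintf("record %s (group %d)", object$id, object$group)) +
    theme_minimal()
  if (fiducials && !is.null(object$truth) && nrow(object$truth$ppw) > 0) {
    fid <- dplyr::filter(object$truth$ppw, !.data$absent)
    fid$t_abs <- (fid$index - 1) / object$fs
    fid <- dplyr::filter(fid, .data$t_abs >= window[1], .data$t_abs <= window[2])
    fid$channel <- factor("pressure pulse wave",
                          levels = levels(long$channel))
    fid$value <- object$signal$ppw[fid$index]
    p <- p + geom_point(data = fid, aes(x = .data$t_abs, y = .data$value,
                                        color = .data$point), size = 1.2) +
      labs(color = "fiducial")
  }
  p
}

#' Confusion-matrix heat map for a CV result
#'
#' @param object A `pf_cv` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pf_cv <- function(object, ...) {
  df <- as.data.frame(as.table(object$cm))
  names(df) <- c("predicted", "actual", "count")
  ggplot(df, aes(x = .data$actual, y = .data$predicted, fill = .data$count)) +
    geom_tile() +
    geom_text(aes(label = .data$count), color = "white") +
    scale_fill_gradient(low = "grey70", high = "steelblue4") +
    labs(title = sprintf("%s: pooled out-of-fold confusion matrix (accuracy %.1f%%)",
                         object$algo, object$metrics$accuracy)) +
    theme_minimal()
}

#' Accuracy against number of selected features
#'
#' Plots the sequential-forward-selection curve with the selected prefix
#' marked.
#'
#' @param sfs Result of [sfs_select()] (list with `curve` and `selected`).
#' @return A ggplot.
#' @export
plot_sfs_curve <- function(sfs) {
  curve <- sfs$curve
  n_sel <- length(sfs$selected)
  ggplot(curve, aes(x = .data$n_features, y = 100 * .data$accuracy)) +
    geom_line() + geom_point(size = 0.8) +
    geom_vline(xintercept = n_sel, linetype = 2, color = "firebrick") +
    labs(x = "number of features (importance order)",
         y = "cross-validated accuracy (%)",
         title = sprintf("sequential forward selection (selected %d features)",
                         n_sel)) +
    theme_minimal()
}

#' Group feature distributions
#'
#' Boxplots of selected features by study group.
#'
#' @param features Feature table from [extract_features()].
#' @param columns Feature columns to plot.
#' @return A ggplot.
#' @export
plot_group_features <- function(features, columns) {
  long <- tidyr::pivot_longer(features[, c("group", columns)],
                              dplyr::all_of(columns),
                              names_to = "feature", values_to = "value")
  ggplot(long, aes(x = factor(.data$group), y = .data$value)) +
    geom_boxplot(outlier.size = 0.5) +
    facet_wrap(~feature, scales = "free_y") +
    labs(x = "group", y = NULL) +
    theme_minimal()
}
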