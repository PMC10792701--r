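#' Tidy a cohort analysis result
#'
#' One row per tested marker with group medians (or proportions for
#' binary markers), test, p, BH q, significance flag and AUC with its
#' DeLong interval.
#'
#' @param x A `hetpanel_cohort`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hetpanel_cohort <- function(x, ...) {
  x$stats
}

#' One-row summary of a cohort analysis
#'
#' @param x A `hetpanel_cohort`.
#' @param ... Unused.
#' @return One-row tibble: sample counts, number of significant markers,
#'   and the LOOCV model AUC with interval (`NA` when the model was
#'   skipped).
#' @export
glance.hetpanel_cohort <- function(x, ...) {
  tibble::tibble(
    n_samples = x$manifest$n_samples,
    n_markers = nrow(x$stats),
    n_significant = sum(x$stats$significant),
    fdr = x$manifest$fdr,
    model_features = paste(x$features_used, collapse = ","),
    model_auc = if (!is.null(x$model)) x$model$auc$auc else NA_real_,
    model_auc_lo = if (!is.null(x$model)) x$model$auc$auc_lo else NA_real_,
    model_auc_hi = if (!is.null(x$model)) x$model$auc$auc_hi else NA_real_)
}

#' Plot a cohort analysis result
#'
#' `type = "auc"` (default) draws the per-marker AUC with DeLong
#' intervals; `type = "roc"` draws the ROC curve of the pooled LOOCV
#' model probabilities; `type = "volcano"` shows group shift (difference
#' of medians) against -log10 q.
#'
#' @param object A `hetpanel_cohort`.
#' @param type `"auc"`, `"roc"` or `"volcano"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hetpanel_cohort <- function(object, type = c("auc", "roc",
                                                      "volcano"), ...) {
  type <- match.arg(type)
  if (type == "auc") {
    d <- dplyr::filter(object$stats, !is.na(.data$auc))
    d$marker <- stats::reorder(d$marker, d$auc)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$auc, y = .data$marker)) +
      ggplot2::geom_vline(xintercept = 0.5, linetype = 2,
                          colour = "grey60") +
      ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$auc_lo,
                                           xmax = .data$auc_hi),
                              height = 0.2, colour = "grey40") +
      ggplot2::geom_point(ggplot2::aes(colour = .data$significant),
                          size = 2) +
      ggplot2::labs(x = "AUC (DeLong 95% CI)", y = NULL,
                    colour = "FDR-significant") +
      ggplot2::theme_minimal()
  } else if (type == "roc") {
    if (is.null(object$model)) abort("no fitted model to plot")
    pr <- object$model$predictions
    positive <- object$manifest$positive
    thr <- sort(unique(pr$looc_probability), decreasing = TRUE)
    pts <- purrr::map_dfr(c(Inf, thr, -Inf), function(t) {
      tibble::tibble(
        tpr = mean(pr$looc_probability[pr$label == positive] >= t),
        fpr = mean(pr$looc_probability[pr$label != positive] >= t))
    })
    ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                           colour = "grey60") +
      ggplot2::geom_step() +
      ggplot2::labs(
        x = "False positive rate", y = "True positive rate",
        title = sprintf("LOOCV model: AUC %.2f (%.2f-%.2f)",
                        object$model$auc$auc, object$model$auc$auc_lo,
                        object$model$auc$auc_hi)) +
      ggplot2::theme_minimal()
  } else {
    d <- dplyr::mutate(object$stats,
                       shift = .data$median_pos - .data$median_neg)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$shift,
                                    y = -log10(.data$q))) +
      ggplot2::geom_hline(yintercept = -log10(object$manifest$fdr),
                          linetype = 2, colour = "grey60") +
      ggplot2::geom_point(ggplot2::aes(colour = .data$significant)) +
      ggplot2::geom_text(ggplot2::aes(label = .data$marker),
                         vjust = -0.6, size = 2.8) +
      ggplot2::labs(x = "Median difference (pos - neg)",
                    y = expression(-log[10] ~ q),
                    colour = "FDR-significant") +
      ggplot2::theme_minimal()
  }
}

#' Marker distributions by group
#'
#' Jittered per-sample values with group medians for a chosen set of
#' biomarkers.
#'
#' @param biomarkers Biomarker tibble with the label column.
#' @param markers Marker columns to show.
#' @param label Group label column (default `"group"`).
#' @return A ggplot object.
#' @export
plot_marker_distributions <- function(biomarkers,
                                      markers = c("tmb", "math",
                                                  "median_tvaf", "ploidy",
                                                  "subclonal_cn_fraction"),
                                      label = "group") {
  markers <- intersect(markers, names(biomarkers))
  long <- tidyr::pivot_longer(
    biomarkers[, c(label, markers)],
    cols = dplyr::all_of(markers), names_to = "marker")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[label]],
                                     y = .data$value,
                                     colour = .data[[label]])) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::stat_summary(fun = median, geom = "crossbar",
                          width = 0.4, linewidth = 0.3,
                          colour = "black") +
    ggplot2::facet_wrap(~marker, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
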