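#' Plot Kaplan-Meier curves by risk group
#'
#' @param object a `survfit_result` from [km_logrank()].
#' @param ... unused.
#' @return a ggplot of the per-group survival step functions, annotated with
#'   the log-rank p-value.
#' @export
autoplot.survfit_result <- function(object, ...) {
  km <- object$km
  start <- km |> group_by(.data$group) |>
    summarise(time = 0, survival = 1, .groups = "drop")
  dat <- bind_rows(start, select(km, "group", "time", "survival")) |>
    arrange(.data$group, .data$time)
  ggplot2::ggplot(dat, ggplot2::aes(.data$time, .data$survival,
                                    colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Overall survival",
                  colour = "Risk group",
                  subtitle = sprintf("log-rank p = %.4g", object$logrank_p)) +
    ggplot2::theme_minimal()
}

#' Plot CP factor loadings for one mode
#'
#' @param object a `cp_factors` object.
#' @param mode which mode to show: `"samples"`, `"slices"` or `"features"`.
#' @param ... unused.
#' @return a ggplot; for the slice mode a loading heatmap (useful for reading
#'   which assay chunks drive each component), otherwise loadings against
#'   index, one panel per component.
#' @export
autoplot.cp_factors <- function(object, mode = c("slices", "samples", "features"),
                                ...) {
  mode <- match.arg(mode)
  dat <- filter(tidy(object), .data$mode == !!mode) |>
    mutate(label = factor(.data$label, levels = unique(.data$label)))
  if (mode == "slices") {
    ggplot2::ggplot(dat, ggplot2::aes(factor(.data$component), .data$label,
                                      fill = .data$value)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient2() +
      ggplot2::labs(x = "Component", y = "Tensor slice", fill = "Loading") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(dat, ggplot2::aes(as.integer(.data$label), .data$value)) +
      ggplot2::geom_point(size = 0.6, alpha = 0.6) +
      ggplot2::facet_wrap(~ component, scales = "free_y") +
      ggplot2::labs(x = mode, y = "Loading") +
      ggplot2::theme_minimal()
  }
}

#' Plot autoencoder training loss by epoch
#'
#' @param object a `trained_autoencoder`.
#' @param ... unused.
#' @return a ggplot of the training MSE per epoch.
#' @export
autoplot.trained_autoencoder <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(.data$epoch, .data$train_loss)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Epoch", y = "Training MSE",
                  title = sprintf("%s: %d -> %d", object$assay %||% "assay",
                                  object$spec$input_dim, object$spec$latent_dim)) +
    ggplot2::theme_minimal()
}

#' Plot top SHAP biomarkers
#'
#' @param object a `shap_attribution`.
#' @param k number of features to show.
#' @param ... unused.
#' @return a ggplot bar chart of signed mean SHAP values for the top-`k`
#'   features by mean absolute attribution.
#' @export
autoplot.shap_attribution <- function(object, k = 10, ...) {
  top <- top_biomarkers(object, k = min(k, ncol(object$phi)))
  top$feature <- factor(top$feature, levels = rev(top$feature))
  ggplot2::ggplot(top, ggplot2::aes(.data$score, .data$feature,
                                    fill = .data$score > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "Mean SHAP value", y = NULL,
                  title = sprintf("%s SHAP, latent %d",
                                  object$method, object$latent_index)) +
    ggplot2::theme_minimal()
}

#' Plot a CORCONDIA rank-selection table
#'
#' @param diagnostics the `diagnostics` tibble from [select_rank()].
#' @param threshold the cutoff to draw.
#' @return a ggplot of core consistency against candidate rank.
#' @export
plot_rank_selection <- function(diagnostics, threshold = 90) {
  ggplot2::ggplot(diagnostics, ggplot2::aes(.data$rank, .data$corcondia)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "CP rank", y = "Core consistency (%)") +
    ggplot2::theme_minimal()
}
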