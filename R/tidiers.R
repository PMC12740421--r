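#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted fusion model
#'
#' Returns the per-epoch training trace in long-friendly wide form: loss
#' components, the lambda-weighted total, and train/validation AUC.
#'
#' @param x An [train_mmdf()] model.
#' @param ... Unused.
#' @return A tibble with one row per epoch.
#' @export
tidy.mmdf_model <- function(x, ...) {
  dplyr::select(x$trace, "epoch", "l_cls", "l_contrast", "l_wgan", "l_total",
                "auc_train", "auc_val")
}

#' Glance at a fitted fusion model
#'
#' @param x An [train_mmdf()] model.
#' @param ... Unused.
#' @return A one-row tibble: final losses, final train/validation AUC,
#'   split sizes, and key hyperparameters.
#' @export
glance.mmdf_model <- function(x, ...) {
  tl <- x$trace[nrow(x$trace), ]
  tibble::tibble(
    epochs = nrow(x$trace),
    l_cls = tl$l_cls, l_contrast = tl$l_contrast, l_wgan = tl$l_wgan,
    l_total = tl$l_total,
    auc_train = tl$auc_train, auc_val = tl$auc_val,
    n_train = sum(x$split$split == "train"),
    n_val = sum(x$split$split == "val"),
    n_test = sum(x$split$split == "test"),
    embed_dim = x$config$embed_dim,
    temperature = x$config$temperature,
    lambda_contrast = x$config$lambda_contrast,
    lambda_wgan = x$config$lambda_wgan
  )
}

#' Plot the training trace
#'
#' Loss components and weighted total against epoch.
#'
#' @param object An [train_mmdf()] model.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mmdf_model <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(object$trace, "epoch", "l_cls", "l_contrast", "l_total"),
    -"epoch", names_to = "component", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a batch similarity matrix
#'
#' Visualizes cross-modal cosine similarities; after contrastive alignment
#' the matched (diagonal) pairs should dominate.
#'
#' @param S Square similarity matrix.
#' @return A ggplot object.
#' @export
plot_similarity <- function(S) {
  df <- tidyr::expand_grid(image = seq_len(nrow(S)), tabular = seq_len(ncol(S)))
  df$similarity <- as.vector(t(S))[(df$image - 1L) * ncol(S) + df$tabular]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tabular, y = .data$image,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot subgroup gating weights
#'
#' Bars of mean modality weight by subgroup with sd error bars, from a
#' [subgroup_weight_report()] table.
#'
#' @param report Output of [subgroup_weight_report()].
#' @return A ggplot object.
#' @export
plot_gating_weights <- function(report) {
  means <- tidyr::pivot_longer(
    dplyr::select(report, "group", dplyr::ends_with("_mean")),
    -"group", names_to = "modality", values_to = "mean")
  means$modality <- sub("^w_", "", sub("_mean$", "", means$modality))
  sds <- tidyr::pivot_longer(
    dplyr::select(report, "group", dplyr::ends_with("_sd")),
    -"group", names_to = "modality", values_to = "sd")
  sds$modality <- sub("^w_", "", sub("_sd$", "", sds$modality))
  df <- dplyr::left_join(means, sds, by = c("group", "modality"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$mean,
                                   fill = .data$modality)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                   ymax = pmin(.data$mean + .data$sd, 1)),
      position = ggplot2::position_dodge(width = 0.9), width = 0.25) +
    ggplot2::labs(x = NULL, y = "mean modality weight", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
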