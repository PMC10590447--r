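# Diagnostic plots.

#' Loss curves of a fitted adversarial autoencoder
#'
#' @param object An `aae_fit`.
#' @param ... Unused.
#' @return A ggplot of all loss components per epoch.
#' @method autoplot aae_fit
#' @export
autoplot.aae_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"epoch",
                              names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss",
                  title = "Adversarial autoencoder training losses") +
    ggplot2::theme_minimal()
}

#' Two-dimensional view of the continuous latent space
#'
#' Projects the z codes onto their first two principal components, coloured
#' by cluster (or any other per-contig label).
#'
#' @param latent An `aae_latent` from [latent_codes()].
#' @param labels Optional per-contig labels: a named vector or a tibble
#'   with `contig` plus a label column (e.g. a cluster table).
#' @return A ggplot.
#' @export
plot_latent <- function(latent, labels = NULL) {
  stopifnot(inherits(latent, "aae_latent"))
  pc <- prcomp(latent$Z, rank. = 2)
  df <- tibble(contig = latent$contig_ids,
               PC1 = pc$x[, 1], PC2 = pc$x[, 2])
  if (!is.null(labels)) {
    if (is.data.frame(labels)) {
      label_col <- setdiff(names(labels), "contig")[1]
      labels <- setNames(labels[[label_col]], labels$contig)
    }
    df$label <- as.character(labels[df$contig])
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                          colour = .data$label))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2))
  }
  p + ggplot2::geom_point(size = 1, alpha = 0.8) +
    ggplot2::labs(title = "Continuous latent space (PCA)") +
    ggplot2::theme_minimal()
}
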