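# ggplot2 views of the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a variance profile with the recovered planes
#'
#' @param object A `variance_profile`.
#' @param focus Optional `focus_result` to annotate.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.variance_profile <- function(object, focus = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$z, .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "focus offset z (µm)",
                  y = "image contrast (σ²/μ)") +
    ggplot2::theme_minimal()
  if (!is.null(focus)) {
    p <- p + ggplot2::geom_vline(xintercept = focus$z_bright_spot,
                                 linetype = 2, colour = "firebrick") +
      ggplot2::geom_vline(xintercept = focus$z_focus, linetype = 3,
                          colour = "steelblue")
  }
  p
}

#' Plot a spectrum set as overlaid traces
#'
#' @param object A `spectrum_set`.
#' @param alpha Line alpha.
#' @param ... Unused.
#' @return A ggplot, coloured by label when labels exist.
#' @export
autoplot.spectrum_set <- function(object, alpha = 0.3, ...) {
  d <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$wavenumber, .data$intensity,
                                       group = .data$spectrum_id))
  if ("label" %in% names(d)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$label),
                                alpha = alpha, linewidth = 0.3)
  } else {
    p <- p + ggplot2::geom_line(alpha = alpha, linewidth = 0.3)
  }
  p + ggplot2::labs(x = "Raman shift (cm⁻¹)", y = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot marginal-relevance scores along the wavenumber axis
#'
#' @param object An `mr_scores` tibble.
#' @param selected Optional channel indices to highlight (e.g. from
#'   [select_mr_channels()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mr_scores <- function(object, selected = NULL, ...) {
  xvar <- if ("wavenumber" %in% names(object)) "wavenumber" else "channel"
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(.data[[xvar]], .data$score)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (xvar == "wavenumber")
      "Raman shift (cm⁻¹)" else "channel",
      y = "MR score (between/within SS)") +
    ggplot2::theme_minimal()
  if (!is.null(selected)) {
    p <- p + ggplot2::geom_point(data = object[selected, ],
                                 colour = "firebrick", size = 2)
  }
  p
}

#' Box plot of per-fold CV accuracies per pipeline
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot mirroring the usual per-fold accuracy box plot.
#' @export
autoplot.cv_report <- function(object, ...) {
  d <- object$fold_metrics
  d$spec <- factor(d$spec, levels = unique(object$metrics$spec))
  ggplot2::ggplot(d, ggplot2::aes(.data$spec, .data$accuracy)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::labs(x = NULL, y = "test-fold accuracy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' PCA score scatter of a screen report
#'
#' @param report A `screen_report` from [run_full_pipeline()].
#' @return A ggplot of the first two principal-component scores.
#' @export
plot_pca_scores <- function(report) {
  d <- report$pca$scores
  lab <- sprintf("PC%d (%0.1f%%)", 1:2, 100 * report$pca$explained)
  ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2,
                                  colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = lab[1], y = lab[2], colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an image tile or mosaic with optional candidate overlay
#'
#' @param img An `image_tile`, `mosaic`, or matrix.
#' @param candidates Optional `candidate_set` to overlay (0-based pixels).
#' @return A ggplot raster.
#' @export
plot_image <- function(img, candidates = NULL) {
  m <- if (inherits(img, "mosaic")) img$mosaic
       else if (inherits(img, "image_tile")) img$pixels else as.matrix(img)
  d <- tidyr::expand_grid(row = seq_len(nrow(m)) - 1,
                          col = seq_len(ncol(m)) - 1)
  d$value <- as.numeric(t(m))[d$row * ncol(m) + d$col + 1]
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$col, -.data$row,
                                       fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (!is.null(candidates) && nrow(candidates) > 0) {
    p <- p + ggplot2::geom_point(
      data = candidates,
      ggplot2::aes(.data$col, -.data$row), inherit.aes = FALSE,
      shape = 4, colour = "yellow", size = 2)
  }
  p
}
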