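#' Sample-score plot for a PCA result
#'
#' Scatter of sample scores on two components; when the PCA carries design
#' annotation, points are coloured by condition and shaped by time.
#'
#' @param object An `interplay_pca`.
#' @param components Two component indices (default 1:2).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot interplay_pca
#' @export
autoplot.interplay_pca <- function(object, components = c(1L, 2L), ...) {
  pcs <- paste0("PC", components)
  ve <- object$variance$var_explained[components]
  lab <- sprintf("%s (%.1f%% of variance)", pcs, 100 * ve)
  dat <- object$scores
  args <- c(
    list(x = rlang::sym(pcs[1L]), y = rlang::sym(pcs[2L])),
    if ("condition" %in% names(dat)) list(colour = rlang::sym("condition")),
    if ("time" %in% names(dat)) list(shape = rlang::sym("time"))
  )
  mapping <- do.call(ggplot2::aes, args)
  ggplot2::ggplot(dat, mapping) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = lab[1L], y = lab[2L]) +
    ggplot2::theme_minimal()
}

#' Interplay category distribution plot
#'
#' Stacked bars of the per-time category fractions over the DEG universe
#' (the machine-readable twin of per-time pie charts).
#'
#' @param summary Output of [summarize_categories()].
#' @return A ggplot.
#' @export
plot_category_summary <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$time, y = .data$fraction,
                               fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "time after injection", y = "fraction of AS01 DEGs",
                  fill = "interplay") +
    ggplot2::theme_minimal()
}

#' Variance-moderation plot
#'
#' Per-gene residual variance against its moderated (posterior) value, with
#' the prior variance marked; visualizes the shrinkage toward the prior.
#'
#' @param fit An `interplay_fit`.
#' @param prior An `eb_prior`.
#' @return A ggplot.
#' @export
plot_moderation <- function(fit, prior) {
  dat <- tibble::tibble(sigma2 = fit$sigma2, var_post = prior$var_post)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sigma2, y = .data$var_post)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = prior$s02, colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "residual variance", y = "moderated variance") +
    ggplot2::theme_minimal()
}
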