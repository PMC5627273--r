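#' Tidy a cell-means fit
#'
#' One row per gene per condition-by-time cell with the fitted mean.
#'
#' @param x An `interplay_fit`.
#' @param ... Unused.
#' @return A tibble `gene`, `condition`, `time`, `estimate`.
#' @method tidy interplay_fit
#' @export
tidy.interplay_fit <- function(x, ...) {
  co <- tibble::as_tibble(x$coefficients)
  co$gene <- x$genes
  co |>
    tidyr::pivot_longer(-"gene", names_to = "cell", values_to = "estimate") |>
    dplyr::left_join(x$cells, by = "cell") |>
    dplyr::select("gene", "condition", "time", "estimate")
}

#' Glance at a cell-means fit
#'
#' @param x An `interplay_fit`.
#' @param ... Unused.
#' @return One-row tibble: gene, sample and cell counts, residual df,
#'   median residual variance.
#' @method glance interplay_fit
#' @export
glance.interplay_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$genes),
    n_samples = nrow(x$design),
    n_cells = nrow(x$cells),
    df_residual = x$df_residual,
    median_sigma2 = stats::median(x$sigma2)
  )
}

#' Tidy an empirical-Bayes prior
#'
#' @param x An `eb_prior`.
#' @param ... Unused.
#' @return One-row tibble with `d0`, `s02`, `df_residual`, `df_total`.
#' @method tidy eb_prior
#' @export
tidy.eb_prior <- function(x, ...) {
  tibble::tibble(d0 = x$d0, s02 = x$s02, df_residual = x$df_residual,
                 df_total = x$df_total)
}

#' Tidy a PCA result
#'
#' @param x An `interplay_pca`.
#' @param matrix Which piece: `"scores"`, `"loadings"` or `"variance"`.
#' @param ... Unused.
#' @return The requested tibble.
#' @method tidy interplay_pca
#' @export
tidy.interplay_pca <- function(x, matrix = c("scores", "loadings",
                                             "variance"), ...) {
  matrix <- match.arg(matrix)
  x[[matrix]]
}

#' Glance at a PCA result
#'
#' @param x An `interplay_pca`.
#' @param ... Unused.
#' @return One-row tibble: observation/variable counts and the variance
#'   explained by the first two components.
#' @method glance interplay_pca
#' @export
glance.interplay_pca <- function(x, ...) {
  ve <- x$variance$var_explained
  tibble::tibble(
    n_obs = nrow(x$scores),
    n_var = nrow(x$loadings),
    n_components = nrow(x$variance),
    pc1_var_explained = ve[1L],
    pc2_var_explained = if (length(ve) > 1L) ve[2L] else NA_real_
  )
}
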