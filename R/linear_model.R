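#' DEG cutoffs
#'
#' Thresholds for calling a gene differentially expressed over the PBS sham:
#' absolute log2 fold change at least `min_abs_log2fc` (default 1, i.e. fold
#' change > 2) and BH-adjusted contrast p-value below `max_adj_p`
#' (default 0.01).
#'
#' @param min_abs_log2fc Minimum |log2 fold change|; must be > 0.
#' @param max_adj_p Maximum adjusted p-value; in (0, 1).
#' @return A list with class `deg_cutoffs`.
#' @export
deg_cutoffs <- function(min_abs_log2fc = 1, max_adj_p = 0.01) {
  stopifnot(min_abs_log2fc > 0, max_adj_p > 0, max_adj_p < 1)
  structure(list(min_abs_log2fc = min_abs_log2fc, max_adj_p = max_adj_p),
            class = "deg_cutoffs")
}

#' Fit per-gene cell means
#'
#' Fits the one-way cell-means model to every gene: one mean per
#' condition-by-time cell, a pooled within-cell residual variance
#' \eqn{s_g^2}, and residual degrees of freedom
#' \eqn{d_g = N_{samples} - N_{cells}} (identical across genes in a complete
#' design). In the balanced layout the cell coefficients are the arithmetic
#' means of the replicate values. Every cell must have at least two
#' replicates so the residual variance is estimable.
#'
#' @param expression Expression tibble (gene column + numeric sample columns).
#' @param design Design tibble with `sample_id`, `condition`, `time`,
#'   `replicate`; samples must match the expression columns.
#' @return An object of class `interplay_fit`: cell coefficient matrix
#'   (genes x cells), `sigma2`, `df_residual`, per-cell replicate counts and
#'   the cell map.
#' @export
fit_cell_means <- function(expression, design) {
  al <- align_samples(expression, design)
  expression <- al$expression
  design <- al$design
  m <- as_expression_matrix(expression)
  cell <- paste(design$condition, as.character(design$time), sep = ".")
  cells <- unique(cell)
  n_per_cell <- table(factor(cell, levels = cells))
  low <- names(n_per_cell)[n_per_cell < 2L]
  if (length(low)) {
    stop("cells with fewer than 2 replicates: ", paste(low, collapse = ", "),
         call. = FALSE)
  }
  # indicator/n: samples x cells, so m %*% ind gives cell means
  ind <- vapply(cells, function(cl) (cell == cl) / sum(cell == cl),
                numeric(length(cell)))
  coef <- m %*% ind
  fitted <- coef[, match(cell, cells), drop = FALSE]
  rss <- rowSums((m - fitted)^2)
  df <- ncol(m) - length(cells)
  if (df < 1L) stop("no residual degrees of freedom", call. = FALSE)
  first_sample <- match(cells, cell)
  cell_map <- tibble::tibble(
    cell = cells,
    condition = design$condition[first_sample],
    time = as.character(design$time)[first_sample]
  )
  structure(list(
    coefficients = coef,
    sigma2 = rss / df,
    df_residual = df,
    n_per_cell = as.integer(n_per_cell) |> setNames(cells),
    cells = cell_map,
    genes = rownames(m),
    design = design
  ), class = "interplay_fit")
}

#' @export
print.interplay_fit <- function(x, ...) {
  cat("Cell-means fit: ", length(x$genes), " genes, ",
      nrow(x$cells), " cells, residual df ", x$df_residual, "\n", sep = "")
  invisible(x)
}

# inverse of the trigamma function by monotone root-finding
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (yy <= 0) return(Inf)
    lo <- 1e-8
    hi <- 1e8
    # trigamma is strictly decreasing from +Inf to 0 on (0, Inf)
    if (trigamma(lo) < yy) return(lo)
    if (trigamma(hi) > yy) return(hi)
    uniroot(function(x) trigamma(x) - yy, c(lo, hi), tol = 1e-10)$root
  }, numeric(1L))
}

#' Estimate the empirical-Bayes variance prior
#'
#' Moment-matches a scaled inverse-chi-square prior \eqn{(d_0, s_0^2)} to the
#' per-gene residual variances, on the log scale: with
#' \eqn{e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)}, solve
#' \eqn{\psi'(d_0/2) = \mathrm{var}(e) - \psi'(d_g/2)} for \eqn{d_0} via the
#' trigamma inverse, then
#' \eqn{s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}}. When the
#' observed spread does not exceed the chi-square sampling spread the prior
#' is degenerate: \eqn{d_0 = \infty} and \eqn{s_0^2 = \exp(\bar e)}, so every
#' posterior variance equals \eqn{s_0^2}.
#'
#' The posterior (moderated) variance is the weighted combination
#' \eqn{s^2_{post,g} = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)}, always between
#' \eqn{s_g^2} and \eqn{s_0^2}.
#'
#' @param fit An `interplay_fit`.
#' @return An object of class `eb_prior` with elements `d0`, `s02`,
#'   `df_residual`, `df_total` and the per-gene posterior variance
#'   `var_post`.
#' @export
estimate_eb_prior <- function(fit) {
  s2 <- fit$sigma2
  dg <- fit$df_residual
  pos <- s2 > 0
  if (sum(pos) < 2L) {
    stop("need at least 2 genes with positive residual variance", call. = FALSE)
  }
  e <- log(s2[pos]) - digamma(dg / 2) + log(dg / 2)
  evar <- var(e) - trigamma(dg / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(mean(e))
  }
  eb_prior(fit, d0 = d0, s02 = s02)
}

#' Construct an empirical-Bayes prior by hand
#'
#' Builds the `eb_prior` object for a given \eqn{(d_0, s_0^2)} instead of
#' estimating it — useful for sensitivity analyses and for recovering the
#' unmoderated analysis in the limit \eqn{d_0 \to 0}.
#'
#' @param fit An `interplay_fit`.
#' @param d0 Prior degrees of freedom (> 0, may be `Inf`).
#' @param s02 Prior variance (> 0).
#' @return An `eb_prior` object.
#' @export
eb_prior <- function(fit, d0, s02) {
  stopifnot(d0 > 0, s02 > 0)
  dg <- fit$df_residual
  var_post <- if (is.infinite(d0)) {
    rep(s02, length(fit$sigma2)) |> setNames(fit$genes)
  } else {
    (d0 * s02 + dg * fit$sigma2) / (d0 + dg)
  }
  structure(list(d0 = d0, s02 = s02, df_residual = dg, df_total = d0 + dg,
                 var_post = var_post),
            class = "eb_prior")
}

#' @export
print.eb_prior <- function(x, ...) {
  cat("Empirical-Bayes prior: d0 = ", format(x$d0), ", s0^2 = ",
      format(x$s02), " (total df ", format(x$df_total), ")\n", sep = "")
  invisible(x)
}

#' Build contrast weights over cells
#'
#' Expands per-condition weights at one time point into a weight vector over
#' all condition-by-time cells of a fit (zero outside that time point).
#'
#' @param fit An `interplay_fit`.
#' @param condition_weights Named numeric vector of weights by condition,
#'   e.g. `c(PBS = -1, AS01 = 1)`.
#' @param time Time label.
#' @return Named numeric vector over the fit's cells.
#' @export
contrast_weights <- function(fit, condition_weights, time) {
  cm <- fit$cells
  w <- setNames(numeric(nrow(cm)), cm$cell)
  sel <- cm$time == as.character(time) &
    cm$condition %in% names(condition_weights)
  if (!any(sel)) stop("no matching cells for time '", time, "'", call. = FALSE)
  found <- cm$condition[sel]
  missing <- setdiff(names(condition_weights)[condition_weights != 0], found)
  if (length(missing)) {
    stop("conditions absent at time '", time, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  w[cm$cell[sel]] <- condition_weights[found]
  w
}

# shared: estimate, unit factor and moderated SE for a cell-weight vector
contrast_moments <- function(fit, prior, weights) {
  cells <- fit$cells$cell
  if (!all(names(weights) %in% cells)) {
    stop("unknown cells in contrast: ",
         paste(setdiff(names(weights), cells), collapse = ", "), call. = FALSE)
  }
  w <- setNames(numeric(length(cells)), cells)
  w[names(weights)] <- weights
  if (all(w == 0)) stop("contrast has no nonzero weight", call. = FALSE)
  estimate <- unname(drop(fit$coefficients %*% w))
  unit <- sqrt(sum(w^2 / fit$n_per_cell[cells]))
  se <- unname(sqrt(prior$var_post)) * unit
  list(estimate = estimate, se = se, df = prior$df_total)
}

#' Moderated contrast test
#'
#' Tests one linear contrast of cell means for every gene with the moderated
#' t-statistic: \eqn{t = \hat c / (s_{post} \sqrt{\sum_c w_c^2 / n_c})} on
#' \eqn{d_0 + d_g} degrees of freedom (normal reference when
#' \eqn{d_0 = \infty}), two-sided p-values, and BH adjustment across genes
#' within the contrast.
#'
#' @param fit An `interplay_fit`.
#' @param prior An `eb_prior`.
#' @param weights Named numeric vector of weights over cells (see
#'   [contrast_weights()]).
#' @param name Contrast label carried into the output.
#' @return Tibble with columns `gene`, `contrast`, `estimate`, `se`, `t`,
#'   `df`, `p`, `adj_p`, `degenerate`.
#' @export
test_contrast <- function(fit, prior, weights, name = "contrast") {
  mo <- contrast_moments(fit, prior, weights)
  est <- mo$estimate
  se <- mo$se
  t <- est / se
  p <- 2 * pt(-abs(t), df = mo$df)
  degen <- se == 0
  if (any(degen)) {
    warning(sum(degen), " gene(s) with zero moderated variance in contrast '",
            name, "'", call. = FALSE)
    p[degen] <- ifelse(est[degen] == 0, 1, 0)
    t[degen] <- ifelse(est[degen] == 0, 0, Inf * sign(est[degen]))
  }
  tibble::tibble(
    gene = fit$genes, contrast = name,
    estimate = est, se = se, t = t, df = mo$df,
    p = p, adj_p = adjust_bh(p), degenerate = degen
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector
#' (`stats::p.adjust` with `method = "BH"`).
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p) {
  p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' DEGs over the PBS sham at one time point: the moderated AS01 - PBS
#' contrast, with `is_deg` true when |log2 fold change| >=
#' `min_abs_log2fc` and BH-adjusted p < `max_adj_p`.
#'
#' @param fit An `interplay_fit`.
#' @param prior An `eb_prior`.
#' @param time Time label.
#' @param cutoffs A [deg_cutoffs()] object.
#' @param treatment,reference Condition labels contrasted (defaults
#'   AS01 vs PBS).
#' @return Tibble with columns `gene`, `time`, `log2fc`, `t`, `p`, `adj_p`,
#'   `is_deg`.
#' @export
call_degs <- function(fit, prior, time, cutoffs = deg_cutoffs(),
                      treatment = "AS01", reference = "PBS") {
  w <- contrast_weights(fit, setNames(c(-1, 1), c(reference, treatment)), time)
  res <- test_contrast(fit, prior, w, name = paste0(treatment, "-", reference))
  tibble::tibble(
    gene = res$gene,
    time = as.character(time),
    log2fc = res$estimate,
    t = res$t,
    p = res$p,
    adj_p = res$adj_p,
    is_deg = abs(res$estimate) >= cutoffs$min_abs_log2fc &
      res$adj_p < cutoffs$max_adj_p
  )
}
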