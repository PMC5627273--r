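#' Principal component analysis of an expression submatrix
#'
#' PCA with samples as observations and genes as variables (typically the
#' union of AS01 DEGs across time points): gene-wise centering, no scaling,
#' singular value decomposition. Component k explains
#' \eqn{\sigma_k^2 / \sum \sigma^2} of the variance; the number of
#' components is min(samples - 1, genes). Each loading column is flipped so
#' its largest-magnitude entry is positive (deterministic sign convention).
#'
#' @param expression Expression tibble.
#' @param genes Optional gene subset (default all rows).
#' @param design Optional design tibble; when given, condition/time are
#'   joined onto the scores for plotting.
#' @return An object of class `interplay_pca` with tibbles `scores`
#'   (sample x components), `loadings` (gene x components, orthonormal
#'   columns) and `variance` (per-component sdev, var_explained,
#'   cumulative).
#' @export
run_pca <- function(expression, genes = NULL, design = NULL) {
  expression <- validate_expression(expression)
  if (!is.null(genes)) {
    missing <- setdiff(genes, expression$gene)
    if (length(missing)) {
      stop("genes absent from expression matrix: ",
           paste(head(missing, 5), collapse = ", "), call. = FALSE)
    }
    expression <- expression[match(genes, expression$gene), ]
  }
  m <- as_expression_matrix(expression)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("need at least 2 genes and 2 samples", call. = FALSE)
  }
  x <- t(m)  # samples x genes
  if (all(apply(x, 2L, var) == 0)) {
    stop("constant expression matrix: no variance to decompose",
         call. = FALSE)
  }
  pr <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(ncol(x), nrow(x) - 1L)
  rot <- pr$rotation[, seq_len(k), drop = FALSE]
  sco <- pr$x[, seq_len(k), drop = FALSE]
  sdev <- pr$sdev[seq_len(k)]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  ve <- pr$sdev^2 / sum(pr$sdev^2)
  scores <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(x)),
    tibble::as_tibble(sco)
  )
  if (!is.null(design)) {
    scores <- dplyr::left_join(
      scores,
      dplyr::mutate(design, time = as.character(.data$time)),
      by = "sample_id"
    )
  }
  structure(list(
    scores = scores,
    loadings = dplyr::bind_cols(tibble::tibble(gene = colnames(x)),
                                tibble::as_tibble(rot)),
    variance = tibble::tibble(
      component = paste0("PC", seq_len(k)),
      sdev = sdev,
      var_explained = ve[seq_len(k)],
      cumulative = cumsum(ve)[seq_len(k)]
    ),
    center = pr$center
  ), class = "interplay_pca")
}

#' @export
print.interplay_pca <- function(x, ...) {
  k <- min(3L, nrow(x$variance))
  cat("PCA: ", nrow(x$scores), " samples x ", nrow(x$loadings), " genes; ",
      "var explained: ",
      paste0(x$variance$component[seq_len(k)], " ",
             sprintf("%.1f%%", 100 * x$variance$var_explained[seq_len(k)]),
             collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Enrichment of gene sets in component loadings
#'
#' Ranks genes by decreasing |loading| on one component and asks whether
#' each gene set concentrates toward the top: a one-sided rank-sum
#' (Wilcoxon) test of the set against the rest, with the rank AUC as effect
#' size (probability that a random set gene outranks a random non-set gene;
#' 0.5 under exchangeability). BH adjustment across sets within the
#' component. Using |loading| makes the result invariant to loading sign
#' flips.
#'
#' @param pca An `interplay_pca`.
#' @param component Component id, e.g. `"PC1"` (or index).
#' @param gene_sets Named list of gene id vectors (e.g. interplay categories
#'   from [classify_genes()] calls).
#' @return Tibble `set`, `component`, `n`, `auc`, `p`, `adj_p`, ascending
#'   in p.
#' @export
enrich_loadings <- function(pca, component, gene_sets) {
  stopifnot(length(gene_sets) > 0, !is.null(names(gene_sets)))
  comp <- if (is.numeric(component)) paste0("PC", component) else component
  if (!comp %in% names(pca$loadings)) {
    stop("unknown component: ", comp, call. = FALSE)
  }
  genes <- pca$loadings$gene
  score <- abs(pca$loadings[[comp]])
  rows <- purrr::imap(gene_sets, function(set, nm) {
    set <- unique(set)
    absent <- setdiff(set, genes)
    if (length(absent)) {
      warning("set '", nm, "': ", length(absent),
              " gene(s) absent from loadings dropped", call. = FALSE)
      set <- intersect(set, genes)
    }
    n1 <- length(set)
    n2 <- length(genes) - n1
    if (n1 == 0L || n2 == 0L) {
      return(tibble::tibble(set = nm, component = comp, n = n1,
                            auc = NA_real_, p = NA_real_))
    }
    in_set <- genes %in% set
    r <- rank(score)
    u <- sum(r[in_set]) - n1 * (n1 + 1) / 2
    auc <- u / (n1 * n2)
    p <- suppressWarnings(
      wilcox.test(score[in_set], score[!in_set],
                  alternative = "greater")$p.value
    )
    tibble::tibble(set = nm, component = comp, n = n1, auc = auc, p = p)
  })
  out <- dplyr::bind_rows(rows)
  out$adj_p <- adjust_bh(out$p)
  dplyr::arrange(out, .data$p)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of the overlap between a hit list and each
#' gene set, relative to a universe. Each set is intersected with the
#' universe before testing; the tail includes the observed overlap, so a
#' zero overlap gives p = 1. BH adjustment across sets; output sorted by
#' ascending p.
#'
#' @param hits Character vector of hit genes (must be a subset of
#'   `universe`).
#' @param universe Character vector of background genes.
#' @param gene_sets Named list of gene id vectors (e.g. from [read_gmt()]).
#' @return Tibble `set`, `n_set`, `n_overlap`, `expected`, `p`, `adj_p`.
#' @export
ora_hypergeometric <- function(hits, universe, gene_sets) {
  hits <- unique(hits)
  universe <- unique(universe)
  if (length(setdiff(hits, universe))) {
    stop("hits must be a subset of the universe", call. = FALSE)
  }
  stopifnot(length(gene_sets) > 0, !is.null(names(gene_sets)))
  n_u <- length(universe)
  n_h <- length(hits)
  rows <- purrr::imap(gene_sets, function(set, nm) {
    set <- intersect(unique(set), universe)
    m <- length(set)
    ov <- length(intersect(hits, set))
    p <- if (m == 0L) 1 else phyper(ov - 1L, m, n_u - m, n_h,
                                    lower.tail = FALSE)
    tibble::tibble(set = nm, n_set = m, n_overlap = ov,
                   expected = n_h * m / n_u, p = p)
  })
  out <- dplyr::bind_rows(rows)
  out$adj_p <- adjust_bh(out$p)
  dplyr::arrange(out, .data$p)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of gene id vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fgsea::gmtPathways(path)
}
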