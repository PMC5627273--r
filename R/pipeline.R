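#' Pipeline run configuration
#'
#' Describes one end-to-end run: either file inputs (`expression_path` +
#' `design_path`) or a simulation block (`simulate`), exactly one of the
#' two; DEG cutoffs; classification level and equivalence margin; PCA mode;
#' optional GMT gene sets for over-representation analysis; output
#' directory and seed.
#'
#' @param expression_path,design_path Input TSV paths (mutually exclusive
#'   with `simulate`).
#' @param simulate A [simulation_config()] (mutually exclusive with paths).
#' @param cutoffs A [deg_cutoffs()].
#' @param alpha Elementary-test level for classification (default 0.05).
#' @param margin Equivalence half-width in log2 units (default 1).
#' @param pca_mode `"expression"` (samples x DEG-expression, default) or
#'   `"effects"` (genes x per-time effect scores).
#' @param gmt_path Optional GMT file for ORA.
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed (overrides the simulation block's seed so one
#'   number governs the whole run).
#' @return A list with class `run_config`.
#' @export
run_config <- function(expression_path = NULL, design_path = NULL,
                       simulate = NULL, cutoffs = deg_cutoffs(),
                       alpha = 0.05, margin = 1,
                       pca_mode = c("expression", "effects"),
                       gmt_path = NULL, out_dir = tempfile("interplay_run_"),
                       seed = 1L) {
  pca_mode <- match.arg(pca_mode)
  has_paths <- !is.null(expression_path) || !is.null(design_path)
  if (has_paths && !is.null(simulate)) {
    stop("give either input paths or a simulate block, not both",
         call. = FALSE)
  }
  if (!has_paths && is.null(simulate)) {
    stop("give input paths or a simulate block", call. = FALSE)
  }
  if (has_paths && (is.null(expression_path) || is.null(design_path))) {
    stop("both expression_path and design_path are required", call. = FALSE)
  }
  if (!is.null(simulate)) {
    stopifnot(inherits(simulate, "simulation_config"))
    simulate$seed <- as.integer(seed)
  }
  structure(list(
    expression_path = expression_path, design_path = design_path,
    simulate = simulate, cutoffs = cutoffs, alpha = alpha, margin = margin,
    pca_mode = pca_mode, gmt_path = gmt_path, out_dir = out_dir,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; the `simulate` block
#' mirrors [simulation_config()] and the `cutoffs` block mirrors
#' [deg_cutoffs()].
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulate)) {
    if (!is.null(y$simulate$proportions)) {
      y$simulate$proportions <- unlist(y$simulate$proportions)
    }
    if (!is.null(y$simulate$times)) {
      y$simulate$times <- as.character(unlist(y$simulate$times))
    }
    do.call(simulation_config, y$simulate)
  }
  cut <- if (!is.null(y$cutoffs)) do.call(deg_cutoffs, y$cutoffs)
    else deg_cutoffs()
  run_config(
    expression_path = y$expression_path, design_path = y$design_path,
    simulate = sim, cutoffs = cut,
    alpha = y$alpha %||% 0.05, margin = y$margin %||% 1,
    pca_mode = y$pca_mode %||% "expression",
    gmt_path = y$gmt_path,
    out_dir = y$out_dir %||% tempfile("interplay_run_"),
    seed = y$seed %||% 1L
  )
}

#' Run the full analysis pipeline
#'
#' Ingest (or simulate) -> cell-means fit -> empirical-Bayes moderation ->
#' per-time DEG calling -> interplay classification of the DEG universe ->
#' category summary -> PCA of the DEG union -> loading enrichment of the
#' interplay categories -> optional ORA -> result tables + JSON manifest.
#' The same config and seed always reproduce byte-identical outputs.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage messages.
#' @return The manifest (named list: parameters, versions, per-stage gene
#'   counts, output paths), invisibly; also written as `manifest.json`.
#' @export
run_full <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(nm) file.path(config$out_dir, nm)
  paths <- list()

  truth <- NULL
  if (!is.null(config$simulate)) {
    say("stage simulate: ", config$simulate$n_genes, " genes, seed ",
        config$seed)
    sim <- generate_dataset(config$simulate)
    expression <- sim$expression
    design <- sim$design
    truth <- sim$truth
    write_table(expression, out("expression.tsv"), digits = NULL)
    write_table(design, out("design.tsv"))
    write_table(truth, out("truth.tsv"))
    paths[c("expression", "design", "truth")] <-
      lapply(c("expression.tsv", "design.tsv", "truth.tsv"), out)
  } else {
    say("stage ingest: ", config$expression_path)
    expression <- read_expression(config$expression_path)
    design <- read_design(config$design_path)
  }
  al <- align_samples(expression, design)
  expression <- al$expression
  design <- al$design

  say("stage fit: ", nrow(expression), " genes x ", nrow(design), " samples")
  fit <- fit_cell_means(expression, design)
  prior <- estimate_eb_prior(fit)
  say("stage moderate: d0 = ", signif(prior$d0, 4),
      ", s0^2 = ", signif(prior$s02, 4))

  times <- levels(design$time)
  degs <- list()
  calls <- list()
  for (tm in times) {
    dg <- call_degs(fit, prior, tm, cutoffs = config$cutoffs)
    deg_genes <- dg$gene[dg$is_deg]
    say("stage degs [", tm, "]: ", length(deg_genes), " / ", nrow(dg),
        " genes pass cutoffs")
    cl <- classify_genes(fit, prior, tm, genes = deg_genes,
                         alpha = config$alpha, margin = config$margin)
    say("stage classify [", tm, "]: ",
        sum(cl$category != "unclassified"), " / ", nrow(cl), " assigned")
    degs[[tm]] <- dg
    calls[[tm]] <- cl
    write_table(dg, out(paste0("degs_", tm, ".tsv")))
    write_table(cl, out(paste0("calls_", tm, ".tsv")))
    paths[[paste0("degs_", tm)]] <- out(paste0("degs_", tm, ".tsv"))
    paths[[paste0("calls_", tm)]] <- out(paste0("calls_", tm, ".tsv"))
  }
  degs <- dplyr::bind_rows(degs)
  calls <- dplyr::bind_rows(calls)

  summary <- summarize_categories(calls)
  write_table(summary, out("category_summary.tsv"))
  write_table(summary, out("category_summary.json"), format = "json")
  paths$category_summary <- out("category_summary.tsv")

  deg_union <- unique(degs$gene[degs$is_deg])
  pca <- NULL
  if (length(deg_union) >= 2L) {
    say("stage pca (", config$pca_mode, "): ", length(deg_union),
        " DEG-union genes")
    pca <- if (config$pca_mode == "expression") {
      run_pca(expression, genes = deg_union, design = design)
    } else {
      run_pca_effects(fit, times, genes = deg_union)
    }
    write_table(pca$scores, out("pca_scores.tsv"))
    write_table(pca$loadings, out("pca_loadings.tsv"))
    write_table(pca$variance, out("pca_variance.tsv"))
    paths[c("pca_scores", "pca_loadings", "pca_variance")] <-
      lapply(c("pca_scores.tsv", "pca_loadings.tsv", "pca_variance.tsv"), out)

    sets <- category_gene_sets(calls)
    if (length(sets)) {
      n_comp <- min(2L, nrow(pca$variance))
      enr <- purrr::map(seq_len(n_comp),
                        ~ enrich_loadings(pca, .x, sets)) |>
        dplyr::bind_rows()
      write_table(enr, out("loading_enrichment.tsv"))
      paths$loading_enrichment <- out("loading_enrichment.tsv")
    }
  } else {
    say("stage pca: skipped (fewer than 2 DEGs)")
  }

  if (!is.null(config$gmt_path) && length(deg_union)) {
    sets <- read_gmt(config$gmt_path)
    ora <- ora_hypergeometric(deg_union, expression$gene, sets)
    write_table(ora, out("ora.tsv"))
    paths$ora <- out("ora.tsv")
  }

  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- score_recovery(calls, truth)
    write_table(recovery$summary, out("recovery_summary.tsv"))
    write_table(recovery$confusion, out("recovery_confusion.tsv"))
    paths$recovery_summary <- out("recovery_summary.tsv")
  }

  manifest <- list(
    package = "interplayr",
    version = as.character(packageVersion("interplayr")),
    seed = config$seed,
    parameters = list(
      cutoffs = unclass(config$cutoffs),
      alpha = config$alpha, margin = config$margin,
      pca_mode = config$pca_mode,
      simulate = if (!is.null(config$simulate)) unclass(config$simulate),
      expression_path = config$expression_path,
      design_path = config$design_path
    ),
    moderation = list(d0 = prior$d0, s02 = prior$s02,
                      df_residual = prior$df_residual),
    counts = list(
      genes = nrow(expression), samples = nrow(design),
      deg_per_time = as.list(setNames(
        vapply(times, function(tm) sum(degs$is_deg[degs$time == tm]),
               integer(1L)), times)),
      deg_union = length(deg_union)
    ),
    outputs = paths
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  say("manifest: ", out("manifest.json"))
  invisible(list(manifest = manifest, fit = fit, prior = prior, degs = degs,
                 calls = calls, summary = summary, pca = pca,
                 recovery = recovery))
}

#' Per-time interplay gene sets from calls
#'
#' Builds named gene sets `<category>_<time>` from assigned calls (sets with
#' fewer than `min_size` genes are dropped), for loading enrichment.
#'
#' @param calls Output of [classify_genes()].
#' @param min_size Minimum set size (default 3).
#' @return Named list of gene id vectors.
#' @export
category_gene_sets <- function(calls, min_size = 3L) {
  assigned <- calls[calls$category != "unclassified", ]
  if (!nrow(assigned)) return(list())
  sp <- split(assigned$gene,
              paste0(assigned$category, "_", assigned$time))
  sp[vapply(sp, length, integer(1L)) >= min_size]
}

#' PCA on per-gene effect scores
#'
#' Alternative PCA mode: observations are genes, variables are the per-time
#' effect scores (theta_M, theta_Q, theta_A at every time point).
#'
#' @param fit An `interplay_fit`.
#' @param times Time labels to include.
#' @param genes Optional gene subset.
#' @return An `interplay_pca` (scores rows are genes).
#' @export
run_pca_effects <- function(fit, times, genes = NULL) {
  eff <- purrr::map(times, ~ compute_effect_scores(fit, .x)) |>
    dplyr::bind_rows() |>
    tidyr::pivot_wider(names_from = "time",
                       values_from = c("theta_m", "theta_q", "theta_a"))
  if (!is.null(genes)) eff <- eff[eff$gene %in% genes, ]
  # reuse run_pca by presenting effects as a variables x observations table
  tbl <- tibble::as_tibble(cbind(
    gene = names(eff)[-1L],
    tibble::as_tibble(t(as.matrix(eff[-1L])), .name_repair = "minimal") |>
      setNames(eff$gene)
  ))
  for (j in seq_along(tbl)[-1L]) tbl[[j]] <- as.numeric(tbl[[j]])
  pca <- run_pca(tbl)
  names(pca$scores)[1L] <- "gene"
  names(pca$loadings)[1L] <- "effect"
  pca
}
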