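#' Simulation configuration
#'
#' Describes a synthetic factorial adjuvant study: Gaussian log2 expression,
#' gene-wise variances from a scaled inverse-chi-square prior, the
#' 4-condition x time design (default PBS/MPL/QS21/AS01 at 2h/4h/6h with 3
#' replicates per cell), and planted per-gene interplay categories at stated
#' effect sizes.
#'
#' Planted effect scores per category (log2 units), with base effect
#' `delta` and deviation effect `delta_extra`:
#' emergence (0, 0, delta); additivity (delta/2, delta/2, delta);
#' synergy (delta/2, delta/2, delta + delta_extra);
#' antagonism (delta/2, delta/2, delta - delta_extra);
#' potentiation_by_QS21 (delta, 0, delta + delta_extra);
#' inhibition_by_QS21 (delta, 0, delta - delta_extra);
#' irrelevance_of_QS21 (delta, 0, delta); MPL-sided variants are the mirror
#' images. Remaining genes are null (all zero).
#'
#' @param n_genes Total number of genes.
#' @param proportions Named fractions of genes per planted category
#'   (default 10% each of the ten categories); the remainder is null. Must
#'   sum to at most 1.
#' @param delta Base effect size in log2 units (default 3).
#' @param delta_extra Deviation effect for synergy / antagonism /
#'   potentiation / inhibition (default 1.5).
#' @param n_rep Replicates per condition-by-time cell (default 3).
#' @param times Time labels (default 2h, 4h, 6h).
#' @param baseline_mean,baseline_sd Gene baseline log2 level distribution
#'   (default Normal(8, 1)).
#' @param d0,s02 Scaled inverse-chi-square noise prior: degrees of freedom
#'   (default 4; `Inf` fixes every gene variance at `s02`) and scale
#'   (default 0.05 log2^2 units).
#' @param time_multiplier Optional named per-time multiplier on the planted
#'   effects (default 1 for every time: effects identical across times).
#' @param seed Integer seed; the dataset is fully determined by the config.
#' @return A list with class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 3000,
                              proportions = NULL,
                              delta = 3,
                              delta_extra = 1.5,
                              n_rep = 3,
                              times = c("2h", "4h", "6h"),
                              baseline_mean = 8,
                              baseline_sd = 1,
                              d0 = 4,
                              s02 = 0.05,
                              time_multiplier = NULL,
                              seed = 1L) {
  lv <- interplay_category_levels()
  if (is.null(proportions)) proportions <- setNames(rep(0.1, length(lv)), lv)
  bad <- setdiff(names(proportions), lv)
  if (length(bad)) {
    stop("unknown categories in proportions: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (sum(proportions) > 1 + 1e-12) {
    stop("category proportions sum to more than 1", call. = FALSE)
  }
  stopifnot(n_genes >= 1, delta >= 0, delta_extra >= 0, n_rep >= 2,
            d0 > 0, s02 > 0, baseline_sd >= 0)
  if (is.null(time_multiplier)) {
    time_multiplier <- setNames(rep(1, length(times)), times)
  }
  stopifnot(identical(sort(names(time_multiplier)), sort(times)))
  structure(list(
    n_genes = as.integer(n_genes), proportions = proportions,
    delta = delta, delta_extra = delta_extra, n_rep = as.integer(n_rep),
    times = times, baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    d0 = d0, s02 = s02, time_multiplier = time_multiplier,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Planted effect scores for a category
#'
#' The noise-free (theta_M, theta_Q, theta_A) triple a planted category
#' receives; these satisfy the category's defining conditions exactly.
#'
#' @param category Category label (or `"null"`).
#' @inheritParams simulation_config
#' @return Named numeric vector `theta_m`, `theta_q`, `theta_a`.
#' @export
planted_effects <- function(category, delta = 3, delta_extra = 1.5) {
  th <- switch(category,
    null                 = c(0, 0, 0),
    emergence            = c(0, 0, delta),
    irrelevance_of_MPL   = c(0, delta, delta),
    irrelevance_of_QS21  = c(delta, 0, delta),
    additivity           = c(delta / 2, delta / 2, delta),
    synergy              = c(delta / 2, delta / 2, delta + delta_extra),
    antagonism           = c(delta / 2, delta / 2, delta - delta_extra),
    potentiation_by_MPL  = c(0, delta, delta + delta_extra),
    potentiation_by_QS21 = c(delta, 0, delta + delta_extra),
    inhibition_by_MPL    = c(0, delta, delta - delta_extra),
    inhibition_by_QS21   = c(delta, 0, delta - delta_extra),
    stop("unknown category: ", category, call. = FALSE)
  )
  setNames(th, c("theta_m", "theta_q", "theta_a"))
}

#' Generate a synthetic factorial dataset with planted truth
#'
#' Draws, per gene, a baseline level \eqn{\mu_g \sim N(\mu_0, sd_0^2)} and a
#' noise variance \eqn{\sigma_g^2 = d_0 s_0^2 / \chi^2_{d_0}} (scaled
#' inverse-chi-square; constant `s02` when `d0 = Inf`), sets cell means
#' PBS = \eqn{\mu_g}, MPL = \eqn{\mu_g + \theta_M}, QS21 =
#' \eqn{\mu_g + \theta_Q}, AS01 = \eqn{\mu_g + \theta_A} with the planted
#' category's effects (scaled by the per-time multiplier), and adds
#' \eqn{N(0, \sigma_g^2)} replicate noise. The same seed always reproduces
#' the identical dataset.
#'
#' @param config A [simulation_config()].
#' @return List with `expression` (tibble), `design` (tibble), `truth`
#'   (tibble `gene`, `time`, `category`, `theta_m`, `theta_q`, `theta_a`,
#'   `sigma2`) and the `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  G <- config$n_genes
  conditions <- c("PBS", "MPL", "QS21", "AS01")
  genes <- sprintf("gene%05d", seq_len(G))

  n_cat <- floor(G * config$proportions)
  if (sum(n_cat) > G) stop("category proportions exceed gene count",
                           call. = FALSE)
  category <- rep("null", G)
  at <- 1L
  for (nm in names(n_cat)) {
    if (n_cat[[nm]] > 0) {
      category[at:(at + n_cat[[nm]] - 1L)] <- nm
      at <- at + n_cat[[nm]]
    }
  }

  mu <- rnorm(G, config$baseline_mean, config$baseline_sd)
  sigma2 <- if (is.infinite(config$d0)) {
    rep(config$s02, G)
  } else {
    config$d0 * config$s02 / rchisq(G, df = config$d0)
  }
  theta <- t(vapply(category, planted_effects, numeric(3L),
                    delta = config$delta, delta_extra = config$delta_extra))
  dimnames(theta) <- NULL

  design <- tidyr::expand_grid(
    time = config$times, condition = conditions,
    replicate = seq_len(config$n_rep)
  ) |>
    dplyr::mutate(
      sample_id = paste0(.data$condition, "_", .data$time, "_r",
                         .data$replicate)
    ) |>
    dplyr::select("sample_id", "condition", "time", "replicate")

  shift <- cbind(PBS = 0, MPL = theta[, 1L], QS21 = theta[, 2L],
                 AS01 = theta[, 3L])
  vals <- matrix(NA_real_, G, nrow(design),
                 dimnames = list(NULL, design$sample_id))
  for (j in seq_len(nrow(design))) {
    cell_mean <- mu + shift[, design$condition[[j]]] *
      config$time_multiplier[[design$time[[j]]]]
    vals[, j] <- cell_mean + rnorm(G, 0, sqrt(sigma2))
  }

  truth <- tidyr::expand_grid(gene = genes, time = config$times) |>
    dplyr::mutate(
      category = category[match(.data$gene, genes)],
      theta_m = theta[match(.data$gene, genes), 1L] *
        unname(config$time_multiplier[.data$time]),
      theta_q = theta[match(.data$gene, genes), 2L] *
        unname(config$time_multiplier[.data$time]),
      theta_a = theta[match(.data$gene, genes), 3L] *
        unname(config$time_multiplier[.data$time]),
      sigma2 = sigma2[match(.data$gene, genes)]
    )

  list(
    expression = dplyr::bind_cols(tibble::tibble(gene = genes),
                                  tibble::as_tibble(vals)),
    design = validate_design(design, times = config$times),
    truth = truth,
    config = config
  )
}

#' Score classification recovery against planted truth
#'
#' Compares interplay calls with the planted categories. Planted (gene,
#' time) pairs absent from the calls (e.g. never reached the DEG universe)
#' count as unclassified. Sensitivity = correctly-called / planted;
#' precision = correctly-called / called (NA when a category was never
#' called). Confusion rows sum to the planted counts.
#'
#' @param calls Output of [classify_genes()] (any number of time points).
#' @param truth Truth tibble from [generate_dataset()].
#' @return List with `summary` (per-category tibble) and `confusion`
#'   (planted x called counts), class `recovery_report`.
#' @export
score_recovery <- function(calls, truth) {
  lv <- interplay_category_levels()
  called_lv <- c(lv, "unclassified")
  if (nrow(calls) > 0L) {
    truth <- truth[truth$time %in% unique(calls$time), ]
  }
  joined <- dplyr::left_join(
    truth[c("gene", "time", "category")] |>
      dplyr::rename(planted = "category"),
    calls[c("gene", "time", "category")] |>
      dplyr::rename(called = "category"),
    by = c("gene", "time")
  ) |>
    dplyr::mutate(called = dplyr::coalesce(.data$called, "unclassified"))

  confusion <- joined |>
    dplyr::mutate(
      planted = factor(.data$planted, levels = c(lv, "null")),
      called = factor(.data$called, levels = called_lv)
    ) |>
    dplyr::count(.data$planted, .data$called, .drop = FALSE, name = "n") |>
    dplyr::mutate(planted = as.character(.data$planted),
                  called = as.character(.data$called))

  summary <- purrr::map(lv, function(cat) {
    n_planted <- sum(joined$planted == cat)
    n_called <- sum(joined$called == cat)
    n_correct <- sum(joined$planted == cat & joined$called == cat)
    tibble::tibble(
      category = cat,
      n_planted = n_planted,
      n_called = n_called,
      n_correct = n_correct,
      sensitivity = if (n_planted > 0) n_correct / n_planted else NA_real_,
      precision = if (n_called > 0) n_correct / n_called else NA_real_
    )
  }) |> dplyr::bind_rows()

  structure(list(summary = summary, confusion = confusion),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery over", sum(x$summary$n_planted), "planted gene-times\n")
  print(x$summary, n = nrow(x$summary))
  invisible(x)
}
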