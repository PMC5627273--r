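#' Elementary contrasts of the interplay machinery
#'
#' The named condition-weight vectors from which every interplay statement is
#' built, all within one time point and in log2 units:
#' `mpl` (\eqn{\theta_M}), `qs21` (\eqn{\theta_Q}), `as01` (\eqn{\theta_A})
#' are effect scores over PBS; `deviation` is
#' \eqn{\theta_A - \theta_M - \theta_Q}, the departure from additivity;
#' `as01_vs_mpl` and `as01_vs_qs21` compare the combination with one single
#' component; `single_sum` (\eqn{\theta_M + \theta_Q}) is used only as a sign
#' reference.
#'
#' @return Named list of condition-weight vectors.
#' @export
interplay_contrasts <- function() {
  list(
    mpl          = c(PBS = -1, MPL = 1),
    qs21         = c(PBS = -1, QS21 = 1),
    as01         = c(PBS = -1, AS01 = 1),
    deviation    = c(PBS = 1, MPL = -1, QS21 = -1, AS01 = 1),
    as01_vs_mpl  = c(MPL = -1, AS01 = 1),
    as01_vs_qs21 = c(QS21 = -1, AS01 = 1),
    single_sum   = c(PBS = -2, MPL = 1, QS21 = 1)
  )
}

#' Declarative interplay category table
#'
#' One row per elementary statement; a category is the conjunction (an
#' intersection-union test) of its rows. `kind` is `"difference"` (the
#' contrast must differ from zero) or `"equivalence"` (the contrast must lie
#' confidently inside the margin interval). A non-`NA` `sign_ref` additionally
#' requires `sign(estimate(contrast)) == sign_mult * sign(estimate(sign_ref))`
#' on the point estimates.
#'
#' The ten categories, in fixed tie-break order: irrelevance of MPL /
#' of QS-21 (one component contributes nothing), additivity, synergy
#' (super-additive deviation in the direction of the combined response),
#' antagonism (deviation opposing the summed single effects, both single
#' components active), potentiation and inhibition by either component (one
#' component inert alone yet boosting or damping the other), and emergence
#' (neither component active alone, combination active).
#'
#' The table is plain data: edit rows to explore variant definitions (e.g.
#' an antagonism requiring only one active single component) without
#' touching code.
#'
#' @return Tibble with columns `category`, `contrast`, `kind`, `sign_ref`,
#'   `sign_mult`.
#' @export
interplay_categories <- function() {
  tribble_ <- function(...) tibble::tribble(...)
  tribble_(
    ~category,             ~contrast,      ~kind,         ~sign_ref,    ~sign_mult,
    "irrelevance_of_MPL",  "mpl",          "equivalence", NA,           NA,
    "irrelevance_of_MPL",  "as01_vs_qs21", "equivalence", NA,           NA,
    "irrelevance_of_QS21", "qs21",         "equivalence", NA,           NA,
    "irrelevance_of_QS21", "as01_vs_mpl",  "equivalence", NA,           NA,
    "additivity",          "mpl",          "difference",  NA,           NA,
    "additivity",          "qs21",         "difference",  NA,           NA,
    "additivity",          "deviation",    "equivalence", NA,           NA,
    "synergy",             "mpl",          "difference",  NA,           NA,
    "synergy",             "qs21",         "difference",  NA,           NA,
    "synergy",             "deviation",    "difference",  "as01",       1,
    "antagonism",          "mpl",          "difference",  NA,           NA,
    "antagonism",          "qs21",         "difference",  NA,           NA,
    "antagonism",          "deviation",    "difference",  "single_sum", -1,
    "potentiation_by_MPL", "mpl",          "equivalence", NA,           NA,
    "potentiation_by_MPL", "qs21",         "difference",  NA,           NA,
    "potentiation_by_MPL", "as01_vs_qs21", "difference",  "qs21",       1,
    "potentiation_by_QS21","qs21",         "equivalence", NA,           NA,
    "potentiation_by_QS21","mpl",          "difference",  NA,           NA,
    "potentiation_by_QS21","as01_vs_mpl",  "difference",  "mpl",        1,
    "inhibition_by_MPL",   "mpl",          "equivalence", NA,           NA,
    "inhibition_by_MPL",   "qs21",         "difference",  NA,           NA,
    "inhibition_by_MPL",   "as01_vs_qs21", "difference",  "qs21",       -1,
    "inhibition_by_QS21",  "qs21",         "equivalence", NA,           NA,
    "inhibition_by_QS21",  "mpl",          "difference",  NA,           NA,
    "inhibition_by_QS21",  "as01_vs_mpl",  "difference",  "mpl",        -1,
    "emergence",           "mpl",          "equivalence", NA,           NA,
    "emergence",           "qs21",         "equivalence", NA,           NA,
    "emergence",           "as01",         "difference",  NA,           NA
  )
}

#' Category names in tie-break order
#' @return Character vector of the ten category labels.
#' @export
interplay_category_levels <- function() {
  unique(interplay_categories()$category)
}

#' Per-gene effect scores over PBS
#'
#' For one time point, the three effect scores in log2 units:
#' \eqn{\theta_M} = mean(MPL) - mean(PBS), \eqn{\theta_Q} = mean(QS21) -
#' mean(PBS), \eqn{\theta_A} = mean(AS01) - mean(PBS). These equal the
#' corresponding [test_contrast()] estimates.
#'
#' @param fit An `interplay_fit`.
#' @param time Time label.
#' @return Tibble `gene`, `time`, `theta_m`, `theta_q`, `theta_a`.
#' @export
compute_effect_scores <- function(fit, time) {
  cw <- interplay_contrasts()
  est <- function(nm) {
    w <- contrast_weights(fit, cw[[nm]], time)
    unname(drop(fit$coefficients[, names(w), drop = FALSE] %*% w))
  }
  tibble::tibble(
    gene = fit$genes,
    time = as.character(time),
    theta_m = est("mpl"),
    theta_q = est("qs21"),
    theta_a = est("as01")
  )
}

#' TOST equivalence test for a contrast
#'
#' Two one-sided moderated t-tests against the margin interval
#' \eqn{[-margin, margin]}: the equivalence p-value is
#' \eqn{\max\{P(T \le (\hat c - m)/SE),\ P(T \ge (\hat c + m)/SE)\}} on
#' \eqn{d_0 + d_g} degrees of freedom. Equivalence is declared when p < alpha;
#' an estimate on the margin has one one-sided p of 0.5, so it can never be
#' declared equivalent at conventional levels.
#'
#' @inheritParams test_contrast
#' @param margin Positive half-width of the equivalence interval (log2
#'   units, default 1).
#' @return Tibble with columns `gene`, `contrast`, `kind`, `estimate`, `se`,
#'   `df`, `margin`, `p`, `degenerate`.
#' @export
test_equivalence <- function(fit, prior, weights, margin = 1,
                             name = "contrast") {
  stopifnot(margin > 0)
  mo <- contrast_moments(fit, prior, weights)
  est <- mo$estimate
  se <- mo$se
  p_lo <- pt((est - margin) / se, df = mo$df)          # H0: c >= margin
  p_hi <- pt((est + margin) / se, df = mo$df, lower.tail = FALSE)
  p <- pmax(p_lo, p_hi)
  degen <- se == 0
  if (any(degen)) {
    warning(sum(degen), " gene(s) with zero moderated variance in ",
            "equivalence test '", name, "'", call. = FALSE)
    p[degen] <- ifelse(abs(est[degen]) < margin, 0, 1)
  }
  tibble::tibble(
    gene = fit$genes, contrast = name, kind = "equivalence",
    estimate = est, se = se, df = mo$df, margin = margin,
    p = p, degenerate = degen
  )
}

#' Classify gene interplay at one time point
#'
#' Evaluates every category of the declarative table as an
#' intersection-union test (IUT): the category p-value is the maximum of its
#' component p-values (moderated difference tests for "different from zero"
#' statements, TOST equivalence tests for "confidently inside the margin"
#' statements), and the category passes when all sign conditions hold on the
#' point estimates and the IUT p-value is below `alpha`. A gene is assigned
#' the passing category with the smallest IUT p-value (ties broken by the
#' fixed table order); with no passing category it is `unclassified`.
#'
#' The three-state logic is deliberate: a contrast is "active" when the
#' difference test rejects, "null" when the equivalence test rejects, and
#' indeterminate otherwise; categories requiring a null do not fire on a
#' merely non-significant contrast.
#'
#' The natural classification universe is the AS01 DEG set at that time
#' point (`genes = degs$gene[degs$is_deg]`); any gene subset in the fit is
#' accepted.
#'
#' @param fit An `interplay_fit`.
#' @param prior An `eb_prior`.
#' @param time Time label.
#' @param genes Genes to classify (default all genes in the fit).
#' @param alpha Per-elementary-test level (default 0.05, unadjusted; the IUT
#'   is already conservative).
#' @param margin Equivalence half-width in log2 units (default 1).
#' @param categories Category table ([interplay_categories()]).
#' @return Tibble with one row per gene: `gene`, `time`, `category`,
#'   `iut_p`, `theta_m`, `theta_q`, `theta_a`, and one `p_diff_*` / `p_eq_*`
#'   column per elementary test used.
#' @export
classify_genes <- function(fit, prior, time, genes = NULL,
                           alpha = 0.05, margin = 1,
                           categories = interplay_categories()) {
  if (is.null(genes)) genes <- fit$genes
  missing <- setdiff(genes, fit$genes)
  if (length(missing)) {
    stop("genes absent from fit: ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  idx <- match(genes, fit$genes)
  cw <- interplay_contrasts()
  used <- unique(categories$contrast)
  refs <- unique(categories$sign_ref[!is.na(categories$sign_ref)])
  unknown <- setdiff(c(used, refs), names(cw))
  if (length(unknown)) {
    stop("category table references undefined contrasts: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  need_diff <- unique(categories$contrast[categories$kind == "difference"])
  need_eq <- unique(categories$contrast[categories$kind == "equivalence"])
  est <- p_diff <- p_eq <- list()
  for (nm in unique(c(used, refs))) {
    w <- contrast_weights(fit, cw[[nm]], time)
    if (nm %in% need_diff) {
      d <- test_contrast(fit, prior, w, name = nm)
      est[[nm]] <- d$estimate[idx]
      p_diff[[nm]] <- d$p[idx]
    } else {
      est[[nm]] <- unname(
        drop(fit$coefficients[, names(w), drop = FALSE] %*% w))[idx]
    }
    if (nm %in% need_eq) {
      p_eq[[nm]] <- test_equivalence(fit, prior, w, margin = margin,
                                     name = nm)$p[idx]
    }
  }

  cats <- unique(categories$category)
  n <- length(genes)
  iut <- matrix(NA_real_, n, length(cats), dimnames = list(NULL, cats))
  pass <- matrix(TRUE, n, length(cats), dimnames = list(NULL, cats))
  for (k in seq_along(cats)) {
    rows <- categories[categories$category == cats[[k]], ]
    pmat <- matrix(0, n, nrow(rows))
    for (i in seq_len(nrow(rows))) {
      pmat[, i] <- if (rows$kind[[i]] == "difference") {
        p_diff[[rows$contrast[[i]]]]
      } else {
        p_eq[[rows$contrast[[i]]]]
      }
      if (!is.na(rows$sign_ref[[i]])) {
        ok <- sign(est[[rows$contrast[[i]]]]) ==
          rows$sign_mult[[i]] * sign(est[[rows$sign_ref[[i]]]])
        ok <- ok & sign(est[[rows$contrast[[i]]]]) != 0
        pass[, k] <- pass[, k] & ok
      }
    }
    iut[, k] <- apply(pmat, 1L, max)
    pass[, k] <- pass[, k] & iut[, k] < alpha
  }

  iut_masked <- iut
  iut_masked[!pass] <- Inf
  best <- apply(iut_masked, 1L, which.min)  # ties -> earliest = table order
  any_pass <- rowSums(pass) > 0
  category <- ifelse(any_pass, cats[best], "unclassified")
  iut_p <- ifelse(any_pass, iut[cbind(seq_len(n), best)], NA_real_)

  out <- tibble::tibble(
    gene = genes,
    time = as.character(time),
    category = category,
    iut_p = iut_p,
    theta_m = est[["mpl"]],
    theta_q = est[["qs21"]],
    theta_a = est[["as01"]]
  )
  for (nm in names(p_diff)) out[[paste0("p_diff_", nm)]] <- p_diff[[nm]]
  for (nm in names(p_eq)) out[[paste0("p_eq_", nm)]] <- p_eq[[nm]]
  out
}

#' Summarize interplay calls over the DEG universe
#'
#' Per time point, the count and fraction of classified genes in each
#' category, including the unclassified remainder. Two fractions are
#' emitted: `fraction` over all classified-universe genes (categories plus
#' unclassified sum to 1) and `fraction_classified` over assigned genes
#' only.
#'
#' @param calls Output of [classify_genes()] (possibly several time points
#'   bound together).
#' @return Tibble `time`, `category`, `n`, `fraction`,
#'   `fraction_classified`, `n_total`.
#' @export
summarize_categories <- function(calls) {
  lv <- c(interplay_category_levels(), "unclassified")
  if (nrow(calls) == 0L) {
    return(tibble::tibble(time = character(), category = character(),
                          n = integer(), fraction = numeric(),
                          fraction_classified = numeric(),
                          n_total = integer()))
  }
  calls |>
    dplyr::mutate(category = factor(.data$category, levels = lv)) |>
    dplyr::count(.data$time, .data$category, .drop = FALSE, name = "n") |>
    dplyr::group_by(.data$time) |>
    dplyr::mutate(
      n_total = sum(.data$n),
      fraction = ifelse(.data$n_total > 0, .data$n / .data$n_total, NA_real_),
      n_classified = sum(.data$n[.data$category != "unclassified"]),
      fraction_classified = dplyr::case_when(
        as.character(.data$category) == "unclassified" ~ NA_real_,
        .data$n_classified == 0 ~ NA_real_,
        TRUE ~ .data$n / .data$n_classified
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(category = as.character(.data$category)) |>
    dplyr::select("time", "category", "n", "fraction",
                  "fraction_classified", "n_total")
}
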