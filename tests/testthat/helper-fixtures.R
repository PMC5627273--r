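# Build a factorial dataset from explicit per-gene effect scores.
# theta: data frame with gene, theta_m, theta_q, theta_a (log2 over PBS).
make_theta_dataset <- function(theta, mu = 8, sigma = 1e-2, n_rep = 3,
                               times = "2h", seed = 1) {
  set.seed(seed)
  conditions <- c("PBS", "MPL", "QS21", "AS01")
  design <- expand.grid(replicate = seq_len(n_rep), condition = conditions,
                        time = times, stringsAsFactors = FALSE)
  design$sample_id <- paste0(design$condition, "_", design$time, "_r",
                             design$replicate)
  design <- tibble::as_tibble(design[c("sample_id", "condition", "time",
                                       "replicate")])
  shift <- cbind(PBS = 0, MPL = theta$theta_m, QS21 = theta$theta_q,
                 AS01 = theta$theta_a)
  vals <- vapply(seq_len(nrow(design)), function(j) {
    mu + shift[, design$condition[[j]]] + rnorm(nrow(theta), 0, sigma)
  }, numeric(nrow(theta)))
  vals <- matrix(vals, nrow = nrow(theta),
                 dimnames = list(NULL, design$sample_id))
  list(
    expression = dplyr::bind_cols(tibble::tibble(gene = theta$gene),
                                  tibble::as_tibble(vals)),
    design = validate_design(design, times = unique(times))
  )
}

# Fit + estimated prior in one call.
fit_with_prior <- function(dat) {
  fit <- fit_cell_means(dat$expression, dat$design)
  list(fit = fit, prior = estimate_eb_prior(fit))
}

# Independent brute-force step-up BH, straight from the definition.
brute_force_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[o[i]] <- min(vapply(i:n, function(j) p[o[j]] * n / j, numeric(1)), 1)
  }
  adj
}

# Independent first-principles IUT evaluator for one gene: recomputes every
# elementary estimate, SE, difference and TOST p straight from the cell
# means and the moderated variance, spells out the ten category conjunctions
# longhand, and returns the assignment. Shares no code with classify_genes.
brute_force_classify <- function(fit, prior, gene, time, alpha = 0.05,
                                 margin = 1) {
  cells <- fit$cells
  g <- match(gene, fit$genes)
  mean_of <- function(cond) {
    unname(fit$coefficients[g, cells$cell[cells$condition == cond &
                                            cells$time == time]])
  }
  n_of <- function(cond) {
    unname(fit$n_per_cell[cells$cell[cells$condition == cond &
                                       cells$time == time]])
  }
  s2 <- prior$var_post[[g]]
  df <- prior$df_total
  mns <- c(PBS = mean_of("PBS"), MPL = mean_of("MPL"),
           QS21 = mean_of("QS21"), AS01 = mean_of("AS01"))
  ns <- c(PBS = n_of("PBS"), MPL = n_of("MPL"),
          QS21 = n_of("QS21"), AS01 = n_of("AS01"))
  lincomb <- function(w) {
    est <- sum(w * mns[names(w)])
    se <- sqrt(s2 * sum(w^2 / ns[names(w)]))
    list(est = est, se = se)
  }
  p_diff <- function(l) 2 * pt(-abs(l$est / l$se), df)
  p_tost <- function(l) {
    max(pt((l$est - margin) / l$se, df),
        pt((l$est + margin) / l$se, df, lower.tail = FALSE))
  }
  M <- lincomb(c(PBS = -1, MPL = 1))
  Q <- lincomb(c(PBS = -1, QS21 = 1))
  A <- lincomb(c(PBS = -1, AS01 = 1))
  D <- lincomb(c(PBS = 1, MPL = -1, QS21 = -1, AS01 = 1))
  AM <- lincomb(c(MPL = -1, AS01 = 1))
  AQ <- lincomb(c(QS21 = -1, AS01 = 1))
  sum_est <- M$est + Q$est

  cand <- list(
    irrelevance_of_MPL = list(p = max(p_tost(M), p_tost(AQ)), ok = TRUE),
    irrelevance_of_QS21 = list(p = max(p_tost(Q), p_tost(AM)), ok = TRUE),
    additivity = list(p = max(p_diff(M), p_diff(Q), p_tost(D)), ok = TRUE),
    synergy = list(p = max(p_diff(M), p_diff(Q), p_diff(D)),
                   ok = sign(D$est) == sign(A$est) && sign(D$est) != 0),
    antagonism = list(p = max(p_diff(M), p_diff(Q), p_diff(D)),
                      ok = sign(D$est) == -sign(sum_est) && sign(D$est) != 0),
    potentiation_by_MPL = list(p = max(p_tost(M), p_diff(Q), p_diff(AQ)),
                               ok = sign(AQ$est) == sign(Q$est) &&
                                 sign(AQ$est) != 0),
    potentiation_by_QS21 = list(p = max(p_tost(Q), p_diff(M), p_diff(AM)),
                                ok = sign(AM$est) == sign(M$est) &&
                                  sign(AM$est) != 0),
    inhibition_by_MPL = list(p = max(p_tost(M), p_diff(Q), p_diff(AQ)),
                             ok = sign(AQ$est) == -sign(Q$est) &&
                               sign(AQ$est) != 0),
    inhibition_by_QS21 = list(p = max(p_tost(Q), p_diff(M), p_diff(AM)),
                              ok = sign(AM$est) == -sign(M$est) &&
                                sign(AM$est) != 0),
    emergence = list(p = max(p_tost(M), p_tost(Q), p_diff(A)), ok = TRUE)
  )
  ps <- vapply(cand, function(x) x$p, numeric(1))
  ok <- vapply(cand, function(x) isTRUE(x$ok), logical(1)) & ps < alpha
  if (!any(ok)) {
    return(list(category = "unclassified", iut_p = NA_real_, all_p = ps))
  }
  ps_ok <- ifelse(ok, ps, Inf)
  k <- which.min(ps_ok)
  list(category = names(cand)[[k]], iut_p = ps[[k]], all_p = ps)
}
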