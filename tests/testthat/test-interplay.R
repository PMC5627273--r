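test_that("effect scores over PBS are the cell-mean contrasts", {
  dat <- make_theta_dataset(
    tibble::tibble(gene = c("forced", "flat"),
                   theta_m = c(1, 0), theta_q = c(0.5, 0),
                   theta_a = c(3, 0)),
    sigma = 0, n_rep = 3
  )
  fit0 <- fit_cell_means(dat$expression, dat$design)
  eff <- compute_effect_scores(fit0, "2h")
  expect_equal(eff$theta_m, c(1, 0))
  expect_equal(eff$theta_q, c(0.5, 0))
  expect_equal(eff$theta_a, c(3, 0))

  # cross-module: theta equals the matching test_contrast estimate
  set.seed(21)
  sim <- generate_dataset(simulation_config(n_genes = 60, seed = 21))
  fit <- fit_cell_means(sim$expression, sim$design)
  pr <- estimate_eb_prior(fit)
  eff2 <- compute_effect_scores(fit, "6h")
  for (nm in c("mpl", "qs21", "as01")) {
    res <- test_contrast(fit, pr,
                         contrast_weights(fit, interplay_contrasts()[[nm]],
                                          "6h"))
    col <- c(mpl = "theta_m", qs21 = "theta_q", as01 = "theta_a")[[nm]]
    expect_equal(eff2[[col]], res$estimate)
  }
})

test_that("TOST equivalence has the boundary, limit and t-CDF properties", {
  # hand-checkable two-cell layout: PBS mean 0, MPL mean = estimate
  build <- function(est, sigma, n_rep) {
    theta <- tibble::tibble(gene = "g1", theta_m = est, theta_q = 0,
                            theta_a = 0)
    make_theta_dataset(theta, mu = 0, sigma = sigma, n_rep = n_rep, seed = 3)
  }
  w_of <- function(fit) contrast_weights(fit, c(PBS = -1, MPL = 1), "2h")

  # estimate pinned exactly at the margin: TOST p >= 0.5, never equivalent
  dat <- build(1, sigma = 0, n_rep = 3)
  fit <- fit_cell_means(dat$expression, dat$design)
  pr <- eb_prior(fit, d0 = Inf, s02 = 1e-12)
  eq <- test_equivalence(fit, pr, w_of(fit), margin = 1)
  expect_gte(eq$p, 0.5 - 1e-6)

  # zero estimate, vanishing SE: p -> 0
  dat0 <- build(0, sigma = 1e-6, n_rep = 6)
  fit0 <- fit_cell_means(dat0$expression, dat0$design)
  pr0 <- eb_prior(fit0, d0 = Inf, s02 = 1e-12)
  eq0 <- test_equivalence(fit0, pr0, w_of(fit0), margin = 1)
  expect_lt(eq0$p, 1e-10)

  # independent Student-t tail oracle on a noisy case
  datn <- build(0.5, sigma = 0.4, n_rep = 5)
  fitn <- fit_cell_means(datn$expression, datn$design)
  prn <- eb_prior(fitn, d0 = 6, s02 = 0.12)
  eqn <- test_equivalence(fitn, prn, w_of(fitn), margin = 1)
  # recompute from the raw replicate values, sharing no package code
  m <- as.matrix(datn$expression[-1])
  pbs <- m[1, grep("^PBS", colnames(m))]
  mpl <- m[1, grep("^MPL", colnames(m))]
  cells <- split(m[1, ], sub("_r[0-9]+$", "", colnames(m)))
  s2g <- sum(vapply(cells, function(x) sum((x - mean(x))^2), numeric(1))) /
    (length(m[1, ]) - length(cells))
  s2post <- (6 * 0.12 + fitn$df_residual * s2g) / (6 + fitn$df_residual)
  se <- sqrt(s2post * (1 / 5 + 1 / 5))
  est <- mean(mpl) - mean(pbs)
  df <- 6 + fitn$df_residual
  p_oracle <- max(pt((est - 1) / se, df), pt((est + 1) / se, df,
                                             lower.tail = FALSE))
  expect_equal(eqn$p, p_oracle, tolerance = 1e-10)
  expect_equal(eqn$estimate, est, tolerance = 1e-10)
})

test_that("noise-free archetypes classify to their defining categories", {
  cases <- tibble::tribble(
    ~gene, ~theta_m, ~theta_q, ~theta_a, ~expected,
    "emer",   0,   0,   3,   "emergence",
    "irrQ",   2,   0,   2,   "irrelevance_of_QS21",
    "irrM",   0,   2,   2,   "irrelevance_of_MPL",
    "addi", 1.5, 1.5,   3,   "additivity",
    "syne", 1.5, 1.5,   5,   "synergy",
    "anta", 1.5, 1.5, 1.2,   "antagonism",
    "potQ",   3,   0, 4.5,   "potentiation_by_QS21",
    "inhQ",   3,   0, 1.5,   "inhibition_by_QS21",
    "potM",   0,   3, 4.5,   "potentiation_by_MPL",
    "inhM",   0,   3, 1.5,   "inhibition_by_MPL"
  )
  dat <- make_theta_dataset(cases[1:4], sigma = 5e-3, n_rep = 12, seed = 13)
  fit <- fit_cell_means(dat$expression, dat$design)
  prior <- estimate_eb_prior(fit)
  calls <- classify_genes(fit, prior, "2h")
  expect_equal(calls$category, cases$expected)
  expect_true(all(calls$iut_p < 0.05))
})

test_that("classification agrees with a first-principles IUT evaluator", {
  sim <- generate_dataset(simulation_config(n_genes = 250, seed = 17))
  fit <- fit_cell_means(sim$expression, sim$design)
  prior <- estimate_eb_prior(fit)
  dg <- call_degs(fit, prior, "4h")
  genes <- dg$gene[dg$is_deg]
  calls <- classify_genes(fit, prior, "4h", genes = genes)
  oracle <- lapply(genes, function(g)
    brute_force_classify(fit, prior, g, "4h"))
  expect_equal(calls$category,
               vapply(oracle, function(o) o$category, character(1)))
  expect_equal(calls$iut_p,
               vapply(oracle, function(o) o$iut_p, numeric(1)),
               tolerance = 1e-12)
})

test_that("the IUT p-value is the maximum of its component p-values", {
  sim <- generate_dataset(simulation_config(n_genes = 120, seed = 23))
  fit <- fit_cell_means(sim$expression, sim$design)
  prior <- estimate_eb_prior(fit)
  calls <- classify_genes(fit, prior, "2h")
  tab <- interplay_categories()
  assigned <- calls[calls$category != "unclassified", ]
  recomputed <- vapply(seq_len(nrow(assigned)), function(i) {
    rows <- tab[tab$category == assigned$category[[i]], ]
    max(vapply(seq_len(nrow(rows)), function(j) {
      col <- paste0(ifelse(rows$kind[[j]] == "difference", "p_diff_",
                           "p_eq_"), rows$contrast[[j]])
      assigned[[col]][[i]]
    }, numeric(1)))
  }, numeric(1))
  expect_equal(assigned$iut_p, recomputed)
  expect_true(all(recomputed < 0.05))
})

test_that("swapping the MPL and QS21 arms mirrors the category labels", {
  sim <- generate_dataset(simulation_config(n_genes = 400, seed = 29))
  fit <- fit_cell_means(sim$expression, sim$design)
  prior <- estimate_eb_prior(fit)
  dg <- call_degs(fit, prior, "4h")
  calls <- classify_genes(fit, prior, "4h", genes = dg$gene[dg$is_deg])

  swapped_design <- sim$design
  swapped_design$condition <- c(PBS = "PBS", MPL = "QS21", QS21 = "MPL",
                                AS01 = "AS01")[sim$design$condition]
  fit_sw <- fit_cell_means(sim$expression, swapped_design)
  prior_sw <- estimate_eb_prior(fit_sw)
  dg_sw <- call_degs(fit_sw, prior_sw, "4h")
  expect_equal(dg_sw$is_deg, dg$is_deg)
  calls_sw <- classify_genes(fit_sw, prior_sw, "4h",
                             genes = dg_sw$gene[dg_sw$is_deg])

  mirror <- c(
    irrelevance_of_MPL = "irrelevance_of_QS21",
    irrelevance_of_QS21 = "irrelevance_of_MPL",
    potentiation_by_MPL = "potentiation_by_QS21",
    potentiation_by_QS21 = "potentiation_by_MPL",
    inhibition_by_MPL = "inhibition_by_QS21",
    inhibition_by_QS21 = "inhibition_by_MPL",
    additivity = "additivity", synergy = "synergy",
    antagonism = "antagonism", emergence = "emergence",
    unclassified = "unclassified"
  )
  expect_equal(calls_sw$category, unname(mirror[calls$category]))
  expect_equal(calls_sw$theta_m, calls$theta_q)
  expect_equal(calls_sw$theta_q, calls$theta_m)
})

test_that("category summaries partition the DEG universe", {
  sim <- generate_dataset(simulation_config(n_genes = 300, seed = 31))
  fit <- fit_cell_means(sim$expression, sim$design)
  prior <- estimate_eb_prior(fit)
  calls <- dplyr::bind_rows(lapply(c("2h", "4h"), function(tm) {
    dg <- call_degs(fit, prior, tm)
    classify_genes(fit, prior, tm, genes = dg$gene[dg$is_deg])
  }))
  smry <- summarize_categories(calls)
  sums <- dplyr::summarise(dplyr::group_by(smry, time),
                           total_frac = sum(fraction),
                           total_n = sum(n),
                           n_total = dplyr::first(n_total))
  expect_equal(sums$total_frac, rep(1, nrow(sums)))
  expect_equal(sums$total_n, sums$n_total)

  # classified-only fractions also sum to 1 where anything was assigned
  cf <- dplyr::summarise(
    dplyr::group_by(smry[smry$category != "unclassified", ], time),
    s = sum(fraction_classified))
  expect_equal(cf$s, rep(1, nrow(cf)))

  # empty calls give an empty summary
  expect_equal(nrow(summarize_categories(calls[0, ])), 0)
})
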