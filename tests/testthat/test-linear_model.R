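test_that("cell-means fit matches hand computation", {
  # constant gene: all cell means 8, zero residual variance
  dat <- make_theta_dataset(
    tibble::tibble(gene = c("flat", "active"), theta_m = c(0, 1),
                   theta_q = c(0, 0.5), theta_a = c(0, 3)),
    sigma = 0, n_rep = 3, times = c("2h", "4h", "6h")
  )
  fit <- fit_cell_means(dat$expression, dat$design)
  expect_equal(unname(fit$coefficients["flat", ]), rep(8, 12))
  expect_equal(fit$sigma2[["flat"]], 0)
  # 12 cells x 3 replicates: residual df = 36 - 12
  expect_equal(fit$df_residual, 24)

  # hand-set replicates: pooled within-cell variance, means = cell averages
  expr <- tibble::tibble(
    gene = "g1",
    a1 = 1, a2 = 3, a3 = 5,   # PBS: mean 3, SS 8
    b1 = 10, b2 = 12          # MPL: mean 11, SS 2
  )
  des <- tibble::tibble(
    sample_id = c("a1", "a2", "a3", "b1", "b2"),
    condition = c("PBS", "PBS", "PBS", "MPL", "MPL"),
    time = "2h", replicate = c(1L, 2L, 3L, 1L, 2L)
  )
  f2 <- fit_cell_means(expr, des)
  expect_equal(unname(f2$coefficients["g1", ]), c(3, 11))
  expect_equal(unname(f2$sigma2), (8 + 2) / (5 - 2))
  expect_equal(f2$df_residual, 3)

  # a single-replicate cell is rejected by name
  des1 <- des[-5, ]
  expect_error(fit_cell_means(expr[-6], des1), "MPL\\.2h")
})

test_that("empirical-Bayes prior: degenerate branch, shrinkage direction, limma agreement", {
  # equal residual variances in every gene -> infinite prior df, equal posteriors
  dat <- make_theta_dataset(
    tibble::tibble(gene = paste0("g", 1:30), theta_m = 0, theta_q = 0,
                   theta_a = 0),
    sigma = 0.3, n_rep = 3, seed = 4
  )
  fit <- fit_cell_means(dat$expression, dat$design)
  fit_const <- fit
  fit_const$sigma2 <- rep(0.25, 30) |> setNames(fit$genes)
  pr_const <- estimate_eb_prior(fit_const)
  expect_identical(pr_const$d0, Inf)
  expect_equal(unname(pr_const$var_post), rep(pr_const$s02, 30))

  # posterior variance always lies between the gene and prior variances
  sim <- generate_dataset(simulation_config(n_genes = 500, seed = 12))
  f <- fit_cell_means(sim$expression, sim$design)
  pr <- estimate_eb_prior(f)
  lo <- pmin(f$sigma2, pr$s02)
  hi <- pmax(f$sigma2, pr$s02)
  expect_true(all(pr$var_post >= lo - 1e-12 & pr$var_post <= hi + 1e-12))

  # independent implementation: limma's squeezeVar on the same variances
  skip_if_not_installed("limma")
  sq <- limma::squeezeVar(f$sigma2, f$df_residual)
  expect_equal(pr$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(pr$s02, sq$var.prior, tolerance = 1e-6)
  expect_equal(unname(pr$var_post), unname(sq$var.post), tolerance = 1e-10)

  # all-zero residual variance is degenerate data
  fit0 <- fit
  fit0$sigma2 <- rep(0, 30) |> setNames(fit$genes)
  expect_error(estimate_eb_prior(fit0), "positive residual variance")
})

test_that("moderated contrast tests behave like t-tests in the right limits", {
  set.seed(1)
  dat <- make_theta_dataset(
    tibble::tibble(gene = paste0("g", 1:40),
                   theta_m = rnorm(40), theta_q = rnorm(40),
                   theta_a = rnorm(40)),
    sigma = 0.4, n_rep = 4, seed = 7
  )
  fit <- fit_cell_means(dat$expression, dat$design)

  # d0 -> 0: moderated p equals the classical pooled two-sample t-test p
  # (two-cell design so the pooled variance is identical)
  two <- list(
    expression = dat$expression[c("gene", grep("^(PBS|AS01)",
                                               names(dat$expression),
                                               value = TRUE))],
    design = dat$design[dat$design$condition %in% c("PBS", "AS01"), ]
  )
  fit2 <- fit_cell_means(two$expression, two$design)
  pr0 <- eb_prior(fit2, d0 = 1e-6, s02 = mean(fit2$sigma2))
  res <- test_contrast(fit2, pr0,
                       contrast_weights(fit2, c(PBS = -1, AS01 = 1), "2h"))
  m <- as.matrix(two$expression[-1])
  pbs_cols <- grep("^PBS", colnames(m))
  for (i in c(1, 17, 40)) {
    tt <- t.test(m[i, -pbs_cols], m[i, pbs_cols], var.equal = TRUE)
    expect_equal(res$p[[i]], tt$p.value, tolerance = 1e-6)
    expect_equal(res$t[[i]], unname(tt$statistic), tolerance = 1e-6)
  }

  # zero estimate -> t = 0, p = 1
  prior <- estimate_eb_prior(fit)
  wz <- contrast_weights(fit, c(PBS = -1, MPL = 1), "2h")
  fitz <- fit
  fitz$coefficients[, ] <- 5
  resz <- test_contrast(fitz, prior, wz)
  expect_equal(resz$t, rep(0, 40))
  expect_equal(resz$p, rep(1, 40))

  # negating the weights flips t, leaves p untouched
  w <- contrast_weights(fit, c(PBS = -1, AS01 = 1), "2h")
  a <- test_contrast(fit, prior, w)
  b <- test_contrast(fit, prior, -w)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)

  # infinite prior df uses the normal reference
  pri <- eb_prior(fit, d0 = Inf, s02 = 0.1)
  ri <- test_contrast(fit, pri, w)
  expect_equal(ri$p, 2 * pnorm(-abs(ri$t)))
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  p4 <- c(0.01, 0.02, 0.04, 0.05)
  expect_equal(adjust_bh(p4), brute_force_bh(p4))
  set.seed(11)
  for (n in c(10, 257, 5000)) {
    p <- runif(n)^1.5
    expect_equal(adjust_bh(p), brute_force_bh(p))
  }
  # monotone in ranks
  p <- runif(100)
  adj <- adjust_bh(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("DEG calling applies both cutoffs to the AS01 - PBS contrast", {
  # identical conditions -> no DEGs
  dat0 <- make_theta_dataset(
    tibble::tibble(gene = paste0("g", 1:50), theta_m = 0, theta_q = 0,
                   theta_a = 0),
    sigma = 0.2, n_rep = 3, seed = 5
  )
  fp <- fit_with_prior(dat0)
  dg0 <- call_degs(fp$fit, fp$prior, "2h")
  expect_equal(sum(dg0$is_deg), 0)

  # planted: exactly the 10 genes with theta_A = 4 at negligible noise
  theta <- tibble::tibble(gene = sprintf("g%03d", 1:100), theta_m = 0,
                          theta_q = 0, theta_a = rep(c(4, 0), c(10, 90)))
  dat <- make_theta_dataset(theta, sigma = 1e-3, n_rep = 3, seed = 6)
  fp <- fit_with_prior(dat)
  dg <- call_degs(fp$fit, fp$prior, "2h")
  expect_identical(dg$gene[dg$is_deg], theta$gene[1:10])

  # a tiny but certain fold change is still not a DEG
  theta2 <- tibble::tibble(gene = sprintf("g%03d", 1:50), theta_m = 0,
                           theta_q = 0, theta_a = rep(c(0.9, 0), c(10, 40)))
  dat2 <- make_theta_dataset(theta2, sigma = 1e-3, n_rep = 3, seed = 8)
  fp2 <- fit_with_prior(dat2)
  dg2 <- call_degs(fp2$fit, fp2$prior, "2h")
  expect_lt(min(dg2$adj_p[1:10]), 1e-9)
  expect_equal(sum(dg2$is_deg), 0)
})
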