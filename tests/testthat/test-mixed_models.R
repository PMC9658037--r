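test_that("design matrices have incidence structure and drop missing plots", {
  fx <- toy_table(c(10, 12, 11, 13), g = 2, r = 2)
  d <- build_design(fx$table, "yield")
  expect_equal(dim(d$X), c(4L, 2L))
  expect_equal(dim(d$Z), c(4L, 2L))
  expect_true(all(rowSums(d$Z) == 1))
  expect_true(all(d$X[, 1] == 1))

  thin <- fx$table[-2L, ]
  class(thin) <- class(fx$table)
  d2 <- build_design(thin, "yield")
  expect_equal(length(d2$y), 3L)
  expect_equal(dim(d2$Z), c(3L, 2L))
  expect_error(build_design(fx$table, "nope"), "not found")

  sim <- simulate_trial(sim_config(seed = 1L))
  d3 <- build_design(sim$phenotypes, sim$traits$name[1])
  expect_equal(length(d3$y), 108L)
})

test_that("henderson solve matches an independently assembled dense MME", {
  set.seed(21)
  g <- 5; r <- 2; n <- g * r
  fx <- toy_table(rnorm(n, 50, 5), g = g, r = r)
  d <- build_design(fx$table, "yield")
  s2a <- 4; s2e <- 2
  sol <- henderson_solve(d, s2a, s2e)
  # independent assembly of the full system
  W <- cbind(d$X, d$Z)
  C <- crossprod(W) + diag(c(rep(0, ncol(d$X)), rep(s2e / s2a, g)))
  ref <- solve(C, crossprod(W, d$y))
  expect_equal(unname(c(sol$b_hat, sol$u_hat)), as.vector(ref),
               tolerance = 1e-10)
})

test_that("BLUPs hit the least-squares-means limit and closed-form shrinkage", {
  set.seed(22)
  g <- 6; r <- 3
  fx <- toy_table(rnorm(g * r, 40, 6), g = g, r = r)
  d <- build_design(fx$table, "yield")

  # no-shrinkage limit: ratio lambda -> 0
  sol <- henderson_solve(d, sigma2_a = 1, sigma2_e = 1e-12)
  gm <- tapply(d$y, rep(seq_len(g), times = r), mean)
  mu <- mean(d$X %*% sol$b_hat)
  expect_equal(unname(sol$u_hat + mu), as.vector(gm), tolerance = 1e-6)

  # balanced, 1 rep, sigma2_a = sigma2_e: u = deviation * r/(r+lambda) = dev/2
  y1 <- rnorm(g, 30, 4)
  d1 <- oneway_design(y1, g, 1)
  sol1 <- henderson_solve(d1, 1, 1)
  dev <- y1 - mean(y1)
  expect_equal(unname(sol1$u_hat), dev / 2, tolerance = 1e-10)

  # shrinkage never exceeds the raw deviation
  sol2 <- henderson_solve(d, 2, 3)
  mu2 <- mean(d$X %*% sol2$b_hat)
  raw_dev <- gm - mean(d$y)
  expect_true(all(abs(sol2$u_hat) <= abs(raw_dev) + 1e-10))

  # sigma2_a = 0: infinite shrinkage, u = 0
  sol0 <- henderson_solve(d, 0, 1)
  expect_equal(unname(sol0$u_hat), rep(0, g))
})

test_that("EM-REML matches the balanced one-way ANOVA closed form", {
  set.seed(23)
  g <- 12; r <- 3
  for (i in 1:5) {
    u <- rnorm(g, 0, 3)
    y <- 50 + rep(u, times = r) + rnorm(g * r, 0, 2)
    an <- anova_components(y, g, r)
    if (an$sigma2_a <= 0) next
    d <- oneway_design(y, g, r)
    vc <- em_reml(d, tol = 1e-12, max_iter = 10000L)
    expect_true(vc$converged)
    expect_equal(vc$sigma2_e, an$sigma2_e, tolerance = 1e-6)
    expect_equal(vc$sigma2_a, an$sigma2_a, tolerance = 1e-6)
  }
})

test_that("EM-REML shrinks to the boundary when genotypes are identical", {
  # the ratio sigma2_a / sigma2_e has sampling noise even at the exact
  # REML optimum, so assert on the median over instances
  set.seed(24)
  g <- 200; r <- 3
  ratios <- vapply(1:5, function(i) {
    y <- 20 + rnorm(g * r, 0, 2)   # zero genotypic variance
    d <- oneway_design(y, g, r)
    vc <- em_reml(d, tol = 1e-10, max_iter = 500L)
    vc$sigma2_a / vc$sigma2_e
  }, numeric(1))
  expect_lt(median(ratios), 0.05)
})

test_that("restricted log-likelihood is non-decreasing along EM iterates", {
  set.seed(25)
  for (i in 1:10) {
    g <- sample(5:8, 1); r <- sample(2:3, 1)
    fx <- toy_table(rnorm(g * r, 30, 5) +
                      rep(rnorm(g, 0, 3), times = r), g = g, r = r)
    d <- build_design(fx$table, "yield")
    vc <- em_reml(d, tol = 1e-10, max_iter = 50L, keep_history = TRUE)
    ll <- apply(vc$history, 1, function(s) reml_loglik(d, s[1], s[2]))
    expect_true(all(diff(ll) > -1e-6))
  }
})

test_that("REML components are invariant to a constant shift", {
  set.seed(26)
  g <- 8; r <- 3
  vals <- rnorm(g * r, 60, 4) + rep(rnorm(g, 0, 2), times = r)
  fx <- toy_table(vals, g = g, r = r)
  d <- build_design(fx$table, "yield")
  fx2 <- toy_table(vals + 1000, g = g, r = r)
  d2 <- build_design(fx2$table, "yield")
  v1 <- em_reml(d, tol = 1e-10, max_iter = 5000L)
  v2 <- em_reml(d2, tol = 1e-10, max_iter = 5000L)
  expect_equal(v1$sigma2_a, v2$sigma2_a, tolerance = 1e-6)
  expect_equal(v1$sigma2_e, v2$sigma2_e, tolerance = 1e-6)
})

test_that("variance components agree with lme4 on an unbalanced instance", {
  skip_if_not_installed("lme4")
  sim <- simulate_trial(sim_config(seed = 31L))
  thin <- delete_plots(sim$phenotypes, 0.15, seed = 2L)
  tr <- sim$traits$name[5]
  d <- build_design(thin, tr)
  vc <- em_reml(d, tol = 1e-10, max_iter = 10000L)
  dat <- thin[thin$trait == tr, ]
  m <- lme4::lmer(value ~ replicate + (1 | genotype), data = dat,
                  REML = TRUE)
  vref <- as.data.frame(lme4::VarCorr(m))
  ref_a <- vref$vcov[vref$grp == "genotype"]
  ref_e <- vref$vcov[vref$grp == "Residual"]
  expect_equal(vc$sigma2_a, ref_a, tolerance = 1e-4)
  expect_equal(vc$sigma2_e, ref_e, tolerance = 1e-4)
})

test_that("heritability formula, bounds and error cases", {
  expect_equal(heritability(2, 1, 3), 6 / 7)
  expect_equal(heritability(0, 1, 3), 0)
  expect_equal(heritability(1, 0, 3), 1)
  expect_error(heritability(1, 1, 0), "positive")
  expect_error(heritability(0, 0, 3), "both")
})

test_that("fit_all_traits returns a complete genotype x trait table", {
  sim <- simulate_trial(sim_config(seed = 7L))
  fit <- fit_all_traits(sim$phenotypes, sim$traits)
  expect_equal(dim(fit$genotypic_values), c(36L, 18L))
  expect_false(anyNA(fit$genotypic_values))
  expect_true(all(fit$h2 >= 0 & fit$h2 <= 1))

  # recovery: predicted vs true genotype effects correlate strongly
  cors <- vapply(sim$traits$name, function(tr)
    stats::cor(fit$genotypic_values[, tr],
               sim$truth$genotype_effects[, tr]), numeric(1))
  expect_true(all(cors >= 0.7))
})

test_that("relabeling genotypes permutes fitted values identically", {
  sim <- simulate_trial(sim_config(n_genotypes = 10, n_traits = 4,
                                   n_factors = 2, seed = 12L))
  fit <- fit_all_traits(sim$phenotypes, sim$traits)
  perm <- setNames(sprintf("H%03d", sample(10)), sim$truth$genotypes)
  ph2 <- sim$phenotypes
  ph2$genotype <- unname(perm[ph2$genotype])
  ph2 <- as_phenotype_table(ph2, sim$traits)
  fit2 <- fit_all_traits(ph2, sim$traits)
  relabeled <- fit$genotypic_values
  rownames(relabeled) <- unname(perm[rownames(relabeled)])
  relabeled <- relabeled[order(rownames(relabeled)), ]
  expect_equal(relabeled, fit2$genotypic_values, tolerance = 1e-8)
})
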