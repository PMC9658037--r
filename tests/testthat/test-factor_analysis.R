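test_that("rescaling is direction-aware, spans [0,100], preserves shape", {
  spec <- trait_spec(c("up", "down"), c("increase", "decrease"))
  bv <- cbind(up = c(2, 6, 10), down = c(2, 6, 10))
  rownames(bv) <- c("a", "b", "c")
  r <- rescale_traits(bv, spec)
  expect_equal(unname(r$values[, "up"]), c(0, 50, 100))
  expect_equal(unname(r$values[, "down"]), c(100, 50, 0))

  # affine invariance: correlation with the original is +/-1 by sense
  set.seed(31)
  bv2 <- cbind(up = rnorm(10), down = rnorm(10))
  r2 <- rescale_traits(bv2, spec)
  expect_equal(stats::cor(bv2[, "up"], r2$values[, "up"]), 1,
               tolerance = 1e-12)
  expect_equal(stats::cor(bv2[, "down"], r2$values[, "down"]), -1,
               tolerance = 1e-12)

  # the genotype with the smallest raw value of a decrease trait gets 100
  expect_equal(unname(r2$values[which.min(bv2[, "down"]), "down"]), 100)

  expect_error(rescale_traits(cbind(up = rep(1, 5), down = 1:5), spec),
               "degenerate")
})

test_that("eigen extraction retains by the Kaiser rule with floor and cap", {
  set.seed(32)
  # independent traits: no eigenvalue clears 1 decisively, floor applies
  x <- matrix(rnorm(500 * 4), 500, 4)
  colnames(x) <- paste0("t", 1:4)
  ex <- extract_factors(x)
  expect_gte(ex$n_factors, 1L)
  expect_equal(sum(ex$eigenvalues), 4, tolerance = 1e-8)

  # spiked case: uniform loading 0.9, top eigenvalue ~ 1 + (p-1)*0.81
  lam <- matrix(0.9, 6, 1)
  sim <- simulate_trial(sim_config(n_genotypes = 500, n_replicates = 2,
                                   n_traits = 6, n_factors = 1,
                                   loading_matrix = lam, seed = 33L))
  u <- sim$truth$genotype_effects
  ex2 <- extract_factors(u)
  expect_equal(ex2$eigenvalues[1], 1 + 5 * 0.81,
               tolerance = 0.05 * (1 + 5 * 0.81))

  # initial loadings reproduce the correlation spectrum
  expect_equal(sum(ex2$loadings[, 1]^2), ex2$eigenvalues[1],
               tolerance = 1e-8)

  expect_error(extract_factors(x[, 1:2]), "at least 3")
})

test_that("varimax leaves perfect simple structure fixed and never lowers
           the criterion", {
  # block-diagonal +/- loadings are already simple structure
  L <- rbind(c(0.9, 0), c(-0.8, 0), c(0.85, 0),
             c(0, 0.9), c(0, -0.85), c(0, 0.8))
  rot <- rotate_varimax(L)
  expect_equal(abs(rot$loadings), abs(L), tolerance = 1e-6)
  # sign convention: largest |loading| per column is positive
  for (k in 1:2)
    expect_gt(rot$loadings[which.max(abs(rot$loadings[, k])), k], 0)

  set.seed(34)
  for (i in 1:20) {
    L <- random_loadings(sample(5:9, 1), 2)
    rot <- rotate_varimax(L)
    expect_gte(varimax_criterion(rot$loadings),
               varimax_criterion(L) - 1e-10)
    # rotation is orthogonal
    expect_equal(crossprod(rot$rotation), diag(2), tolerance = 1e-8)
  }
})

test_that("varimax criterion matches a brute-force angle grid", {
  set.seed(35)
  for (i in 1:5) {
    L <- random_loadings(6, 2)
    rot <- rotate_varimax(L)
    expect_equal(varimax_criterion(rot$loadings), grid_varimax(L),
                 tolerance = 1e-4)
  }
})

test_that("communalities are squared-loading row sums, rotation-invariant", {
  # published reference rows: stem number and tuber yield
  expect_equal(round(sum(c(-0.94, 0.16, -0.09, 0, 0)^2), 2), 0.92)
  expect_equal(round(sum(c(-0.03, 0.10, -0.01, -0.87, -0.12)^2), 2), 0.78)

  L <- rbind(c(0.6, 0.5), c(0.3, -0.7), c(0, 0))
  cm <- communalities(L)
  expect_equal(cm$communality, rowSums(L^2))
  expect_equal(cm$communality + cm$specificity, rep(1, 3))
  expect_equal(cm$communality[3], 0)

  set.seed(36)
  L2 <- random_loadings(8, 3)
  rot <- rotate_varimax(L2)
  expect_equal(communalities(rot$loadings)$communality,
               communalities(L2)$communality, tolerance = 1e-8)

  expect_error(communalities(matrix(2, 2, 2)), "exceeds 1")
})

test_that("factor scores center at zero and reduce to the row mean for a
           single uniform factor", {
  set.seed(37)
  sim <- simulate_trial(sim_config(seed = 38L))
  fit <- fit_all_traits(sim$phenotypes, sim$traits)
  resc <- rescale_traits(fit$genotypic_values, sim$traits)
  fm <- fit_factor_model(resc$values)
  expect_equal(unname(colMeans(fm$scores)), rep(0, fm$n_factors),
               tolerance = 1e-10)

  # single factor, equal loadings: score is a monotone function of the
  # standardized row mean
  lam <- matrix(0.9, 5, 1)
  sim1 <- simulate_trial(sim_config(n_genotypes = 200, n_replicates = 2,
                                    n_traits = 5, n_factors = 1,
                                    loading_matrix = lam,
                                    heritabilities = 0.95, seed = 39L))
  u <- sim1$truth$genotype_effects
  spec1 <- sim1$traits
  r1 <- rescale_traits(u, spec1)
  ex1 <- extract_factors(r1$values)
  L1 <- ex1$loadings[, 1, drop = FALSE]
  fs <- factor_scores(r1$values, ex1$correlation, L1)
  zm <- rowMeans(scale(r1$values))
  expect_gt(abs(stats::cor(fs$scores[, 1], zm)), 0.999)
})

test_that("a genotype at the per-trait optimum matches the ideotype score", {
  spec <- trait_spec(c("a", "b", "c", "d"),
                     c("increase", "increase", "decrease", "increase"))
  set.seed(40)
  bv <- matrix(rnorm(40), 10, 4, dimnames = list(sprintf("G%02d", 1:10),
                                                 spec$name))
  # make G01 the best on every trait under its sense
  bv[1, c(1, 2, 4)] <- apply(bv[, c(1, 2, 4)], 2, max) + 1
  bv[1, 3] <- min(bv[, 3]) - 1
  r <- rescale_traits(bv, spec)
  fm <- fit_factor_model(r$values)
  expect_equal(unname(fm$scores["G01", ]),
               unname(fm$ideotype_scores), tolerance = 1e-10)
})

test_that("permuting genotype rows permutes the scores identically", {
  set.seed(41)
  sim <- simulate_trial(sim_config(n_genotypes = 12, n_traits = 6,
                                   n_factors = 2, seed = 42L))
  u <- sim$truth$genotype_effects
  r <- rescale_traits(u, sim$traits)
  fm <- fit_factor_model(r$values)
  perm <- sample(nrow(u))
  r2 <- r$values[perm, ]
  ex2 <- extract_factors(r2)
  fs2 <- factor_scores(r2, ex2$correlation,
                       rotate_varimax(ex2$loadings)$loadings)
  # same rows, same scores (up to factor order/sign fixed by convention)
  expect_equal(abs(fs2$scores[rownames(fm$scores), , drop = FALSE]),
               abs(fm$scores), tolerance = 1e-8)
})
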