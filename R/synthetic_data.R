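#' Default block-structured loading matrix
#'
#' Traits are assigned to factors in contiguous blocks (sizes as equal as
#' possible) with a single primary loading per trait and zero
#' cross-loadings. With 18 traits and 5 factors the blocks are 4/4/4/3/3,
#' mirroring the grouping a replicated yam trial exhibits.
#'
#' @param n_traits number of traits.
#' @param n_factors number of common factors.
#' @param loading primary loading value (genotypic scale), default 0.9.
#' @return an `n_traits` x `n_factors` matrix.
#' @export
default_loadings <- function(n_traits, n_factors, loading = 0.9) {
  if (n_factors > n_traits) stop("more factors than traits")
  sizes <- rep(n_traits %/% n_factors, n_factors)
  extra <- n_traits %% n_factors
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  lam <- matrix(0, n_traits, n_factors)
  row <- 1L
  for (k in seq_len(n_factors)) {
    lam[row:(row + sizes[k] - 1L), k] <- loading
    row <- row + sizes[k]
  }
  lam
}

#' Simulation configuration for a replicated multi-trait trial
#'
#' Defaults emulate a 6 x 6 triple-lattice yam parental trial: 36
#' genotypes, 3 replicates, 18 traits whose genotypic covariance follows a
#' 5-factor structure. Heritability is controlled on the entry-mean basis:
#' the residual variance is derived per trait as
#' `sigma2_e = sigma2_a * (1 - h2) * r / h2`, so that
#' `sigma2_a / (sigma2_a + sigma2_e / r) = h2`.
#'
#' Primary loadings default to 0.9 on the genotypic scale with entry-mean
#' h2 = 0.85. BLUP-scale trait correlations are attenuated by h2
#' (approximately `lambda^2 * h2` within a factor block), so these values
#' place the downstream factor analysis in the regime a real clonal trial
#' with mean communality near 0.7-0.8 occupies.
#'
#' @param n_genotypes,n_replicates,n_traits,n_factors design dimensions.
#' @param loading_matrix optional traits x factors loading matrix
#'   (genotypic correlation scale); generated by [default_loadings()] if
#'   absent.
#' @param uniquenesses per-trait unique variances in (0, 1); default
#'   `1 - rowSums(loading_matrix^2)`.
#' @param heritabilities per-trait entry-mean heritability, strictly in
#'   (0, 1); recycled if scalar.
#' @param trait_means per-trait population means (positive, so percentage
#'   gains are well defined); default an even spread over 20..105.
#' @param genotypic_cv genotypic coefficient of variation: the genotypic
#'   SD of trait j is `genotypic_cv * trait_means[j]`.
#' @param block_effect_sd SD of replicate-level fixed effects, expressed in
#'   genotypic-SD units per trait (default 0.5).
#' @param incomplete_blocks if `TRUE`, add a random incomplete-block effect
#'   (blocks of `sqrt(n_genotypes)` within each replicate, SD half a
#'   genotypic SD) and record block membership; default `FALSE`, matching
#'   a model with replicate effects only.
#' @param seed integer seed; all randomness flows from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genotypes = 36L, n_replicates = 3L,
                       n_traits = 18L, n_factors = 5L,
                       loading_matrix = NULL, uniquenesses = NULL,
                       heritabilities = 0.85, trait_means = NULL,
                       genotypic_cv = 0.10, block_effect_sd = 0.5,
                       incomplete_blocks = FALSE, seed = 1L) {
  if (is.null(loading_matrix))
    loading_matrix <- default_loadings(n_traits, n_factors)
  loading_matrix <- as.matrix(loading_matrix)
  if (nrow(loading_matrix) != n_traits || ncol(loading_matrix) != n_factors)
    stop("loading_matrix must be n_traits x n_factors")
  comm <- rowSums(loading_matrix^2)
  if (is.null(uniquenesses)) uniquenesses <- 1 - comm
  if (length(uniquenesses) == 1L)
    uniquenesses <- rep(uniquenesses, n_traits)
  if (any(uniquenesses <= 0))
    stop("uniquenesses must be positive; loading rows too long")
  if (any(comm + uniquenesses <= 0)) stop("degenerate trait variance")
  heritabilities <- rep_len(heritabilities, n_traits)
  if (any(heritabilities <= 0) || any(heritabilities >= 1))
    stop("heritabilities must lie strictly inside (0, 1)")
  if (is.null(trait_means))
    trait_means <- seq(20, by = 5, length.out = n_traits)
  trait_means <- rep_len(trait_means, n_traits)
  if (any(trait_means <= 0)) stop("trait means must be positive")
  structure(list(
    n_genotypes = as.integer(n_genotypes),
    n_replicates = as.integer(n_replicates),
    n_traits = as.integer(n_traits),
    n_factors = as.integer(n_factors),
    loading_matrix = loading_matrix,
    uniquenesses = uniquenesses,
    heritabilities = heritabilities,
    trait_means = trait_means,
    genotypic_cv = genotypic_cv,
    block_effect_sd = block_effect_sd,
    incomplete_blocks = isTRUE(incomplete_blocks),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Factor-model covariance matrix
#'
#' `Lambda %*% t(Lambda) + diag(psi)`; must be symmetric positive
#' definite.
#'
#' @param loadings traits x factors loading matrix.
#' @param uniquenesses per-trait positive unique variances.
#' @return traits x traits covariance matrix.
#' @export
factor_covariance <- function(loadings, uniquenesses) {
  loadings <- as.matrix(loadings)
  if (length(uniquenesses) != nrow(loadings))
    stop("uniquenesses length must match loading rows")
  if (any(uniquenesses <= 0)) stop("uniquenesses must be positive")
  s <- tcrossprod(loadings) + diag(uniquenesses, nrow(loadings))
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("factor covariance is not positive definite")
  s
}

#' Simulate a replicated multi-trait trial
#'
#' Genotype effects follow the factor model `U0 = F Lambda' + E` with `F`
#' standard normal and `E` diagonal-uniqueness noise; each column is then
#' standardized and scaled so trait j has genotypic variance
#' `sigma2_a(j) = (genotypic_cv * mean_j)^2`. Phenotypes are
#' `y = mean_j + block_r + u_ij + e_ijr` with residual variance chosen so
#' the entry-mean heritability equals the configured `h2_j` (see
#' [sim_config()]).
#'
#' @param config a [sim_config()].
#' @return a list with `phenotypes` (a `phenotype_table`), `truth` (list:
#'   `genotype_effects` g x p matrix, `sigma2_a`, `sigma2_e`, `h2`,
#'   `loadings`, `block_effects` r x p matrix, `trait_means`,
#'   `trait_names`, `genotypes`) and `traits` (a [trait_spec()]).
#' @export
simulate_trial <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$n_genotypes; r <- config$n_replicates
  p <- config$n_traits; k <- config$n_factors
  set.seed(config$seed)

  traits <- if (p == 18L) yam_trait_specs() else
    trait_spec(sprintf("trait%02d", seq_len(p)),
               rep("increase", p), rep("", p))

  sigma_a <- config$genotypic_cv * config$trait_means
  sigma2_a <- sigma_a^2
  h2 <- config$heritabilities
  sigma2_e <- sigma2_a * (1 - h2) * r / h2

  fac <- matrix(stats::rnorm(g * k), g, k)
  uni <- matrix(stats::rnorm(g * p), g, p) %*%
    diag(sqrt(config$uniquenesses), p)
  u0 <- fac %*% t(config$loading_matrix) + uni
  # scale columns to the target genotypic variance (theoretical scaling,
  # so the empirical variance converges to sigma2_a as g grows)
  theo_sd <- sqrt(rowSums(config$loading_matrix^2) + config$uniquenesses)
  u <- sweep(u0, 2L, theo_sd, "/") %*% diag(sigma_a, p)

  block_eff <- matrix(stats::rnorm(r * p), r, p) %*%
    diag(config$block_effect_sd * sigma_a, p)

  geno <- sprintf("G%03d", seq_len(g))
  reps <- sprintf("R%d", seq_len(r))
  tnames <- traits$name

  ib_side <- if (config$incomplete_blocks) as.integer(round(sqrt(g))) else NA
  rows <- vector("list", r)
  for (j in seq_len(r)) {
    if (config$incomplete_blocks) {
      perm <- sample.int(g)
      ib <- integer(g)
      ib[perm] <- rep(seq_len(ceiling(g / ib_side)), each = ib_side,
                      length.out = g)
      ib_eff <- matrix(stats::rnorm(max(ib) * p), max(ib), p) %*%
        diag(0.5 * sigma_a, p)
      block_lab <- sprintf("%s-B%d", reps[j], ib)
      extra <- ib_eff[ib, , drop = FALSE]
    } else {
      block_lab <- rep(reps[j], g)
      extra <- matrix(0, g, p)
    }
    res <- matrix(stats::rnorm(g * p), g, p) %*% diag(sqrt(sigma2_e), p)
    y <- matrix(config$trait_means, g, p, byrow = TRUE) +
      matrix(block_eff[j, ], g, p, byrow = TRUE) + u + extra + res
    rows[[j]] <- data.frame(
      genotype = rep(geno, p),
      replicate = reps[j],
      block = rep(block_lab, p),
      trait = rep(tnames, each = g),
      value = as.vector(y),
      stringsAsFactors = FALSE
    )
  }
  ph <- do.call(rbind, rows)
  ph <- as_phenotype_table(ph, traits)

  dimnames(u) <- list(geno, tnames)
  dimnames(block_eff) <- list(reps, tnames)
  truth <- list(genotype_effects = u, sigma2_a = stats::setNames(sigma2_a, tnames),
                sigma2_e = stats::setNames(sigma2_e, tnames),
                h2 = stats::setNames(h2, tnames),
                loadings = config$loading_matrix,
                block_effects = block_eff,
                trait_means = stats::setNames(config$trait_means, tnames),
                trait_names = tnames, genotypes = geno)
  list(phenotypes = ph, truth = truth, traits = traits)
}

#' Delete plots at random to create unbalanced data
#'
#' Removes a stated fraction of (genotype, replicate) plots — all traits
#' of the plot — to exercise the unbalanced mixed-model solve.
#'
#' @param table a phenotype table.
#' @param fraction fraction of plots to delete, in \[0, 1).
#' @param seed integer seed.
#' @return the thinned phenotype table.
#' @export
delete_plots <- function(table, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction < 1)
  set.seed(seed)
  plots <- unique(table[, c("genotype", "replicate")])
  n_drop <- floor(fraction * nrow(plots))
  if (n_drop == 0L) return(table)
  drop <- plots[sample.int(nrow(plots), n_drop), , drop = FALSE]
  key <- paste(table$genotype, table$replicate)
  keep <- !key %in% paste(drop$genotype, drop$replicate)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(table)
  out
}

#' Tucker congruence between two loading matrices
#'
#' Column-wise congruence coefficients
#' `phi(x, y) = sum(xy) / sqrt(sum(x^2) sum(y^2))` after greedy column
#' matching (highest |phi| first) and sign alignment, so rotation-induced
#' column permutations and reflections do not penalize the comparison.
#'
#' @param a,b traits x factors matrices with equal dimensions (e.g. true
#'   vs estimated rotated loadings).
#' @return list with `per_factor` (matched |phi| per column of `a`) and
#'   `mean` (their average).
#' @export
tucker_congruence <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("loading matrices must match in shape")
  k <- ncol(a)
  phi <- crossprod(a, b) /
    sqrt(outer(colSums(a^2), colSums(b^2)))
  per <- numeric(k)
  rows <- seq_len(k); cols <- seq_len(k)
  m <- abs(phi)
  for (i in seq_len(k)) {
    idx <- which(m == max(m[rows, cols, drop = FALSE])[1] &
                   row(m) %in% rows & col(m) %in% cols, arr.ind = TRUE)
    r <- idx[1, 1]; cc <- idx[1, 2]
    per[r] <- m[r, cc]
    rows <- setdiff(rows, r); cols <- setdiff(cols, cc)
    if (length(rows))
      m[r, ] <- -Inf
    if (length(cols))
      m[, cc] <- -Inf
  }
  list(per_factor = per, mean = mean(per))
}
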