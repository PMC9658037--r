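#' Direction-aware 0-100 rescaling of genotypic values
#'
#' Maps each trait column affinely onto \[0, 100\] so that larger is
#' always better: for `sense = "increase"` the column maximum maps to 100;
#' for `sense = "decrease"` the column minimum maps to 100 (reversal).
#' Rescaling preserves each column's correlation structure up to sign.
#'
#' @param bv genotypes x traits numeric matrix of genotypic values
#'   (column names must match trait names).
#' @param traits [trait_spec()] table giving each trait's sense.
#' @return list with `values` (rescaled matrix, columns in TraitSpec
#'   order) and `senses` (named character vector of directions applied).
#' @export
rescale_traits <- function(bv, traits) {
  bv <- as.matrix(bv)
  keep <- intersect(traits$name, colnames(bv))
  if (!length(keep)) stop("no trait columns match the trait specification")
  out <- matrix(NA_real_, nrow(bv), length(keep),
                dimnames = list(rownames(bv), keep))
  senses <- stats::setNames(traits$sense[match(keep, traits$name)], keep)
  for (tr in keep) {
    x <- bv[, tr]
    rng <- range(x)
    if (rng[1] == rng[2])
      stop("degenerate trait (constant column): ", tr)
    out[, tr] <- if (senses[tr] == "increase")
      100 * (x - rng[1]) / (rng[2] - rng[1])
    else
      100 * (rng[2] - x) / (rng[2] - rng[1])
  }
  list(values = out, senses = senses)
}

#' Eigen extraction with Kaiser retention
#'
#' Eigen-decomposes the trait correlation matrix of the rescaled values;
#' retains factors with eigenvalue strictly greater than 1 (Kaiser), with
#' a floor of one retained factor and a cap of `n_genotypes - 1`. Initial
#' loading column k is `eigenvector_k * sqrt(eigenvalue_k)`.
#'
#' @param resc genotypes x traits rescaled matrix (the `values` element of
#'   [rescale_traits()]).
#' @return list with `correlation`, `eigenvalues` (descending),
#'   `n_factors`, `loadings` (initial, traits x n_factors).
#' @export
extract_factors <- function(resc) {
  resc <- as.matrix(resc)
  p <- ncol(resc); g <- nrow(resc)
  if (p < 3L) stop("factor analysis needs at least 3 traits")
  if (g < p + 1L)
    warning("fewer genotypes than traits + 1; correlation matrix is ",
            "singular or near-singular")
  sds <- apply(resc, 2L, stats::sd)
  if (any(sds == 0))
    stop("degenerate trait (zero variance): ",
         paste(colnames(resc)[sds == 0], collapse = ", "))
  R <- stats::cor(resc)
  ed <- eigen(R, symmetric = TRUE)
  ev <- ed$values
  nf <- sum(ev > 1)
  nf <- max(1L, min(nf, g - 1L))
  L <- ed$vectors[, seq_len(nf), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(nf)]), nf)
  dimnames(L) <- list(colnames(resc), paste0("F", seq_len(nf)))
  list(correlation = R, eigenvalues = ev, n_factors = nf, loadings = L)
}

#' Varimax criterion of a loading matrix
#'
#' The raw varimax objective evaluated on Kaiser-normalized loadings
#' (rows divided by the square root of their communality):
#' `sum_k [ sum_j b_jk^4 - (sum_j b_jk^2)^2 / p ]`.
#'
#' @param loadings traits x factors matrix.
#' @param normalize apply Kaiser row-normalization first (default `TRUE`).
#' @return scalar criterion value.
#' @export
varimax_criterion <- function(loadings, normalize = TRUE) {
  B <- as.matrix(loadings)
  if (normalize) {
    h <- sqrt(rowSums(B^2))
    h[h == 0] <- 1
    B <- B / h
  }
  p <- nrow(B)
  sum(colSums(B^4) - colSums(B^2)^2 / p)
}

#' Varimax rotation with sign convention
#'
#' Orthogonal rotation maximizing the Kaiser-normalized varimax criterion
#' (via [stats::varimax()] with a tight tolerance). A single factor is
#' returned unrotated. Each column's sign is fixed so its
#' largest-magnitude loading is positive — cosmetic only; distances and
#' probabilities downstream are unaffected.
#'
#' @param loadings initial traits x factors loading matrix.
#' @return list with `loadings` (rotated) and `rotation` (the orthogonal
#'   matrix applied, including sign flips).
#' @export
rotate_varimax <- function(loadings) {
  L <- as.matrix(loadings)
  nf <- ncol(L)
  if (nf == 1L) {
    rot <- diag(1)
  } else {
    vm <- stats::varimax(L, normalize = TRUE, eps = 1e-10)
    L <- L %*% vm$rotmat
    rot <- vm$rotmat
  }
  flip <- vapply(seq_len(ncol(L)), function(k) {
    j <- which.max(abs(L[, k]))
    if (L[j, k] < 0) -1 else 1
  }, numeric(1))
  L <- sweep(L, 2L, flip, "*")
  rot <- sweep(rot, 2L, flip, "*")
  dimnames(L) <- dimnames(loadings)
  list(loadings = L, rotation = rot)
}

#' Communalities and specificities
#'
#' Communality of trait j is the row sum of its squared retained
#' loadings; specificity is its complement. Communalities are invariant
#' under orthogonal rotation.
#'
#' @param loadings traits x factors (rotated) loading matrix.
#' @return data.frame with `trait`, `communality`, `specificity`.
#' @export
communalities <- function(loadings) {
  L <- as.matrix(loadings)
  if (any(!is.finite(L))) stop("loadings must be finite")
  h2 <- rowSums(L^2)
  if (any(h2 > 1 + 1e-8))
    stop("communality exceeds 1: invalid loadings")
  data.frame(trait = rownames(L) %||% paste0("t", seq_len(nrow(L))),
             communality = h2, specificity = 1 - h2,
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Regression factor scores for genotypes and the ideotype
#'
#' Scores are `Zstd %*% solve(R) %*% A` where `Zstd` is the
#' column-standardized rescaled matrix, `R` the trait correlation matrix
#' and `A` the rotated loadings. The ideotype — the 1 x p vector of 100s,
#' the best rescaled value for every trait — is standardized with the
#' genotype columns' means and SDs and scored identically. A ridge of
#' `1e-8` on the diagonal is applied if `R` is computationally singular.
#'
#' @param resc genotypes x traits rescaled matrix.
#' @param correlation traits x traits correlation matrix.
#' @param loadings rotated traits x factors loading matrix.
#' @return list with `scores` (genotypes x factors) and `ideotype`
#'   (length-n_factors vector).
#' @export
factor_scores <- function(resc, correlation, loadings) {
  resc <- as.matrix(resc)
  mu <- colMeans(resc)
  sds <- apply(resc, 2L, stats::sd)
  if (any(sds == 0)) stop("zero-variance trait column in score input")
  Zstd <- sweep(sweep(resc, 2L, mu, "-"), 2L, sds, "/")
  z_ideo <- (100 - mu) / sds
  W <- tryCatch(solve(correlation, loadings), error = function(e) {
    message("correlation matrix singular; applying 1e-8 ridge")
    solve(correlation + diag(1e-8, nrow(correlation)), loadings)
  })
  scores <- Zstd %*% W
  dimnames(scores) <- list(rownames(resc), colnames(loadings))
  list(scores = scores,
       ideotype = stats::setNames(as.vector(z_ideo %*% W),
                                  colnames(loadings)))
}

#' Fit the full factor model of rescaled genotypic values
#'
#' Convenience wrapper: [extract_factors()] then [rotate_varimax()],
#' [communalities()] and [factor_scores()].
#'
#' @param resc rescaled matrix (the `values` of [rescale_traits()]).
#' @return list of class `factor_model` with `correlation`,
#'   `eigenvalues`, `n_factors`, `loadings` (rotated), `communality`
#'   (data.frame), `scores`, `ideotype_scores`.
#' @export
fit_factor_model <- function(resc) {
  ex <- extract_factors(resc)
  rot <- rotate_varimax(ex$loadings)
  comm <- communalities(rot$loadings)
  fs <- factor_scores(resc, ex$correlation, rot$loadings)
  structure(list(correlation = ex$correlation,
                 eigenvalues = ex$eigenvalues,
                 n_factors = ex$n_factors,
                 loadings = rot$loadings,
                 communality = comm,
                 scores = fs$scores,
                 ideotype_scores = fs$ideotype),
            class = "factor_model")
}
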