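#' Build design matrices for one trait
#'
#' Assembles `y`, the fixed-effect incidence `X` (replicate effects,
#' treatment/reference coding with an intercept) and the genotype
#' incidence `Z` for the model `y = Xb + Zu + e`. Rows are ordered by
#' (replicate, genotype); missing plots are simply dropped (unbalanced
#' solve, no imputation).
#'
#' @param table a phenotype table.
#' @param trait trait label present in the table.
#' @return list with `y`, `X`, `Z`, `genotypes` (column order of `Z`),
#'   `replicates`, and `reps_per_genotype`.
#' @export
build_design <- function(table, trait) {
  d <- table[table$trait == trait, , drop = FALSE]
  if (nrow(d) == 0L) stop("trait not found in phenotype table: ", trait)
  d <- d[order(d$replicate, d$genotype), , drop = FALSE]
  geno_levels <- sort(unique(d$genotype))
  rep_levels <- sort(unique(d$replicate))
  gf <- factor(d$genotype, levels = geno_levels)
  rf <- factor(d$replicate, levels = rep_levels)
  X <- stats::model.matrix(~rf)        # intercept + drop-first dummies
  colnames(X) <- c("(Intercept)", rep_levels[-1L])
  Z <- stats::model.matrix(~ gf - 1)
  colnames(Z) <- geno_levels
  list(y = d$value, X = X, Z = Z,
       genotypes = geno_levels, replicates = rep_levels,
       reps_per_genotype = as.vector(table(gf)))
}

#' Solve Henderson's mixed-model equations
#'
#' Solves the `R = sigma2_e I`, `G = sigma2_a I` specialization
#' \deqn{\left[\begin{array}{cc} X'X & X'Z \\ Z'X & Z'Z + \lambda I
#' \end{array}\right] \left[\begin{array}{c} b \\ u \end{array}\right] =
#' \left[\begin{array}{c} X'y \\ Z'y \end{array}\right]}
#' with \eqn{\lambda = \sigma^2_e / \sigma^2_a}. Fixed effects use
#' reference coding so the system is full rank. `sigma2_a = 0` is the
#' infinite-shrinkage limit and returns `u = 0`.
#'
#' @param d design list from [build_design()].
#' @param sigma2_a genotypic variance (>= 0).
#' @param sigma2_e residual variance (> 0).
#' @param compute_c_uu if `FALSE`, skip materializing the g x g `c_uu`
#'   block (its trace is always returned).
#' @return list with `b_hat`, `u_hat` (named by genotype), `c_uu` (the
#'   u-block of the inverse coefficient matrix, needed by EM-REML) and
#'   `trace_c_uu`.
#' @export
henderson_solve <- function(d, sigma2_a, sigma2_e, compute_c_uu = TRUE) {
  stopifnot(sigma2_e > 0, sigma2_a >= 0)
  X <- d$X; Z <- d$Z; y <- d$y
  p <- ncol(X); g <- ncol(Z)
  if (sigma2_a == 0) {
    b <- solve(crossprod(X), crossprod(X, y))
    return(list(b_hat = stats::setNames(as.vector(b), colnames(X)),
                u_hat = stats::setNames(rep(0, g), colnames(Z)),
                c_uu = matrix(0, g, g), trace_c_uu = 0))
  }
  parts <- attr(d, "mme_parts")
  if (is.null(parts)) parts <- mme_parts(d)
  lambda <- sigma2_e / sigma2_a
  # eigen-form solve of the absorbed system (Z'MZ + lambda I) u = Z'My
  # with M = I - X (X'X)^-1 X': u = Q (Q'rhs / (delta + lambda)). This
  # stays stable in the lambda -> 0 limit, where the joint MME are
  # singular (intercept vs. mean of u); (Z'MZ + lambda I)^-1 is exactly
  # the u-block of the inverse MME coefficient matrix EM-REML needs.
  qr_rhs <- crossprod(parts$Q, parts$rhs)
  u <- parts$Q %*% (qr_rhs / (parts$delta + lambda))
  b <- parts$XtXi %*% crossprod(X, y - Z %*% u)
  c_uu <- if (compute_c_uu)
    parts$Q %*% (t(parts$Q) / (parts$delta + lambda))
  list(b_hat = stats::setNames(as.vector(b), colnames(X)),
       u_hat = stats::setNames(as.vector(u), colnames(Z)),
       c_uu = c_uu,
       trace_c_uu = sum(1 / (parts$delta + lambda)))
}

# Precompute the pieces of the absorbed mixed-model equations that do
# not depend on the variance components: the eigendecomposition of
# Z'MZ and the fixed-effect projector.
mme_parts <- function(d) {
  X <- d$X; Z <- d$Z; y <- d$y
  XtXi <- solve(crossprod(X))
  XtZ <- crossprod(X, Z)
  S0 <- crossprod(Z) - crossprod(XtZ, XtXi %*% XtZ)
  ed <- eigen(S0, symmetric = TRUE)
  rhs <- crossprod(Z, y) - crossprod(XtZ, XtXi %*% crossprod(X, y))
  list(Q = ed$vectors, delta = pmax(ed$values, 0), XtXi = XtXi,
       rhs = rhs)
}

#' EM-REML variance components for the one-trait mixed model
#'
#' Expectation-maximization REML on the Henderson system: at each
#' iteration the MME are solved at the current components and updated as
#' \deqn{\sigma^2_a \leftarrow (u'u + \sigma^2_e\,\mathrm{tr}(C^{uu}))/g}
#' \deqn{\sigma^2_e \leftarrow (y'y - b'X'y - u'Z'y)/(n - \mathrm{rank}(X))}
#' where \eqn{C^{uu}} is the u-block of the inverse coefficient matrix.
#' Updates are floored at `1e-12` (boundary REML); iteration stops when
#' both components change by less than `tol` relatively.
#'
#' @param d design list from [build_design()].
#' @param tol relative convergence tolerance (default `1e-8`).
#' @param max_iter iteration cap (default 500).
#' @param init optional `c(sigma2_a, sigma2_e)` starting values.
#' @param keep_history if `TRUE`, attach the per-iteration component path.
#' @return list with `sigma2_a`, `sigma2_e`, `n_iter`, `converged`, and
#'   (optionally) `history` (matrix with one row per iteration).
#' @export
em_reml <- function(d, tol = 1e-8, max_iter = 500L, init = NULL,
                    keep_history = FALSE) {
  y <- d$y; X <- d$X; Z <- d$Z
  n <- length(y); g <- ncol(Z)
  rx <- qr(X)$rank
  if (n <= rx + 1L) stop("too few observations for REML (n <= rank(X) + 1)")
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  s2a <- if (is.null(init)) vy / 2 else init[1]
  s2e <- if (is.null(init)) vy / 2 else init[2]
  floor_v <- 1e-12
  s2a <- max(s2a, floor_v); s2e <- max(s2e, floor_v)
  yy <- sum(y^2)
  hist_m <- if (keep_history) matrix(NA_real_, max_iter, 2L,
                                     dimnames = list(NULL, c("sigma2_a", "sigma2_e")))
  attr(d, "mme_parts") <- mme_parts(d)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    sol <- henderson_solve(d, s2a, s2e, compute_c_uu = FALSE)
    u <- sol$u_hat; b <- sol$b_hat
    new_a <- (sum(u^2) + s2e * sol$trace_c_uu) / g
    new_e <- (yy - sum(b * crossprod(X, y)) - sum(u * crossprod(Z, y))) /
      (n - rx)
    if (!is.finite(new_a) || !is.finite(new_e))
      stop("non-finite EM update at iteration ", it)
    new_a <- max(new_a, floor_v); new_e <- max(new_e, floor_v)
    if (keep_history) hist_m[it, ] <- c(new_a, new_e)
    rel <- max(abs(new_a - s2a) / max(s2a, floor_v),
               abs(new_e - s2e) / max(s2e, floor_v))
    s2a <- new_a; s2e <- new_e
    if (rel < tol) { converged <- TRUE; break }
  }
  out <- list(sigma2_a = s2a, sigma2_e = s2e, n_iter = it,
              converged = converged)
  if (keep_history) out$history <- hist_m[seq_len(it), , drop = FALSE]
  out
}

#' Entry-mean broad-sense heritability
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_e / r_eff)`, clipped to \[0, 1\].
#' `r_eff` is the effective replication, taken downstream as the harmonic
#' mean of per-genotype replicate counts.
#'
#' @param sigma2_a genotypic variance (>= 0).
#' @param sigma2_e residual variance (>= 0); not both zero.
#' @param r_eff effective number of replicates (> 0).
#' @return heritability in \[0, 1\].
#' @export
heritability <- function(sigma2_a, sigma2_e, r_eff) {
  if (r_eff <= 0) stop("effective replication must be positive")
  if (sigma2_a < 0 || sigma2_e < 0) stop("variances must be non-negative")
  if (sigma2_a == 0 && sigma2_e == 0) stop("variances must not both be zero")
  min(max(sigma2_a / (sigma2_a + sigma2_e / r_eff), 0), 1)
}

#' Fit one trait's mixed model
#'
#' EM-REML variance components, Henderson BLUPs, entry-mean heritability
#' and predicted genotypic values (grand fixed-effect mean + BLUP, which
#' is invariant to the fixed-effect coding).
#'
#' @param table phenotype table.
#' @param trait trait label.
#' @inheritParams em_reml
#' @return list of class `mixed_fit`: `trait`, `components`, `b_hat`,
#'   `u_hat`, `genotypic_values`, `h2`, `r_eff`, `grand_mean`.
#' @export
fit_trait <- function(table, trait, tol = 1e-8, max_iter = 500L) {
  d <- build_design(table, trait)
  vc <- em_reml(d, tol = tol, max_iter = max_iter)
  sol <- henderson_solve(d, vc$sigma2_a, vc$sigma2_e)
  mu <- mean(d$X %*% sol$b_hat)     # average fixed-effect value
  r_eff <- 1 / mean(1 / d$reps_per_genotype)
  h2 <- heritability(vc$sigma2_a, vc$sigma2_e, r_eff)
  structure(list(trait = trait, components = vc, b_hat = sol$b_hat,
                 u_hat = sol$u_hat,
                 genotypic_values = mu + sol$u_hat,
                 h2 = h2, r_eff = r_eff, grand_mean = mu),
            class = "mixed_fit")
}

#' Fit mixed models for every trait
#'
#' @param table phenotype table.
#' @param traits [trait_spec()] table; all its traits are fitted.
#' @inheritParams em_reml
#' @return list with `genotypic_values` (genotypes x traits matrix of
#'   predicted genotypic values), `h2` (named per-trait vector) and `fits`
#'   (named list of `mixed_fit`). Traits that fail to converge are kept,
#'   flagged, and reported with a warning.
#' @export
fit_all_traits <- function(table, traits, tol = 1e-8, max_iter = 500L) {
  present <- intersect(traits$name, unique(table$trait))
  if (length(present) < length(traits$name))
    warning("traits absent from data skipped: ",
            paste(setdiff(traits$name, present), collapse = ", "))
  fits <- lapply(present, function(tr)
    fit_trait(table, tr, tol = tol, max_iter = max_iter))
  names(fits) <- present
  not_conv <- present[!vapply(fits, function(f) f$components$converged,
                              logical(1))]
  if (length(not_conv))
    warning("EM-REML did not converge for: ",
            paste(not_conv, collapse = ", "))
  genos <- sort(unique(table$genotype))
  bv <- matrix(NA_real_, length(genos), length(present),
               dimnames = list(genos, present))
  for (tr in present) bv[names(fits[[tr]]$genotypic_values), tr] <-
    fits[[tr]]$genotypic_values
  list(genotypic_values = bv,
       h2 = vapply(fits, function(f) f$h2, numeric(1)),
       fits = fits)
}
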