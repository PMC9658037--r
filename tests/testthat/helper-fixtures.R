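# Shared fixtures built in code.

# A tiny balanced phenotype table: g genotypes x r replicates, one trait,
# from explicit values (row-major by replicate).
toy_table <- function(values, g, r, trait = "yield",
                      sense = "increase") {
  stopifnot(length(values) == g * r)
  spec <- trait_spec(trait, sense)
  df <- data.frame(
    genotype = rep(sprintf("G%02d", seq_len(g)), times = r),
    replicate = rep(sprintf("R%d", seq_len(r)), each = g),
    block = rep(sprintf("R%d", seq_len(r)), each = g),
    trait = trait,
    value = values,
    stringsAsFactors = FALSE
  )
  list(table = as_phenotype_table(df, spec), spec = spec)
}

# Balanced one-way design (intercept-only fixed part), for ANOVA oracles.
oneway_design <- function(y, g, r) {
  stopifnot(length(y) == g * r)
  Z <- stats::model.matrix(~ factor(rep(seq_len(g), times = r)) - 1)
  colnames(Z) <- sprintf("G%02d", seq_len(g))
  list(y = y, X = matrix(1, g * r, 1, dimnames = list(NULL, "(Intercept)")),
       Z = Z, genotypes = colnames(Z), replicates = "R1",
       reps_per_genotype = rep(r, g))
}

# Closed-form ANOVA/REML estimates for balanced one-way data.
anova_components <- function(y, g, r) {
  grp <- rep(seq_len(g), times = r)
  means <- tapply(y, grp, mean)
  mse <- sum((y - means[grp])^2) / (g * (r - 1))
  msg <- r * sum((means - mean(y))^2) / (g - 1)
  list(sigma2_e = mse, sigma2_a = (msg - mse) / r, msg = msg, mse = mse)
}

# Restricted log-likelihood for y = Xb + Zu + e at given components
# (direct dense evaluation, independent of the EM path).
reml_loglik <- function(d, s2a, s2e) {
  n <- length(d$y)
  V <- s2a * tcrossprod(d$Z) + diag(s2e, n)
  Vi <- solve(V)
  XtViX <- crossprod(d$X, Vi %*% d$X)
  P <- Vi - Vi %*% d$X %*% solve(XtViX, crossprod(d$X, Vi))
  -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
            drop(crossprod(d$y, P %*% d$y)))
}

# Brute-force varimax over a single rotation angle (2-factor case),
# evaluating the Kaiser-normalized criterion on a fine grid.
grid_varimax <- function(loadings, step = 0.001) {
  best <- -Inf
  for (th in seq(0, pi / 2, by = step)) {
    Rm <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    v <- varimax_criterion(loadings %*% Rm)
    if (v > best) best <- v
  }
  best
}

# Random positive-definite-compatible loading matrix (rows shorter than 1).
random_loadings <- function(p, k) {
  L <- matrix(stats::runif(p * k, -1, 1), p, k)
  L / sqrt(rowSums(L^2)) * sqrt(stats::runif(p, 0.3, 0.95))
}
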