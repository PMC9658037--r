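#' Genotype-ideotype distance in factor space
#'
#' Root-mean-square difference between a genotype's factor scores and the
#' ideotype's: `d_i = sqrt(mean_k (score_ik - ideo_k)^2)`. The
#' `"euclidean"` method multiplies by `sqrt(n_factors)`; rankings and
#' spatial probabilities are identical under either convention since they
#' differ by a positive constant.
#'
#' @param scores genotypes x factors score matrix.
#' @param ideo length-n_factors ideotype score vector.
#' @param method `"rms"` (default) or `"euclidean"`.
#' @return named non-negative distance per genotype.
#' @export
ideotype_distance <- function(scores, ideo, method = c("rms", "euclidean")) {
  method <- match.arg(method)
  scores <- as.matrix(scores)
  if (ncol(scores) == 0L) stop("need at least one factor")
  if (length(ideo) != ncol(scores))
    stop("ideotype scores must match the factor dimensionality")
  diffs <- sweep(scores, 2L, ideo, "-")
  d <- sqrt(rowMeans(diffs^2))
  if (method == "euclidean") d <- d * sqrt(ncol(scores))
  d
}

#' Spatial probability of similarity to the ideotype
#'
#' Inverse-distance weights normalized to sum to one:
#' `P_i = (1/d_i) / sum_k (1/d_k)`. A genotype at distance zero
#' coincides with the ideotype and receives probability 1 (all others 0),
#' the limit convention, with a message.
#'
#' @param distances positive genotype-ideotype distances.
#' @return probabilities summing to 1, same names as `distances`.
#' @export
spatial_probability <- function(distances) {
  if (any(distances < 0)) stop("distances must be non-negative")
  zero <- distances == 0
  if (any(zero)) {
    message("genotype(s) at zero ideotype distance receive the limit ",
            "probability: ", paste(names(distances)[zero], collapse = ", "))
    p <- as.numeric(zero) / sum(zero)
    names(p) <- names(distances)
    return(p)
  }
  w <- 1 / distances
  w / sum(w)
}

#' Select the top genotypes at a given intensity
#'
#' Returns the top `ceiling(intensity * g)` genotypes by descending
#' spatial probability; ties are broken by ascending genotype label so the
#' selection is deterministic.
#'
#' @param probabilities named per-genotype probabilities.
#' @param intensity selection intensity, a fraction in (0, 1\].
#' @return ordered character vector of selected genotype labels.
#' @export
select_genotypes <- function(probabilities, intensity) {
  if (!is.numeric(intensity) || intensity <= 0 || intensity > 1)
    stop("selection intensity must lie in (0, 1]")
  g <- length(probabilities)
  n_sel <- ceiling(intensity * g)
  ord <- order(-probabilities, names(probabilities))
  names(probabilities)[ord][seq_len(n_sel)]
}

#' Per-factor strength/weakness decomposition
#'
#' The contribution of factor k to genotype i's index distance:
#' `(score_ik - ideo_k)^2 / sum_k (score_ik - ideo_k)^2`. Rows sum to 1.
#' The smaller a factor's share, the closer that genotype sits to the
#' ideotype on the traits loading on it. A genotype at zero distance gets
#' the uniform share `1/n_factors` (limit convention, with a message).
#' The equal-contribution reference `1/n_factors` is attached as attribute
#' `"reference"` (the dashed line of a radar rendering).
#'
#' @param scores genotypes x factors score matrix.
#' @param ideo ideotype score vector.
#' @return genotypes x factors matrix of proportions.
#' @export
strengths_weaknesses <- function(scores, ideo) {
  scores <- as.matrix(scores)
  if (length(ideo) != ncol(scores))
    stop("ideotype scores must match the factor dimensionality")
  sq <- sweep(scores, 2L, ideo, "-")^2
  tot <- rowSums(sq)
  out <- sq / tot
  if (any(tot == 0)) {
    message("genotype(s) at zero distance get uniform factor shares")
    out[tot == 0, ] <- 1 / ncol(scores)
  }
  attr(out, "reference") <- 1 / ncol(scores)
  out
}

#' Compute the full FAI-BLUP index
#'
#' Distances, spatial probabilities, ranking, the selected set at the
#' given intensity, and the per-factor strength/weakness shares.
#'
#' @param model a `factor_model` from [fit_factor_model()].
#' @param intensity selection intensity in (0, 1\].
#' @return list of class `fai_result`: `distances`, `probabilities`,
#'   `ranking`, `selected`, `contributions`, `reference`
#'   (`1/n_factors`), `intensity`.
#' @export
fai_index <- function(model, intensity) {
  d <- ideotype_distance(model$scores, model$ideotype_scores)
  p <- spatial_probability(d)
  ranking <- names(p)[order(-p, names(p))]
  structure(list(
    distances = d,
    probabilities = p,
    ranking = ranking,
    selected = select_genotypes(p, intensity),
    contributions = strengths_weaknesses(model$scores,
                                         model$ideotype_scores),
    reference = 1 / model$n_factors,
    intensity = intensity
  ), class = "fai_result")
}
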