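#' Predicted selection gain for one trait
#'
#' `SG% = (xs - xo) * h2 / xo * 100`: the percent selection differential
#' discounted by heritability.
#'
#' @param xs mean of the selected genotypes.
#' @param xo mean of the original population (non-zero).
#' @param h2 heritability in \[0, 1\].
#' @return percent gain.
#' @export
selection_gain <- function(xs, xo, h2) {
  if (any(xo == 0)) stop("original mean is zero: percent gain undefined")
  if (any(h2 < 0 | h2 > 1)) stop("heritability must lie in [0, 1]")
  (xs - xo) * h2 / xo * 100
}

#' Classify a gain against the desired sense
#'
#' Goal = 100 when the sign of the gain agrees with the desired direction
#' (positive for `increase`, negative for `decrease`); 0 otherwise
#' (including exactly zero gain).
#'
#' @param gain numeric gain(s), percent.
#' @param sense `"increase"` or `"decrease"` per gain.
#' @return integer vector of 100 / 0 flags.
#' @export
classify_goal <- function(gain, sense) {
  ifelse((sense == "increase" & gain > 0) |
           (sense == "decrease" & gain < 0), 100L, 0L)
}

#' Sense-grouped totals of desired gains
#'
#' Sums gains over rows with goal = 100, separately for each sense.
#'
#' @param gains data.frame with columns `sense`, `goal`, `gain_percent`.
#' @return list with `total_increase` and `total_decrease`.
#' @export
gain_totals <- function(gains) {
  keep <- gains$goal == 100
  list(
    total_increase = sum(gains$gain_percent[keep &
                                              gains$sense == "increase"]),
    total_decrease = sum(gains$gain_percent[keep &
                                              gains$sense == "decrease"])
  )
}

#' Per-trait selection-gain table
#'
#' For each trait: the mean genotypic value of the selected set (`xs`),
#' the overall mean (`xo`), the gain `(xs - xo) * h2 / xo * 100`, the
#' factor on which the trait loads highest (by absolute rotated loading),
#' the goal flag, and the sense-grouped totals. Defaults to the
#' BLUP-based genotypic-value scale; `scale = "raw"` uses raw per-genotype
#' plot means instead (then `bv` must be that matrix).
#'
#' @param bv genotypes x traits matrix of genotypic values.
#' @param selected character vector of selected genotype labels (subset of
#'   `rownames(bv)`).
#' @param h2 named per-trait heritability vector.
#' @param traits [trait_spec()] table.
#' @param loadings optional rotated loadings (traits x factors) used to
#'   attribute each trait to a factor; omitted, the factor column is `NA`.
#' @return list of class `gain_table`: `rows` (data.frame with `factor`,
#'   `trait`, `sense`, `goal`, `mean_selected`, `mean_original`, `h2`,
#'   `gain_percent`), `total_increase`, `total_decrease`.
#' @export
gains_table <- function(bv, selected, h2, traits, loadings = NULL) {
  bv <- as.matrix(bv)
  if (!length(selected)) stop("selected set must be non-empty")
  if (!all(selected %in% rownames(bv)))
    stop("selected genotypes not present in the genotypic-value table: ",
         paste(setdiff(selected, rownames(bv)), collapse = ", "))
  tnames <- intersect(traits$name, colnames(bv))
  miss_h2 <- setdiff(tnames, names(h2))
  if (length(miss_h2))
    stop("missing heritability for trait(s): ",
         paste(miss_h2, collapse = ", "))
  sense <- stats::setNames(traits$sense[match(tnames, traits$name)], tnames)
  xs <- colMeans(bv[selected, tnames, drop = FALSE])
  xo <- colMeans(bv[, tnames, drop = FALSE])
  gain <- selection_gain(xs, xo, h2[tnames])
  fac <- if (is.null(loadings)) rep(NA_character_, length(tnames)) else {
    L <- as.matrix(loadings)[tnames, , drop = FALSE]
    colnames(L)[apply(abs(L), 1L, which.max)]
  }
  rows <- data.frame(factor = fac, trait = tnames,
                     sense = unname(sense),
                     goal = classify_goal(gain, sense),
                     mean_selected = unname(xs),
                     mean_original = unname(xo),
                     h2 = unname(h2[tnames]),
                     gain_percent = unname(gain),
                     row.names = NULL, stringsAsFactors = FALSE)
  tot <- gain_totals(rows)
  structure(list(rows = rows,
                 total_increase = tot$total_increase,
                 total_decrease = tot$total_decrease),
            class = "gain_table")
}
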