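#' Published reference factor loadings
#'
#' Rotated five-factor loadings, communalities and specificities reported
#' for the 18-trait panel of a published 36-genotype white Guinea yam
#' parental trial (values as printed, 2 decimal places). Used to validate
#' the communality arithmetic and the factor-attribution rule against an
#' independent, real-data analysis.
#'
#' @return data.frame with columns `trait`, `F1`..`F5`, `communality`,
#'   `specificity`.
#' @export
reference_loadings <- function() {
  utils::read.csv(system.file("extdata", "reference_loadings.csv",
                              package = "faiselect"),
                  stringsAsFactors = FALSE)
}

#' Published reference selection gains
#'
#' Per-trait predicted selection gains, desired senses and goal flags
#' reported for the same published yam trial as
#' [reference_loadings()] (values as printed, 2 decimal places). The
#' printed totals over desired rows are 148.91 (increase) and -29.26
#' (decrease).
#'
#' @return data.frame with columns `factor`, `trait`, `sense`, `goal`,
#'   `gain_percent`.
#' @export
reference_gains <- function() {
  utils::read.csv(system.file("extdata", "reference_gains.csv",
                              package = "faiselect"),
                  stringsAsFactors = FALSE)
}
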