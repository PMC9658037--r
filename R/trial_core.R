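#' Build a trait-specification table
#'
#' A trait specification declares, for every analyzed trait, the desired
#' direction of selection (`sense`) and its measurement units. The sense
#' drives the direction-aware rescaling in [rescale_traits()] and the goal
#' classification in [gains_table()].
#'
#' @param name character vector of unique trait labels.
#' @param sense character vector, one of `"increase"` or `"decrease"` per
#'   trait: the direction in which change is desired.
#' @param units character vector of unit labels (free text, carried along,
#'   never converted).
#' @return A `data.frame` with columns `name`, `sense`, `units` and class
#'   `trait_spec`.
#' @examples
#' trait_spec(c("yield", "virus"), c("increase", "decrease"),
#'            c("t/ha", "%*days"))
#' @export
trait_spec <- function(name, sense, units = rep("", length(name))) {
  name <- as.character(name)
  sense <- as.character(sense)
  if (anyDuplicated(name))
    stop("trait names must be unique; duplicated: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  bad <- !sense %in% c("increase", "decrease")
  if (any(bad))
    stop("sense must be 'increase' or 'decrease'; got: ",
         paste(unique(sense[bad]), collapse = ", "))
  if (length(sense) != length(name) || length(units) != length(name))
    stop("name, sense and units must have equal length")
  out <- data.frame(name = name, sense = sense,
                    units = as.character(units),
                    stringsAsFactors = FALSE)
  class(out) <- c("trait_spec", "data.frame")
  out
}

#' Default 18-trait white Guinea yam specification
#'
#' The agronomic and food-quality trait panel of a replicated white Guinea
#' yam (*Dioscorea rotundata*) parental trial: maximum values are desired
#' for yield, quality and vigour traits, minimum values for yam mosaic
#' virus pressure, peel loss and the two pasting-onset traits.
#'
#' @return A [trait_spec()] table with 18 rows.
#' @export
yam_trait_specs <- function() {
  trait_spec(
    name = c("yam_mosaic_virus", "pasting_temperature", "pasting_time",
             "peel_loss", "leaf_chlorophyll", "stem_number",
             "stem_diameter", "tuber_number", "tuber_yield",
             "dry_matter", "peak_viscosity", "holding_strength",
             "breakdown_value", "final_paste_viscosity", "starch_yield",
             "flour_yield", "protein_content", "ash_content"),
    sense = c("decrease", "decrease", "decrease",
              "decrease", "increase", "increase",
              "increase", "increase", "increase",
              "increase", "increase", "increase",
              "increase", "increase", "increase",
              "increase", "increase", "increase"),
    units = c("%*days", "degC", "s",
              "%", "SPAD", "count",
              "mm", "count", "t/ha",
              "%", "cP", "cP",
              "cP", "cP", "%",
              "%", "%", "%")
  )
}

#' Read a long-format phenotype table
#'
#' Reads trial observations from a CSV with header columns
#' `genotype,replicate,block,trait,value`. Rows whose trait label is not in
#' `traits` are an error. Duplicate `(genotype, replicate, trait)` records
#' are averaged with a warning (field data commonly contain
#' re-measurements). Missing plots are simply absent; they are dropped from
#' the design matrices downstream rather than imputed.
#'
#' @param path CSV file path (UTF-8, `.` decimal separator).
#' @param traits a [trait_spec()] table; observations are validated against
#'   its trait names.
#' @return A validated phenotype `data.frame` (class `phenotype_table`)
#'   with character columns `genotype`, `replicate`, `block`, `trait` and
#'   numeric `value`.
#' @export
read_phenotypes <- function(path, traits) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("genotype", "replicate", "block", "trait", "value")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("phenotype CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  val <- suppressWarnings(as.numeric(raw$value))
  if (anyNA(val)) {
    bad <- which(is.na(val))
    stop("non-numeric value in phenotype CSV at data row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  raw$value <- val
  as_phenotype_table(raw[need], traits)
}

#' Validate a phenotype data frame
#'
#' @param df data frame with columns `genotype`, `replicate`, `block`,
#'   `trait`, `value`.
#' @param traits a [trait_spec()] table.
#' @return the validated table, duplicates averaged, class
#'   `phenotype_table`.
#' @export
as_phenotype_table <- function(df, traits) {
  stopifnot(is.data.frame(df))
  unknown <- setdiff(unique(df$trait), traits$name)
  if (length(unknown))
    stop("unknown trait label(s) in phenotype data: ",
         paste(unknown, collapse = ", "))
  if (any(!is.finite(df$value)))
    stop("phenotype values must be finite")
  key <- paste(df$genotype, df$replicate, df$trait, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate (genotype, replicate, trait) records averaged: ",
            sum(duplicated(key)), " extra row(s)")
    df <- stats::aggregate(value ~ genotype + replicate + block + trait,
                           data = df, FUN = mean)
  }
  df <- df[order(df$replicate, df$genotype, df$trait), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Write a phenotype table as CSV
#'
#' Writes the same long-format dialect [read_phenotypes()] reads.
#'
#' @param table a phenotype table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, c("genotype", "replicate",
                                            "block", "trait", "value")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert an ordinal 1-5 disease severity score to percent
#'
#' Linear map anchored at score 1 (no visible symptom) = 0% and score 5
#' (high severity) = 100%: `((score - 1) / 4) * 100`.
#'
#' @param score integer-valued score(s) in 1..5.
#' @return percent severity in \[0, 100\].
#' @export
severity_to_percent <- function(score) {
  if (any(!is.finite(score)) || any(score < 1 | score > 5) ||
      any(score != round(score)))
    stop("severity score must be an integer in 1..5")
  (score - 1) / 4 * 100
}

#' Area under the disease progress curve (AUDPC)
#'
#' Trapezoidal integral of percent severity over assessment days:
#' `sum_i ((y_i + y_{i+1}) / 2) * (t_{i+1} - t_i)`.
#'
#' @param severities percent severities `y_i` in \[0, 100\].
#' @param times strictly increasing assessment times (days after
#'   planting), same length as `severities`.
#' @return area in percent-days (non-negative).
#' @export
audpc <- function(severities, times) {
  n <- length(times)
  if (n < 2L || length(severities) != n)
    stop("need at least 2 (time, severity) points of equal length")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (any(!is.finite(severities)) || any(severities < 0 | severities > 100))
    stop("severities must be finite percentages in [0, 100]")
  sum((severities[-n] + severities[-1L]) / 2 * diff(times))
}

#' Starch content from evaporating-dish masses
#'
#' `100 * (w3 - w1) / (w2 - w1)`: the dry-starch mass as a percentage of
#' the wet-starch mass.
#'
#' @param w1 mass of the evaporating dish (g).
#' @param w2 mass of dish + wet starch (g); must exceed `w1`.
#' @param w3 mass of dish + dried starch (g); in `[w1, w2]`.
#' @return starch content, percent in \[0, 100\].
#' @export
starch_content <- function(w1, w2, w3) {
  if (any(w2 <= w1)) stop("wet starch mass must be positive (w2 > w1)")
  if (any(w3 < w1) || any(w3 > w2))
    stop("dried mass must satisfy w1 <= w3 <= w2")
  100 * (w3 - w1) / (w2 - w1)
}

#' Flour yield from fresh-tuber and dried-flour masses
#'
#' `100 * wdf / wftbr`.
#'
#' @param wdf dried flour mass (kg), non-negative.
#' @param wftbr fresh tuber mass (kg), positive.
#' @return flour yield, percent.
#' @export
flour_yield <- function(wdf, wftbr) {
  if (any(wftbr <= 0)) stop("fresh tuber mass must be positive")
  if (any(wdf < 0)) stop("dried flour mass must be non-negative")
  100 * wdf / wftbr
}
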