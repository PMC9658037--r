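#' PCA summary of a genotypic-value table
#'
#' Principal components of the column-standardized genotypic values:
#' eigenvalues, variance explained, cumulative variance, Kaiser-retained
#' component count, and genotype scores. A light companion to the factor
#' analysis, useful for screening the dimensionality of the trait panel.
#'
#' @param bv genotypes x traits numeric matrix.
#' @return list with `eigenvalues`, `variance_explained`,
#'   `cumulative_variance`, `n_kaiser`, `scores`.
#' @export
pca_summary <- function(bv) {
  bv <- as.matrix(bv)
  if (ncol(bv) < 3L) stop("PCA summary needs at least 3 traits")
  sds <- apply(bv, 2L, stats::sd)
  if (any(sds == 0))
    stop("degenerate trait (constant column): ",
         paste(colnames(bv)[sds == 0], collapse = ", "))
  pc <- stats::prcomp(bv, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  ve <- ev / sum(ev)
  list(eigenvalues = ev,
       variance_explained = ve,
       cumulative_variance = cumsum(ve),
       n_kaiser = sum(ev > 1),
       scores = pc$x)
}

#' Pipeline configuration
#'
#' Exactly one of `sim` (a [sim_config()]) or `phenotype_csv` +
#' `trait_csv` paths must be supplied.
#'
#' @param sim optional [sim_config()] for a simulated trial.
#' @param phenotype_csv,trait_csv optional input CSV paths (long-format
#'   phenotypes; trait spec with columns `name,sense,units`).
#' @param intensity selection intensity in (0, 1\].
#' @param gain_scale `"blup"` (default) or `"raw"`: the scale on which
#'   selected/original means enter the gain formula.
#' @param tol,max_iter EM-REML controls.
#' @param out_dir optional output directory; when given, every
#'   intermediate artifact and a run manifest are written there.
#' @param seed integer seed driving any randomness.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL, phenotype_csv = NULL,
                            trait_csv = NULL, intensity = 0.2,
                            gain_scale = c("blup", "raw"),
                            tol = 1e-8, max_iter = 500L,
                            out_dir = NULL, seed = 1L) {
  gain_scale <- match.arg(gain_scale)
  has_sim <- !is.null(sim)
  has_files <- !is.null(phenotype_csv) || !is.null(trait_csv)
  if (has_sim == has_files)
    stop("supply exactly one of: a sim_config, or phenotype_csv + trait_csv")
  if (has_files && (is.null(phenotype_csv) || is.null(trait_csv)))
    stop("file input needs both phenotype_csv and trait_csv")
  if (intensity <= 0 || intensity > 1)
    stop("selection intensity must lie in (0, 1]")
  structure(list(sim = sim, phenotype_csv = phenotype_csv,
                 trait_csv = trait_csv, intensity = intensity,
                 gain_scale = gain_scale, tol = tol,
                 max_iter = as.integer(max_iter),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a trait-specification CSV
#'
#' Columns `name,sense,units`.
#'
#' @param path CSV path.
#' @return a [trait_spec()] table.
#' @export
read_trait_specs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "sense", "units")
  if (!all(need %in% names(df)))
    stop("trait CSV must have columns: ", paste(need, collapse = ", "))
  trait_spec(df$name, df$sense, df$units)
}

raw_genotype_means <- function(table, traits) {
  tnames <- intersect(traits$name, unique(table$trait))
  genos <- sort(unique(table$genotype))
  m <- matrix(NA_real_, length(genos), length(tnames),
              dimnames = list(genos, tnames))
  ag <- stats::aggregate(value ~ genotype + trait, data = table, FUN = mean)
  m[cbind(ag$genotype, ag$trait)] <- ag$value
  m
}

#' Run the full multi-trait selection pipeline
#'
#' Simulate or ingest a trial, fit per-trait mixed models, rescale the
#' genotypic values, fit the factor model, compute the FAI-BLUP index and
#' selection at the configured intensity, build the gains table and a PCA
#' summary. When `out_dir` is set, every intermediate table is written
#' (CSV/JSON) together with a manifest of options and file checksums.
#'
#' @param cfg a [pipeline_config()].
#' @return list of class `fai_pipeline`: `phenotypes`, `traits`, `fits`,
#'   `genotypic_values`, `h2`, `rescaled`, `factor_model`, `fai`,
#'   `gains`, `pca`, `truth` (simulation only), `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  set.seed(cfg$seed)
  if (!is.null(cfg$sim)) {
    sim <- simulate_trial(cfg$sim)
    table <- sim$phenotypes; traits <- sim$traits; truth <- sim$truth
  } else {
    traits <- read_trait_specs(cfg$trait_csv)
    table <- read_phenotypes(cfg$phenotype_csv, traits)
    truth <- NULL
  }
  fit <- fit_all_traits(table, traits, tol = cfg$tol,
                        max_iter = cfg$max_iter)
  bv <- fit$genotypic_values
  resc <- rescale_traits(bv, traits)
  fm <- fit_factor_model(resc$values)
  fai <- fai_index(fm, cfg$intensity)
  gain_bv <- if (cfg$gain_scale == "blup") bv
             else raw_genotype_means(table, traits)
  gains <- gains_table(gain_bv, fai$selected, fit$h2, traits,
                       loadings = fm$loadings)
  pca <- pca_summary(bv)

  manifest <- list(seed = cfg$seed, intensity = cfg$intensity,
                   gain_scale = cfg$gain_scale,
                   n_genotypes = nrow(bv), n_traits = ncol(bv),
                   n_factors = fm$n_factors,
                   n_selected = length(fai$selected),
                   converged = vapply(fit$fits, function(f)
                     f$components$converged, logical(1)))
  out <- structure(list(phenotypes = table, traits = traits,
                        fits = fit$fits, genotypic_values = bv,
                        h2 = fit$h2, rescaled = resc, factor_model = fm,
                        fai = fai, gains = gains, pca = pca,
                        truth = truth, manifest = manifest),
                   class = "fai_pipeline")
  if (!is.null(cfg$out_dir)) out$manifest <- write_reports(out, cfg$out_dir)
  out
}

#' Write pipeline artifacts and a checksum manifest
#'
#' @param res a `fai_pipeline` result.
#' @param out_dir output directory (created if needed).
#' @return the manifest list (also written as `manifest.json`), with an
#'   md5 checksum per written file.
#' @export
write_reports <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fm <- res$factor_model
  paths <- character(0)

  f <- file.path(out_dir, "phenotypes.csv")
  write_phenotypes(res$phenotypes, f); paths <- c(paths, f)

  f <- file.path(out_dir, "genotypic_values.csv")
  utils::write.csv(res$genotypic_values, f, quote = FALSE)
  paths <- c(paths, f)

  load_tab <- data.frame(trait = rownames(fm$loadings),
                         as.data.frame(unclass(fm$loadings)),
                         communality = fm$communality$communality,
                         specificity = fm$communality$specificity,
                         row.names = NULL)
  f <- file.path(out_dir, "loadings.csv")
  utils::write.csv(load_tab, f, row.names = FALSE, quote = FALSE)
  paths <- c(paths, f)

  sc <- rbind(fm$scores, ideotype = fm$ideotype_scores)
  f <- file.path(out_dir, "factor_scores.csv")
  utils::write.csv(sc, f, quote = FALSE); paths <- c(paths, f)

  rank_tab <- data.frame(genotype = res$fai$ranking,
                         distance = res$fai$distances[res$fai$ranking],
                         probability = res$fai$probabilities[res$fai$ranking],
                         selected = res$fai$ranking %in% res$fai$selected,
                         row.names = NULL)
  f <- file.path(out_dir, "ranking.csv")
  utils::write.csv(rank_tab, f, row.names = FALSE, quote = FALSE)
  paths <- c(paths, f)

  gains_tab <- rbind(
    res$gains$rows[, c("factor", "trait", "sense", "goal", "gain_percent")],
    data.frame(factor = "", trait = "Total (Increase)", sense = "", goal = NA,
               gain_percent = res$gains$total_increase),
    data.frame(factor = "", trait = "Total (Decrease)", sense = "", goal = NA,
               gain_percent = res$gains$total_decrease))
  f <- file.path(out_dir, "gains.csv")
  utils::write.csv(gains_tab, f, row.names = FALSE, quote = FALSE)
  paths <- c(paths, f)

  f <- file.path(out_dir, "fit_diagnostics.json")
  diag <- lapply(res$fits, function(x)
    list(sigma2_a = x$components$sigma2_a,
         sigma2_e = x$components$sigma2_e,
         n_iter = x$components$n_iter,
         converged = x$components$converged, h2 = x$h2))
  jsonlite::write_json(diag, f, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, f)

  manifest <- c(res$manifest[setdiff(names(res$manifest), "checksums")],
                list(checksums = as.list(tools::md5sum(paths))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
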