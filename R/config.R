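#' @keywords internal
"_PACKAGE"

## Fixed centrifugation order of the six pellet fractions (x 1000 g).
PELLET_FRACTIONS <- c("1k", "3k", "6k", "12k", "24k", "78k")

## Seven-point pool fractions: six pellets plus the final supernatant
## (the cytosol fraction).
POOL_FRACTIONS <- c(PELLET_FRACTIONS, "cytosol")

## The 12 compartment classes resolved by the SVM classifier.
SVM_CLASSES <- c(
  "nucleus", "cytosol", "mitochondria", "vacuole", "plasma membrane",
  "Golgi", "ER", "ribosome", "nuclear envelope", "proteasome",
  "lipid droplets", "peroxisomes"
)

## Closed vocabulary of reference-annotation categories: 18 localization
## categories plus "ambiguous" and "unknown".
REFERENCE_CATEGORIES <- c(
  "actin-associated", "cell wall", "COPI", "COPII", "cytosol", "ER",
  "endosomes", "ERGIC", "Golgi", "lipid droplets", "mitochondria",
  "nucleus", "nuclear envelope", "peroxisomes", "plasma membrane",
  "proteasome", "ribosome", "vacuole", "ambiguous", "unknown"
)

## Reference categories with no SVM counterpart; dropped before
## prediction/reference agreement scoring.
UNMATCHABLE_CATEGORIES <- c("actin-associated", "ambiguous", "COPI",
                            "COPII", "ERGIC", "unknown")

## Post-ER secretory pathway compartments (destinations downstream of the ER).
POST_ER_COMPARTMENTS <- c("ERGIC", "Golgi", "plasma membrane", "cell wall",
                          "vacuole", "endosomes")

#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline with its default. Defaults
#' reproduce the published analysis settings: profiles need at least three
#' consecutive quantified pellet fractions and a mean MS/MS count of two;
#' movement-reproducibility (MR) pre-filtering requires all pairwise cosine
#' correlations above 0.9; the robust outlier test uses a static data
#' proportion of 0.75 over 11 iterations; hits require M > 1.3, R > 0.8 and
#' a movement p-value < 0.05 in at least two of three replicates; cytosolic
#' pool hits require FDR < 5%, p < 0.05 (DTT) and p < 0.1 (tunicamycin) and
#' an absolute pool change above 10 percentage points in the same direction;
#' ER-shift candidates need a Pearson correlation with the average ER marker
#' profile above 0.75 under stress; SVM hyperparameters are searched over
#' C in [1, 30] and gamma in [1, 50] for 5 iterations with five-fold
#' cross-validation; confidence tiers switch at scores of 0.95, 0.8, 0.65
#' and 0.4; imputation draws from a normal distribution down-shifted by 1.8
#' SD with width 0.3 SD; the volcano analysis uses S0 = 0.1 at a 5%
#' permutation FDR.
#'
#' @param ... named overrides for individual defaults.
#' @return A named list of class \code{doms_config}.
#' @examples
#' cfg <- doms_config(m_cutoff = 2)
#' cfg$m_cutoff
#' @export
doms_config <- function(...) {
  cfg <- list(
    min_consecutive_fractions = 3L,
    min_avg_ms_count = 2,
    cosine_prefilter = 0.9,
    static_proportion = 0.75,
    outlier_iterations = 11L,
    m_cutoff = 1.3,
    r_cutoff = 0.8,
    per_replicate_p = 0.05,
    min_significant_replicates = 2L,
    pool_change_cutoff = 10,
    pool_p_dtt = 0.05,
    pool_p_tm = 0.1,
    er_correl_cutoff = 0.75,
    dual_localization_pool_cutoff = 0.30,
    svm_c_range = c(1, 30),
    svm_gamma_range = c(1, 50),
    svm_search_iterations = 5L,
    confidence_tiers = c(very_high = 0.95, high = 0.8, medium = 0.65,
                         low = 0.4),
    impute_downshift = 1.8,
    impute_width = 0.3,
    volcano_s0 = 0.1,
    volcano_fdr = 0.05,
    rng_seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots))))
      stop("all configuration overrides must be named")
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  stopifnot(cfg$min_consecutive_fractions >= 1,
            cfg$cosine_prefilter >= -1, cfg$cosine_prefilter <= 1,
            cfg$static_proportion > 0, cfg$static_proportion <= 1,
            cfg$outlier_iterations >= 1,
            cfg$m_cutoff >= 0, cfg$r_cutoff >= -1, cfg$r_cutoff <= 1,
            cfg$volcano_s0 >= 0, cfg$volcano_fdr > 0, cfg$volcano_fdr < 1)
  structure(cfg, class = "doms_config")
}

#' Read or write a configuration as YAML
#'
#' @param path file path.
#' @param cfg a \code{doms_config} object.
#' @return \code{read_config} returns a \code{doms_config};
#'   \code{write_config} returns \code{path} invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  tiers <- vals$confidence_tiers
  if (!is.null(tiers)) vals$confidence_tiers <- unlist(tiers)
  do.call(doms_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "doms_config"))
  out <- unclass(cfg)
  out$confidence_tiers <- as.list(out$confidence_tiers)
  yaml::write_yaml(out, path)
  invisible(path)
}
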