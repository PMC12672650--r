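## Synthetic fractionation simulator.
##
## Generates differential-centrifugation experiments with known ground
## truth (compartment memberships, planted relocalization events, planted
## abundance changes) so that mapping, classification, MR, pool and
## volcano stages can all be validated without deposited data.

#' Default compartment templates
#'
#' Twelve pellet-fraction abundance templates, one per SVM class, emulating
#' the partial separation of subcellular compartments across the 1k-78k x g
#' pellets: nuclei and nuclear envelopes sediment early, mitochondria and
#' peroxisomes in the mid pellets, Golgi and vacuole membranes later, and
#' ribosomes almost entirely in the 78k pellet. Each template carries a
#' \code{cytosol_leak}: the share of the compartment's protein recovered in
#' the final supernatant (close to 1 for cytosolic proteins, small for
#' membrane-bound organelles).
#'
#' @return named list of templates, each a list with \code{name},
#'   \code{pellet_profile} (6 values summing to 1) and \code{cytosol_leak}.
#'   Pairwise L1 distances between pellet profiles are at least 0.4.
#' @export
default_templates <- function() {
  tpl <- list(
    "nucleus"          = list(p = c(0.72, 0.14, 0.06, 0.04, 0.02, 0.02), leak = 0.03),
    "cytosol"          = list(p = c(0.22, 0.14, 0.12, 0.14, 0.14, 0.24), leak = 0.90),
    "mitochondria"     = list(p = c(0.08, 0.20, 0.42, 0.16, 0.08, 0.06), leak = 0.02),
    "vacuole"          = list(p = c(0.07, 0.13, 0.22, 0.30, 0.18, 0.10), leak = 0.05),
    "plasma membrane"  = list(p = c(0.36, 0.13, 0.05, 0.04, 0.23, 0.19), leak = 0.02),
    "Golgi"            = list(p = c(0.05, 0.10, 0.14, 0.18, 0.33, 0.20), leak = 0.05),
    "ER"               = list(p = c(0.14, 0.36, 0.26, 0.12, 0.07, 0.05), leak = 0.02),
    "ribosome"         = list(p = c(0.02, 0.03, 0.04, 0.07, 0.14, 0.70), leak = 0.20),
    "nuclear envelope" = list(p = c(0.42, 0.33, 0.12, 0.06, 0.04, 0.03), leak = 0.02),
    "proteasome"       = list(p = c(0.06, 0.07, 0.08, 0.11, 0.26, 0.42), leak = 0.40),
    "lipid droplets"   = list(p = c(0.12, 0.28, 0.08, 0.05, 0.12, 0.35), leak = 0.03),
    "peroxisomes"      = list(p = c(0.04, 0.07, 0.28, 0.46, 0.10, 0.05), leak = 0.03)
  )
  lapply(stats::setNames(names(tpl), names(tpl)), function(nm) {
    p <- tpl[[nm]]$p
    names(p) <- PELLET_FRACTIONS
    list(name = nm, pellet_profile = p / sum(p),
         cytosol_leak = tpl[[nm]]$leak)
  })
}

#' Simulation configuration
#'
#' @param n_proteins number of simulated protein groups.
#' @param n_relocalizers number of proteins with a planted localization
#'   shift in the treatment condition(s).
#' @param alpha_shift_sizes mixing fractions (toward a second compartment)
#'   sampled for planted relocalizers.
#' @param replicate_cv multiplicative replicate noise, as a coefficient of
#'   variation (default 10%).
#' @param detection_threshold intensity below which a measurement is
#'   censored to missing (left-censoring).
#' @param ms_count_rate Poisson rate per decade of intensity above the
#'   detection threshold for simulated MS/MS counts.
#' @param n_abundance_changers number of proteins with a planted abundance
#'   change under treatment.
#' @param abundance_log2fc_sizes magnitudes sampled (with random sign) for
#'   planted abundance changes.
#' @param reloc_from optional compartment names: relocalizers are drawn
#'   only from proteins of these compartments (default: any).
#' @param reloc_to optional compartment names: the destination compartment
#'   of each planted shift is drawn from these (default: any other).
#' @param seed integer RNG seed; the sole source of randomness.
#' @return list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_proteins = 1200L,
                              n_relocalizers = round(0.05 * n_proteins),
                              alpha_shift_sizes = c(0.5, 0.7, 0.9),
                              replicate_cv = 0.10,
                              detection_threshold = 3e5,
                              ms_count_rate = 3,
                              n_abundance_changers = round(0.1 * n_proteins),
                              abundance_log2fc_sizes = c(1, 2),
                              reloc_from = NULL, reloc_to = NULL,
                              seed = 1L) {
  stopifnot(n_proteins >= 24, n_relocalizers >= 0, replicate_cv >= 0,
            detection_threshold >= 0, ms_count_rate >= 0,
            all(alpha_shift_sizes >= 0), all(alpha_shift_sizes <= 1))
  structure(list(n_proteins = as.integer(n_proteins),
                 n_relocalizers = as.integer(n_relocalizers),
                 alpha_shift_sizes = alpha_shift_sizes,
                 replicate_cv = replicate_cv,
                 detection_threshold = detection_threshold,
                 ms_count_rate = ms_count_rate,
                 n_abundance_changers = as.integer(n_abundance_changers),
                 abundance_log2fc_sizes = abundance_log2fc_sizes,
                 reloc_from = reloc_from, reloc_to = reloc_to,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

## Default per-fraction relative BCA protein yields (sum < 1: losses).
default_yields <- function(conditions) {
  y <- c("1k" = 0.10, "3k" = 0.09, "6k" = 0.08, "12k" = 0.08,
         "24k" = 0.07, "78k" = 0.07, "cytosol" = 0.35)
  do.call(rbind, lapply(conditions, function(cc)
    data.frame(condition = cc, fraction = names(y), yield = unname(y),
               stringsAsFactors = FALSE)))
}

## Per-protein RNG stream: a fixed integer hash of (seed, index), < 2^31,
## so each protein's noise is reproducible independently of table order.
protein_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(i) * 7919) %% 2147483629)
}

lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)   # mean exactly 1
}

#' Simulate a fractionation experiment with known ground truth
#'
#' Per protein: the expected pellet distribution is a mixture
#' (1 - alpha) * template_A + alpha * template_B of two compartment
#' templates, scaled by a per-protein abundance drawn log-uniformly over
#' four decades. The cytosol-fraction signal is the compartment leak share.
#' Measured intensities emulate equal-protein-load LFQ: amount divided by
#' the fraction's relative protein yield, multiplied by log-normal noise
#' (CV = \code{replicate_cv}), then left-censored to missing below the
#' detection threshold. MS/MS counts are Poisson with rate proportional to
#' log-intensity above threshold. The first condition is the control
#' (alpha = alpha_control = 0); planted relocalizers switch to
#' alpha_treatment in every other condition, and planted abundance changers
#' scale by 2^log2fc. A full-proteome sample per map carries total
#' abundance with its own noise.
#'
#' @param cfg a \code{\link{simulation_config}}.
#' @param templates compartment templates (default
#'   \code{\link{default_templates}}).
#' @param conditions condition names; first is the control.
#' @param n_replicates replicates per condition.
#' @param treatment_templates optional template list used in the
#'   non-control conditions (same names as \code{templates}); a globally
#'   displaced template emulates a whole-organelle fractionation shift.
#' @return list of class \code{doms_simulation} with elements
#'   \code{table} (an \code{\link{experiment_table}}), \code{truth}
#'   (data.frame of planted ground truth), \code{yields} (data.frame) and
#'   \code{templates}.
#' @export
simulate_experiment <- function(cfg = simulation_config(),
                                templates = default_templates(),
                                conditions = c("control", "DTT"),
                                n_replicates = 3L,
                                treatment_templates = NULL) {
  if (is.null(treatment_templates)) treatment_templates <- templates
  stopifnot(identical(names(treatment_templates), names(templates)))
  if (cfg$n_relocalizers > 0 && length(templates) < 2)
    stop("at least 2 compartment templates needed to plant relocalizers")
  n <- cfg$n_proteins
  k <- length(templates)
  cls <- names(templates)
  ids <- sprintf("P%04d", seq_len(n))

  ## assignment-level draws from the global seed
  set.seed(cfg$seed)
  compartment <- cls[((seq_len(n) - 1L) %% k) + 1L]   # balanced classes
  abundance <- 10^stats::runif(n, 6, 10)              # 4 decades
  pool <- if (is.null(cfg$reloc_from)) seq_len(n)
          else which(compartment %in% cfg$reloc_from)
  reloc_idx <- sample(pool, min(cfg$n_relocalizers, length(pool)))
  second <- rep(NA_character_, n)
  second[reloc_idx] <- vapply(reloc_idx, function(i) {
    dest <- if (is.null(cfg$reloc_to)) cls else cfg$reloc_to
    dest <- setdiff(dest, compartment[i])
    if (!length(dest)) stop("no destination compartment available for ",
                            compartment[i])
    if (length(dest) == 1) dest else sample(dest, 1)
  }, character(1))
  alpha_treat <- numeric(n)
  alpha_treat[reloc_idx] <- sample(cfg$alpha_shift_sizes,
                                   length(reloc_idx), replace = TRUE)
  ab_idx <- sample(setdiff(seq_len(n), reloc_idx),
                   min(cfg$n_abundance_changers, n - length(reloc_idx)))
  log2fc <- numeric(n)
  log2fc[ab_idx] <- sample(c(-1, 1), length(ab_idx), replace = TRUE) *
    sample(cfg$abundance_log2fc_sizes, length(ab_idx), replace = TRUE)

  yields <- default_yields(conditions)
  yvec <- yields_vector(yields, conditions[1])
  fractions <- c(POOL_FRACTIONS, "full_proteome")
  samples <- standard_layout(conditions, n_replicates, fractions)
  nsamp <- nrow(samples)
  intensity <- matrix(NA_real_, n, nsamp)
  ms_count <- matrix(NA_real_, n, nsamp)
  s_cond <- samples$condition
  s_frac <- samples$fraction
  is_control <- s_cond == conditions[1]

  tpl_ctrl <- vapply(templates, function(t) t$pellet_profile, numeric(6))
  tpl_trt <- vapply(treatment_templates, function(t) t$pellet_profile,
                    numeric(6))
  tpl_leak <- vapply(templates, function(t) t$cytosol_leak, numeric(1))

  for (i in seq_len(n)) {
    set.seed(protein_seed(cfg$seed, i))
    a_trt <- alpha_treat[i]
    comp_b <- if (!is.na(second[i])) second[i] else compartment[i]
    la <- tpl_leak[compartment[i]]
    lb <- tpl_leak[comp_b]
    for (j in seq_len(nsamp)) {
      alpha <- if (is_control[j]) 0 else a_trt
      tpl <- if (is_control[j]) tpl_ctrl else tpl_trt
      pa <- tpl[, compartment[i]]
      pb <- tpl[, comp_b]
      abund <- abundance[i] * if (is_control[j]) 1 else 2^log2fc[i]
      leak <- (1 - alpha) * la + alpha * lb
      f <- s_frac[j]
      if (f == "full_proteome") {
        amount <- abund
        meas <- amount * lognormal_factor(1, cfg$replicate_cv)
      } else {
        if (f == "cytosol") {
          amount <- abund * leak
        } else {
          share <- (1 - alpha) * pa[f] + alpha * pb[f]
          amount <- abund * (1 - leak) * share
        }
        meas <- amount / yvec[f] * lognormal_factor(1, cfg$replicate_cv)
      }
      if (meas >= cfg$detection_threshold) {
        intensity[i, j] <- meas
        ms_count[i, j] <- stats::rpois(
          1, cfg$ms_count_rate *
            max(0, log10(meas / max(cfg$detection_threshold, 1))))
      }
    }
  }

  truth <- data.frame(protein_id = ids, compartment = compartment,
                      second_compartment = second,
                      alpha_control = 0, alpha_treatment = alpha_treat,
                      relocalizer = alpha_treat > 0,
                      abundance_log2fc = log2fc,
                      copies_per_cell = round(abundance / 100),
                      stringsAsFactors = FALSE)
  tab <- experiment_table(ids, ids, intensity, ms_count,
                          samples[, c("condition", "replicate", "fraction")])
  structure(list(table = tab, truth = truth, yields = yields,
                 templates = templates, config = cfg,
                 conditions = conditions, n_replicates = n_replicates),
            class = "doms_simulation")
}

#' @export
print.doms_simulation <- function(x, ...) {
  cat(sprintf("doms_simulation: %d proteins, %d planted relocalizers, %d abundance changers\n",
              nrow(x$truth), sum(x$truth$relocalizer),
              sum(x$truth$abundance_log2fc != 0)))
  cat("conditions:", paste(x$conditions, collapse = ", "),
      sprintf("(%d replicates)\n", x$n_replicates))
  invisible(x)
}

#' Synthetic reference annotations for a simulation
#'
#' Derives a reference-annotation table from simulated ground truth:
#' the category is the planted control compartment; transmembrane domains,
#' signal peptides and transit peptides follow compartment-typical rules
#' (secretory-pathway proteins carry a signal peptide and/or TM domains,
#' mitochondrial proteins a transit peptide); molecular weights are drawn
#' log-normally around 50 kDa.
#'
#' @param sim a \code{doms_simulation}.
#' @return annotation data.frame (synthetic; columns as
#'   \code{\link{read_annotations}}).
#' @export
synthetic_annotations <- function(sim) {
  truth <- sim$truth
  n <- nrow(truth)
  set.seed(protein_seed(sim$config$seed, n + 1L))
  secretory <- c("ER", "Golgi", "plasma membrane", "vacuole")
  n_tm <- integer(n)
  sp <- logical(n)
  tp <- logical(n)
  for (i in seq_len(n)) {
    comp <- truth$compartment[i]
    if (comp %in% secretory) {
      ## mix of lumenal/soluble (SP only) and membrane (TM) proteins
      if (stats::runif(1) < 0.3) { sp[i] <- TRUE; n_tm[i] <- 0L }
      else { n_tm[i] <- sample(1:8, 1); sp[i] <- stats::runif(1) < 0.5 }
    } else if (comp == "mitochondria") {
      tp[i] <- TRUE
      n_tm[i] <- sample(0:2, 1)
    } else if (comp %in% c("lipid droplets", "peroxisomes",
                           "nuclear envelope")) {
      n_tm[i] <- sample(0:2, 1)
    }
  }
  data.frame(protein_id = truth$protein_id, category = truth$compartment,
             n_tm_domains = n_tm, has_signal_peptide = sp,
             has_transit_peptide = tp,
             molecular_weight = round(stats::rlnorm(n, log(5e4), 0.4)),
             stringsAsFactors = FALSE)
}

#' Write a simulated experiment as a fixture directory
#'
#' Emits \code{protein_groups.tsv} (MaxQuant dialect, readable by
#' \code{\link{read_protein_groups}}), \code{truth.tsv},
#' \code{yields.tsv} and \code{annotations.tsv} (synthetic).
#'
#' @param sim a \code{doms_simulation}.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(protein_groups = file.path(dir, "protein_groups.tsv"),
             truth = file.path(dir, "truth.tsv"),
             yields = file.path(dir, "yields.tsv"),
             annotations = file.path(dir, "annotations.tsv"))
  write_protein_groups(sim$table, paths["protein_groups"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$yields, paths["yields"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(synthetic_annotations(sim), paths["annotations"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
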