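## Full-proteome statistics: left-censored imputation, volcano analysis
## with permutation FDR, cross-treatment concordance, and proteomic-ruler
## copy numbers.

#' Impute left-censored missing values
#'
#' Per column of a log-transformed intensity matrix, draws missing entries
#' from a normal distribution down-shifted relative to the observed
#' values: Normal(mean - downshift * sd, (width * sd)^2). This emulates
#' values missing because they fall below the detection limit.
#'
#' @param log2_matrix numeric matrix (proteins x samples), log scale.
#' @param downshift down-shift in observed-SD units (default 1.8).
#' @param width width of the imputation distribution in observed-SD units
#'   (default 0.3).
#' @param seed integer RNG seed.
#' @return the completed matrix; observed entries untouched.
#' @export
impute_missing <- function(log2_matrix, downshift = 1.8, width = 0.3,
                           seed = 1L) {
  x <- as.matrix(log2_matrix)
  set.seed(seed)
  for (j in seq_len(ncol(x))) {
    obs <- x[, j][!is.na(x[, j])]
    if (length(obs) < 2) stop("column ", j, " has fewer than 2 observed values")
    miss <- which(is.na(x[, j]))
    if (length(miss)) {
      m <- mean(obs); s <- stats::sd(obs)
      x[miss, j] <- stats::rnorm(length(miss), m - downshift * s, width * s)
    }
  }
  x
}

## Modified (SAM-style) t statistic: mean difference over pooled-variance
## standard error inflated by s0.
modified_t <- function(a_mat, b_mat, s0) {
  na <- ncol(a_mat); nb <- ncol(b_mat)
  ma <- rowMeans(a_mat); mb <- rowMeans(b_mat)
  va <- apply(a_mat, 1, stats::var); vb <- apply(b_mat, 1, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  (ma - mb) / (se + s0)
}

## All balanced relabelings of group-label columns for the permutation FDR
## (choose(n, na) at small n; random relabelings otherwise).
balanced_relabelings <- function(n_total, n_a, max_random = 250L, seed = 1L) {
  n_all <- choose(n_total, n_a)
  if (n_all <= max_random) {
    idx <- utils::combn(n_total, n_a, simplify = FALSE)
  } else {
    set.seed(seed)
    idx <- lapply(seq_len(max_random), function(i) sort(sample(n_total, n_a)))
  }
  idx
}

#' Volcano analysis with permutation-based FDR
#'
#' Per protein: log2 fold change (group A minus group B), two-tailed
#' pooled-variance t-test p-value, and the S0-modified t statistic
#' t' = delta-mean / (SE + s0). Significance is a threshold on |t'| chosen
#' by group-label permutation: for a candidate cut-off c, the estimated
#' FDR is the median over relabelings of the permuted exceedance count
#' divided by the observed count; the smallest c with FDR <= \code{fdr}
#' defines the hits.
#'
#' @param group_a,group_b numeric matrices (proteins x replicates),
#'   log2 scale, imputation already applied.
#' @param s0 variance-stabilizing offset (default 0.1).
#' @param fdr target false discovery rate (default 0.05).
#' @param n_permutations maximum number of random relabelings when the
#'   exhaustive set is large (default 250).
#' @param seed RNG seed for random relabelings.
#' @return object of class \code{doms_volcano}: data.frame \code{results}
#'   with \code{log2_fc}, \code{p_value}, \code{modified_t},
#'   \code{significant}, plus the |t'| cut-off and estimated FDR.
#' @export
volcano_test <- function(group_a, group_b, s0 = 0.1, fdr = 0.05,
                         n_permutations = 250L, seed = 1L) {
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  stopifnot(nrow(group_a) == nrow(group_b))
  if (ncol(group_a) != ncol(group_b))
    stop("unequal replicate counts")
  if (s0 <= 0 ) {
    va <- apply(group_a, 1, stats::var); vb <- apply(group_b, 1, stats::var)
    if (any(va + vb == 0))
      stop("zero within-group variance with s0 = 0")
  }
  na <- ncol(group_a)
  lfc <- rowMeans(group_a) - rowMeans(group_b)
  tt <- modified_t(group_a, group_b, s0)
  pp <- vapply(seq_len(nrow(group_a)), function(i)
    student_t_test(group_a[i, ], group_b[i, ])$p, numeric(1))
  joint <- cbind(group_a, group_b)
  relab <- balanced_relabelings(2 * na, na, n_permutations, seed)
  perm_t <- vapply(relab, function(ia) {
    abs(modified_t(joint[, ia, drop = FALSE],
                   joint[, -ia, drop = FALSE], s0))
  }, numeric(nrow(joint)))
  obs <- abs(tt)
  cand <- sort(unique(obs), decreasing = TRUE)
  cutoff <- Inf; est_fdr <- NA_real_
  for (c0 in cand) {
    n_obs <- sum(obs >= c0)
    n_perm <- stats::median(colSums(perm_t >= c0))
    f <- n_perm / n_obs
    if (f <= fdr) { cutoff <- c0; est_fdr <- f } else break
  }
  results <- data.frame(log2_fc = lfc, p_value = pp, modified_t = tt,
                        significant = is.finite(cutoff) & obs >= cutoff,
                        row.names = rownames(group_a))
  structure(list(results = results, cutoff = cutoff, est_fdr = est_fdr,
                 s0 = s0, fdr = fdr, n_relabelings = length(relab)),
            class = "doms_volcano")
}

#' @export
print.doms_volcano <- function(x, ...) {
  cat(sprintf("volcano analysis: %d proteins, %d significant (S0 = %g, permutation FDR <= %g%%)\n",
              nrow(x$results), sum(x$results$significant), x$s0,
              100 * x$fdr))
  if (is.finite(x$cutoff))
    cat(sprintf("  |t'| cut-off %.3f (estimated FDR %.3f, %d relabelings)\n",
                x$cutoff, x$est_fdr, x$n_relabelings))
  invisible(x)
}

#' @export
plot.doms_volcano <- function(x, ...) {
  r <- x$results
  plot(r$log2_fc, -log10(r$p_value), pch = 16, cex = 0.5,
       col = ifelse(r$significant, "firebrick", "grey40"),
       xlab = expression(log[2] ~ "fold change"),
       ylab = expression(-log[10] ~ italic(p)), ...)
  invisible(x)
}

#' Concordance of hits across two volcano analyses
#'
#' @param volcano_a,volcano_b \code{doms_volcano} objects on the same
#'   protein universe.
#' @return list with shared/unique hit ids and the fraction of shared and
#'   unique hits whose fold changes agree in sign across the two analyses.
#' @export
shared_unique_hits <- function(volcano_a, volcano_b) {
  ra <- volcano_a$results; rb <- volcano_b$results
  ids <- intersect(rownames(ra), rownames(rb))
  ha <- ids[ra[ids, "significant"]]
  hb <- ids[rb[ids, "significant"]]
  shared <- intersect(ha, hb)
  unique_a <- setdiff(ha, hb)
  unique_b <- setdiff(hb, ha)
  sign_match <- function(set) {
    if (!length(set)) return(NA_real_)
    mean(sign(ra[set, "log2_fc"]) == sign(rb[set, "log2_fc"]))
  }
  list(shared = shared, unique_a = unique_a, unique_b = unique_b,
       shared_concordance = sign_match(shared),
       unique_a_concordance = sign_match(unique_a),
       unique_b_concordance = sign_match(unique_b))
}

#' Ploidy from cellular DNA content
#'
#' @param dna_pg_per_cell DNA mass per cell in pg.
#' @param genome_pg mass of one genome in pg.
#' @return genomes per cell (report to one decimal: 0.022/0.013 gives 1.7).
#' @export
estimate_ploidy <- function(dna_pg_per_cell, genome_pg) {
  if (dna_pg_per_cell <= 0 || genome_pg <= 0)
    stop("DNA masses must be positive")
  dna_pg_per_cell / genome_pg
}

#' Genome mass from base-pair count
#'
#' Mass of a double-stranded genome: base pairs times the average molar
#' mass of one base pair (650 g/mol) over Avogadro's number, in pg.
#' 12.1 Mbp (the yeast genome) gives 0.013 pg.
#'
#' @param base_pairs number of base pairs.
#' @return genome mass in pg.
#' @export
genome_mass <- function(base_pairs) {
  stopifnot(base_pairs >= 0)
  base_pairs * 650 / 6.02214076e23 * 1e12
}

#' Interpolate intracellular protein concentration between ploidies
#'
#' Linear interpolation between the haploid (94 g/l) and diploid (79 g/l)
#' yeast protein concentrations; a ploidy of 1.7 gives 83 g/l (integer
#' report truncates 83.5).
#'
#' @param ploidy genomes per cell; values outside [1, 2] are extrapolated
#'   with a warning.
#' @param haploid_gl,diploid_gl anchor concentrations in g/l.
#' @return list with \code{value} (exact interpolated g/l) and
#'   \code{reported} (truncated integer g/l).
#' @export
interpolate_concentration <- function(ploidy, haploid_gl = 94,
                                      diploid_gl = 79) {
  if (ploidy < 1 || ploidy > 2)
    warning("ploidy outside [1, 2]; extrapolating")
  value <- haploid_gl + (ploidy - 1) * (diploid_gl - haploid_gl)
  list(value = value, reported = trunc(value))
}

#' Proteomic-ruler copy numbers
#'
#' Anchors total MS signal to cellular DNA mass via histone signal: the
#' total protein mass per cell is M = dna_pg * sum(I) / sum(I_histones)
#' (histone mass tracks DNA mass). Copies per protein are proportional to
#' intensity over molecular weight, scaled so that the summed protein mass
#' equals M. Cell volume follows from M and the total protein
#' concentration, giving molar concentrations.
#'
#' @param intensities named numeric vector of raw intensities.
#' @param molecular_weights molecular weights in g/mol (same names).
#' @param histone_ids ids of the histone anchor proteins.
#' @param dna_pg DNA mass per cell in pg (default 0.022).
#' @param conc_gl total protein concentration in g/l (default 83).
#' @return object of class \code{doms_ruler}: data.frame \code{results}
#'   (\code{copies_per_cell}, \code{concentration} in mol/l), plus
#'   \code{total_protein_pg} and \code{cell_volume_l}.
#' @export
proteomic_ruler <- function(intensities, molecular_weights, histone_ids,
                            dna_pg = 0.022, conc_gl = 83) {
  stopifnot(length(intensities) == length(molecular_weights),
            !is.null(names(intensities)))
  ok <- is.finite(intensities) & intensities > 0
  hist_i <- intensities[intersect(histone_ids, names(intensities)[ok])]
  if (!length(hist_i) || sum(hist_i) == 0)
    stop("no measured histone signal")
  total_mass_g <- dna_pg * 1e-12 * sum(intensities[ok]) / sum(hist_i)
  NA_ <- 6.02214076e23
  raw <- ifelse(ok, intensities / molecular_weights, NA_real_)
  scale <- total_mass_g * NA_ / sum(intensities[ok])
  copies <- raw * scale
  volume_l <- total_mass_g / conc_gl
  conc <- copies / (NA_ * volume_l)
  results <- data.frame(copies_per_cell = copies, concentration = conc,
                        row.names = names(intensities))
  structure(list(results = results,
                 total_protein_pg = total_mass_g * 1e12,
                 cell_volume_l = volume_l, dna_pg = dna_pg,
                 conc_gl = conc_gl),
            class = "doms_ruler")
}

#' @export
print.doms_ruler <- function(x, ...) {
  cat(sprintf("proteomic ruler: %d proteins\n", nrow(x$results)))
  cat(sprintf("  total protein %.3g pg/cell, cell volume %.3g fl (at %g g/l)\n",
              x$total_protein_pg, x$cell_volume_l * 1e15, x$conc_gl))
  invisible(x)
}
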