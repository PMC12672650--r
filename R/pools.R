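## Cytosolic-pool estimation and shift testing, organelle-level shift
## analysis, and the ER-redistribution candidate cascade with
## lumenal/post-ER annotation filters.

#' Yield-weighted 7-point pool profile
#'
#' Weights the seven fraction intensities (six pellets + cytosol) by the
#' per-fraction relative protein yields and renormalizes to sum 1. The
#' seventh entry is the protein's cytosolic pool; the first six sum to its
#' non-cytosolic pool.
#'
#' @param intensities_7 numeric vector of 7 intensities (NA = missing).
#' @param yields numeric vector of 7 relative protein yields (> 0).
#' @return normalized 7-point pool profile.
#' @export
pool_profile <- function(intensities_7, yields) {
  stopifnot(length(intensities_7) == 7, length(yields) == 7,
            all(yields > 0))
  x <- intensities_7
  x[is.na(x)] <- 0
  w <- x * yields
  s <- sum(w)
  if (s == 0) stop("undefined pool profile: all weighted intensities zero")
  stats::setNames(w / s, POOL_FRACTIONS)
}

#' Cytosolic pools for one condition
#'
#' @param table an \code{\link{experiment_table}}.
#' @param condition condition name.
#' @param yields yields data.frame (see \code{\link{read_yields}}).
#' @param replicates replicate indices (default all).
#' @return matrix proteins x replicates of cytosolic pool fractions; NA
#'   where the cytosol fraction was not quantified or no fraction was
#'   measured.
#' @export
cytosolic_pools <- function(table, condition, yields, replicates = NULL) {
  if (is.null(replicates))
    replicates <- sort(unique(table$samples$replicate[
      table$samples$condition == condition]))
  yv <- yields_vector(yields, condition)
  out <- vapply(replicates, function(r) {
    ints <- fraction_matrix(table, condition, r, POOL_FRACTIONS)
    colnames(ints) <- POOL_FRACTIONS
    cy_missing <- is.na(ints[, "cytosol"])
    ints[is.na(ints)] <- 0
    w <- sweep(ints, 2, yv, "*")
    s <- rowSums(w)
    pool <- ifelse(s > 0, w[, "cytosol"] / s, NA_real_)
    pool[cy_missing] <- NA_real_
    pool
  }, numeric(length(table$protein_id)))
  rownames(out) <- table$protein_id
  colnames(out) <- paste0("rep", replicates)
  out
}

#' Cytosolic pool shift test
#'
#' Tests, per protein, whether the cytosolic pool changes from control to
#' each of two treatments with a paired two-tailed t-test (replicate i
#' paired with replicate i), combines the two p-values with Fisher's
#' method, and adjusts across proteins with Benjamini-Hochberg. Hits must
#' satisfy: adjusted FDR < 5%; p < \code{cfg$pool_p_dtt} for the first
#' treatment and p < \code{cfg$pool_p_tm} for the second; an absolute pool
#' change above \code{cfg$pool_change_cutoff} percentage points under both
#' treatments; and the same direction of change (positive = toward the
#' cytosol). Proteins need a measured pool in all replicates of at least
#' one treatment condition to enter the test.
#'
#' @param control,treatment1,treatment2 matrices of pool fractions
#'   (proteins x replicates, as from \code{\link{cytosolic_pools}}).
#' @param cfg a \code{\link{doms_config}}.
#' @return object of class \code{doms_pool_shift}: per-protein data.frame
#'   with changes (percentage points), p-values, combined and adjusted p,
#'   and hit flag.
#' @export
pool_shift_test <- function(control, treatment1, treatment2,
                            cfg = doms_config()) {
  ids <- rownames(control)
  stopifnot(identical(ids, rownames(treatment1)),
            identical(ids, rownames(treatment2)))
  eligible <- rowSums(!is.na(treatment1)) == ncol(treatment1) |
    rowSums(!is.na(treatment2)) == ncol(treatment2)
  ids <- ids[eligible]
  res <- do.call(rbind, lapply(ids, function(id) {
    d1 <- 100 * mean(treatment1[id, ] - control[id, ], na.rm = TRUE)
    d2 <- 100 * mean(treatment2[id, ] - control[id, ], na.rm = TRUE)
    data.frame(protein_id = id,
               change_1 = d1, change_2 = d2,
               p_1 = paired_t_p(treatment1[id, ], control[id, ]),
               p_2 = paired_t_p(treatment2[id, ], control[id, ]),
               stringsAsFactors = FALSE)
  }))
  has_both <- !is.na(res$p_1) & !is.na(res$p_2)
  res$combined_p <- NA_real_
  res$combined_p[has_both] <- vapply(which(has_both), function(i)
    fisher_combine(c(res$p_1[i], res$p_2[i])), numeric(1))
  res$adjusted_p <- NA_real_
  res$adjusted_p[has_both] <- stats::p.adjust(res$combined_p[has_both],
                                              method = "BH")
  res$hit <- has_both &
    !is.na(res$adjusted_p) & res$adjusted_p < 0.05 &
    res$p_1 < cfg$pool_p_dtt & res$p_2 < cfg$pool_p_tm &
    abs(res$change_1) > cfg$pool_change_cutoff &
    abs(res$change_2) > cfg$pool_change_cutoff &
    sign(res$change_1) == sign(res$change_2)
  res$hit[is.na(res$hit)] <- FALSE
  structure(list(results = res, cfg = cfg), class = "doms_pool_shift")
}

#' @export
print.doms_pool_shift <- function(x, ...) {
  cat(sprintf("cytosolic pool shift test: %d proteins, %d hits\n",
              nrow(x$results), sum(x$results$hit)))
  invisible(x)
}

#' Organelle-level profile shift test
#'
#' For each organelle: the average normalized marker profile is computed
#' per replicate and condition. At each of the six profile datapoints a
#' two-tailed paired t-test compares conditions across replicates; the
#' smallest of the six p-values multiplied by six (capped at 1) is the
#' Q-value. The shift magnitude is the mean, over cognate replicate pairs,
#' of the L1 distance between average profiles, binned as negligible
#' (< 0.1, within typical inter-replicate scatter), small (< 0.2), medium
#' (< 0.3) or large (>= 0.3). An organelle is flagged shifted if Q < 0.05
#' and the magnitude exceeds 0.1.
#'
#' @param control_profiles,treatment_profiles lists of normalized profile
#'   matrices, one per replicate.
#' @param markers named character vector: protein id -> organelle.
#' @param cfg a \code{\link{doms_config}}.
#' @param exclude organelles left out (too few markers for a robust
#'   average; default lipid droplets and peroxisomes).
#' @param min_markers minimum markers per organelle (default 5).
#' @return object of class \code{doms_organelle_shift}: per-organelle
#'   data.frame with n_markers, Q, distance, magnitude, shifted.
#' @export
organelle_shift_test <- function(control_profiles, treatment_profiles,
                                 markers, cfg = doms_config(),
                                 exclude = c("lipid droplets",
                                             "peroxisomes"),
                                 min_markers = 5L) {
  stopifnot(length(control_profiles) == length(treatment_profiles))
  nrep <- length(control_profiles)
  ids <- Reduce(intersect, c(lapply(control_profiles, rownames),
                             lapply(treatment_profiles, rownames)))
  markers <- markers[names(markers) %in% ids & !markers %in% exclude]
  organelles <- sort(unique(markers))
  rows <- lapply(organelles, function(org) {
    mids <- names(markers)[markers == org]
    if (length(mids) < min_markers) return(NULL)
    avg_c <- t(vapply(control_profiles, function(m)
      colMeans(m[mids, , drop = FALSE]), numeric(6)))
    avg_t <- t(vapply(treatment_profiles, function(m)
      colMeans(m[mids, , drop = FALSE]), numeric(6)))
    p6 <- vapply(1:6, function(j) paired_t_p(avg_t[, j], avg_c[, j]),
                 numeric(1))
    q <- min(1, 6 * min(p6, na.rm = TRUE))
    dist <- mean(vapply(seq_len(nrep), function(r)
      sum(abs(avg_t[r, ] - avg_c[r, ])), numeric(1)))
    magnitude <- if (dist < 0.1) "negligible" else if (dist < 0.2) "small"
      else if (dist < 0.3) "medium" else "large"
    data.frame(organelle = org, n_markers = length(mids), Q = q,
               distance = dist, magnitude = magnitude,
               shifted = q < 0.05 & dist > 0.1, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  structure(list(results = res, cfg = cfg),
            class = "doms_organelle_shift")
}

#' @export
print.doms_organelle_shift <- function(x, ...) {
  cat("organelle shift test:\n")
  print(x$results, row.names = FALSE)
  invisible(x)
}

#' ER lumenal proteins
#'
#' ER-category proteins carrying a signal peptide and no transmembrane
#' domains.
#'
#' @param annotations annotation data.frame.
#' @return character vector of protein ids.
#' @export
classify_lumenal_er <- function(annotations) {
  with(annotations, protein_id[category == "ER" & has_signal_peptide &
                                 n_tm_domains == 0])
}

#' Post-ER secretory pathway proteins
#'
#' Proteins with an ER-targeting signal peptide and/or at least one
#' transmembrane domain, without a mitochondrial transit peptide, and
#' localized to a post-ER secretory compartment (ERGIC, Golgi, plasma
#' membrane, cell wall, vacuole or endosomes).
#'
#' @param annotations annotation data.frame.
#' @param localizations named character vector: protein id -> localization
#'   used for the compartment filter (e.g. reference category or SVM
#'   prediction); defaults to the annotation category.
#' @return character vector of protein ids.
#' @export
classify_post_er <- function(annotations, localizations = NULL) {
  if (is.null(localizations))
    localizations <- stats::setNames(annotations$category,
                                     annotations$protein_id)
  ids <- annotations$protein_id
  topo <- (annotations$has_signal_peptide | annotations$n_tm_domains >= 1) &
    !annotations$has_transit_peptide
  loc <- localizations[ids]
  ids[topo & !is.na(loc) & loc %in% POST_ER_COMPARTMENTS]
}

#' ER-redistribution candidates
#'
#' Screens for proteins shifting towards the ER under stress. Per protein,
#' the condition-average 6-point profile is correlated (Pearson) with the
#' average ER marker profile under control and under treatment;
#' delta-correlER is the difference. Candidates must be: a hit in the MR
#' analysis; have positive delta-correlER; correlate with the ER marker
#' average above \code{cfg$er_correl_cutoff} under treatment; and have a
#' post-ER secretory pathway localization. Proteins failing only the
#' positive-delta filter are reported as near misses.
#'
#' @param control_profiles,treatment_profiles lists of normalized profile
#'   matrices, one per replicate.
#' @param er_marker_ids protein ids of the ER markers.
#' @param mr_hits named logical vector of MR hit flags.
#' @param post_er_ids ids with post-ER secretory localization.
#' @param cfg a \code{\link{doms_config}}.
#' @return object of class \code{doms_er_shift}: per-protein data.frame
#'   with correlations, delta_correl_er, filter flags, candidate and
#'   near_miss.
#' @export
er_shift_candidates <- function(control_profiles, treatment_profiles,
                                er_marker_ids, mr_hits, post_er_ids,
                                cfg = doms_config()) {
  ids <- Reduce(intersect, c(lapply(control_profiles, rownames),
                             lapply(treatment_profiles, rownames)))
  avg <- function(profs, set) {
    m <- Reduce(`+`, lapply(profs, function(x) x[set, , drop = FALSE])) /
      length(profs)
    sweep(m, 1, rowSums(m), "/")
  }
  er_ids <- intersect(er_marker_ids, ids)
  if (!length(er_ids)) stop("no ER markers among profiled proteins")
  er_c <- colMeans(avg(control_profiles, er_ids))
  er_t <- colMeans(avg(treatment_profiles, er_ids))
  prof_c <- avg(control_profiles, ids)
  prof_t <- avg(treatment_profiles, ids)
  const <- apply(prof_c, 1, stats::sd) == 0 |
    apply(prof_t, 1, stats::sd) == 0
  cor_c <- rep(NA_real_, length(ids))
  cor_t <- rep(NA_real_, length(ids))
  cor_c[!const] <- as.vector(stats::cor(t(prof_c[!const, , drop = FALSE]),
                                        er_c))
  cor_t[!const] <- as.vector(stats::cor(t(prof_t[!const, , drop = FALSE]),
                                        er_t))
  delta <- cor_t - cor_c
  hit <- ids %in% names(mr_hits)[mr_hits]
  post <- ids %in% post_er_ids
  pass_cor <- !is.na(cor_t) & cor_t > cfg$er_correl_cutoff
  pass_delta <- !is.na(delta) & delta > 0
  candidate <- hit & pass_delta & pass_cor & post
  near_miss <- hit & !pass_delta & pass_cor & post
  res <- data.frame(protein_id = ids, correl_con_er = cor_c,
                    correl_dtt_er = cor_t, delta_correl_er = delta,
                    mr_hit = hit, post_er = post,
                    undefined_correlation = const,
                    candidate = candidate, near_miss = near_miss,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(results = res, er_profile_control = er_c,
                 er_profile_treatment = er_t, cfg = cfg),
            class = "doms_er_shift")
}

#' @export
print.doms_er_shift <- function(x, ...) {
  r <- x$results
  cat(sprintf("ER-shift screen: %d proteins, %d candidates, %d near misses\n",
              nrow(r), sum(r$candidate), sum(r$near_miss)))
  invisible(x)
}
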