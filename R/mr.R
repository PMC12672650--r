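## Movement-reproducibility (MR) analysis: delta profiles, robust
## multivariate outlier p-values, Fisher/BH combination into M-scores,
## R-scores and hit calling.

#' Pre-filter proteins for MR analysis
#'
#' Keeps proteins profiled in all replicates of both conditions whose
#' within-condition replicate profiles all have pairwise cosine
#' correlations above \code{cfg$cosine_prefilter}.
#'
#' @param control_profiles,treatment_profiles lists of normalized profile
#'   matrices, one per replicate (shared row names = protein ids).
#' @param cfg a \code{\link{doms_config}}.
#' @return character vector of eligible protein ids.
#' @export
mr_prefilter <- function(control_profiles, treatment_profiles,
                         cfg = doms_config()) {
  ids <- Reduce(intersect, c(lapply(control_profiles, rownames),
                             lapply(treatment_profiles, rownames)))
  keep <- vapply(ids, function(id) {
    for (side in list(control_profiles, treatment_profiles)) {
      prof <- vapply(side, function(m) m[id, ], numeric(6))
      nr <- ncol(prof)
      for (a in seq_len(nr - 1)) for (b in (a + 1):nr)
        if (cosine_similarity(prof[, a], prof[, b]) <= cfg$cosine_prefilter)
          return(FALSE)
    }
    TRUE
  }, logical(1))
  ids[keep]
}

#' Replicate-paired delta profiles
#'
#' Treatment minus control normalized profile, replicate i paired with
#' replicate i. Each delta sums to 0 (difference of two sum-1 vectors).
#'
#' @param control,treatment lists of profile matrices (one per replicate,
#'   identical row order) or single profile vectors.
#' @return list of delta matrices (or a single delta vector).
#' @export
delta_profiles <- function(control, treatment) {
  if (!is.list(control)) return(treatment - control)
  if (length(control) != length(treatment))
    stop("unpaired replicates: ", length(control), " control vs ",
         length(treatment), " treatment")
  Map(function(cc, tt) {
    stopifnot(identical(rownames(cc), rownames(tt)))
    tt - cc
  }, control, treatment)
}

## MCD-style asymptotic consistency factor for a covariance estimated from
## the central `alpha` fraction of a p-variate normal sample.
trim_consistency <- function(alpha, p) {
  stats::pchisq(stats::qchisq(alpha, df = p), df = p + 2) / alpha
}

## Per-protein whitening transforms for delta profiles. Under
## multiplicative measurement noise, a protein with mean normalized
## profile p has delta covariance proportional to
## P (I - 1 p^T)(I - p 1^T) P with P = diag(p) -- known up to the common
## noise scale. Whitening by its inverse square root (in the sum-zero
## subspace) makes delta scatter comparable across compartments.
delta_whiteners <- function(profiles, floor = 1e-3) {
  B <- sum_zero_basis(6)
  p6 <- pmax(profiles, floor)
  p6 <- sweep(p6, 1, rowSums(p6), "/")
  lapply(seq_len(nrow(p6)), function(i) {
    p <- p6[i, ]
    A <- diag(p) %*% (diag(6) - outer(rep(1, 6), p))
    C <- t(B) %*% A %*% t(A) %*% B
    e <- eigen(C, symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12))) %*% t(e$vectors)
  })
}

#' Robust multivariate outlier p-values for delta profiles
#'
#' Per replicate, estimates the location and scatter of the delta-profile
#' cloud from its least-moving \code{cfg$static_proportion} (iteratively
#' re-trimmed for \code{cfg$outlier_iterations} rounds), then converts
#' robust squared Mahalanobis distances into upper-tail chi-square
#' p-values with 5 degrees of freedom (deltas live in the rank-5 sum-zero
#' subspace). When \code{profiles} (per-protein mean normalized profiles)
#' are supplied, each protein's delta is first whitened by its
#' profile-implied noise covariance, so that proteins from compartments
#' with very different profile shapes are tested on a common scale. The
#' trimmed covariance is rescaled by the normal-model consistency factor
#' so that null p-values are uniform.
#'
#' @param deltas list of delta matrices (proteins x 6), one per replicate.
#' @param cfg a \code{\link{doms_config}}.
#' @param profiles optional matrix (proteins x 6) of mean normalized
#'   profiles used for per-protein whitening.
#' @return matrix of p-values, proteins x replicates.
#' @export
robust_outlier_pvalues <- function(deltas, cfg = doms_config(),
                                   profiles = NULL) {
  if (!is.list(deltas)) deltas <- list(deltas)
  n <- nrow(deltas[[1]])
  if (n < 20) stop("need at least 20 proteins for the outlier test")
  B <- sum_zero_basis(6)
  W <- if (!is.null(profiles)) delta_whiteners(profiles) else NULL
  cons <- trim_consistency(cfg$static_proportion, 5)
  h <- ceiling(cfg$static_proportion * n)
  out <- vapply(deltas, function(X) {
    Y <- X %*% B
    if (!is.null(W))
      Y <- t(vapply(seq_len(n), function(i) drop(W[[i]] %*% Y[i, ]),
                    numeric(5)))
    subset <- seq_len(n)
    mu <- NULL; S <- NULL
    for (it in seq_len(cfg$outlier_iterations)) {
      mu <- colMeans(Y[subset, , drop = FALSE])
      S <- stats::cov(Y[subset, , drop = FALSE])
      if (rcond(S) < 1e-12) {
        warning("singular scatter matrix; ridge-regularized")
        S <- S + diag(1e-8 * mean(diag(S)) + 1e-300, ncol(S))
      }
      d2 <- stats::mahalanobis(Y, mu, S)
      subset <- order(d2)[seq_len(h)]
    }
    d2 <- stats::mahalanobis(Y, mu, S / cons)
    stats::pchisq(d2, df = 5, lower.tail = FALSE)
  }, numeric(n))
  rownames(out) <- rownames(deltas[[1]])
  out
}

#' Movement score from replicate p-values
#'
#' Combines each protein's replicate p-values with Fisher's method,
#' adjusts the joint p-values across proteins with Benjamini-Hochberg, and
#' -log10-transforms the adjusted p-value into the movement score M. An
#' adjusted p of 0.01 gives M = 2 (movement at an estimated FDR of 1%);
#' the 5%-FDR significance cut-off corresponds to M = 1.3.
#'
#' @param p_per_replicate matrix of p-values, proteins x replicates.
#' @return data.frame with \code{joint_p}, \code{adjusted_p} and \code{M}.
#' @export
m_score <- function(p_per_replicate) {
  p_per_replicate <- as.matrix(p_per_replicate)
  joint <- apply(p_per_replicate, 1, fisher_combine)
  adjusted <- stats::p.adjust(joint, method = "BH")
  data.frame(joint_p = joint, adjusted_p = adjusted, M = -log10(adjusted),
             row.names = rownames(p_per_replicate))
}

#' Reproducibility score of replicate delta profiles
#'
#' Median of the pairwise Pearson correlations of a protein's replicate
#' delta profiles (rep1 vs rep2, rep1 vs rep3, rep2 vs rep3). A constant
#' delta profile has no defined correlation; NA is returned and the
#' protein cannot become a hit.
#'
#' @param deltas matrix with one replicate delta profile per row (or a
#'   list of vectors).
#' @return the R-score in [-1, 1], or NA.
#' @export
r_score <- function(deltas) {
  if (is.list(deltas)) deltas <- do.call(rbind, deltas)
  nr <- nrow(deltas)
  stopifnot(nr >= 2)
  if (any(apply(deltas, 1, stats::sd) == 0)) return(NA_real_)
  cors <- c()
  for (a in seq_len(nr - 1)) for (b in (a + 1):nr)
    cors <- c(cors, stats::cor(deltas[a, ], deltas[b, ]))
  stats::median(cors)
}

#' Call relocalization hits
#'
#' A protein is a hit iff M > \code{m_cutoff} (default 1.3, FDR < 5%),
#' R > \code{r_cutoff} (default 0.8) and its movement p-value is below
#' \code{per_replicate_p} in at least \code{min_significant_replicates}
#' replicates.
#'
#' @param M movement scores.
#' @param R reproducibility scores (NA allowed; never a hit).
#' @param p_per_replicate matrix of replicate p-values.
#' @param cfg a \code{\link{doms_config}}.
#' @return logical hit flags.
#' @export
call_hits <- function(M, R, p_per_replicate, cfg = doms_config()) {
  n_sig <- rowSums(as.matrix(p_per_replicate) < cfg$per_replicate_p)
  hit <- M > cfg$m_cutoff & !is.na(R) & R > cfg$r_cutoff &
    n_sig >= cfg$min_significant_replicates
  hit & !is.na(hit)
}

#' Movement-reproducibility analysis of two mapped conditions
#'
#' Full MR pipeline: quality filtering of each map, cosine pre-filtering,
#' replicate-paired delta profiles, robust multivariate outlier p-values,
#' Fisher/BH combination into M-scores, R-scores and hit calling.
#'
#' @param table an \code{\link{experiment_table}} containing both
#'   conditions.
#' @param control,treatment condition names.
#' @param cfg a \code{\link{doms_config}}.
#' @return object of class \code{doms_mr}: a list with \code{results}
#'   (per-protein data.frame: replicate p-values, joint/adjusted p, M, R,
#'   hit), \code{deltas} (per-replicate delta matrices), \code{profiles}
#'   (per condition, per replicate) and the configuration.
#' @export
mr_analysis <- function(table, control = "control", treatment = "DTT",
                        cfg = doms_config()) {
  reps_c <- sort(unique(table$samples$replicate[
    table$samples$condition == control]))
  reps_t <- sort(unique(table$samples$replicate[
    table$samples$condition == treatment]))
  if (!identical(reps_c, reps_t))
    stop("replicate count mismatch between ", control, " and ", treatment)
  prof <- function(cond) lapply(reps_c, function(r)
    map_profiles(table, cond, r, cfg = cfg))
  pc <- prof(control)
  pt <- prof(treatment)
  ids <- mr_prefilter(pc, pt, cfg)
  pc <- lapply(pc, function(m) m[ids, , drop = FALSE])
  pt <- lapply(pt, function(m) m[ids, , drop = FALSE])
  deltas <- delta_profiles(pc, pt)
  mean_prof <- (Reduce(`+`, pc) + Reduce(`+`, pt)) / (2 * length(pc))
  pmat <- robust_outlier_pvalues(deltas, cfg, profiles = mean_prof)
  colnames(pmat) <- paste0("p", seq_along(deltas))
  ms <- m_score(pmat)
  R <- vapply(seq_along(ids), function(i)
    r_score(t(vapply(deltas, function(d) d[i, ], numeric(6)))),
    numeric(1))
  hit <- call_hits(ms$M, R, pmat, cfg)
  results <- data.frame(protein_id = ids, pmat, ms, R = R, hit = hit,
                        stringsAsFactors = FALSE, row.names = NULL)
  structure(list(results = results, deltas = deltas,
                 profiles = list(control = pc, treatment = pt),
                 control = control, treatment = treatment, cfg = cfg),
            class = "doms_mr")
}

#' @export
print.doms_mr <- function(x, ...) {
  cat(sprintf("MR analysis: %s vs %s\n", x$treatment, x$control))
  cat(sprintf("  %d proteins tested, %d hits (M > %.2g, R > %.2g, >=%d of %d replicate p < %.2g)\n",
              nrow(x$results), sum(x$results$hit), x$cfg$m_cutoff,
              x$cfg$r_cutoff, x$cfg$min_significant_replicates,
              length(x$deltas), x$cfg$per_replicate_p))
  invisible(x)
}

#' @export
summary.doms_mr <- function(object, ...) {
  r <- object$results
  out <- list(n = nrow(r), n_hits = sum(r$hit),
              m_quartiles = stats::quantile(r$M, c(0.25, 0.5, 0.75)),
              r_quartiles = stats::quantile(r$R, c(0.25, 0.5, 0.75),
                                            na.rm = TRUE),
              hits = r[r$hit, c("protein_id", "M", "R")])
  class(out) <- "summary.doms_mr"
  out
}

#' @export
print.summary.doms_mr <- function(x, ...) {
  cat(sprintf("%d proteins tested, %d hits\n", x$n, x$n_hits))
  cat("M-score quartiles:", paste(signif(x$m_quartiles, 3), collapse = " / "),
      "\n")
  cat("R-score quartiles:", paste(signif(x$r_quartiles, 3), collapse = " / "),
      "\n")
  if (nrow(x$hits)) {
    cat("top hits:\n")
    top <- x$hits[order(-x$hits$M), ][seq_len(min(10, nrow(x$hits))), ]
    print(top, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.doms_mr <- function(x, ...) {
  r <- x$results
  plot(r$R, r$M, xlab = "R-score", ylab = "M-score",
       pch = 16, cex = 0.5, col = ifelse(r$hit, "firebrick", "grey40"),
       main = sprintf("MR analysis: %s vs %s", x$treatment, x$control), ...)
  graphics::abline(h = x$cfg$m_cutoff, v = x$cfg$r_cutoff, lty = 2)
  invisible(x)
}
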