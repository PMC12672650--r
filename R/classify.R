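## Compartment classification: RBF-SVM training with randomized
## hyperparameter search, the iterative marker-refinement loop, confidence
## tiers, F1 benchmarking, reference-agreement scoring and the
## neighborhood predictor.

#' Train the compartment SVM
#'
#' Multi-class RBF-kernel SVM with probability outputs. Hyperparameters
#' are selected by randomized search over C in \code{cfg$svm_c_range}
#' (uniform) and gamma in \code{cfg$svm_gamma_range} (log-uniform),
#' \code{cfg$svm_search_iterations} candidate settings each scored by
#' stratified five-fold cross-validated accuracy. Classes with fewer than
#' 5 markers are excluded with a warning.
#'
#' @param profiles numeric matrix, proteins x features (row names = ids).
#' @param markers named character vector: protein id -> class.
#' @param cfg a \code{\link{doms_config}}.
#' @param seed integer seed; the search and fold assignment (and libsvm's
#'   internal probability calibration) are deterministic given it.
#' @return object of class \code{doms_svm}.
#' @export
train_svm <- function(profiles, markers, cfg = doms_config(), seed = 1L) {
  markers <- markers[names(markers) %in% rownames(profiles)]
  counts <- table(markers)
  small <- names(counts)[counts < 5]
  if (length(small)) {
    warning("class(es) with too few markers excluded: ",
            paste(small, collapse = ", "))
    markers <- markers[!markers %in% small]
  }
  classes <- sort(unique(markers))
  if (length(classes) < 2) stop("need at least 2 classes with >= 5 markers")
  x <- profiles[names(markers), , drop = FALSE]
  y <- factor(unname(markers), levels = classes)

  set.seed(seed)
  n_iter <- cfg$svm_search_iterations
  cand <- data.frame(
    cost = stats::runif(n_iter, cfg$svm_c_range[1], cfg$svm_c_range[2]),
    gamma = exp(stats::runif(n_iter, log(cfg$svm_gamma_range[1]),
                             log(cfg$svm_gamma_range[2]))))
  ## stratified 5-fold assignment
  folds <- integer(length(y))
  for (cl in classes) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(1:5, length(idx)))
  }
  cand$accuracy <- vapply(seq_len(n_iter), function(i) {
    correct <- 0L
    for (f in 1:5) {
      tr <- folds != f
      if (length(unique(y[tr])) < length(classes)) next
      m <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                      cost = cand$cost[i], gamma = cand$gamma[i])
      pred <- stats::predict(m, x[!tr, , drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    correct / length(y)
  }, numeric(1))
  best <- which.max(cand$accuracy)
  set.seed(seed + 1L)   # controls libsvm's probability-calibration CV
  model <- e1071::svm(x, y, kernel = "radial", cost = cand$cost[best],
                      gamma = cand$gamma[best], probability = TRUE)
  structure(list(model = model, classes = classes,
                 cost = cand$cost[best], gamma = cand$gamma[best],
                 cv_accuracy = cand$accuracy[best], search = cand,
                 markers = markers),
            class = "doms_svm")
}

#' @export
print.doms_svm <- function(x, ...) {
  cat(sprintf("compartment SVM: %d classes, %d markers\n",
              length(x$classes), length(x$markers)))
  cat(sprintf("  RBF kernel, C = %.2f, gamma = %.2f (CV accuracy %.3f)\n",
              x$cost, x$gamma, x$cv_accuracy))
  invisible(x)
}

#' Confidence tier of a classification score
#'
#' Strict greater-than thresholds: > 0.95 very_high, > 0.8 high,
#' > 0.65 medium, > 0.4 low, otherwise best_guess (a score of exactly
#' 0.4 is best_guess).
#'
#' @param max_score numeric vector of top class scores in [0, 1].
#' @param tiers named thresholds (default from \code{\link{doms_config}}).
#' @return character vector of tiers.
#' @export
confidence_tier <- function(max_score,
                            tiers = doms_config()$confidence_tiers) {
  stopifnot(all(max_score >= 0 & max_score <= 1))
  out <- rep("best_guess", length(max_score))
  out[max_score > tiers["low"]] <- "low"
  out[max_score > tiers["medium"]] <- "medium"
  out[max_score > tiers["high"]] <- "high"
  out[max_score > tiers["very_high"]] <- "very_high"
  out
}

#' Classify profiles with a trained compartment SVM
#'
#' @param svm_fit a \code{doms_svm}.
#' @param profiles numeric matrix, proteins x features.
#' @param cfg a \code{\link{doms_config}}.
#' @return object of class \code{doms_classification}: data.frame
#'   \code{results} (assigned class, top score, tier, tie flag) and the
#'   full score matrix (rows sum to 1).
#' @export
classify_profiles <- function(svm_fit, profiles, cfg = doms_config()) {
  pred <- stats::predict(svm_fit$model, profiles, probability = TRUE)
  scores <- attr(pred, "probabilities")[, svm_fit$classes, drop = FALSE]
  scores <- scores / rowSums(scores)
  rownames(scores) <- rownames(profiles)
  top <- apply(scores, 1, max)
  tie <- apply(scores, 1, function(s) sum(s == max(s)) > 1)
  assigned <- colnames(scores)[apply(scores, 1, which.max)]  # lexicographic
  results <- data.frame(protein_id = rownames(profiles),
                        assigned_class = assigned, score = top,
                        tier = confidence_tier(top, cfg$confidence_tiers),
                        tie = tie, stringsAsFactors = FALSE,
                        row.names = NULL)
  structure(list(results = results, scores = scores),
            class = "doms_classification")
}

#' @export
print.doms_classification <- function(x, ...) {
  cat(sprintf("compartment classification: %d proteins\n", nrow(x$results)))
  print(table(x$results$tier))
  invisible(x)
}

#' Initial marker selection from reference annotations
#'
#' Mirrors the construction of the first training set: for each SVM class,
#' the \code{top_n} most abundant reference proteins of that class (all
#' members for classes smaller than \code{top_n}). Reference categories
#' are first merged onto the SVM vocabulary (endosomes into vacuole, cell
#' wall into plasma membrane) and unmatchable categories dropped.
#'
#' @param annotations annotation data.frame (see
#'   \code{\link{read_annotations}}).
#' @param abundance named numeric vector of protein abundances.
#' @param profiled ids of profiled proteins to restrict to.
#' @param top_n per-class cap for abundant classes (default 100).
#' @return named character vector: protein id -> class.
#' @export
initial_markers <- function(annotations, abundance, profiled,
                            top_n = 100L) {
  ref <- merge_reference_categories(
    stats::setNames(annotations$category, annotations$protein_id))
  ref <- ref[names(ref) %in% profiled & ref %in% SVM_CLASSES]
  out <- character(0)
  for (cl in unique(ref)) {
    ids <- names(ref)[ref == cl]
    if (length(ids) > top_n)
      ids <- ids[order(-abundance[ids])][seq_len(top_n)]
    out <- c(out, stats::setNames(rep(cl, length(ids)), ids))
  }
  out
}

#' Iterative marker-refinement training loop
#'
#' Repeatedly trains the SVM on the current marker set and classifies all
#' profiled proteins. The next training set consists of the correctly
#' recalled markers plus every non-marker whose prediction has at least
#' medium confidence and matches its reference annotation. The loop stops
#' when training-set recall is 100% and no further proteins are added;
#' it errors if it has not converged after \code{max_rounds}.
#'
#' @param initial named character vector: protein id -> class (the first
#'   training set).
#' @param profiles numeric matrix, proteins x features.
#' @param reference named character vector: protein id -> reference class
#'   (already on the SVM vocabulary).
#' @param cfg a \code{\link{doms_config}}.
#' @param seed integer seed.
#' @param max_rounds maximum iterations (default 20).
#' @return list with \code{markers} (final set), \code{fit} (final
#'   \code{doms_svm}), \code{classification} (final
#'   \code{doms_classification} of all profiles), and \code{audit}
#'   (per-round recall / set sizes).
#' @export
iterate_marker_training <- function(initial, profiles, reference,
                                    cfg = doms_config(), seed = 1L,
                                    max_rounds = 20L) {
  markers <- initial
  audit <- data.frame()
  for (round in seq_len(max_rounds)) {
    # fixed training seed: the converged state is then a fixed point, so
    # rerunning the loop on its own output terminates immediately
    fit <- train_svm(profiles, markers, cfg, seed = seed)
    cls <- classify_profiles(fit, profiles, cfg)
    res <- cls$results
    assigned <- stats::setNames(res$assigned_class, res$protein_id)
    tiers <- stats::setNames(res$tier, res$protein_id)
    in_set <- names(markers)[markers %in% fit$classes]
    recalled <- in_set[assigned[in_set] == markers[in_set]]
    recall <- length(recalled) / length(in_set)
    candidates <- setdiff(rownames(profiles), names(markers))
    candidates <- candidates[candidates %in% names(reference)]
    add <- candidates[
      tiers[candidates] %in% c("very_high", "high", "medium") &
        assigned[candidates] == reference[candidates]]
    audit <- rbind(audit, data.frame(
      round = round, n_markers = length(markers), recall = recall,
      n_additions = length(add)))
    next_set <- c(stats::setNames(markers[recalled], recalled),
                  stats::setNames(unname(assigned[add]), add))
    converged <- recall == 1 && length(add) == 0 &&
      length(next_set) == length(markers)
    if (converged)
      return(list(markers = markers, fit = fit, classification = cls,
                  audit = audit, rounds = round))
    markers <- next_set
  }
  stop("marker training did not converge after ", max_rounds,
       " rounds; audit:\n",
       paste(utils::capture.output(print(audit)), collapse = "\n"))
}

## per-class F1 from predicted and true labels
f1_by_class <- function(predicted, truth, classes) {
  vapply(classes, function(cl) {
    tp <- sum(predicted == cl & truth == cl)
    fp <- sum(predicted == cl & truth != cl)
    fn <- sum(predicted != cl & truth == cl)
    if (2 * tp + fp + fn == 0) return(NA_real_)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
}

#' Benchmark classification performance with a marker hold-out
#'
#' Splits the markers 80:20 (stratified) into training and leave-out test
#' sets, trains with cross-validated hyperparameter search on the 80%, and
#' reports per-class F1 scores averaged over 20 random 75% subsamples of
#' the test-set predictions. Classes with too few members for an
#' informative test set (by default lipid droplets and peroxisomes) are
#' excluded.
#'
#' @param profiles numeric matrix, proteins x features.
#' @param markers named character vector: id -> class.
#' @param cfg a \code{\link{doms_config}}.
#' @param seed integer seed.
#' @param exclude classes excluded from benchmarking.
#' @param n_subsamples,subsample_frac subsampling scheme for the averaged
#'   F1 (defaults 20 and 0.75).
#' @return list with \code{f1} (named per-class averages), \code{macro_f1}
#'   and the test-set ids.
#' @export
benchmark_f1 <- function(profiles, markers, cfg = doms_config(),
                         seed = 1L,
                         exclude = c("lipid droplets", "peroxisomes"),
                         n_subsamples = 20L, subsample_frac = 0.75) {
  markers <- markers[!markers %in% exclude]
  set.seed(seed)
  test_ids <- character(0)
  for (cl in unique(markers)) {
    ids <- names(markers)[markers == cl]
    n_test <- max(1L, round(0.2 * length(ids)))
    test_ids <- c(test_ids, sample(ids, n_test))
  }
  train_ids <- setdiff(names(markers), test_ids)
  fit <- train_svm(profiles, markers[train_ids], cfg, seed = seed)
  cls <- classify_profiles(fit, profiles[test_ids, , drop = FALSE], cfg)
  predicted <- stats::setNames(cls$results$assigned_class,
                               cls$results$protein_id)
  classes <- sort(unique(markers))
  f1_mat <- matrix(NA_real_, n_subsamples, length(classes),
                   dimnames = list(NULL, classes))
  for (s in seq_len(n_subsamples)) {
    sub <- sample(test_ids, round(subsample_frac * length(test_ids)))
    f1_mat[s, ] <- f1_by_class(predicted[sub], markers[sub], classes)
  }
  f1 <- colMeans(f1_mat, na.rm = TRUE)
  list(f1 = f1, macro_f1 = mean(f1, na.rm = TRUE), test_ids = test_ids,
       fit = fit)
}

#' Merge reference categories onto the SVM vocabulary
#'
#' Pools endosomes into vacuole and cell wall into plasma membrane (the
#' SVM does not resolve them); other categories pass through.
#'
#' @param categories character vector of reference categories.
#' @return merged categories.
#' @export
merge_reference_categories <- function(categories) {
  categories[categories == "endosomes"] <- "vacuole"
  categories[categories == "cell wall"] <- "plasma membrane"
  categories
}

#' Agreement of SVM predictions with a reference annotation
#'
#' Drops reference categories unavailable to the SVM (actin-associated,
#' ambiguous, COPI, COPII, ERGIC, unknown), merges endosomes into vacuole
#' and cell wall into plasma membrane, then scores a prediction as a match
#' if it equals the merged reference category, or if the prediction is
#' cytosol and the protein's measured cytosolic pool exceeds
#' \code{cfg$dual_localization_pool_cutoff} (a secondary cytosolic
#' localization).
#'
#' @param predictions named character vector: id -> predicted class.
#' @param reference named character vector: id -> reference category.
#' @param cytosolic_pools named numeric vector of cytosolic pool fractions
#'   (missing ids count as pool 0).
#' @param cfg a \code{\link{doms_config}}.
#' @return list with \code{agreement} (fraction) and \code{table}
#'   (per-protein match table).
#' @export
agreement_with_reference <- function(predictions, reference,
                                     cytosolic_pools = numeric(0),
                                     cfg = doms_config()) {
  ids <- intersect(names(predictions), names(reference))
  ref <- reference[ids]
  keep <- !(ref %in% UNMATCHABLE_CATEGORIES)
  ids <- ids[keep]
  ref <- merge_reference_categories(reference[ids])
  pred <- predictions[ids]
  pool <- rep(0, length(ids))
  names(pool) <- ids
  common <- intersect(ids, names(cytosolic_pools))
  pool[common] <- cytosolic_pools[common]
  match <- pred == ref |
    (pred == "cytosol" & pool > cfg$dual_localization_pool_cutoff)
  tbl <- data.frame(protein_id = ids, predicted = unname(pred),
                    reference = unname(ref), cytosolic_pool = unname(pool),
                    match = unname(match), stringsAsFactors = FALSE)
  list(agreement = mean(match), table = tbl)
}

#' Neighborhood predictor
#'
#' The k proteins with the most similar subcellular distribution to a
#' query, by Pearson-correlation distance (1 - r) on concatenated
#' replicate profiles.
#'
#' @param query_id protein id.
#' @param profiles numeric matrix, proteins x features.
#' @param k number of neighbors.
#' @return data.frame of neighbors ordered by distance.
#' @export
neighborhood <- function(query_id, profiles, k = 10L) {
  if (!query_id %in% rownames(profiles)) stop("unknown id: ", query_id)
  q <- profiles[query_id, ]
  others <- setdiff(rownames(profiles), query_id)
  d <- 1 - as.vector(stats::cor(q, t(profiles[others, , drop = FALSE])))
  ord <- order(d)
  out <- data.frame(protein_id = others[ord], distance = d[ord],
                    stringsAsFactors = FALSE)
  utils::head(out, k)
}
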