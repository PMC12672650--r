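## End-to-end orchestration: steady-state mapping runs and
## control-vs-treatment comparison runs, with a provenance manifest.

stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- tryCatch(force(expr), error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  list(value = value, seconds = proc.time()[["elapsed"]] - t0)
}

file_hash <- function(paths) {
  vapply(paths, function(p)
    if (file.exists(p)) as.character(tools::md5sum(p)) else NA_character_,
    character(1))
}

#' Steady-state mapping run
#'
#' Orchestrates the full steady-state analysis of one condition: quality
#' filtering, normalized profiles concatenated across replicates, PCA,
#' iterative marker training and SVM classification of all mapped
#' proteins, cytosolic pools, and the neighborhood index. Outputs are
#' written as TSVs when \code{out_dir} is given.
#'
#' @param table an \code{\link{experiment_table}}.
#' @param annotations annotation data.frame.
#' @param yields yields data.frame.
#' @param cfg a \code{\link{doms_config}}.
#' @param condition condition to map (default "control").
#' @param out_dir optional output directory for TSV reports.
#' @param seed integer seed.
#' @return list with \code{profiles} (concatenated matrix), \code{pca},
#'   \code{markers}, \code{classification}, \code{pools} (per-replicate
#'   cytosolic pools), \code{agreement} and \code{manifest}.
#' @export
run_steady_state <- function(table, annotations, yields,
                             cfg = doms_config(), condition = "control",
                             out_dir = NULL, seed = cfg$rng_seed) {
  timings <- list()
  s <- stage("profiles", concatenated_profiles(table, condition, cfg = cfg))
  profiles <- s$value; timings$profiles <- s$seconds
  s <- stage("pca", pca_project(profiles))
  pca <- s$value; timings$pca <- s$seconds

  abundance <- rowMeans(table$intensity[, table$samples$fraction ==
                                          "full_proteome", drop = FALSE],
                        na.rm = TRUE)
  abundance[is.nan(abundance)] <- 0
  s <- stage("markers", {
    init <- initial_markers(annotations, abundance, rownames(profiles))
    reference <- merge_reference_categories(
      stats::setNames(annotations$category, annotations$protein_id))
    reference <- reference[reference %in% SVM_CLASSES]
    iterate_marker_training(init, profiles, reference, cfg, seed = seed)
  })
  training <- s$value; timings$markers <- s$seconds

  s <- stage("pools", cytosolic_pools(table, condition, yields))
  pools <- s$value; timings$pools <- s$seconds
  mean_pool <- rowMeans(pools, na.rm = TRUE)
  mean_pool <- mean_pool[!is.nan(mean_pool)]

  predictions <- stats::setNames(training$classification$results$assigned_class,
                                 training$classification$results$protein_id)
  reference_all <- stats::setNames(annotations$category,
                                   annotations$protein_id)
  s <- stage("agreement",
             agreement_with_reference(predictions, reference_all,
                                      mean_pool, cfg))
  agreement <- s$value; timings$agreement <- s$seconds

  manifest <- list(seed = seed, condition = condition,
                   n_proteins = length(table$protein_id),
                   n_mapped = nrow(profiles),
                   n_markers = length(training$markers),
                   timings = timings, cfg = unclass(cfg))
  out <- list(profiles = profiles, pca = pca, markers = training$markers,
              training_audit = training$audit,
              classification = training$classification,
              pools = pools, agreement = agreement, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_matrix(profiles, file.path(out_dir, "profiles.tsv"))
    write_tsv_matrix(pca$scores, file.path(out_dir, "pca.tsv"))
    utils::write.table(training$classification$results,
                       file.path(out_dir, "classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_tsv_matrix(pools, file.path(out_dir, "cytosolic_pools.tsv"))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  out
}

#' Control-versus-treatment comparison run
#'
#' Orchestrates the dynamic analysis: MR analysis per treatment, cytosolic
#' pool shift test combining two treatments, organelle-level shift test,
#' and the ER-redistribution candidate screen for the first treatment.
#'
#' @param table an \code{\link{experiment_table}} with all conditions.
#' @param markers named character vector: protein id -> compartment (the
#'   trained marker set).
#' @param annotations annotation data.frame.
#' @param yields yields data.frame.
#' @param cfg a \code{\link{doms_config}}.
#' @param control control condition name.
#' @param treatments two treatment condition names (first drives the MR/ER
#'   screen, both drive the pool shift test).
#' @param out_dir optional output directory.
#' @return list with \code{mr} (per treatment), \code{pool_shift},
#'   \code{organelle_shift} (per treatment), \code{er_shift},
#'   \code{report} (joint per-protein table) and \code{manifest}.
#' @export
run_comparison <- function(table, markers, annotations, yields,
                           cfg = doms_config(), control = "control",
                           treatments = c("DTT", "Tm"), out_dir = NULL) {
  stopifnot(length(treatments) >= 1)
  timings <- list()
  mr <- list()
  for (trt in treatments) {
    s <- stage(paste0("mr_", trt), mr_analysis(table, control, trt, cfg))
    mr[[trt]] <- s$value; timings[[paste0("mr_", trt)]] <- s$seconds
  }
  pool_shift <- NULL
  if (length(treatments) >= 2) {
    s <- stage("pool_shift", {
      pc <- cytosolic_pools(table, control, yields)
      p1 <- cytosolic_pools(table, treatments[1], yields)
      p2 <- cytosolic_pools(table, treatments[2], yields)
      pool_shift_test(pc, p1, p2, cfg)
    })
    pool_shift <- s$value; timings$pool_shift <- s$seconds
  }
  organelle_shift <- list()
  for (trt in treatments) {
    s <- stage(paste0("organelle_shift_", trt), {
      m1 <- mr[[trt]]
      organelle_shift_test(m1$profiles$control, m1$profiles$treatment,
                           markers, cfg)
    })
    organelle_shift[[trt]] <- s$value
    timings[[paste0("organelle_shift_", trt)]] <- s$seconds
  }
  s <- stage("er_shift", {
    m1 <- mr[[treatments[1]]]
    er_ids <- names(markers)[markers == "ER"]
    mr_hits <- stats::setNames(m1$results$hit, m1$results$protein_id)
    post <- classify_post_er(annotations)
    er_shift_candidates(m1$profiles$control, m1$profiles$treatment,
                        er_ids, mr_hits, post, cfg)
  })
  er_shift <- s$value; timings$er_shift <- s$seconds

  m1 <- mr[[treatments[1]]]$results
  report <- m1[, c("protein_id", "M", "R", "hit")]
  er <- er_shift$results
  report <- merge(report,
                  er[, c("protein_id", "delta_correl_er", "candidate")],
                  by = "protein_id", all.x = TRUE)
  if (!is.null(pool_shift))
    report <- merge(report,
                    pool_shift$results[, c("protein_id", "change_1",
                                           "p_1", "hit")],
                    by = "protein_id", all.x = TRUE,
                    suffixes = c("", "_pool"))
  manifest <- list(control = control, treatments = treatments,
                   n_tested = vapply(mr, function(m) nrow(m$results), 0),
                   n_hits = vapply(mr, function(m) sum(m$results$hit), 0),
                   timings = timings, cfg = unclass(cfg))
  out <- list(mr = mr, pool_shift = pool_shift,
              organelle_shift = organelle_shift, er_shift = er_shift,
              report = report, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (trt in treatments)
      utils::write.table(mr[[trt]]$results,
                         file.path(out_dir, paste0("mr_", trt, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report, file.path(out_dir, "report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  out
}
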