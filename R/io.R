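## Readers, writers, profile construction and quality filtering.
##
## The central container is the experiment_table: per-protein LFQ
## intensities and MS/MS counts over samples keyed by
## (condition, replicate, fraction). Missing measurements are NA,
## distinct from a literal 0 in the source file.

sample_key <- function(condition, replicate, fraction) {
  paste(condition, replicate, fraction, sep = "_")
}

#' Construct an experiment table
#'
#' @param protein_id character vector of unique protein (group) ids.
#' @param gene_name character vector of gene names (same length).
#' @param intensity numeric matrix, proteins x samples; NA = not quantified.
#' @param ms_count numeric matrix of MS/MS spectral counts, same shape.
#' @param samples data.frame with columns \code{condition}, \code{replicate},
#'   \code{fraction}; one row per column of \code{intensity}.
#' @return an object of class \code{experiment_table}.
#' @export
experiment_table <- function(protein_id, gene_name, intensity, ms_count,
                             samples) {
  protein_id <- as.character(protein_id)
  if (anyDuplicated(protein_id))
    stop("duplicate protein_id: ",
         paste(unique(protein_id[duplicated(protein_id)]), collapse = ", "))
  stopifnot(nrow(intensity) == length(protein_id),
            identical(dim(intensity), dim(ms_count)),
            nrow(samples) == ncol(intensity),
            all(c("condition", "replicate", "fraction") %in% names(samples)))
  keys <- sample_key(samples$condition, samples$replicate, samples$fraction)
  if (anyDuplicated(keys))
    stop("duplicate sample key: ", keys[duplicated(keys)][1])
  dimnames(intensity) <- list(protein_id, keys)
  dimnames(ms_count) <- list(protein_id, keys)
  structure(list(protein_id = protein_id,
                 gene_name = as.character(gene_name),
                 intensity = intensity, ms_count = ms_count,
                 samples = samples),
            class = "experiment_table")
}

#' @export
print.experiment_table <- function(x, ...) {
  cat(sprintf("experiment_table: %d proteins x %d samples\n",
              length(x$protein_id), nrow(x$samples)))
  cat("conditions:", paste(unique(x$samples$condition), collapse = ", "), "\n")
  cat("fractions: ", paste(unique(x$samples$fraction), collapse = ", "), "\n")
  invisible(x)
}

#' Read a MaxQuant-style protein-groups table
#'
#' Expects a tab-separated file with one row per protein group, columns
#' \code{"LFQ intensity <sample>"} and \code{"MS/MS count <sample>"} for
#' every sample named in \code{layout}, and (optionally) the MaxQuant flag
#' columns \code{Reverse}, \code{Only identified by site} and
#' \code{Potential contaminant}. Rows flagged \code{"+"} in any flag column
#' are dropped. Empty cells become NA; a literal 0 is kept as 0.
#'
#' @param path path to the TSV file.
#' @param layout data.frame mapping sample names to keys; columns
#'   \code{sample}, \code{condition}, \code{replicate}, \code{fraction}.
#' @return an \code{\link{experiment_table}}.
#' @export
read_protein_groups <- function(path, layout) {
  stopifnot(all(c("sample", "condition", "replicate", "fraction")
                %in% names(layout)))
  raw <- utils::read.delim(path, check.names = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  int_cols <- paste("LFQ intensity", layout$sample)
  cnt_cols <- paste("MS/MS count", layout$sample)
  missing_cols <- setdiff(c(int_cols, cnt_cols), names(raw))
  if (length(missing_cols))
    stop("missing declared column(s): ", paste(missing_cols, collapse = ", "))
  drop <- rep(FALSE, nrow(raw))
  for (flag in c("Reverse", "Only identified by site",
                 "Potential contaminant")) {
    if (flag %in% names(raw))
      drop <- drop | (!is.na(raw[[flag]]) & raw[[flag]] == "+")
  }
  raw <- raw[!drop, , drop = FALSE]
  ids <- raw[["Protein IDs"]]
  if (is.null(ids)) stop("missing declared column(s): Protein IDs")
  genes <- if ("Gene names" %in% names(raw)) raw[["Gene names"]] else ids
  genes[is.na(genes)] <- ""
  intensity <- as.matrix(raw[, int_cols, drop = FALSE])
  ms_count <- as.matrix(raw[, cnt_cols, drop = FALSE])
  storage.mode(intensity) <- "double"
  storage.mode(ms_count) <- "double"
  experiment_table(ids, genes, intensity, ms_count,
                   layout[, c("condition", "replicate", "fraction")])
}

#' Write an experiment table as a MaxQuant-dialect TSV
#'
#' Round-trips through \code{\link{read_protein_groups}} losslessly for
#' finite values, preserving missingness (written as empty cells).
#'
#' @param table an \code{experiment_table}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_protein_groups <- function(table, path) {
  keys <- colnames(table$intensity)
  df <- data.frame("Protein IDs" = table$protein_id,
                   "Gene names" = table$gene_name,
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_along(keys))
    df[[paste("LFQ intensity", keys[j])]] <- table$intensity[, j]
  for (j in seq_along(keys))
    df[[paste("MS/MS count", keys[j])]] <- table$ms_count[, j]
  df[["Reverse"]] <- ""
  df[["Only identified by site"]] <- ""
  df[["Potential contaminant"]] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

## Layout whose sample names are the serialized keys themselves, as written
## by write_protein_groups / the simulator.
#' Standard sample layout for serialized keys
#'
#' Builds the layout data.frame for files whose sample names are
#' \code{"<condition>_<replicate>_<fraction>"}.
#'
#' @param conditions character vector of condition names.
#' @param n_replicates replicates per condition.
#' @param fractions fraction names (default: six pellets, cytosol,
#'   full_proteome).
#' @return a layout data.frame for \code{\link{read_protein_groups}}.
#' @export
standard_layout <- function(conditions, n_replicates,
                            fractions = c(POOL_FRACTIONS, "full_proteome")) {
  g <- expand.grid(fraction = fractions, replicate = seq_len(n_replicates),
                   condition = conditions, stringsAsFactors = FALSE)
  data.frame(sample = sample_key(g$condition, g$replicate, g$fraction),
             condition = g$condition, replicate = g$replicate,
             fraction = g$fraction, stringsAsFactors = FALSE)
}

## Extract the proteins x fractions intensity (or count) matrix for one
## (condition, replicate), columns in the fixed centrifugation order.
fraction_matrix <- function(table, condition, replicate,
                            fractions = PELLET_FRACTIONS,
                            what = c("intensity", "ms_count")) {
  what <- match.arg(what)
  keys <- sample_key(condition, replicate, fractions)
  absent <- setdiff(keys, colnames(table$intensity))
  if (length(absent))
    stop("sample(s) not present in table: ", paste(absent, collapse = ", "))
  table[[what]][, keys, drop = FALSE]
}

#' Quality-filter proteins for mapping
#'
#' Keeps proteins with at least \code{cfg$min_consecutive_fractions}
#' consecutive quantified intensities among the six pellet fractions (in
#' centrifugation order 1k to 78k; a 0 intensity counts as not quantified)
#' and a mean MS/MS count across the six fractions (missing counted as 0)
#' of at least \code{cfg$min_avg_ms_count}.
#'
#' @param table an \code{experiment_table}.
#' @param condition,replicate which map to filter.
#' @param cfg a \code{\link{doms_config}}.
#' @return character vector of kept protein ids.
#' @export
filter_map_profiles <- function(table, condition, replicate,
                                cfg = doms_config()) {
  ints <- fraction_matrix(table, condition, replicate)
  cnts <- fraction_matrix(table, condition, replicate, what = "ms_count")
  measured <- !is.na(ints) & ints > 0
  run_len <- apply(measured, 1, function(m) {
    r <- rle(m)
    mx <- r$lengths[r$values]
    if (length(mx)) max(mx) else 0L
  })
  cnts[is.na(cnts)] <- 0
  mean_count <- rowMeans(cnts)
  table$protein_id[run_len >= cfg$min_consecutive_fractions &
                     mean_count >= cfg$min_avg_ms_count]
}

#' Normalize a fraction profile to sum 1
#'
#' Divides the six pellet-fraction intensities by their total to obtain the
#' 0-to-1 normalized profile; missing values count as 0.
#'
#' @param intensities numeric vector of 6 non-negative values (NA allowed).
#' @return numeric vector summing to 1.
#' @export
normalize_profile <- function(intensities) {
  x <- intensities
  x[is.na(x)] <- 0
  if (any(x < 0)) stop("negative intensity")
  s <- sum(x)
  if (s == 0) stop("undefined profile: all intensities are zero or missing")
  x / s
}

#' Normalized profile matrix for one map
#'
#' @param table an \code{experiment_table}.
#' @param condition,replicate which map.
#' @param proteins protein ids to include (default: those passing
#'   \code{\link{filter_map_profiles}}).
#' @param cfg a \code{\link{doms_config}}.
#' @return matrix (proteins x 6) of row-normalized profiles.
#' @export
map_profiles <- function(table, condition, replicate, proteins = NULL,
                         cfg = doms_config()) {
  if (is.null(proteins))
    proteins <- filter_map_profiles(table, condition, replicate, cfg)
  ints <- fraction_matrix(table, condition, replicate)[proteins, ,
                                                       drop = FALSE]
  ints[is.na(ints)] <- 0
  s <- rowSums(ints)
  if (any(s == 0)) stop("undefined profile for: ",
                        paste(proteins[s == 0], collapse = ", "))
  sweep(ints, 1, s, "/")
}

#' Average replicate profiles within a condition
#'
#' Arithmetic mean per fraction over replicate profiles, renormalized to
#' sum 1.
#'
#' @param profiles a list of profile vectors (or a matrix with one profile
#'   per row), one per replicate.
#' @return a single normalized profile.
#' @export
condition_average_profile <- function(profiles) {
  if (is.list(profiles)) profiles <- do.call(rbind, profiles)
  stopifnot(nrow(profiles) >= 1)
  normalize_profile(colMeans(profiles))
}

#' Concatenated replicate profiles
#'
#' Joins the normalized 6-fraction profiles of several maps column-wise
#' (6 columns per map) for proteins profiled in every map, the input
#' representation for joint PCA, SVM classification and the neighborhood
#' predictor.
#'
#' @param table an \code{experiment_table}.
#' @param conditions condition name(s).
#' @param replicates replicate indices (default: all for each condition).
#' @param cfg a \code{\link{doms_config}}.
#' @return matrix, proteins x (6 * n_maps), each 6-block summing to 1.
#' @export
concatenated_profiles <- function(table, conditions, replicates = NULL,
                                  cfg = doms_config()) {
  if (is.null(replicates))
    replicates <- sort(unique(table$samples$replicate[
      table$samples$condition %in% conditions &
        table$samples$fraction %in% PELLET_FRACTIONS]))
  maps <- expand.grid(replicate = replicates, condition = conditions,
                      stringsAsFactors = FALSE)
  kept <- lapply(seq_len(nrow(maps)), function(i)
    filter_map_profiles(table, maps$condition[i], maps$replicate[i], cfg))
  proteins <- Reduce(intersect, kept)
  blocks <- lapply(seq_len(nrow(maps)), function(i)
    map_profiles(table, maps$condition[i], maps$replicate[i], proteins, cfg))
  out <- do.call(cbind, blocks)
  colnames(out) <- unlist(lapply(seq_len(nrow(maps)), function(i)
    sample_key(maps$condition[i], maps$replicate[i], PELLET_FRACTIONS)))
  out
}

#' Project profiles onto the first two principal components
#'
#' Columns are mean-centered (not scaled) before the decomposition.
#'
#' @param profiles numeric matrix, proteins x features (>= 3 proteins).
#' @return list with \code{scores} (proteins x 2, columns PC1/PC2) and
#'   \code{explained} (variance fractions of PC1 and PC2).
#' @export
pca_project <- function(profiles) {
  stopifnot(nrow(profiles) >= 3, ncol(profiles) >= 2)
  pc <- stats::prcomp(profiles, center = TRUE, scale. = FALSE)
  # perfectly collinear data are fine (PC2 variance 0); only fully
  # degenerate input (all points identical) cannot be projected
  if (sum(pc$sdev > 1e-12) < 1) stop("profile matrix has rank < 1")
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, 1:2, drop = FALSE]
  colnames(scores) <- c("PC1", "PC2")
  list(scores = scores, explained = ev[1:2])
}

#' Read a reference annotation table
#'
#' TSV with columns \code{protein_id}, \code{category} (one of the 20
#' reference categories), \code{n_tm_domains}, \code{has_signal_peptide},
#' \code{has_transit_peptide}, \code{molecular_weight} (g/mol).
#'
#' @param path path to the TSV.
#' @return a data.frame with typed columns.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("protein_id", "category", "n_tm_domains", "has_signal_peptide",
            "has_transit_peptide", "molecular_weight")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation file lacks column(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(ann$category), REFERENCE_CATEGORIES)
  if (length(bad)) stop("unknown reference categor(ies): ",
                        paste(bad, collapse = ", "))
  ann$has_signal_peptide <- as.logical(ann$has_signal_peptide)
  ann$has_transit_peptide <- as.logical(ann$has_transit_peptide)
  ann
}

#' Read per-fraction protein yields
#'
#' TSV with columns \code{condition}, \code{fraction}, \code{yield}
#' (relative BCA protein recovery; the fractions of one condition sum to
#' at most 1).
#'
#' @param path path to the TSV.
#' @return data.frame of yields.
#' @export
read_yields <- function(path) {
  y <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("condition", "fraction", "yield")
  miss <- setdiff(need, names(y))
  if (length(miss)) stop("yields file lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(y$yield < 0)) stop("negative yield")
  y
}

#' Yield weights for one condition
#'
#' @param yields data.frame from \code{\link{read_yields}}.
#' @param condition condition name.
#' @return named numeric vector over the seven pool fractions.
#' @export
yields_vector <- function(yields, condition) {
  y <- yields[yields$condition == condition, ]
  if (!nrow(y)) stop("no yields for condition: ", condition)
  out <- stats::setNames(y$yield, y$fraction)[POOL_FRACTIONS]
  if (any(is.na(out))) stop("yields missing for fraction(s): ",
                            paste(POOL_FRACTIONS[is.na(out)], collapse = ", "))
  out
}

#' Write a matrix with row names as a TSV
#'
#' @param x matrix or data.frame.
#' @param path output path.
#' @param id_column name for the row-name column.
#' @return \code{path}, invisibly.
#' @export
write_tsv_matrix <- function(x, path, id_column = "protein_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
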