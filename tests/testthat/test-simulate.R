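test_that("default templates are normalized, distinct and shaped as intended", {
  tpl <- default_templates()
  expect_length(tpl, 12)
  P <- vapply(tpl, function(t) t$pellet_profile, numeric(6))
  expect_equal(unname(colSums(P)), rep(1, 12), tolerance = 1e-12)
  d <- as.matrix(stats::dist(t(P), method = "manhattan"))
  expect_gte(min(d[upper.tri(d)]), 0.4)
  expect_equal(unname(which.max(P[, "ribosome"])), 6L)  # 78k pellet
  # heavy organelles sediment early
  for (nm in c("nucleus", "nuclear envelope", "ER"))
    expect_lte(which.max(P[, nm]), 2L)
  expect_gte(tpl$cytosol$cytosol_leak, 0.8)
})

test_that("simulation is reproducible from its seed", {
  cfg <- simulation_config(n_proteins = 60, n_relocalizers = 5, seed = 5)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$table$intensity, s2$table$intensity)
  expect_identical(s1$table$ms_count, s2$table$ms_count)
  expect_identical(s1$truth, s2$truth)
})

test_that("mean delta profile vanishes without planted shifts", {
  # 50 replicates of an unshifted protein: the replicate-mean delta
  # profile must shrink towards zero (within 3 standard errors)
  cfg <- simulation_config(n_proteins = 30, n_relocalizers = 0,
                           n_abundance_changers = 0, seed = 13)
  sim <- simulate_experiment(cfg, n_replicates = 50)
  pc <- lapply(1:50, function(r)
    map_profiles(sim$table, "control", r,
                 proteins = sim$truth$protein_id))
  pt <- lapply(1:50, function(r)
    map_profiles(sim$table, "DTT", r, proteins = sim$truth$protein_id))
  deltas <- delta_profiles(pc, pt)
  # restrict to fully quantified proteins: left-censoring near the
  # detection limit biases deltas of partially missing profiles
  pellet_keys <- colnames(sim$table$intensity)[
    sim$table$samples$fraction %in% PELLET_FRACTIONS]
  complete <- sim$truth$protein_id[
    rowSums(is.na(sim$table$intensity[, pellet_keys])) == 0]
  z <- unlist(lapply(head(complete, 5), function(id) {
    d <- t(vapply(deltas, function(x) x[id, ], numeric(6)))
    colMeans(d) / (apply(d, 2, stats::sd) / sqrt(50))
  }))
  # 30 standardized means: allow the expected single ~3-sigma excursion
  expect_lte(sum(abs(z) > 3), 1)
  expect_lt(max(abs(z)), 4)
})

test_that("a full alpha switch moves the mean delta to the template difference", {
  tpl <- default_templates()
  cfg <- simulation_config(n_proteins = 40, n_relocalizers = 1,
                           alpha_shift_sizes = 1,
                           n_abundance_changers = 0,
                           reloc_from = "vacuole", reloc_to = "ER",
                           replicate_cv = 0.05, seed = 17)
  sim <- simulate_experiment(cfg, n_replicates = 50)
  id <- sim$truth$protein_id[sim$truth$relocalizer][1]
  pc <- lapply(1:50, function(r)
    map_profiles(sim$table, "control", r, proteins = id))
  pt <- lapply(1:50, function(r)
    map_profiles(sim$table, "DTT", r, proteins = id))
  mean_delta <- colMeans(t(vapply(seq_len(50), function(r)
    pt[[r]][1, ] - pc[[r]][1, ], numeric(6))))
  # expected delta in measured space: yield-distorted ER minus vacuole
  y <- yields_vector(sim$yields, "control")[1:6]
  meas <- function(nm) {
    m <- tpl[[nm]]$pellet_profile / y
    m / sum(m)
  }
  expected <- meas("ER") - meas("vacuole")
  expect_lt(max(abs(mean_delta - expected)), 0.02)
})

test_that("fixture round-trips through the readers", {
  sim <- sim_small()
  dir <- withr::local_tempdir()
  paths <- write_fixture(sim, dir)
  layout <- standard_layout(c("control", "DTT"), 3)
  back <- read_protein_groups(paths["protein_groups"], layout)
  expect_equal(back$intensity[, colnames(back$intensity)],
               sim$table$intensity[, colnames(back$intensity)],
               tolerance = 1e-12)
  truth <- utils::read.delim(paths["truth"])
  expect_equal(nrow(truth), nrow(sim$truth))
  y <- read_yields(paths["yields"])
  for (cc in unique(y$condition))
    expect_lte(sum(y$yield[y$condition == cc]), 1)
  ann <- read_annotations(paths["annotations"])
  expect_equal(nrow(ann), nrow(sim$truth))
})

test_that("planted relocalization strength orders the M-score response", {
  cfg <- function(a, seed) simulation_config(
    n_proteins = 250, n_relocalizers = 25, alpha_shift_sizes = a,
    n_abundance_changers = 0, seed = seed)
  med_m <- vapply(c(0.3, 0.6, 0.9), function(a) {
    sim <- simulate_experiment(cfg(a, 19))
    mr <- mr_analysis(sim$table, "control", "DTT")
    planted <- sim$truth$protein_id[sim$truth$relocalizer]
    stats::median(mr$results$M[mr$results$protein_id %in% planted])
  }, numeric(1))
  expect_true(all(diff(med_m) > 0))
})
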