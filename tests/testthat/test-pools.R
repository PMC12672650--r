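test_that("pool profile weighting matches hand arithmetic", {
  y <- rep(1, 7)
  all_cyt <- pool_profile(c(0, 0, 0, 0, 0, 0, 5), y)
  expect_equal(unname(all_cyt["cytosol"]), 1)
  equal <- pool_profile(rep(2, 7), y)
  expect_equal(unname(equal), rep(1 / 7, 7))
  # intensities (1,...,1,2), yields (0.1 x6, 0.4): pool = 0.8/1.4
  p <- pool_profile(c(1, 1, 1, 1, 1, 1, 2), c(rep(0.1, 6), 0.4))
  expect_equal(unname(p["cytosol"]), 0.8 / 1.4, tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_error(pool_profile(rep(0, 7), y), "undefined")
})

test_that("cytosolic pools recover the planted leak shares", {
  sim <- sim_map()
  pools <- cytosolic_pools(sim$table, "control", sim$yields)
  truth <- sim$truth
  leak <- vapply(sim$templates, function(t) t$cytosol_leak, numeric(1))
  mean_pool <- rowMeans(pools, na.rm = TRUE)
  for (comp in c("cytosol", "ER", "proteasome")) {
    ids <- truth$protein_id[truth$compartment == comp]
    got <- stats::median(mean_pool[ids], na.rm = TRUE)
    expect_lt(abs(got - leak[comp]), 0.05)
  }
})

test_that("pool shift test applies every hit filter", {
  set.seed(30)
  n <- 60
  ids <- sprintf("P%02d", 1:n)
  ctrl <- matrix(0.30 + stats::rnorm(3 * n, 0, 0.01), n, 3,
                 dimnames = list(ids, NULL))
  t1 <- ctrl + stats::rnorm(3 * n, 0, 0.01)
  t2 <- ctrl + stats::rnorm(3 * n, 0, 0.01)
  eps <- function() stats::rnorm(3, 0, 0.005)
  # planted +20-point shift in both treatments
  t1[1, ] <- ctrl[1, ] + 0.20 + eps(); t2[1, ] <- ctrl[1, ] + 0.20 + eps()
  # +5-point shift: significant but below the 10-point filter
  t1[2, ] <- ctrl[2, ] + 0.05 + eps(); t2[2, ] <- ctrl[2, ] + 0.05 + eps()
  # opposite directions: excluded by the same-sign rule
  t1[3, ] <- ctrl[3, ] + 0.20 + eps(); t2[3, ] <- ctrl[3, ] - 0.20 + eps()
  ps <- pool_shift_test(ctrl, t1, t2)
  r <- ps$results; rownames(r) <- r$protein_id
  expect_true(r["P01", "hit"])
  expect_false(r["P02", "hit"])
  expect_false(r["P03", "hit"])
  expect_lte(sum(r$hit), 2)
  # no-change proteins carry p near 1 region, never hits
  expect_false(any(r$hit[4:10]))
})

test_that("proteins without complete treatment pools are excluded", {
  ids <- sprintf("P%02d", 1:30)
  ctrl <- matrix(0.3, 30, 3, dimnames = list(ids, NULL))
  t1 <- ctrl; t2 <- ctrl
  t1[1, 2] <- NA; t2[1, ] <- NA   # P01 has no complete treatment
  ps <- pool_shift_test(ctrl, t1, t2)
  expect_false("P01" %in% ps$results$protein_id)
})

test_that("organelle shift test computes Q, distance and magnitude bins", {
  ids <- sprintf("P%02d", 1:12)
  mk <- stats::setNames(rep(c("ER", "vacuole"), each = 6), ids)
  base_er <- c(0.14, 0.36, 0.26, 0.12, 0.07, 0.05)
  base_vac <- c(0.07, 0.13, 0.22, 0.30, 0.18, 0.10)
  mk_profiles <- function(shift, jitter_seed) {
    set.seed(jitter_seed)
    lapply(1:3, function(r) {
      m <- rbind(
        t(vapply(1:6, function(i) base_er + shift, numeric(6))),
        t(vapply(1:6, function(i) base_vac, numeric(6))))
      m <- m + stats::rnorm(length(m), 0, 0.002)
      m <- m / rowSums(m)
      rownames(m) <- ids
      m
    })
  }
  ctrl <- mk_profiles(rep(0, 6), 31)
  # displace ER by a large profile shift, leave vacuole untouched
  trt <- mk_profiles(c(0.12, -0.20, 0.02, 0.02, 0.02, 0.02), 32)
  os <- organelle_shift_test(ctrl, trt, mk)
  r <- os$results; rownames(r) <- r$organelle
  expect_true(r["ER", "shifted"])
  expect_false(r["vacuole", "shifted"])
  expect_equal(r["ER", "magnitude"], "large")  # L1 = 0.4
  expect_equal(r["vacuole", "magnitude"], "negligible")
  # identical conditions: distance ~ 0, not shifted
  os0 <- organelle_shift_test(ctrl, ctrl, mk)
  expect_false(any(os0$results$shifted))
  # the x6 correction is applied to the smallest datapoint p-value
  avg_c <- t(vapply(ctrl, function(m) colMeans(m[1:6, ]), numeric(6)))
  avg_t <- t(vapply(trt, function(m) colMeans(m[1:6, ]), numeric(6)))
  p6 <- vapply(1:6, function(j) doms:::paired_t_p(avg_t[, j], avg_c[, j]),
               numeric(1))
  expect_equal(r["ER", "Q"], min(1, 6 * min(p6)), tolerance = 1e-12)
})

test_that("extreme average profiles reach the maximal distance bin", {
  ids <- sprintf("P%02d", 1:10)
  mk <- stats::setNames(rep("Golgi", 10), ids)
  a <- c(1, 0, 0, 0, 0, 0); b <- c(0, 1, 0, 0, 0, 0)
  jitter <- function(p, s) {
    set.seed(s)
    m <- t(vapply(1:10, function(i) abs(p + stats::rnorm(6, 0, 1e-4)),
                  numeric(6)))
    m <- m / rowSums(m); rownames(m) <- ids; m
  }
  ctrl <- lapply(1:3, function(r) jitter(a, r))
  trt <- lapply(1:3, function(r) jitter(b, r + 10))
  os <- organelle_shift_test(ctrl, trt, mk)
  expect_equal(os$results$distance, 2, tolerance = 1e-3)
  expect_equal(os$results$magnitude, "large")
})

test_that("lumenal and post-ER annotation filters follow the topology rules", {
  ann <- data.frame(
    protein_id = c("L1", "M1", "G1", "E1", "T1", "C1"),
    category = c("ER", "ER", "Golgi", "ER", "Golgi", "cytosol"),
    n_tm_domains = c(0L, 1L, 1L, 0L, 2L, 0L),
    has_signal_peptide = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    has_transit_peptide = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    molecular_weight = 5e4, stringsAsFactors = FALSE)
  expect_equal(classify_lumenal_er(ann), "L1")   # SP, no TM, ER only
  post <- classify_post_er(ann)
  expect_true("G1" %in% post)                    # Golgi, 1 TM, no transit
  expect_false("T1" %in% post)                   # transit peptide
  expect_false("M1" %in% post)                   # ER is not post-ER
  expect_false("C1" %in% post)                   # no SP/TM
})

test_that("ER-shift screen flags planted movers and only them", {
  sim <- cached("er_sim", function() simulate_experiment(
    simulation_config(n_proteins = 500, n_relocalizers = 15,
                      alpha_shift_sizes = 0.9,
                      reloc_from = c("vacuole", "Golgi"),
                      reloc_to = "ER", n_abundance_changers = 0,
                      seed = 33)))
  ann <- synthetic_annotations(sim)
  mr <- mr_analysis(sim$table, "control", "DTT")
  markers <- stats::setNames(sim$truth$compartment, sim$truth$protein_id)
  er_ids <- names(markers)[markers == "ER"]
  mr_hits <- stats::setNames(mr$results$hit, mr$results$protein_id)
  post <- classify_post_er(ann)
  er <- er_shift_candidates(mr$profiles$control, mr$profiles$treatment,
                            er_ids, mr_hits, post)
  r <- er$results
  planted <- sim$truth$protein_id[sim$truth$relocalizer]
  in_universe <- planted[planted %in% r$protein_id]
  expect_gte(mean(in_universe %in% r$protein_id[r$candidate]), 0.9)
  expect_lte(sum(!r$protein_id[r$candidate] %in% planted), 1)
  # an unshifted ER-resident protein has delta correl ~ 0, no candidacy
  er_resident <- intersect(er_ids, r$protein_id)
  expect_lt(max(abs(r$delta_correl_er[r$protein_id %in% er_resident])),
            0.2)
  expect_false(any(r$candidate[r$protein_id %in% er_resident]))
})
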