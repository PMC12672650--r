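test_that("imputation draws from the down-shifted normal and is seeded", {
  m <- matrix(stats::rnorm(40, 20, 1), 20, 2)
  expect_identical(impute_missing(m, seed = 1), m)   # nothing to impute
  set.seed(99)
  big <- matrix(stats::rnorm(2e4, 20, 1), ncol = 2)
  big[sample(length(big), 1e4)] <- NA
  done <- impute_missing(big, downshift = 1.8, width = 0.3, seed = 4)
  expect_false(anyNA(done))
  obs_mask <- !is.na(big)
  expect_identical(done[obs_mask], big[obs_mask])
  imputed <- done[!obs_mask]
  # observed column stats are ~N(20, 1): imputed ~ N(18.2, 0.3^2)
  n_imp <- length(imputed)
  expect_lt(abs(mean(imputed) - 18.2), 0.1 + 3 * 0.3 / sqrt(n_imp))
  expect_lt(abs(stats::sd(imputed) - 0.3), 0.05)
  expect_identical(done, impute_missing(big, 1.8, 0.3, seed = 4))
  expect_error(impute_missing(matrix(NA_real_, 3, 1), seed = 1),
               "observed")
})

test_that("volcano t statistics match the closed-form oracle", {
  a <- matrix(c(1, 2, 3), 1); b <- matrix(c(4, 5, 6), 1)
  ref <- stats::t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  v <- volcano_test(rbind(a, a + 10), rbind(b, b), s0 = 0.1, seed = 1)
  expect_equal(v$results$p_value[1], ref$p.value, tolerance = 1e-10)
  expect_equal(abs(unname(ref$statistic)), 3.674, tolerance = 1e-3)
  expect_equal(v$results$log2_fc[1], -3)
})

test_that("identical groups yield no volcano hits", {
  set.seed(6)
  m <- matrix(stats::rnorm(300, 20), ncol = 3)
  v <- volcano_test(m, m + stats::rnorm(300, 0, 1e-9), s0 = 0.1, seed = 1)
  expect_equal(sum(v$results$significant), 0)
})

test_that("raising s0 never increases the modified statistic", {
  set.seed(7)
  a <- matrix(stats::rnorm(60, 21), ncol = 3)
  b <- matrix(stats::rnorm(60, 20), ncol = 3)
  t1 <- abs(doms:::modified_t(a, b, 0.1))
  t2 <- abs(doms:::modified_t(a, b, 0.5))
  expect_true(all(t2 <= t1 + 1e-12))
})

test_that("volcano hit rate respects the permutation FDR on planted changes", {
  sim <- sim_small()
  tab <- sim$table
  g <- function(cond) log2(tab$intensity[
    , paste(cond, 1:3, "full_proteome", sep = "_")])
  a <- g("DTT"); b <- g("control")
  keep <- rowSums(!is.na(a)) >= 3 | rowSums(!is.na(b)) >= 3
  m <- impute_missing(cbind(a, b)[keep, ], seed = 9)
  v <- volcano_test(m[, 1:3], m[, 4:6], s0 = 0.1, fdr = 0.05, seed = 2)
  changed <- sim$truth$protein_id[sim$truth$abundance_log2fc != 0]
  hits <- rownames(v$results)[v$results$significant]
  expect_gte(mean(changed %in% hits), 0.9)       # |log2fc| >= 1 planted
  expect_lte(mean(!hits %in% changed), 0.15)
})

test_that("shared and unique hits are partitioned with sign concordance", {
  r <- function(fc, sig) structure(list(results = data.frame(
    log2_fc = fc, p_value = 0.5, modified_t = 0, significant = sig,
    row.names = paste0("P", seq_along(fc)))), class = "doms_volcano")
  va <- r(c(1, 2, -1, 0.5), c(TRUE, TRUE, TRUE, FALSE))
  vb <- r(c(2, 1, 1, 0.5), c(TRUE, TRUE, FALSE, TRUE))
  s <- shared_unique_hits(va, vb)
  expect_setequal(s$shared, c("P1", "P2"))
  expect_setequal(s$unique_a, "P3")
  expect_setequal(s$unique_b, "P4")
  expect_equal(s$shared_concordance, 1)
  none <- shared_unique_hits(r(1, FALSE), r(1, FALSE))
  expect_length(none$shared, 0)
  same <- shared_unique_hits(va, va)
  expect_equal(same$shared_concordance, 1)
})

test_that("ploidy, genome mass and concentration reproduce the yeast anchors", {
  expect_equal(round(estimate_ploidy(0.022, 0.013), 1), 1.7)
  expect_equal(estimate_ploidy(0.013, 0.013), 1)
  expect_equal(estimate_ploidy(0.026, 0.013), 2)
  expect_error(estimate_ploidy(0, 0.013), "positive")
  expect_equal(signif(genome_mass(12.1e6), 2), 0.013)
  expect_equal(genome_mass(0), 0)
  expect_equal(genome_mass(2e6), 2 * genome_mass(1e6))
  expect_equal(interpolate_concentration(1)$value, 94)
  expect_equal(interpolate_concentration(2)$value, 79)
  expect_equal(interpolate_concentration(1.7)$reported, 83)
  expect_warning(conc <- interpolate_concentration(2.5), "extrapolating")
})

test_that("proteomic ruler reproduces hand-computed copy numbers", {
  # two proteins: histone I=1 MW=1e4, other I=9 MW=1e5, DNA 0.013 pg.
  # total mass M = 0.013e-12 * 10 g; scale = M*NA/10;
  # copies = I/MW * scale
  avogadro <- 6.02214076e23
  M <- 0.013e-12 * 10
  expected_h <- (1 / 1e4) * M * avogadro / 10
  expected_o <- (9 / 1e5) * M * avogadro / 10
  r <- proteomic_ruler(c(h = 1, o = 9), c(h = 1e4, o = 1e5), "h",
                       dna_pg = 0.013, conc_gl = 83)
  expect_equal(r$results["h", "copies_per_cell"], expected_h,
               tolerance = 1e-12)
  expect_equal(r$results["o", "copies_per_cell"], expected_o,
               tolerance = 1e-12)
  # summed protein mass per cell equals the ruler total
  total <- sum(r$results$copies_per_cell * c(1e4, 1e5)) / avogadro
  expect_equal(total, M, tolerance = 1e-6 * M)
  # scale invariance of copies
  r2 <- proteomic_ruler(c(h = 7, o = 63), c(h = 1e4, o = 1e5), "h",
                        dna_pg = 0.013, conc_gl = 83)
  expect_equal(r2$results$copies_per_cell, r$results$copies_per_cell,
               tolerance = 1e-12)
  # one histone carrying all intensity: total mass = DNA mass
  r3 <- proteomic_ruler(c(h = 5), c(h = 2e4), "h", dna_pg = 0.022)
  expect_equal(r3$total_protein_pg, 0.022, tolerance = 1e-12)
  expect_error(proteomic_ruler(c(a = 1), c(a = 1e4), "h"), "histone")
})
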