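test_that("confidence tiers apply strict thresholds", {
  expect_equal(confidence_tier(0.96), "very_high")
  expect_equal(confidence_tier(0.95), "high")       # strict >
  expect_equal(confidence_tier(0.66), "medium")
  expect_equal(confidence_tier(0.40), "best_guess") # boundary, strict >
  expect_equal(confidence_tier(0.41), "low")
  expect_equal(confidence_tier(c(0, 1)), c("best_guess", "very_high"))
  expect_error(confidence_tier(1.2))
})

test_that("SVM training is separable-exact and seed-deterministic", {
  set.seed(10)
  x <- rbind(matrix(stats::rnorm(180, 0, 0.05), ncol = 6),
             matrix(stats::rnorm(180, 1, 0.05), ncol = 6))
  rownames(x) <- paste0("P", 1:60)
  markers <- stats::setNames(rep(c("ER", "Golgi"), each = 30),
                             rownames(x))
  fit1 <- train_svm(x, markers, seed = 2)
  expect_equal(fit1$cv_accuracy, 1)
  fit2 <- train_svm(x, markers, seed = 2)
  expect_equal(c(fit1$cost, fit1$gamma), c(fit2$cost, fit2$gamma))
  # hyperparameters stay inside the searched ranges
  expect_true(fit1$cost >= 1 && fit1$cost <= 30)
  expect_true(fit1$gamma >= 1 && fit1$gamma <= 50)
  # classes with < 5 markers are excluded with a warning
  small <- c(markers, stats::setNames(rep("vacuole", 3), paste0("V", 1:3)))
  xs <- rbind(x, matrix(stats::rnorm(18, 2, 0.05), ncol = 6,
                        dimnames = list(paste0("V", 1:3), NULL)))
  expect_warning(fit3 <- train_svm(xs, small, seed = 2), "too few")
  expect_false("vacuole" %in% fit3$classes)
})

test_that("classification scores sum to one and argmax sets the class", {
  profiles <- map_profiles_cached()
  sim <- sim_map()
  markers <- stats::setNames(sim$truth$compartment, sim$truth$protein_id)
  markers <- markers[names(markers) %in% rownames(profiles)]
  fit <- train_svm(profiles, markers, seed = 3)
  cls <- classify_profiles(fit, profiles)
  expect_equal(unname(rowSums(cls$scores)), rep(1, nrow(cls$scores)),
               tolerance = 1e-6)
  top <- colnames(cls$scores)[apply(cls$scores, 1, which.max)]
  expect_identical(cls$results$assigned_class, top)
  expect_true(all(cls$results$tier %in%
                    c("very_high", "high", "medium", "low", "best_guess")))
})

test_that("iterative marker training converges and is idempotent", {
  profiles <- map_profiles_cached()
  sim <- sim_map()
  truth <- stats::setNames(sim$truth$compartment, sim$truth$protein_id)
  reference <- truth[names(truth) %in% rownames(profiles)]
  # start from a third of each class
  set.seed(11)
  init <- unlist(lapply(split(names(reference), reference), function(ids)
    stats::setNames(reference[ids[seq_len(ceiling(length(ids) / 3))]],
                    ids[seq_len(ceiling(length(ids) / 3))])))
  names(init) <- sub("^[^.]+\\.", "", names(init))
  res <- iterate_marker_training(init, profiles, reference, seed = 4)
  expect_equal(res$audit$recall[nrow(res$audit)], 1)
  expect_gte(length(res$markers), length(init))
  # markers that were correctly labeled initially remain in the final set
  correct_init <- names(init)[init == reference[names(init)]]
  expect_true(all(correct_init %in% names(res$markers)))
  # rerunning on its own output adds nothing
  res2 <- iterate_marker_training(res$markers, profiles, reference,
                                  seed = 4)
  expect_setequal(names(res2$markers), names(res$markers))
  expect_equal(res2$rounds, 1)
})

test_that("deliberately mislabeled proteins never enter the marker set", {
  profiles <- map_profiles_cached()
  sim <- sim_map()
  truth <- stats::setNames(sim$truth$compartment, sim$truth$protein_id)
  reference <- truth[names(truth) %in% rownames(profiles)]
  # mislabel every ribosome protein as nucleus in the reference
  poisoned <- reference
  poisoned[poisoned == "ribosome"] <- "nucleus"
  init <- reference[reference != "ribosome"]
  init <- unlist(lapply(split(names(init), init[names(init)]),
                        function(ids) init[ids[1:10]]))
  names(init) <- sub("^[^.]+\\.", "", names(init))
  res <- iterate_marker_training(init, profiles, poisoned, seed = 4)
  ribo <- names(reference)[reference == "ribosome"]
  expect_false(any(ribo %in% names(res$markers)))
})

test_that("F1 matches the confusion-table formula and flags random guessing", {
  pred <- c(rep("a", 8), rep("b", 2), rep("b", 7), rep("a", 3))
  truth <- c(rep("a", 10), rep("b", 10))
  f1 <- doms:::f1_by_class(pred, truth, c("a", "b"))
  # class a: tp=8 fp=3 fn=2 -> F1 = 16/(16+3+2)
  expect_equal(unname(f1["a"]), 16 / 21, tolerance = 1e-12)
  expect_equal(unname(f1["b"]), 14 / (14 + 2 + 3), tolerance = 1e-12)
  # random guesses over k balanced classes give F1 near 1/k
  set.seed(12)
  k <- 4; n <- 4000
  tr <- sample(letters[1:k], n, replace = TRUE)
  pr <- sample(letters[1:k], n, replace = TRUE)
  f1r <- doms:::f1_by_class(pr, tr, letters[1:k])
  expect_true(all(abs(f1r - 1 / k) < 0.05))
})

test_that("benchmark reaches full marks on separable simulated markers", {
  profiles <- map_profiles_cached()
  sim <- sim_map()
  markers <- stats::setNames(sim$truth$compartment, sim$truth$protein_id)
  markers <- markers[names(markers) %in% rownames(profiles)]
  bm <- benchmark_f1(profiles, markers, seed = 6)
  expect_gte(bm$macro_f1, 0.95)
  expect_false(any(c("lipid droplets", "peroxisomes") %in% names(bm$f1)))
})

test_that("reference agreement pools categories and honors cytosolic pools", {
  pred <- c(A = "vacuole", B = "cytosol", C = "ER", D = "nucleus")
  ref <- c(A = "endosomes", B = "nucleus", C = "ER", D = "COPI")
  pools <- c(B = 0.45)
  agr <- agreement_with_reference(pred, ref, pools)
  # D is dropped (COPI not matchable); A matches via pooling,
  # B via the dual-localization rule, C directly
  expect_equal(nrow(agr$table), 3)
  expect_equal(agr$agreement, 1)
  agr2 <- agreement_with_reference(pred, ref, c(B = 0.1))
  expect_equal(agr2$agreement, 2 / 3)
  same <- agreement_with_reference(c(X = "ER"), c(X = "ER"))
  expect_equal(same$agreement, 1)
})

test_that("neighborhood ranks by correlation distance", {
  profiles <- map_profiles_cached()
  sim <- sim_map()
  truth <- stats::setNames(sim$truth$compartment, sim$truth$protein_id)
  # a duplicated profile is the closest neighbor at distance ~0
  m <- rbind(profiles, dup = profiles[1, ])
  nb <- neighborhood(rownames(profiles)[1], m, k = 1)
  expect_equal(nb$protein_id[1], "dup")
  expect_lt(nb$distance[1], 1e-12)
  # k larger than the universe returns everyone, ordered
  small <- profiles[1:5, ]
  nb2 <- neighborhood(rownames(small)[1], small, k = 100)
  expect_equal(nrow(nb2), 4)
  expect_true(all(diff(nb2$distance) >= 0))
  expect_error(neighborhood("nope", profiles), "unknown")
  # neighbors of an ER protein are ER proteins
  er_id <- names(truth)[truth == "ER" & names(truth) %in%
                          rownames(profiles)][1]
  nb3 <- neighborhood(er_id, profiles, k = 10)
  expect_gte(mean(truth[nb3$protein_id] == "ER"), 0.9)
})
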