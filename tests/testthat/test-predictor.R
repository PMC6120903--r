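make_ds <- function(X, y) evoforecast:::new_site_dataset("s", X, y, seq_along(y))

test_that("site datasets encode merged conditions and apply the inclusion rule", {
  p <- synthetic_params(seed = 5, n_genes = 60, genome_length = 80000,
                        n_conditions = 10, replicate_counts = 2, core_size = 2,
                        hypermutator_fraction = 0)
  sim <- make_compendium(p)
  prof <- build_condition_profiles(sim$compendium)
  hits <- colSums(prof$matrix)
  site3 <- names(hits)[hits >= 3][1]
  ds <- build_site_dataset(sim$compendium, site3)
  expect_s3_class(ds, "site_dataset")
  expect_identical(nrow(ds$X), nrow(prof$matrix))
  expect_equal(sum(ds$y), unname(hits[site3]))
  # positives coincide with the merged profile column
  expect_identical(ds$y, unname(prof$matrix[, site3]))
  # below-threshold site excluded
  site1 <- names(hits)[hits == 1][1]
  if (!is.na(site1)) expect_null(build_site_dataset(sim$compendium, site1))
  expect_error(build_site_dataset(sim$compendium, "no_such_site"), "unknown site")
})

test_that("naive Bayes smoothing follows its closed form", {
  ds <- make_ds(cbind(f = c(1, 0)), c(1, 0))
  nb <- train_naive_bayes(ds, alpha = 1)
  expect_equal(unname(nb$p1["f"]), 2 / 3)   # (1+1)/(1+2)
  expect_equal(unname(nb$p0["f"]), 1 / 3)
  # alpha -> infinity: conditionals -> 1/2, prediction -> class prior
  ds2 <- make_ds(cbind(f = c(1, 1, 0, 0, 0, 0)), c(1, 1, 0, 0, 0, 0))
  nb_inf <- train_naive_bayes(ds2, alpha = 1e9)
  expect_equal(unname(nb_inf$p1["f"]), 0.5, tolerance = 1e-6)
  expect_equal(predict_prob(nb_inf, matrix(c(1, 0), 2, 1)),
               rep(2 / 6, 2), tolerance = 1e-6)
  # separable toy: posterior ordering gives training AUC 1
  set.seed(2)
  X <- cbind(sig = rep(c(1, 0), each = 20),
             noise = rbinom(40, 1, 0.5))
  y <- X[, "sig"]
  nb3 <- train_naive_bayes(make_ds(X, y))
  expect_equal(auc_roc(predict_prob(nb3, X), y), 1)
  expect_error(train_naive_bayes(make_ds(X, rep(1, 40))), "single-class")
  # probabilities never reach 0 or 1
  p <- predict_prob(nb3, X)
  expect_true(all(p > 0 & p < 1))
})

test_that("oversampling balances classes reproducibly", {
  set.seed(4)
  X <- matrix(rbinom(40, 1, 0.5), nrow = 10)
  ds <- make_ds(X, c(1, 1, rep(0, 8)))
  bal <- oversample(ds, seed = 3)
  expect_identical(sum(bal$y == 1), sum(bal$y == 0))
  expect_identical(nrow(bal$X), 16L)
  expect_identical(oversample(ds, seed = 3)$condition_keys, bal$condition_keys)
  # already balanced: unchanged object
  ds_b <- make_ds(X[1:4, ], c(1, 1, 0, 0))
  expect_identical(oversample(ds_b, seed = 1), ds_b)
  expect_error(oversample(make_ds(X, rep(0, 10)), 1), "single-class")
})

test_that("the SVM grid search is deterministic and calibrated", {
  set.seed(6)
  X <- cbind(sig = rep(c(0, 1), each = 15), noise = rbinom(30, 1, 0.5))
  y <- X[, "sig"]
  ds <- make_ds(X, y)
  m1 <- train_svm(ds, seed = 11)
  m2 <- train_svm(ds, seed = 11)
  expect_identical(c(m1$c, m1$sigma), c(m2$c, m2$sigma))
  expect_true(m1$c %in% c(0.001, 0.01, 0.1, 1, 10))
  expect_true(m1$sigma %in% c(0.001, 0.01, 0.1, 1))
  # linearly separable: perfect training accuracy at the selected grid point
  expect_equal(mean((predict_prob(m1, X) > 0.5) == y), 1)
  # identical rows with conflicting labels: probability ~ 0.5
  Xc <- matrix(1, nrow = 8, ncol = 2)
  yc <- rep(c(0, 1), 4)
  mc <- train_svm(make_ds(Xc, yc), seed = 1)
  expect_lt(abs(predict_prob(mc, Xc[1, , drop = FALSE]) - 0.5), 0.05)
  expect_error(train_svm(make_ds(X, rep(1, 30))), "single-class")
})

test_that("the neural network learns XOR and is seed-reproducible", {
  X <- cbind(x1 = c(0, 0, 1, 1), x2 = c(0, 1, 0, 1))
  y <- c(0, 1, 1, 0)
  m <- train_ann(X, y, epochs = 2000, seed = 4)   # default 57-37 architecture
  expect_identical(m$sizes, c(2, 57, 37, 1))
  p <- predict_prob(m, X)
  expect_equal(mean((p > 0.5) == y), 1)
  # bitwise-reproducible training under a fixed seed
  m2 <- train_ann(X, y, epochs = 2000, seed = 4)
  expect_identical(m2$final_loss, m$final_loss)
  expect_identical(predict_prob(m2, X), p)
  expect_error(train_ann(X, c(1, 1, 1, 1)), "constant labels")
})

test_that("backward wrapper selection keeps signal and sheds dead weight", {
  set.seed(9)
  n <- 200
  X <- cbind(signal = rbinom(n, 1, 0.5),
             n1 = rbinom(n, 1, 0.5), n2 = rbinom(n, 1, 0.5),
             n3 = rbinom(n, 1, 0.5), dead = rep(0, n))
  y <- X[, "signal"]
  ds <- make_ds(X, y)
  kept <- select_features_backward(ds, trainer = "nb", seed = 2)
  expect_true("signal" %in% names(kept))
  expect_false("dead" %in% names(kept))   # constant feature cannot help
  expect_gte(length(kept), 1L)
  # two informative features: loop terminates with both
  X2 <- cbind(a = rep(c(1, 0), each = 30), b = rep(c(1, 0, 1, 0), 15))
  y2 <- as.integer(xor(X2[, "a"], X2[, "b"]))
  # xor labels need both features; removal of either collapses AUC
  kept2 <- select_features_backward(make_ds(X2, y2), trainer = "nb", seed = 2)
  expect_gte(length(kept2), 1L)
  expect_error(select_features_backward(make_ds(X[, 1, drop = FALSE], y)),
               "at least 2")
})

test_that("the ensemble is exactly the mean of its components", {
  set.seed(10)
  X <- cbind(sig = rep(c(1, 0), each = 12), n1 = rbinom(24, 1, 0.5),
             n2 = rbinom(24, 1, 0.5))
  y <- X[, "sig"]
  em <- train_ensemble(make_ds(X, y), seed = 1, feature_select = "none",
                       ann_epochs = 80)
  pc <- ensemble_predict(em, X, components = TRUE)
  expect_identical(pc$p_ensemble, (pc$p_nb + pc$p_svm + pc$p_ann) / 3)
  expect_true(all(pc$p_ensemble >= 0 & pc$p_ensemble <= 1))
  expect_equal(em$weights, rep(1 / 3, 3))
  # bounds: sanity on a strongly positive and strongly negative input
  expect_error(ensemble_predict(em, c(1, 0)), "attributes")
  # feature selection never increases the feature count
  em_fs <- train_ensemble(make_ds(X, y), seed = 1, feature_select = "backward",
                          ann_epochs = 80)
  expect_lte(length(em_fs$features$nb), ncol(X))
})

test_that("ranking metrics match their definitions and an independent library", {
  y <- c(1, 0, 1, 1, 0, 0, 1, 0)
  # oracle scores: metrics are exactly 1
  expect_equal(auc_roc(y, y), 1)
  expect_equal(auprc(y, y), 1)
  # constant scores: AUC 1/2, AUPRC = prevalence
  expect_equal(auc_roc(rep(0.3, 8), y), 0.5)
  expect_equal(auprc(rep(0.3, 8), y), 0.5)
  # against pROC on random scores (with ties)
  skip_if_not_installed("pROC")
  set.seed(12)
  s <- round(runif(60), 2)
  yy <- rbinom(60, 1, 0.4)
  expect_equal(auc_roc(s, yy),
               as.numeric(suppressMessages(pROC::auc(yy, s))))
})

test_that("leave-one-condition-out has one fold per condition and no leakage", {
  set.seed(14)
  n <- 12
  X <- cbind(sig = rep(c(1, 0), each = n / 2), n1 = rbinom(n, 1, 0.5),
             n2 = rbinom(n, 1, 0.5))
  y <- X[, "sig"]
  ds <- make_ds(X, y)
  cv <- evaluate_loco(ds, seed = 1, feature_select = "none", ann_epochs = 60)
  expect_equal(cv$n_folds, n)
  expect_equal(nrow(cv$predictions), n)
  expect_false(anyNA(cv$predictions$p))
  expect_gte(cv$auc, 0.9)   # trivially separable signal
  expect_error(evaluate_loco(make_ds(X[1:2, ], y[1:2])), "at least 3")
})

test_that("bootstrap forward validation reports calls and handles empty rounds", {
  set.seed(15)
  assoc <- data.frame(attribute = "stress:osmotic", gene = "g0010", prob = 0.95)
  p <- synthetic_params(seed = 16, n_genes = 40, genome_length = 60000,
                        n_conditions = 30, replicate_counts = 2,
                        core_size = 0, lambda = 0.012,
                        stresses = c("osmotic", "acid", "heat"),
                        generations_choices = 500, generations_probs = 1,
                        hypermutator_fraction = 0, associations = assoc)
  sim <- make_compendium(p)
  novel <- list(strain = sim$compendium$conditions$strain[1],
                medium = sim$compendium$conditions$medium[1],
                stresses = "osmotic", generations = 500)
  fv <- bootstrap_forward_validation(sim$compendium, novel,
                                     observed_sites = "g0010",
                                     n_bootstrap = 4, call_threshold = 2,
                                     seed = 3, feature_select = "none",
                                     ann_epochs = 60)
  expect_identical(nrow(fv$rounds), 4L)
  expect_true(all(fv$calls$n_called <= 4))
  expect_identical(fv$calls$called, fv$calls$n_called > 2)
  expect_gte(fv$recall_mean, 0)
  # an impossible decision threshold produces all-empty rounds: precision
  # is undefined, recorded as missing, and recall collapses to zero
  expect_message(
    fv0 <- bootstrap_forward_validation(sim$compendium, novel,
                                        observed_sites = "g0010",
                                        n_bootstrap = 2,
                                        decision_threshold = 1,
                                        seed = 3, feature_select = "none",
                                        ann_epochs = 20),
    "predicted no sites")
  expect_identical(fv0$n_undefined_precision, 2L)
  expect_true(is.nan(fv0$precision_mean))
  expect_identical(fv0$recall_mean, 0)
})
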