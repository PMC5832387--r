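test_that("train/test split is disjoint, sized and reproducible", {
  set.seed(41)
  y <- random_assoc(10, 4, density = 0.5)
  x <- matrix(rnorm(40), 10, 4, dimnames = list(rownames(y), paste0("f", 1:4)))
  spl <- split_train_test(y, x, seed = 3)
  expect_equal(length(spl$train$drug_ids), 8L)
  expect_equal(length(spl$test$drug_ids), 2L)
  expect_length(intersect(spl$train$drug_ids, spl$test$drug_ids), 0L)
  expect_setequal(c(spl$train$drug_ids, spl$test$drug_ids), rownames(y))
  spl2 <- split_train_test(y, x, seed = 3)
  expect_identical(spl$train$drug_ids, spl2$train$drug_ids)
  expect_error(split_train_test(y[1:4, ], x[1:4, ], seed = 1), "at least 5")
  expect_error(split_train_test(y, x[c(2:10, 1), ][, ], seed = 1), NA)
  rownames(x)[1] <- "other"
  expect_error(split_train_test(y, x, seed = 1), "different drugs")
})

test_that("every drug lands in the test set about 20% of the time", {
  y <- random_assoc(50, 3, density = 0.5)
  x <- matrix(rnorm(150), 50, 3, dimnames = list(rownames(y), paste0("f", 1:3)))
  hits <- setNames(numeric(50), rownames(y))
  n_seeds <- 50
  for (s in seq_len(n_seeds)) {
    spl <- split_train_test(y, x, seed = s)
    hits[spl$test$drug_ids] <- hits[spl$test$drug_ids] + 1
  }
  freq <- hits / n_seeds
  expect_true(all(freq > 0.2 - 0.18 & freq < 0.2 + 0.18))
  expect_equal(mean(freq), 0.2, tolerance = 1e-9)
})

test_that("every classifier separates an easy two-cluster problem", {
  b <- separable_bundle(n_per_class = 20, shift = 8)
  spl_idx <- c(seq(1, 40, by = 4))
  test <- list(x = b$x[spl_idx, , drop = FALSE],
               y = b$y[spl_idx, , drop = FALSE],
               drug_ids = b$drug_ids[spl_idx])
  train <- list(x = b$x[-spl_idx, , drop = FALSE],
                y = b$y[-spl_idx, , drop = FALSE],
                drug_ids = b$drug_ids[-spl_idx])
  for (nm in c("logreg_l2", "svm_rbf", "knn", "gaussian_nb",
               "random_forest")) {
    ps <- fit_predict_ovr(classifier_spec(nm), train, test, seed = 1)
    expect_equal(unname(ps$predictions[, 1]), unname(test$y[, 1]),
                 info = nm)
    expect_true(all(ps$scores >= 0 & ps$scores <= 1), info = nm)
  }
})

test_that("degenerate labels are skipped with reasons", {
  b <- separable_bundle()
  y <- cbind(b$y, allpos = 1L, onepos = c(1L, rep(0L, nrow(b$y) - 1)))
  train <- list(x = b$x[1:30, ], y = y[1:30, ], drug_ids = b$drug_ids[1:30])
  test <- list(x = b$x[31:40, ], y = y[31:40, ], drug_ids = b$drug_ids[31:40])
  ps <- fit_predict_ovr(classifier_spec("logreg_l2"), train, test, seed = 1)
  expect_setequal(ps$skipped_labels$label, c("allpos", "onepos"))
  expect_equal(ps$skipped_labels$reason[ps$skipped_labels$label == "allpos"],
               "single-class")
  expect_false("allpos" %in% ps$label_ids)
  # all labels degenerate is an error
  train_bad <- list(x = train$x, y = y[1:30, 2:3], drug_ids = train$drug_ids)
  expect_error(fit_predict_ovr(classifier_spec("logreg_l2"), train_bad,
                               test, seed = 1), "zero evaluable")
})

test_that("soft voting averages member probabilities", {
  b <- separable_bundle()
  train <- list(x = b$x[1:30, ], y = b$y[1:30, , drop = FALSE],
                drug_ids = b$drug_ids[1:30])
  test <- list(x = b$x[31:40, ], y = b$y[31:40, , drop = FALSE],
               drug_ids = b$drug_ids[31:40])
  members <- list(classifier_spec("logreg_l2"), classifier_spec("knn"),
                  classifier_spec("gaussian_nb"))
  ens <- classifier_spec("voting_ensemble", members = members)
  ps_ens <- fit_predict_ovr(ens, train, test, seed = 5)
  member_scores <- lapply(members, function(m)
    fit_predict_ovr(m, train, test, seed = 5)$scores)
  expect_equal(ps_ens$scores, Reduce(`+`, member_scores) / 3,
               tolerance = 1e-12)
  # identical members: the ensemble reproduces the member exactly
  twin <- classifier_spec("voting_ensemble",
                          members = list(classifier_spec("logreg_l2"),
                                         classifier_spec("logreg_l2")))
  ps_twin <- fit_predict_ovr(twin, train, test, seed = 5)
  ps_single <- fit_predict_ovr(classifier_spec("logreg_l2"), train, test,
                               seed = 5)
  expect_equal(ps_twin$scores, ps_single$scores, tolerance = 1e-12)
  expect_error(classifier_spec("voting_ensemble",
                               members = list(classifier_spec("knn"))),
               "at least 2")
})

test_that("the ovr_model object predicts like fit_predict_ovr", {
  b <- separable_bundle()
  train <- list(x = b$x[1:30, ], y = b$y[1:30, , drop = FALSE],
                drug_ids = b$drug_ids[1:30])
  test_x <- b$x[31:40, ]
  fit <- ovr_fit(train$x, train$y, classifier_spec("logreg_l2"), seed = 2)
  expect_s3_class(fit, "ovr_model")
  sc <- predict(fit, test_x, type = "prob")
  expect_equal(dim(sc), c(10L, 1L))
  cls <- predict(fit, test_x, type = "class")
  expect_true(all(cls %in% 0:1))
  ps <- predict(fit, test_x, type = "prediction_set")
  expect_s3_class(ps, "prediction_set")
  expect_equal(ps$scores, sc)
  expect_output(print(fit), "One-vs-rest")
})

test_that("fold sizes are near-equal and k = n reduces to LOOCV", {
  folds <- adrhier:::fold_assignment(sprintf("d%03d", 1:103), 5, seed = 1)
  expect_equal(sort(unname(lengths(folds)), decreasing = TRUE),
               c(21L, 21L, 21L, 20L, 20L))
  expect_setequal(unlist(folds), sprintf("d%03d", 1:103))

  set.seed(43)
  n <- 12
  x <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(sprintf("d%02d", 1:n), paste0("f", 1:3)))
  y <- matrix(rbinom(n * 2, 1, 0.5), n, 2,
              dimnames = list(rownames(x), c("a", "b")))
  bundle <- list(x = x, y = y, drug_ids = rownames(x))
  cv_n <- cross_validate(classifier_spec("logreg_l2"), bundle, k = n,
                         seed = 7)
  lo <- loocv(classifier_spec("logreg_l2"), bundle, seed = 7)
  expect_equal(cv_n$scheme, "loocv")
  expect_equal(cv_n$mean_report$auc, lo$mean_report$auc)
})

test_that("LOOCV pools held-out scores before computing metrics", {
  # micro-fixture: verify pooled AUC against a hand-refit pooled oracle
  set.seed(44)
  n <- 8
  x <- matrix(rnorm(n * 2), n, 2,
              dimnames = list(sprintf("d%d", 1:n), c("f1", "f2")))
  y <- matrix(c(rep(1L, 4), rep(0L, 4)), n, 1,
              dimnames = list(rownames(x), "lab"))
  bundle <- list(x = x, y = y, drug_ids = rownames(x))
  spec <- classifier_spec("knn", k = 3)
  lo <- loocv(spec, bundle, seed = 9)
  pooled <- lo$pooled_predictions
  expect_equal(pooled$drug_ids, rownames(x))
  # oracle: refit each fold by hand and pool, then compute AUC directly
  hand_scores <- vapply(seq_len(n), function(i) {
    pred <- class::knn(x[-i, ], x[i, , drop = FALSE],
                       factor(y[-i, 1], levels = c(0, 1)), k = 3,
                       prob = TRUE)
    p <- attr(pred, "prob")
    if (pred == "1") p else 1 - p
  }, 0)
  expect_equal(as.numeric(auc_roc(hand_scores, y[, 1])),
               as.numeric(lo$mean_report$auc))
})

test_that("cross-validation is deterministic under a fixed seed", {
  set.seed(45)
  ds <- generate_dataset(synth_config(n_drugs = 40, n_se = 70,
                                      n_organs = 8, n_subsystems = 4,
                                      n_systems = 2, seed = 46))
  y <- coarse_grain(ds$associations, ds$schema, "system")
  feats <- clean_features(ds$features)
  pcs <- pca_reduce(feats, k = 10)
  bundle <- list(x = pcs$scores, y = y, drug_ids = rownames(y))
  cv1 <- cross_validate(classifier_spec("random_forest", num_trees = 100),
                        bundle, k = 3, seed = 11)
  cv2 <- cross_validate(classifier_spec("random_forest", num_trees = 100),
                        bundle, k = 3, seed = 11)
  expect_identical(cv1$mean_report$weighted_performance,
                   cv2$mean_report$weighted_performance)
  expect_equal(length(cv1$fold_reports), 3L)
})

test_that("training on permuted labels yields chance-level AUC", {
  aucs <- vapply(1:6, function(s) {
    ds <- generate_dataset(synth_config(n_drugs = 80, n_se = 100,
                                        n_organs = 10, n_subsystems = 5,
                                        n_systems = 3, beta = 2,
                                        target_density = 0.05, seed = s))
    y <- coarse_grain(ds$associations, ds$schema, "organ")
    set.seed(s + 500)
    y_perm <- y[sample(nrow(y)), , drop = FALSE]
    rownames(y_perm) <- rownames(y)
    feats <- clean_features(ds$features)
    pcs <- pca_reduce(feats, k = 10)
    spl <- split_train_test(association_matrix(y_perm, "organ"),
                            pcs$scores, seed = s)
    ps <- fit_predict_ovr(classifier_spec("logreg_l2"), spl$train,
                          spl$test, seed = s)
    as.numeric(evaluate_predictions(ps, spl$test$y)$auc)
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.07)
})

test_that("test-set labels never influence training or scores", {
  set.seed(47)
  ds <- generate_dataset(synth_config(n_drugs = 50, n_se = 70,
                                      n_organs = 8, n_subsystems = 4,
                                      n_systems = 2, target_density = 0.06,
                                      seed = 48))
  y <- coarse_grain(ds$associations, ds$schema, "organ")
  pcs <- pca_reduce(clean_features(ds$features), k = 10)
  spl <- split_train_test(y, pcs$scores, seed = 12)
  ps1 <- fit_predict_ovr(classifier_spec("logreg_l2"), spl$train, spl$test,
                         seed = 12)
  # shuffle the held-out labels; scores must be bit-identical
  test2 <- spl$test
  test2$y <- test2$y[sample(nrow(test2$y)), , drop = FALSE]
  rownames(test2$y) <- rownames(spl$test$y)
  ps2 <- fit_predict_ovr(classifier_spec("logreg_l2"), spl$train, test2,
                         seed = 12)
  expect_identical(ps1$scores, ps2$scores)
})

test_that("ensemble and cross-validation track holdout performance", {
  ds <- generate_dataset(synth_config(n_drugs = 80, n_se = 100,
                                      n_organs = 10, n_subsystems = 5,
                                      n_systems = 3, target_density = 0.05,
                                      seed = 49))
  y <- coarse_grain(ds$associations, ds$schema, "organ")
  pcs <- pca_reduce(clean_features(ds$features), k = 10,
                    fit_ids = split_train_test(y, clean_features(ds$features),
                                               seed = 13)$train$drug_ids)
  spl <- split_train_test(y, pcs$scores, seed = 13)
  members <- list(classifier_spec("logreg_l2"), classifier_spec("knn"),
                  classifier_spec("gaussian_nb"))
  wps <- vapply(members, function(m) {
    ps <- fit_predict_ovr(m, spl$train, spl$test, seed = 13)
    as.numeric(evaluate_predictions(ps, spl$test$y)$weighted_performance)
  }, 0)
  ens <- fit_predict_ovr(classifier_spec("voting_ensemble",
                                         members = members),
                         spl$train, spl$test, seed = 13)
  wp_ens <- as.numeric(
    evaluate_predictions(ens, spl$test$y)$weighted_performance)
  # soft voting should not fall materially below its weakest member
  expect_gte(wp_ens, min(wps) - 0.05)

  # training-side CV mean AUC is close to the holdout AUC
  cv <- suppressWarnings(
    cross_validate(classifier_spec("logreg_l2"), spl$train, k = 5,
                   seed = 13))
  hold <- evaluate_predictions(
    fit_predict_ovr(classifier_spec("logreg_l2"), spl$train, spl$test,
                    seed = 13), spl$test$y)
  expect_lt(abs(as.numeric(cv$mean_report$auc) - as.numeric(hold$auc)), 0.1)
})
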