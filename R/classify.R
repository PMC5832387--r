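# One-vs-rest (binary relevance) multi-label classification. Each label
# gets an independent binary classifier; labels with fewer than two
# positives or two negatives in training are skipped and reported. The
# classifier suite mirrors common practice for descriptor-based
# side-effect prediction: L2 logistic regression, RBF SVM, k-nearest
# neighbours, Gaussian naive Bayes, random forest, and a soft-voting
# ensemble averaging member probabilities.

classifier_names <- c("logreg_l2", "svm_rbf", "knn", "gaussian_nb",
                      "random_forest", "voting_ensemble")

default_hyperparams <- list(
  logreg_l2 = list(C = 1),
  svm_rbf = list(cost = 1, gamma = NULL),  # NULL: 1 / (n_features * var(x))
  knn = list(k = 5),
  gaussian_nb = list(),
  random_forest = list(num_trees = 500),
  voting_ensemble = list()
)

#' Describe a classifier
#'
#' @param name one of `"logreg_l2"`, `"svm_rbf"`, `"knn"`,
#'   `"gaussian_nb"`, `"random_forest"`, `"voting_ensemble"`.
#' @param ... hyperparameter overrides (`C` for logistic regression;
#'   `cost`, `gamma` for the SVM; `k` for kNN; `num_trees` for the
#'   forest).
#' @param members for `voting_ensemble`, a list of at least two member
#'   `classifier_spec`s (all members produce probabilities).
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(name, ..., members = NULL) {
  name <- match.arg(name, classifier_names)
  hp <- utils::modifyList(default_hyperparams[[name]], list(...))
  if (name == "voting_ensemble") {
    if (is.null(members) || length(members) < 2L) {
      stop("voting_ensemble needs at least 2 member specs")
    }
    stopifnot(all(vapply(members, inherits, TRUE, "classifier_spec")))
    if (any(vapply(members, function(m) m$name, "") == "voting_ensemble")) {
      stop("nested voting ensembles are not supported")
    }
  }
  structure(list(name = name, hyperparams = hp, members = members),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("Classifier:", x$name)
  if (length(x$hyperparams) > 0L) {
    hp <- x$hyperparams[!vapply(x$hyperparams, is.null, TRUE)]
    if (length(hp) > 0L) {
      cat(" (", paste(names(hp), unlist(hp), sep = "=", collapse = ", "),
          ")", sep = "")
    }
  }
  cat("\n")
  if (!is.null(x$members)) {
    cat("  members:", paste(vapply(x$members, function(m) m$name, ""),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

# fit one binary classifier; returns a function(newx) -> P(class 1)
fit_binary <- function(spec, x, y01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed %% .Machine$integer.max)
  yf <- factor(y01, levels = c(0, 1))
  switch(spec$name,
    logreg_l2 = {
      lambda <- 1 / (nrow(x) * spec$hyperparams$C)
      m <- glmnet::glmnet(x, yf, family = "binomial", alpha = 0,
                          lambda = lambda)
      function(newx) as.numeric(stats::predict(m, newx, type = "response"))
    },
    svm_rbf = {
      gamma <- spec$hyperparams$gamma
      if (is.null(gamma)) gamma <- 1 / (ncol(x) * stats::var(as.vector(x)))
      m <- e1071::svm(x, yf, kernel = "radial", cost = spec$hyperparams$cost,
                      gamma = gamma, probability = TRUE)
      function(newx) {
        attr(stats::predict(m, newx, probability = TRUE),
             "probabilities")[, "1"]
      }
    },
    knn = {
      k <- spec$hyperparams$k
      function(newx) {
        pred <- class::knn(train = x, test = newx, cl = yf, k = k,
                           prob = TRUE)
        p_win <- attr(pred, "prob")
        ifelse(pred == "1", p_win, 1 - p_win)
      }
    },
    gaussian_nb = {
      df <- as.data.frame(x)
      m <- e1071::naiveBayes(df, yf)
      function(newx) stats::predict(m, as.data.frame(newx),
                                    type = "raw")[, "1"]
    },
    random_forest = {
      m <- ranger::ranger(y = yf, x = as.data.frame(x), probability = TRUE,
                          num.trees = spec$hyperparams$num_trees,
                          seed = if (is.null(seed)) NULL
                                 else seed %% .Machine$integer.max,
                          num.threads = 1L)
      function(newx) {
        stats::predict(m, data = as.data.frame(newx),
                       num.threads = 1L)$predictions[, "1"]
      }
    },
    stop("fit_binary cannot fit ", spec$name)
  )
}

# labels fit-able in training: need >= 2 positives and >= 2 negatives
evaluable_labels <- function(y) {
  pos <- colSums(y)
  neg <- nrow(y) - pos
  keep <- pos >= 2L & neg >= 2L
  reasons <- ifelse(pos == 0L | neg == 0L, "single-class", "too-few-examples")
  list(keep = colnames(y)[keep],
       skipped = if (all(keep)) {
         data.frame(label = character(0), reason = character(0))
       } else {
         data.frame(label = colnames(y)[!keep], reason = reasons[!keep],
                    row.names = NULL)
       })
}

#' Split drugs into training and test sets
#'
#' @param associations binary drug x label matrix.
#' @param features feature (or principal-component score) matrix with
#'   the same drug ids in its row names.
#' @param fraction fraction of drugs assigned to training.
#' @param seed integer seed making the split reproducible.
#' @return list with `train` and `test`, each a bundle
#'   `list(x, y, drug_ids)`.
#' @export
split_train_test <- function(associations, features, fraction = 0.8,
                             seed = NULL) {
  ids <- rownames(associations)
  if (!setequal(ids, rownames(features))) {
    stop("associations and features cover different drugs")
  }
  n <- length(ids)
  if (n < 5L) stop("need at least 5 drugs to split")
  if (!is.null(seed)) set.seed(seed)
  n_train <- round(fraction * n)
  train_ids <- sort(sample(ids, n_train))
  test_ids <- sort(setdiff(ids, train_ids))
  bundle <- function(sel) list(x = features[sel, , drop = FALSE],
                               y = associations[sel, , drop = FALSE],
                               drug_ids = sel)
  list(train = bundle(train_ids), test = bundle(test_ids))
}

new_prediction_set <- function(drug_ids, label_ids, scores, predictions,
                               skipped, threshold) {
  structure(list(drug_ids = drug_ids, label_ids = label_ids,
                 scores = scores, predictions = predictions,
                 skipped_labels = skipped, threshold = threshold),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("Predictions for %d drugs x %d labels (threshold %.2f; %d labels skipped)\n",
              length(x$drug_ids), length(x$label_ids), x$threshold,
              nrow(x$skipped_labels)))
  invisible(x)
}

#' Fit one-vs-rest classifiers and score a test set
#'
#' Trains one independent binary classifier per label on the training
#' bundle and returns probability scores and thresholded predictions for
#' the test drugs. The voting ensemble averages member probabilities
#' label by label (soft voting).
#'
#' @param spec a `classifier_spec`.
#' @param train,test bundles from [split_train_test()].
#' @param threshold decision threshold on the probability scale for the
#'   point predictions. The F score is *not* threshold-free, so the
#'   threshold is recorded in every downstream report.
#' @param seed integer seed; per-label fitting seeds are derived from it
#'   so a full run is reproducible.
#' @return A `prediction_set`: scores and binary predictions
#'   (test drugs x evaluable labels) plus the skipped labels and reasons.
#' @export
fit_predict_ovr <- function(spec, train, test, threshold = 0.5,
                            seed = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  ev <- evaluable_labels(train$y)
  if (length(ev$keep) == 0L) stop("zero evaluable labels in training data")
  specs <- if (spec$name == "voting_ensemble") spec$members else list(spec)

  score_one_member <- function(member) {
    sc <- matrix(NA_real_, nrow(test$x), length(ev$keep),
                 dimnames = list(test$drug_ids, ev$keep))
    for (j in seq_along(ev$keep)) {
      lab <- ev$keep[j]
      predict_fun <- fit_binary(member, train$x, train$y[, lab],
                                seed = if (is.null(seed)) NULL else seed + j)
      sc[, j] <- predict_fun(test$x)
    }
    sc
  }
  member_scores <- lapply(specs, score_one_member)
  scores <- Reduce(`+`, member_scores) / length(member_scores)
  preds <- matrix(as.integer(scores >= threshold), nrow(scores), ncol(scores),
                  dimnames = dimnames(scores))
  new_prediction_set(test$drug_ids, ev$keep, scores, preds, ev$skipped,
                     threshold)
}

#' Fit a one-vs-rest multi-label model
#'
#' The model-object interface to the same machinery as
#' [fit_predict_ovr()]: fit once, predict on any new feature matrix.
#'
#' @param x training feature matrix (drugs x features).
#' @param y binary training label matrix (drugs x labels).
#' @param spec a `classifier_spec`.
#' @param seed integer seed for reproducible fitting.
#' @return Object of class `ovr_model` with `predict`, `print` and
#'   `summary` methods.
#' @export
ovr_fit <- function(x, y, spec, seed = NULL) {
  stopifnot(inherits(spec, "classifier_spec"),
            identical(rownames(x), rownames(y)))
  ev <- evaluable_labels(y)
  if (length(ev$keep) == 0L) stop("zero evaluable labels in training data")
  specs <- if (spec$name == "voting_ensemble") spec$members else list(spec)
  models <- lapply(seq_along(specs), function(m) {
    lapply(seq_along(ev$keep), function(j) {
      fit_binary(specs[[m]], x, y[, ev$keep[j]],
                 seed = if (is.null(seed)) NULL else seed + j + 7919L * m)
    })
  })
  structure(list(spec = spec, models = models, label_ids = ev$keep,
                 skipped_labels = ev$skipped, n_train = nrow(x),
                 seed = seed),
            class = "ovr_model")
}

#' @export
print.ovr_model <- function(x, ...) {
  cat(sprintf("One-vs-rest %s model: %d labels fitted on %d drugs (%d labels skipped)\n",
              x$spec$name, length(x$label_ids), x$n_train,
              nrow(x$skipped_labels)))
  invisible(x)
}

#' @export
summary.ovr_model <- function(object, ...) {
  print(object)
  print(object$spec)
  if (nrow(object$skipped_labels) > 0L) {
    cat("Skipped labels:\n")
    print(object$skipped_labels)
  }
  invisible(object)
}

#' Predict method for one-vs-rest models
#'
#' @param object an `ovr_model`.
#' @param newdata feature matrix for the drugs to score.
#' @param type `"prob"` for the probability score matrix, `"class"` for
#'   a thresholded binary matrix, `"prediction_set"` for the full object.
#' @param threshold decision threshold for `"class"`/`"prediction_set"`.
#' @param ... unused.
#' @return Matrix of scores or classes, or a `prediction_set`.
#' @export
predict.ovr_model <- function(object, newdata,
                              type = c("prob", "class", "prediction_set"),
                              threshold = 0.5, ...) {
  type <- match.arg(type)
  scores_by_member <- lapply(object$models, function(member) {
    sc <- vapply(member, function(f) f(newdata), numeric(nrow(newdata)))
    if (is.null(dim(sc))) sc <- matrix(sc, nrow = nrow(newdata))
    dimnames(sc) <- list(rownames(newdata), object$label_ids)
    sc
  })
  scores <- Reduce(`+`, scores_by_member) / length(scores_by_member)
  if (type == "prob") return(scores)
  preds <- matrix(as.integer(scores >= threshold), nrow(scores), ncol(scores),
                  dimnames = dimnames(scores))
  if (type == "class") return(preds)
  new_prediction_set(rownames(newdata), object$label_ids, scores, preds,
                     object$skipped_labels, threshold)
}

# near-equal shuffled fold sizes: n = 103, k = 5 -> 21 21 21 20 20
fold_assignment <- function(ids, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(ids)
  sizes <- rep(n %/% k, k)
  if (n %% k > 0L) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  split(sample(ids), rep(seq_len(k), times = sizes))
}

#' k-fold cross-validation of a one-vs-rest classifier
#'
#' Drugs are shuffled into k near-equal folds; each fold serves once as
#' validation. Folds in which no label is evaluable are recorded as `NA`
#' and excluded from the mean with a warning.
#'
#' @param spec a `classifier_spec`.
#' @param bundle `list(x, y, drug_ids)` as produced by
#'   [split_train_test()] (typically the training bundle).
#' @param k number of folds.
#' @param seed integer seed for fold assignment and fitting.
#' @param threshold decision threshold.
#' @param aggregation metric aggregation mode.
#' @return Object of class `cv_result`: per-fold `metric_report`s, their
#'   field-wise mean, the scheme and the seed.
#' @export
cross_validate <- function(spec, bundle, k = 5L, seed = NULL,
                           threshold = 0.5, aggregation = "macro") {
  n <- length(bundle$drug_ids)
  if (k > n) stop("k exceeds number of drugs")
  if (k == n) return(loocv(spec, bundle, threshold = threshold,
                           aggregation = aggregation, seed = seed))
  folds <- fold_assignment(bundle$drug_ids, k, seed = seed)
  reports <- vector("list", k)
  for (i in seq_len(k)) {
    val_ids <- folds[[i]]
    tr_ids <- setdiff(bundle$drug_ids, val_ids)
    tr <- list(x = bundle$x[tr_ids, , drop = FALSE],
               y = bundle$y[tr_ids, , drop = FALSE], drug_ids = tr_ids)
    va <- list(x = bundle$x[val_ids, , drop = FALSE],
               y = bundle$y[val_ids, , drop = FALSE], drug_ids = val_ids)
    reports[[i]] <- tryCatch({
      ps <- fit_predict_ovr(spec, tr, va, threshold = threshold,
                            seed = if (is.null(seed)) NULL else seed + 101L * i)
      evaluate_predictions(ps, va$y, aggregation = aggregation)
    }, error = function(e) {
      warning("fold ", i, " not evaluable: ", conditionMessage(e))
      NA
    })
  }
  ok <- !vapply(reports, function(r) length(r) == 1L && is.na(r[[1]][1]),
                TRUE)
  if (!any(ok)) stop("no evaluable folds")
  num_fields <- c("precision", "recall", "f2", "auc", "aupr",
                  "weighted_performance", "n_labels_evaluated",
                  "n_labels_skipped")
  mean_vals <- lapply(num_fields, function(f) {
    mean(vapply(reports[ok], function(r) as.numeric(r[[f]]), 0), na.rm = TRUE)
  })
  names(mean_vals) <- num_fields
  mean_report <- new_metric_report(
    mean_vals[setdiff(num_fields, c("n_labels_evaluated", "n_labels_skipped"))],
    n_eval = mean_vals$n_labels_evaluated,
    n_skip = mean_vals$n_labels_skipped,
    aggregation = aggregation, threshold = threshold)
  structure(list(fold_reports = reports, mean_report = mean_report,
                 scheme = "kfold", k = k, seed = seed),
            class = "cv_result")
}

#' Leave-one-out cross-validation
#'
#' Each drug is held out in turn; held-out probability scores are pooled
#' across all drugs *before* computing metrics (per-fold ranking metrics
#' are undefined for a single held-out item). Labels must be evaluable
#' in every fold to enter the pooled matrix.
#'
#' @inheritParams cross_validate
#' @return A `cv_result` with scheme `"loocv"`; `mean_report` holds the
#'   pooled-score metrics and `pooled_predictions` the pooled
#'   `prediction_set`.
#' @export
loocv <- function(spec, bundle, threshold = 0.5, aggregation = "macro",
                  seed = NULL) {
  ids <- bundle$drug_ids
  n <- length(ids)
  score_rows <- vector("list", n)
  labels_per_fold <- vector("list", n)
  for (i in seq_len(n)) {
    tr_ids <- ids[-i]
    tr <- list(x = bundle$x[tr_ids, , drop = FALSE],
               y = bundle$y[tr_ids, , drop = FALSE], drug_ids = tr_ids)
    te <- list(x = bundle$x[ids[i], , drop = FALSE],
               y = bundle$y[ids[i], , drop = FALSE], drug_ids = ids[i])
    ps <- fit_predict_ovr(spec, tr, te, threshold = threshold,
                          seed = if (is.null(seed)) NULL else seed + 101L * i)
    score_rows[[i]] <- ps$scores
    labels_per_fold[[i]] <- ps$label_ids
  }
  common <- Reduce(intersect, labels_per_fold)
  if (length(common) == 0L) stop("no label evaluable in every fold")
  scores <- do.call(rbind, lapply(score_rows, function(s)
    s[, common, drop = FALSE]))
  rownames(scores) <- ids
  preds <- matrix(as.integer(scores >= threshold), n, length(common),
                  dimnames = dimnames(scores))
  not_pooled <- setdiff(colnames(bundle$y), common)
  pooled <- new_prediction_set(
    ids, common, scores, preds,
    data.frame(label = not_pooled,
               reason = rep("skipped in some fold", length(not_pooled))),
    threshold)
  rep <- evaluate_predictions(pooled, bundle$y, aggregation = aggregation)
  structure(list(fold_reports = list(), mean_report = rep,
                 pooled_predictions = pooled, scheme = "loocv", k = n,
                 seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Cross-validation (%s, k = %d)\n", x$scheme, x$k))
  print(x$mean_report)
  invisible(x)
}
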