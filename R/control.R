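# Size-matched random-aggregation null control. Aggregating labels at
# all inflates apparent performance (coarser labels are denser and
# easier), so the anatomical grouping is compared against pseudo-organs /
# pseudo-sub-systems / pseudo-systems: random partitions of the side
# effects whose category-size multiset exactly matches the anatomical
# one. Only the grouping varies across replicates — the train/test split,
# feature representation and classifier seeds are held fixed — so the
# z-score isolates the value of anatomically meaningful grouping.

#' Random partition with a prescribed size multiset
#'
#' Side-effect ids are uniformly shuffled and filled into pseudo-category
#' slots of the given sizes, yielding a uniform draw over all partitions
#' with that size multiset.
#'
#' @param ids character vector of side-effect ids.
#' @param sizes integer vector of category sizes; must sum to
#'   `length(ids)`.
#' @param seed optional integer seed.
#' @return Object of class `pseudo_schema`: a named character vector
#'   mapping each id to a pseudo-category, with attributes `sizes` and
#'   `seed`.
#' @export
size_matched_partition <- function(ids, sizes, seed = NULL) {
  sizes <- as.integer(sizes)
  if (sum(sizes) != length(ids)) {
    stop("sizes sum to ", sum(sizes), " but there are ", length(ids), " ids")
  }
  if (any(sizes < 1L)) stop("all category sizes must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  shuffled <- sample(ids)
  mapping <- stats::setNames(rep(pad_id("pseudo", length(sizes)), sizes),
                             shuffled)[ids]
  structure(mapping, sizes = sort(as.integer(table(mapping))),
            seed = seed, class = "pseudo_schema")
}

#' @export
print.pseudo_schema <- function(x, ...) {
  cat(sprintf("Pseudo-schema: %d ids in %d size-matched random categories\n",
              length(x), length(attr(x, "sizes"))))
  invisible(x)
}

#' Size-matched random-aggregation control experiment
#'
#' Runs the anatomical-aggregation experiment at one hierarchy level,
#' then repeats it `n_reps` times with random pseudo-categories matching
#' the anatomical category sizes. The same train/test split, principal
#' component scores and classifier seeds are reused in every run, so the
#' grouping is the only varying factor. Replicates in which no label is
#' evaluable are dropped (more than 20% dropped is an error).
#'
#' @param dataset a `synth_dataset`, or any list with elements
#'   `associations` (side-effect-level binary matrix), `features`
#'   (numeric matrix) and `schema` (`anatomical_schema`).
#' @param spec a `classifier_spec`.
#' @param level hierarchy level to aggregate to.
#' @param n_reps number of random replicates (100 for full runs; 20 is a
#'   practical desk-scale default).
#' @param seed integer seed governing split, fits and partitions.
#' @param pca_k number of principal components (capped at the feasible
#'   maximum); `NULL` for min(100, limit).
#' @param fraction training fraction for the holdout split.
#' @param threshold decision threshold.
#' @param metric which report field the z-score is computed on.
#' @return Object of class `random_control`: replicate metric values,
#'   their mean and sd, the anatomical value, and
#'   `z = (anatomical - mean) / sd`.
#' @export
run_random_control <- function(dataset, spec,
                               level = c("organ", "sub_system", "system"),
                               n_reps = 20L, seed = 1L, pca_k = NULL,
                               fraction = 0.8, threshold = 0.5,
                               metric = "weighted_performance") {
  level <- match.arg(level)
  stopifnot(inherits(spec, "classifier_spec"))
  assoc <- dataset$associations
  schema <- dataset$schema

  feats <- clean_features(dataset$features)
  split0 <- split_train_test(assoc, feats, fraction = fraction, seed = seed)
  if (is.null(pca_k)) {
    pca_k <- min(100L, length(split0$train$drug_ids) - 1L, ncol(feats))
  }
  pcs <- pca_reduce(feats, k = pca_k, fit_ids = split0$train$drug_ids)

  run_one <- function(y_level) {
    spl <- split_train_test(y_level, pcs$scores, fraction = fraction,
                            seed = seed)
    ps <- fit_predict_ovr(spec, spl$train, spl$test, threshold = threshold,
                          seed = seed)
    evaluate_predictions(ps, spl$test$y, aggregation = "macro")
  }

  anatomical_report <- run_one(coarse_grain(assoc, schema, level))

  stats_level <- schema_stats(exclude_misc(schema), level)
  sizes <- sort(as.integer(stats_level$counts))
  se_ids <- colnames(assoc)[colnames(assoc) %in%
                              exclude_misc(schema)$terms$side_effect]

  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    pseudo <- size_matched_partition(se_ids, sizes, seed = seed + 1000L + r)
    stopifnot(identical(attr(pseudo, "sizes"), sizes))  # conservation
    y_pseudo <- aggregate_columns(assoc[, se_ids, drop = FALSE], pseudo,
                                  level = "pseudo")
    reps[[r]] <- tryCatch(run_one(y_pseudo), error = function(e) {
      message("replicate ", r, " dropped: ", conditionMessage(e))
      NULL
    })
  }
  dropped <- vapply(reps, is.null, TRUE)
  if (mean(dropped) > 0.2) {
    stop(sum(dropped), " of ", n_reps, " control replicates dropped (>20%)")
  }
  reps <- reps[!dropped]

  take <- function(rep_list, field) {
    vapply(rep_list, function(r) as.numeric(r[[field]]), 0)
  }
  values <- take(reps, metric)
  companions <- data.frame(
    precision = take(reps, "precision"), recall = take(reps, "recall"),
    f2 = take(reps, "f2"), auc = take(reps, "auc"),
    aupr = take(reps, "aupr"),
    weighted_performance = take(reps, "weighted_performance"))
  anatomical_value <- as.numeric(anatomical_report[[metric]])
  mu <- mean(values)
  sdev <- if (length(values) >= 2L) stats::sd(values) else NA_real_
  z <- if (!is.na(sdev) && sdev > 0) (anatomical_value - mu) / sdev else {
    if (is.na(sdev)) warning("fewer than 2 replicates; z-score is NA")
    NA_real_
  }
  structure(list(replicate_values = values, replicate_metrics = companions,
                 mean = mu, sd = sdev, n_reps = length(values),
                 n_dropped = sum(dropped), level = level,
                 classifier = spec$name, metric = metric,
                 anatomical_value = anatomical_value,
                 anatomical_report = anatomical_report,
                 z_score = z, seed = seed),
            class = "random_control")
}

#' @export
print.random_control <- function(x, ...) {
  cat(sprintf("Random-aggregation control (%s level, %s, %d replicates)\n",
              x$level, x$classifier, x$n_reps))
  cat(sprintf("  anatomical %s = %.3f | random mean %.3f (sd %.4f)\n",
              x$metric, x$anatomical_value, x$mean, x$sd))
  cat(sprintf("  z-score = %s\n",
              if (is.na(x$z_score)) "NA" else sprintf("%.2f", x$z_score)))
  invisible(x)
}

#' Enhancement of anatomical over random aggregation
#'
#' @param anatomical_report the anatomical `metric_report` (or a bare
#'   numeric value of the control's metric).
#' @param control a `random_control` for the same level, classifier and
#'   metric.
#' @return list with `difference` (anatomical minus random mean) and
#'   `z_score`.
#' @export
enhancement_over_random <- function(anatomical_report, control) {
  stopifnot(inherits(control, "random_control"))
  value <- if (inherits(anatomical_report, "metric_report")) {
    as.numeric(anatomical_report[[control$metric]])
  } else {
    as.numeric(anatomical_report)
  }
  if (is.na(value)) stop("anatomical value undefined for metric ",
                         control$metric)
  z <- if (!is.na(control$sd) && control$sd > 0) {
    (value - control$mean) / control$sd
  } else NA_real_
  list(difference = value - control$mean, z_score = z)
}
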