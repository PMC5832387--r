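# End-to-end experiment orchestration: data (synthetic or files) ->
# feature reduction -> per level x classifier holdout + cross-validation
# metrics, optional size-matched random controls -> CSV/JSON reports plus
# a manifest sufficient to re-run bit-identically.

#' Build and validate an experiment configuration
#'
#' @param data `"synthetic"`, or a list with paths `sider_se` (the
#'   drug--event TSV), `schema` (anatomical schema TSV/CSV) and
#'   `features` (CSV, first column the drug id).
#' @param synth a `synth_config` used when `data = "synthetic"`.
#' @param levels hierarchy levels to evaluate; `"side_effect"` means no
#'   coarse-graining.
#' @param classifiers list of `classifier_spec`s (or names).
#' @param pca_k number of principal components (capped at the feasible
#'   maximum).
#' @param pca_fit_scope `"train_only"` (default; no leakage) or `"all"`.
#' @param cv_folds folds for training-side cross-validation; 0 disables.
#' @param n_random_reps replicates for the random-aggregation control; 0
#'   disables the control.
#' @param fraction training fraction of the holdout split.
#' @param threshold decision threshold.
#' @param aggregation metric aggregation mode.
#' @param seed integer seed for the whole experiment.
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(data = "synthetic", synth = synth_config(),
                              levels = c("side_effect", "organ",
                                         "sub_system", "system"),
                              classifiers = list("random_forest"),
                              pca_k = 100L, pca_fit_scope = "train_only",
                              cv_folds = 5L, n_random_reps = 0L,
                              fraction = 0.8, threshold = 0.5,
                              aggregation = "macro", seed = 1L,
                              out_dir = NULL) {
  levels <- match.arg(levels, several.ok = TRUE)
  if (length(classifiers) < 1L) stop("need at least one classifier")
  classifiers <- lapply(classifiers, function(cl) {
    if (inherits(cl, "classifier_spec")) cl else classifier_spec(cl)
  })
  pca_fit_scope <- match.arg(pca_fit_scope, c("train_only", "all"))
  if (!identical(data, "synthetic")) {
    stopifnot(is.list(data),
              all(c("sider_se", "schema", "features") %in% names(data)))
    for (p in unlist(data)) {
      if (!file.exists(p)) stop("input file not found: ", p)
    }
  }
  structure(list(data = data, synth = synth, levels = levels,
                 classifiers = classifiers, pca_k = as.integer(pca_k),
                 pca_fit_scope = pca_fit_scope,
                 cv_folds = as.integer(cv_folds),
                 n_random_reps = as.integer(n_random_reps),
                 fraction = fraction, threshold = threshold,
                 aggregation = aggregation, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' Scalar fields of [experiment_config()] map directly; `classifiers` is
#' a list of names, and `synth` a mapping of [synth_config()] arguments.
#'
#' @param path YAML file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$synth)) raw$synth <- do.call(synth_config, raw$synth)
  do.call(experiment_config, raw)
}

load_experiment_data <- function(config) {
  if (identical(config$data, "synthetic")) {
    synth <- config$synth
    if (is.null(synth$seed)) synth$seed <- config$seed
    ds <- generate_dataset(synth)
    list(associations = ds$associations, features = ds$features,
         schema = ds$schema,
         counts = list(n_drugs = nrow(ds$associations),
                       n_se = ncol(ds$associations)))
  } else {
    recs <- read_sider_se(config$data$sider_se)
    pt <- filter_preferred_terms(recs)
    assoc <- build_association_matrix(pt)
    schema <- read_schema(config$data$schema)
    ftab <- utils::read.csv(config$data$features, check.names = FALSE)
    feats <- as.matrix(ftab[, -1, drop = FALSE])
    rownames(feats) <- as.character(ftab[[1]])
    common <- intersect(rownames(assoc), rownames(feats))
    if (length(common) < 5L) stop("fewer than 5 drugs shared by matrix and features")
    list(associations = assoc[common, , drop = FALSE],
         features = feats[common, , drop = FALSE], schema = schema,
         counts = c(attr(pt, "filter_report"),
                    list(n_drugs = length(common), n_se = ncol(assoc))))
  }
}

level_labels <- function(assoc, schema, level) {
  if (level == "side_effect") {
    keep <- colnames(assoc) %in% exclude_misc(schema)$terms$side_effect
    assoc[, keep, drop = FALSE]
  } else {
    coarse_grain(assoc, schema, level, drop_unknown = TRUE)
  }
}

#' Run a full hierarchical side-effect prediction experiment
#'
#' For every configured hierarchy level and classifier: holdout metrics
#' (macro and micro), training-side cross-validation, and optionally the
#' size-matched random-aggregation control. Results are returned and,
#' when `out_dir` is set, written as `metrics.csv`, `metrics.json`,
#' `random_control.csv` and `manifest.json`.
#'
#' @param config an `experiment_config`.
#' @return Object of class `experiment_result` (invisibly when writing
#'   files): `metrics` data.frame, `controls` list, `manifest` list.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  t_start <- Sys.time()
  dat <- load_experiment_data(config)
  feats <- clean_features(dat$features)
  split0 <- split_train_test(dat$associations, feats,
                             fraction = config$fraction, seed = config$seed)
  k_eff <- min(config$pca_k, length(split0$train$drug_ids) - 1L, ncol(feats))
  pcs <- pca_reduce(feats, k = k_eff,
                    fit_ids = if (config$pca_fit_scope == "train_only")
                      split0$train$drug_ids else NULL)

  rows <- list(); controls <- list()
  for (level in config$levels) {
    y <- level_labels(dat$associations, dat$schema, level)
    spl <- split_train_test(y, pcs$scores, fraction = config$fraction,
                            seed = config$seed)
    for (spec in config$classifiers) {
      ps <- fit_predict_ovr(spec, spl$train, spl$test,
                            threshold = config$threshold, seed = config$seed)
      for (mode in c("macro", "micro")) {
        rep <- evaluate_predictions(ps, spl$test$y, aggregation = mode)
        row <- metric_report_table(stats::setNames(list(rep), "holdout"))
        row$scheme <- "holdout"
        row$level <- level; row$classifier <- spec$name
        rows[[length(rows) + 1L]] <- row
      }
      if (config$cv_folds >= 2L) {
        cv <- cross_validate(spec, spl$train, k = config$cv_folds,
                             seed = config$seed,
                             threshold = config$threshold,
                             aggregation = config$aggregation)
        row <- metric_report_table(stats::setNames(list(cv$mean_report), "cv"))
        row$scheme <- sprintf("cv%d", config$cv_folds)
        row$level <- level; row$classifier <- spec$name
        rows[[length(rows) + 1L]] <- row
      }
      if (config$n_random_reps > 0L && level != "side_effect") {
        ctl <- run_random_control(dat, spec, level = level,
                                  n_reps = config$n_random_reps,
                                  seed = config$seed, pca_k = k_eff,
                                  fraction = config$fraction,
                                  threshold = config$threshold)
        controls[[paste(level, spec$name, sep = ".")]] <- ctl
      }
    }
  }
  metrics <- do.call(rbind, rows)
  metrics$name <- NULL
  metrics <- metrics[c("level", "classifier", "scheme", "aggregation",
                       setdiff(names(metrics),
                               c("level", "classifier", "scheme",
                                 "aggregation")))]

  manifest <- list(
    package_version = as.character(utils::packageVersion("adrhier")),
    seed = config$seed,
    timestamp = format(t_start, "%Y-%m-%d %H:%M:%S"),
    elapsed_sec = as.numeric(Sys.time() - t_start, units = "secs"),
    data = if (identical(config$data, "synthetic")) "synthetic" else config$data,
    counts = dat$counts,
    n_features_clean = ncol(feats),
    pca = list(k = k_eff, fitted_on = pcs$fitted_on,
               variance_explained = variance_explained(pcs)),
    levels = config$levels,
    classifiers = lapply(config$classifiers, function(s)
      list(name = s$name, hyperparams = s$hyperparams)),
    fraction = config$fraction, threshold = config$threshold,
    cv_folds = config$cv_folds, n_random_reps = config$n_random_reps,
    dropped_control_replicates = sum(vapply(controls, function(c)
      c$n_dropped, 0L))
  )

  result <- structure(list(metrics = metrics, controls = controls,
                           manifest = manifest, config = config),
                      class = "experiment_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(metrics, file.path(config$out_dir, "metrics.json"),
                         dataframe = "rows", na = "null", digits = NA)
    if (length(controls) > 0L) {
      ctab <- do.call(rbind, lapply(names(controls), function(nm) {
        c <- controls[[nm]]
        data.frame(level = c$level, classifier = c$classifier,
                   metric = c$metric, anatomical = c$anatomical_value,
                   random_mean = c$mean, random_sd = c$sd,
                   n_reps = c$n_reps, z_score = c$z_score)
      }))
      utils::write.csv(ctab, file.path(config$out_dir, "random_control.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    return(invisible(result))
  }
  result
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Experiment:", nrow(x$metrics), "metric rows over levels",
      paste(unique(x$metrics$level), collapse = ", "), "\n")
  show <- x$metrics[x$metrics$aggregation == "macro" &
                      x$metrics$scheme == "holdout",
                    c("level", "classifier", "f2", "auc",
                      "weighted_performance")]
  print(show, row.names = FALSE, digits = 3)
  if (length(x$controls) > 0L) {
    cat("Random-aggregation controls:\n")
    for (nm in names(x$controls)) {
      c <- x$controls[[nm]]
      cat(sprintf("  %s / %s: anatomical %.3f vs random %.3f (z = %.2f)\n",
                  c$level, c$classifier, c$anatomical_value, c$mean,
                  c$z_score))
    }
  }
  invisible(x)
}
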