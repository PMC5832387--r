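#' Clean and standardize a drug feature table
#'
#' Molecular descriptor tables mix incommensurate units (masses, counts,
#' energies, surface areas), so columns are centered and scaled to unit
#' variance before dimension reduction. Columns containing any missing
#' value, and constant columns, are dropped with a message.
#'
#' @param x numeric matrix (drugs x features) with row and column names.
#' @return Standardized numeric matrix; each surviving column has mean 0
#'   and variance 1.
#' @export
clean_features <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  has_na <- apply(x, 2L, anyNA)
  if (any(has_na)) {
    message(sum(has_na), " feature column(s) with missing values dropped")
    x <- x[, !has_na, drop = FALSE]
  }
  v <- apply(x, 2L, stats::var)
  if (any(v == 0)) {
    message(sum(v == 0), " constant feature column(s) dropped")
    x <- x[, v > 0, drop = FALSE]
  }
  if (ncol(x) < 2L) stop("fewer than 2 usable feature columns remain")
  scale(x, center = TRUE, scale = apply(x, 2L, stats::sd))[, , drop = FALSE]
}

#' Reduce features to principal component scores
#'
#' Projects drugs onto the top-k principal components of the feature
#' table. By default the rotation is fitted on a designated training
#' subset only and then applied to all rows, avoiding information leakage
#' from test drugs into the representation; fitting on all rows is
#' available to mirror pipelines that reduce before splitting.
#'
#' @param x standardized feature matrix (see [clean_features()]).
#' @param k number of components to keep.
#' @param fit_ids row names to fit the rotation on, or `NULL` to fit on
#'   all rows.
#' @return An object of class `pca_result`: list with `scores` (all rows
#'   x k), `explained_variance_ratio` (length k, within the fitted rows),
#'   `k`, and `fitted_on` (`"train_only"` or `"all"`).
#' @export
pca_reduce <- function(x, k, fit_ids = NULL) {
  fit_rows <- if (is.null(fit_ids)) x else {
    missing_ids <- setdiff(fit_ids, rownames(x))
    if (length(missing_ids) > 0L) stop("fit_ids not in feature matrix")
    x[fit_ids, , drop = FALSE]
  }
  kmax <- min(nrow(fit_rows) - 1L, ncol(x))
  if (k < 1L || k > kmax) {
    stop(sprintf("k must be in [1, %d] for %d fitted rows and %d features",
                 kmax, nrow(fit_rows), ncol(x)))
  }
  pc <- stats::prcomp(fit_rows, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- scale(x, center = pc$center, scale = FALSE) %*%
    pc$rotation[, seq_len(k), drop = FALSE]
  structure(
    list(scores = scores, explained_variance_ratio = evr[seq_len(k)],
         k = k, fitted_on = if (is.null(fit_ids)) "all" else "train_only"),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA: %d components over %d drugs (fitted on %s rows)\n",
              x$k, nrow(x$scores), x$fitted_on))
  cat(sprintf("  cumulative variance explained: %.1f%%\n",
              100 * sum(x$explained_variance_ratio)))
  invisible(x)
}

#' Cumulative variance explained by the first k components
#'
#' @param result a `pca_result`.
#' @param k number of leading components (`k = 0` gives 0).
#' @return Fraction of total variance in `[0, 1]`.
#' @export
variance_explained <- function(result, k = result$k) {
  stopifnot(inherits(result, "pca_result"), k >= 0, k <= result$k)
  if (k == 0L) return(0)
  sum(result$explained_variance_ratio[seq_len(k)])
}
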