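# Parsers for SIDER-dialect drug--side-effect tables. The files are
# headerless, tab-separated and may be gzip-compressed; the column layout
# is the SIDER 4.1 dialect. All three parsers return the same record shape
# so downstream code is indifferent to the source file.

sider_record_cols <- c("stitch_flat_id", "stitch_stereo_id",
                       "umls_id_label", "concept_type",
                       "umls_id_meddra", "side_effect_name")

read_sider_lines <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

parse_sider_generic <- function(path, min_fields, pick) {
  lines <- read_sider_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty SIDER file: ", path)
    out <- as.data.frame(stats::setNames(
      replicate(length(sider_record_cols), character(0), simplify = FALSE),
      sider_record_cols))
    attr(out, "n_malformed") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= min_fields
  n_bad <- sum(!ok)
  if (n_bad > 0.1 * length(lines)) {
    stop(sprintf("%d of %d lines malformed (>10%%); sample: %s",
                 n_bad, length(lines),
                 paste(utils::head(lines[!ok], 2L), collapse = " | ")))
  }
  if (n_bad > 0L) message(n_bad, " malformed line(s) skipped in ", basename(path))
  recs <- pick(fields[ok])
  rownames(recs) <- NULL
  attr(recs, "n_malformed") <- n_bad
  recs
}

#' Parse a SIDER `meddra_all_se` table
#'
#' Columns: STITCH flat id, STITCH stereo id, UMLS id (label), MedDRA
#' concept type (LLT or PT), UMLS id (MedDRA), side-effect name.
#' Gzip-compressed files are read transparently. Lines with fewer than six
#' fields are skipped with a message; more than 10% malformed lines is an
#' error.
#'
#' @param path path to the (optionally gzipped) tab-separated file.
#' @return data.frame of records with columns `stitch_flat_id`,
#'   `stitch_stereo_id`, `umls_id_label`, `concept_type`,
#'   `umls_id_meddra`, `side_effect_name`; the count of malformed lines is
#'   attached as attribute `n_malformed`.
#' @export
read_sider_se <- function(path) {
  parse_sider_generic(path, min_fields = 6L, pick = function(fields) {
    m <- do.call(rbind, lapply(fields, function(f) f[1:6]))
    stats::setNames(as.data.frame(m, stringsAsFactors = FALSE),
                    sider_record_cols)
  })
}

#' Parse a SIDER `meddra_freq` table
#'
#' The frequency table carries the same identifying fields as the main
#' side-effect table plus frequency annotations in columns 4 to 7; only
#' the identifying fields are retained, in the common record shape.
#'
#' @inheritParams read_sider_se
#' @return data.frame in the same shape as [read_sider_se()].
#' @export
read_sider_freq <- function(path) {
  parse_sider_generic(path, min_fields = 10L, pick = function(fields) {
    m <- do.call(rbind, lapply(fields, function(f) f[c(1, 2, 3, 8, 9, 10)]))
    stats::setNames(as.data.frame(m, stringsAsFactors = FALSE),
                    sider_record_cols)
  })
}

#' Parse a SIDER `meddra_all_indications` table
#'
#' Indications name conditions a drug treats rather than adverse events;
#' records are returned in the common shape (the stereo id, absent from
#' this file, is set to `NA`).
#'
#' @inheritParams read_sider_se
#' @return data.frame in the same shape as [read_sider_se()].
#' @export
read_sider_indications <- function(path) {
  parse_sider_generic(path, min_fields = 7L, pick = function(fields) {
    m <- do.call(rbind, lapply(fields, function(f)
      c(f[1], NA_character_, f[2], f[5], f[6], f[7])))
    stats::setNames(as.data.frame(m, stringsAsFactors = FALSE),
                    sider_record_cols)
  })
}

#' Keep MedDRA Preferred Terms only
#'
#' Lowest Level Terms are lexical variants of Preferred Terms describing
#' the same medical concept, so analyses keep PT records only. Records
#' with an empty or "NA" id or side-effect name ("null entries") are
#' dropped as well.
#'
#' @param records data.frame of SIDER records.
#' @return The filtered records; a list attribute `filter_report` holds
#'   `n_in`, `n_pt` and `n_dropped_null`.
#' @export
filter_preferred_terms <- function(records) {
  n_in <- nrow(records)
  pt <- records[records$concept_type == "PT", , drop = FALSE]
  n_pt <- nrow(pt)
  essential <- c("stitch_flat_id", "umls_id_label", "side_effect_name")
  null_row <- Reduce(`|`, lapply(pt[essential], function(col) {
    is.na(col) | col == "" | col == "NA"
  }))
  out <- pt[!null_row, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_report") <- list(n_in = n_in, n_pt = n_pt,
                                     n_dropped_null = sum(null_row))
  out
}

#' Build the binary drug x side-effect matrix
#'
#' Each distinct (drug, side effect) pair becomes a 1; duplicates
#' collapse. Drugs are keyed by flat STITCH id by default (stereo
#' selectable).
#'
#' @param records PT-filtered SIDER records.
#' @param drug_key `"flat"` or `"stereo"` STITCH identifier.
#' @return Binary association matrix at side-effect level.
#' @export
build_association_matrix <- function(records, drug_key = c("flat", "stereo")) {
  drug_key <- match.arg(drug_key)
  if (nrow(records) == 0L) stop("no records; cannot build an empty matrix")
  id_col <- if (drug_key == "flat") "stitch_flat_id" else "stitch_stereo_id"
  drugs <- sort(unique(records[[id_col]]))
  ses <- sort(unique(records$side_effect_name))
  mat <- matrix(0L, length(drugs), length(ses), dimnames = list(drugs, ses))
  mat[cbind(match(records[[id_col]], drugs),
            match(records$side_effect_name, ses))] <- 1L
  association_matrix(mat, level = "side_effect")
}

#' Per-drug and per-label degree distributions
#'
#' Real drug--event data are heavily skewed: a few drugs report very many
#' side effects and a few side effects are reported for very many drugs.
#' Row and column sums of the association matrix expose that skew.
#'
#' @param mat binary association matrix.
#' @return list with `per_drug` and `per_label` named count vectors and a
#'   `summary` (max, median, skewness per side).
#' @export
degree_distributions <- function(mat) {
  if (length(mat) == 0L) stop("empty matrix")
  per_drug <- rowSums(mat)
  per_label <- colSums(mat)
  summ <- function(x) c(max = max(x), median = stats::median(x),
                        skewness = e1071::skewness(x))
  list(per_drug = per_drug, per_label = per_label,
       summary = list(drug = summ(per_drug), label = summ(per_label)))
}

#' Fraction of zero entries in an association matrix
#'
#' @param mat binary association matrix.
#' @return The fraction of entries equal to zero, in `[0, 1]`.
#' @export
sparsity <- function(mat) {
  if (length(mat) == 0L) stop("empty matrix")
  1 - sum(mat) / length(mat)
}
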