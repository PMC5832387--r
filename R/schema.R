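#' Construct an anatomical classification schema
#'
#' An anatomical schema maps every side-effect term to exactly one organ,
#' one sub-system and one system, forming a tree: each organ belongs to a
#' single sub-system and each sub-system to a single system. Terms whose
#' organ label is in the miscellaneous set are flagged `is_misc` and are
#' normally excluded before classification experiments.
#'
#' @param terms data.frame with columns `side_effect`, `organ`,
#'   `sub_system`, `system` (character).
#' @param misc_labels character vector of organ labels to treat as
#'   miscellaneous, or `NULL` for the default rule: any organ label
#'   beginning with "misc" (case-insensitive), which also covers a
#'   bare "MISC" label.
#' @return An object of class `anatomical_schema`: a list with elements
#'   `terms` (the validated data.frame, including a logical `is_misc`
#'   column), `misc_labels` (the set supplied, or `NULL` for the default
#'   rule) and `level_names`.
#' @seealso [read_schema()], [exclude_misc()], [schema_stats()],
#'   [coarse_grain()]
#' @export
anatomical_schema <- function(terms, misc_labels = NULL) {
  required <- c("side_effect", "organ", "sub_system", "system")
  missing_cols <- setdiff(required, names(terms))
  if (length(missing_cols) > 0L) {
    stop("schema is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  terms <- terms[required]
  for (col in required) terms[[col]] <- as.character(terms[[col]])
  if (any(is.na(terms)) || any(unlist(terms) == "")) {
    stop("schema contains empty or missing entries")
  }

  terms <- unique(terms)
  dup <- terms$side_effect[duplicated(terms$side_effect)]
  if (length(dup) > 0L) {
    stop("conflicting duplicate mapping for side effect(s): ",
         paste(unique(dup), collapse = ", "))
  }

  # tree structure: organ -> one sub_system, sub_system -> one system
  org_map <- unique(terms[c("organ", "sub_system")])
  bad_org <- org_map$organ[duplicated(org_map$organ)]
  if (length(bad_org) > 0L) {
    stop("organ(s) mapped to more than one sub-system: ",
         paste(unique(bad_org), collapse = ", "))
  }
  sub_map <- unique(terms[c("sub_system", "system")])
  bad_sub <- sub_map$sub_system[duplicated(sub_map$sub_system)]
  if (length(bad_sub) > 0L) {
    stop("sub-system(s) mapped to more than one system: ",
         paste(unique(bad_sub), collapse = ", "))
  }

  if (is.null(misc_labels)) {
    terms$is_misc <- grepl("^misc", terms$organ, ignore.case = TRUE)
  } else {
    terms$is_misc <- terms$organ %in% misc_labels
  }
  rownames(terms) <- NULL

  structure(
    list(terms = terms, misc_labels = misc_labels,
         level_names = c("organ", "sub_system", "system")),
    class = "anatomical_schema"
  )
}

#' Read an anatomical schema from a delimited text file
#'
#' The file must have a header row naming the columns `side_effect`,
#' `organ`, `sub_system` and `system`. The delimiter is chosen from the
#' file extension (`.csv` is comma-separated, anything else tab-separated).
#' Rows repeating an identical mapping are deduplicated silently; a side
#' effect mapped to two different organs is an error.
#'
#' @param path path to a TSV or CSV schema file.
#' @inheritParams anatomical_schema
#' @return An `anatomical_schema` object.
#' @export
read_schema <- function(path, misc_labels = NULL) {
  if (!file.exists(path)) stop("schema file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  terms <- utils::read.table(path, header = TRUE, sep = sep,
                             quote = "\"", comment.char = "",
                             stringsAsFactors = FALSE)
  anatomical_schema(terms, misc_labels = misc_labels)
}

#' @export
print.anatomical_schema <- function(x, ...) {
  tn <- x$terms
  cat("Anatomical schema:", nrow(tn), "side-effect terms\n")
  non_misc <- tn[!tn$is_misc, , drop = FALSE]
  cat(sprintf("  non-MISC: %d terms in %d organs, %d sub-systems, %d systems\n",
              nrow(non_misc), length(unique(non_misc$organ)),
              length(unique(non_misc$sub_system)),
              length(unique(non_misc$system))))
  cat(sprintf("  MISC terms: %d\n", sum(tn$is_misc)))
  invisible(x)
}

#' Drop miscellaneous terms from a schema
#'
#' Side effects too ambiguous to assign to a single organ live in
#' miscellaneous bins (a global MISC plus per-system `misc_*` classes) and
#' are excluded from classification experiments.
#'
#' @param schema an `anatomical_schema`.
#' @return A new `anatomical_schema` with only non-MISC terms; the input
#'   is unchanged.
#' @export
exclude_misc <- function(schema) {
  stopifnot(inherits(schema, "anatomical_schema"))
  keep <- schema$terms[!schema$terms$is_misc, , drop = FALSE]
  if (nrow(keep) == 0L) stop("all terms are miscellaneous; empty schema")
  anatomical_schema(keep, misc_labels = schema$misc_labels)
}

#' Category counts at one level of the hierarchy
#'
#' Counts how many member side effects each organ / sub-system / system
#' carries. MISC terms are included only if present in the schema (call
#' [exclude_misc()] first to drop them).
#'
#' @param schema an `anatomical_schema`.
#' @param level one of `"organ"`, `"sub_system"`, `"system"`.
#' @return An object of class `level_stats`: list with `level`,
#'   `n_categories`, and `counts`, a named integer vector sorted by count
#'   descending.
#' @export
schema_stats <- function(schema, level = c("organ", "sub_system", "system")) {
  stopifnot(inherits(schema, "anatomical_schema"))
  level <- match.arg(level)
  tab <- table(schema$terms[[level]])
  counts <- sort(as.integer(tab), decreasing = TRUE)
  names(counts) <- names(tab)[order(as.integer(tab), decreasing = TRUE)]
  structure(list(level = level, n_categories = length(counts),
                 counts = counts),
            class = "level_stats")
}

#' @export
print.level_stats <- function(x, ...) {
  cat(sprintf("Level '%s': %d categories\n", x$level, x$n_categories))
  print(utils::head(x$counts, 10L))
  if (x$n_categories > 10L) cat("  ...\n")
  invisible(x)
}

#' Write level statistics to CSV or JSON
#'
#' @param stats a `level_stats` object.
#' @param path output file path.
#' @param format `"csv"` or `"json"`; defaults to the file extension.
#' @return `path`, invisibly.
#' @export
write_level_stats <- function(stats, path, format = NULL) {
  stopifnot(inherits(stats, "level_stats"))
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    df <- data.frame(category = names(stats$counts),
                     n_side_effects = as.integer(stats$counts))
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(level = stats$level, n_categories = stats$n_categories,
           counts = as.list(stats$counts)),
      path, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Construct a binary association matrix
#'
#' Drugs in rows, labels in columns, entries in \{0, 1\}. The `level`
#' attribute records the resolution of the labels (side effects, organs,
#' sub-systems or systems).
#'
#' @param entries binary matrix with unique row names (drug ids) and
#'   unique column names (label ids).
#' @param level label resolution.
#' @return The validated integer matrix with a `level` attribute.
#' @export
association_matrix <- function(entries,
                               level = c("side_effect", "organ",
                                         "sub_system", "system", "pseudo")) {
  level <- match.arg(level)
  entries <- as.matrix(entries)
  if (is.null(rownames(entries)) || is.null(colnames(entries))) {
    stop("association matrix needs row names (drugs) and column names (labels)")
  }
  if (anyDuplicated(rownames(entries)) || anyDuplicated(colnames(entries))) {
    stop("duplicate drug or label ids in association matrix")
  }
  if (!all(entries %in% c(0L, 1L))) stop("entries must be 0/1")
  storage.mode(entries) <- "integer"
  attr(entries, "level") <- level
  entries
}

#' OR-aggregate matrix columns by an arbitrary label-to-category map
#'
#' A category is positive for a drug if the drug carries at least one
#' member label (logical OR). This is the aggregation primitive behind
#' both anatomical coarse-graining and the pseudo-category null control.
#'
#' @param mat binary association matrix (labels in columns).
#' @param mapping named character vector: `mapping[label] = category`.
#'   Must cover every column of `mat`.
#' @param level level tag for the result.
#' @return Binary association matrix with one column per category.
#' @export
aggregate_columns <- function(mat, mapping, level = "pseudo") {
  missing_lab <- setdiff(colnames(mat), names(mapping))
  if (length(missing_lab) > 0L) {
    stop("no category mapping for column(s): ",
         paste(utils::head(missing_lab, 5L), collapse = ", "))
  }
  cats <- sort(unique(unname(mapping[colnames(mat)])))
  out <- matrix(0L, nrow(mat), length(cats),
                dimnames = list(rownames(mat), cats))
  for (k in seq_along(cats)) {
    members <- colnames(mat)[mapping[colnames(mat)] == cats[k]]
    out[, k] <- as.integer(
      rowSums(mat[, members, drop = FALSE]) > 0L)
  }
  association_matrix(out, level = level)
}

#' Coarse-grain a side-effect matrix to a coarser anatomical level
#'
#' Aggregates side-effect columns into organ, sub-system or system
#' categories by logical OR: a drug is positive for a category if it has
#' at least one reported member side effect. MISC terms are excluded
#' before aggregation by default.
#'
#' @param mat binary drug x side-effect matrix (columns named by side
#'   effect, as produced by [build_association_matrix()]).
#' @param schema an `anatomical_schema` covering the matrix columns.
#' @param level target level: `"organ"`, `"sub_system"` or `"system"`.
#' @param drop_unknown if `TRUE`, side-effect columns absent from the
#'   schema are dropped with a message instead of raising an error.
#' @param keep_misc if `TRUE`, MISC terms are aggregated like any others;
#'   by default their columns are removed first.
#' @return Binary association matrix at the requested level.
#' @export
coarse_grain <- function(mat, schema,
                         level = c("organ", "sub_system", "system"),
                         drop_unknown = FALSE, keep_misc = FALSE) {
  stopifnot(inherits(schema, "anatomical_schema"))
  level <- match.arg(level)
  terms <- schema$terms
  if (!keep_misc) terms <- terms[!terms$is_misc, , drop = FALSE]

  known <- colnames(mat) %in% schema$terms$side_effect
  unknown <- colnames(mat)[!known]
  if (length(unknown) > 0L && !drop_unknown) {
    stop("side effect(s) not in schema: ",
         paste(utils::head(unknown, 5L), collapse = ", "),
         if (length(unknown) > 5L) sprintf(" (and %d more)", length(unknown) - 5L),
         "; use drop_unknown = TRUE to exclude them")
  }
  if (length(unknown) > 0L) {
    message(length(unknown), " unknown side-effect column(s) dropped")
  }
  keep_cols <- colnames(mat)[colnames(mat) %in% terms$side_effect]
  if (length(keep_cols) == 0L) stop("no matrix columns remain after filtering")
  mat <- mat[, keep_cols, drop = FALSE]

  mapping <- stats::setNames(terms[[level]], terms$side_effect)
  aggregate_columns(mat, mapping, level = level)
}
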