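#' Construct a feature abundance table
#'
#' A feature table is the central container of the package: a nonnegative
#' numeric matrix of features (rows) by samples (columns), tagged with the
#' functional level of its rows (KO, module or pathway) and a flag recording
#' whether abundances have been normalized to the single-copy scale.
#'
#' @param abundance numeric matrix, features x samples, with unique rownames
#'   (feature ids) and colnames (sample ids). All values must be finite and
#'   nonnegative.
#' @param level one of `"KO"`, `"module"`, `"pathway"`.
#' @param normalized logical; `TRUE` once abundances are on the single-copy
#'   (average copy number per cell) scale.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(abundance, level = c("KO", "module", "pathway"),
                          normalized = FALSE) {
  level <- match.arg(level)
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  if (is.null(rownames(abundance)) || is.null(colnames(abundance))) {
    stop("abundance matrix must have feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(abundance))) {
    stop("feature ids must be unique within a table")
  }
  if (anyDuplicated(colnames(abundance))) {
    stop("sample ids must be unique within a table")
  }
  if (any(!is.finite(abundance)) || any(abundance < 0)) {
    stop("all abundances must be finite and >= 0")
  }
  structure(list(abundance = abundance, level = level,
                 normalized = isTRUE(normalized)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d %s features x %d samples (%s)\n",
              nrow(x$abundance), x$level, ncol(x$abundance),
              if (x$normalized) "normalized" else "raw counts"))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$abundance)

#' @export
as.matrix.feature_table <- function(x, ...) x$abundance

#' Subset a feature table by samples and/or features
#'
#' @param x a [feature_table].
#' @param features,samples character vectors of ids to keep (default: all).
#' @return a [feature_table] restricted to the requested rows/columns.
#' @export
ft_subset <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "feature_table"))
  m <- x$abundance
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(m))
    if (length(missing)) {
      stop("features absent from table: ", paste(missing, collapse = ", "))
    }
    m <- m[features, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(m))
    if (length(missing)) {
      stop("samples absent from table: ", paste(missing, collapse = ", "))
    }
    m <- m[, samples, drop = FALSE]
  }
  feature_table(m, x$level, x$normalized)
}

#' Write / read a feature table as TSV
#'
#' The on-disk format is a plain TSV with a `feature_id` first column and one
#' column per sample; level and normalization status are carried by the
#' caller (and by the pipeline manifest), not the file.
#'
#' @param x a [feature_table].
#' @param path file path.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  df <- data.frame(feature_id = rownames(x$abundance), x$abundance,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param level,normalized level tag and normalization flag to attach on read.
#' @export
read_feature_table <- function(path, level = c("KO", "module", "pathway"),
                               normalized = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"feature_id" %in% names(df)) {
    stop("feature table TSV must have a 'feature_id' column: ", path)
  }
  m <- as.matrix(df[, setdiff(names(df), "feature_id"), drop = FALSE])
  rownames(m) <- df$feature_id
  feature_table(m, match.arg(level), normalized)
}

#' Write / read sample metadata as TSV
#'
#' Metadata carries one row per sample: `sample_id`, `subject_id`,
#' `age_months`, `cohort`, and optional 0/1 diet and antibiotics flags
#' (`breastfed`, `formula_fed`, `abx_current`, `abx_prior`).
#'
#' @param meta a data.frame of sample metadata.
#' @param path file path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("sample_id", "subject_id", "age_months", "cohort")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    stop("metadata is missing required columns: ", paste(missing, collapse = ", "))
  }
  meta
}
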