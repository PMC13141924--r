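#' Feature table container
#'
#' A `feature_table` holds a samples x features abundance matrix together with
#' a scale flag recording what the numbers are. It is the common currency of
#' every analysis stage: ASV and genus count tables, relative abundances,
#' CLR-transformed values, and continuous KO/pathway scores all travel in this
#' container. On disk tables are stored features x samples (the common amplicon
#' convention); in memory they are samples x features.
#'
#' @param abund numeric matrix, samples in rows, features in columns; both
#'   dimnames must be set and unique.
#' @param scale one of `"counts"` (nonnegative integers), `"relative"`
#'   (rows sum to 1), `"clr"` (centered log-ratio values, rows sum to 0) or
#'   `"score"` (nonnegative continuous abundances, e.g. predicted KO scores).
#'
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(abund, scale = c("counts", "relative", "clr", "score")) {
  scale <- match.arg(scale)
  if (!is.matrix(abund) || !is.numeric(abund))
    stop("`abund` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(abund)) || is.null(colnames(abund)))
    stop("`abund` must have sample rownames and feature colnames", call. = FALSE)
  if (anyDuplicated(rownames(abund)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(abund)[duplicated(rownames(abund))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(abund)))
    stop("duplicate feature ids: ",
         paste(unique(colnames(abund)[duplicated(colnames(abund))]), collapse = ", "),
         call. = FALSE)
  if (anyNA(abund)) {
    bad <- which(is.na(abund), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing cell at sample '%s', feature '%s'",
                 rownames(abund)[bad[1L]], colnames(abund)[bad[2L]]), call. = FALSE)
  }
  if (scale %in% c("counts", "relative", "score") && any(abund < 0)) {
    bad <- which(abund < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value at sample '%s', feature '%s'",
                 rownames(abund)[bad[1L]], colnames(abund)[bad[2L]]), call. = FALSE)
  }
  if (scale == "counts" && any(abund != round(abund))) {
    bad <- which(abund != round(abund), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer count at sample '%s', feature '%s'",
                 rownames(abund)[bad[1L]], colnames(abund)[bad[2L]]), call. = FALSE)
  }
  if (scale == "relative") {
    rs <- rowSums(abund)
    if (any(abs(rs - 1) > 1e-9))
      stop("relative-scale rows must sum to 1; first offender: sample '",
           rownames(abund)[which(abs(rs - 1) > 1e-9)[1L]], "'", call. = FALSE)
  }
  structure(list(abund = abund, scale = scale), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features, scale = %s\n",
              nrow(x$abund), ncol(x$abund), x$scale))
  invisible(x)
}

#' @rdname feature_table
#' @param x a `feature_table`.
#' @export
ft_matrix <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  x$abund
}

#' @rdname feature_table
#' @export
ft_samples <- function(x) rownames(ft_matrix(x))

#' @rdname feature_table
#' @export
ft_features <- function(x) colnames(ft_matrix(x))

#' Convert a count or score table to per-sample relative abundances
#'
#' @param x a `feature_table` on the counts or score scale with positive
#'   per-sample totals.
#' @return a `feature_table` on the relative scale.
#' @export
ft_relative <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  if (x$scale == "relative") return(x)
  if (!x$scale %in% c("counts", "score"))
    stop("cannot renormalize a table on scale '", x$scale, "'", call. = FALSE)
  m <- ft_matrix(x)
  tot <- rowSums(m)
  if (any(tot <= 0))
    stop("zero-total sample: ", rownames(m)[which(tot <= 0)[1L]], call. = FALSE)
  feature_table(m / tot, scale = "relative")
}

# Subset a feature table by sample and/or feature ids, preserving the scale
# flag (a subset of a relative table is revalidated by the caller if needed).
ft_subset <- function(x, samples = NULL, features = NULL) {
  m <- ft_matrix(x)
  if (!is.null(samples)) {
    missing <- setdiff(samples, rownames(m))
    if (length(missing))
      stop("samples not in table: ", paste(missing, collapse = ", "), call. = FALSE)
    m <- m[samples, , drop = FALSE]
  }
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(m))
    if (length(missing))
      stop("features not in table: ", paste(missing, collapse = ", "), call. = FALSE)
    m <- m[, features, drop = FALSE]
  }
  structure(list(abund = m, scale = x$scale), class = "feature_table")
}

#' Validate sample metadata for a partially paired two-tissue cohort
#'
#' Metadata carry one row per sample with the patient the sample came from and
#' its tissue label. The paired/clustered design encoded here drives every
#' mixed model and every patient-level resampling procedure in the package.
#'
#' @param df data.frame with columns `sample_id`, `patient_id`, `tissue`
#'   (levels `NC` and `LUAD`); extra covariate columns are carried along.
#' @return the validated data.frame with `tissue` as a factor with levels
#'   `c("NC", "LUAD")` so model coefficients read LUAD minus NC.
#' @export
cohort_metadata <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("sample_id", "patient_id", "tissue")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("metadata missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata", call. = FALSE)
  lev <- unique(as.character(df$tissue))
  if (!all(lev %in% c("NC", "LUAD")))
    stop("tissue must only contain levels 'LUAD' and 'NC'; found: ",
         paste(setdiff(lev, c("NC", "LUAD")), collapse = ", "), call. = FALSE)
  df$tissue <- factor(as.character(df$tissue), levels = c("NC", "LUAD"))
  rownames(df) <- NULL
  df
}

# Align a table with metadata: every table sample must be described.
align_metadata <- function(table, metadata) {
  metadata <- cohort_metadata(metadata)
  ids <- ft_samples(table)
  missing <- setdiff(ids, metadata$sample_id)
  if (length(missing))
    stop("samples absent from metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  metadata[match(ids, metadata$sample_id), , drop = FALSE]
}
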