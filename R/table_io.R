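#' Read a feature table from TSV (or BIOM)
#'
#' Tables are stored on disk features x samples: the first column holds the
#' feature id and the remaining column names are sample ids. If the first
#' column is named `sample_id` the orientation is taken as samples x features
#' instead. Files ending in `.biom` are read through the biomformat package.
#'
#' @param path file path to a TSV (or BIOM 2.1 JSON) table.
#' @param scale scale flag passed to [feature_table()].
#' @return a validated [feature_table()] (samples x features in memory).
#' @export
read_feature_table <- function(path, scale = "counts") {
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the 'biomformat' package", call. = FALSE)
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix") # features x samples
    return(feature_table(t(m), scale = scale))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("table must have an id column plus data columns", call. = FALSE)
  id_col <- names(df)[1L]
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1L, drop = FALSE], 2, as.numeric))) &
                   !is.na(as.matrix(df[, -1L, drop = FALSE])), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-numeric cell at row '%s', column '%s'",
                   ids[bad[1L, 1L]], colnames(df[, -1L, drop = FALSE])[bad[1L, 2L]]),
           call. = FALSE)
    stop("table contains non-numeric cells", call. = FALSE)
  }
  rownames(m) <- ids
  if (identical(id_col, "sample_id")) feature_table(m, scale = scale)
  else feature_table(t(m), scale = scale)
}

#' Write a feature table as TSV (features x samples on disk)
#'
#' @param table a [feature_table()].
#' @param path output path.
#' @param id_name name used for the feature-id column.
#' @export
write_feature_table <- function(table, path, id_name = "feature_id") {
  m <- t(ft_matrix(table)) # features x samples on disk
  df <- data.frame(id = rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write cohort metadata TSV
#'
#' @param path TSV with columns `sample_id`, `patient_id`, `tissue`.
#' @return validated metadata data.frame (see [cohort_metadata()]).
#' @export
read_cohort_metadata <- function(path) {
  cohort_metadata(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' @rdname read_cohort_metadata
#' @param metadata validated metadata.
#' @export
write_cohort_metadata <- function(metadata, path) {
  df <- cohort_metadata(metadata)
  df$tissue <- as.character(df$tissue)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy map
#'
#' A taxonomy map assigns each feature (ASV) a ranked lineage string of the
#' form `d__...;p__...;c__...;o__...;f__...;g__...` (species optional).
#' Placeholder tokens such as `unclassified_f__X` or `norank_c__Y` are allowed
#' and are treated as distinct genus-level units.
#'
#' @param path TSV with columns `feature_id` and `lineage`.
#' @return data.frame with columns `feature_id`, `lineage`.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("feature_id", "lineage") %in% names(df)))
    stop("taxonomy file needs columns 'feature_id' and 'lineage'", call. = FALSE)
  df$feature_id <- as.character(df$feature_id)
  df$lineage <- as.character(df$lineage)
  if (anyDuplicated(df$feature_id))
    stop("duplicate feature ids in taxonomy", call. = FALSE)
  df
}

#' @rdname read_taxonomy
#' @param taxonomy taxonomy data.frame.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy[, c("feature_id", "lineage")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Truncate a lineage at the genus rank. Genus identity is the full lineage
# string down to g__ so that identical genus names in different families (and
# unclassified_/norank_ placeholders) never collide.
genus_lineage <- function(lineage) {
  parts <- strsplit(lineage, ";", fixed = TRUE)
  vapply(parts, function(p) paste(p[seq_len(min(6L, length(p)))], collapse = ";"), "")
}

# Short display label: the genus token (or the deepest classified token).
genus_label <- function(lineage) {
  gl <- genus_lineage(lineage)
  vapply(strsplit(gl, ";", fixed = TRUE), function(p) p[length(p)], "")
}

#' Basic low-abundance ASV filter
#'
#' Retains features detected (count > 0) in at least `min_samples` samples
#' AND with a total of at least `min_total_reads` reads across the data set.
#' Defaults correspond to the common "at least two samples, >= 10 reads"
#' rule for amplicon data sets.
#'
#' @param table counts-scale [feature_table()].
#' @param min_samples minimum number of samples a feature must appear in.
#' @param min_total_reads minimum total reads across all samples.
#' @return filtered `feature_table`.
#' @export
basic_asv_filter <- function(table, min_samples = 2, min_total_reads = 10) {
  stopifnot(inherits(table, "feature_table"))
  if (table$scale != "counts")
    stop("basic_asv_filter requires a counts-scale table", call. = FALSE)
  m <- ft_matrix(table)
  keep <- colSums(m > 0) >= min_samples & colSums(m) >= min_total_reads
  feature_table(m[, keep, drop = FALSE], scale = "counts")
}

#' Remove chloroplast and mitochondrial features
#'
#' Drops features whose lineage contains a chloroplast or mitochondrial token
#' (case-insensitive); these are host/plastid 16S signals, not bacteria.
#'
#' @param table a [feature_table()].
#' @param taxonomy taxonomy map covering every feature of `table`.
#' @return filtered table; the number of removed features is reported.
#' @export
organelle_filter <- function(table, taxonomy) {
  stopifnot(inherits(table, "feature_table"))
  feats <- ft_features(table)
  idx <- match(feats, taxonomy$feature_id)
  if (anyNA(idx))
    stop("features without taxonomy: ",
         paste(feats[is.na(idx)], collapse = ", "), call. = FALSE)
  organelle <- grepl("chloroplast|mitochondri", taxonomy$lineage[idx],
                     ignore.case = TRUE)
  if (any(organelle))
    p16_log("organelle_filter: removed %d chloroplast/mitochondrial feature(s)",
            sum(organelle))
  ft_subset(table, features = feats[!organelle])
}

#' Aggregate an ASV table to genus level
#'
#' Sums ASV counts within each genus-level lineage. Placeholder genera
#' (`unclassified_f__X`, `norank_c__Y`) are kept as distinct units; two
#' unclassified placeholders from different parents never merge because genus
#' identity is the full lineage truncated at the genus rank.
#'
#' @param asv_table counts-scale ASV [feature_table()].
#' @param taxonomy taxonomy map covering all ASVs.
#' @return counts-scale genus `feature_table`; feature ids are genus-level
#'   lineage strings.
#' @export
aggregate_to_genus <- function(asv_table, taxonomy) {
  stopifnot(inherits(asv_table, "feature_table"))
  if (asv_table$scale != "counts")
    stop("aggregate_to_genus requires a counts-scale table", call. = FALSE)
  feats <- ft_features(asv_table)
  idx <- match(feats, taxonomy$feature_id)
  if (anyNA(idx))
    stop("ASVs without taxonomy: ", paste(feats[is.na(idx)], collapse = ", "),
         call. = FALSE)
  gl <- genus_lineage(taxonomy$lineage[idx])
  m <- ft_matrix(asv_table)
  agg <- t(rowsum(t(m), group = gl)) # samples x genera
  feature_table(agg[, sort(colnames(agg)), drop = FALSE], scale = "counts")
}

#' Read a rooted phylogenetic tree (Newick)
#'
#' @param path Newick file.
#' @param features optional feature ids that must all be tree tips (e.g. the
#'   ASVs used for UniFrac); missing tips raise an error listing them.
#' @return an `ape::phylo` tree.
#' @export
read_rooted_tree <- function(path, features = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path, call. = FALSE)
  if (!is.null(features)) {
    missing <- setdiff(features, tree$tip.label)
    if (length(missing))
      stop("tree is missing tips: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  tree
}

#' Read a KO-to-module map
#'
#' @param path TSV with columns `module` and `ko_id`; each KO must belong to
#'   exactly one module.
#' @return data.frame with columns `module`, `ko_id`.
#' @export
read_module_map <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_module_map(df)
}

#' @rdname read_module_map
#' @param module_map data.frame with columns `module`, `ko_id`.
#' @export
validate_module_map <- function(module_map) {
  if (!all(c("module", "ko_id") %in% names(module_map)))
    stop("module map needs columns 'module' and 'ko_id'", call. = FALSE)
  module_map$module <- as.character(module_map$module)
  module_map$ko_id <- as.character(module_map$ko_id)
  dup <- unique(module_map$ko_id[duplicated(module_map$ko_id)])
  if (length(dup))
    stop("KO(s) assigned to more than one module: ",
         paste(dup, collapse = ", "), call. = FALSE)
  module_map
}

#' Write a named list of result data.frames as TSV files
#'
#' @param objects named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_results <- function(objects, out_dir) {
  stopifnot(is.list(objects), !is.null(names(objects)), all(nzchar(names(objects))))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(objects)) {
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    df <- objects[[nm]]
    stopifnot(is.data.frame(df))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
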