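#' Summarize a clinical characteristics count table
#'
#' Clinical baseline tables for cohort studies report categorical
#' characteristics as counts with percentages of the column total. This
#' helper recomputes the percentages from the raw counts, e.g. to verify a
#' published table or to build one from scratch.
#'
#' @param counts data.frame with columns `characteristic`, `count`, `total`.
#' @return the input with an added `percent` column (`100 * count / total`).
#' @export
clinical_percentages <- function(counts) {
  need <- c("characteristic", "count", "total")
  missing <- setdiff(need, names(counts))
  if (length(missing))
    stop("counts table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(counts$count < 0) || any(counts$total <= 0))
    stop("counts must be nonnegative and totals positive", call. = FALSE)
  if (any(counts$count > counts$total))
    stop("count exceeds total for: ",
         paste(counts$characteristic[counts$count > counts$total], collapse = ", "),
         call. = FALSE)
  counts$percent <- 100 * counts$count / counts$total
  counts
}

#' Read a clinical characteristics count TSV
#'
#' @param path TSV with columns `characteristic`, `count`, `total`. A cohort
#'   baseline fixture is shipped under
#'   `system.file("extdata", "cohort_characteristics.tsv", package = "paired16S")`.
#' @return data.frame with the percentages added (see
#'   [clinical_percentages()]).
#' @export
read_clinical_counts <- function(path) {
  clinical_percentages(utils::read.delim(path, sep = "\t",
                                         stringsAsFactors = FALSE))
}
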