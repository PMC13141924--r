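#' Prevalence filter
#'
#' Retains features present (count > 0) in at least `min_prevalence` of
#' samples. The 15% default is the conventional pre-modeling filter for
#' genus-level differential abundance.
#'
#' @param table counts-scale [feature_table()].
#' @param min_prevalence minimum presence fraction in `[0, 1]`.
#' @return filtered table; an empty result raises a warning, not an error.
#' @export
prevalence_filter <- function(table, min_prevalence = 0.15) {
  stopifnot(inherits(table, "feature_table"))
  if (table$scale != "counts")
    stop("prevalence_filter requires counts", call. = FALSE)
  assert_prob(min_prevalence, "min_prevalence")
  m <- ft_matrix(table)
  prev <- colMeans(m > 0)
  keep <- prev >= min_prevalence
  if (!any(keep)) warning("prevalence filter removed every feature")
  structure(list(abund = m[, keep, drop = FALSE], scale = "counts"),
            class = "feature_table")
}

#' Genus-level differential abundance under the partially paired design
#'
#' CLR-transforms the (prevalence-filtered) genus counts with a pseudocount
#' of 1, fits one random-intercept LMM per genus (tissue fixed effect,
#' patient random intercept), and BH-adjusts across genera. This is a
#' documented CLR-LMM analog of a compound-Poisson (CPLM) mixed-model engine:
#' it preserves the paired design and the direction semantics of the
#' coefficients while modeling log-ratio abundances rather than counts.
#'
#' @param table counts-scale genus [feature_table()], prevalence-filtered.
#' @param metadata cohort metadata covering all samples.
#' @param pseudocount CLR pseudocount (default 1).
#' @param q_threshold significance label threshold on the q-value.
#' @return data.frame with columns `genus`, `coefficient` (LUAD vs NC on the
#'   CLR scale), `prevalence`, `p`, `q`, `direction`
#'   (`enriched`/`depleted` in LUAD), `significant`; sorted by `q` then `p`.
#' @export
differential_abundance <- function(table, metadata, pseudocount = 1,
                                   q_threshold = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  if (table$scale != "counts")
    stop("differential_abundance expects a counts table", call. = FALSE)
  metadata <- align_metadata(table, metadata)
  prev <- colMeans(ft_matrix(table) > 0)
  clr <- clr_transform(table, pseudocount = pseudocount)
  scr <- lmm_screen(clr, metadata)
  out <- data.frame(genus = scr$feature,
                    coefficient = scr$beta,
                    prevalence = unname(prev[scr$feature]),
                    p = scr$p,
                    q = scr$fdr,
                    direction = ifelse(scr$beta >= 0, "enriched", "depleted"),
                    significant = scr$fdr < q_threshold,
                    converged = scr$converged,
                    stringsAsFactors = FALSE)
  out[order(out$q, out$p), ]
}
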