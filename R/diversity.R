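#' Rarefy a count table to even depth
#'
#' Per sample, subsamples reads without replacement to exactly `depth` reads
#' (a single seeded draw; optionally the average of several draws, rounded to
#' integer counts, via `n_draws`). Defaults to the minimum sample total, the
#' usual "rarefy to minimum sequencing depth" rule.
#'
#' @param table counts-scale [feature_table()].
#' @param depth target reads per sample; default `min(rowSums)`.
#' @param seed RNG seed.
#' @param n_draws number of independent rarefaction draws to average.
#' @return counts-scale rarefied table.
#' @export
rarefy <- function(table, depth = NULL, seed = 1, n_draws = 1) {
  stopifnot(inherits(table, "feature_table"))
  if (table$scale != "counts") stop("rarefy requires counts", call. = FALSE)
  m <- ft_matrix(table)
  tot <- rowSums(m)
  depth <- depth %||% min(tot)
  low <- tot < depth
  if (any(low))
    stop("sample(s) below rarefaction depth ", depth, ": ",
         paste(rownames(m)[low], collapse = ", "), call. = FALSE)
  out <- withr::with_seed(seed, {
    # rrarefy's "smallest count" advisory misfires on tables whose rarest
    # feature exceeds one read; the subsampling itself is exact
    draws <- lapply(seq_len(n_draws), function(i)
      suppressWarnings(vegan::rrarefy(m, sample = depth)))
    if (n_draws == 1L) draws[[1L]] else round(Reduce(`+`, draws) / n_draws)
  })
  feature_table(out, scale = "counts")
}

#' Alpha-diversity indices per sample
#'
#' Computes observed richness (Sobs), bias-corrected Chao1
#' `S + F1(F1-1)/(2(F2+1))`, ACE (abundance-based coverage estimator, rare
#' cutoff 10; `NA` when undefined, e.g. all-singleton samples), Shannon
#' entropy (natural log) and the Simpson dominance index
#' `sum n_i(n_i-1) / (N(N-1))`. Chao1 and ACE are delegated to
#' [vegan::estimateR()]; Shannon to [vegan::diversity()].
#'
#' @param table counts-scale [feature_table()], typically rarefied first.
#' @return data.frame with columns `sample_id`, `sobs`, `chao1`, `ace`,
#'   `shannon`, `simpson`.
#' @export
alpha_diversity <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (table$scale != "counts") stop("alpha_diversity requires counts", call. = FALSE)
  m <- ft_matrix(table)
  if (any(rowSums(m) <= 0))
    stop("zero-total sample: ", rownames(m)[which(rowSums(m) <= 0)[1L]],
         call. = FALSE)
  est <- vegan::estimateR(m) # rows: S.obs, S.chao1, se, S.ACE, se
  shannon <- vegan::diversity(m, index = "shannon")
  N <- rowSums(m)
  simpson <- rowSums(m * (m - 1)) / (N * (N - 1))
  simpson[N <= 1] <- 1
  ace <- est["S.ACE", ]
  ace[!is.finite(ace)] <- NA_real_
  data.frame(sample_id = rownames(m),
             sobs = unname(est["S.obs", ]),
             chao1 = unname(est["S.chao1", ]),
             ace = unname(ace),
             shannon = unname(shannon),
             simpson = unname(simpson),
             stringsAsFactors = FALSE)
}

#' Test alpha-diversity indices between tissues with LMMs
#'
#' One random-intercept LMM per index (tissue fixed effect, patient random
#' intercept), BH-adjusted across the indices of the level.
#'
#' @param alpha data.frame from [alpha_diversity()].
#' @param metadata cohort metadata covering every alpha row.
#' @return data.frame `index`, `beta`, `se`, `p`, `fdr` ordered by `fdr`.
#' @export
alpha_group_test <- function(alpha, metadata) {
  metadata <- cohort_metadata(metadata)
  md <- metadata[match(alpha$sample_id, metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id))
    stop("alpha rows missing from metadata", call. = FALSE)
  indices <- setdiff(names(alpha), "sample_id")
  rows <- lapply(indices, function(ix) {
    y <- alpha[[ix]]
    ok <- is.finite(y)
    r <- fit_random_intercept_lmm(y[ok], md[ok, , drop = FALSE])
    data.frame(index = ix, beta = r$beta, se = r$se, p = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out <- out[order(out$fdr, out$p), ]
  rownames(out) <- NULL
  out
}

#' Beta-diversity distance matrix
#'
#' Supported metrics: `bray_curtis` (on per-sample relative abundances),
#' `binary_hamming` (fraction of the table's features whose presence differs;
#' denominator configurable to the pairwise union), `unweighted_unifrac` and
#' `weighted_unifrac` (normalized; via phyloseq, a rooted tree covering every
#' feature is required).
#'
#' @param table counts-scale (or relative) [feature_table()].
#' @param metric one of the four metric names.
#' @param tree rooted `phylo` tree (UniFrac metrics only).
#' @param binary_denominator `"all"` (fixed-length Hamming, default) or
#'   `"union"`.
#' @return object of class `dist` with sample labels; the metric name is
#'   attached as attribute `metric`.
#' @export
beta_distance <- function(table, metric = c("bray_curtis", "binary_hamming",
                                            "unweighted_unifrac", "weighted_unifrac"),
                          tree = NULL, binary_denominator = c("all", "union")) {
  metric <- match.arg(metric)
  binary_denominator <- match.arg(binary_denominator)
  stopifnot(inherits(table, "feature_table"))
  m <- ft_matrix(table)
  d <- switch(metric,
    bray_curtis = {
      rel <- ft_matrix(ft_relative(table))
      vegan::vegdist(rel, method = "bray")
    },
    binary_hamming = {
      pres <- m > 0
      if (binary_denominator == "all") {
        stats::dist(pres, method = "manhattan") / ncol(pres)
      } else {
        n <- nrow(pres)
        out <- matrix(0, n, n, dimnames = list(rownames(pres), rownames(pres)))
        for (i in seq_len(n - 1)) for (j in (i + 1):n) {
          union_ij <- sum(pres[i, ] | pres[j, ])
          diff_ij <- sum(xor(pres[i, ], pres[j, ]))
          out[i, j] <- out[j, i] <- if (union_ij == 0) 0 else diff_ij / union_ij
        }
        stats::as.dist(out)
      }
    },
    unweighted_unifrac = unifrac_dist(table, tree, weighted = FALSE),
    weighted_unifrac = unifrac_dist(table, tree, weighted = TRUE))
  attr(d, "metric") <- metric
  d
}

unifrac_dist <- function(table, tree, weighted) {
  if (is.null(tree)) stop("UniFrac metrics require a tree", call. = FALSE)
  feats <- ft_features(table)
  missing <- setdiff(feats, tree$tip.label)
  if (length(missing))
    stop("tree is missing tips: ", paste(missing, collapse = ", "), call. = FALSE)
  otu <- phyloseq::otu_table(ft_matrix(table), taxa_are_rows = FALSE)
  ps <- phyloseq::phyloseq(otu, phyloseq::phy_tree(ape::keep.tip(tree, feats)))
  phyloseq::UniFrac(ps, weighted = weighted, normalized = TRUE)
}

#' Principal coordinate analysis (PCoA)
#'
#' Gower double-centering and eigendecomposition via [stats::cmdscale()].
#' Negative eigenvalues are reported as-is (no Cailliez/Lingoes correction);
#' explained-variance fractions are computed over the positive eigenvalues.
#'
#' @param d a `dist` object or symmetric distance matrix.
#' @param k number of axes to return (default: all with positive eigenvalue).
#' @return list with `coordinates` (samples x axes), `eigenvalues`, and
#'   `explained` (fractions over positive eigenvalues).
#' @export
pcoa_ordination <- function(d, k = NULL) {
  if (!inherits(d, "dist")) {
    dm <- as.matrix(d)
    if (!isSymmetric(unname(dm), tol = 1e-8))
      stop("distance matrix must be symmetric", call. = FALSE)
    d <- stats::as.dist(dm)
  }
  n <- attr(d, "Size")
  # asking for n-1 axes triggers a benign advisory whenever some
  # eigenvalues are <= 0, which is the norm for non-Euclidean distances
  sc <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- sc$eig
  pos <- sum(eig > 1e-12)
  k <- min(k %||% pos, pos)
  coords <- sc$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(k))
  explained <- ifelse(eig > 0, eig / sum(eig[eig > 0]), 0)
  list(coordinates = coords, eigenvalues = eig,
       explained = explained[seq_len(k)])
}

#' PERMANOVA on a distance matrix
#'
#' Anderson's pseudo-F from distance-based sums of squares, with a seeded
#' unrestricted (free) label permutation test, delegated to
#' [vegan::adonis2()] over an explicitly generated permutation matrix.
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_permutations)`. Free permutation
#' is only exactly calibrated for exchangeable samples; for paired designs a
#' restricted mode permuting within patients is available via `strata`.
#'
#' @param d `dist` object or symmetric matrix.
#' @param groups group label per sample (>= 2 groups, each >= 2 samples).
#' @param n_permutations number of permutations (ignored when `permutations`
#'   is supplied).
#' @param seed RNG seed for the permutation draw.
#' @param strata optional blocking factor (e.g. patient id); permutations are
#'   then restricted to shuffle labels within blocks.
#' @param permutations optional explicit permutation matrix (rows = permuted
#'   index vectors), e.g. a full enumeration for exact small-sample tests.
#' @return list of class `permanova_result`: `r_squared`, `pseudo_f`,
#'   `p_value`, `n_permutations`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = 1,
                      strata = NULL, permutations = NULL) {
  if (!inherits(d, "dist")) {
    dm <- as.matrix(d)
    if (!isSymmetric(unname(dm), tol = 1e-8))
      stop("distance matrix must be symmetric", call. = FALSE)
    d <- stats::as.dist(dm)
  }
  n <- attr(d, "Size")
  groups <- as.factor(groups)
  if (length(groups) != n) stop("one group label per sample required", call. = FALSE)
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(tab < 2L))
    stop("group(s) with fewer than 2 samples: ",
         paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)
  if (is.null(permutations)) {
    permutations <- withr::with_seed(seed, {
      if (is.null(strata)) {
        t(replicate(n_permutations, sample.int(n)))
      } else {
        strata <- as.factor(strata)
        t(replicate(n_permutations, {
          idx <- seq_len(n)
          for (lv in levels(strata)) {
            block <- which(strata == lv)
            if (length(block) > 1L) idx[block] <- sample(block)
          }
          idx
        }))
      }
    })
  }
  df <- data.frame(groups = groups)
  fit <- vegan::adonis2(d ~ groups, data = df, permutations = permutations)
  structure(list(r_squared = fit$R2[1L], pseudo_f = fit$F[1L],
                 p_value = fit$`Pr(>F)`[1L], n_permutations = nrow(permutations)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: R2 = %.3f, pseudo-F = %.3f, p = %.4g (%d permutations)\n",
              x$r_squared, x$pseudo_f, x$p_value, x$n_permutations))
  invisible(x)
}
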