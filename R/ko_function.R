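# Normalize a nonnegative KO/pathway table to per-sample relative abundance
# and CLR-transform it. The default pseudocount is half the smallest nonzero
# relative value of the table ("small pseudocount" for continuous predicted
# abundances); genus-level marker analyses use pc = 1 instead.
normalize_clr <- function(table, pseudocount = NULL) {
  stopifnot(inherits(table, "feature_table"))
  rel <- ft_relative(table)
  m <- ft_matrix(rel)
  pc <- pseudocount %||% (min(m[m > 0]) / 2)
  clr_transform(rel, pseudocount = pc)
}

#' KO-level LMM screen with leave-one-patient-out stability
#'
#' Each KO's relative abundance is CLR-transformed and tested with the
#' random-intercept LMM (tissue fixed effect, patient random intercept).
#' Stability is assessed by leave-one-patient-out (LOPO) refitting: for every
#' patient the model is refitted with all of that patient's samples removed.
#' Effects are summarized by `beta_median` (median of the LOPO estimates) and
#' `sign_consistency` (fraction of LOPO estimates sharing the sign of
#' `beta_median`; defined 0 when `beta_median` is 0). Prevalence is the
#' fraction of samples with raw abundance > 0. Failed LOPO refits are skipped
#' and tallied.
#'
#' @param ko_table nonnegative KO [feature_table()] (score or counts scale).
#' @param metadata cohort metadata.
#' @param module_map KO-to-module map covering every KO
#'   (see [read_module_map()]).
#' @param pseudocount CLR pseudocount; default half the smallest nonzero
#'   relative abundance.
#' @return data.frame of class `lopo_records` with columns `ko`, `module`,
#'   `beta_full`, `beta_median`, `sign_consistency`, `prevalence`,
#'   `n_lopo`, `n_failed`.
#' @export
ko_lopo_screen <- function(ko_table, metadata, module_map, pseudocount = NULL) {
  stopifnot(inherits(ko_table, "feature_table"))
  metadata <- align_metadata(ko_table, metadata)
  module_map <- validate_module_map(module_map)
  kos <- ft_features(ko_table)
  mod_idx <- match(kos, module_map$ko_id)
  if (anyNA(mod_idx))
    stop("KO(s) missing from module map: ",
         paste(kos[is.na(mod_idx)], collapse = ", "), call. = FALSE)
  raw <- ft_matrix(ko_table)
  clr <- ft_matrix(normalize_clr(ko_table, pseudocount))
  patients <- unique(metadata$patient_id)
  rows <- lapply(seq_along(kos), function(j) {
    y <- clr[, j]
    full <- fit_random_intercept_lmm(y, metadata)
    lopo <- rep(NA_real_, length(patients))
    for (i in seq_along(patients)) {
      keep <- metadata$patient_id != patients[i]
      r <- tryCatch(
        fit_random_intercept_lmm(y[keep], metadata[keep, , drop = FALSE]),
        error = function(e) NULL)
      if (!is.null(r) && is.finite(r$beta)) lopo[i] <- r$beta
    }
    betas <- lopo[is.finite(lopo)]
    bm <- if (length(betas)) stats::median(betas) else NA_real_
    sc <- if (!is.finite(bm) || bm == 0) 0
          else mean(sign(betas) == sign(bm))
    data.frame(ko = kos[j], module = module_map$module[mod_idx[j]],
               beta_full = full$beta, beta_median = bm,
               sign_consistency = sc,
               prevalence = mean(raw[, j] > 0),
               n_lopo = length(betas),
               n_failed = sum(!is.finite(lopo)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("lopo_records", class(out))
  out
}

#' Retain KOs by pre-specified gates and partition by direction
#'
#' Retention requires, conjunctively and with inclusive boundaries:
#' `prevalence >= prevalence_min`, `|beta_median| >= beta_min`, and
#' `sign_consistency >= consistency_min`. Retained KOs are partitioned into
#' LUAD-upregulated and LUAD-downregulated subsets by the sign of
#' `beta_median`; a module may contribute KOs to both subsets.
#'
#' @param records output of [ko_lopo_screen()].
#' @param prevalence_min,beta_min,consistency_min retention thresholds.
#' @return list with `records` (input plus `retained` and `direction`
#'   columns), `up` and `down` (data.frames of retained KOs per direction).
#' @export
retain_and_partition <- function(records, prevalence_min = 0.20,
                                 beta_min = 0.30, consistency_min = 0.90) {
  stopifnot(is.data.frame(records))
  retained <- records$prevalence >= prevalence_min &
    abs(records$beta_median) >= beta_min &
    records$sign_consistency >= consistency_min
  retained[is.na(retained)] <- FALSE
  direction <- ifelse(records$beta_median > 0, "up",
                      ifelse(records$beta_median < 0, "down", NA_character_))
  direction[!retained] <- NA_character_
  records$retained <- retained
  records$direction <- direction
  list(records = records,
       up = records[retained & direction == "up", , drop = FALSE],
       down = records[retained & direction == "down", , drop = FALSE])
}

#' Direction-specific module scores
#'
#' For each (module, direction) with a nonempty retained KO subset, the score
#' of a sample is the unweighted mean CLR abundance over the subset's KOs.
#' The up and down subsets of a module are disjoint by construction, so their
#' scores summarize different KOs.
#'
#' @param ko_table nonnegative KO [feature_table()].
#' @param partition output of [retain_and_partition()].
#' @param pseudocount CLR pseudocount (same default as [ko_lopo_screen()]).
#' @return list with `scores` (samples x subsets matrix, columns named
#'   `module|direction`) and `subsets` (data.frame `module`, `direction`,
#'   `n_kos`); empty subsets are skipped with a log entry.
#' @export
module_scores <- function(ko_table, partition, pseudocount = NULL) {
  stopifnot(inherits(ko_table, "feature_table"))
  clr <- ft_matrix(normalize_clr(ko_table, pseudocount))
  sets <- rbind(partition$up, partition$down)
  if (is.null(sets) || nrow(sets) == 0L) {
    p16_log("module_scores: no retained KOs")
    return(list(scores = matrix(0, nrow(clr), 0,
                                dimnames = list(rownames(clr), NULL)),
                subsets = data.frame(module = character(0),
                                     direction = character(0),
                                     n_kos = integer(0))))
  }
  key <- unique(sets[, c("module", "direction")])
  cols <- list(); meta <- list()
  for (i in seq_len(nrow(key))) {
    sel <- sets$ko[sets$module == key$module[i] & sets$direction == key$direction[i]]
    sel <- intersect(sel, colnames(clr))
    if (!length(sel)) next
    cols[[paste(key$module[i], key$direction[i], sep = "|")]] <-
      rowMeans(clr[, sel, drop = FALSE])
    meta[[length(meta) + 1L]] <- data.frame(module = key$module[i],
                                            direction = key$direction[i],
                                            n_kos = length(sel),
                                            stringsAsFactors = FALSE)
  }
  scores <- do.call(cbind, cols)
  rownames(scores) <- rownames(clr)
  list(scores = scores, subsets = do.call(rbind, meta))
}

#' Test direction-specific module scores between tissues
#'
#' One random-intercept LMM per (module, direction) score, BH-adjusted within
#' each direction separately.
#'
#' @param scores output of [module_scores()].
#' @param metadata cohort metadata.
#' @param fdr_threshold significance threshold on the within-direction FDR.
#' @return data.frame `module`, `direction`, `n_kos`, `beta`, `se`, `p`,
#'   `fdr`, `significant`.
#' @export
module_score_test <- function(scores, metadata, fdr_threshold = 0.05) {
  metadata <- cohort_metadata(metadata)
  sm <- scores$scores
  if (ncol(sm) == 0L)
    return(data.frame(module = character(0), direction = character(0),
                      n_kos = integer(0), beta = numeric(0), se = numeric(0),
                      p = numeric(0), fdr = numeric(0),
                      significant = logical(0)))
  md <- metadata[match(rownames(sm), metadata$sample_id), , drop = FALSE]
  out <- scores$subsets
  fits <- lapply(seq_len(ncol(sm)), function(j)
    fit_random_intercept_lmm(sm[, j], md))
  out$beta <- vapply(fits, `[[`, 0, "beta")
  out$se <- vapply(fits, `[[`, 0, "se")
  out$p <- vapply(fits, `[[`, 0, "p_value")
  out$fdr <- NA_real_
  for (d in unique(out$direction)) {
    sel <- out$direction == d
    out$fdr[sel] <- bh_adjust(out$p[sel])
  }
  out$significant <- out$fdr < fdr_threshold
  out[order(out$direction, out$fdr), ]
}

#' Level-3 pathway differential test
#'
#' Normalizes pathway abundances per sample, CLR-transforms with a small
#' pseudocount, and runs the per-feature LMM screen with BH adjustment across
#' pathways.
#'
#' @param pathway_table nonnegative pathway [feature_table()].
#' @param metadata cohort metadata.
#' @param pseudocount CLR pseudocount; default half the smallest nonzero
#'   relative abundance.
#' @return data.frame as from [lmm_screen()] (`feature` = pathway id).
#' @export
pathway_level_test <- function(pathway_table, metadata, pseudocount = NULL) {
  stopifnot(inherits(pathway_table, "feature_table"))
  clr <- normalize_clr(pathway_table, pseudocount)
  lmm_screen(clr, metadata)
}
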