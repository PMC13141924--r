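#' Patient-level cluster bootstrap
#'
#' Each iteration draws patients with replacement up to the original patient
#' count; all samples of a drawn patient enter the training set (duplicated
#' once per draw) and the out-of-bag (OOB) set is every sample of an undrawn
#' patient. Resampling whole patients keeps paired samples together and
#' prevents information leakage between a patient's tumor and NC samples.
#'
#' @param patients character vector of patient ids (unique ids are resampled;
#'   >= 5 distinct patients required).
#' @param n_bootstrap number of bootstrap iterations.
#' @param seed RNG seed.
#' @return list of length `n_bootstrap`; each element a character multiset of
#'   drawn patient ids.
#' @export
cluster_bootstrap <- function(patients, n_bootstrap, seed = 1) {
  up <- unique(as.character(patients))
  if (length(up) < 5L) stop("need at least 5 patients", call. = FALSE)
  withr::with_seed(seed, {
    lapply(seq_len(n_bootstrap), function(i) sample(up, length(up), replace = TRUE))
  })
}

# One stability-selection iteration: given the CLR matrix, labels, patient
# ids and a drawn patient multiset, standardize with training statistics
# only, choose the elastic-net penalty by patient-grouped CV, and return the
# selected features plus OOB predicted probabilities. All leakage-sensitive
# quantities (Z-statistics, lambda) are computed from training rows alone.
.stability_iteration <- function(clr_mat, labels, patients, draw,
                                 alpha_mixing = 0.5, n_lambda = 20L,
                                 n_folds = 5L) {
  train_idx <- unlist(lapply(draw, function(p) which(patients == p)),
                      use.names = FALSE)
  oob_idx <- which(!patients %in% draw)
  y_tr <- labels[train_idx]
  if (length(unique(y_tr)) < 2L)
    return(list(ok = FALSE))
  x_tr <- clr_mat[train_idx, , drop = FALSE]
  mu <- colMeans(x_tr)
  sd_tr <- apply(x_tr, 2, stats::sd)
  usable <- sd_tr > 0
  z_tr <- sweep(sweep(x_tr[, usable, drop = FALSE], 2, mu[usable]), 2,
                sd_tr[usable], `/`)
  # patient-grouped folds: every row of a patient shares a fold. Patients
  # are shuffled within strata defined by their tissue composition so no
  # fold's training complement can lose a whole class by bad luck alone.
  tr_pat <- patients[train_idx]
  up_tr <- unique(tr_pat)
  k <- min(n_folds, length(up_tr))
  has_nc <- vapply(up_tr, function(p) any(y_tr[tr_pat == p] == "NC"), TRUE)
  ordered_pat <- c(sample(up_tr[has_nc]), sample(up_tr[!has_nc]))
  fold_of <- stats::setNames(rep(seq_len(k), length.out = length(up_tr)),
                             ordered_pat)
  foldid <- unname(fold_of[tr_pat])
  # small grouped folds routinely trip glmnet's "too few observations per
  # fold" advisory for the AUC measure; the fit itself is fine. A resample
  # whose folds still degenerate to one class is reported as not usable.
  cv <- tryCatch(suppressWarnings(
    glmnet::cv.glmnet(z_tr, y_tr, family = "binomial",
                      alpha = alpha_mixing, nlambda = n_lambda,
                      foldid = foldid, type.measure = "auc",
                      standardize = FALSE)),
    error = function(e) NULL)
  if (is.null(cv)) return(list(ok = FALSE))
  co <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1L]
  selected <- colnames(z_tr)[co != 0]
  coefs <- stats::setNames(rep(0, ncol(clr_mat)), colnames(clr_mat))
  coefs[colnames(z_tr)] <- co
  oob_prob <- NULL
  if (length(oob_idx)) {
    z_oob <- sweep(sweep(clr_mat[oob_idx, usable, drop = FALSE], 2, mu[usable]),
                   2, sd_tr[usable], `/`)
    oob_prob <- as.numeric(stats::predict(cv, newx = z_oob, s = "lambda.min",
                                          type = "response"))
  }
  list(ok = TRUE, selected = selected, coefs = coefs,
       oob_idx = oob_idx, oob_prob = oob_prob,
       lambda = cv$lambda.min)
}

#' Cluster-bootstrap stability selection of genus markers
#'
#' Per bootstrap iteration: CLR-transform (pseudocount 1), Z-score
#' standardize using training-set statistics only, fit an elastic-net
#' logistic model with the penalty chosen by patient-grouped cross-validation
#' over a logarithmic grid (maximizing training-fold AUC), and record which
#' features enter the model with a nonzero coefficient. Selection frequency
#' is `times selected / n_bootstrap`; the stable panel is every feature whose
#' frequency exceeds `threshold`. Each sample's OOB score is the mean
#' predicted probability over iterations in which its patient was out of bag.
#'
#' @param table counts-scale genus [feature_table()].
#' @param metadata cohort metadata; both tissue classes must be present.
#' @param pseudocount CLR pseudocount.
#' @param alpha_mixing elastic-net mixing parameter in `(0, 1]`.
#' @param n_bootstrap number of bootstrap iterations.
#' @param threshold selection-frequency threshold defining the panel
#'   (frequencies must exceed it strictly).
#' @param n_lambda penalty-grid size.
#' @param n_folds cross-validation folds (grouped by patient).
#' @param oob_aggregate `"mean"` (default) or `"median"` OOB aggregation.
#' @param seed RNG seed; the full result is reproducible from config + seed.
#' @return list of class `stability_selection_result`: `selection_frequency`
#'   (named vector), `panel`, `coefficients` (features x iterations matrix),
#'   `oob_score` / `oob_times` per sample, `labels`, `patients`, `n_bootstrap`,
#'   `threshold`, `n_redrawn`.
#' @export
stability_select <- function(table, metadata, pseudocount = 1,
                             alpha_mixing = 0.5, n_bootstrap = 500,
                             threshold = 0.60, n_lambda = 20, n_folds = 5,
                             oob_aggregate = c("mean", "median"), seed = 1) {
  stopifnot(inherits(table, "feature_table"))
  oob_aggregate <- match.arg(oob_aggregate)
  metadata <- align_metadata(table, metadata)
  if (length(unique(metadata$tissue)) < 2L)
    stop("both tissue classes required", call. = FALSE)
  clr <- ft_matrix(clr_transform(table, pseudocount = pseudocount))
  labels <- factor(metadata$tissue, levels = c("NC", "LUAD"))
  patients <- metadata$patient_id
  up <- unique(patients)
  if (length(up) < 5L) stop("need at least 5 patients", call. = FALSE)
  feats <- colnames(clr)
  sel_count <- stats::setNames(numeric(length(feats)), feats)
  coef_mat <- matrix(0, length(feats), n_bootstrap,
                     dimnames = list(feats, NULL))
  oob_sum <- stats::setNames(numeric(nrow(clr)), rownames(clr))
  oob_list <- vector("list", nrow(clr))
  oob_times <- stats::setNames(integer(nrow(clr)), rownames(clr))
  n_redrawn <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(n_bootstrap)) {
      it <- NULL
      for (attempt in seq_len(100L)) {
        draw <- sample(up, length(up), replace = TRUE)
        it <- .stability_iteration(clr, labels, patients, draw,
                                   alpha_mixing = alpha_mixing,
                                   n_lambda = n_lambda, n_folds = n_folds)
        if (it$ok) break
        n_redrawn <- n_redrawn + 1L
      }
      if (!it$ok)
        stop("could not draw a two-class bootstrap resample", call. = FALSE)
      sel_count[it$selected] <- sel_count[it$selected] + 1
      coef_mat[names(it$coefs), b] <- it$coefs
      if (length(it$oob_idx)) {
        oob_sum[it$oob_idx] <- oob_sum[it$oob_idx] + it$oob_prob
        oob_times[it$oob_idx] <- oob_times[it$oob_idx] + 1L
        if (oob_aggregate == "median") {
          for (j in seq_along(it$oob_idx)) {
            i <- it$oob_idx[j]
            oob_list[[i]] <- c(oob_list[[i]], it$oob_prob[j])
          }
        }
      }
    }
  })
  if (n_redrawn > 0)
    p16_log("stability_select: redrew %d single-class resample(s)", n_redrawn)
  freq <- sel_count / n_bootstrap
  oob_score <- ifelse(oob_times > 0, oob_sum / pmax(oob_times, 1L), NA_real_)
  if (oob_aggregate == "median")
    oob_score <- vapply(seq_along(oob_list), function(i)
      if (oob_times[i] > 0) stats::median(oob_list[[i]]) else NA_real_, 0)
  names(oob_score) <- rownames(clr)
  structure(list(selection_frequency = freq,
                 panel = names(freq)[freq > threshold],
                 coefficients = coef_mat,
                 oob_score = oob_score,
                 oob_times = oob_times,
                 labels = labels, patients = patients,
                 n_bootstrap = n_bootstrap, threshold = threshold,
                 pseudocount = pseudocount, n_redrawn = n_redrawn),
            class = "stability_selection_result")
}

#' @export
print.stability_selection_result <- function(x, ...) {
  cat(sprintf("<stability_selection_result> %d iterations, threshold %.2f\n",
              x$n_bootstrap, x$threshold))
  cat("panel:", if (length(x$panel)) paste(x$panel, collapse = ", ") else "(empty)",
      "\n")
  invisible(x)
}

#' Out-of-bag ROC of a stability-selection run
#'
#' ROC/AUC with confidence interval on the aggregated OOB scores versus the
#' true tissue labels. Samples never out of bag are excluded (count
#' reported).
#'
#' @param result a [stability_select()] result.
#' @param ci_method passed to [roc_auc_ci()].
#' @return a `roc_result` (see [roc_auc_ci()]) with attribute `n_excluded`.
#' @export
oob_roc <- function(result, ci_method = "delong") {
  stopifnot(inherits(result, "stability_selection_result"))
  scored <- result$oob_times > 0
  if (sum(!scored) > 0)
    p16_log("oob_roc: %d sample(s) never out-of-bag, excluded", sum(!scored))
  lab <- result$labels[scored]
  if (min(table(lab)) < 2L)
    stop("fewer than 2 OOB-scored samples in a class", call. = FALSE)
  r <- roc_auc_ci(lab, result$oob_score[scored], ci_method = ci_method,
                  patients = result$patients[scored])
  attr(r, "n_excluded") <- sum(!scored)
  r
}

#' Refit the stable marker panel and report apparent performance
#'
#' Single multivariable logistic fit of the panel on CLR + Z-scored features
#' over all samples, lightly ridge-regularized so the fit exists under
#' complete separation. Reports log-odds coefficients and the apparent
#' (training) ROC.
#'
#' @param table counts-scale genus [feature_table()].
#' @param metadata cohort metadata.
#' @param panel nonempty character vector of panel features.
#' @param pseudocount CLR pseudocount.
#' @param ridge_lambda small fixed ridge penalty.
#' @return list with `coefficients` (named log-odds, intercept included),
#'   `apparent_roc` (a `roc_result`), and `scores` (fitted probabilities).
#' @export
refit_panel <- function(table, metadata, panel, pseudocount = 1,
                        ridge_lambda = 0.01) {
  stopifnot(inherits(table, "feature_table"))
  if (length(panel) == 0L) stop("panel is empty", call. = FALSE)
  metadata <- align_metadata(table, metadata)
  clr <- ft_matrix(clr_transform(table, pseudocount = pseudocount))
  missing <- setdiff(panel, colnames(clr))
  if (length(missing))
    stop("panel features not in table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  x <- scale(clr[, panel, drop = FALSE])
  y <- factor(metadata$tissue, levels = c("NC", "LUAD"))
  if (length(panel) == 1L) x <- cbind(x, 0) # glmnet needs >= 2 columns
  # glmnet's small-class advisory is expected on compact cohorts
  fit <- suppressWarnings(
    glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                   lambda = ridge_lambda, standardize = FALSE))
  co <- as.numeric(stats::coef(fit))
  names(co) <- rownames(stats::coef(fit))
  co <- co[c("(Intercept)", panel)]
  scores <- as.numeric(stats::predict(fit, newx = x, type = "response"))
  names(scores) <- rownames(clr)
  list(coefficients = co,
       apparent_roc = roc_auc_ci(y, scores),
       scores = scores)
}
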