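#' Centered log-ratio (CLR) transform
#'
#' Per sample, `clr(x) = log(x + pc) - mean(log(x + pc))` over features, so
#' each CLR row sums to zero. The pseudocount keeps zeros finite; genus-level
#' marker analyses here use `pc = 1`, continuous KO/pathway tables use half
#' the smallest nonzero value by default (see [ko_lopo_screen()]).
#'
#' @param table nonnegative [feature_table()] (counts, relative or score).
#' @param pseudocount positive offset added before taking logs.
#' @return a `feature_table` on the clr scale.
#' @export
clr_transform <- function(table, pseudocount = 1) {
  stopifnot(inherits(table, "feature_table"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0)
    stop("`pseudocount` must be a single positive number", call. = FALSE)
  if (table$scale == "clr") stop("table is already CLR-transformed", call. = FALSE)
  lg <- log(ft_matrix(table) + pseudocount)
  feature_table(lg - rowMeans(lg), scale = "clr")
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH with monotone enforcement, mapped back to the input
#' order. Thin validating wrapper over [stats::p.adjust()].
#'
#' @param p vector of p-values in `[0, 1]` (NA allowed, propagated).
#' @return vector of q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("`p` must be numeric", call. = FALSE)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Random-intercept linear mixed model for a paired two-tissue design
#'
#' Fits `y = b0 + b * 1[tissue == LUAD] + u_patient + e` by REML
#' ([lmerTest::lmer()]), testing the tissue coefficient with a Wald t test on
#' Kenward-Roger denominator degrees of freedom (Satterthwaite fallback) —
#' the large-sample z reference is anticonservative at the patient counts
#' these partially paired cohorts have.
#' When the patient variance is estimated on the boundary (zero) the fit
#' coincides with OLS and is flagged `boundary`. If the mixed fit fails, an
#' OLS fallback is returned with `converged = FALSE`.
#'
#' @param y numeric response, one value per metadata row.
#' @param metadata cohort metadata (see [cohort_metadata()]); both tissue
#'   levels and at least two patients are required.
#' @return list of class `lmm_result`: `beta` (LUAD minus NC), `se`, `p_value`,
#'   `n_samples`, `n_patients`, `converged`, `boundary`.
#' @export
fit_random_intercept_lmm <- function(y, metadata) {
  metadata <- cohort_metadata(metadata)
  if (length(y) != nrow(metadata))
    stop("`y` must have one value per metadata row", call. = FALSE)
  if (length(unique(metadata$patient_id)) < 2L)
    stop("need at least two patients", call. = FALSE)
  if (length(unique(metadata$tissue)) < 2L)
    stop("both tissue levels must be present", call. = FALSE)
  df <- data.frame(y = y, tissue = metadata$tissue, patient = metadata$patient_id)
  res <- list(beta = NA_real_, se = NA_real_, p_value = NA_real_,
              n_samples = nrow(df), n_patients = length(unique(df$patient)),
              converged = FALSE, boundary = FALSE)
  if (stats::sd(y) == 0) {
    # constant response: no tissue effect, nothing to estimate
    res$beta <- 0; res$se <- NA_real_; res$p_value <- 1
    res$converged <- TRUE; res$boundary <- TRUE
    class(res) <- "lmm_result"
    return(res)
  }
  est <- tryCatch(
    suppressMessages(suppressWarnings({
      fit <- lmerTest::lmer(y ~ tissue + (1 | patient), data = df, REML = TRUE,
                            control = lme4::lmerControl(check.conv.singular = "ignore"))
      # Kenward-Roger df; Satterthwaite as fallback when KR degenerates
      sm <- tryCatch(stats::coef(summary(fit, ddf = "Kenward-Roger")),
                     error = function(e) stats::coef(summary(fit)))
      if (!is.finite(sm["tissueLUAD", "Pr(>|t|)"]))
        sm <- stats::coef(summary(fit))
      list(beta = unname(sm["tissueLUAD", "Estimate"]),
           se = unname(sm["tissueLUAD", "Std. Error"]),
           df = unname(sm["tissueLUAD", "df"]),
           p = unname(sm["tissueLUAD", "Pr(>|t|)"]),
           boundary = lme4::isSingular(fit, tol = 1e-6))
    })),
    error = function(e) NULL)
  if (!is.null(est)) {
    res$beta <- est$beta
    res$se <- est$se
    res$p_value <- est$p
    res$converged <- TRUE
    res$boundary <- est$boundary
    # Satterthwaite occasionally degenerates (df ~ 0) on pathological fits;
    # fall back to the large-sample Wald reference for those
    if (!is.finite(res$p_value) && is.finite(res$se) && res$se > 0)
      res$p_value <- 2 * stats::pnorm(-abs(res$beta / res$se))
  } else {
    ols <- stats::lm(y ~ tissue, data = df)
    sm <- summary(ols)$coefficients
    if ("tissueLUAD" %in% rownames(sm)) {
      res$beta <- sm["tissueLUAD", "Estimate"]
      res$se <- sm["tissueLUAD", "Std. Error"]
      res$p_value <- sm["tissueLUAD", "Pr(>|t|)"]
    }
  }
  if (!is.finite(res$p_value) && is.finite(res$beta) && abs(res$beta) < 1e-12) {
    # degenerate (e.g. near-constant) response: no evidence of an effect
    res$p_value <- 1
  }
  class(res) <- "lmm_result"
  res
}

#' Per-feature LMM screen with BH adjustment
#'
#' Fits [fit_random_intercept_lmm()] for every feature column of a table and
#' adjusts p-values across features with BH. Failed fits are reported with
#' `converged = FALSE`, never silently dropped.
#'
#' @param table a [feature_table()] (any scale; typically CLR).
#' @param metadata cohort metadata describing every table sample.
#' @return data.frame with one row per feature (`feature`, `beta`, `se`, `p`,
#'   `fdr`, `converged`, `boundary`), ordered by `fdr` then `p`.
#' @export
lmm_screen <- function(table, metadata) {
  metadata <- align_metadata(table, metadata)
  m <- ft_matrix(table)
  rows <- lapply(colnames(m), function(f) {
    r <- fit_random_intercept_lmm(m[, f], metadata)
    data.frame(feature = f, beta = r$beta, se = r$se, p = r$p_value,
               converged = r$converged, boundary = r$boundary,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out <- out[order(out$fdr, out$p), c("feature", "beta", "se", "p", "fdr",
                                      "converged", "boundary")]
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks for ties; two-sided p from `t = rho * sqrt((n-2)/(1-rho^2))`
#' on `n - 2` degrees of freedom. A constant input yields `rho = NA` with a
#' warning (correlation undefined).
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return list with `rho` and `p_value`.
#' @export
spearman_assoc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 4L) stop("need at least 4 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_))
  }
  rho <- stats::cor(rank(x), rank(y))
  list(rho = rho, p_value = spearman_p(rho, n))
}

# Two-sided t-approximation p for a Spearman rho at sample size n (vectorized).
spearman_p <- function(rho, n) {
  r <- pmin(pmax(rho, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  p
}

# All pairwise Spearman correlations of a samples x features matrix.
# Returns rho and p matrices (features x features); constant columns give NA.
spearman_matrix <- function(m) {
  n <- nrow(m)
  ranks <- apply(m, 2, rank)
  rho <- suppressWarnings(stats::cor(ranks))
  const <- apply(m, 2, function(v) stats::sd(v) == 0)
  rho[const, ] <- NA_real_
  rho[, const] <- NA_real_
  p <- spearman_p(rho, n)
  p[is.na(rho)] <- NA_real_
  list(rho = rho, p = p)
}

#' ROC curve AUC with confidence interval
#'
#' AUC via the Mann-Whitney formulation (ties count one half), with a 95%
#' DeLong confidence interval by default ([pROC]); an optional patient-level
#' bootstrap percentile interval resamples whole patients so paired samples
#' travel together.
#'
#' @param labels tissue labels (factor/character with levels NC, LUAD, or 0/1
#'   with 1 the positive class).
#' @param scores numeric predicted scores, larger meaning more LUAD-like.
#' @param ci_method `"delong"` (default) or `"patient_bootstrap"`.
#' @param patients patient ids (required for `"patient_bootstrap"`).
#' @param n_boot bootstrap replicates for the percentile interval.
#' @param seed RNG seed for the bootstrap interval.
#' @return list of class `roc_result`: `auc`, `ci_low`, `ci_high`, `labels`,
#'   `scores`, `ci_method`.
#' @export
roc_auc_ci <- function(labels, scores, ci_method = c("delong", "patient_bootstrap"),
                       patients = NULL, n_boot = 2000, seed = 1) {
  ci_method <- match.arg(ci_method)
  lab <- as_binary_labels(labels)
  if (length(unique(lab)) < 2L)
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  r <- pROC::roc(response = lab, predictor = scores, levels = c("NC", "LUAD"),
                 direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  if (ci_method == "delong") {
    ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
    lo <- max(0, ci[1L]); hi <- min(1, ci[3L])
  } else {
    if (is.null(patients)) stop("patient ids required for patient_bootstrap CI",
                                call. = FALSE)
    aucs <- withr::with_seed(seed, {
      up <- unique(patients)
      replicate(n_boot, {
        draw <- sample(up, length(up), replace = TRUE)
        idx <- unlist(lapply(draw, function(p) which(patients == p)))
        lb <- lab[idx]
        if (length(unique(lb)) < 2L) return(NA_real_)
        rb <- pROC::roc(lb, scores[idx], levels = c("NC", "LUAD"),
                        direction = "<", quiet = TRUE)
        as.numeric(pROC::auc(rb))
      })
    })
    qs <- stats::quantile(aucs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    lo <- qs[1L]; hi <- qs[2L]
  }
  structure(list(auc = auc, ci_low = min(lo, auc), ci_high = max(hi, auc),
                 labels = lab, scores = scores, ci_method = ci_method),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI: %.3f-%.3f, %s)\n",
              x$auc, x$ci_low, x$ci_high, x$ci_method))
  invisible(x)
}

# Normalize assorted label encodings to a factor with levels NC < LUAD.
as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.numeric(labels) || is.logical(labels)) {
    labels <- ifelse(as.numeric(labels) > 0, "LUAD", "NC")
  }
  if (!all(labels %in% c("NC", "LUAD")))
    stop("labels must be NC/LUAD (or 0/1)", call. = FALSE)
  factor(labels, levels = c("NC", "LUAD"))
}
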