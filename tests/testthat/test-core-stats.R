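test_that("CLR transform matches the closed form and sums to zero", {
  ft <- feature_table(matrix(c(1, 3, 1, 1, 1, 1), nrow = 2, byrow = TRUE,
                             dimnames = list(c("s2", "s1"), c("f1", "f2", "f3"))),
                      "counts")
  clr <- ft_matrix(clr_transform(ft, pseudocount = 1))
  expect_equal(unname(clr["s1", ]), c(0, 0, 0))
  # sample [3,1], pc=1: log(4), log(2) centered -> +/- log(2)/2
  two <- feature_table(matrix(c(3, 1), 1, dimnames = list("s", c("a", "b"))),
                       "counts")
  v <- ft_matrix(clr_transform(two, 1))
  expect_equal(unname(v[1, ]), c(log(2) / 2, -log(2) / 2), tolerance = 1e-12)
  expect_error(clr_transform(two, 0), "positive")
  # property: rows sum to 0 on random tables
  co <- tiny_cohort(seed = 21)
  rs <- rowSums(ft_matrix(clr_transform(co$genus, 1)))
  expect_true(all(abs(rs) < 1e-9))
})

test_that("CLR is exactly invariant to per-sample scaling when the pseudocount scales", {
  co <- tiny_cohort(seed = 4)
  m <- ft_matrix(co$genus)
  a <- ft_matrix(clr_transform(feature_table(m, "counts"), 1))
  b <- ft_matrix(clr_transform(feature_table(m * 7, "counts"), 7))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("BH adjustment reproduces the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)       # m = 1 is the identity
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  p <- c(0.001, 0.04, 0.03, 0.9, 0.5)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12)) # monotone in rank of p
  expect_equal(max(q), max(p))                  # BH never decreases the max p
})

test_that("LMM recovers an exactly forced paired difference", {
  md <- paired_metadata(6)
  b <- stats::setNames(rnorm(6, 0, 3), unique(md$patient_id))
  d <- 1.75
  y <- b[md$patient_id] + d * (md$tissue == "LUAD")
  r <- fit_random_intercept_lmm(y, md)
  expect_equal(r$beta, d, tolerance = 1e-6)
  expect_true(r$converged)
})

test_that("LMM handles constant responses and matches OLS at the variance boundary", {
  md <- paired_metadata(6)
  rc <- fit_random_intercept_lmm(rep(2.5, nrow(md)), md)
  expect_equal(rc$beta, 0, tolerance = 1e-10)
  expect_equal(rc$p_value, 1)
  # patient means all zero by construction: variance component estimated at
  # the boundary, so the fit must coincide with OLS
  z <- rep(c(1, -1), 3)
  y <- c(z, -z) # metadata rows: all NC then all LUAD; (y_N, y_T) = (z_i, -z_i)
  r <- fit_random_intercept_lmm(y, md)
  ols <- summary(lm(y ~ tissue, data = md))$coefficients
  expect_true(r$boundary)
  expect_equal(r$beta, ols["tissueLUAD", "Estimate"], tolerance = 1e-6)
  expect_equal(r$se, ols["tissueLUAD", "Std. Error"], tolerance = 1e-6)
  luad <- md$tissue == "LUAD"
  expect_error(fit_random_intercept_lmm(y[luad], md[luad, ]), "both tissue")
})

test_that("LMM recovers a planted effect with patient random intercepts", {
  md <- paired_metadata(200)
  y <- withr::with_seed(42, {
    u <- rnorm(200, 0, 1)
    names(u) <- unique(md$patient_id)
    u[md$patient_id] + 1 * (md$tissue == "LUAD") + rnorm(nrow(md), 0, 0.5)
  })
  r <- fit_random_intercept_lmm(y, md)
  expect_gt(r$beta, 0.9)
  expect_lt(r$beta, 1.1)
  expect_false(r$boundary)
})

test_that("lmm_screen adjusts across features and keeps single-feature fdr == p", {
  co <- tiny_cohort(seed = 33)
  clr <- clr_transform(co$genus, 1)
  scr <- lmm_screen(clr, co$metadata)
  expect_identical(nrow(scr), length(ft_features(co$genus)))
  expect_true(all(diff(scr$fdr) >= -1e-12))
  one <- lmm_screen(paired16S:::ft_subset(clr, features = ft_features(clr)[1]),
                    co$metadata)
  expect_equal(one$fdr, one$p)
})

test_that("Spearman association matches cor.test and a permutation oracle", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 3, 6, 5)
  r <- spearman_assoc(x, y)
  expect_equal(r$rho, unname(cor(x, y, method = "spearman")), tolerance = 1e-12)
  # monotone relations
  expect_equal(spearman_assoc(x, exp(x))$rho, 1)
  expect_equal(spearman_assoc(x, rev(x))$rho, -1)
  expect_warning(spearman_assoc(x, rep(1, 6)), "constant")
  # exhaustive permutation oracle at n = 6: two-sided tail of |rho|
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(z) length(unique(z)) == 6L), ]
  rho_perm <- apply(perms, 1, function(idx) cor(x, y[idx], method = "spearman"))
  p_exact <- mean(abs(rho_perm) >= abs(r$rho) - 1e-12)
  expect_lt(abs(r$p_value - p_exact), 0.02)
})

test_that("AUC follows the Mann-Whitney conventions and DeLong CI brackets it", {
  r <- roc_auc_ci(c("NC", "NC", "LUAD", "LUAD"), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(r$auc, 1)
  tied <- roc_auc_ci(c("NC", "NC", "LUAD", "LUAD"), rep(0.5, 4))
  expect_equal(tied$auc, 0.5)
  s <- c(0.3, 0.9, 0.2, 0.7, 0.4, 0.8)
  lab <- c("NC", "LUAD", "NC", "LUAD", "NC", "LUAD")
  a1 <- roc_auc_ci(lab, s)$auc
  expect_equal(a1 + roc_auc_ci(lab, -s)$auc, 1)          # complement identity
  expect_equal(roc_auc_ci(lab, exp(10 * s))$auc, a1)     # monotone invariance
  expect_true(a1 >= roc_auc_ci(lab, s)$ci_low &&
                a1 <= roc_auc_ci(lab, s)$ci_high)
  expect_error(roc_auc_ci(rep("LUAD", 4), s[1:4]), "both classes")
})
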