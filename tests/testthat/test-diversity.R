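test_that("rarefaction equalizes depths and matches the hypergeometric mean", {
  co <- tiny_cohort(seed = 9)
  r <- rarefy(co$genus, seed = 1)
  expect_true(all(rowSums(ft_matrix(r)) == min(rowSums(ft_matrix(co$genus)))))
  # depth equal to a sample's total leaves that sample unchanged
  m <- rbind(S1 = c(4L, 3L, 3L), S2 = c(20L, 5L, 5L))
  colnames(m) <- paste0("g", 1:3)
  ft <- feature_table(m, "counts")
  r10 <- rarefy(ft, depth = 10, seed = 3)
  expect_equal(ft_matrix(r10)["S1", ], m["S1", ])
  expect_error(rarefy(ft, depth = 11), "S1")
  # E[count] = depth * x / N for subsampling without replacement
  draws <- vapply(1:600, function(s) ft_matrix(rarefy(ft, 10, seed = s))["S2", "g1"], 0)
  expect_equal(mean(draws), 10 * 20 / 30, tolerance = 0.02 * 10 * 20 / 30)
})

test_that("alpha indices match their closed forms", {
  counts_row <- function(x) {
    m <- matrix(x, 1, dimnames = list("A", paste0("g", seq_along(x))))
    feature_table(m, "counts")
  }
  a <- alpha_diversity(counts_row(c(5L, 1L, 1L, 2L)))
  expect_equal(a$sobs, 4)
  expect_equal(a$chao1, 4 + 2 * 1 / (2 * 2)) # F1=2, F2=1, bias-corrected
  expect_equal(alpha_diversity(counts_row(rep(1L, 4)))$shannon, log(4),
               tolerance = 1e-12)
  one <- alpha_diversity(counts_row(10L))
  expect_equal(one$simpson, 1)
  expect_equal(one$shannon, 0)
  expect_error(alpha_diversity(counts_row(0L)))
})

test_that("richness estimators never fall below observed richness", {
  co <- tiny_cohort(seed = 14)
  a <- alpha_diversity(rarefy(co$genus, seed = 2))
  expect_true(all(a$chao1 >= a$sobs - 1e-9))
  expect_true(all(a$ace >= a$sobs - 1e-9, na.rm = TRUE))
  expect_true(all(a$simpson >= 0 & a$simpson <= 1))
})

test_that("planted richness expansion is detected by richness-index LMMs", {
  co <- simulate_cohort(simulation_config(
    n_patients = 50, n_genera = 80, n_planted_diff = 0,
    n_rare_expansion = 40, rare_presence_nc = 0.05, rare_presence_luad = 0.35,
    seed = 19))
  a <- alpha_diversity(rarefy(co$genus, seed = 1))
  tests <- alpha_group_test(a, co$metadata)
  rich <- tests[tests$index %in% c("sobs", "chao1"), ]
  expect_true(all(rich$beta > 0))
  expect_true(all(rich$fdr < 0.05))
  # single index: fdr equals p
  single <- alpha_group_test(a[, c("sample_id", "shannon")], co$metadata)
  expect_equal(single$fdr, single$p)
})

test_that("beta distances match hand-computed values and axioms", {
  m <- rbind(S1 = c(2, 0), S2 = c(0, 2), S3 = c(2, 0))
  colnames(m) <- c("g1", "g2")
  ft <- feature_table(m, "counts")
  bc <- as.matrix(beta_distance(ft, "bray_curtis"))
  expect_equal(bc["S1", "S2"], 1)
  expect_equal(bc["S1", "S3"], 0)
  bh <- as.matrix(beta_distance(ft, "binary_hamming"))
  expect_equal(bh["S1", "S2"], 1)
  m2 <- rbind(S1 = c(1, 0, 1), S2 = c(1, 1, 0))
  colnames(m2) <- paste0("g", 1:3)
  expect_equal(as.matrix(beta_distance(feature_table(m2, "counts"),
                                       "binary_hamming"))["S1", "S2"], 2 / 3)
  # presence-based metrics ignore per-sample abundance rescaling
  m3 <- m2; m3["S1", ] <- m3["S1", ] * 50
  expect_equal(as.matrix(beta_distance(feature_table(m3, "counts"), "binary_hamming")),
               as.matrix(beta_distance(feature_table(m2, "counts"), "binary_hamming")))
})

test_that("UniFrac distances are valid and vanish for identical samples", {
  co <- tiny_cohort(n_patients = 8, seed = 5)
  for (metric in c("unweighted_unifrac", "weighted_unifrac")) {
    d <- as.matrix(beta_distance(co$asv, metric, tree = co$tree))
    expect_true(all(abs(diag(d)) < 1e-12))
    expect_equal(d, t(d), tolerance = 1e-12)
    expect_true(all(d >= -1e-12 & d <= 1 + 1e-12))
  }
  dup <- ft_matrix(co$asv)[c(1, 1, 2, 3), ]
  rownames(dup) <- paste0("S", 1:4)
  d2 <- as.matrix(beta_distance(feature_table(dup, "counts"),
                                "unweighted_unifrac", tree = co$tree))
  expect_equal(d2["S1", "S2"], 0)
  expect_error(beta_distance(co$genus, "unweighted_unifrac", tree = co$tree),
               "missing tips")
})

test_that("PCoA reproduces known geometry", {
  # three equidistant points: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(paste0("S", 1:3), paste0("S", 1:3))
  e <- pcoa_ordination(d3)
  pos <- e$eigenvalues[e$eigenvalues > 1e-10]
  expect_equal(length(pos), 2L)
  expect_equal(pos[1], pos[2], tolerance = 1e-9)
  # Euclidean distances from known 2-D points are reconstructed exactly
  pts <- withr::with_seed(3, matrix(rnorm(20), 10, 2))
  rownames(pts) <- paste0("S", 1:10)
  d <- dist(pts)
  rec <- dist(pcoa_ordination(d, k = 2)$coordinates)
  expect_equal(as.numeric(rec), as.numeric(d), tolerance = 1e-8)
  # duplicate samples land on coincident coordinates
  ddup <- as.matrix(dist(pts[c(1, 1, 2, 3), ]))
  cdup <- pcoa_ordination(ddup)$coordinates
  expect_equal(cdup[1, ], cdup[2, ], tolerance = 1e-9)
  expect_error(pcoa_ordination(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PERMANOVA p-value matches full enumeration on a small design", {
  pts <- withr::with_seed(7, matrix(rnorm(12), 6, 2))
  rownames(pts) <- paste0("S", 1:6)
  d <- dist(pts)
  groups <- rep(c("a", "b"), each = 3)
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(z) length(unique(z)) == 6L), ]
  res <- permanova(d, groups, permutations = perms)
  f_obs <- pseudo_f_oracle(d, groups)
  expect_equal(res$pseudo_f, f_obs, tolerance = 1e-9)
  f_perm <- apply(perms, 1, function(idx) pseudo_f_oracle(as.matrix(d)[idx, idx], groups))
  p_oracle <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + nrow(perms))
  expect_equal(res$p_value, p_oracle, tolerance = 1e-9)
})

test_that("PERMANOVA reaches its floor under complete separation and scales invariantly", {
  pts <- withr::with_seed(2, rbind(matrix(rnorm(20, 0, 0.05), 10, 2),
                                   matrix(rnorm(20, 10, 0.05), 10, 2)))
  rownames(pts) <- paste0("S", 1:20)
  d <- dist(pts)
  groups <- rep(c("a", "b"), each = 10)
  res <- permanova(d, groups, n_permutations = 199, seed = 4)
  expect_equal(res$p_value, 1 / 200)
  scaled <- permanova(d * 13, groups, n_permutations = 199, seed = 4)
  expect_equal(scaled$r_squared, res$r_squared, tolerance = 1e-12)
  expect_equal(scaled$p_value, res$p_value)
  expect_error(permanova(d, c("a", rep("b", 19)), 99), "fewer than 2")
})
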