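test_that("cohort design honours the pairing probability", {
  cfg0 <- simulation_config(n_patients = 10, p_both_tissues = 0, seed = 1)
  md0 <- simulate_cohort_design(cfg0)
  expect_equal(nrow(md0), 10L)
  expect_true(all(md0$tissue == "LUAD"))
  cfg1 <- simulation_config(n_patients = 10, p_both_tissues = 1, seed = 1)
  md1 <- simulate_cohort_design(cfg1)
  expect_equal(nrow(md1), 20L)
  expect_equal(sum(table(md1$patient_id) == 2), 10L)
  expect_error(simulation_config(n_patients = 1), ">= 2")
})

test_that("expected number of paired patients matches the cohort target", {
  cfg <- simulation_config(n_patients = 34, p_both_tissues = 14 / 34)
  pairs <- vapply(1:300, function(s) {
    md <- simulate_cohort_design(cfg, seed = s)
    sum(table(md$patient_id) == 2)
  }, 0)
  expect_lt(abs(mean(pairs) - 14), 1) # Monte-Carlo mean within +/- 1
})

test_that("genus table equals the ASV table aggregated through taxonomy", {
  co <- tiny_cohort(seed = 2)
  agg <- aggregate_to_genus(co$asv, co$taxonomy)
  gm <- ft_matrix(co$genus)
  expect_equal(ft_matrix(agg)[rownames(gm), colnames(gm)], gm)
  # all planted/rare ids exist in the emitted table
  expect_true(all(co$ground_truth$planted_diff_genera$genus %in% ft_features(co$genus)))
  expect_true(all(co$ground_truth$rare_expansion_taxa %in% ft_features(co$genus)))
  expect_true(all(co$ground_truth$planted_kos$ko %in% ft_features(co$ko)))
  expect_true(all(co$ground_truth$planted_kos$direction %in% c("up", "down")))
})

test_that("a null generator produces no systematic CLR tissue difference", {
  cfg <- simulation_config(n_patients = 200, p_both_tissues = 1, n_genera = 30,
                           n_planted_diff = 0, effect_logfc = 0,
                           n_rare_expansion = 0, sigma_patient = 0, seed = 6)
  co <- simulate_cohort(cfg)
  clr <- ft_matrix(clr_transform(co$genus, 1))
  md <- co$metadata
  diff <- colMeans(clr[md$tissue == "LUAD", ]) - colMeans(clr[md$tissue == "NC", ])
  expect_lt(mean(abs(diff)), 0.1)
})

test_that("simulated trees are rooted, binary, positive and deterministic", {
  tr2 <- simulate_tree(c("A", "B"), seed = 1)
  expect_equal(length(tr2$tip.label), 2L)
  expect_true(all(tr2$edge.length > 0))
  tr <- simulate_tree(paste0("t", 1:17), seed = 9)
  expect_true(ape::is.rooted(tr) && ape::is.binary(tr))
  expect_equal(tr$Nnode, 16L) # n - 1 internal nodes
  expect_identical(ape::write.tree(simulate_tree(paste0("t", 1:17), seed = 9)),
                   ape::write.tree(tr))
  expect_error(simulate_tree(c("A", "A"), seed = 1), "duplicate")
})

test_that("function tables follow the loading model and group sums", {
  co <- tiny_cohort(seed = 12)
  cfg0 <- simulation_config(n_patients = co$config$n_patients,
                            n_genera = co$config$n_genera,
                            n_planted_diff = 0, n_rare_expansion = 0,
                            n_kos = length(ft_features(co$genus)),
                            n_planted_kos = 0, seed = 12)
  ng <- length(ft_features(co$genus))
  ident <- diag(ng)
  dimnames(ident) <- list(ft_features(co$genus), paste0("K", seq_len(ng)))
  fun <- simulate_function_tables(cfg0, co$genus, co$metadata,
                                  loading = ident, noise_sd = 0)
  rel <- ft_matrix(ft_relative(co$genus))
  expect_equal(ft_matrix(fun$ko), rel[, ft_features(co$genus)] * 1e4,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(simulate_function_tables(cfg0, co$genus, co$metadata,
                                        loading = -ident), "nonnegative")
  # pathway entries are sums over member KOs
  fun2 <- simulate_function_tables(co$config, co$genus, co$metadata)
  km <- ft_matrix(fun2$ko); pm <- ft_matrix(fun2$pathway)
  for (pw in colnames(pm)[1:3]) {
    members <- fun2$pathway_map$ko_id[fun2$pathway_map$pathway == pw]
    expect_equal(pm[, pw], rowSums(km[, members, drop = FALSE]),
                 tolerance = 1e-9)
  }
  # each KO sits in exactly one module
  expect_identical(anyDuplicated(fun2$module_map$ko_id), 0L)
})

test_that("planted KO effects are recoverable by the downstream LMM", {
  cfg <- simulation_config(n_patients = 100, p_both_tissues = 1, n_genera = 40,
                           n_rare_expansion = 0, n_kos = 10, n_planted_kos = 2,
                           ko_effect = 1, seed = 23)
  co <- simulate_cohort(cfg)
  recs <- lmm_screen(paired16S:::normalize_clr(co$ko), co$metadata)
  planted <- co$ground_truth$planted_kos
  for (i in seq_len(nrow(planted))) {
    b <- recs$beta[recs$feature == planted$ko[i]]
    expect_true(if (planted$direction[i] == "up") b > 0 else b < 0)
  }
})

test_that("fixture bundles are byte-identical under a fixed seed and round trip", {
  cfg <- simulation_config(n_patients = 8, n_genera = 15, n_rare_expansion = 3,
                           n_kos = 12, n_planted_kos = 2, seed = 77)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  emit_fixture_bundle(cfg, d1)
  emit_fixture_bundle(cfg, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  expect_identical(unname(tools::md5sum(file.path(d1, f1))),
                   unname(tools::md5sum(file.path(d2, f2))))
  bundle <- read_fixture_bundle(d1)
  co <- simulate_cohort(cfg)
  expect_equal(ft_matrix(bundle$genus), ft_matrix(co$genus))
  expect_equal(ft_matrix(bundle$ko), ft_matrix(co$ko), tolerance = 1e-6)
  expect_identical(bundle$metadata$sample_id, co$metadata$sample_id)
  expect_equal(sort(bundle$tree$tip.label), sort(co$tree$tip.label))
  expect_equal(bundle$ground_truth$planted_diff_genera$genus,
               co$ground_truth$planted_diff_genera$genus)
  # emitted tables pass the validators on re-read
  expect_s3_class(basic_asv_filter(bundle$asv), "feature_table")
})
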