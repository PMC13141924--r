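test_that("feature table TSV round trip preserves values and ids", {
  m <- matrix(c(5, 0, 3, 2, 1, 0, 0, 7, 4, 1, 2, 9), nrow = 3,
              dimnames = list(paste0("S", 1:3), paste0("ASV", 1:4)))
  ft <- feature_table(m, "counts")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ft, path, id_name = "asv_id")
  back <- read_feature_table(path, "counts")
  expect_identical(dim(ft_matrix(back)), dim(m))
  expect_equal(ft_matrix(back)[rownames(m), colnames(m)], m)
})

test_that("malformed tables are rejected with the offending cell named", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("asv_id\tS1\tS2", "ASV1\t3\t-2", "ASV2\t1\t0"), path)
  expect_error(read_feature_table(path, "counts"), "negative.*S2.*ASV1")
  writeLines(c("asv_id\tS1\tS2", "ASV1\t3\tx", "ASV2\t1\t0"), path)
  expect_error(read_feature_table(path, "counts"), "non-numeric")
  m <- matrix(1, 2, 2, dimnames = list(c("A", "A"), c("f1", "f2")))
  expect_error(feature_table(m, "counts"), "duplicate sample")
  m2 <- matrix(1, 2, 2, dimnames = list(c("A", "B"), c("f1", "f1")))
  expect_error(feature_table(m2, "counts"), "duplicate feature")
})

test_that("BIOM tables are read into the same container", {
  m <- matrix(c(5, 0, 3, 2, 1, 6), nrow = 2,
              dimnames = list(c("S1", "S2"), paste0("ASV", 1:3)))
  b <- biomformat::make_biom(t(m))
  path <- withr::local_tempfile(fileext = ".biom")
  biomformat::write_biom(b, path)
  back <- read_feature_table(path, "counts")
  expect_equal(ft_matrix(back)[rownames(m), colnames(m)], m)
})

test_that("basic filter applies prevalence and total-read rules at the boundary", {
  m <- rbind(S1 = c(100, 5, 5, 0), S2 = c(0, 4, 5, 1), S3 = c(0, 0, 0, 1))
  colnames(m) <- c("one_sample_many_reads", "two_samples_9_reads",
                   "two_samples_10_reads", "two_samples_2_reads")
  flt <- basic_asv_filter(feature_table(m, "counts"))
  expect_identical(ft_features(flt), "two_samples_10_reads")
  expect_error(basic_asv_filter(clr_transform(feature_table(m, "counts"))),
               "counts")
})

test_that("organelle filter removes chloroplast/mitochondrial lineages only", {
  m <- matrix(1:8, 2, 4, dimnames = list(c("S1", "S2"), paste0("ASV", 1:4)))
  tax <- data.frame(
    feature_id = paste0("ASV", 1:4),
    lineage = c("d__Bacteria;p__X;c__Y;o__Chloroplast;f__Z;g__W",
                "d__Bacteria;p__X;c__Y;o__Bacillales;f__Z;g__W",
                "d__Eukaryota;p__X;c__Y;o__Rickettsiales;f__Mitochondria;g__W",
                "d__Bacteria;p__X;c__Y;o__O;f__F;g__G"))
  out <- suppressMessages(organelle_filter(feature_table(m, "counts"), tax))
  expect_setequal(ft_features(out), c("ASV2", "ASV4"))
  # no organelles: unchanged
  clean <- organelle_filter(feature_table(m[, c(2, 4)], "counts"), tax)
  expect_identical(ft_matrix(clean), m[, c(2, 4)])
  expect_error(organelle_filter(feature_table(m, "counts"), tax[-1, ]),
               "without taxonomy")
})

test_that("genus aggregation sums ASVs, conserves totals and keeps placeholders apart", {
  m <- matrix(c(3, 1, 4, 2, 5, 0, 7, 1), nrow = 2,
              dimnames = list(c("S1", "S2"), paste0("ASV", 1:4)))
  tax <- data.frame(
    feature_id = paste0("ASV", 1:4),
    lineage = c("d__B;p__P;c__C;o__O;f__F1;g__G1",
                "d__B;p__P;c__C;o__O;f__F1;g__G1",
                "d__B;p__P;c__C;o__O;f__A;unclassified_f__A",
                "d__B;p__P;c__C;o__O;f__B;unclassified_f__B"))
  g <- aggregate_to_genus(feature_table(m, "counts"), tax)
  gm <- ft_matrix(g)
  expect_equal(unname(gm[, "d__B;p__P;c__C;o__O;f__F1;g__G1"]), c(3 + 4, 1 + 2))
  expect_equal(rowSums(gm), rowSums(m)) # per-sample totals conserved
  expect_equal(ncol(gm), 3L)            # the two placeholders stay distinct
})

test_that("basic and organelle filters commute", {
  co <- tiny_cohort(seed = 3)
  tax <- co$taxonomy
  tax$lineage[1] <- sub("g__[^;]*$", "g__Chloroplast", tax$lineage[1])
  t1 <- suppressMessages(organelle_filter(basic_asv_filter(co$asv), tax))
  t2 <- suppressMessages(basic_asv_filter(organelle_filter(co$asv, tax)))
  expect_identical(ft_matrix(t1), ft_matrix(t2))
})

test_that("tree and module-map readers validate their inputs", {
  tree <- simulate_tree(paste0("ASV", 1:5), seed = 2)
  path <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tree, path)
  back <- read_rooted_tree(path)
  expect_setequal(back$tip.label, tree$tip.label)
  expect_equal(sort(back$edge.length), sort(tree$edge.length), tolerance = 1e-9)
  expect_error(read_rooted_tree(path, features = c("ASV1", "ASV9")), "ASV9")

  mm <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("module\tko_id", "m1\tK1", "m2\tK1"), mm)
  expect_error(read_module_map(mm), "more than one module")
  writeLines(c("module\tko_id", "m1\tK1", "m2\tK2"), mm)
  expect_identical(read_module_map(mm)$ko_id, c("K1", "K2"))
})

test_that("result TSVs are re-readable", {
  dir <- withr::local_tempdir()
  df <- data.frame(feature = c("a", "b"), beta = c(1.5, -0.25), p = c(0.01, 0.2))
  write_results(list(screen = df), dir)
  back <- read.delim(file.path(dir, "screen.tsv"))
  expect_equal(back, df)
})
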