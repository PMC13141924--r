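# Shared fixture builders. Everything is generated in code; no stored data.

# Small paired cohort with sensible defaults for fast tests.
tiny_cohort <- function(n_patients = 16, n_genera = 30, n_rare_expansion = 6,
                        n_kos = 24, n_planted_kos = 4, seed = 11, ...) {
  simulate_cohort(simulation_config(
    n_patients = n_patients, n_genera = n_genera,
    n_rare_expansion = n_rare_expansion, n_kos = n_kos,
    n_planted_kos = n_planted_kos, seed = seed, ...))
}

# Fully balanced paired metadata: every patient has one NC and one LUAD sample.
paired_metadata <- function(n_patients) {
  pid <- sprintf("P%02d", seq_len(n_patients))
  cohort_metadata(data.frame(
    sample_id = c(paste0(pid, "_N"), paste0(pid, "_T")),
    patient_id = c(pid, pid),
    tissue = rep(c("NC", "LUAD"), each = n_patients)))
}

# Counts table with a latent-factor correlation block: the first
# `block_size` genera share a common factor (pairwise Spearman near 1),
# remaining genera are independent noise. Used for network tests.
block_correlated_table <- function(n_samples = 30, n_genera = 40,
                                   block_size = 9, seed = 5) {
  withr::with_seed(seed, {
    z <- stats::rnorm(n_samples)
    m <- matrix(stats::rlnorm(n_samples * n_genera, 3, 1), n_samples, n_genera)
    for (j in seq_len(block_size))
      m[, j] <- exp(3 + 2 * z + stats::rnorm(n_samples, 0, 0.1))
    dimnames(m) <- list(sprintf("S%02d", seq_len(n_samples)),
                        sprintf("g__B%02d", seq_len(n_genera)))
    feature_table(round(m), scale = "counts")
  })
}

# Paired KO table where LUAD samples carry a uniform multiplicative shift on
# selected KOs (K1, K2). Each patient has its own KO baseline shared by both
# samples, with small within-pair noise, so planted pair-level effects
# dominate sampling noise by construction at any seed.
homogeneous_ko_cohort <- function(n_patients = 10, shift = exp(1.2), seed = 3) {
  md <- paired_metadata(n_patients)
  withr::with_seed(seed, {
    level <- matrix(rlnorm(n_patients * 6, 4, 0.3), n_patients, 6,
                    dimnames = list(unique(md$patient_id), paste0("K", 1:6)))
    base <- level[md$patient_id, ] *
      matrix(rlnorm(nrow(md) * 6, 0, 0.1), nrow(md), 6)
    rownames(base) <- md$sample_id
    base[md$tissue == "LUAD", 1:2] <- base[md$tissue == "LUAD", 1:2] * shift
    list(table = feature_table(base, "score"), metadata = md,
         module_map = data.frame(module = rep(c("m1", "m2", "m3"), each = 2),
                                 ko_id = paste0("K", 1:6)))
  })
}

# Single-driver variant: one extreme patient carries the whole effect on K1
# while everyone else drifts the other way; the drift is strong enough that
# removing the driver reliably flips the estimated sign.
single_driver_ko_cohort <- function(n_patients = 8, seed = 9) {
  cohort <- homogeneous_ko_cohort(n_patients = n_patients, shift = 1, seed = seed)
  m <- ft_matrix(cohort$table)
  md <- cohort$metadata
  m[md$tissue == "LUAD", 1] <- m[md$tissue == "LUAD", 1] * exp(-0.6)
  driver <- md$sample_id[md$patient_id == "P01" & md$tissue == "LUAD"]
  m[driver, 1] <- m[driver, 1] * exp(12)
  cohort$table <- feature_table(m, "score")
  cohort
}

# Anderson pseudo-F computed directly from squared distances and group sums
# of squares; independent oracle for the PERMANOVA implementation.
pseudo_f_oracle <- function(dmat, labels) {
  dmat <- as.matrix(dmat)
  n <- nrow(dmat)
  labels <- as.character(labels)
  a <- length(unique(labels))
  ss_total <- sum(dmat[upper.tri(dmat)]^2) / n
  ss_within <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    sub <- dmat[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}
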