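#' Configuration for the synthetic paired-cohort generator
#'
#' The generator emulates a partially paired tumor/noncancerous 16S cohort:
#' every patient contributes a LUAD sample and a Bernoulli subset also
#' contributes an NC sample, genus abundances follow a logistic-normal-
#' multinomial model with a patient random intercept, a set of planted genera
#' carry signed tissue effects on the log scale, and a block of rare taxa has
#' elevated presence probability in LUAD (mirroring an expansion of
#' low-prevalence taxa in tumors). ASVs partition each genus, a coalescent
#' tree covers the ASVs, and KO/pathway tables are derived from the genus
#' profile through a nonnegative loading matrix with planted tissue-scaled
#' KOs. Defaults reflect a cohort of 34 patients with an expected 14
#' tumor/NC pairs.
#'
#' @param n_patients number of patients (>= 2); each contributes a LUAD sample.
#' @param p_both_tissues probability a patient also contributes an NC sample.
#' @param n_genera number of genera.
#' @param n_planted_diff number of genera with planted tissue effects.
#' @param effect_logfc absolute log-scale tissue effect of planted genera
#'   (signs alternate across planted genera).
#' @param n_rare_expansion number of low-abundance taxa with elevated
#'   presence probability in LUAD.
#' @param rare_presence_nc,rare_presence_luad presence probabilities of the
#'   rare-expansion taxa in NC and LUAD samples.
#' @param sigma_patient SD of the patient random intercept (log scale).
#' @param sigma_noise SD of per-sample-per-genus log-scale noise.
#' @param library_size_logmean,library_size_logsd log-normal library-size
#'   parameters.
#' @param asv_per_genus_range integer interval; ASVs per genus drawn uniformly.
#' @param n_kos,n_planted_kos,ko_effect KO-table parameters: number of KOs,
#'   number with planted tissue effects, and the absolute log-scale effect.
#' @param ko_noise_sd SD of multiplicative log-normal noise on KO scores.
#' @param seed integer RNG seed; a fixed seed reproduces the bundle exactly.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 34,
                              p_both_tissues = 14 / 34,
                              n_genera = 150,
                              n_planted_diff = 7,
                              effect_logfc = 1.5,
                              n_rare_expansion = 30,
                              rare_presence_nc = 0.05,
                              rare_presence_luad = 0.25,
                              sigma_patient = 0.8,
                              sigma_noise = 0.6,
                              library_size_logmean = log(10000),
                              library_size_logsd = 0.4,
                              asv_per_genus_range = c(1L, 6L),
                              n_kos = 200,
                              n_planted_kos = 40,
                              ko_effect = 1.0,
                              ko_noise_sd = 0.3,
                              seed = 1) {
  cfg <- list(
    n_patients = assert_count(n_patients, "n_patients", min = 2L),
    p_both_tissues = assert_prob(p_both_tissues, "p_both_tissues"),
    n_genera = assert_count(n_genera, "n_genera"),
    n_planted_diff = assert_count(n_planted_diff, "n_planted_diff", min = 0L),
    effect_logfc = effect_logfc,
    n_rare_expansion = assert_count(n_rare_expansion, "n_rare_expansion", min = 0L),
    rare_presence_nc = assert_prob(rare_presence_nc, "rare_presence_nc"),
    rare_presence_luad = assert_prob(rare_presence_luad, "rare_presence_luad"),
    sigma_patient = sigma_patient,
    sigma_noise = sigma_noise,
    library_size_logmean = library_size_logmean,
    library_size_logsd = library_size_logsd,
    asv_per_genus_range = as.integer(asv_per_genus_range),
    n_kos = assert_count(n_kos, "n_kos"),
    n_planted_kos = assert_count(n_planted_kos, "n_planted_kos", min = 0L),
    ko_effect = ko_effect,
    ko_noise_sd = ko_noise_sd,
    seed = assert_count(seed, "seed", min = 0L))
  if (cfg$sigma_patient < 0 || cfg$sigma_noise < 0 || cfg$ko_noise_sd < 0)
    stop("standard deviations must be >= 0", call. = FALSE)
  if (length(cfg$asv_per_genus_range) != 2L ||
      any(cfg$asv_per_genus_range < 1L) ||
      cfg$asv_per_genus_range[1L] > cfg$asv_per_genus_range[2L])
    stop("asv_per_genus_range must be an increasing integer pair >= 1", call. = FALSE)
  if (cfg$n_planted_diff + cfg$n_rare_expansion > cfg$n_genera)
    stop("planted + rare-expansion genera exceed n_genera", call. = FALSE)
  if (cfg$n_planted_kos > cfg$n_kos)
    stop("n_planted_kos exceeds n_kos", call. = FALSE)
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate the partially paired cohort design
#'
#' Every patient contributes a LUAD sample; a Bernoulli(`p_both_tissues`)
#' subset also contributes an NC sample, so paired samples share the patient
#' id.
#'
#' @param config a [simulation_config()] (or `n_patients` plus
#'   `p_both_tissues` through `...` defaults).
#' @param seed optional seed overriding `config$seed`.
#' @return cohort metadata data.frame (see [cohort_metadata()]).
#' @export
simulate_cohort_design <- function(config = simulation_config(), seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  seed <- seed %||% config$seed
  n <- config$n_patients
  if (n < 2L) stop("invalid design: need at least 2 patients", call. = FALSE)
  withr::with_seed(seed, {
    pid <- sprintf("P%03d", seq_len(n))
    paired <- stats::runif(n) < config$p_both_tissues
    nc_ids <- if (any(paired)) paste0(pid[paired], "_N") else character(0)
    md <- data.frame(
      sample_id = c(paste0(pid, "_T"), nc_ids),
      patient_id = c(pid, pid[paired]),
      tissue = c(rep("LUAD", n), rep("NC", sum(paired))),
      stringsAsFactors = FALSE)
    cohort_metadata(md[order(md$patient_id, md$tissue), , drop = FALSE])
  })
}

# Internal: genus-level log-abundance model and multinomial count draw.
# Returns genus counts plus the latent structures recorded as ground truth.
simulate_genus_counts <- function(config, metadata, seed) {
  withr::with_seed(seed, {
    ng <- config$n_genera
    genera <- sprintf("g__Genus%03d", seq_len(ng))
    rare_idx <- if (config$n_rare_expansion > 0)
      seq.int(ng - config$n_rare_expansion + 1L, ng) else integer(0)
    regular_idx <- setdiff(seq_len(ng), rare_idx)

    baseline <- stats::rnorm(ng, 0, 1.5)
    baseline[rare_idx] <- stats::rnorm(length(rare_idx), -3, 0.5)

    # planted differential genera: moderately abundant regular genera
    if (config$n_planted_diff > length(regular_idx))
      stop("n_planted_diff exceeds the number of non-rare genera", call. = FALSE)
    cand <- regular_idx[baseline[regular_idx] >= stats::median(baseline[regular_idx])]
    if (length(cand) < config$n_planted_diff)
      cand <- regular_idx[order(baseline[regular_idx],
                                decreasing = TRUE)][seq_len(config$n_planted_diff)]
    planted_idx <- sort(sample(cand, config$n_planted_diff))
    signs <- rep(c(1, -1), length.out = config$n_planted_diff)
    effects <- rep(0, ng)
    effects[planted_idx] <- signs * abs(config$effect_logfc)

    patients <- unique(metadata$patient_id)
    u <- stats::rnorm(length(patients), 0, config$sigma_patient)
    names(u) <- patients

    ns <- nrow(metadata)
    is_luad <- metadata$tissue == "LUAD"
    eta <- matrix(rep(baseline, each = ns), nrow = ns) +
      matrix(stats::rnorm(ns * ng, 0, config$sigma_noise), nrow = ns)
    eta <- eta + u[metadata$patient_id]
    eta[is_luad, ] <- eta[is_luad, ] + rep(effects, each = sum(is_luad))

    if (length(rare_idx)) {
      pres_p <- ifelse(is_luad, config$rare_presence_luad, config$rare_presence_nc)
      for (g in rare_idx) {
        absent <- stats::runif(ns) >= pres_p
        eta[absent, g] <- -Inf
      }
    }

    libsize <- round(stats::rlnorm(ns, config$library_size_logmean,
                                   config$library_size_logsd))
    libsize <- pmax(libsize, 100L)
    counts <- matrix(0L, ns, ng, dimnames = list(metadata$sample_id, genera))
    for (s in seq_len(ns)) {
      w <- exp(eta[s, ] - max(eta[s, ][is.finite(eta[s, ])]))
      w[!is.finite(w)] <- 0
      counts[s, ] <- as.integer(stats::rmultinom(1, libsize[s], prob = w / sum(w)))
    }
    list(counts = counts,
         planted = data.frame(genus = genera[planted_idx],
                              effect = effects[planted_idx],
                              stringsAsFactors = FALSE),
         rare_taxa = genera[rare_idx],
         patient_effects = u,
         genera = genera)
  })
}

#' Simulate genus and ASV count tables with taxonomy
#'
#' Genus counts follow the logistic-normal-multinomial model described in
#' [simulation_config()]; each genus's counts are then partitioned across its
#' ASVs with fixed per-genus Dirichlet weights, so the genus table equals the
#' ASV table aggregated through the taxonomy map exactly.
#'
#' @param config a [simulation_config()].
#' @param metadata cohort metadata from [simulate_cohort_design()].
#' @param seed optional seed overriding `config$seed`.
#' @return list with `genus` and `asv` count [feature_table()]s, `taxonomy`
#'   (ASV lineage map), and `truth` (planted genera, rare taxa, patient
#'   effects).
#' @export
simulate_genus_asv_tables <- function(config, metadata, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  metadata <- cohort_metadata(metadata)
  seed <- seed %||% config$seed
  g <- simulate_genus_counts(config, metadata, seed = derive_seed(seed, "genus"))
  withr::with_seed(derive_seed(seed, "asv"), {
    ng <- length(g$genera)
    n_asv_per <- sample(seq.int(config$asv_per_genus_range[1L],
                                config$asv_per_genus_range[2L]),
                        ng, replace = TRUE)
    phyla <- sprintf("p__Phylum%02d", 1:8)
    fam <- sprintf("f__Family%03d", seq_len(ng))
    phy_of_genus <- sample(phyla, ng, replace = TRUE)
    lineages <- sprintf("d__Bacteria;%s;c__Class%02d;o__Order%02d;%s;%s",
                        phy_of_genus,
                        match(phy_of_genus, phyla), match(phy_of_genus, phyla),
                        fam, g$genera)
    asv_ids <- character(0); asv_lineage <- character(0)
    asv_counts_list <- vector("list", ng)
    for (i in seq_len(ng)) {
      k <- n_asv_per[i]
      ids <- sprintf("ASV%04d", length(asv_ids) + seq_len(k))
      w <- stats::rgamma(k, shape = 1.5, rate = 1)
      w <- w / sum(w)
      gc <- g$counts[, i]
      split <- t(vapply(gc, function(tot) {
        if (tot == 0) integer(k) else as.integer(stats::rmultinom(1, tot, prob = w))
      }, integer(k)))
      if (k == 1L) split <- matrix(gc, ncol = 1L)
      colnames(split) <- ids
      asv_counts_list[[i]] <- split
      asv_ids <- c(asv_ids, ids)
      asv_lineage <- c(asv_lineage, rep(lineages[i], k))
    }
    asv_counts <- do.call(cbind, asv_counts_list)
    rownames(asv_counts) <- metadata$sample_id
    genus_tab <- feature_table(g$counts, scale = "counts")
    # genus feature ids in the emitted table are full genus-level lineages,
    # matching what aggregate_to_genus() produces
    colnames(genus_tab$abund) <- genus_lineage(lineages)
    ord <- order(colnames(genus_tab$abund))
    genus_tab$abund <- genus_tab$abund[, ord, drop = FALSE]
    taxonomy <- data.frame(feature_id = asv_ids, lineage = asv_lineage,
                           stringsAsFactors = FALSE)
    lin_of <- genus_lineage(lineages)
    names(lin_of) <- g$genera
    truth <- list(
      planted_diff_genera = data.frame(
        genus = unname(lin_of[g$planted$genus]),
        effect = g$planted$effect, stringsAsFactors = FALSE),
      rare_expansion_taxa = unname(lin_of[g$rare_taxa]),
      patient_effects = g$patient_effects)
    list(genus = genus_tab,
         asv = feature_table(asv_counts, scale = "counts"),
         taxonomy = taxonomy,
         truth = truth)
  })
}

#' Simulate a rooted binary tree over ASV ids
#'
#' Random coalescent joins with exponential waiting times ([ape::rcoal()]);
#' cheap, reproducible, and carries no biological claim beyond providing
#' positive branch lengths for UniFrac.
#'
#' @param asv_ids unique tip labels (>= 2).
#' @param seed RNG seed.
#' @return rooted binary `phylo` tree with `length(asv_ids)` tips.
#' @export
simulate_tree <- function(asv_ids, seed = 1) {
  if (length(asv_ids) < 2L) stop("need at least 2 tips", call. = FALSE)
  if (anyDuplicated(asv_ids))
    stop("duplicate tip ids: ",
         paste(unique(asv_ids[duplicated(asv_ids)]), collapse = ", "),
         call. = FALSE)
  withr::with_seed(seed, ape::rcoal(length(asv_ids), tip.label = asv_ids))
}

#' Simulate predicted KO and pathway tables with a module map
#'
#' KO scores are a nonnegative genus-to-KO loading applied to genus relative
#' abundances, times multiplicative log-normal noise; planted KOs are
#' additionally scaled by `exp(+/- ko_effect)` in LUAD samples. The pathway
#' table is a grouped sum of KOs and the module map assigns each KO to
#' exactly one of ten named host-microbe interaction modules.
#'
#' @param config a [simulation_config()].
#' @param genus_table genus counts [feature_table()].
#' @param metadata cohort metadata.
#' @param seed optional seed overriding `config$seed`.
#' @param loading optional explicit genera x KO nonnegative loading matrix.
#' @param noise_sd optional override of `config$ko_noise_sd`.
#' @return list with `ko` and `pathway` score [feature_table()]s,
#'   `module_map`, `pathway_map` (pathway membership of each KO), and
#'   `planted_kos` (data.frame `ko`, `direction`).
#' @export
simulate_function_tables <- function(config, genus_table, metadata, seed = NULL,
                                     loading = NULL, noise_sd = NULL) {
  stopifnot(inherits(config, "simulation_config"), inherits(genus_table, "feature_table"))
  metadata <- align_metadata(genus_table, metadata)
  seed <- seed %||% config$seed
  noise_sd <- noise_sd %||% config$ko_noise_sd
  withr::with_seed(derive_seed(seed, "function"), {
    rel <- ft_matrix(ft_relative(genus_table))
    ng <- ncol(rel)
    nk <- config$n_kos
    kos <- sprintf("K%05d", seq_len(nk))
    if (is.null(loading)) {
      loading <- matrix(0, ng, nk, dimnames = list(colnames(rel), kos))
      for (j in seq_len(nk)) {
        src <- sample.int(ng, min(3L, ng))
        loading[src, j] <- stats::rgamma(length(src), shape = 2, rate = 1)
      }
    } else {
      if (any(loading < 0))
        stop("loading matrix must be nonnegative", call. = FALSE)
      if (nrow(loading) != ng)
        stop("loading must have one row per genus", call. = FALSE)
      kos <- colnames(loading) %||% kos[seq_len(ncol(loading))]
      nk <- ncol(loading)
    }
    ko <- rel %*% loading * 1e4
    if (noise_sd > 0)
      ko <- ko * exp(matrix(stats::rnorm(length(ko), 0, noise_sd), nrow(ko)))
    colnames(ko) <- kos
    planted <- integer(0); dirs <- character(0)
    if (config$n_planted_kos > 0 && nk >= config$n_planted_kos) {
      planted <- sort(sample.int(nk, config$n_planted_kos))
      dirs <- rep(c("up", "down"), length.out = length(planted))
      is_luad <- metadata$tissue == "LUAD"
      mult <- ifelse(dirs == "up", exp(abs(config$ko_effect)),
                     exp(-abs(config$ko_effect)))
      ko[is_luad, planted] <- sweep(ko[is_luad, planted, drop = FALSE], 2, mult, `*`)
    }
    modules <- c("lps_lipid_a", "peptidoglycan", "secretion_systems",
                 "biofilm_qs", "fatty_acid_metabolism", "beta_lactam_resistance",
                 "scfa_metabolism", "tryptophan_indole", "redox_stress",
                 "nitrogen_sulfur")
    module_map <- data.frame(module = rep(modules, length.out = nk)[sample.int(nk)],
                             ko_id = kos, stringsAsFactors = FALSE)
    n_path <- max(3L, ceiling(nk / 8))
    path_of <- sprintf("pathway%03d", rep(seq_len(n_path), length.out = nk))
    pathway <- t(rowsum(t(ko), group = path_of))
    list(ko = feature_table(ko, scale = "score"),
         pathway = feature_table(pathway, scale = "score"),
         module_map = validate_module_map(module_map),
         pathway_map = data.frame(pathway = path_of, ko_id = kos,
                                  stringsAsFactors = FALSE),
         planted_kos = data.frame(ko = kos[planted], direction = dirs,
                                  stringsAsFactors = FALSE))
  })
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running design, genus/ASV tables, tree and function
#' tables, and assembling the ground truth.
#'
#' @param config a [simulation_config()].
#' @return list of class `synthetic_cohort` with elements `config`,
#'   `metadata`, `genus`, `asv`, `taxonomy`, `tree`, `ko`, `pathway`,
#'   `module_map`, `ground_truth`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  metadata <- simulate_cohort_design(config)
  tabs <- simulate_genus_asv_tables(config, metadata)
  tree <- simulate_tree(ft_features(tabs$asv), seed = derive_seed(config$seed, "tree"))
  fun <- simulate_function_tables(config, tabs$genus, metadata)
  truth <- list(planted_diff_genera = tabs$truth$planted_diff_genera,
                rare_expansion_taxa = tabs$truth$rare_expansion_taxa,
                planted_kos = fun$planted_kos,
                patient_effects = tabs$truth$patient_effects)
  structure(list(config = config, metadata = metadata, genus = tabs$genus,
                 asv = tabs$asv, taxonomy = tabs$taxonomy, tree = tree,
                 ko = fun$ko, pathway = fun$pathway,
                 module_map = fun$module_map, ground_truth = truth),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk as a fixture bundle
#'
#' Emits genus/ASV/KO/pathway tables (TSV, features x samples), metadata TSV,
#' taxonomy TSV, Newick tree, module map TSV, ground truth (YAML) and a config
#' echo (YAML). Re-running with the same config reproduces identical bytes.
#'
#' @param cohort a `synthetic_cohort` (or a [simulation_config()], which is
#'   simulated first).
#' @param out_dir output directory.
#' @return invisibly, the bundle directory.
#' @export
emit_fixture_bundle <- function(cohort, out_dir) {
  if (inherits(cohort, "simulation_config")) cohort <- simulate_cohort(cohort)
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir, call. = FALSE)
  write_feature_table(cohort$genus, file.path(out_dir, "genus_table.tsv"), "genus")
  write_feature_table(cohort$asv, file.path(out_dir, "asv_table.tsv"), "asv_id")
  write_feature_table(cohort$ko, file.path(out_dir, "ko_table.tsv"), "ko_id")
  write_feature_table(cohort$pathway, file.path(out_dir, "pathway_table.tsv"),
                      "pathway_id")
  write_cohort_metadata(cohort$metadata, file.path(out_dir, "metadata.tsv"))
  write_taxonomy(cohort$taxonomy, file.path(out_dir, "taxonomy.tsv"))
  ape::write.tree(cohort$tree, file.path(out_dir, "tree.nwk"))
  utils::write.table(cohort$module_map, file.path(out_dir, "module_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- cohort$ground_truth
  yaml::write_yaml(list(
    planted_diff_genera = list(genus = gt$planted_diff_genera$genus,
                               effect = gt$planted_diff_genera$effect),
    rare_expansion_taxa = gt$rare_expansion_taxa,
    planted_kos = list(ko = gt$planted_kos$ko,
                       direction = gt$planted_kos$direction),
    patient_effects = as.list(gt$patient_effects)),
    file.path(out_dir, "ground_truth.yaml"))
  yaml::write_yaml(unclass(cohort$config), file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Read a fixture bundle from disk
#'
#' @param dir directory written by [emit_fixture_bundle()].
#' @return list with the same elements as [simulate_cohort()] (ground truth
#'   included when present).
#' @export
read_fixture_bundle <- function(dir) {
  gt_path <- file.path(dir, "ground_truth.yaml")
  gt <- if (file.exists(gt_path)) yaml::read_yaml(gt_path) else NULL
  ground_truth <- if (!is.null(gt)) list(
    planted_diff_genera = data.frame(genus = unlist(gt$planted_diff_genera$genus),
                                     effect = unlist(gt$planted_diff_genera$effect),
                                     stringsAsFactors = FALSE),
    rare_expansion_taxa = unlist(gt$rare_expansion_taxa),
    planted_kos = data.frame(ko = unlist(gt$planted_kos$ko) %||% character(0),
                             direction = unlist(gt$planted_kos$direction) %||% character(0),
                             stringsAsFactors = FALSE),
    patient_effects = unlist(gt$patient_effects)) else NULL
  list(metadata = read_cohort_metadata(file.path(dir, "metadata.tsv")),
       genus = read_feature_table(file.path(dir, "genus_table.tsv"), "counts"),
       asv = read_feature_table(file.path(dir, "asv_table.tsv"), "counts"),
       taxonomy = read_taxonomy(file.path(dir, "taxonomy.tsv")),
       tree = read_rooted_tree(file.path(dir, "tree.nwk")),
       ko = read_feature_table(file.path(dir, "ko_table.tsv"), "score"),
       pathway = read_feature_table(file.path(dir, "pathway_table.tsv"), "score"),
       module_map = read_module_map(file.path(dir, "module_map.tsv")),
       ground_truth = ground_truth)
}
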