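#' Default pipeline run configuration
#'
#' A run configuration is a nested list with a `paths` block naming the input
#' files (a fixture bundle layout; see [emit_fixture_bundle()]), a global
#' `seed` from which each stage deterministically derives its own seed, a
#' `skip` vector of stage names, and one parameter block per stage exposing
#' every tunable default of the underlying functions.
#'
#' @param input_dir directory holding the input bundle.
#' @param out_dir output directory.
#' @param seed global seed.
#' @return nested configuration list.
#' @export
default_run_config <- function(input_dir = ".", out_dir = "pipeline_out",
                               seed = 1) {
  list(
    paths = list(
      genus_table = file.path(input_dir, "genus_table.tsv"),
      asv_table = file.path(input_dir, "asv_table.tsv"),
      taxonomy = file.path(input_dir, "taxonomy.tsv"),
      metadata = file.path(input_dir, "metadata.tsv"),
      tree = file.path(input_dir, "tree.nwk"),
      ko_table = file.path(input_dir, "ko_table.tsv"),
      pathway_table = file.path(input_dir, "pathway_table.tsv"),
      module_map = file.path(input_dir, "module_map.tsv")),
    out_dir = out_dir,
    seed = seed,
    skip = character(0),
    filters = list(min_samples = 2, min_total_reads = 10),
    diversity = list(rarefy_depth = NULL, n_permutations = 999,
                     metrics_genus = c("bray_curtis", "binary_hamming"),
                     metrics_asv = c("unweighted_unifrac", "weighted_unifrac")),
    diffab = list(min_prevalence = 0.15, pseudocount = 1, q_threshold = 0.05),
    markers = list(pseudocount = 1, alpha_mixing = 0.5, n_bootstrap = 500,
                   threshold = 0.60, n_lambda = 20, n_folds = 5),
    network = list(rho_min = 0.7, p_max = 0.05, min_prevalence = 0.2,
                   n_bootstrap = 500, top_k = 10, stability_min = 0.6),
    functions = list(prevalence_min = 0.20, beta_min = 0.30,
                     consistency_min = 0.90, fdr_threshold = 0.05))
}

#' Read a pipeline configuration from YAML
#'
#' Keys absent from the file keep their defaults; unknown keys are rejected.
#' The effective, default-resolved configuration is echoed into the output
#' directory by [run_pipeline()].
#'
#' @param path YAML file.
#' @param input_dir,out_dir,seed defaults used for keys the file omits.
#' @return nested configuration list.
#' @export
read_run_config <- function(path, input_dir = ".", out_dir = "pipeline_out",
                            seed = 1) {
  user <- yaml::read_yaml(path)
  merge_config(default_run_config(input_dir, out_dir, seed), user, "")
}

merge_config <- function(base, user, prefix) {
  if (is.null(user)) return(base)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(prefix, unknown, collapse = ", "), call. = FALSE)
  for (k in names(user)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], user[[k]], paste0(prefix, k, "."))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Run the full downstream analysis pipeline
#'
#' Executes, in order: feature filtering, diversity (alpha + beta +
#' PERMANOVA), differential abundance, marker stability selection, per-group
#' co-occurrence networks, and KO/pathway functional analysis. Each stage is
#' skippable, writes its results as TSV, and derives its seed from the global
#' seed, so identical config + seed reproduce identical outputs byte for
#' byte. A deterministic `run_report.yaml` records versions, effective
#' parameters, the seed and the documented methodological deviations;
#' wall-clock stage timings go to `run_log.txt`, which is outside the
#' determinism contract.
#'
#' @param config configuration list from [default_run_config()] or
#'   [read_run_config()].
#' @return invisibly, a list with the per-stage results and the report.
#' @export
run_pipeline <- function(config = default_run_config()) {
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  skip <- config$skip %||% character(0)
  timings <- list()
  results <- list()
  report <- list(
    package_version = as.character(utils::packageVersion("paired16S")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    skipped = skip,
    parameters = config[c("filters", "diversity", "diffab", "markers",
                          "network", "functions")],
    deviations = c(
      "differential abundance uses a CLR + random-intercept LMM engine (not a compound-Poisson mixed model)",
      "LMM inference uses Wald t tests with Kenward-Roger degrees of freedom on the tissue coefficient",
      "ROC confidence intervals use the DeLong method unless configured otherwise",
      "PERMANOVA uses unrestricted permutations; with paired samples this assumes exchangeability (restricted mode available)",
      "network node prevalence filter (0.2) and bootstrap ranking (mean of degree and closeness ranks) are package defaults"))

  stage <- function(name, fun) {
    if (name %in% skip) {
      p16_log("pipeline: skipping stage '%s'", name)
      return(NULL)
    }
    t0 <- proc.time()[["elapsed"]]
    res <- fun(derive_seed(config$seed, name))
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }

  # --- load & filter ------------------------------------------------------
  metadata <- read_cohort_metadata(config$paths$metadata)
  taxonomy <- read_taxonomy(config$paths$taxonomy)
  asv <- read_feature_table(config$paths$asv_table, "counts")
  results$filters <- stage("filters", function(seed) {
    flt <- basic_asv_filter(asv, config$filters$min_samples,
                            config$filters$min_total_reads)
    flt <- organelle_filter(flt, taxonomy)
    genus <- aggregate_to_genus(flt, taxonomy)
    write_feature_table(flt, file.path(out_dir, "asv_filtered.tsv"), "asv_id")
    write_feature_table(genus, file.path(out_dir, "genus_filtered.tsv"), "genus")
    list(asv = flt, genus = genus)
  })
  asv_use <- results$filters$asv %||% asv
  genus_use <- results$filters$genus %||%
    read_feature_table(config$paths$genus_table, "counts")

  # --- diversity ----------------------------------------------------------
  results$diversity <- stage("diversity", function(seed) {
    cfgd <- config$diversity
    rare <- rarefy(genus_use, depth = cfgd$rarefy_depth, seed = seed)
    alpha <- alpha_diversity(rare)
    alpha_tests <- alpha_group_test(alpha, metadata)
    tree <- read_rooted_tree(config$paths$tree, features = ft_features(asv_use))
    perm <- list(); dist_list <- list()
    md <- align_metadata(genus_use, metadata)
    for (metric in cfgd$metrics_genus) {
      d <- beta_distance(genus_use, metric)
      dist_list[[metric]] <- d
      perm[[metric]] <- permanova(d, md$tissue, cfgd$n_permutations,
                                  seed = derive_seed(seed, metric))
    }
    for (metric in cfgd$metrics_asv) {
      d <- beta_distance(asv_use, metric, tree = tree)
      dist_list[[metric]] <- d
      perm[[metric]] <- permanova(d, md$tissue, cfgd$n_permutations,
                                  seed = derive_seed(seed, metric))
    }
    perm_df <- do.call(rbind, lapply(names(perm), function(mn)
      data.frame(metric = mn, r_squared = perm[[mn]]$r_squared,
                 pseudo_f = perm[[mn]]$pseudo_f, p = perm[[mn]]$p_value,
                 n_permutations = perm[[mn]]$n_permutations)))
    pco <- pcoa_ordination(dist_list[[1L]], k = 2)
    write_results(list(alpha_indices = alpha, alpha_tests = alpha_tests,
                       permanova = perm_df,
                       pcoa_axes = data.frame(sample_id = rownames(pco$coordinates),
                                              pco$coordinates)),
                  out_dir)
    list(alpha = alpha, alpha_tests = alpha_tests, permanova = perm_df)
  })

  # --- differential abundance --------------------------------------------
  results$diffab <- stage("diffab", function(seed) {
    tab <- prevalence_filter(genus_use, config$diffab$min_prevalence)
    da <- differential_abundance(tab, metadata, config$diffab$pseudocount,
                                 config$diffab$q_threshold)
    write_results(list(differential_abundance = da), out_dir)
    da
  })

  # --- marker stability selection ----------------------------------------
  results$markers <- stage("markers", function(seed) {
    cfgm <- config$markers
    tab <- prevalence_filter(genus_use, config$diffab$min_prevalence)
    ss <- stability_select(tab, metadata, pseudocount = cfgm$pseudocount,
                           alpha_mixing = cfgm$alpha_mixing,
                           n_bootstrap = cfgm$n_bootstrap,
                           threshold = cfgm$threshold,
                           n_lambda = cfgm$n_lambda, n_folds = cfgm$n_folds,
                           seed = seed)
    oroc <- tryCatch(oob_roc(ss), error = function(e) NULL)
    refit <- if (length(ss$panel))
      refit_panel(tab, metadata, ss$panel, pseudocount = cfgm$pseudocount)
      else NULL
    freq_df <- data.frame(genus = names(ss$selection_frequency),
                          selection_frequency = unname(ss$selection_frequency))
    freq_df <- freq_df[order(-freq_df$selection_frequency, freq_df$genus), ]
    roc_df <- data.frame(
      kind = c("apparent", "oob"),
      auc = c(if (is.null(refit)) NA else refit$apparent_roc$auc,
              if (is.null(oroc)) NA else oroc$auc),
      ci_low = c(if (is.null(refit)) NA else refit$apparent_roc$ci_low,
                 if (is.null(oroc)) NA else oroc$ci_low),
      ci_high = c(if (is.null(refit)) NA else refit$apparent_roc$ci_high,
                  if (is.null(oroc)) NA else oroc$ci_high))
    panel_df <- if (is.null(refit))
      data.frame(term = character(0), log_odds = numeric(0))
      else data.frame(term = names(refit$coefficients),
                      log_odds = unname(refit$coefficients))
    write_results(list(marker_frequencies = freq_df,
                       marker_panel = panel_df,
                       marker_oob_scores = data.frame(
                         sample_id = names(ss$oob_score),
                         oob_score = unname(ss$oob_score),
                         oob_times = unname(ss$oob_times)),
                       marker_roc = roc_df), out_dir)
    list(selection = ss, oob = oroc, refit = refit)
  })

  # --- co-occurrence networks --------------------------------------------
  results$network <- stage("network", function(seed) {
    cfgn <- config$network
    md <- align_metadata(genus_use, metadata)
    out <- list()
    for (grp in c("NC", "LUAD")) {
      gs <- md$sample_id[md$tissue == grp]
      net <- build_network(genus_use, gs, rho_min = cfgn$rho_min,
                           p_max = cfgn$p_max,
                           min_prevalence = cfgn$min_prevalence, group = grp)
      topo <- topology_metrics(net)
      cent <- centralities(net)
      stab <- bootstrap_stable_nodes(genus_use, metadata, grp,
                                     n_bootstrap = cfgn$n_bootstrap,
                                     top_k = cfgn$top_k,
                                     stability_min = cfgn$stability_min,
                                     seed = derive_seed(seed, grp),
                                     rho_min = cfgn$rho_min,
                                     p_max = cfgn$p_max,
                                     min_prevalence = cfgn$min_prevalence)
      cent$stability <- unname(stab$stability[cent$node])
      write_results(stats::setNames(list(
        net$edges, cent,
        data.frame(density = topo$density, mean_degree = topo$mean_degree,
                   clustering_coefficient = topo$clustering_coefficient,
                   n_nodes = topo$n_nodes, n_edges = topo$n_edges),
        data.frame(node = stab$stable_nodes)),
        paste0("network_", tolower(grp), c("_edges", "_nodes", "_topology",
                                           "_stable_nodes"))), out_dir)
      out[[grp]] <- list(network = net, topology = topo, centralities = cent,
                         stable = stab)
    }
    out
  })

  # --- KO / pathway functions --------------------------------------------
  results$functions <- stage("functions", function(seed) {
    cfgf <- config$functions
    ko <- read_feature_table(config$paths$ko_table, "score")
    pathway <- read_feature_table(config$paths$pathway_table, "score")
    module_map <- read_module_map(config$paths$module_map)
    recs <- ko_lopo_screen(ko, metadata, module_map)
    part <- retain_and_partition(recs, cfgf$prevalence_min, cfgf$beta_min,
                                 cfgf$consistency_min)
    sc <- module_scores(ko, part)
    mtest <- module_score_test(sc, metadata, cfgf$fdr_threshold)
    ptest <- pathway_level_test(pathway, metadata)
    score_df <- data.frame(sample_id = rownames(sc$scores), sc$scores,
                           check.names = FALSE)
    write_results(list(ko_lopo = part$records, module_scores = score_df,
                       module_tests = mtest, pathway_tests = ptest), out_dir)
    list(records = part, module_tests = mtest, pathway_tests = ptest)
  })

  yaml::write_yaml(report, file.path(out_dir, "run_report.yaml"))
  writeLines(c(sprintf("run at %s", format(Sys.time())),
               vapply(names(timings), function(nm)
                 sprintf("stage %-10s %8.2f s", nm, timings[[nm]]), "")),
             file.path(out_dir, "run_log.txt"))
  invisible(list(results = results, report = report, out_dir = out_dir))
}
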