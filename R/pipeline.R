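pipeline_defaults <- function() {
  list(
    seed = 1L,
    stages = list(variance = TRUE, index = TRUE, power = FALSE, dmp = TRUE),
    generator = list(n_probes = 1500L, n_studies = 6L, samples_per_study = 40L,
                     study_offset_sd = 0.3, n_sex_dmps = 60L,
                     sex_effect_delta = 0.2, noise_sd = 0.5),
    qc = list(signal_min = 10, max_beadarray_failures = 2L,
              gran_threshold = 0.25, drop_sex_chrom = TRUE,
              drop_cross_reactive = TRUE, drop_snp = FALSE),
    adjust = list(strategy = "all_batches"),
    variance = list(n_probes = 200L, n_studies = 4L, n_reps = 5L),
    index = list(dim = 200L, metric = "euclidean", M = 16L,
                 ef_construction = 200L, ef_search = 300L, k = 10L),
    power = list(N_grid = c(50, 100, 200), delta_grid = c(0.1, 0.2),
                 n_sims = 5L, n_target_dmps = 100L,
                 fdr_threshold = 0.05, detect_limit = 0.01, tau = 0.01),
    dmp = list(top_k = 100L, n_sv = 2L)
  )
}

check_known_keys <- function(cfg, template, path = "") {
  unknown <- setdiff(names(cfg), names(template))
  if (length(unknown))
    stop_invalid("unknown config key(s): ",
                 paste0(path, unknown, collapse = ", "))
  for (nm in names(cfg)) {
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]])) &&
        is.list(cfg[[nm]]))
      check_known_keys(cfg[[nm]], template[[nm]], paste0(path, nm, "$"))
  }
  invisible(TRUE)
}

#' Pipeline configuration
#'
#' Builds a validated configuration for [run_pipeline()] by merging
#' user overrides into the defaults. Unknown keys are rejected with an
#' error naming the key. Configurations round-trip through YAML
#' ([yaml::read_yaml()] lists are accepted as `overrides`).
#'
#' @param overrides named list (possibly nested) of settings to change.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(overrides = list()) {
  template <- pipeline_defaults()
  check_known_keys(overrides, template)
  cfg <- modifyList(template, overrides)
  structure(cfg, class = "pipeline_config")
}

stage_output <- function(manifest, path) c(manifest, path)

#' Run the full synthetic-compilation analysis pipeline
#'
#' Executes the stages in dependency order: synthetic data generation,
#' preprocessing (sample QC, granulocyte filter on deconvolution-estimated
#' fractions, probe filters), study-effect removal, then the toggled
#' analysis stages (variance decomposition, search index, power curve,
#' sex-DMP calling and replication). Every output file is listed in a
#' manifest with md5 checksums, and the resolved configuration is written
#' next to the outputs as YAML. All stage seeds derive deterministically
#' from `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return list with `status` (0 on success), `manifest` (data frame of
#'   file paths and checksums; partial on failure) and `outputs` (the
#'   in-memory stage results).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (!inherits(config, "pipeline_config"))
    config <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  outputs <- list()
  status <- 0L
  err <- NULL
  yaml::write_yaml(unclass(config), file.path(out_dir, "config_resolved.yaml"))
  manifest <- c(manifest, file.path(out_dir, "config_resolved.yaml"))
  tryCatch({
    ## synth ------------------------------------------------------------
    gen <- do.call(generator_config,
                   c(config$generator, list(seed = derive_seed(config$seed, "generator"))))
    reference <- generate_reference_profiles(gen$n_probes,
                                             seed = derive_seed(config$seed, "reference"))
    dataset <- generate_dataset(gen, reference)
    synth_dir <- file.path(out_dir, "synth")
    write_dataset_tsv(dataset, synth_dir)
    manifest <- c(manifest, list.files(synth_dir, full.names = TRUE))
    outputs$dataset <- dataset

    ## preprocess --------------------------------------------------------
    qc_dec <- qc_filter_samples(dataset$qc, config$qc$signal_min,
                                config$qc$max_beadarray_failures)
    est_frac <- deconvolve_cell_fractions(dataset$beta, reference)
    gran_keep <- filter_granulocytes(est_frac[, "Gran"],
                                     dataset$metadata$sample_type,
                                     config$qc$gran_threshold)
    keep_samples <- qc_dec$keep & gran_keep
    qc_report <- data.frame(qc_dec,
                            gran_estimate = est_frac[, "Gran"],
                            gran_keep = gran_keep,
                            final_keep = keep_samples)
    write_table_tsv(qc_report, file.path(out_dir, "qc_report.tsv"))
    manifest <- c(manifest, file.path(out_dir, "qc_report.tsv"))
    probe_keep <- filter_probes(dataset$annotation, config$qc$drop_sex_chrom,
                                config$qc$drop_cross_reactive, config$qc$drop_snp)
    beta <- dataset$beta[probe_keep, keep_samples, drop = FALSE]
    metadata <- dataset$metadata[keep_samples, , drop = FALSE]
    metadata[, CELL_TYPES] <- est_frac[keep_samples, ]
    outputs$metadata <- metadata

    ## adjust ------------------------------------------------------------
    M <- beta_to_m(beta)
    spec <- adjustment_spec(strategy = config$adjust$strategy)
    M_adj <- remove_study_effects(M, metadata, spec)
    beta_adj <- m_to_beta(M_adj)
    write_beta_tsv(M_adj, file.path(out_dir, "m_adjusted.tsv"))
    manifest <- c(manifest, file.path(out_dir, "m_adjusted.tsv"))

    ## variance ----------------------------------------------------------
    if (isTRUE(config$stages$variance)) {
      sim <- run_bias_simulation(list(beta = beta, metadata = metadata),
                                 n_probes = config$variance$n_probes,
                                 n_studies = config$variance$n_studies,
                                 n_reps = config$variance$n_reps,
                                 seed = derive_seed(config$seed, "variance"))
      write_table_tsv(sim$fev, file.path(out_dir, "bias_sim_fev.tsv"))
      write_table_tsv(sim$ratios, file.path(out_dir, "bias_sim_ratios.tsv"))
      manifest <- c(manifest, file.path(out_dir, c("bias_sim_fev.tsv",
                                                   "bias_sim_ratios.tsv")))
      outputs$bias_sim <- sim
    }

    ## hashed profiles (index + PCA share them) --------------------------
    hashed <- hash_features(beta_adj, dim = config$index$dim,
                            hash_seed = derive_seed(config$seed, "hash"))
    if (isTRUE(config$stages$variance)) {
      pca <- pca_fev(hashed, metadata,
                     n_components = min(10L, nrow(metadata) - 1L))
      pca_df <- data.frame(component = seq_along(pca$eigenvalues),
                           eigenvalue = pca$eigenvalues,
                           percent_var = pca$percent_var, pca$category_fev)
      write_table_tsv(pca_df, file.path(out_dir, "pca_fev.tsv"))
      manifest <- c(manifest, file.path(out_dir, "pca_fev.tsv"))
      outputs$pca <- pca
    }
    if (isTRUE(config$stages$index)) {
      idx <- build_index(hashed, metric = config$index$metric,
                         M = config$index$M,
                         ef_construction = config$index$ef_construction,
                         ef_search = config$index$ef_search,
                         seed = derive_seed(config$seed, "index"))
      save_index(idx, file.path(out_dir, "search_index.rds"))
      res <- query_neighbors(idx, hashed, k = config$index$k)
      freq <- label_frequency(res, metadata, "sample_type")
      write_table_tsv(data.frame(sample_id = metadata$sample_id, freq),
                      file.path(out_dir, "neighbor_label_freq.tsv"))
      manifest <- c(manifest, file.path(out_dir, c("search_index.rds",
                                                   "neighbor_label_freq.tsv")))
      outputs$index <- idx
    }

    ## power -------------------------------------------------------------
    if (isTRUE(config$stages$power)) {
      ref_dist <- estimate_reference(beta)
      pcfg <- power_config(N_grid = config$power$N_grid,
                           delta_grid = config$power$delta_grid,
                           n_target_dmps = config$power$n_target_dmps,
                           n_sims = config$power$n_sims,
                           fdr_threshold = config$power$fdr_threshold,
                           detect_limit = config$power$detect_limit,
                           tau = config$power$tau,
                           seed = derive_seed(config$seed, "power"))
      curve <- power_curve(ref_dist, pcfg)
      minn <- find_min_n(curve)
      write_table_tsv(curve, file.path(out_dir, "power_curve.tsv"))
      write_table_tsv(minn, file.path(out_dir, "power_min_n.tsv"))
      manifest <- c(manifest, file.path(out_dir, c("power_curve.tsv",
                                                   "power_min_n.tsv")))
      outputs$power <- list(curve = curve, min_n = minn)
    }

    ## dmp ---------------------------------------------------------------
    if (isTRUE(config$stages$dmp)) {
      sv <- surrogate_variables(M, metadata[c(CELL_TYPES, "age", "sex",
                                              "platform", "study_id")],
                                k = config$dmp$n_sv)
      dmps <- call_sex_dmps(M, metadata, surrogates = sv)
      write_table_tsv(dmps, file.path(out_dir, "sex_dmps.tsv"))
      manifest <- c(manifest, file.path(out_dir, "sex_dmps.tsv"))
      disc <- discovery_set(dataset$truth$sex_dmp_ids,
                            sign(dataset$truth$sex_dmp_delta),
                            source = "planted")
      ranked <- dmps$probe_id[order(dmps$p_value)]
      curve <- concordance_at_top(ranked, disc,
                                  max_rank = min(config$dmp$top_k, nrow(dmps)))
      write_table_tsv(data.frame(rank = seq_along(curve), overlap = curve),
                      file.path(out_dir, "concordance.tsv"))
      manifest <- c(manifest, file.path(out_dir, "concordance.tsv"))
      outputs$dmps <- dmps
      outputs$concordance <- curve
    }
  }, error = function(e) {
    status <<- 1L
    err <<- conditionMessage(e)
  })
  mf <- data.frame(file = manifest,
                   md5 = unname(tools::md5sum(manifest)),
                   stringsAsFactors = FALSE)
  write_table_tsv(mf, file.path(out_dir, "manifest.tsv"))
  list(status = status, manifest = mf, outputs = outputs, error = err)
}
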