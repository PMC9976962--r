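#' Blood cell types modelled by the package
#'
#' The six leukocyte fractions used throughout: CD4+ T cells, CD8+ T cells,
#' natural killer cells, B cells, monocytes and granulocytes.
#' @export
CELL_TYPES <- c("CD4T", "CD8T", "NK", "Bcell", "Mono", "Gran")

#' Controlled vocabulary of blood sample types
#' @export
SAMPLE_TYPES <- c("whole_blood", "cord_blood", "pbmc", "other")

#' Generate reference methylation profiles for six blood cell types
#'
#' Builds a synthetic reference panel for reference-based deconvolution:
#' a probes-by-6 matrix of mean Beta-values, one column per cell type.
#' A designated subset of probes is cell-type-discriminating (the target
#' cell type's mean is separated from every other cell type by at least
#' 0.3 on the Beta scale), which makes the deconvolution problem
#' identifiable; remaining probes share a common baseline with small
#' cell-specific jitter.
#'
#' @param n_probes number of probes (>= 6).
#' @param seed integer seed; identical seeds give identical panels.
#' @param disc_fraction fraction of probes reserved as discriminating
#'   (split evenly over the six cell types).
#' @return An object of class `cell_type_reference`: a list with
#'   `probe_ids`, `profiles` (probes x 6 matrix in \[0,1\]), `cell_names`,
#'   and `discriminating` (named character vector mapping discriminating
#'   probe ids to the cell type they mark).
#' @export
generate_reference_profiles <- function(n_probes, seed = 1L, disc_fraction = 0.3) {
  if (!is.numeric(n_probes) || length(n_probes) != 1L || n_probes < 6)
    stop_invalid("n_probes must be a single number >= 6")
  n_probes <- as.integer(n_probes)
  with_seed(seed, {
    probe_ids <- sprintf("cg%08d", seq_len(n_probes))
    profiles <- matrix(0, n_probes, 6L, dimnames = list(probe_ids, CELL_TYPES))
    n_disc_per <- max(1L, floor(n_probes * disc_fraction / 6))
    disc_idx <- seq_len(min(n_probes, 6L * n_disc_per))
    disc_type <- rep(CELL_TYPES, each = n_disc_per)[seq_along(disc_idx)]
    # non-discriminating baseline: mid-range mean, small cell-specific jitter
    base <- rbeta(n_probes, 2, 2) * 0.8 + 0.1
    jitter <- matrix(runif(n_probes * 6L, -0.04, 0.04), n_probes, 6L)
    profiles[] <- clamp(base + jitter, 0.02, 0.98)
    # discriminating probes: hypomethylated everywhere except the target type
    for (i in seq_along(disc_idx)) {
      p <- disc_idx[i]
      profiles[p, ] <- runif(6L, 0.05, 0.25)
      profiles[p, disc_type[i]] <- runif(1L, 0.70, 0.90)
    }
    structure(list(probe_ids = probe_ids,
                   profiles = profiles,
                   cell_names = CELL_TYPES,
                   discriminating = setNames(disc_type, probe_ids[disc_idx])),
              class = "cell_type_reference")
  })
}

#' @export
print.cell_type_reference <- function(x, ...) {
  cat("Cell-type reference panel:", length(x$probe_ids), "probes x",
      length(x$cell_names), "cell types;",
      length(x$discriminating), "discriminating probes\n")
  invisible(x)
}

#' Configuration for the synthetic compilation generator
#'
#' Bundles and validates every knob of [generate_dataset()]. Effects are
#' additive on the natural-logit scale of the Beta-value (an M-value-like
#' scale) and mapped back through the inverse logit.
#'
#' @param n_probes number of probes.
#' @param n_studies number of studies in the compilation.
#' @param samples_per_study samples per study (scalar or length-`n_studies`).
#' @param study_offset_sd SD of the per-study additive offset (logit scale).
#' @param platforms the two array platform labels; each study is assigned
#'   one platform at random.
#' @param shared_probe_fraction fraction of probes shared by both platforms;
#'   the remainder are annotated as exclusive to the second platform.
#' @param sample_type_probs named proportions over `SAMPLE_TYPES`; must sum
#'   to 1. Sample type is drawn per sample.
#' @param dirichlet_alpha named list of 6-vectors, one per sample type:
#'   Dirichlet concentrations for the cell-composition mixture.
#' @param pbmc_gran_contam_prob probability a PBMC sample carries residual
#'   granulocyte contamination (a heavy upper tail, drawn U(0.2, 0.5)),
#'   exercising the granulocyte QC filter.
#' @param n_sex_dmps number of planted sex-associated probes.
#' @param sex_effect_delta target male-female mean Beta difference at
#'   planted probes, in (0, 1).
#' @param age_slope_sd SD of per-probe linear age slopes (logit units per
#'   year of age).
#' @param ancestry_loading_sd SD of per-probe loadings on the two genetic
#'   ancestry scores (logit units per score SD).
#' @param noise_sd SD of iid Gaussian measurement noise (logit scale).
#' @param seed integer seed; the full dataset is a deterministic function
#'   of (config, seed).
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_probes = 2000L,
                             n_studies = 6L,
                             samples_per_study = 40L,
                             study_offset_sd = 0.3,
                             platforms = c("hm450k", "epic"),
                             shared_probe_fraction = 0.9,
                             sample_type_probs = c(whole_blood = 0.5,
                                                   cord_blood = 0.15,
                                                   pbmc = 0.25,
                                                   other = 0.10),
                             dirichlet_alpha = NULL,
                             pbmc_gran_contam_prob = 0.05,
                             n_sex_dmps = 100L,
                             sex_effect_delta = 0.2,
                             age_slope_sd = 0.005,
                             ancestry_loading_sd = 0.1,
                             noise_sd = 0.5,
                             seed = 1L) {
  if (is.null(dirichlet_alpha)) {
    dirichlet_alpha <- list(
      whole_blood = c(CD4T = 8, CD8T = 4, NK = 2, Bcell = 2, Mono = 2, Gran = 30),
      cord_blood  = c(CD4T = 6, CD8T = 4, NK = 3, Bcell = 2, Mono = 2, Gran = 25),
      pbmc        = c(CD4T = 12, CD8T = 8, NK = 4, Bcell = 4, Mono = 4, Gran = 0.3),
      other       = c(CD4T = 8, CD8T = 5, NK = 3, Bcell = 3, Mono = 3, Gran = 15))
  }
  cfg <- list(n_probes = as.integer(n_probes), n_studies = as.integer(n_studies),
              samples_per_study = as.integer(samples_per_study),
              study_offset_sd = study_offset_sd, platforms = platforms,
              shared_probe_fraction = shared_probe_fraction,
              sample_type_probs = sample_type_probs,
              dirichlet_alpha = dirichlet_alpha,
              pbmc_gran_contam_prob = pbmc_gran_contam_prob,
              n_sex_dmps = as.integer(n_sex_dmps),
              sex_effect_delta = sex_effect_delta,
              age_slope_sd = age_slope_sd,
              ancestry_loading_sd = ancestry_loading_sd,
              noise_sd = noise_sd, seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n_probes < 1L || cfg$n_studies < 1L || any(cfg$samples_per_study < 1L))
    stop_invalid("counts must be positive")
  if (!length(cfg$samples_per_study) %in% c(1L, cfg$n_studies))
    stop_invalid("samples_per_study must be scalar or one entry per study")
  if (abs(sum(cfg$sample_type_probs) - 1) > 1e-8)
    stop_invalid("sample_type_probs must sum to 1")
  if (!setequal(names(cfg$sample_type_probs), SAMPLE_TYPES))
    stop_invalid("sample_type_probs must be named by SAMPLE_TYPES")
  if (cfg$n_sex_dmps > 0 &&
      (cfg$sex_effect_delta <= 0 || cfg$sex_effect_delta >= 1))
    stop_invalid("sex_effect_delta must lie in (0, 1)")
  if (length(cfg$platforms) != 2L) stop_invalid("exactly two platforms expected")
  if (any(vapply(cfg$dirichlet_alpha, length, 1L) != 6L))
    stop_invalid("each dirichlet_alpha entry must have 6 concentrations")
  invisible(cfg)
}

# Logit-scale shift that produces an expected Beta-scale group difference
# of `delta` (signed) for a probe whose per-sample logit signal takes the
# values in `eta_row` before measurement noise. The expectation integrates
# over the empirical signal distribution and N(0, sd^2) noise (mid-point
# quadrature), so the shift compensates the inverse-logit shrinkage, which
# is asymmetric between up- and down-shifts.
calibrate_logit_shift <- function(eta_row, delta, noise_sd) {
  base <- if (length(eta_row) > 200) {
    quantile(eta_row, (seq_len(200) - 0.5) / 200, names = FALSE)
  } else eta_row
  z <- stats::qnorm((seq_len(21) - 0.5) / 21) * noise_sd
  x <- outer(base, z, "+")
  f <- function(l) mean(inv_logit(x + l)) - mean(inv_logit(x)) - delta
  lim <- 20 * sign(delta)
  if (sign(f(lim)) == sign(delta) * -1) return(lim)  # unreachable target
  stats::uniroot(f, sort(c(0, lim)), tol = 1e-10)$root
}

#' Generate a synthetic multi-study blood methylation compilation
#'
#' Emulates the structure of cross-study DNAm array compilations: several
#' studies with additive per-study offsets, two platforms sharing most
#' probes, three named blood sample types plus an "other" class,
#' Dirichlet-mixed six-cell-type composition, sex/age/ancestry-driven
#' methylation effects, planted sex DMPs, and Gaussian measurement noise.
#' All effects are additive on the natural-logit (M-value-like) scale and
#' mapped back to Beta-values, which are clamped to \[1e-6, 1 - 1e-6\].
#' PBMC samples draw granulocyte fractions near zero with a configurable
#' contaminated upper tail.
#'
#' @param config a [generator_config()].
#' @param reference a [generate_reference_profiles()] panel with exactly
#'   `config$n_probes` probes.
#' @return An object of class `synthetic_dnam_dataset`: list with
#'   `beta` (probes x samples matrix), `metadata` (one row per sample:
#'   study, platform, sample type, sex, age, two ancestry scores, six true
#'   cell fractions), `annotation` (per-probe chromosome, island relation,
#'   cross-reactive/SNP flags, platform availability), `qc` (per-sample
#'   signal and BeadArray quality metrics), and `truth` (planted sex-DMP
#'   ids and signed Beta-scale deltas, true cell fractions, true study
#'   offsets, age slopes and ancestry loadings).
#' @export
generate_dataset <- function(config, reference) {
  validate_generator_config(config)
  if (!inherits(reference, "cell_type_reference"))
    stop_invalid("reference must be a cell_type_reference")
  if (length(reference$probe_ids) != config$n_probes)
    stop_invalid("reference probe count (", length(reference$probe_ids),
                 ") must equal config$n_probes (", config$n_probes, ")")
  with_seed(config$seed, {
    n_probes <- config$n_probes
    probe_ids <- reference$probe_ids
    n_per <- rep(config$samples_per_study, length.out = config$n_studies)
    n_samples <- sum(n_per)
    study_id <- rep(sprintf("study%02d", seq_len(config$n_studies)), times = n_per)
    sample_ids <- sprintf("s%05d", seq_len(n_samples))

    ## probe annotation --------------------------------------------------
    chrom <- sample(c(paste0("chr", 1:22), "chrX", "chrY"), n_probes,
                    replace = TRUE,
                    prob = c(rep(0.96 / 22, 22), 0.03, 0.01))
    island_relation <- sample(c("island", "shore", "shelf", "open_sea"),
                              n_probes, replace = TRUE,
                              prob = c(0.30, 0.25, 0.10, 0.35))
    cross_reactive <- runif(n_probes) < 0.03
    snp_overlap <- runif(n_probes) < 0.02
    n_excl <- round((1 - config$shared_probe_fraction) * n_probes)
    platform_avail <- rep("both", n_probes)
    if (n_excl > 0)
      platform_avail[sample.int(n_probes, n_excl)] <- config$platforms[2L]
    annotation <- data.frame(probe_id = probe_ids, chromosome = chrom,
                             island_relation = island_relation,
                             cross_reactive = cross_reactive,
                             snp_overlap = snp_overlap,
                             platforms = platform_avail,
                             stringsAsFactors = FALSE)

    ## sample-level covariates -------------------------------------------
    study_platform <- setNames(sample(config$platforms, config$n_studies,
                                      replace = TRUE), unique(study_id))
    # guarantee both platforms appear when there are >= 2 studies
    if (config$n_studies >= 2L && length(unique(study_platform)) == 1L)
      study_platform[config$n_studies] <- setdiff(config$platforms,
                                                  study_platform[1L])
    platform <- unname(study_platform[study_id])
    sample_type <- sample(names(config$sample_type_probs), n_samples,
                          replace = TRUE, prob = config$sample_type_probs)
    sex <- sample(c("female", "male"), n_samples, replace = TRUE)
    age <- runif(n_samples, 20, 70)
    age[sample_type == "cord_blood"] <- 0
    anc <- matrix(rnorm(2 * n_samples), n_samples, 2,
                  dimnames = list(NULL, c("ancestry_pc1", "ancestry_pc2")))

    ## cell compositions --------------------------------------------------
    w <- matrix(0, n_samples, 6, dimnames = list(sample_ids, CELL_TYPES))
    for (st in unique(sample_type)) {
      idx <- which(sample_type == st)
      w[idx, ] <- rdirichlet(length(idx), config$dirichlet_alpha[[st]])
    }
    pbmc_idx <- which(sample_type == "pbmc")
    contam <- pbmc_idx[runif(length(pbmc_idx)) < config$pbmc_gran_contam_prob]
    if (length(contam)) {
      g <- runif(length(contam), 0.2, 0.5)
      others <- w[contam, -6, drop = FALSE]
      w[contam, -6] <- others * (1 - g) / rowSums(others)
      w[contam, 6] <- g
    }

    ## planted sex DMPs ---------------------------------------------------
    autosomal <- !(chrom %in% c("chrX", "chrY"))
    ref_base <- rowMeans(reference$profiles)
    eligible <- which(autosomal & !cross_reactive & platform_avail == "both" &
                        ref_base > 0.2 & ref_base < 0.65 &
                        !(probe_ids %in% names(reference$discriminating)))
    if (config$n_sex_dmps > length(eligible))
      stop_invalid("not enough eligible autosomal probes for n_sex_dmps")
    dmp_idx <- sort(sample(eligible, config$n_sex_dmps))
    dmp_sign <- sample(c(-1, 1), config$n_sex_dmps, replace = TRUE)

    ## assemble logit-scale signal ---------------------------------------
    eps <- 1e-6
    mix <- reference$profiles %*% t(w)            # probes x samples
    eta <- logit(clamp(mix, eps, 1 - eps))
    offsets <- setNames(rnorm(config$n_studies, 0, config$study_offset_sd),
                        unique(study_id))
    eta <- eta + matrix(offsets[study_id], n_probes, n_samples, byrow = TRUE)
    age_slopes <- rnorm(n_probes, 0, config$age_slope_sd)
    if (config$age_slope_sd > 0)
      eta <- eta + outer(age_slopes, age)
    anc_load <- matrix(rnorm(2 * n_probes, 0, config$ancestry_loading_sd),
                       n_probes, 2)
    if (config$ancestry_loading_sd > 0)
      eta <- eta + tcrossprod(anc_load, anc)
    # sex shifts are calibrated on the realized signal distribution so the
    # male-female Beta difference lands on sex_effect_delta
    male <- sex == "male"
    if (config$n_sex_dmps > 0) {
      dmp_shift <- vapply(seq_along(dmp_idx), function(i)
        calibrate_logit_shift(eta[dmp_idx[i], ],
                              dmp_sign[i] * config$sex_effect_delta,
                              config$noise_sd), numeric(1))
      eta[dmp_idx, male] <- eta[dmp_idx, male] + dmp_shift
    }
    if (config$noise_sd > 0)
      eta <- eta + matrix(rnorm(n_probes * n_samples, 0, config$noise_sd),
                          n_probes, n_samples)
    beta <- clamp(inv_logit(eta), eps, 1 - eps)
    dimnames(beta) <- list(probe_ids, sample_ids)

    ## per-sample QC metrics ----------------------------------------------
    bad <- runif(n_samples) < 0.03
    log2_median_M <- rnorm(n_samples, 11.5, 0.5)
    log2_median_U <- rnorm(n_samples, 11.3, 0.5)
    log2_median_M[bad] <- rnorm(sum(bad), 9.4, 0.3)
    log2_median_U[bad] <- rnorm(sum(bad), 9.3, 0.3)
    beadarray_failures <- rbinom(n_samples, 5, 0.02)
    qc <- data.frame(sample_id = sample_ids,
                     log2_median_M = log2_median_M,
                     log2_median_U = log2_median_U,
                     beadarray_failures = beadarray_failures,
                     stringsAsFactors = FALSE)

    metadata <- data.frame(sample_id = sample_ids, study_id = study_id,
                           platform = platform, sample_type = sample_type,
                           sex = sex, age = age,
                           ancestry_pc1 = anc[, 1], ancestry_pc2 = anc[, 2],
                           w, stringsAsFactors = FALSE)
    truth <- list(sex_dmp_ids = probe_ids[dmp_idx],
                  sex_dmp_delta = setNames(dmp_sign * config$sex_effect_delta,
                                           probe_ids[dmp_idx]),
                  cell_fractions = w,
                  study_offsets = offsets,
                  age_slopes = setNames(age_slopes, probe_ids),
                  ancestry_loadings = anc_load)
    structure(list(beta = beta, metadata = metadata, annotation = annotation,
                   qc = qc, truth = truth, config = config),
              class = "synthetic_dnam_dataset")
  })
}

#' @export
print.synthetic_dnam_dataset <- function(x, ...) {
  cat("Synthetic DNAm compilation:", nrow(x$beta), "probes x", ncol(x$beta),
      "samples;", length(unique(x$metadata$study_id)), "studies;",
      length(x$truth$sex_dmp_ids), "planted sex DMPs\n")
  invisible(x)
}
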