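# Shared fixtures, built once per test run. Sizes are kept small: the
# statistical properties under test (recovery, calibration, orthogonality)
# are scale-free.

fix_ref <- generate_reference_profiles(400, seed = 101)

fix_dataset <- generate_dataset(
  generator_config(n_probes = 400, n_studies = 5, samples_per_study = 30,
                   study_offset_sd = 0.4, n_sex_dmps = 40,
                   sex_effect_delta = 0.2, noise_sd = 0.4, seed = 202),
  fix_ref)

# metadata with deconvolution-estimated cell fractions, as the pipeline
# models it (estimated fractions do not sum exactly to 1)
fix_est_meta <- local({
  est <- deconvolve_cell_fractions(fix_dataset$beta, fix_ref)
  meta <- fix_dataset$metadata
  meta[, CELL_TYPES] <- est
  meta
})

# wrap a plain matrix as hashed profiles (for index tests that plant
# geometry directly)
as_hashed <- function(X, dim = ncol(X), hash_seed = 0L, signed = TRUE) {
  structure(X, class = c("hashed_profiles", "matrix", "array"),
            dim_target = as.integer(dim), hash_seed = as.integer(hash_seed),
            signed = signed)
}

# random metadata for property tests over randomized designs
random_metadata <- function(n, include = c("study_id", "sex", "age")) {
  out <- data.frame(row.names = seq_len(n))
  if ("study_id" %in% include)
    out$study_id <- sample(sprintf("st%d", 1:3), n, replace = TRUE)
  if ("platform" %in% include)
    out$platform <- sample(c("hm450k", "epic"), n, replace = TRUE)
  if ("sex" %in% include)
    out$sex <- sample(c("female", "male"), n, replace = TRUE)
  if ("age" %in% include) out$age <- runif(n, 0, 70)
  if ("ancestry_pc1" %in% include) out$ancestry_pc1 <- rnorm(n)
  out
}
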