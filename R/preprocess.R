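#' Convert Beta-values to M-values
#'
#' M = log2(b / (1 - b)) after clamping b to \[epsilon, 1 - epsilon\], the
#' standard logit2 transform used for linear modelling of methylation
#' fractions. Inverse of [m_to_beta()] for values inside the clamp bounds.
#'
#' @param beta numeric vector or probes-by-samples matrix of methylation
#'   fractions in \[0, 1\].
#' @param epsilon clamp bound in (0, 0.5); boundary Beta-values are pulled
#'   inside so the transform stays finite.
#' @return M-values with the same shape and dimnames as `beta`.
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  if (epsilon <= 0 || epsilon >= 0.5)
    stop_invalid("epsilon must lie in (0, 0.5)")
  b <- clamp(beta, epsilon, 1 - epsilon)
  log2(b / (1 - b))
}

#' Convert M-values back to Beta-values
#' @param m numeric vector or matrix of M-values.
#' @return Beta-values in (0, 1), same shape as `m`.
#' @export
m_to_beta <- function(m) {
  1 / (1 + 2^(-m))
}

#' Sample quality-control filter on signal and BeadArray metrics
#'
#' A sample is removed when (i) its log2 median methylated and
#' unmethylated signals are both below `signal_min`, or (ii) it failed at
#' least `max_beadarray_failures` of the five most informative BeadArray
#' quality metrics. Samples with missing metrics are removed with their
#' own reason code.
#'
#' @param qc data frame with columns `sample_id`, `log2_median_M`,
#'   `log2_median_U`, `beadarray_failures` (count in 0..5).
#' @param signal_min threshold for rule (i); default 10.
#' @param max_beadarray_failures threshold for rule (ii); default 2
#'   (inclusive).
#' @return data frame with `sample_id`, `keep` (logical) and `reason`
#'   (one of "ok", "signal", "beadarray", "missing_metric"; when both
#'   rules fire, "signal" is reported).
#' @export
qc_filter_samples <- function(qc, signal_min = 10, max_beadarray_failures = 2L) {
  need <- c("sample_id", "log2_median_M", "log2_median_U", "beadarray_failures")
  if (!all(need %in% names(qc)))
    stop_invalid("qc must contain columns: ", paste(need, collapse = ", "))
  miss <- is.na(qc$log2_median_M) | is.na(qc$log2_median_U) |
    is.na(qc$beadarray_failures)
  signal <- !miss & qc$log2_median_M < signal_min & qc$log2_median_U < signal_min
  bead <- !miss & qc$beadarray_failures >= max_beadarray_failures
  reason <- rep("ok", nrow(qc))
  reason[bead] <- "beadarray"
  reason[signal] <- "signal"
  reason[miss] <- "missing_metric"
  data.frame(sample_id = qc$sample_id, keep = reason == "ok",
             reason = reason, stringsAsFactors = FALSE)
}

#' Granulocyte-contamination filter for PBMC samples
#'
#' PBMC preparations deplete granulocytes, so a high estimated granulocyte
#' fraction marks a contaminated or mislabelled sample. Removal applies
#' only to PBMC samples with `Gran >= threshold` (inclusive); other sample
#' types always pass.
#'
#' @param gran_fraction numeric vector of estimated granulocyte fractions.
#' @param sample_type character vector of sample types (same length).
#' @param threshold inclusive cut-off, default 0.25.
#' @return logical keep-vector.
#' @export
filter_granulocytes <- function(gran_fraction, sample_type, threshold = 0.25) {
  if (length(gran_fraction) != length(sample_type))
    stop_invalid("gran_fraction and sample_type lengths differ")
  !(sample_type == "pbmc" & gran_fraction >= threshold)
}

#' Probe filters: sex chromosomes, cross-reactive and SNP-overlap probes
#'
#' @param annotation data frame with columns `probe_id`, `chromosome`
#'   (chr1..chr22, chrX, chrY), `cross_reactive`, `snp_overlap`.
#' @param drop_sex_chrom drop probes on chrX/chrY.
#' @param drop_cross_reactive drop probes flagged cross-reactive.
#' @param drop_snp drop probes overlapping known SNPs.
#' @return logical keep-mask in annotation (probe) order.
#' @export
filter_probes <- function(annotation, drop_sex_chrom = TRUE,
                          drop_cross_reactive = TRUE, drop_snp = FALSE) {
  valid_chrom <- c(paste0("chr", 1:22), "chrX", "chrY")
  bad <- setdiff(unique(annotation$chromosome), valid_chrom)
  if (length(bad))
    stop_invalid("unknown chromosome label(s): ", paste(bad, collapse = ", "))
  keep <- rep(TRUE, nrow(annotation))
  if (drop_sex_chrom) keep <- keep & !(annotation$chromosome %in% c("chrX", "chrY"))
  if (drop_cross_reactive) keep <- keep & !annotation$cross_reactive
  if (drop_snp) keep <- keep & !annotation$snp_overlap
  keep
}

# Ordered rule table for sample-type harmonization; first match wins.
.sample_type_rules <- list(
  list(pattern = "cord", type = "cord_blood"),
  list(pattern = "umbilical", type = "cord_blood"),
  list(pattern = "pbmc", type = "pbmc"),
  list(pattern = "peripheral\\s+blood\\s+mononuclear", type = "pbmc"),
  list(pattern = "mononuclear", type = "pbmc"),
  list(pattern = "whole\\s+blood", type = "whole_blood"),
  list(pattern = "peripheral\\s+blood(?!\\s+mononuclear)", type = "whole_blood"),
  list(pattern = "^blood$", type = "whole_blood")
)

#' Harmonize a free-text sample-type label to the controlled vocabulary
#'
#' Case-insensitive, ordered regular-expression rules map heterogeneous
#' study-supplied tissue descriptions onto `whole_blood`, `cord_blood`,
#' `pbmc` or the fallback `other`. First matching rule wins.
#'
#' @param label character vector of free-text labels.
#' @return character vector of controlled sample types.
#' @export
harmonize_sample_type <- function(label) {
  if (any(!nzchar(label)) || any(is.na(label)))
    stop_invalid("labels must be non-empty strings")
  vapply(tolower(trimws(label)), function(x) {
    for (rule in .sample_type_rules)
      if (grepl(rule$pattern, x, perl = TRUE)) return(rule$type)
    "other"
  }, character(1), USE.NAMES = FALSE)
}
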