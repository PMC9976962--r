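#' Read and write probes-by-samples Beta matrices as TSV
#'
#' The matrix is stored as plain TSV with a `probe_id` first column and
#' one column per sample; [read_beta_tsv()] restores the numeric matrix
#' with its dimnames. The same pair serves M-value matrices.
#'
#' @param beta probes-by-samples numeric matrix with dimnames.
#' @param path file path.
#' @export
write_beta_tsv <- function(beta, path) {
  df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beta_tsv
#' @export
read_beta_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$probe_id
  m
}

#' Read and write per-sample or per-probe tables as TSV
#' @param x data frame.
#' @param path file path.
#' @export
write_table_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Serialize a synthetic compilation to a directory of TSV files
#'
#' Writes `beta.tsv`, `metadata.tsv`, `annotation.tsv`, `qc.tsv` and the
#' ground truth (`truth_dmps.tsv`, `truth_offsets.tsv`,
#' `truth_fractions.tsv`); [read_dataset_tsv()] restores the round-trip.
#'
#' @param dataset a `synthetic_dnam_dataset`.
#' @param dir output directory (created if missing).
#' @export
write_dataset_tsv <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_beta_tsv(dataset$beta, file.path(dir, "beta.tsv"))
  write_table_tsv(dataset$metadata, file.path(dir, "metadata.tsv"))
  write_table_tsv(dataset$annotation, file.path(dir, "annotation.tsv"))
  write_table_tsv(dataset$qc, file.path(dir, "qc.tsv"))
  write_table_tsv(data.frame(probe_id = dataset$truth$sex_dmp_ids,
                             delta = unname(dataset$truth$sex_dmp_delta)),
                  file.path(dir, "truth_dmps.tsv"))
  write_table_tsv(data.frame(study_id = names(dataset$truth$study_offsets),
                             offset = unname(dataset$truth$study_offsets)),
                  file.path(dir, "truth_offsets.tsv"))
  write_table_tsv(data.frame(sample_id = rownames(dataset$truth$cell_fractions),
                             dataset$truth$cell_fractions),
                  file.path(dir, "truth_fractions.tsv"))
  invisible(dir)
}

#' @rdname write_dataset_tsv
#' @export
read_dataset_tsv <- function(dir) {
  dmps <- read_table_tsv(file.path(dir, "truth_dmps.tsv"))
  offs <- read_table_tsv(file.path(dir, "truth_offsets.tsv"))
  fr <- read_table_tsv(file.path(dir, "truth_fractions.tsv"))
  frm <- as.matrix(fr[, -1, drop = FALSE])
  rownames(frm) <- fr$sample_id
  structure(list(beta = read_beta_tsv(file.path(dir, "beta.tsv")),
                 metadata = read_table_tsv(file.path(dir, "metadata.tsv")),
                 annotation = read_table_tsv(file.path(dir, "annotation.tsv")),
                 qc = read_table_tsv(file.path(dir, "qc.tsv")),
                 truth = list(sex_dmp_ids = dmps$probe_id,
                              sex_dmp_delta = setNames(dmps$delta, dmps$probe_id),
                              cell_fractions = frm,
                              study_offsets = setNames(offs$offset, offs$study_id)),
                 config = NULL),
            class = "synthetic_dnam_dataset")
}
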