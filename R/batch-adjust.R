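#' Default covariates preserved during study-effect removal
#'
#' The 11 non-technical modelling variables: sample type, the six cell
#' fractions, age, sex and two genetic ancestry scores.
#' @export
default_preserve_covariates <- function() {
  c("sample_type", "age", "sex", "ancestry_pc1", "ancestry_pc2", CELL_TYPES)
}

#' Specification of a study-bias adjustment
#'
#' Two strategies are supported. `all_batches` ("uniform adjustment")
#' treats every study label as its own batch level. `subset_batches`
#' ("exact adjustment") keeps only the chosen studies as distinct batch
#' levels and collapses all remaining studies into a single reference
#' level before coding.
#'
#' @param batch_variable metadata column holding the batch label.
#' @param covariates metadata columns whose effects must be preserved.
#' @param strategy `"all_batches"` or `"subset_batches"`.
#' @param subset study ids forming the batch levels (subset strategy only);
#'   conventionally 2-4 studies.
#' @return list of class `adjustment_spec`.
#' @export
adjustment_spec <- function(batch_variable = "study_id",
                            covariates = default_preserve_covariates(),
                            strategy = c("all_batches", "subset_batches"),
                            subset = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "subset_batches") {
    if (is.null(subset) || length(subset) == 0L)
      stop_invalid("subset_batches strategy requires a non-empty subset")
    if (length(subset) < 2L || length(subset) > 4L)
      warning("subset size outside the conventional 2-4 range")
  } else if (!is.null(subset)) {
    stop_invalid("subset must be NULL for the all_batches strategy")
  }
  structure(list(batch_variable = batch_variable, covariates = covariates,
                 strategy = strategy, subset = subset),
            class = "adjustment_spec")
}

# Orthonormal basis of the column space of X, tolerant of rank deficiency.
ortho_basis <- function(X, tol = 1e-10) {
  qrX <- qr(X, tol = tol)
  if (qrX$rank == 0L) return(matrix(0, nrow(X), 0))
  qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
}

#' Remove additive study effects from M-values
#'
#' Per probe, jointly fits M = intercept + covariates beta + batch gamma
#' + error by least squares, with sum-to-zero batch coding, and returns
#' M minus the fitted batch component. Covariate-associated variation is
#' preserved. Under the `subset_batches` strategy, studies outside the
#' subset are merged into one reference level before coding. The
#' operation is an orthogonal projection, hence idempotent.
#'
#' @param M probes-by-samples matrix of M-values (column names are
#'   sample ids matching `metadata$sample_id` order).
#' @param metadata per-sample data frame containing the batch variable
#'   and every covariate named in `spec`.
#' @param spec an [adjustment_spec()].
#' @return adjusted M-value matrix, same shape and dimnames.
#' @export
remove_study_effects <- function(M, metadata, spec = adjustment_spec()) {
  if (!inherits(spec, "adjustment_spec")) stop_invalid("spec must be an adjustment_spec")
  if (ncol(M) != nrow(metadata))
    stop_invalid("M columns and metadata rows differ")
  batch_raw <- metadata[[spec$batch_variable]]
  if (is.null(batch_raw) || anyNA(batch_raw))
    stop_invalid("every sample needs a batch label in '", spec$batch_variable, "'")
  if (spec$strategy == "subset_batches") {
    unknown <- setdiff(spec$subset, unique(batch_raw))
    if (length(unknown))
      stop_invalid("subset studies absent from data: ", paste(unknown, collapse = ", "))
    batch_raw <- ifelse(batch_raw %in% spec$subset, batch_raw, ".reference")
  }
  batch <- factor(batch_raw)
  if (nlevels(batch) < 2L) return(M)  # single batch: nothing estimable

  B <- model.matrix(~ batch,
                    contrasts.arg = list(batch = "contr.sum"))[, -1, drop = FALSE]
  covs <- intersect(spec$covariates, names(metadata))
  Xcov <- if (length(covs)) {
    model.matrix(~ ., data = as.data.frame(metadata[covs]))
  } else {
    matrix(1, nrow(metadata), 1)
  }
  Q <- ortho_basis(Xcov)
  B_res <- B - Q %*% crossprod(Q, B)
  # a batch column whose residual vanishes lies in the covariate span
  aliased_col <- which(sqrt(colSums(B_res^2)) <
                         1e-8 * pmax(sqrt(colSums(B^2)), 1))
  if (length(aliased_col)) {
    # name the covariate most correlated with each confounded batch column
    culprits <- vapply(aliased_col, function(j) {
      cors <- suppressWarnings(abs(stats::cor(Xcov[, -1, drop = FALSE], B[, j])))
      if (!length(cors) || all(is.na(cors))) "intercept"
      else colnames(Xcov)[-1][which.max(cors)]
    }, character(1))
    stop("batch '", spec$batch_variable, "' is confounded with covariate(s): ",
         paste(unique(culprits), collapse = ", "))
  }
  if (qr(B_res)$rank < ncol(B))
    stop("batch '", spec$batch_variable,
         "' design is rank-deficient after preserving covariates")
  Y <- t(M)                                    # samples x probes
  gamma <- solve(crossprod(B_res), crossprod(B_res, Y))
  t(Y - B %*% gamma)
}
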