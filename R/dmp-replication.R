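#' Surrogate variables from residual structure
#'
#' Residualizes the M-value matrix against the known design and returns
#' the top-k left singular vectors of the residual (sample side) as
#' surrogate covariates. These absorb hidden structure (e.g. an
#' unrecorded batch) orthogonal to the modelled variables. This is a
#' deliberately simple residual-SVD variant of surrogate variable
#' analysis.
#'
#' @param M probes-by-samples M-value matrix.
#' @param design per-sample data frame (or numeric matrix) of known
#'   variables to protect.
#' @param k number of surrogate variables; `k = 0` returns a zero-column
#'   matrix; `k >= n - rank(design)` is an error.
#' @return samples-by-k matrix of surrogate covariates (unit norm).
#' @export
surrogate_variables <- function(M, design, k = 2L) {
  Y <- t(M)
  X <- if (is.data.frame(design)) model.matrix(~ ., data = design) else cbind(1, design)
  n <- nrow(Y)
  qrX <- qr(X)
  if (k < 0) stop_invalid("k must be non-negative")
  if (k >= n - qrX$rank)
    stop_invalid("k (", k, ") must be below n - design rank (",
                 n - qrX$rank, ")")
  if (k == 0L) return(matrix(0, n, 0))
  R <- Y - qr.fitted(qrX, Y)
  sv <- svd(R, nu = k, nv = 0)
  out <- sv$u
  colnames(out) <- paste0("SV", seq_len(k))
  out
}

#' Call sex-associated differentially methylated probes
#'
#' Per probe, ordinary least squares of the M-values on sex plus
#' adjustment covariates (by default the six cell fractions, age,
#' platform and study ID) plus optional surrogate variables. The sex
#' coefficient is the male-minus-female M-value difference; its
#' two-sided t-test p-value is adjusted with Bonferroni (default) or
#' Benjamini-Hochberg.
#'
#' @param M probes-by-samples M-value matrix.
#' @param metadata per-sample data frame with `sex` ("female"/"male") and
#'   the covariate columns.
#' @param covariates metadata columns to adjust for.
#' @param surrogates optional samples-by-k matrix from
#'   [surrogate_variables()].
#' @param adjust_method `"bonferroni"` or `"BH"`.
#' @return data frame of class `dmp_result`, one row per probe:
#'   `probe_id`, `p_value`, `adjusted_p`, `effect` (male - female, M
#'   scale), `direction` (sign of effect).
#' @export
call_sex_dmps <- function(M, metadata,
                          covariates = c(CELL_TYPES, "age", "platform", "study_id"),
                          surrogates = NULL,
                          adjust_method = c("bonferroni", "BH")) {
  adjust_method <- match.arg(adjust_method)
  if (ncol(M) != nrow(metadata)) stop_invalid("M/metadata size mismatch")
  sex <- factor(metadata$sex, levels = c("female", "male"))
  if (nlevels(droplevels(sex)) < 2L)
    stop_invalid("both sexes must be represented")
  covariates <- intersect(covariates, names(metadata))
  Xc <- if (length(covariates)) {
    model.matrix(~ ., data = as.data.frame(metadata[covariates]))[, -1, drop = FALSE]
  } else NULL
  X <- cbind(`(Intercept)` = 1, sexmale = as.numeric(sex == "male"), Xc)
  if (!is.null(surrogates) && ncol(surrogates) > 0) X <- cbind(X, surrogates)
  # drop covariates aliased with preceding columns; sex itself must stay
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- qrX$pivot[(qrX$rank + 1):ncol(X)]
    if (2L %in% aliased)
      stop("sex is confounded with the adjustment covariates")
    warning("dropping aliased covariate column(s): ",
            paste(colnames(X)[aliased], collapse = ", "))
    X <- X[, -aliased, drop = FALSE]
    qrX <- qr(X)
  }
  Y <- t(M)
  n <- nrow(X); p <- ncol(X)
  coefs <- qr.coef(qrX, Y)
  res <- Y - qr.fitted(qrX, Y)
  sigma2 <- colSums(res^2) / (n - p)
  XtXinv <- solve(crossprod(X))
  se <- sqrt(sigma2 * XtXinv[2L, 2L])
  effect <- coefs["sexmale", ]
  tstat <- effect / se
  pval <- 2 * pt(-abs(tstat), df = n - p)
  structure(data.frame(probe_id = rownames(M),
                       p_value = unname(pval),
                       adjusted_p = unname(p.adjust(pval, method = adjust_method)),
                       effect = unname(effect),
                       direction = sign(unname(effect)),
                       stringsAsFactors = FALSE),
            class = c("dmp_result", "data.frame"),
            adjust_method = adjust_method)
}

#' Top-k most significant probes
#'
#' The k smallest p-values; ties broken by larger absolute effect, then
#' probe id, so the set is invariant to input row order.
#'
#' @param results a `dmp_result` table.
#' @param k set size (<= number of probes).
#' @return character vector of k probe ids.
#' @export
top_k_set <- function(results, k = 1000L) {
  if (k > nrow(results)) stop_invalid("k exceeds the number of probes")
  o <- order(results$p_value, -abs(results$effect), results$probe_id)
  results$probe_id[o][seq_len(k)]
}

#' A discovery DMP set from a prior study
#'
#' @param probe_ids unique probe ids.
#' @param direction optional named (or aligned) vector of effect signs.
#' @param source free-text label of the originating study.
#' @return list of class `discovery_set`.
#' @export
discovery_set <- function(probe_ids, direction = NULL, source = "") {
  if (anyDuplicated(probe_ids)) stop_invalid("discovery probe ids must be unique")
  if (!is.null(direction)) {
    if (is.null(names(direction))) names(direction) <- probe_ids
    direction <- sign(direction)
  }
  structure(list(probe_ids = probe_ids, direction = direction,
                 source = source), class = "discovery_set")
}

#' Concordance at the top
#'
#' Cumulative overlap between a p-value-ranked probe list and a discovery
#' set: `curve[r]` is the number of discovery probes among the top r.
#'
#' @param ranked_probe_ids probe ids ordered by increasing p-value
#'   (unique).
#' @param discovery a [discovery_set()].
#' @param max_rank largest rank to report.
#' @return integer vector of length `max_rank`, non-decreasing, bounded
#'   by `min(rank, |discovery|)`.
#' @export
concordance_at_top <- function(ranked_probe_ids, discovery,
                               max_rank = length(ranked_probe_ids)) {
  if (anyDuplicated(ranked_probe_ids)) stop_invalid("ranked ids must be unique")
  max_rank <- min(max_rank, length(ranked_probe_ids))
  cumsum(ranked_probe_ids[seq_len(max_rank)] %in% discovery$probe_ids)
}

#' Replication summary of a discovery DMP set in two tissues
#'
#' Partitions the discovery probes replicated in either tissue into
#' only-tissue-1, only-tissue-2 and both; reports the replication
#' percentage (rounded to an integer, with the exact fraction kept
#' alongside) and, where directions are available, the fraction of
#' replicated probes whose effect direction agrees between the discovery
#' set and every tissue that replicated them.
#'
#' @param set_t1,set_t2 probe-id sets called significant in tissues 1, 2.
#' @param discovery a [discovery_set()] (non-empty).
#' @param effects_t1,effects_t2 optional named effect (or sign) vectors
#'   for direction comparison.
#' @return list of class `replication_summary`: `n_discovery`,
#'   `n_replicated_either`, `n_only_tissue1`, `n_only_tissue2`, `n_both`,
#'   `percent_replicated` (rounded), `fraction_replicated`,
#'   `direction_agreement_fraction` (NA without direction data).
#' @export
replication_summary <- function(set_t1, set_t2, discovery,
                                effects_t1 = NULL, effects_t2 = NULL) {
  if (!length(discovery$probe_ids)) stop_invalid("empty discovery set")
  d <- discovery$probe_ids
  in1 <- d %in% set_t1
  in2 <- d %in% set_t2
  either <- in1 | in2
  n_both <- sum(in1 & in2)
  n_only1 <- sum(in1 & !in2)
  n_only2 <- sum(!in1 & in2)
  frac <- sum(either) / length(d)
  agree <- NA_real_
  if (!is.null(discovery$direction)) {
    rep_ids <- d[either]
    ok <- vapply(rep_ids, function(pid) {
      signs <- c(
        if (pid %in% set_t1 && !is.null(effects_t1)) sign(effects_t1[[pid]]),
        if (pid %in% set_t2 && !is.null(effects_t2)) sign(effects_t2[[pid]]))
      if (!length(signs)) return(NA)
      all(signs == discovery$direction[[pid]])
    }, logical(1))
    if (any(!is.na(ok))) agree <- mean(ok, na.rm = TRUE)
  }
  structure(list(n_discovery = length(d),
                 n_replicated_either = sum(either),
                 n_only_tissue1 = n_only1,
                 n_only_tissue2 = n_only2,
                 n_both = n_both,
                 percent_replicated = round(100 * frac),
                 fraction_replicated = frac,
                 direction_agreement_fraction = agree),
            class = "replication_summary")
}

#' @export
print.replication_summary <- function(x, ...) {
  cat(sprintf("Replication: %d/%d = %d%% of discovery DMPs (tissue1 only %d, tissue2 only %d, both %d)\n",
              x$n_replicated_either, x$n_discovery, x$percent_replicated,
              x$n_only_tissue1, x$n_only_tissue2, x$n_both))
  if (!is.na(x$direction_agreement_fraction))
    cat(sprintf("Direction agreement: %.0f%%\n",
                100 * x$direction_agreement_fraction))
  invisible(x)
}

#' Fraction of probes at or proximal to a CpG island
#'
#' @param probe_ids probe ids (e.g. replicated DMPs).
#' @param annotation probe annotation with `probe_id`, `island_relation`.
#' @param proximal_relations relations counted as proximal; default
#'   island and shore.
#' @return list: `n_proximal`, `n_total`, `fraction`, `percent`
#'   (rounded to integer).
#' @export
island_overlap <- function(probe_ids, annotation,
                           proximal_relations = c("island", "shore")) {
  idx <- match(probe_ids, annotation$probe_id)
  if (anyNA(idx))
    stop_invalid("annotation missing probes: ",
                 paste(head(probe_ids[is.na(idx)]), collapse = ", "))
  prox <- annotation$island_relation[idx] %in% proximal_relations
  list(n_proximal = sum(prox), n_total = length(probe_ids),
       fraction = mean(prox), percent = round(100 * mean(prox)))
}

#' Sex differences in estimated cell fractions
#'
#' Welch two-sample t-test per cell type with BH adjustment across the
#' six tests; the reported difference is male minus female.
#'
#' @param fractions samples-by-6 matrix (columns named by `CELL_TYPES`).
#' @param sex character/factor of "female"/"male" (each >= 2 samples).
#' @param adjust_method p-value adjustment across cell types.
#' @return data frame: `cell_type`, `mean_diff`, `p_value`, `adjusted_p`.
#' @export
cell_fraction_sex_test <- function(fractions, sex, adjust_method = "BH") {
  sex <- factor(sex, levels = c("female", "male"))
  if (any(table(sex) < 2L)) stop_invalid("both sexes need >= 2 samples")
  male <- sex == "male"
  res <- lapply(colnames(fractions), function(ct) {
    x <- fractions[, ct]
    tt <- t.test(x[male], x[!male])
    data.frame(cell_type = ct,
               mean_diff = mean(x[male]) - mean(x[!male]),
               p_value = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adjusted_p <- p.adjust(out$p_value, method = adjust_method)
  out
}
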