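#' The 13 modelling variables and their categories
#'
#' Fixed order used for sequential ANOVA: technical variables first
#' (platform, study), then demographic (age, sex, two ancestry scores),
#' then biological (sample type, six cell fractions). Putting the
#' technical block first lets study ID absorb shared variance before the
#' biological variables are credited, which is conservative when asking
#' how much biology explains.
#'
#' @return `fev_variables()`: character vector of the 13 variable names in
#'   model order. `fev_categories()`: named vector mapping each variable
#'   to "technical", "demographic" or "biological".
#' @export
fev_variables <- function() {
  c("platform", "study_id", "age", "sex", "ancestry_pc1", "ancestry_pc2",
    "sample_type", CELL_TYPES)
}

#' @rdname fev_variables
#' @export
fev_categories <- function() {
  setNames(c("technical", "technical", "demographic", "demographic",
             "demographic", "demographic", "biological",
             rep("biological", 6)), fev_variables())
}

# Build per-variable design blocks from metadata. Numeric variables give a
# single column; categorical variables give one dummy column per level
# (redundancy with the intercept is absorbed by orthogonalization).
# Constant variables are dropped (or raise an error, per on_alias).
fev_design_blocks <- function(metadata, variables, on_alias) {
  blocks <- list()
  dropped <- character(0)
  for (v in variables) {
    x <- metadata[[v]]
    if (is.null(x)) stop_invalid("variable '", v, "' missing from metadata")
    if (is.numeric(x)) {
      if (length(unique(x)) < 2L) {
        if (on_alias == "error") stop("variable '", v, "' is constant")
        dropped <- c(dropped, v)
        blocks[[v]] <- matrix(0, length(x), 0)
      } else blocks[[v]] <- matrix(x, ncol = 1)
    } else {
      f <- factor(x)
      if (nlevels(f) < 2L) {
        if (on_alias == "error") stop("categorical variable '", v,
                                      "' has fewer than 2 levels")
        dropped <- c(dropped, v)
        blocks[[v]] <- matrix(0, length(x), 0)
      } else blocks[[v]] <- model.matrix(~ f - 1)
    }
  }
  if (length(dropped))
    warning("constant variable(s) dropped from the model: ",
            paste(dropped, collapse = ", "))
  blocks
}

# Sequential (type-I) sums of squares for one or many responses sharing a
# design, by incremental orthogonalization of term blocks against the
# basis accumulated so far. Aliased directions contribute no new basis
# vectors, hence zero incremental SS. Y: samples x responses.
sequential_ss <- function(Y, blocks, on_alias = "error", tol = 1e-9) {
  n <- nrow(Y)
  Q <- matrix(1 / sqrt(n), n, 1)                   # intercept
  ss <- matrix(0, length(blocks), ncol(Y),
               dimnames = list(names(blocks), colnames(Y)))
  for (i in seq_along(blocks)) {
    Z <- blocks[[i]]
    if (ncol(Z) == 0L) next
    Z <- Z - Q %*% crossprod(Q, Z)
    Z <- Z - Q %*% crossprod(Q, Z)                 # re-orthogonalize
    nrm <- sqrt(colSums(Z^2))
    scale_ref <- pmax(sqrt(colSums(blocks[[i]]^2)), 1)
    keep <- nrm > tol * scale_ref
    if (!any(keep)) {
      if (on_alias == "error")
        stop("design is singular: term '", names(blocks)[i],
             "' is aliased with preceding terms")
      next
    }
    qz <- qr(Z[, keep, drop = FALSE])
    r <- qz$rank
    if (r == 0L) next
    Qz <- qr.Q(qz)[, seq_len(r), drop = FALSE]
    ss[i, ] <- colSums(crossprod(Qz, Y)^2)
    Q <- cbind(Q, Qz)
  }
  ss
}

#' Fraction of explained variance from sequential ANOVA
#'
#' For a per-sample response, fits the multiple-regression model with the
#' variables in the documented fixed order (technical, demographic,
#' biological by default) and reports each variable's type-I sum of
#' squares as a fraction of the total (centered) sum of squares, plus the
#' residual fraction. Fractions and the residual always sum to 1.
#'
#' @param response numeric vector, one value per sample (e.g. one probe's
#'   M-values, or a principal-component score).
#' @param metadata per-sample data frame holding the variables.
#' @param variables variables in model order; default [fev_variables()]
#'   restricted to columns present in `metadata`.
#' @param categories named category map; default [fev_categories()].
#' @param on_alias `"error"` (default): a term fully aliased with
#'   preceding terms, or a constant variable, raises an error naming it;
#'   `"drop"`: such terms are kept in the table with zero FEV.
#' @return data frame of class `fev_table` with columns `variable`,
#'   `category`, `fev`; the last row is the residual fraction.
#' @export
anova_fev <- function(response, metadata, variables = NULL,
                      categories = fev_categories(),
                      on_alias = c("error", "drop")) {
  on_alias <- match.arg(on_alias)
  if (is.null(variables)) variables <- intersect(fev_variables(), names(metadata))
  Y <- matrix(response, ncol = 1)
  fevs <- fev_matrix(Y, metadata, variables, on_alias)
  fev_table(fevs[, 1], variables, categories)
}

# FEV for many responses at once. Y: samples x responses. Returns a
# (variables + residual) x responses matrix.
fev_matrix <- function(Y, metadata, variables, on_alias = "error") {
  if (nrow(Y) != nrow(metadata)) stop_invalid("response/metadata size mismatch")
  blocks <- fev_design_blocks(metadata, variables, on_alias)
  total_df <- 1 + sum(vapply(blocks, ncol, 1L))
  if (nrow(Y) <= total_df)
    stop_invalid("need more samples (", nrow(Y), ") than model columns (",
                 total_df, ")")
  Yc <- sweep(Y, 2, colMeans(Y))
  ss_total <- colSums(Yc^2)
  if (any(ss_total == 0)) stop("constant response: total variance is zero")
  ss <- sequential_ss(Y, blocks, on_alias = on_alias)
  fev <- sweep(ss, 2, ss_total, "/")
  resid <- pmax(1 - colSums(fev), 0)
  rbind(fev, residual = resid)
}

fev_table <- function(fev_vec, variables, categories) {
  structure(data.frame(
    variable = c(variables, "residual"),
    category = c(unname(categories[variables]), "residual"),
    fev = unname(fev_vec[c(variables, "residual")]),
    stringsAsFactors = FALSE), class = c("fev_table", "data.frame"))
}

#' @export
print.fev_table <- function(x, digits = 4, ...) {
  cat("Fraction of explained variance (sequential ANOVA):\n")
  print.data.frame(transform(x, fev = signif(fev, digits)), row.names = FALSE)
  invisible(x)
}

#' Ratio of non-residual variance fractions
#'
#' Compares an adjusted model's explained (non-residual) variance share
#' with the unadjusted model's: (1 - residual_adj) / (1 - residual_unadj).
#' A value below 1 means the adjustment removed variance that the model
#' used to explain.
#'
#' @param adjusted,unadjusted `fev_table`s for the same response.
#' @return a single ratio; `NA` (flagged with attribute `undefined`) when
#'   the unadjusted model explains nothing.
#' @export
nonresidual_ratio <- function(adjusted, unadjusted) {
  ra <- adjusted$fev[adjusted$variable == "residual"]
  ru <- unadjusted$fev[unadjusted$variable == "residual"]
  if ((1 - ru) <= 0) return(structure(NA_real_, undefined = TRUE))
  (1 - ra) / (1 - ru)
}

#' Study-bias adjustment simulation
#'
#' Repeats the four-step experiment that quantifies what study-identifier
#' adjustment does to explained variance: per repetition, (i) draw
#' `n_probes` probes and `n_studies` studies at random and compute their
#' M-values; (ii) remove study effects uniformly across all sampled
#' studies ("adjustment 1"), and exactly on a random subset of 2-4 of
#' them ("adjustment 2": the analysis restricts to the subset's samples
#' and every subset study is its own batch level); (iii) run sequential
#' ANOVA per probe for the three model variants; (iv) collect FEV per
#' variable. Per-probe FEVs are
#' aggregated by the median within each repetition, and the per-probe
#' non-residual ratio (adjusted over unadjusted) is summarized by its
#' median.
#'
#' @param dataset a `synthetic_dnam_dataset`, or any list with `beta`
#'   (probes x samples) and `metadata`.
#' @param n_probes,n_studies probes and studies sampled per repetition
#'   (without replacement).
#' @param n_reps number of repetitions.
#' @param seed RNG seed for all sampling.
#' @param variables model variables; default [fev_variables()] present in
#'   the metadata.
#' @param metadata optional replacement metadata (e.g. with
#'   deconvolution-estimated rather than true cell fractions).
#' @return object of class `bias_simulation_result`: list with `fev`
#'   (long data frame: rep, model, variable, category, median_fev),
#'   `ratios` (rep, model, nonresidual_ratio), and `sampled` (per-rep
#'   probe and study draws).
#' @export
run_bias_simulation <- function(dataset, n_probes = 500L, n_studies = 5L,
                                n_reps = 20L, seed = 1L, variables = NULL,
                                metadata = NULL) {
  beta <- dataset$beta
  meta <- metadata %||% dataset$metadata
  if (is.null(variables)) variables <- intersect(fev_variables(), names(meta))
  studies <- unique(meta$study_id)
  if (length(studies) < n_studies)
    stop_invalid("dataset has fewer than ", n_studies, " studies")
  if (nrow(beta) < n_probes)
    stop_invalid("dataset has fewer than ", n_probes, " probes")
  categories <- fev_categories()
  with_seed(seed, {
    fev_rows <- list()
    ratio_rows <- list()
    sampled <- vector("list", n_reps)
    for (rep_i in seq_len(n_reps)) {
      repeat {
        st <- sample(studies, n_studies)
        counts <- table(meta$study_id[meta$study_id %in% st])
        if (all(counts >= 2L)) break
        warning("sampled study with < 2 samples; resampling")
      }
      probes <- sample(rownames(beta), n_probes)
      keep <- meta$study_id %in% st
      sub_meta <- meta[keep, , drop = FALSE]
      M <- beta_to_m(beta[probes, keep, drop = FALSE])
      sizes <- seq(2L, min(4L, n_studies))
      subset2 <- sample(st, if (length(sizes) == 1L) sizes else sample(sizes, 1L))
      in2 <- sub_meta$study_id %in% subset2
      meta2 <- sub_meta[in2, , drop = FALSE]
      variants <- list(
        unadjusted = list(
          M = M, meta = sub_meta),
        adjustment1 = list(
          M = remove_study_effects(M, sub_meta,
                                   adjustment_spec(strategy = "all_batches")),
          meta = sub_meta),
        adjustment2 = list(
          M = remove_study_effects(M[, in2, drop = FALSE], meta2,
                                   adjustment_spec(strategy = "all_batches")),
          meta = meta2))
      fevs <- lapply(variants, function(V)
        fev_matrix(t(V$M), V$meta, variables, on_alias = "drop"))
      for (mod in names(fevs)) {
        med <- apply(fevs[[mod]], 1, median)
        fev_rows[[length(fev_rows) + 1L]] <- data.frame(
          rep = rep_i, model = mod, variable = names(med),
          category = c(unname(categories[names(med)[-length(med)]]), "residual"),
          median_fev = unname(med), stringsAsFactors = FALSE)
        if (mod != "unadjusted") {
          r_adj <- 1 - fevs[[mod]]["residual", ]
          r_un <- 1 - fevs$unadjusted["residual", ]
          ratio <- median(ifelse(r_un > 0, r_adj / r_un, NA_real_), na.rm = TRUE)
          ratio_rows[[length(ratio_rows) + 1L]] <- data.frame(
            rep = rep_i, model = mod, nonresidual_ratio = ratio)
        }
      }
      sampled[[rep_i]] <- list(probes = probes, studies = st, subset2 = subset2)
    }
    structure(list(fev = do.call(rbind, fev_rows),
                   ratios = do.call(rbind, ratio_rows),
                   sampled = sampled),
              class = "bias_simulation_result")
  })
}

#' @export
print.bias_simulation_result <- function(x, ...) {
  cat("Study-bias adjustment simulation:", max(x$fev$rep), "repetitions\n")
  med <- stats::aggregate(median_fev ~ model + variable, x$fev, median)
  study <- med[med$variable == "study_id", ]
  cat("median FEV(study_id) by model:\n")
  print(setNames(signif(study$median_fev, 3), study$model))
  cat("median non-residual ratio:\n")
  r <- stats::aggregate(nonresidual_ratio ~ model, x$ratios, median)
  print(setNames(signif(r$nonresidual_ratio, 3), r$model))
  invisible(x)
}

#' Variance decomposition of hashed-profile principal components
#'
#' Centered PCA (via singular value decomposition) of hashed sample
#' profiles, followed by sequential ANOVA of each of the top component
#' scores against the modelling variables; per-component FEV is also
#' aggregated by variable category.
#'
#' @param hashed a [hash_features()] matrix (samples x dim).
#' @param metadata per-sample data frame.
#' @param n_components number of leading components to analyse.
#' @param variables model variables (default: [fev_variables()] present).
#' @return object of class `pca_fev_result`: list with `eigenvalues`
#'   (non-increasing), `percent_var`, `fev` (components x variables +
#'   residual matrix) and `category_fev` (components x categories).
#' @export
pca_fev <- function(hashed, metadata, n_components = 10L, variables = NULL) {
  X <- unclass(hashed)
  if (nrow(X) < n_components)
    stop_invalid("need at least as many samples as components")
  if (is.null(variables)) variables <- intersect(fev_variables(), names(metadata))
  const <- apply(X, 2, function(col) max(col) - min(col) == 0)
  if (any(const)) {
    warning(sum(const), " constant hashed column(s) dropped")
    X <- X[, !const, drop = FALSE]
  }
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = n_components, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  eig <- sv$d^2 / (nrow(X) - 1)
  pct <- 100 * sv$d^2 / sum(sv$d^2)
  fev <- t(fev_matrix(scores, metadata, variables, on_alias = "drop"))
  categories <- c(fev_categories()[variables], residual = "residual")
  cats <- unique(unname(categories))
  category_fev <- sapply(cats, function(cg)
    rowSums(fev[, names(categories)[categories == cg], drop = FALSE]))
  structure(list(eigenvalues = eig[seq_len(n_components)],
                 percent_var = pct[seq_len(n_components)],
                 fev = fev, category_fev = category_fev),
            class = "pca_fev_result")
}

#' @export
print.pca_fev_result <- function(x, ...) {
  cat("PCA variance decomposition (", nrow(x$fev), " components)\n", sep = "")
  print(round(cbind(percent_var = x$percent_var, x$category_fev), 3))
  invisible(x)
}
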