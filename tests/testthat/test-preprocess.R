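test_that("beta_to_m matches the logit2 transform at anchor points", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0.2), -2)
  expect_error(beta_to_m(0.5, epsilon = 0.7), class = "invalid_argument")
})

test_that("beta_to_m and m_to_beta invert each other inside the clamp", {
  b <- seq(0.001, 0.999, length.out = 200)
  expect_equal(m_to_beta(beta_to_m(b, epsilon = 1e-6)), b, tolerance = 1e-12)
  # boundary values are absorbed by clamping, not propagated to +-Inf
  expect_true(all(is.finite(beta_to_m(c(0, 1)))))
})

test_that("sample QC applies the two removal rules with reason codes", {
  qc <- data.frame(sample_id = paste0("s", 1:5),
                   log2_median_M = c(9.8, 9.8, 12.0, 11.5, NA),
                   log2_median_U = c(9.9, 10.5, 12.0, 11.5, 11.0),
                   beadarray_failures = c(0L, 1L, 2L, 1L, 0L))
  dec <- qc_filter_samples(qc)
  expect_equal(dec$keep, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(dec$reason, c("signal", "ok", "beadarray", "ok", "missing_metric"))
})

test_that("QC decisions depend only on the stated metrics", {
  qc <- fix_dataset$qc
  base <- qc_filter_samples(qc)
  shuffled <- qc[, c("beadarray_failures", "sample_id", "log2_median_U",
                     "log2_median_M")]
  expect_equal(qc_filter_samples(shuffled)$keep, base$keep)
})

test_that("granulocyte filter is PBMC-scoped and inclusive at the threshold", {
  keep <- filter_granulocytes(c(0.30, 0.30, 0.25, 0.249),
                              c("pbmc", "whole_blood", "pbmc", "pbmc"))
  expect_equal(keep, c(FALSE, TRUE, FALSE, TRUE))
})

test_that("probe filters respect switches and report unknown chromosomes", {
  ann <- data.frame(probe_id = paste0("p", 1:10),
                    chromosome = c(rep("chr1", 6), "chrX", "chrY", "chr2", "chr3"),
                    cross_reactive = c(rep(TRUE, 3), rep(FALSE, 7)),
                    snp_overlap = c(rep(FALSE, 9), TRUE))
  expect_equal(sum(filter_probes(ann, FALSE, TRUE, FALSE)), 7)
  expect_equal(sum(filter_probes(ann, TRUE, FALSE, FALSE)), 8)
  expect_equal(sum(filter_probes(ann, FALSE, FALSE, FALSE)), 10)
  ann$chromosome[1] <- "chr99"
  expect_error(filter_probes(ann), class = "invalid_argument")
})

test_that("sample-type harmonization maps keywords, first match wins", {
  expect_equal(harmonize_sample_type("peripheral whole blood"), "whole_blood")
  expect_equal(harmonize_sample_type("Umbilical cord blood"), "cord_blood")
  expect_equal(harmonize_sample_type("PBMC"), "pbmc")
  expect_equal(harmonize_sample_type("peripheral blood mononuclear cells"), "pbmc")
  expect_equal(harmonize_sample_type("buffy coat"), "other")
  expect_equal(harmonize_sample_type(c("Whole Blood", "cord blood sample")),
               c("whole_blood", "cord_blood"))
  expect_error(harmonize_sample_type(""), class = "invalid_argument")
})

test_that("deconvolution recovers pure and mixed profiles exactly", {
  disc <- names(fix_ref$discriminating)
  pure <- fix_ref$profiles[disc, "Gran"]
  names(pure) <- disc
  w <- deconvolve_cell_fractions(pure, fix_ref)
  expect_equal(as.vector(w), c(0, 0, 0, 0, 0, 1), tolerance = 1e-8)
  mix <- 0.5 * fix_ref$profiles[, "CD4T"] + 0.5 * fix_ref$profiles[, "Bcell"]
  names(mix) <- fix_ref$probe_ids
  w2 <- deconvolve_cell_fractions(mix, fix_ref)
  expect_equal(as.vector(w2), c(0.5, 0, 0, 0.5, 0, 0), tolerance = 1e-6)
})

test_that("deconvolution agrees with an interior-point oracle on noisy mixtures", {
  set.seed(33)
  disc <- names(fix_ref$discriminating)
  R <- fix_ref$profiles[disc, ]
  w_true <- c(0.3, 0.2, 0.1, 0.15, 0.05, 0.2)
  b <- drop(R %*% w_true) + rnorm(nrow(R), 0, 0.02)
  names(b) <- disc
  mine <- deconvolve_cell_fractions(b, fix_ref)
  obj <- function(w) sum((b - R %*% w)^2)
  oracle <- constrOptim(rep(1 / 12, 6), obj,
                        grad = function(w) drop(-2 * t(R) %*% (b - R %*% w)),
                        ui = rbind(diag(6), rep(-1, 6)), ci = c(rep(0, 6), -1),
                        outer.iterations = 200, outer.eps = 1e-10)
  expect_lte(obj(unclass(mine)), obj(oracle$par) + 1e-8)
  expect_equal(as.vector(mine), oracle$par, tolerance = 1e-3)
})

test_that("deconvolution is invariant to duplicating discriminating probes", {
  set.seed(44)
  disc <- names(fix_ref$discriminating)
  b <- drop(fix_ref$profiles[disc, ] %*% c(0.4, 0.1, 0.1, 0.1, 0.1, 0.2)) +
    rnorm(length(disc), 0, 0.01)
  names(b) <- disc
  w1 <- deconvolve_cell_fractions(b, fix_ref)
  # duplicate every discriminating probe in a doubled panel
  ref2 <- fix_ref
  dup_ids <- paste0(disc, "_dup")
  ref2$probe_ids <- c(fix_ref$probe_ids, dup_ids)
  ref2$profiles <- rbind(fix_ref$profiles,
                         `rownames<-`(fix_ref$profiles[disc, ], dup_ids))
  ref2$discriminating <- setNames(rep(fix_ref$discriminating, 2),
                                  c(disc, dup_ids))
  b2 <- setNames(c(b, b), c(disc, dup_ids))
  w2 <- deconvolve_cell_fractions(b2, ref2)
  expect_equal(as.vector(w1), as.vector(w2), tolerance = 1e-8)
})

test_that("a rank-deficient reference names the collinear columns", {
  ref <- fix_ref
  ref$profiles[, "CD8T"] <- ref$profiles[, "CD4T"]
  expect_error(
    deconvolve_cell_fractions(setNames(ref$profiles[names(ref$discriminating), 1],
                                       names(ref$discriminating)), ref),
    "collinear")
})
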