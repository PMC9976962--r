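test_that("surrogate variables recover a planted hidden batch", {
  set.seed(71)
  n <- 60
  hidden <- rep(c(-1, 1), each = n / 2)[sample(n)]
  known <- data.frame(age = runif(n, 20, 70))
  M <- matrix(rnorm(200 * n, 0, 0.3), 200, n) + outer(rnorm(200, 0, 1), hidden)
  dimnames(M) <- list(sprintf("p%03d", 1:200), sprintf("s%03d", 1:n))
  sv <- surrogate_variables(M, known, k = 2)
  expect_equal(dim(sv), c(n, 2))
  expect_gt(abs(cor(sv[, 1], hidden)), 0.9)
  expect_equal(ncol(surrogate_variables(M, known, k = 0)), 0)
  expect_error(surrogate_variables(M, known, k = n), class = "invalid_argument")
})

test_that("surrogate variables stay small without hidden structure", {
  set.seed(72)
  n <- 60
  known <- data.frame(age = runif(n))
  M <- matrix(rnorm(300 * n), 300, n,
              dimnames = list(sprintf("p%03d", 1:300), sprintf("s%03d", 1:n)))
  sv <- surrogate_variables(M, known, k = 5)
  R <- t(M) - qr.fitted(qr(model.matrix(~ age, known)), t(M))
  tot <- sum(R^2)
  expl <- colSums((t(R) %*% sv)^2 / colSums(sv^2)) / tot
  expect_true(all(expl[-1] < 0.05))
})

test_that("planted sex DMPs rank first and directions agree", {
  ref <- generate_reference_profiles(1000, seed = 81)
  cfg <- generator_config(n_probes = 1000, n_studies = 2, samples_per_study = 200,
                          n_sex_dmps = 10, sex_effect_delta = 0.2,
                          noise_sd = 0.4, seed = 82)
  ds <- generate_dataset(cfg, ref)
  est <- deconvolve_cell_fractions(ds$beta, ref)
  meta <- ds$metadata
  meta[, CELL_TYPES] <- est
  M <- beta_to_m(ds$beta)
  res <- suppressWarnings(call_sex_dmps(M, meta))
  top10 <- top_k_set(res, 10)
  expect_setequal(top10, ds$truth$sex_dmp_ids)
  eff <- setNames(res$effect, res$probe_id)
  expect_true(all(sign(eff[ds$truth$sex_dmp_ids]) ==
                    sign(ds$truth$sex_dmp_delta)))
  expect_true(all(res$adjusted_p >= res$p_value))
  expect_error(call_sex_dmps(M, transform(meta, sex = "female")),
               class = "invalid_argument")
})

test_that("sex p-values are uniform for null probes", {
  set.seed(83)
  n <- 100
  meta <- data.frame(sex = sample(c("female", "male"), n, TRUE),
                     age = runif(n, 20, 70))
  M <- matrix(rnorm(400 * n), 400, n,
              dimnames = list(sprintf("p%03d", 1:400), sprintf("s%03d", 1:n)))
  res <- call_sex_dmps(M, meta, covariates = "age")
  expect_gt(suppressWarnings(stats::ks.test(res$p_value, "punif")$p.value), 0.01)
})

test_that("a cell-composition-mediated sex difference is absorbed by adjustment", {
  set.seed(84)
  n <- 300
  sex <- rep(c("female", "male"), each = n / 2)
  # granulocyte fraction differs by sex; the probe tracks the fraction only
  gran <- rnorm(n, 0.5, 0.05) + ifelse(sex == "male", -0.05, 0.05)
  M <- matrix(0, 2, n, dimnames = list(c("p1", "p2"), sprintf("s%03d", 1:n)))
  M[1, ] <- 3 * gran + rnorm(n, 0, 0.3)
  M[2, ] <- rnorm(n, 0, 0.3)
  meta <- data.frame(sex = sex, Gran = gran)
  unadj <- call_sex_dmps(M, meta, covariates = character(0))
  adj <- call_sex_dmps(M, meta, covariates = "Gran")
  expect_lt(unadj$p_value[1], 1e-6)
  expect_gt(adj$p_value[1], 0.01)
})

test_that("top-k tie-breaks match an exhaustive sort oracle", {
  res <- data.frame(probe_id = c("p5", "p1", "p3", "p2", "p4"),
                    p_value = c(0.01, 0.02, 0.02, 0.02, 0.5),
                    adjusted_p = 1, effect = c(1, 0.5, 2, 0.5, 3),
                    direction = 1)
  # rank: p5 (smallest p), then among the 0.02 tie: p3 (|effect| 2),
  # then p1 vs p2 (equal effect) by probe id
  expect_equal(top_k_set(res, 3), c("p5", "p3", "p1"))
  expect_equal(top_k_set(res, 5), c("p5", "p3", "p1", "p2", "p4"))
  expect_equal(top_k_set(res[sample(5), ], 3), c("p5", "p3", "p1"))
  expect_error(top_k_set(res, 6), class = "invalid_argument")
})

test_that("concordance curves follow identity, zero and hypergeometric baselines", {
  ranked <- sprintf("p%04d", 1:1000)
  d_top <- discovery_set(ranked[1:50])
  expect_equal(concordance_at_top(ranked, d_top, 50), 1:50)
  d_none <- discovery_set(sprintf("q%04d", 1:50))
  expect_equal(concordance_at_top(ranked, d_none, 100), rep(0L, 100))
  set.seed(85)
  draws <- vapply(1:200, function(i)
    concordance_at_top(sample(ranked), discovery_set(sample(ranked, 50)),
                       100)[100], numeric(1))
  se <- sd(draws) / sqrt(200)
  expect_lt(abs(mean(draws) - 5), 2 * se + 0.3)
  curve <- concordance_at_top(sample(ranked), d_top, 400)
  expect_true(all(diff(curve) >= 0))
  expect_true(all(curve <= pmin(seq_along(curve), 50)))
})

test_that("replication summary reproduces the printed worked example", {
  d <- discovery_set(sprintf("d%03d", 1:292))
  only1 <- d$probe_ids[1:42]
  both <- d$probe_ids[43:95]
  only2 <- d$probe_ids[96:112]
  set1 <- c(only1, both, sprintf("extra%02d", 1:7))
  set2 <- c(only2, both, sprintf("extra%02d", 8:9))
  rs <- replication_summary(set1, set2, d)
  expect_equal(rs$n_only_tissue1, 42)
  expect_equal(rs$n_only_tissue2, 17)
  expect_equal(rs$n_both, 53)
  expect_equal(rs$n_replicated_either, 112)
  expect_equal(rs$percent_replicated, 38)
  d2 <- discovery_set(sprintf("e%03d", 1:544))
  rs2 <- replication_summary(d2$probe_ids[1:250], character(0), d2)
  expect_equal(rs2$percent_replicated, 46)
  expect_error(replication_summary(set1, set2, discovery_set(character(0))),
               class = "invalid_argument")
})

test_that("replication partition identity holds on random sets", {
  set.seed(86)
  universe <- sprintf("u%04d", 1:500)
  for (i in 1:25) {
    d <- discovery_set(sample(universe, sample(10:100, 1)))
    s1 <- sample(universe, sample(0:200, 1))
    s2 <- sample(universe, sample(0:200, 1))
    rs <- replication_summary(s1, s2, d)
    expect_equal(rs$n_only_tissue1 + rs$n_only_tissue2 + rs$n_both,
                 rs$n_replicated_either)
    expect_lte(rs$n_replicated_either, rs$n_discovery)
  }
})

test_that("direction agreement is 1 for consistently signed replications", {
  d <- discovery_set(c("a", "b", "c"), direction = c(a = 1, b = -1, c = 1))
  eff1 <- c(a = 0.5, b = -0.2)
  eff2 <- c(b = -0.4, c = 0.9)
  rs <- replication_summary(c("a", "b"), c("b", "c"), d, eff1, eff2)
  expect_equal(rs$direction_agreement_fraction, 1)
  rs2 <- replication_summary(c("a", "b"), c("b", "c"), d,
                             c(a = -0.5, b = -0.2), eff2)
  expect_equal(rs2$direction_agreement_fraction, 2 / 3)
})

test_that("island overlap reproduces the printed fraction", {
  ann <- data.frame(probe_id = sprintf("p%03d", 1:112),
                    island_relation = c(rep("island", 60), rep("shore", 24),
                                        rep("open_sea", 28)))
  io <- island_overlap(ann$probe_id, ann)
  expect_equal(io$n_proximal, 84)
  expect_equal(io$percent, 75)
  io0 <- island_overlap(ann$probe_id[85:112], ann)
  expect_equal(io0$percent, 0)
  io1 <- island_overlap(ann$probe_id[1:60], ann)
  expect_equal(io1$percent, 100)
  expect_error(island_overlap("zzz", ann), class = "invalid_argument")
})

test_that("cell-fraction sex test detects a planted granulocyte excess", {
  set.seed(87)
  n <- 500
  sex <- rep(c("female", "male"), each = n)
  fr <- matrix(rnorm(2 * n * 6, 0.15, 0.02), 2 * n, 6,
               dimnames = list(NULL, CELL_TYPES))
  fr[sex == "female", "Gran"] <- fr[sex == "female", "Gran"] + 0.03
  res <- cell_fraction_sex_test(fr, sex)
  gran <- res[res$cell_type == "Gran", ]
  expect_lt(gran$adjusted_p, 1e-3)
  expect_lt(gran$mean_diff, 0)
  expect_true(all(res$adjusted_p >= res$p_value))
  same <- cell_fraction_sex_test(matrix(0.2, 20, 6,
                                        dimnames = list(NULL, CELL_TYPES)) +
                                   rnorm(120, 0, 1e-3),
                                 rep(c("female", "male"), 10))
  expect_true(all(abs(same$mean_diff) < 0.01))
})
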