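test_that("sequential FEV matches the stats::anova oracle", {
  y <- beta_to_m(fix_dataset$beta[101, ])
  vars <- intersect(fev_variables(), names(fix_est_meta))
  ft <- anova_fev(y, fix_est_meta)
  df <- data.frame(y = y, fix_est_meta[vars])
  fit <- lm(stats::reformulate(vars, "y"), data = df)
  a <- anova(fit)
  ss <- setNames(a[["Sum Sq"]], rownames(a))
  oracle <- unname(c(ss[vars], ss["Residuals"]) / sum(ss))
  expect_equal(ft$fev, oracle, tolerance = 1e-10)
})

test_that("a perfectly explanatory binary variable takes FEV 1", {
  set.seed(51)
  meta <- random_metadata(40, include = c("sex", "age"))
  y <- as.numeric(meta$sex == "male")
  ft <- anova_fev(y, meta, variables = c("sex", "age"),
                  categories = c(sex = "demographic", age = "demographic"))
  expect_equal(ft$fev[ft$variable == "sex"], 1, tolerance = 1e-12)
  expect_equal(ft$fev[ft$variable == "residual"], 0, tolerance = 1e-12)
})

test_that("balanced orthogonal 2x2 design splits FEV equally and order-invariantly", {
  x1 <- rep(c(0, 1), each = 10)
  x2 <- rep(c(0, 1), times = 10)
  meta <- data.frame(x1 = x1, x2 = x2)
  y <- x1 + x2
  cats <- c(x1 = "technical", x2 = "technical")
  f12 <- anova_fev(y, meta, variables = c("x1", "x2"), categories = cats)
  f21 <- anova_fev(y, meta, variables = c("x2", "x1"), categories = cats)
  expect_equal(f12$fev[f12$variable == "x1"], 0.5, tolerance = 1e-12)
  expect_equal(f12$fev[f12$variable == "x2"], 0.5, tolerance = 1e-12)
  expect_equal(f21$fev[match(c("x1", "x2"), f21$variable)],
               f12$fev[match(c("x1", "x2"), f12$variable)], tolerance = 1e-12)
})

test_that("pure-noise responses leave most variance residual", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(1000 + s)
    meta <- random_metadata(200, include = c("study_id", "sex", "age"))
    y <- rnorm(200)
    ft <- anova_fev(y, meta, variables = c("study_id", "sex", "age"),
                    categories = c(study_id = "technical", sex = "demographic",
                                   age = "demographic"))
    if (ft$fev[ft$variable == "residual"] > 0.9) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("fully aliased terms error by default and drop on request", {
  meta <- data.frame(a = rep(c("u", "v"), each = 10),
                     b = rep(c("u", "v"), each = 10))
  y <- rnorm(20)
  cats <- c(a = "technical", b = "technical")
  expect_error(anova_fev(y, meta, variables = c("a", "b"), categories = cats),
               "aliased")
  ft <- anova_fev(y, meta, variables = c("a", "b"), categories = cats,
                  on_alias = "drop")
  expect_equal(ft$fev[ft$variable == "b"], 0)
  expect_equal(sum(ft$fev), 1, tolerance = 1e-12)
})

test_that("nonresidual ratio follows its closed form", {
  tab <- function(res) {
    structure(data.frame(variable = c("x", "residual"),
                         category = c("technical", "residual"),
                         fev = c(1 - res, res)),
              class = c("fev_table", "data.frame"))
  }
  expect_equal(nonresidual_ratio(tab(0.5), tab(0.5)), 1.0)
  expect_equal(nonresidual_ratio(tab(0.8), tab(0.5)), 0.4)
  und <- nonresidual_ratio(tab(0.3), tab(1.0))
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))
})

test_that("bias simulation is deterministic and directionally correct", {
  ds <- list(beta = fix_dataset$beta, metadata = fix_est_meta)
  sim1 <- suppressWarnings(run_bias_simulation(ds, n_probes = 80,
                                               n_studies = 3, n_reps = 4,
                                               seed = 77))
  sim2 <- suppressWarnings(run_bias_simulation(ds, n_probes = 80,
                                               n_studies = 3, n_reps = 4,
                                               seed = 77))
  expect_identical(sim1$sampled, sim2$sampled)
  expect_identical(sim1$fev, sim2$fev)
  study <- subset(sim1$fev, variable == "study_id")
  med <- tapply(study$median_fev, study$model, median)
  expect_gt(med["unadjusted"], med["adjustment1"])
  expect_gt(med["unadjusted"], med["adjustment2"])
  expect_true(all(sim1$ratios$nonresidual_ratio < 1))
})

test_that("bias simulation under pure noise keeps nonresidual FEV small", {
  set.seed(88)
  n <- 120
  beta <- matrix(runif(150 * n, 0.3, 0.7), 150, n,
                 dimnames = list(sprintf("p%03d", 1:150), sprintf("s%03d", 1:n)))
  meta <- data.frame(sample_id = colnames(beta),
                     study_id = sample(sprintf("st%d", 1:4), n, TRUE),
                     sex = sample(c("female", "male"), n, TRUE),
                     age = runif(n, 20, 70))
  sim <- suppressWarnings(
    run_bias_simulation(list(beta = beta, metadata = meta),
                        n_probes = 60, n_studies = 3, n_reps = 4, seed = 9,
                        variables = c("study_id", "sex", "age")))
  nonres <- subset(sim$fev, variable != "residual")
  expect_lt(median(nonres$median_fev), 0.1)
})

test_that("hashed-profile PCA attributes planted structure to its variable", {
  set.seed(99)
  n <- 80
  ids <- sprintf("cg%04d", 1:500)
  anc <- rnorm(n)
  # probes load on ancestry; plus iid noise
  load <- rnorm(500, 0, 0.5)
  beta <- 0.5 + outer(load, anc) * 0.1 + matrix(rnorm(500 * n, 0, 0.01), 500, n)
  beta <- pmin(pmax(beta, 0.01), 0.99)
  dimnames(beta) <- list(ids, sprintf("s%03d", 1:n))
  meta <- data.frame(sample_id = colnames(beta), ancestry_pc1 = anc,
                     sex = sample(c("female", "male"), n, TRUE))
  h <- hash_features(beta, dim = 100, hash_seed = 1)
  # an empty hash bucket yields a constant column, dropped with a warning
  expect_warning(pf <- pca_fev(h, meta, n_components = 5,
                               variables = c("ancestry_pc1", "sex")),
                 "constant")
  expect_gt(pf$fev["PC1", "ancestry_pc1"], 0.9)
  expect_true(all(diff(pf$eigenvalues) <= 1e-9))
  expect_equal(unname(rowSums(pf$fev)), rep(1, 5), tolerance = 1e-9)
})
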