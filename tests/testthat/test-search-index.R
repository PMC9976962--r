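make_cluster_profiles <- function(n = 90, d = 20, k = 3, sep = 20, seed = 61) {
  set.seed(seed)
  centers <- matrix(rnorm(k * d, 0, 1), k, d) * sep
  cl <- rep(seq_len(k), length.out = n)
  X <- centers[cl, ] + matrix(rnorm(n * d), n, d)
  rownames(X) <- sprintf("s%03d", seq_len(n))
  list(X = as_hashed(X), cluster = cl)
}

test_that("every indexed sample is its own nearest neighbour", {
  cp <- make_cluster_profiles(n = 40)
  idx <- build_index(cp$X, seed = 3)
  res <- query_neighbors(idx, cp$X, k = 1)
  expect_true(all(vapply(seq_along(res), function(i)
    res[[i]]$sample_ids[1] == rownames(cp$X)[i], TRUE)))
  expect_true(all(vapply(res, function(r) r$distances[1] < 1e-5, TRUE)))
})

test_that("brute force matches an independent quadratic scan", {
  set.seed(64)
  X <- matrix(rnorm(50 * 8), 50, 8, dimnames = list(sprintf("s%02d", 1:50), NULL))
  hp <- as_hashed(X)
  q <- rnorm(8)
  mine <- brute_force_knn(q, hp, k = 5)
  d <- apply(X, 1, function(r) sqrt(sum((r - q)^2)))
  o <- order(d, rownames(X))[1:5]
  expect_identical(mine$sample_ids, rownames(X)[o])
  expect_equal(mine$distances, unname(d[o]))
  expect_true(all(diff(mine$distances) >= 0))
  expect_error(brute_force_knn(q, hp, k = 0), class = "invalid_argument")
  expect_error(brute_force_knn(q, hp, k = 51), class = "invalid_argument")
  full <- brute_force_knn(q, hp, k = 50)
  expect_equal(length(full$sample_ids), 50)
})

test_that("approximate search achieves high recall against the oracle", {
  set.seed(65)
  X <- matrix(rnorm(500 * 30), 500, 30,
              dimnames = list(sprintf("s%03d", 1:500), NULL))
  hp <- as_hashed(X)
  idx <- build_index(hp, seed = 6)
  res <- query_neighbors(idx, hp, k = 10)
  recall <- mean(vapply(seq_len(500), function(i) {
    truth <- brute_force_knn(X[i, ], hp, 10)$sample_ids
    length(intersect(res[[i]]$sample_ids, truth)) / 10
  }, numeric(1)))
  expect_gte(recall, 0.9)
})

test_that("planted clusters dominate their queries' neighbour lists", {
  cp <- make_cluster_profiles(n = 90, sep = 25)
  idx <- build_index(cp$X, seed = 8)
  res <- query_neighbors(idx, cp$X, k = 20)
  purity <- vapply(seq_along(res), function(i) {
    nb <- match(res[[i]]$sample_ids, rownames(cp$X))
    mean(cp$cluster[nb] == cp$cluster[i])
  }, numeric(1))
  expect_gte(mean(purity), 0.95)
})

test_that("index construction is deterministic under a fixed seed", {
  cp <- make_cluster_profiles(n = 60)
  i1 <- build_index(cp$X, seed = 11)
  i2 <- build_index(cp$X, seed = 11)
  r1 <- query_neighbors(i1, cp$X, k = 5)
  r2 <- query_neighbors(i2, cp$X, k = 5)
  expect_identical(r1, r2)
})

test_that("hashing-parameter mismatch and oversized k are errors", {
  cp <- make_cluster_profiles(n = 30)
  idx <- build_index(cp$X, seed = 2)
  wrong <- as_hashed(unclass(cp$X), hash_seed = 99L)
  expect_error(query_neighbors(idx, wrong, k = 3), "parameters")
  expect_error(query_neighbors(idx, cp$X, k = 31), class = "invalid_argument")
  bad <- unclass(cp$X)
  bad[2, 1] <- NA
  expect_error(build_index(as_hashed(bad)), class = "invalid_argument")
})

test_that("serialization round-trips to identical query results", {
  cp <- make_cluster_profiles(n = 40)
  idx <- build_index(cp$X, seed = 4)
  path <- tempfile(fileext = ".rds")
  save_index(idx, path)
  idx2 <- load_index(path)
  expect_identical(query_neighbors(idx, cp$X, k = 7),
                   query_neighbors(idx2, cp$X, k = 7))
  unlink(path)
})

test_that("exact fallback and cosine metric behave consistently", {
  cp <- make_cluster_profiles(n = 40)
  idx <- build_index(cp$X, seed = 5)
  approx <- query_neighbors(idx, cp$X, k = 5)
  exact <- query_neighbors(idx, cp$X, k = 5, exact = TRUE)
  agree <- mean(vapply(seq_along(approx), function(i)
    length(intersect(approx[[i]]$sample_ids, exact[[i]]$sample_ids)) / 5,
    numeric(1)))
  expect_gte(agree, 0.9)
  idxc <- build_index(cp$X, metric = "cosine", seed = 5)
  resc <- query_neighbors(idxc, cp$X, k = 3)
  expect_true(all(vapply(resc, function(r) all(r$distances >= -1e-12), TRUE)))
})

test_that("neighbour label frequencies count proportions correctly", {
  meta <- data.frame(sample_id = c("a", "b", "c", "d"),
                     sample_type = c("whole_blood", "whole_blood", "pbmc", "other"))
  r <- structure(list(sample_ids = c("a", "b", "c", "d"),
                      distances = c(0, 1, 2, 3), k = 4), class = "query_result")
  freq <- label_frequency(list(r), meta)
  expect_equal(unname(freq[1, "whole_blood"]), 0.5)
  expect_equal(unname(freq[1, "pbmc"]), 0.25)
  expect_equal(unname(freq[1, "other"]), 0.25)
  expect_equal(sum(freq), 1)
  # unknown neighbour falls into "other"
  r2 <- structure(list(sample_ids = c("a", "zz"), distances = c(0, 1), k = 2),
                  class = "query_result")
  freq2 <- label_frequency(list(r2), meta)
  expect_equal(unname(freq2[1, "other"]), 0.5)
})
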