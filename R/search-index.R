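# Internal distance helpers. Work on squared euclidean distances; for the
# cosine metric rows are pre-normalized to unit length, so squared
# euclidean distance is 2 * cosine distance (monotone equivalent).
row_dist2 <- function(X, row_norm2, ids, q, qn2) {
  pmax(row_norm2[ids] - 2 * drop(X[ids, , drop = FALSE] %*% q) + qn2, 0)
}

report_dist <- function(d2, metric) {
  if (metric == "cosine") d2 / 2 else sqrt(d2)
}

#' Build an approximate nearest-neighbour index over hashed profiles
#'
#' Constructs a hierarchical navigable small-world (HNSW) graph over the
#' rows of a hashed-profile matrix: each sample is assigned a random top
#' layer (geometric, rate 1/log(M)), inserted by greedy beam search from
#' the current entry point, and linked to its closest `M` neighbours per
#' layer (2M on the ground layer). Queries descend the layers greedily
#' and run a beam search of width `ef_search` on the ground layer.
#'
#' @param hashed a [hash_features()] matrix (samples x dim); rows are the
#'   indexed samples. Non-finite values are an error.
#' @param metric `"euclidean"` or `"cosine"` (rows unit-normalized;
#'   reported distance is 1 - cosine similarity).
#' @param M neighbours per node on upper layers (ground layer keeps 2M).
#' @param ef_construction beam width during construction.
#' @param ef_search default beam width during queries.
#' @param seed RNG seed for the layer draws; fixed seed + params give an
#'   identical graph.
#' @return object of class `knn_index`.
#' @export
build_index <- function(hashed, metric = c("euclidean", "cosine"),
                        M = 16L, ef_construction = 200L, ef_search = 300L,
                        seed = 1L) {
  metric <- match.arg(metric)
  X <- unclass(hashed)
  if (nrow(X) < 2L) stop_invalid("need at least 2 samples to index")
  bad <- which(!apply(X, 1, function(r) all(is.finite(r))))
  if (length(bad))
    stop_invalid("non-finite values in samples: ",
                 paste(rownames(X)[bad], collapse = ", "))
  sample_ids <- rownames(X) %||% sprintf("row%d", seq_len(nrow(X)))
  if (metric == "cosine") {
    nrm <- sqrt(rowSums(X^2))
    if (any(nrm == 0)) stop_invalid("zero-norm rows cannot use the cosine metric")
    X <- X / nrm
  }
  n <- nrow(X)
  row_norm2 <- rowSums(X^2)
  mL <- 1 / log(M)
  levels <- with_seed(seed, pmin(floor(-log(runif(n)) * mL), 12L))
  adj <- vector("list", n)          # adj[[i]][[lev + 1]] = integer neighbours
  for (i in seq_len(n)) adj[[i]] <- rep(list(integer(0)), levels[i] + 1L)
  entry <- 1L
  max_level <- levels[1L]
  for (i in seq(2L, n)) {
    q <- X[i, ]
    qn2 <- row_norm2[i]
    ep <- entry
    lev <- max_level
    while (lev > levels[i]) {
      ep <- hnsw_search_layer(X, row_norm2, adj, q, qn2, ep, 1L, lev)$ids[1L]
      lev <- lev - 1L
    }
    while (lev >= 0L) {
      res <- hnsw_search_layer(X, row_norm2, adj, q, qn2, ep,
                               ef_construction, lev)
      m_max <- if (lev == 0L) 2L * M else M
      nbrs <- res$ids[seq_len(min(M, length(res$ids)))]
      adj[[i]][[lev + 1L]] <- nbrs
      for (j in nbrs) {
        lst <- c(adj[[j]][[lev + 1L]], i)
        if (length(lst) > m_max) {
          d2 <- row_dist2(X, row_norm2, lst, X[j, ], row_norm2[j])
          lst <- lst[order(d2)[seq_len(m_max)]]
        }
        adj[[j]][[lev + 1L]] <- lst
      }
      ep <- res$ids[1L]
      lev <- lev - 1L
    }
    if (levels[i] > max_level) {
      max_level <- levels[i]
      entry <- i
    }
  }
  structure(list(X = X, row_norm2 = row_norm2, adj = adj, levels = levels,
                 entry = entry, max_level = max_level, metric = metric,
                 M = as.integer(M), ef_construction = as.integer(ef_construction),
                 ef_search = as.integer(ef_search), seed = as.integer(seed),
                 sample_ids = sample_ids, hash_params = hash_params(hashed)),
            class = "knn_index")
}

# Beam search on one layer; returns up to ef node indices ordered by
# ascending distance to q.
hnsw_search_layer <- function(X, row_norm2, adj, q, qn2, eps, ef, lev) {
  visited <- rep(FALSE, nrow(X))
  visited[eps] <- TRUE
  d0 <- row_dist2(X, row_norm2, eps, q, qn2)
  cand_ids <- eps; cand_d <- d0
  res_ids <- eps; res_d <- d0
  while (length(cand_ids)) {
    j <- which.min(cand_d)
    c_id <- cand_ids[j]; c_d <- cand_d[j]
    cand_ids <- cand_ids[-j]; cand_d <- cand_d[-j]
    if (length(res_ids) >= ef && c_d > max(res_d)) break
    nbr_list <- adj[[c_id]]
    nbrs <- if (length(nbr_list) > lev) nbr_list[[lev + 1L]] else integer(0)
    nbrs <- nbrs[!visited[nbrs]]
    if (!length(nbrs)) next
    visited[nbrs] <- TRUE
    nd <- row_dist2(X, row_norm2, nbrs, q, qn2)
    res_ids <- c(res_ids, nbrs); res_d <- c(res_d, nd)
    if (length(res_ids) > ef) {
      o <- order(res_d)[seq_len(ef)]
      res_ids <- res_ids[o]; res_d <- res_d[o]
    }
    keep <- nd <= max(res_d)
    cand_ids <- c(cand_ids, nbrs[keep]); cand_d <- c(cand_d, nd[keep])
  }
  o <- order(res_d)
  list(ids = res_ids[o], d2 = res_d[o])
}

#' @export
print.knn_index <- function(x, ...) {
  cat("HNSW index:", nrow(x$X), "samples,", ncol(x$X), "dims, metric =",
      x$metric, ", M =", x$M, ", ef =", x$ef_search, "\n")
  invisible(x)
}

query_result <- function(ids, distances, k) {
  structure(list(sample_ids = unname(ids), distances = unname(distances),
                 k = k), class = "query_result")
}

#' Exact k-nearest-neighbour search (brute force oracle)
#'
#' Scans every indexed profile and returns the exact `k` smallest
#' distances. Ties are broken by lexicographic sample id, making the
#' result fully deterministic.
#'
#' @param query_vector numeric vector (same dimension as the profiles).
#' @param hashed samples-by-dim matrix of reference profiles.
#' @param k number of neighbours (1 <= k <= number of samples).
#' @param metric `"euclidean"` or `"cosine"`.
#' @return a `query_result`: ordered `sample_ids`, non-decreasing
#'   `distances`, and `k`.
#' @export
brute_force_knn <- function(query_vector, hashed, k,
                            metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  X <- unclass(hashed)
  if (k <= 0) stop_invalid("k must be positive")
  if (k > nrow(X)) stop_invalid("k exceeds the number of samples")
  ids <- rownames(X) %||% sprintf("row%d", seq_len(nrow(X)))
  q <- as.numeric(query_vector)
  if (metric == "cosine") {
    nrm <- sqrt(rowSums(X^2))
    X <- X / nrm
    q <- q / sqrt(sum(q^2))
  }
  d2 <- pmax(rowSums(X^2) - 2 * drop(X %*% q) + sum(q^2), 0)
  o <- order(d2, ids)[seq_len(k)]
  query_result(ids[o], report_dist(d2[o], metric), k)
}

#' Query the approximate index
#'
#' Runs the HNSW beam search for each query profile. Queries must have
#' been hashed with exactly the same parameters as the indexed profiles
#' (dimension, hash seed, signedness, checked via stored attributes);
#' a mismatch is an error, not a warning.
#'
#' @param index a [build_index()] object.
#' @param queries a [hash_features()] matrix of query profiles.
#' @param k neighbours per query; must not exceed the index size.
#' @param ef beam width (default: the index's `ef_search`, floored at k).
#' @param exact if TRUE, bypass the graph and use the exact scan.
#' @return list of `query_result`, one per query row.
#' @export
query_neighbors <- function(index, queries, k = 1000L, ef = NULL, exact = FALSE) {
  if (!inherits(index, "knn_index")) stop_invalid("index must be a knn_index")
  qp <- hash_params(queries)
  if (!identical(qp, index$hash_params))
    stop("hashing parameters of queries do not match the index (",
         "index: dim=", index$hash_params$dim, " seed=", index$hash_params$hash_seed,
         " signed=", index$hash_params$signed,
         "; queries: dim=", qp$dim, " seed=", qp$hash_seed,
         " signed=", qp$signed, ")")
  n <- nrow(index$X)
  if (k > n) stop_invalid("k (", k, ") exceeds index size (", n, ")")
  Q <- unclass(queries)
  if (exact) {
    Xr <- index$X
    rownames(Xr) <- index$sample_ids
    return(lapply(seq_len(nrow(Q)), function(i)
      brute_force_knn(Q[i, ], Xr, k, metric = index$metric)))
  }
  ef <- max(ef %||% index$ef_search, k)
  lapply(seq_len(nrow(Q)), function(i) {
    q <- Q[i, ]
    if (index$metric == "cosine") q <- q / sqrt(sum(q^2))
    qn2 <- sum(q^2)
    ep <- index$entry
    lev <- index$max_level
    while (lev > 0L) {
      ep <- hnsw_search_layer(index$X, index$row_norm2, index$adj, q, qn2,
                              ep, 1L, lev)$ids[1L]
      lev <- lev - 1L
    }
    res <- hnsw_search_layer(index$X, index$row_norm2, index$adj, q, qn2,
                             ep, ef, 0L)
    take <- seq_len(min(k, length(res$ids)))
    ids <- index$sample_ids[res$ids[take]]
    d <- report_dist(res$d2[take], index$metric)
    o <- order(d, ids)
    query_result(ids[o], d[o], k)
  })
}

#' Neighbour label frequencies per query
#'
#' For each query result, the proportion of returned neighbours carrying
#' each value of a metadata label (e.g. sample type). Neighbours missing
#' from the metadata, or with a missing label, are counted under
#' `"other"`. Proportions sum to 1 per query.
#'
#' @param results list of `query_result` (from [query_neighbors()]).
#' @param metadata per-sample data frame with a `sample_id` column.
#' @param label_field metadata column to tabulate.
#' @return queries-by-labels matrix of proportions.
#' @export
label_frequency <- function(results, metadata, label_field = "sample_type") {
  if (inherits(results, "query_result")) results <- list(results)
  labels <- setNames(as.character(metadata[[label_field]]), metadata$sample_id)
  all_levels <- sort(unique(c(labels, "other")))
  out <- matrix(0, length(results), length(all_levels),
                dimnames = list(NULL, all_levels))
  for (i in seq_along(results)) {
    lab <- labels[results[[i]]$sample_ids]
    lab[is.na(lab)] <- "other"
    tab <- table(factor(lab, levels = all_levels))
    out[i, ] <- as.numeric(tab) / length(results[[i]]$sample_ids)
  }
  out
}

#' Persist / restore a search index
#'
#' The index (graph, profiles, metric and hashing attributes) round-trips
#' through a single RDS file; restored indexes answer queries
#' identically.
#'
#' @param index a `knn_index`.
#' @param path file path.
#' @export
save_index <- function(index, path) {
  saveRDS(index, path)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  idx <- readRDS(path)
  if (!inherits(idx, "knn_index")) stop_invalid("file does not contain a knn_index")
  idx
}
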