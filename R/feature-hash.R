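#' Feature-hash probe-level Beta profiles to a fixed low dimension
#'
#' The hashing trick: each probe id is hashed (MurmurHash3, 32-bit) to one
#' of `dim` buckets, optionally with a pseudo-random sign from an
#' independent hash bit, and each sample's bucket value is the signed sum
#' of its Beta-values over the probes landing in that bucket. Signed
#' hashing makes hashed inner products unbiased estimates of the original
#' inner products; the map is linear in the per-sample profile and fully
#' deterministic given (probe ids, dim, hash_seed, signed).
#'
#' @param beta probes-by-samples matrix with unique probe-id rownames.
#' @param dim target dimension (>= 2; default 1000). A warning is issued
#'   when `dim` exceeds the probe count.
#' @param hash_seed integer seed of the hash family (not an RNG seed).
#' @param signed use the signed variant (default TRUE).
#' @return samples-by-`dim` matrix of class `hashed_profiles` with the
#'   hashing parameters stored as attributes (`dim`, `hash_seed`,
#'   `signed`), so downstream consumers can verify compatibility.
#' @export
hash_features <- function(beta, dim = 1000L, hash_seed = 0L, signed = TRUE) {
  if (dim < 2) stop_invalid("dim must be >= 2")
  probe_ids <- rownames(beta)
  if (is.null(probe_ids)) stop_invalid("beta must have probe-id rownames")
  if (anyDuplicated(probe_ids)) stop_invalid("duplicate probe ids")
  if (dim > nrow(beta))
    warning("target dim (", dim, ") exceeds probe count (", nrow(beta), ")")
  dim <- as.integer(dim)
  bucket <- murmur3_hash(probe_ids, as.integer(hash_seed)) %% dim  # 0-based
  sgn <- if (signed) {
    1 - 2 * (murmur3_hash(probe_ids, as.integer(hash_seed) + 1L) %% 2)
  } else {
    rep(1, nrow(beta))
  }
  signed_beta <- beta * sgn
  agg <- rowsum(signed_beta, group = bucket)        # occupied buckets x samples
  out <- matrix(0, ncol(beta), dim,
                dimnames = list(colnames(beta), paste0("h", seq_len(dim))))
  out[, as.integer(rownames(agg)) + 1L] <- t(agg)
  structure(out, class = c("hashed_profiles", "matrix", "array"),
            dim_target = dim, hash_seed = as.integer(hash_seed),
            signed = signed)
}

hash_params <- function(h) {
  list(dim = attr(h, "dim_target"), hash_seed = attr(h, "hash_seed"),
       signed = attr(h, "signed"))
}

#' @export
print.hashed_profiles <- function(x, ...) {
  p <- hash_params(x)
  cat("Hashed profiles:", nrow(x), "samples x", p$dim, "buckets (seed",
      p$hash_seed, if (p$signed) "signed" else "unsigned", ")\n")
  invisible(x)
}
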