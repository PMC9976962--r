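#' @useDynLib methcompile, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats anova coef lm model.matrix p.adjust pt qbeta rbeta rbinom
#'   rnorm runif sd setNames t.test var prcomp quantile rgamma median
#' @importFrom utils read.delim write.table head modifyList
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` runs code on the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stage label, deterministically
# and below 2^31 (R integers are 32-bit).
derive_seed <- function(seed, label) {
  h <- murmur3_hash(paste0("seed:", label), as.integer(seed %% 2147483647))
  as.integer(abs(h) %% 2147483587L) + 1L
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# Dirichlet draws: n x length(alpha) matrix of compositions.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n), rate = 1), nrow = n)
  g / rowSums(g)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_invalid <- function(...) {
  stop(structure(class = c("invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
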