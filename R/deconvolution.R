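# Exact solver for the small constrained least-squares problem
#   min ||b - R w||^2  s.t.  w >= 0,  sum(w) <= 1
# by enumeration of active sets with a KKT check. R has few columns
# (6 cell types), so all 2^(k+1) candidate active sets are cheap to test,
# and convexity guarantees the feasible KKT point found is the global
# optimum.
solve_fraction_qp <- function(R, b, tol = 1e-9) {
  k <- ncol(R)
  RtR <- crossprod(R)
  Rtb <- crossprod(R, b)
  best <- NULL
  best_obj <- Inf
  for (mask in 0:(2^k - 1)) {
    free <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) == 0)
    for (sum_active in c(FALSE, TRUE)) {
      w <- numeric(k)
      nu <- 0
      if (length(free) == 0L) {
        if (sum_active) next  # sum(w)=1 infeasible with no free coords
      } else if (!sum_active) {
        sol <- tryCatch(solve(RtR[free, free, drop = FALSE],
                              Rtb[free, , drop = FALSE]),
                        error = function(e) NULL)
        if (is.null(sol)) next
        w[free] <- sol
      } else {
        nf <- length(free)
        A <- rbind(cbind(2 * RtR[free, free, drop = FALSE], rep(1, nf)),
                   c(rep(1, nf), 0))
        rhs <- c(2 * Rtb[free, ], 1)
        sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
        if (is.null(sol)) next
        w[free] <- sol[seq_len(nf)]
        nu <- sol[nf + 1L]
      }
      # primal feasibility
      if (any(w < -tol) || sum(w) > 1 + tol) next
      # dual feasibility: grad + nu*1 - mu = 0 with mu >= 0 on zeroed coords
      g <- 2 * (RtR %*% w - Rtb)
      mu <- g + nu
      zeroed <- setdiff(seq_len(k), free)
      if (length(zeroed) && any(mu[zeroed] < -tol)) next
      if (sum_active && nu < -tol) next
      obj <- sum((b - R %*% w)^2)
      if (obj < best_obj - 1e-12) {
        best_obj <- obj
        best <- pmax(w, 0)
      }
    }
  }
  if (is.null(best)) stop("constrained least-squares solver failed to find a KKT point")
  best
}

#' Reference-based blood cell-type deconvolution
#'
#' Estimates the six leukocyte fractions of bulk methylation profiles by
#' constrained least squares against a cell-type reference panel: per
#' sample, minimize ||b - R w||^2 subject to w >= 0 and sum(w) <= 1, where
#' R holds the reference mean Beta-values at discriminating probes. The
#' reported fractions are w itself (not renormalized); the residual
#' 1 - sum(w) is the unexplained share of the mixture.
#'
#' @param beta numeric vector (one sample) or probes-by-samples matrix of
#'   Beta-values, with probe ids as names/rownames.
#' @param reference a [generate_reference_profiles()]-style panel (class
#'   `cell_type_reference`).
#' @param probes probe ids to use; defaults to the panel's discriminating
#'   probes. Must be present in both `beta` and the reference.
#' @return samples-by-6 matrix of estimated fractions (a plain named
#'   vector for a single sample), with an `"unexplained"` attribute
#'   holding 1 - rowSums(w).
#' @export
deconvolve_cell_fractions <- function(beta, reference,
                                      probes = names(reference$discriminating)) {
  if (!inherits(reference, "cell_type_reference"))
    stop_invalid("reference must be a cell_type_reference")
  vec_in <- is.null(dim(beta))
  if (vec_in) beta <- matrix(beta, ncol = 1, dimnames = list(names(beta), "s1"))
  if (is.null(rownames(beta))) stop_invalid("beta must carry probe ids")
  probes <- intersect(probes, rownames(beta))
  if (length(probes) < 6)
    stop_invalid("need at least 6 shared discriminating probes")
  R <- reference$profiles[probes, , drop = FALSE]
  qrR <- qr(R)
  if (qrR$rank < ncol(R)) {
    aliased <- colnames(R)[qrR$pivot[(qrR$rank + 1):ncol(R)]]
    stop("reference panel is rank-deficient; collinear cell-type columns: ",
         paste(aliased, collapse = ", "))
  }
  B <- beta[probes, , drop = FALSE]
  w <- t(apply(B, 2, function(b) solve_fraction_qp(R, b)))
  colnames(w) <- reference$cell_names
  rownames(w) <- colnames(B)
  unexplained <- 1 - rowSums(w)
  if (vec_in) {
    out <- setNames(w[1, ], reference$cell_names)
    attr(out, "unexplained") <- unname(unexplained)
    out
  } else {
    attr(w, "unexplained") <- unexplained
    w
  }
}
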