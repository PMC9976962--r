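#' Per-probe reference distribution for power simulations
#'
#' Empirical mean and variance of each probe's Beta-values across
#' samples, clipped to the Beta-distribution feasible region
#' (variance < mean * (1 - mean)). Variance uses the population
#' convention (divisor n).
#'
#' @param beta probes-by-samples matrix of Beta-values (>= 10 samples).
#' @return data frame of class `reference_distribution` with `probe_id`,
#'   `mean`, `variance`.
#' @export
estimate_reference <- function(beta) {
  if (ncol(beta) < 10L) stop_invalid("need at least 10 samples")
  m <- rowMeans(beta)
  v <- rowMeans(beta^2) - m^2                   # population variance
  m <- clamp(m, 1e-4, 1 - 1e-4)
  v <- clamp(v, 0, 0.999 * m * (1 - m))
  structure(data.frame(probe_id = rownames(beta) %||%
                         sprintf("p%06d", seq_along(m)),
                       mean = m, variance = v,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("reference_distribution", "data.frame"))
}

beta_shape <- function(mean, variance) {
  # moment-matched Beta(a, b); variance must be < mean (1 - mean)
  nu <- mean * (1 - mean) / variance - 1
  list(a = mean * nu, b = (1 - mean) * nu)
}

#' Simulate a two-group EWAS experiment from a reference distribution
#'
#' Draws a probes-by-N Beta matrix for two groups of (roughly) equal
#' size. `n_target_dmps` probes are sampled without replacement as true
#' DMPs; each receives a mean shift drawn from Normal(delta, tau^2)
#' truncated positive, with a random sign, applied to the second group.
#' Shifted means falling outside (0, 1), or shifts that make the probe's
#' variance infeasible, are re-drawn (count recorded in attribute
#' `n_redraws`). Per sample and probe, values are Beta-distributed with
#' the probe's (possibly shifted) mean and its reference dispersion.
#' Probes with zero reference variance are constant.
#'
#' @param ref a [estimate_reference()] table.
#' @param N total samples (>= 4); split floor(N/2) / ceiling(N/2).
#' @param delta target mean Beta difference between groups.
#' @param n_target_dmps number of planted DMPs.
#' @param tau SD of the per-probe effect-size draw.
#' @param seed RNG seed.
#' @return list of class `power_sim_data`: `beta` (probes x N),
#'   `group` (factor of length N), `truth` (data frame: probe_id,
#'   is_target, shift — signed Beta-scale shift, 0 for non-targets).
#' @export
simulate_two_groups <- function(ref, N, delta, n_target_dmps = 500L,
                                tau = 0.01, seed = 1L) {
  if (N < 4) stop_invalid("N must be >= 4")
  n_probes <- nrow(ref)
  if (n_target_dmps > n_probes) stop_invalid("more targets than probes")
  with_seed(seed, {
    n1 <- floor(N / 2); n2 <- N - n1
    group <- factor(rep(c("g1", "g2"), c(n1, n2)))
    targets <- sort(sample.int(n_probes, n_target_dmps))
    shift <- numeric(n_probes)
    n_redraws <- 0L
    for (t in targets) {
      repeat {
        d <- if (tau > 0) abs(rnorm(1, delta, tau)) else delta
        s <- sample(c(-1, 1), 1)
        m2 <- ref$mean[t] + s * d
        if (m2 > 1e-4 && m2 < 1 - 1e-4 &&
            ref$variance[t] < m2 * (1 - m2)) {
          shift[t] <- s * d
          break
        }
        n_redraws <- n_redraws + 1L
        if (n_redraws > 1000L * n_target_dmps)
          stop("infeasible mean/dispersion: effect shifts cannot be placed")
      }
    }
    draw_block <- function(means, n) {
      out <- matrix(0, n_probes, n)
      pos <- ref$variance > 0
      if (any(pos)) {
        sh <- beta_shape(means[pos], ref$variance[pos])
        out[pos, ] <- matrix(rbeta(sum(pos) * n, sh$a, sh$b), ncol = n)
      }
      out[!pos, ] <- matrix(rep(means[!pos], n), ncol = n)
      out
    }
    beta <- cbind(draw_block(ref$mean, n1), draw_block(ref$mean + shift, n2))
    dimnames(beta) <- list(ref$probe_id,
                           sprintf("%s_%03d", as.character(group), seq_len(N)))
    truth <- data.frame(probe_id = ref$probe_id,
                        is_target = seq_len(n_probes) %in% targets,
                        shift = shift, stringsAsFactors = FALSE)
    structure(list(beta = beta, group = group, truth = truth),
              class = "power_sim_data", n_redraws = n_redraws)
  })
}

#' Per-probe two-group Welch t-test on M-values
#'
#' Converts Beta-values to M-values and runs a vectorized Welch
#' two-sample t-test per probe (two-sided). Probes with zero variance in
#' both groups get p = 1 and are flagged in the `"degenerate"` attribute.
#'
#' @param beta probes-by-samples matrix.
#' @param group two-level factor over the samples (each level >= 2).
#' @return named vector of two-sided p-values (attribute `degenerate`:
#'   logical vector of zero-variance probes).
#' @export
test_dmps <- function(beta, group) {
  group <- factor(group)
  if (nlevels(group) != 2L) stop_invalid("group must have exactly 2 levels")
  if (any(table(group) < 2L)) stop_invalid("both groups need >= 2 samples")
  M <- beta_to_m(beta)
  i1 <- group == levels(group)[1L]
  n1 <- sum(i1); n2 <- sum(!i1)
  m1 <- rowMeans(M[, i1, drop = FALSE]); m2 <- rowMeans(M[, !i1, drop = FALSE])
  v1 <- rowSums((M[, i1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((M[, !i1, drop = FALSE] - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  degenerate <- se2 == 0
  tstat <- ifelse(degenerate, 0, (m1 - m2) / sqrt(se2))
  df <- ifelse(degenerate, 1,
               se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))))
  p <- 2 * pt(-abs(tstat), df)
  p[degenerate] <- ifelse(abs(m1 - m2)[degenerate] == 0, 1, 0)
  structure(setNames(p, rownames(beta)), degenerate = degenerate)
}

#' Marginal power at an FDR threshold with a detection limit
#'
#' Applies Benjamini-Hochberg to the p-values and computes marginal
#' power: among planted targets whose absolute Beta-scale shift exceeds
#' `detect_limit`, the fraction discovered. Returns `NA` (flagged) when
#' no target exceeds the detection limit.
#'
#' @param pvals per-probe p-values, aligned with `truth`.
#' @param truth the `truth` data frame from [simulate_two_groups()].
#' @param fdr_threshold BH threshold (default 0.05).
#' @param detect_limit minimum detectable Beta difference (default 0.01).
#' @return power in \[0, 1\], with attribute `n_eligible`.
#' @export
compute_power <- function(pvals, truth, fdr_threshold = 0.05,
                          detect_limit = 0.01) {
  if (length(pvals) != nrow(truth)) stop_invalid("pvals/truth misaligned")
  discovered <- p.adjust(pvals, method = "BH") <= fdr_threshold
  eligible <- truth$is_target & abs(truth$shift) > detect_limit
  if (!any(eligible)) return(structure(NA_real_, n_eligible = 0L))
  structure(sum(discovered & eligible) / sum(eligible),
            n_eligible = sum(eligible))
}

#' Power configuration
#'
#' @param N_grid total sample sizes (default 50 to 850 by 100).
#' @param delta_grid target group mean differences.
#' @param n_target_dmps planted DMPs per simulation.
#' @param n_sims simulations per grid point.
#' @param fdr_threshold BH threshold.
#' @param detect_limit technical detection threshold on the Beta scale.
#' @param tau SD of the per-probe effect-size draw.
#' @param seed master seed; each grid point / simulation derives its own.
#' @return list of class `power_config`.
#' @export
power_config <- function(N_grid = seq(50, 850, by = 100),
                         delta_grid = c(0.05, 0.1, 0.2),
                         n_target_dmps = 500L, n_sims = 100L,
                         fdr_threshold = 0.05, detect_limit = 0.01,
                         tau = 0.01, seed = 1L) {
  stopifnot(length(N_grid) > 0, length(delta_grid) > 0,
            all(N_grid >= 4), all(delta_grid > 0 & delta_grid < 1),
            fdr_threshold > 0, fdr_threshold < 1, n_sims >= 1)
  structure(list(N_grid = N_grid, delta_grid = delta_grid,
                 n_target_dmps = as.integer(n_target_dmps),
                 n_sims = as.integer(n_sims),
                 fdr_threshold = fdr_threshold, detect_limit = detect_limit,
                 tau = tau, seed = as.integer(seed)),
            class = "power_config")
}

#' Simulation-based power curve over sample size and effect size
#'
#' For every (N, delta) grid point, runs `n_sims` two-group simulations
#' from the reference distribution, tests all probes, and averages the
#' marginal power at the FDR threshold. The Monte-Carlo standard error of
#' the mean is reported alongside.
#'
#' @param ref a [estimate_reference()] table.
#' @param config a [power_config()].
#' @return data frame of class `power_curve`: `N`, `delta`, `power`,
#'   `mc_se`, `n_sims`.
#' @export
power_curve <- function(ref, config = power_config()) {
  grid <- expand.grid(N = config$N_grid, delta = config$delta_grid)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    N <- grid$N[g]; delta <- grid$delta[g]
    pw <- vapply(seq_len(config$n_sims), function(s) {
      sim <- simulate_two_groups(
        ref, N, delta, config$n_target_dmps, config$tau,
        seed = derive_seed(config$seed, sprintf("power_%d_%g_%d", N, delta, s)))
      p <- test_dmps(sim$beta, sim$group)
      compute_power(p, sim$truth, config$fdr_threshold, config$detect_limit)
    }, numeric(1))
    data.frame(N = N, delta = delta, power = mean(pw, na.rm = TRUE),
               mc_se = sd(pw, na.rm = TRUE) / sqrt(sum(!is.na(pw))),
               n_sims = config$n_sims)
  })
  structure(do.call(rbind, rows), class = c("power_curve", "data.frame"))
}

#' Minimal sample size reaching a target power
#'
#' For each delta, the smallest grid N whose mean power meets `target`;
#' a linearly interpolated crossing between the bracketing grid points is
#' reported separately.
#'
#' @param curve a [power_curve()] result.
#' @param target power target (default 0.8).
#' @return data frame with `delta`, `min_N_grid`, `min_N_interp`
#'   (NA when the target is never reached).
#' @export
find_min_n <- function(curve, target = 0.8) {
  out <- lapply(split(curve, curve$delta), function(cd) {
    cd <- cd[order(cd$N), ]
    hit <- which(cd$power >= target)
    if (!length(hit))
      return(data.frame(delta = cd$delta[1], min_N_grid = NA_real_,
                        min_N_interp = NA_real_))
    i <- hit[1L]
    interp <- if (i == 1L) cd$N[1L] else {
      cd$N[i - 1L] + (target - cd$power[i - 1L]) /
        (cd$power[i] - cd$power[i - 1L]) * (cd$N[i] - cd$N[i - 1L])
    }
    data.frame(delta = cd$delta[1], min_N_grid = cd$N[i],
               min_N_interp = interp)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.power_curve <- function(x, ...) {
  cat("Power curve (", length(unique(x$delta)), " effect sizes x ",
      length(unique(x$N)), " sample sizes, ", x$n_sims[1],
      " sims/point)\n", sep = "")
  print.data.frame(transform(x, power = round(power, 3),
                             mc_se = signif(mc_se, 2)), row.names = FALSE)
  invisible(x)
}
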