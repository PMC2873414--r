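#' Mismatch distribution (pairwise difference spectrum)
#'
#' Relative frequencies of pairwise mutational-step counts over sequence
#' pairs. With `dedup = TRUE` the sample is first reduced to one
#' representative per (haplotype, locality) pair: a haplotype seen repeatedly
#' in one local population is counted once, but counted again for every
#' additional local population in which it occurs. This de-duplication
#' removes the spike at zero differences contributed by locally common
#' haplotypes while retaining geographic signal.
#'
#' @param aln a [haplo_alignment()].
#' @param dedup logical; apply the per-locality de-duplication rule.
#' @return numeric vector of relative frequencies named `"0", "1", ...` up to
#'   the largest observed difference; attribute `n_seq` records how many
#'   sequences entered the pairwise comparison.
#' @export
mismatch_distribution <- function(aln, dedup = TRUE) {
  stopifnot(inherits(aln, "haplo_alignment"))
  ht <- collapse_haplotypes(aln)
  if (dedup) {
    mult <- (ht$counts > 0) * 1L          # one copy per (haplotype, locality)
    w <- rowSums(mult)
  } else {
    w <- ht$haplotypes$total_count
  }
  n_seq <- sum(w)
  if (n_seq < 2L) stop("fewer than 2 sequences after de-duplication")
  pw <- pairwise_steps(ht$rep_seq)$steps
  counts <- integer(max(pw) + 1L)
  H <- nrow(pw)
  for (g in seq_len(H)) {
    if (w[g] >= 2) counts[1L] <- counts[1L] + choose(w[g], 2)  # within: 0 steps
    if (g < H) for (h in (g + 1L):H) {
      k <- pw[g, h]
      counts[k + 1L] <- counts[k + 1L] + w[g] * w[h]
    }
  }
  while (length(counts) > 1L && counts[length(counts)] == 0L)
    counts <- counts[-length(counts)]
  x <- counts / sum(counts)
  names(x) <- 0:(length(x) - 1L)
  attr(x, "n_seq") <- n_seq
  x
}

#' Harpending's raggedness index
#'
#' \deqn{r = \sum_{i=1}^{d_{max}+1} (x_i - x_{i-1})^2} with
#' \eqn{x_{d_{max}+1} = 0}. Smooth, unimodal mismatch distributions (recent
#' sudden expansion) give small `r`; multimodal distributions from stationary
#' populations give large `r`.
#'
#' @param observed relative-frequency vector over difference classes
#'   `0..dmax`.
#' @return the raggedness index, in `[0, 2]`.
#' @export
raggedness <- function(observed) {
  sum(diff(c(observed, 0))^2)
}

# Sudden-expansion expected mismatch probabilities for classes 0..dmax under
# the large-final-size simplification: at the expansion (tau mutational time
# units ago) pairwise differences are geometric with mean theta0; since then
# every pair has accumulated Poisson(tau) further differences.
sudden_expansion_mismatch <- function(tau, theta0, dmax) {
  tau <- max(tau, 0); theta0 <- max(theta0, 0)   # optimisers may step epsilon outside bounds
  j <- 0:dmax
  if (theta0 == 0) geo <- c(1, rep(0, dmax))
  else geo <- exp(j * log(theta0) - (j + 1) * log1p(theta0))
  pois <- stats::dpois(j, tau)
  vapply(j, function(d) sum(pois[1:(d + 1)] * geo[(d + 1):1]), 0)
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Least-squares fit of the sudden-expansion expectation (large final
#' population size) to an observed mismatch vector, giving the expansion
#' parameters \eqn{\tau} (mutational time since expansion) and
#' \eqn{\theta_0} (pre-expansion diversity), plus Harpending's raggedness
#' `r` with a parametric-bootstrap p-value: coalescent replicates are
#' simulated under the fitted expansion at the same sample size, each
#' replicate is refitted, and the p-value is the fraction with simulated
#' raggedness at least as large as observed (large `r` = poor fit to
#' expansion).
#'
#' The fit minimises \eqn{\sum_j (x_j - F_j(\tau, \theta_0))^2} over
#' \eqn{\tau \in [0, 2 d_{max}]}, \eqn{\theta_0 \in [0, d]} from five grid
#' starts (convergence tolerance 1e-8).
#'
#' @param observed relative-frequency vector over classes `0..dmax`
#'   (sums to 1), e.g. from [mismatch_distribution()].
#' @param n number of sequences behind `observed` (bootstrap sample size);
#'   defaults to the `n_seq` attribute when present.
#' @param n_reps parametric-bootstrap replicates.
#' @param seed integer seed.
#' @return object of class `mismatch_result`: `observed`, `expected`,
#'   `tau_hat`, `theta0_hat`, `raggedness`, `p_value`, `n_reps`, `seed`.
#' @export
fit_sudden_expansion <- function(observed, n = attr(observed, "n_seq"),
                                 n_reps = 500, seed = 1) {
  x <- as.numeric(observed)
  if (abs(sum(x) - 1) > 1e-9) stop("observed frequencies must sum to 1")
  r_obs <- raggedness(x)
  if (length(x) < 3L) {
    warning("degenerate mismatch vector (fewer than 3 classes); no fit")
    return(structure(list(observed = x, expected = NULL, tau_hat = NA_real_,
                          theta0_hat = NA_real_, raggedness = r_obs,
                          p_value = NA_real_, n_reps = 0L, seed = seed),
                     class = "mismatch_result"))
  }
  dmax <- length(x) - 1L
  fit <- .fit_mismatch_lsq(x)
  if (is.null(n)) stop("sample size n is required for the bootstrap")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  r_sim <- vapply(seq_len(n_reps), function(i) {
    xs <- .sim_expansion_mismatch(n, fit$tau, fit$theta0)
    if (length(xs) >= 3L)
      .fit_mismatch_lsq(xs)    # refit, as the observed vector was fitted
    raggedness(xs)
  }, 0)
  structure(list(observed = x,
                 expected = sudden_expansion_mismatch(fit$tau, fit$theta0, dmax),
                 tau_hat = fit$tau, theta0_hat = fit$theta0,
                 raggedness = r_obs,
                 p_value = mean(r_sim >= r_obs),
                 n_reps = n_reps, seed = seed),
            class = "mismatch_result")
}

# bounded least squares with 5 grid starts
.fit_mismatch_lsq <- function(x) {
  dmax <- length(x) - 1L
  d_obs <- sum((0:dmax) * x)
  obj <- function(p) {
    v <- sum((x - sudden_expansion_mismatch(p[1L], p[2L], dmax))^2)
    if (is.finite(v)) v else 1e10
  }
  up <- c(max(2 * dmax, 1), max(d_obs, 1e-3))
  starts <- list(c(d_obs, 0.1 * up[2L]), c(0.5 * d_obs + 0.1, 0.5 * up[2L]),
                 c(1.5 * d_obs + 0.1, 0.02 * up[2L]),
                 c(0.1, 0.9 * up[2L]), c(min(2 * d_obs + 0.2, up[1L]), 1e-3))
  best <- NULL
  for (s in starts) {
    f <- stats::optim(pmin(pmax(s, 0), up), obj, method = "L-BFGS-B",
                      lower = c(0, 0), upper = up,
                      control = list(factr = 1e-8 / .Machine$double.eps))
    if (is.null(best) || f$value < best$value) best <- f
  }
  list(tau = best$par[1L], theta0 = best$par[2L], ssd = best$value)
}

#' Simulate a mismatch distribution under the sudden-expansion model
#'
#' Draws one coalescent replicate of `n` sequences under the sudden-expansion
#' model with parameters `tau` and `theta0` (final population size taken
#' large) and returns its mismatch vector. This is the same simulator the
#' parametric bootstrap of [fit_sudden_expansion()] uses; exposing it makes
#' calibration checks of the raggedness test straightforward.
#'
#' @param n number of sequences.
#' @param tau mutational time since the expansion.
#' @param theta0 pre-expansion scaled mutation rate.
#' @param seed integer seed.
#' @return relative-frequency vector over difference classes, with the
#'   `n_seq` attribute set.
#' @export
simulate_mismatch_null <- function(n, tau, theta0, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  x <- .sim_expansion_mismatch(n, tau, theta0)
  attr(x, "n_seq") <- n
  x
}

# one coalescent replicate under the fitted sudden expansion (final size
# taken large: theta1 = 1000), returning the simulated mismatch vector
.sim_expansion_mismatch <- function(n, tau, theta0, theta1 = 1000) {
  tr <- sim_genealogy(rep(0, n),
                      demography = demography_expansion(
                        time = max(tau, 1e-8) / theta1,
                        factor = theta1 / max(theta0, 1e-6)))
  mu <- .drop_mutations(tr, theta1)
  D <- .pair_diff_matrix(tr, mu)
  cnt <- tabulate(D[upper.tri(D)] + 1L)
  if (!length(cnt)) cnt <- 1L
  x <- cnt / sum(cnt)
  names(x) <- 0:(length(x) - 1L)
  x
}

#' @export
print.mismatch_result <- function(x, ...) {
  cat(sprintf("sudden-expansion fit: tau = %.3f, theta0 = %.3f; raggedness r = %.4f (P = %.3f, %d reps)\n",
              x$tau_hat, x$theta0_hat, x$raggedness, x$p_value, x$n_reps))
  invisible(x)
}
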