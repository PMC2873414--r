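# log(a + b) from log a, log b, tolerating -Inf
.logaddexp <- function(la, lb) {
  m <- pmax(la, lb)
  out <- m + log1p(exp(pmin(la, lb) - m))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

# log of unsigned Stirling numbers of the first kind, |S1(n, k)| for k = 1..n,
# via the recurrence |S1(n+1, k)| = n |S1(n, k)| + |S1(n, k-1)| carried in log
# space (needed well beyond n = 900, far past double-precision overflow).
log_stirling1_row <- function(n) {
  stopifnot(n >= 1)
  row <- 0 # log|S1(1,1)|
  if (n == 1L) return(row)
  for (i in 1L:(n - 1L)) {
    row <- .logaddexp(c(-Inf, row), log(i) + c(row, -Inf))
  }
  row
}

#' Ewens sampling distribution of the number of alleles
#'
#' Probability that a neutral sample of size `n` with scaled mutation rate
#' `theta` contains exactly `k` distinct alleles:
#' \deqn{P(K = k) = \frac{|S_1(n,k)|\,\theta^k}{\prod_{i=0}^{n-1}(\theta+i)}}
#' with \eqn{|S_1|} the unsigned Stirling numbers of the first kind, computed
#' in log space.
#'
#' @param n sample size (>= 1).
#' @param theta scaled mutation rate (> 0).
#' @return numeric vector of probabilities over `k = 1..n` (sums to 1).
#' @export
ewens_k_distribution <- function(n, theta) {
  stopifnot(n >= 1)
  if (!is.numeric(theta) || theta <= 0) stop("theta must be > 0")
  lp <- log_stirling1_row(n) + seq_len(n) * log(theta) -
    sum(log(theta + 0:(n - 1)))
  exp(lp)
}

# log P(K >= k_obs) under the Ewens distribution
.log_ewens_tail <- function(n, theta, k_obs) {
  lp <- log_stirling1_row(n) + seq_len(n) * log(theta) -
    sum(log(theta + 0:(n - 1)))
  tail <- lp[k_obs:n]
  m <- max(tail)
  m + log(sum(exp(tail - m)))
}

#' Fu's Fs test of neutrality / demographic expansion
#'
#' Estimates \eqn{\hat\theta} by the mean number of pairwise differences `d`,
#' computes \eqn{S' = P(K \ge k_{obs} \mid \hat\theta)} from the Ewens
#' sampling distribution, and
#' \deqn{F_s = \ln\frac{S'}{1 - S'}.}
#' An excess of haplotypes relative to the Ewens expectation (recent
#' expansion) makes \eqn{F_s} strongly negative. The p-value is the lower
#' tail over neutral constant-size coalescent replicates simulated at
#' \eqn{\hat\theta} (each replicate re-estimates \eqn{\theta} from its own
#' pairwise differences); following the original test, significance is
#' conventionally assessed at the 0.02 level.
#'
#' @param aln a [haplo_alignment()] with at least 2 sequences.
#' @param n_reps coalescent replicates for the p-value (>= 100).
#' @param seed integer seed for the null simulation.
#' @return object of class `fs_result`: `k_obs`, `theta_hat`, `s_prime`,
#'   `fs`, `p_value`, `n_reps`, `seed`.
#' @export
fu_fs <- function(aln, n_reps = 1000, seed = 1) {
  stopifnot(inherits(aln, "haplo_alignment"))
  if (aln$n < 2L) stop("need at least 2 sequences")
  if (n_reps < 100) stop("n_reps must be >= 100")
  div <- diversity_summary(aln)
  k_obs <- div$k
  theta_hat <- div$d
  if (k_obs == 1L || theta_hat == 0)
    stop("degenerate data: a single haplotype or d = 0; Fs is undefined")
  fs_obs <- .fs_statistic(aln$n, theta_hat, k_obs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fs_sim <- vapply(seq_len(n_reps), function(i) {
    tr <- sim_genealogy(rep(0, aln$n))
    mu <- .drop_mutations(tr, theta_hat)
    s <- .infinite_sites_summary(tr, mu)
    if (s$k == 1L || s$d == 0) Inf else .fs_statistic(aln$n, s$d, s$k)
  }, 0)
  structure(list(k_obs = k_obs, theta_hat = theta_hat,
                 s_prime = exp(.log_ewens_tail(aln$n, theta_hat, k_obs)),
                 fs = fs_obs,
                 p_value = mean(fs_sim <= fs_obs),
                 n_reps = n_reps, seed = seed),
            class = "fs_result")
}

# Fs from (n, theta, k) in log space: ln(S'/(1-S'))
.fs_statistic <- function(n, theta, k_obs) {
  lS <- .log_ewens_tail(n, theta, k_obs)
  if (lS >= 0) return(Inf)                      # S' = 1 (k_obs = 1)
  lS - log(-expm1(lS))
}

#' @export
print.fs_result <- function(x, ...) {
  cat(sprintf("Fu's Fs = %.3f (k = %d, theta_hat = %.3f, S' = %.3g), P = %.3f [%d reps]\n",
              x$fs, x$k_obs, x$theta_hat, x$s_prime, x$p_value, x$n_reps))
  invisible(x)
}

# save/restore global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}
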