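#' Analytic haplotype rarefaction curve
#'
#' Expected number of distinct haplotypes in a random subsample of `m`
#' individuals drawn without replacement from a sample with haplotype counts
#' `counts` (hypergeometric rarefaction):
#' \deqn{E[K_m] = \sum_h \left[1 - \binom{n - n_h}{m} / \binom{n}{m}\right]}
#' computed with log binomial coefficients so sample sizes in the hundreds
#' pose no overflow problem.
#'
#' @param counts positive integer vector of per-haplotype counts.
#' @param m_values subsample sizes, each in `1..sum(counts)`.
#' @return numeric vector `E[K_m]` parallel to `m_values`.
#' @export
rarefaction_curve <- function(counts, m_values) {
  counts <- as.integer(counts)
  stopifnot(all(counts >= 1))
  n <- sum(counts)
  if (any(m_values < 1 | m_values > n))
    stop("all m values must lie in 1..n = ", n)
  vapply(m_values, function(m) {
    sum(1 - exp(lchoose(n - counts, m) - lchoose(n, m)))
  }, 0)
}

#' Extrapolated total haplotype richness
#'
#' Fits the asymptotic accumulation (Clench / Michaelis-Menten) model
#' \eqn{K(m) = K_{max} m / (B + m)} to the analytic rarefaction curve by
#' least squares; the asymptote \eqn{K_{max}} estimates the total number of
#' haplotypes in the population the sample was drawn from. The standard
#' error is the standard deviation of \eqn{K_{max}} over bootstrap resamples
#' of individuals (with replacement, same `n`, curve recomputed and
#' refitted per resample).
#'
#' @param counts positive integer haplotype counts (>= 3 distinct
#'   haplotypes).
#' @param n_boot bootstrap resamples (>= 100).
#' @param seed integer seed.
#' @param m_values subsample sizes used for the fit; default `1..n`.
#' @return object of class `rarefaction_curve`: `m_values`, `expected_k`,
#'   `k_obs`, `k_total_hat`, `k_total_se`, `n_boot`, `seed`.
#' @export
estimate_total_richness <- function(counts, n_boot = 200, seed = 1,
                                    m_values = NULL) {
  counts <- as.integer(counts)
  if (length(counts) < 3L) stop("need at least 3 distinct haplotypes")
  if (n_boot < 100) stop("n_boot must be >= 100")
  n <- sum(counts)
  if (is.null(m_values)) m_values <- seq_len(n)
  ek <- rarefaction_curve(counts, m_values)
  k_hat <- .fit_clench(m_values, ek)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ind <- rep(seq_along(counts), counts)
  boot <- vapply(seq_len(n_boot), function(b) {
    cb <- tabulate(sample(ind, n, replace = TRUE))
    cb <- cb[cb > 0]
    mb <- seq_len(n)
    .fit_clench(mb, rarefaction_curve(cb, mb))
  }, 0)
  structure(list(m_values = m_values, expected_k = ek,
                 k_obs = length(counts),
                 k_total_hat = k_hat, k_total_se = stats::sd(boot),
                 n_boot = n_boot, seed = seed),
            class = "rarefaction_curve")
}

# Clench asymptote via nls with a Michaelis-Menten self-start; grid fallback
.fit_clench <- function(m, ek) {
  df <- data.frame(m = m, ek = ek)
  fit <- tryCatch(
    stats::nls(ek ~ SSmicmen(m, Kmax, B), data = df),
    error = function(e) e)
  if (inherits(fit, "error")) {
    obj <- function(p) sum((ek - p[1L] * m / (p[2L] + m))^2)
    best <- stats::optim(c(max(ek) * 1.1, max(m) / 4), obj,
                         method = "L-BFGS-B",
                         lower = c(max(ek), 1e-6),
                         upper = c(10 * max(ek), 10 * max(m)))
    if (!is.finite(best$value))
      stop("asymptotic richness fit failed: ", conditionMessage(fit))
    return(best$par[1L])
  }
  unname(stats::coef(fit)["Kmax"])
}

#' @export
print.rarefaction_curve <- function(x, ...) {
  cat(sprintf("observed %d haplotypes; extrapolated richness %.2f +/- %.2f (%d bootstraps)\n",
              x$k_obs, x$k_total_hat, x$k_total_se, x$n_boot))
  invisible(x)
}

#' Write a rarefaction curve as TSV
#' @param rc an [estimate_total_richness()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_rarefaction_tsv <- function(rc, path) {
  utils::write.table(data.frame(m = rc$m_values, expected_k = rc$expected_k),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
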