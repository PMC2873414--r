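#' Diversity summary for an alignment
#'
#' Computes the classical expansion-sensitive summaries for one population
#' stratum: the number of segregating sites `s`, the mean number of pairwise
#' mutational steps `d` over all \eqn{\binom{n}{2}} sequence pairs, nucleotide
#' diversity `pi = d / L_eff` (with `L_eff` the mean number of pairwise
#' comparable, i.e. non-N, sites), unbiased haplotype diversity
#' \eqn{H_D = \frac{n}{n-1}(1 - \sum_h p_h^2)}, and the ratio `s/d`. A high
#' `s/d` together with high `H_D` and low `pi` is the signature of a recent
#' demographic expansion.
#'
#' Pairwise steps are counted between haplotype representatives and weighted
#' by haplotype counts; pairs within a haplotype contribute zero steps.
#'
#' @param aln a [haplo_alignment()] with `n >= 2`.
#' @return object of class `diversity_summary`: `n`, `s`, `d`, `pi`, `hd`,
#'   `s_over_d` (NULL when `d = 0`), `k` (number of haplotypes), `L_eff`.
#' @export
diversity_summary <- function(aln) {
  stopifnot(inherits(aln, "haplo_alignment"))
  if (aln$n < 2L) stop("need at least 2 sequences")
  ht <- collapse_haplotypes(aln)
  pw <- pairwise_steps(ht$rep_seq)
  cnt <- ht$haplotypes$total_count
  n <- aln$n
  npairs <- n * (n - 1) / 2
  between <- tcrossprod(cnt)        # c_g * c_h
  diag(between) <- 0
  sum_steps <- sum(between * pw$steps) / 2
  self_comp <- vapply(seq_len(nrow(ht$rep_seq)),
                      function(i) sum(ht$rep_seq[i, ] != "N"), 0)
  sum_comp <- sum(between * pw$comparable) / 2 +
    sum(choose(cnt, 2) * self_comp)
  d <- sum_steps / npairs
  L_eff <- sum_comp / npairs
  p <- cnt / n
  hd <- n / (n - 1) * (1 - sum(p^2))
  s <- length(classify_sites(aln)$variable_sites)
  structure(list(n = n, s = s, d = d, pi = d / L_eff, hd = hd,
                 s_over_d = if (d > 0) s / d else NULL,
                 k = nrow(ht$haplotypes), L_eff = L_eff),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf(
    "n = %d, haplotypes k = %d, s = %d, d = %.3f, pi = %.4f, Hd = %.3f%s\n",
    x$n, x$k, x$s, x$d, x$pi, x$hd,
    if (is.null(x$s_over_d)) "" else sprintf(", s/d = %.2f", x$s_over_d)))
  invisible(x)
}

#' Between-haplogroup sequence divergence
#'
#' Mean per-site divergence between two groups of samples
#' (\eqn{d_{XY}}), the within-group per-site diversities \eqn{d_X, d_Y},
#' and the net divergence \eqn{d_A = d_{XY} - (d_X + d_Y)/2}, which corrects
#' the raw between-group divergence for polymorphism inherited from the
#' common ancestral population. Per-pair per-site divergence is
#' `steps / comparable sites`. Within-group diversities are
#' frequency-weighted (averaged over ordered pairs including
#' self-comparisons, \eqn{d_X = \sum_{i,j} d_{ij}/n^2}), the convention
#' under which two identical groups have `d_a = 0` exactly; groups with a
#' single sequence have zero within-group diversity.
#'
#' @param aln a [haplo_alignment()].
#' @param assignment haplogroup labels: either a [partition_haplogroups()]
#'   result (per-haplotype labels, expanded via [collapse_haplotypes()]) or a
#'   per-sample vector named by sample id with values `"1"`/`"2"`
#'   (`"unassigned"` samples are dropped).
#' @return object of class `divergence_result` with `d_xy`, `d_x`, `d_y`,
#'   `d_a`, `n_x`, `n_y`.
#' @export
group_divergence <- function(aln, assignment) {
  stopifnot(inherits(aln, "haplo_alignment"))
  lab <- .sample_labels(aln, assignment)
  gx <- names(lab)[lab == "1"]; gy <- names(lab)[lab == "2"]
  if (!length(gx) || !length(gy)) stop("both haplogroups must be non-empty")
  idx <- function(ids) match(ids, rownames(aln$seq))
  between <- function(rows_a, rows_b) {
    tot <- 0
    for (i in rows_a) for (j in rows_b) {
      cmp <- seq_compare(aln$seq[i, ], aln$seq[j, ])
      tot <- tot + cmp$steps / cmp$comparable
    }
    tot / (length(rows_a) * length(rows_b))
  }
  within <- function(rows) {
    if (length(rows) < 2L) return(0)
    tot <- 0
    for (i in seq_along(rows)[-length(rows)])
      for (j in (i + 1L):length(rows)) {
        cmp <- seq_compare(aln$seq[rows[i], ], aln$seq[rows[j], ])
        tot <- tot + cmp$steps / cmp$comparable
      }
    2 * tot / length(rows)^2      # ordered pairs incl. self-comparisons
  }
  d_xy <- between(idx(gx), idx(gy))
  d_x <- within(idx(gx))
  d_y <- within(idx(gy))
  structure(list(d_xy = d_xy, d_x = d_x, d_y = d_y,
                 d_a = d_xy - (d_x + d_y) / 2,
                 n_x = length(gx), n_y = length(gy)),
            class = "divergence_result")
}

#' @export
print.divergence_result <- function(x, ...) {
  cat(sprintf("d_XY = %.4f, d_X = %.4f, d_Y = %.4f, net d_A = %.4f (n = %d/%d)\n",
              x$d_xy, x$d_x, x$d_y, x$d_a, x$n_x, x$n_y))
  invisible(x)
}

# resolve a per-haplotype or per-sample assignment to per-sample labels
.sample_labels <- function(aln, assignment) {
  if (inherits(assignment, "haplogroup_assignment")) {
    ht <- collapse_haplotypes(aln)
    lab <- assignment$labels[ht$assignment]
    names(lab) <- names(ht$assignment)
  } else {
    lab <- assignment
    if (is.null(names(lab)) && length(lab) == aln$n)
      names(lab) <- rownames(aln$seq)
  }
  lab <- lab[names(lab) %in% rownames(aln$seq)]
  lab[lab %in% c("1", "2")]
}
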