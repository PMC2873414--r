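# Mutational-step convention shared by the whole pipeline:
#   * sites where either sequence is N are excluded pairwise;
#   * a base-base difference is one step;
#   * a maximal run of contiguous columns in which the SAME sequence is gapped
#     and the other is not counts as ONE indel event (one step), matching the
#     way an insertion/deletion is scored as a single mutational step;
#   * columns that are masked (N) or gapped in both sequences are transparent:
#     they neither count as differences nor break an indel run.

#' Count mutational steps between two aligned sequences
#'
#' @param a,b character vectors of equal length over `A,C,G,T,-,N`.
#' @return a list with `steps` (integer), `comparable` (number of pairwise
#'   non-N sites) and `gap_events` (how many of the steps were indel runs).
#' @export
seq_compare <- function(a, b) {
  stopifnot(length(a) == length(b))
  mask <- a == "N" | b == "N"
  comparable <- sum(!mask)
  diff <- !mask & a != b
  gap_diff <- diff & (a == "-" | b == "-")
  sub_steps <- sum(diff & !gap_diff)
  gap_events <- 0L
  if (any(gap_diff)) {
    pos <- which(gap_diff)
    ori <- ifelse(a[pos] == "-", 1L, 2L)
    transparent <- mask | (a == "-" & b == "-")
    new_run <- c(TRUE, vapply(seq_along(pos)[-1L], function(i) {
      gapcols <- (pos[i - 1L] + 1L):(pos[i] - 1L)
      ori[i] != ori[i - 1L] ||
        (pos[i] > pos[i - 1L] + 1L && !all(transparent[gapcols]))
    }, NA))
    gap_events <- sum(new_run)
  }
  list(steps = sub_steps + gap_events, comparable = comparable,
       gap_events = gap_events)
}

#' Mutational steps between two sequences
#' @inheritParams seq_compare
#' @return integer step count.
#' @export
seq_steps <- function(a, b) seq_compare(a, b)$steps

#' Pairwise step and comparable-site matrices for a sequence matrix
#'
#' @param mat character matrix (sequences x sites).
#' @return list of two symmetric matrices, `steps` and `comparable`.
#' @export
pairwise_steps <- function(mat) {
  n <- nrow(mat)
  steps <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  comp <- matrix(ncol(mat), n, n, dimnames = dimnames(steps))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        cmp <- seq_compare(mat[i, ], mat[j, ])
        steps[i, j] <- steps[j, i] <- cmp$steps
        comp[i, j] <- comp[j, i] <- cmp$comparable
      }
    }
  }
  list(steps = steps, comparable = comp)
}
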