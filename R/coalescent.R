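# Hudson-style coalescent engine for a single non-recombining locus.
#
# Time runs backwards from the present in units of N_f generations (N_f the
# mitochondrial effective population size of the reference deme), so that a
# pair of lineages in a deme of relative size 1 coalesces at rate 1 and a
# lineage accumulates mutations at rate theta/2 per unit time, giving the
# usual E[pairwise differences] = theta for a constant population.
#
# Supported structure: one or two demes with piecewise-constant relative
# sizes (constant, or a sudden expansion: size 1 towards the present and
# 1/factor beyond the expansion time), symmetric per-lineage migration, a
# deme split (backwards merge) at `split_time`, and serially sampled tips
# (ancient samples enter the genealogy at their age).

#' Demography descriptors
#'
#' `demography_constant()` keeps the relative deme size at 1 throughout;
#' `demography_expansion(time, factor)` models a sudden expansion: the deme
#' has relative size 1 from the present back to `time` (coalescent units) and
#' size `1/factor` earlier, i.e. the population grew `factor`-fold at `time`.
#'
#' @param time expansion time, in coalescent units before present.
#' @param factor growth factor (> 1 for an expansion).
#' @return a demography descriptor list.
#' @export
demography_constant <- function() {
  structure(list(type = "constant"), class = "demography")
}

#' @rdname demography_constant
#' @export
demography_expansion <- function(time, factor) {
  stopifnot(time >= 0, factor > 0)
  structure(list(type = "sudden_expansion", time = time, factor = factor),
            class = "demography")
}

.deme_size <- function(demog, t) {
  if (demog$type == "constant") 1
  else if (t < demog$time) 1 else 1 / demog$factor
}

.deme_breaks <- function(demog) {
  if (demog$type == "constant") numeric(0) else demog$time
}

#' Simulate a coalescent genealogy
#'
#' @param sample_times entry time of each tip (0 = present), coalescent units.
#' @param sample_demes deme (1 or 2) of each tip.
#' @param demography a [demography_constant()]/[demography_expansion()]
#'   descriptor, or a list of two (one per deme).
#' @param split_time time (backwards) at which the two demes merge into the
#'   ancestral deme; `Inf` for a single panmictic deme.
#' @param migration per-lineage scaled migration rate between demes.
#' @param anc_size relative size of the ancestral (post-split) deme.
#' @return list with `parent`, `time` (per node), `n_tips`, `root`,
#'   `edge_length` (branch above each non-root node) and `n_desc` (tips below
#'   each node). Tips are nodes `1..n`, internal nodes follow.
#' @export
sim_genealogy <- function(sample_times, sample_demes = NULL,
                          demography = demography_constant(),
                          split_time = Inf, migration = 0, anc_size = 1) {
  n <- length(sample_times)
  stopifnot(n >= 2)
  if (is.null(sample_demes)) sample_demes <- rep(1L, n)
  if (inherits(demography, "demography")) demography <- list(demography, demography)
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes); parent[] <- NA_integer_
  node_time <- numeric(n_nodes)
  node_time[seq_len(n)] <- sample_times
  ord <- order(sample_times)
  pending <- ord[sample_times[ord] > 0]
  active <- ord[sample_times[ord] <= 0]
  deme <- integer(n_nodes)
  deme[seq_len(n)] <- sample_demes
  t <- 0
  nxt <- n + 1L
  brk <- sort(unique(c(.deme_breaks(demography[[1L]]),
                       .deme_breaks(demography[[2L]]),
                       if (is.finite(split_time)) split_time)))
  repeat {
    if (length(active) <= 1L && length(pending) == 0L) break
    merged <- t >= split_time
    k1 <- sum(deme[active] == 1L); k2 <- sum(deme[active] == 2L)
    if (merged) {
      r_c1 <- choose(k1 + k2, 2) / anc_size
      r_c2 <- 0; r_m <- 0
    } else {
      r_c1 <- choose(k1, 2) / .deme_size(demography[[1L]], t)
      r_c2 <- choose(k2, 2) / .deme_size(demography[[2L]], t)
      r_m <- (k1 + k2) * migration
    }
    total <- r_c1 + r_c2 + r_m
    bound <- min(c(brk[brk > t], if (length(pending)) node_time[pending[1L]],
                   Inf))
    if (total <= 0) {
      if (!is.finite(bound)) stop("coalescent cannot proceed (rate 0)")
      t <- bound
    } else {
      w <- stats::rexp(1L, total)
      if (t + w >= bound) {
        t <- bound
      } else {
        t <- t + w
        u <- stats::runif(1L) * total
        if (u < r_c1 + r_c2) {
          d <- if (u < r_c1) (if (merged) 0L else 1L) else 2L
          pool <- if (merged) active else active[deme[active] == d]
          pick <- sample(length(pool), 2L)
          a <- pool[pick[1L]]; b <- pool[pick[2L]]
          parent[a] <- parent[b] <- nxt
          node_time[nxt] <- t
          deme[nxt] <- if (merged) 1L else d
          active <- c(setdiff(active, c(a, b)), nxt)
          nxt <- nxt + 1L
        } else {
          m <- active[sample(length(active), 1L)]
          deme[m] <- 3L - deme[m]
        }
      }
    }
    if (length(pending)) {
      arrive <- pending[node_time[pending] <= t]
      if (length(arrive)) {
        active <- c(active, arrive)
        pending <- setdiff(pending, arrive)
      }
    }
  }
  root <- active
  edge_length <- node_time[parent] - node_time
  edge_length[root] <- NA_real_
  n_desc <- integer(n_nodes)
  n_desc[seq_len(n)] <- 1L
  for (v in order(node_time)) {      # children always earlier than parents
    if (!is.na(parent[v])) n_desc[parent[v]] <- n_desc[parent[v]] + n_desc[v]
  }
  list(parent = parent, time = node_time, n_tips = n, root = root,
       edge_length = edge_length, n_desc = n_desc)
}

# Poisson mutations under the infinite-sites model; returns per-node counts
# of mutations on the branch above each non-root node.
.drop_mutations <- function(tree, theta) {
  len <- tree$edge_length
  len[is.na(len)] <- 0
  stats::rpois(length(len), theta / 2 * len)
}

# Summaries of an infinite-sites mutation drop: number of distinct
# haplotypes k, mean pairwise differences d, segregating sites S.
.infinite_sites_summary <- function(tree, mut) {
  n <- tree$n_tips
  npairs <- n * (n - 1) / 2
  seg <- tree$n_desc >= 1L & tree$n_desc <= n - 1L & mut > 0L
  d <- sum(mut * tree$n_desc * (n - tree$n_desc)) / npairs
  key <- character(length(tree$parent))
  for (v in rev(order(tree$time))) {   # preorder: parents before children
    p <- tree$parent[v]
    pre <- if (is.na(p)) "" else key[p]
    key[v] <- if (mut[v] > 0L) paste0(pre, ",", v) else pre
  }
  k <- length(unique(key[seq_len(n)]))
  list(k = k, d = d, S = sum(mut[seg]))
}

# Pairwise difference counts between all tips (infinite sites): each mutated
# branch adds its count to every pair it separates. O(edges * n^2); meant for
# modest n (mismatch-style vectors).
.pair_diff_matrix <- function(tree, mut) {
  n <- tree$n_tips
  below <- matrix(FALSE, length(tree$parent), n)
  below[cbind(seq_len(n), seq_len(n))] <- TRUE
  for (v in order(tree$time)) {
    p <- tree$parent[v]
    if (!is.na(p)) below[p, ] <- below[p, ] | below[v, ]
  }
  D <- matrix(0L, n, n)
  for (v in which(mut > 0L)) {
    inb <- below[v, ]
    if (all(inb) || !any(inb)) next
    D[inb, !inb] <- D[inb, !inb] + mut[v]
  }
  D + t(D)
}
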