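#' Probability of parsimony and the statistical-parsimony connection limit
#'
#' In a statistical-parsimony (TCS-style) network, two haplotypes may be
#' connected at `j` mutational steps only while the probability that such a
#' connection is free of superimposed (multiple-hit) changes stays above the
#' chosen confidence. The package computes, for `j` observed differences
#' over `L` sites, the single-hit probability per observed difference under
#' a Jukes-Cantor correction at the maximum-likelihood pairwise divergence
#' \eqn{p = j/L}:
#' \deqn{\lambda = -\tfrac{3}{4}\log(1 - \tfrac{4p}{3}), \qquad
#'       u_j = \frac{\lambda e^{-\lambda}}{p},}
#' (`u_j` is the probability that a site showing a difference experienced
#' exactly one substitution) and aggregates it over the `j - 1` inferred
#' intermediate nodes of a `j`-step connection:
#' \deqn{P_j = u_j^{\,j-1}.}
#' A single step is always parsimonious (\eqn{P_1 = 1}). The convention is
#' anchored on the published 95\% limit of 6 steps for 230 bp control-region
#' alignments and is monotone in both `L` and the confidence level.
#'
#' @param L alignment length in sites (>= 1).
#' @param confidence connection confidence, in (0, 1); default 0.95.
#' @return `parsimony_limit()`: the largest integer `j` with
#'   \eqn{P_j >} `confidence`. `parsimony_probability()`: \eqn{P_j} itself.
#' @export
parsimony_limit <- function(L, confidence = 0.95) {
  stopifnot(L >= 1, confidence > 0, confidence < 1)
  j <- 1L
  while (j + 1L < 0.75 * L &&
         parsimony_probability(j + 1L, L) > confidence) j <- j + 1L
  j
}

#' @param j number of observed differences (steps) between two haplotypes.
#' @rdname parsimony_limit
#' @export
parsimony_probability <- function(j, L) {
  stopifnot(j >= 1, L >= 1)
  if (j >= 0.75 * L) return(0)
  p <- j / L
  lam <- -0.75 * log1p(-4 * p / 3)
  u <- lam * exp(-lam) / p
  u^(j - 1)
}

#' Build a statistical-parsimony haplotype network
#'
#' Haplotype pairs are connected in non-decreasing step distance (ties broken
#' lexicographically by haplotype id). A connection at distance `k > 1`
#' introduces `k - 1` inferred intermediate nodes; pairs farther apart than
#' the connection limit stay in separate components. Within one distance
#' level, every connection that would join the same two components as an
#' earlier equal-distance connection is retained but flagged as an
#' alternative (ambiguous) path, mirroring the dashed alternative
#' connections of published parsimony networks.
#'
#' @param ht a [collapse_haplotypes()] result (or any object with a
#'   `rep_seq` character matrix whose rownames are haplotype ids).
#' @param limit connection limit in steps, e.g. from [parsimony_limit()].
#' @return object of class `parsimony_network`: `nodes` (data.frame `id`,
#'   `is_inferred`), `edges` (data.frame `from`, `to`, `distance` of the
#'   sampled pair the edge belongs to, `is_alternative`), `limit`,
#'   `components` (named membership vector over sampled haplotypes),
#'   `haplotype_ids`.
#' @export
build_network <- function(ht, limit) {
  rep_seq <- if (inherits(ht, "haplotype_table")) ht$rep_seq else ht$rep_seq
  stopifnot(is.matrix(rep_seq), limit >= 1)
  ids <- rownames(rep_seq)
  H <- length(ids)
  pw <- pairwise_steps(rep_seq)$steps
  nodes <- data.frame(id = ids, is_inferred = FALSE, stringsAsFactors = FALSE)
  edges <- data.frame(from = character(0), to = character(0),
                      distance = integer(0), is_alternative = logical(0),
                      stringsAsFactors = FALSE)
  comp <- stats::setNames(seq_len(H), ids)     # union-find over sampled haplotypes
  n_interm <- 0L
  if (H >= 2L) {
    pairs <- which(upper.tri(pw), arr.ind = TRUE)
    pd <- pw[pairs]
    ord <- order(pd, ids[pairs[, 1L]], ids[pairs[, 2L]])
    pairs <- pairs[ord, , drop = FALSE]; pd <- pd[ord]
    for (lev in sort(unique(pd))) {
      if (lev < 1L || lev > limit) next
      snapshot <- comp
      at <- which(pd == lev)
      for (idx in at) {
        a <- ids[pairs[idx, 1L]]; b <- ids[pairs[idx, 2L]]
        if (snapshot[a] == snapshot[b]) next   # already linked at <= this level
        alt <- unname(comp[a] == comp[b])      # merged earlier within this level
        chain <- a
        if (lev > 1L) {
          interm <- paste0("i", n_interm + seq_len(lev - 1L))
          n_interm <- n_interm + lev - 1L
          nodes <- rbind(nodes, data.frame(id = interm, is_inferred = TRUE,
                                           stringsAsFactors = FALSE))
          chain <- c(chain, interm)
        }
        chain <- c(chain, b)
        edges <- rbind(edges, data.frame(
          from = unname(chain[-length(chain)]), to = unname(chain[-1L]),
          distance = lev, is_alternative = alt, stringsAsFactors = FALSE))
        if (!alt) comp[comp == comp[b]] <- comp[a]
      }
    }
  }
  comp_ids <- match(comp, unique(comp))
  names(comp_ids) <- ids
  structure(list(nodes = nodes, edges = edges, limit = limit,
                 components = comp_ids, haplotype_ids = ids),
            class = "parsimony_network")
}

#' @export
print.parsimony_network <- function(x, ...) {
  cat("parsimony network:", sum(!x$nodes$is_inferred), "haplotypes +",
      sum(x$nodes$is_inferred), "inferred nodes;",
      nrow(x$edges), "edges (", sum(x$edges$is_alternative), "alternative );",
      "limit", x$limit, "steps;", max(x$components), "component(s)\n")
  invisible(x)
}

#' Convert a parsimony network to an igraph graph
#' @param net a [build_network()] result.
#' @param include_alternative keep ambiguous alternative edges.
#' @return an igraph undirected graph.
#' @export
as_igraph <- function(net, include_alternative = TRUE) {
  e <- net$edges
  if (!include_alternative) e <- e[!e$is_alternative, , drop = FALSE]
  igraph::graph_from_data_frame(e[, c("from", "to")], directed = FALSE,
                                vertices = net$nodes$id)
}

#' Partition network haplotypes into two haplogroups from seed haplotypes
#'
#' Each sampled haplotype is labelled by the seed set to which its shortest
#' network path (over all edges, alternative ones included) is strictly
#' shorter; equidistant or unreachable haplotypes remain `"unassigned"`.
#'
#' @param net a [build_network()] result.
#' @param seeds1,seeds2 disjoint, non-empty character vectors of haplotype
#'   ids present in the network.
#' @return object of class `haplogroup_assignment` with `labels` (named
#'   vector over sampled haplotypes, values `"1"`, `"2"` or `"unassigned"`).
#' @export
partition_haplogroups <- function(net, seeds1, seeds2) {
  stopifnot(length(seeds1) >= 1, length(seeds2) >= 1)
  if (length(intersect(seeds1, seeds2)))
    stop("seed sets share haplotype(s): ",
         paste(intersect(seeds1, seeds2), collapse = ", "))
  miss <- setdiff(c(seeds1, seeds2), net$haplotype_ids)
  if (length(miss)) stop("seed haplotype(s) not in network: ",
                         paste(miss, collapse = ", "))
  g <- as_igraph(net)
  dist <- igraph::distances(g, v = net$haplotype_ids)
  d1 <- apply(dist[, seeds1, drop = FALSE], 1L, min)
  d2 <- apply(dist[, seeds2, drop = FALSE], 1L, min)
  lab <- ifelse(d1 < d2, "1", ifelse(d2 < d1, "2", "unassigned"))
  names(lab) <- net$haplotype_ids
  structure(list(labels = lab, seeds1 = seeds1, seeds2 = seeds2),
            class = "haplogroup_assignment")
}

#' @export
print.haplogroup_assignment <- function(x, ...) {
  print(table(x$labels))
  invisible(x)
}

#' Export a network as edge-list TSV or DOT
#'
#' The TSV has columns `node1, node2, is_alternative, is_inferred1,
#' is_inferred2`; the DOT output renders sampled haplotypes as circles and
#' inferred intermediates as points, with alternative connections dashed.
#'
#' @param net a [build_network()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  inf <- stats::setNames(net$nodes$is_inferred, net$nodes$id)
  out <- data.frame(node1 = net$edges$from, node2 = net$edges$to,
                    is_alternative = net$edges$is_alternative,
                    is_inferred1 = unname(inf[net$edges$from]),
                    is_inferred2 = unname(inf[net$edges$to]))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
write_network_dot <- function(net, path) {
  inf <- stats::setNames(net$nodes$is_inferred, net$nodes$id)
  lines <- c("graph parsimony_network {",
             paste0("  \"", net$nodes$id, "\" [shape=",
                    ifelse(net$nodes$is_inferred, "point", "circle"), "];"),
             paste0("  \"", net$edges$from, "\" -- \"", net$edges$to, "\"",
                    ifelse(net$edges$is_alternative, " [style=dashed]", ""),
                    ";"),
             "}")
  writeLines(lines, path)
  invisible(path)
}
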