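test_that("the 95% connection limit reproduces published anchors and is monotone", {
  expect_identical(parsimony_limit(230, 0.95), 6L)
  j57 <- parsimony_limit(57); j230 <- parsimony_limit(230)
  j661 <- parsimony_limit(661)
  expect_lte(j57, j230); expect_lte(j230, j661)
  # lowering the confidence can only lengthen acceptable connections
  limits <- vapply(c(0.99, 0.95, 0.8, 0.5, 0.1), function(cf)
    parsimony_limit(230, cf), 0L)
  expect_true(all(diff(limits) >= 0))
  # a single step is always parsimonious
  expect_gte(parsimony_limit(10, 0.99), 1L)
  p <- vapply(1:12, function(j) parsimony_probability(j, 230), 0)
  expect_true(all(diff(p) < 0))                 # decreasing in j
})

test_that("networks use unit edges, inferred intermediates and the limit", {
  ht1 <- collapse_haplotypes(aln_fix(c("AAA", "AAT")))
  net1 <- build_network(ht1, 6)
  expect_equal(nrow(net1$nodes), 2L)
  expect_equal(nrow(net1$edges), 1L)
  expect_false(any(net1$nodes$is_inferred))

  # distance-2 pair: one inferred intermediate on the chain
  ht2 <- collapse_haplotypes(aln_fix(c("AAAA", "AATT")))
  net2 <- build_network(ht2, 6)
  expect_equal(sum(net2$nodes$is_inferred), 1L)
  expect_equal(nrow(net2$edges), 2L)
  g <- as_igraph(net2)
  expect_equal(unname(igraph::distances(g, "h1", "h2")[1, 1]), 2)

  # an outlier farther than the limit stays in its own component
  far <- paste(rep("T", 12), collapse = "")
  near <- c("AAAAAAAAAAAA", "AAAAAAAAAAAT", "AAAAAAAAAATT")
  net3 <- build_network(collapse_haplotypes(aln_fix(c(near, far))), 3)
  expect_equal(max(net3$components), 2L)
  expect_equal(unname(net3$components["h4"]), 2L)

  # all pairwise distances 1: exactly h nodes, ties kept as alternatives
  ht4 <- collapse_haplotypes(aln_fix(c("A", "C", "G")))
  net4 <- build_network(ht4, 6)
  expect_equal(nrow(net4$nodes), 3L)
  expect_equal(sum(net4$edges$is_alternative), 1L)
  expect_equal(nrow(net4$edges), 3L)
})

test_that("components separate exactly the pairs beyond the connection limit", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(6:14, 1)
    mat <- matrix(sample(c("A", "G"), n * 20, replace = TRUE, prob = c(.8, .2)),
                  n, 20)
    ht <- collapse_haplotypes(haplo_alignment(mat))
    limit <- 3L
    net <- build_network(ht, limit)
    pw <- pairwise_steps(ht$rep_seq)$steps
    ids <- net$haplotype_ids
    for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1):length(ids)) {
      same <- net$components[ids[i]] == net$components[ids[j]]
      if (pw[ids[i], ids[j]] <= limit) expect_true(same)
      if (!same) expect_gt(pw[ids[i], ids[j]], limit)
    }
  }
})

test_that("haplogroup partitioning follows shortest paths, ties stay unassigned", {
  # two components, one seed each: everything labelled by component
  far <- paste(rep("T", 12), collapse = "")
  near <- c("AAAAAAAAAAAA", "AAAAAAAAAAAT")
  net <- build_network(collapse_haplotypes(aln_fix(c(near, far))), 3)
  asg <- partition_haplogroups(net, "h1", "h3")
  expect_equal(unname(asg$labels), c("1", "1", "2"))

  # linear chain with a midpoint haplotype: the midpoint is a tie
  chain <- c(a = "AAAAAAAA", m = "AAAATTAA", b = "AATTTTAA")
  net2 <- build_network(collapse_haplotypes(aln_fix(chain)), 6)
  asg2 <- partition_haplogroups(net2, "h1", "h3")
  expect_equal(unname(asg2$labels["h2"]), "unassigned")

  # swapping seed sets swaps the labels
  asg3 <- partition_haplogroups(net2, "h3", "h1")
  expect_equal(unname(asg3$labels["h1"]), "2")
  expect_equal(unname(asg3$labels["h3"]), "1")

  expect_error(partition_haplogroups(net2, "h1", "h1"), "share")
  expect_error(partition_haplogroups(net2, "h1", "zz"), "not in network")
})

test_that("network exports carry the edge and node annotations", {
  ht <- collapse_haplotypes(aln_fix(c("AAAA", "AATT")))
  net <- build_network(ht, 6)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  dot <- withr::local_tempfile(fileext = ".dot")
  write_network_tsv(net, tsv)
  tab <- utils::read.delim(tsv)
  expect_equal(names(tab), c("node1", "node2", "is_alternative",
                             "is_inferred1", "is_inferred2"))
  expect_equal(nrow(tab), 2L)
  expect_true(any(tab$is_inferred2 | tab$is_inferred1))
  write_network_dot(net, dot)
  txt <- readLines(dot)
  expect_true(any(grepl("graph parsimony_network", txt)))
  expect_true(any(grepl("point", txt)))
})
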