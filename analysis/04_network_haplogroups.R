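#!/usr/bin/env Rscript
# Stage 4: statistical-parsimony network, haplogroup partitioning and
# between-haplogroup divergence.

suppressPackageStartupMessages(library(wolfmtdna))

data_dir <- file.path("results", "data")
out <- "results"
aln <- read_alignment(file.path(data_dir, "synthetic_alignment.fasta"),
                      file.path(data_dir, "synthetic_metadata.tsv"))
truth <- jsonlite::read_json(file.path(data_dir, "synthetic_truth.json"),
                             simplifyVector = TRUE)

limit <- parsimony_limit(aln$L, confidence = 0.95)
message("95% parsimony connection limit for ", aln$L, " bp: ", limit,
        " steps")

ht <- collapse_haplotypes(aln)
net <- build_network(ht, limit)
print(net)
write_network_tsv(net, file.path(out, "network.tsv"))
write_network_dot(net, file.path(out, "network.dot"))

# seed haplotypes: the most common haplotype of each true haplogroup
lab <- stats::setNames(truth$samples$haplogroup, truth$samples$sample_id)
pick <- function(g, avoid = character(0)) {
  tab <- sort(table(ht$assignment[names(lab)[lab == g]]), decreasing = TRUE)
  setdiff(names(tab), avoid)[1L]
}
s1 <- pick("1"); s2 <- pick("2", avoid = s1)
asg <- partition_haplogroups(net, s1, s2)
message("haplogroup assignment from seeds ", s1, " / ", s2, ":")
print(asg)

tr <- tapply(lab[names(ht$assignment)], ht$assignment,
             function(z) if (length(unique(z)) == 1) z[[1]] else NA)
message("agreement with simulation truth: ",
        round(100 * mean(asg$labels == tr[net$haplotype_ids], na.rm = TRUE)),
        "% of haplotypes")

dv <- group_divergence(aln, asg)
message("between-haplogroup divergence:")
print(dv)
jsonlite::write_json(
  list(connection_limit = limit, seeds = c(s1, s2),
       labels = as.list(asg$labels),
       divergence = unclass(dv)),
  file.path(out, "haplogroups.json"), auto_unbox = TRUE, digits = NA)
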