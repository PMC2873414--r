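#!/usr/bin/env Rscript
# Stage 5: haplotype rarefaction and total-richness extrapolation, for all
# modern samples and for the eastern subset (excluding the two low-diversity
# peninsular populations), mirroring the way sampling completeness is
# usually assessed.

suppressPackageStartupMessages(library(wolfmtdna))

data_dir <- file.path("results", "data")
out <- "results"
seed <- 1L
aln <- read_alignment(file.path(data_dir, "synthetic_alignment.fasta"),
                      file.path(data_dir, "synthetic_metadata.tsv"))

richness_of <- function(sub, label, file_tag) {
  counts <- collapse_haplotypes(sub)$haplotypes$total_count
  rc <- estimate_total_richness(counts, n_boot = 500, seed = seed + 303L)
  message(label, ": ", rc$k_obs, " haplotypes observed in ", sub$n,
          " samples; extrapolated total ",
          sprintf("%.2f +/- %.2f", rc$k_total_hat, rc$k_total_se))
  write_rarefaction_tsv(rc, file.path(out, paste0("rarefaction_",
                                                  file_tag, ".tsv")))
  list(k_obs = rc$k_obs, k_total_hat = rc$k_total_hat,
       k_total_se = rc$k_total_se, n = sub$n)
}

keep_modern <- is.na(aln$meta$age_bp)
modern <- haplo_alignment(aln$seq[keep_modern, , drop = FALSE],
                          aln$meta[keep_modern, , drop = FALSE])
all_mod <- richness_of(modern, "all modern", "all")

keep_east <- !(modern$meta$region %in% c("iberia", "apennine"))
eastern <- haplo_alignment(modern$seq[keep_east, , drop = FALSE],
                           modern$meta[keep_east, , drop = FALSE])
east <- richness_of(eastern, "eastern (no peninsulas)", "eastern")

jsonlite::write_json(list(all_modern = all_mod, eastern = east),
                     file.path(out, "richness.json"),
                     auto_unbox = TRUE, digits = NA)
message("wrote rarefaction curves and richness.json under ", out)
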