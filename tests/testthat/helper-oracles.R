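# Independent oracles and fixture builders used across the suite.

# alignment from named strings, with optional metadata columns
aln_fix <- function(x, locality = NULL, region = NULL, age_bp = NULL) {
  if (is.null(names(x))) names(x) <- paste0("s", seq_along(x))
  meta <- NULL
  if (!is.null(locality) || !is.null(region) || !is.null(age_bp)) {
    meta <- data.frame(sample_id = names(x),
                       locality = if (is.null(locality)) "unknown" else locality,
                       region = if (is.null(region)) "unknown" else region,
                       stringsAsFactors = FALSE)
    if (!is.null(age_bp)) meta$age_bp <- age_bp
  }
  haplo_alignment(x, meta)
}

# naive per-position mismatch count (no gap-run logic); valid as an oracle on
# fixtures free of gaps and N
naive_diffs <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Ewens allele-count distribution by exhaustive recursion over the
# Chinese-restaurant construction (independent of the Stirling-number route)
crp_k_dist <- function(n, theta) {
  out <- numeric(n)
  rec <- function(i, tables, prob) {
    if (i > n) {
      k <- length(tables)
      out[k] <<- out[k] + prob
      return(invisible())
    }
    denom <- theta + i - 1
    for (j in seq_along(tables)) {
      t2 <- tables; t2[j] <- t2[j] + 1L
      rec(i + 1L, t2, prob * tables[j] / denom)
    }
    rec(i + 1L, c(tables, 1L), prob * theta / denom)
  }
  rec(2L, 1L, 1)
  out
}

# Monte-Carlo rarefaction: subsample m individuals without replacement
mc_rarefaction <- function(counts, m, reps, seed) {
  set.seed(seed)
  ind <- rep(seq_along(counts), counts)
  k <- replicate(reps, length(unique(sample(ind, m))))
  list(mean = mean(k), se = stats::sd(k) / sqrt(reps))
}

# single-population simulation config (one deme; split never happens)
single_pop_cfg <- function(n, theta, demog, seed, L = 230, indel = 0.2) {
  simulation_config(n_modern = n, n_ancient = 0, ancient_ages_bp = NULL,
                    L = L, theta = theta, demography = demog,
                    split_time = Inf, hap2_fraction_modern = 0,
                    region_weights = c(iberia = 0, apennine = 0,
                                       central = 0.5, eastern = 0.5),
                    indel_prob = indel, seed = seed)
}

# Fu's Fs from an alignment through the public API (no coalescent p-value)
fs_statistic_of <- function(aln) {
  dv <- diversity_summary(aln)
  sp <- sum(ewens_k_distribution(aln$n, dv$d)[dv$k:aln$n])
  log(sp / (1 - sp))
}

# two-haplogroup config used for label-recovery checks: star-like clusters
# (recent expansion) separated by a deep split
two_group_cfg <- function(n, seed) {
  simulation_config(n_modern = n, n_ancient = 0, ancient_ages_bp = NULL,
                    theta = 4, demography = demography_expansion(0.6, 100),
                    split_time = 3, seed = seed)
}

# per-haplotype true labels (NA when a haplotype mixes demes)
truth_by_haplotype <- function(ht, truth) {
  lab <- stats::setNames(truth$samples$haplogroup, truth$samples$sample_id)
  tapply(lab[names(ht$assignment)], ht$assignment,
         function(z) if (length(unique(z)) == 1L) z[[1L]] else NA_character_)
}

# seed haplotypes: the most common haplotype of each true haplogroup
seed_haps <- function(ht, truth) {
  lab <- stats::setNames(truth$samples$haplogroup, truth$samples$sample_id)
  pick <- function(g, avoid = character(0)) {
    tab <- sort(table(ht$assignment[names(lab)[lab == g]]), decreasing = TRUE)
    setdiff(names(tab), avoid)[1L]
  }
  s1 <- pick("1")
  list(s1 = s1, s2 = pick("2", avoid = s1))
}
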