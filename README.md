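# wolfmtdna

Population-genetic analysis of short mtDNA control-region alignments,
built around a classic ancient-DNA question: the European grey wolf
carries two mitochondrial haplogroups today at roughly 76% / 24%, yet
almost every ancient wolf sequenced from the last glacial period belongs
to the now-minor haplogroup. Did one matriline largely replace the other?
`wolfmtdna` provides, for anyone working with this kind of data
(phylogeographers, ancient-DNA labs, conservation geneticists), the full
computational chain needed to ask and answer that question on their own
alignments — plus a seeded coalescent generator so every stage is testable
without touching real data.

## What it computes

* **Haplotypes and sites** — collapse aligned sequences (alphabet
  `A,C,G,T,-,N`) into haplotypes under an explicit step convention (a
  contiguous gap run is one indel event; `N` sites are excluded pairwise);
  classify variable sites as transitions, transversions or indels.
* **Diversity and expansion statistics** — haplotype diversity
  *H<sub>D</sub>* = n/(n−1)·(1−Σp<sub>h</sub>²), nucleotide diversity π,
  mean pairwise differences *d*, the ratio *s/d*; Fu's
  *F<sub>s</sub>* = ln(S′/(1−S′)) with S′ the Ewens-sampling probability
  of at least the observed haplotype count (Stirling numbers in log space,
  coalescent null for the p-value); the mismatch distribution with a
  least-squares sudden-expansion fit F<sub>j</sub>(τ, θ₀) and Harpending's
  raggedness r with a parametric-bootstrap test.
* **Statistical-parsimony networks** — TCS-style construction with
  inferred intermediates, flagged alternative connections, the 95%
  connection limit computed from sequence length (6 steps at 230 bp), and
  seed-based haplogroup partitioning; between-haplogroup divergence
  d<sub>XY</sub> and net d<sub>A</sub> = d<sub>XY</sub> − (d<sub>X</sub>+d<sub>Y</sub>)/2.
* **Rarefaction** — analytic hypergeometric haplotype accumulation
  E[K<sub>m</sub>] and a Clench-asymptote extrapolation of total richness
  with a bootstrap SE.
* **Ancient-vs-modern binomial tests** — exact log-space point and tail
  probabilities of an ancient haplogroup configuration under modern
  frequencies, and the smallest haplogroup frequency that would make the
  observation plausible at a given α.
* **Synthetic data** — a Hudson-style structured coalescent (two demes,
  split, migration, sudden expansion, serial ancient sampling) with
  finite-sites, transition-biased, indel-capable mutation.

## Worked example

Simulate a study-structured dataset and run the full pipeline:

```r
library(wolfmtdna)

cfg <- run_config(out_dir = "out",
                  sim = simulation_config(seed = 1),
                  seed = 1)
bundle <- run_full_analysis(cfg)

print(bundle$stats$diversity)
#> n = 947, haplotypes k = 32, s = 40, d = 4.447, pi = 0.0193, Hd = 0.822, s/d = 9.00
print(bundle$stats$fs)
#> Fu's Fs = -2.800 (k = 32, theta_hat = 4.447, S' = 0.0574), P = 0.317 [1000 reps]
print(bundle$network$divergence)
#> d_XY = 0.0406, d_X = 0.0060, d_Y = 0.0099, net d_A = 0.0326 (n = 711/260)
```

A high *H<sub>D</sub>* with low π and high *s/d*, a negative
*F<sub>s</sub>*, and a smooth mismatch distribution are the joint
signature of a recent demographic expansion; the network separates the
two simulated haplogroups (net divergence d<sub>A</sub> ≈ 0.03 per site
here) and recovers every haplotype's true haplogroup.

The ancient-vs-modern argument at the published frequency configuration —
modern haplogroups at 76% / 24% and 23 of 24 ancient samples in
haplogroup 2:

```r
modern  <- frequency_table(data.frame(label = c(rep("1", 76), rep("2", 24)),
                                      region = "europe"), "region")
ancient <- frequency_table(data.frame(label = c("1", rep("2", 23)),
                                      region = "europe"), "region")
compare_ancient_modern(modern, ancient)
#> modern haplogroup-2 frequency: 0.240
#> ancient composition: 23 of 24 in haplogroup 2
#> P(exactly 23 of 24 | modern freq) = 1.01e-13
#> P(at least 23 of 24 | modern freq) = 1.03e-13
#> haplogroup-2 frequency needed for P >= 0.05: 82.5%
```

Drawing 23 of 24 from a 24%-frequency haplogroup has probability
~10<sup>−13</sup>; the ancient composition only becomes plausible (P ≥
0.05) if that haplogroup's frequency was at least 82.5% — the
quantitative core of the replacement argument.

## The analysis compendium

`analysis/` holds the numbered drivers that reproduce the whole study
flow on the synthetic dataset, writing their tables under `results/`:

```sh
Rscript analysis/01_simulate.R             # dataset + truth record
Rscript analysis/02_haplotypes.R           # haplotype table, variable sites
Rscript analysis/03_diversity_expansion.R  # Hd/pi/s/d, Fs, mismatch fit
Rscript analysis/04_network_haplogroups.R  # network, partition, divergence
Rscript analysis/05_rarefaction.R          # richness extrapolation
Rscript analysis/06_ancient_binomial.R     # frequency tables + binomial report
```

Run them in order; each prints a short narrative of what it found.

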