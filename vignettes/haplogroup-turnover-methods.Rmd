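---
title: "Methods: haplotype networks, expansion statistics and ancient-vs-modern haplogroup tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype networks, expansion statistics and ancient-vs-modern haplogroup tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`wolfmtdna` implements the population-genetic computations behind a classic
phylogeographic question: did one mitochondrial haplogroup of European grey
wolves replace another in frequency between the late Pleistocene and today?
The package takes short aligned mtDNA control-region fragments with
per-sample metadata (locality, region, radiocarbon age) and carries them
through haplotype collapsing, diversity and demographic-expansion
statistics, statistical-parsimony network construction with haplogroup
partitioning, rarefaction-based richness extrapolation, and exact binomial
tests of ancient-versus-modern haplogroup composition. A seeded coalescent
generator produces synthetic datasets with the same structure, so the whole
pipeline is testable without any sequence download.

This vignette is the package's methodological record: the conventions, the
models, the tunable parameters and their defaults, the numerical choices,
and the limits of what the synthetic-data tests demonstrate.

## Distance and haplotype conventions

All statistics rest on one mutational-step convention (`seq_compare()`):

* sites where either sequence carries `N` are excluded pairwise;
* a base–base difference is one step;
* a maximal run of contiguous columns in which the same sequence is gapped
  and the other is not is **one** indel event (one step). Columns that are
  masked or gapped in both sequences are transparent — they neither count
  as differences nor break a run.

The gap-run rule mirrors how a single insertion/deletion spanning several
alignment columns is counted as one mutational step when two haplogroups
are described as "five steps apart". Where an alignment distinguishes
haplotypes only inside a shared gap region, this one-event-per-run rule is
a genuine choice; alignments that weight every gap column separately will
count more steps.

Two samples share a haplotype iff they are zero steps apart. Sequences
containing `N` are compared on their `N`-free columns; when this makes a
sequence compatible with more than one haplotype it merges into the
*earliest* one — a deterministic, conservative rule for a situation the
underlying data leave ambiguous. Haplotype ids `h1, h2, ...` follow first
appearance in the input, and all reported positions are 1-based inclusive.

## Diversity summaries

For `n` sequences, `diversity_summary()` reports the segregating-site count
`s`, the mean pairwise step count
\(d = \binom{n}{2}^{-1}\sum_{i<j} k_{ij}\), nucleotide diversity
\(\pi = d / L_{\mathrm{eff}}\) with \(L_{\mathrm{eff}}\) the mean number of
pairwise comparable (non-`N`) sites, the unbiased haplotype diversity
\(H_D = \frac{n}{n-1}\bigl(1-\sum_h p_h^2\bigr)\), and the ratio \(s/d\).
Recent demographic expansion inflates the number of rare variants, so high
\(H_D\), low \(\pi\) and a high \(s/d\) together are an expansion
signature. Pairwise comparisons are made between haplotype representatives
and weighted by haplotype counts, so the cost scales with the number of
haplotypes rather than samples.

Between-group divergence (`group_divergence()`) reports
\(d_{XY}\) (mean per-site divergence over all between-group pairs), the
within-group diversities and the net divergence
\(d_A = d_{XY} - (d_X + d_Y)/2\), which strips ancestral polymorphism out
of the raw between-group distance. Within-group diversities here are
frequency-weighted (ordered pairs including self-comparisons,
\(d_X=\sum_{ij}d_{ij}/n^2\)): that is the convention under which two
identical groups have exactly \(d_A = 0\), and it differs from the
unbiased pairwise mean by a factor \((n-1)/n\), negligible at the sample
sizes this pipeline targets.

## Fu's Fs

`fu_fs()` estimates \(\hat\theta\) by `d`, computes the probability under
the Ewens sampling distribution of seeing at least the observed number of
haplotypes,
\[
S' = \sum_{k \ge k_{obs}} \frac{|S_1(n,k)|\,\hat\theta^k}
      {\prod_{i=0}^{n-1}(\hat\theta+i)},
\]
and reports \(F_s = \ln\!\bigl(S'/(1-S')\bigr)\). The unsigned Stirling
numbers of the first kind are computed by their additive recurrence
entirely in log space — at \(n \approx 950\) they exceed \(10^{2400}\), so
a linear-space log-sum-exp sweep is the only viable route. For \(n = 2\)
the definition collapses to \(F_s = \ln\hat\theta\) exactly, which the
tests exploit as a closed-form oracle.

The p-value is the lower tail — the fraction of neutral, constant-size
coalescent replicates at \(\hat\theta\) whose \(F_s\) (re-estimated from
each replicate's own `d` and haplotype count) is at most the observed
value. More negative is more extreme; following the test's original
calibration, significance is conventionally declared at `P < 0.02`.
`theta_hat = d` is likewise the original estimator choice. Replicates with
a single haplotype or zero pairwise differences have \(S'=1\); they are
assigned \(F_s=+\infty\) and so never count toward the lower tail.

## Mismatch distribution and the sudden-expansion model

`mismatch_distribution()` tabulates relative frequencies of pairwise step
counts. With `dedup = TRUE` the sample is first reduced to one
representative per (haplotype, locality): a haplotype common in one local
population is counted once there, but counted again for each additional
local population where it occurs. Without the rule, locally abundant
haplotypes flood the zero-difference class; removing copies entirely would
erase the geographic replication the analysis cares about.

The sudden-expansion expectation with a large post-expansion size is the
convolution of a geometric (the pre-expansion equilibrium at
\(\theta_0\)) with a Poisson (the \(\tau\) mutational time units since
expansion):
\[
F_j(\tau, \theta_0) = \sum_{i=0}^{j}
  e^{-\tau}\frac{\tau^{\,j-i}}{(j-i)!}\;
  \frac{\theta_0^{\,i}}{(1+\theta_0)^{\,i+1}} .
\]
`fit_sudden_expansion()` minimises the summed squared deviation between
the observed vector and \(F_j\) with `optim` (L-BFGS-B) over
\(\tau \in [0, 2d_{max}]\), \(\theta_0 \in [0, d]\), from five grid starts
(convergence tolerance 1e-8); the multi-start guards against the shallow
ridge the two parameters form when the observed hump is wide. Harpending's
raggedness
\(r = \sum_{i=1}^{d_{max}+1}(x_i - x_{i-1})^2\) (with a trailing zero
class) is small for the smooth unimodal distributions of expanded
populations. Its p-value is an upper-tail parametric bootstrap: coalescent
replicates under the *fitted* expansion (final size represented by
\(\theta_1 = 1000\), i.e. effectively infinite on the scale of any fitted
\(\theta_0\)), same sample size, each refitted, counting replicates with
\(r_{sim} \ge r_{obs}\). A single-class observed vector returns \(r = 1\)
with a warning and no fit. `simulate_mismatch_null()` exposes the
bootstrap's simulator; the test suite uses it to confirm that p-values are
approximately uniform under the model itself (fraction below 0.05 within
[0.01, 0.12] across 200 model-true replicates).

The bootstrap presumes the idealized infinite-sites expansion model. Data
from the finite-sites generator (or reality) are slightly more ragged than
that ideal, so p-values on such data lean anti-conservative; the test is
best read, as usual, as a goodness-of-fit screen rather than a sharp test.

## Statistical-parsimony networks

Haplotype networks are built TCS-style: pairs are connected in
non-decreasing step distance, a connection at distance \(k\) introduces
\(k-1\) inferred intermediate nodes, and connections stop at the
*connection limit* — the largest distance at which a parsimonious (no
superimposed changes) connection remains credible at the chosen
confidence.

For the limit, the package fixes the following estimator
(`parsimony_probability()`): with \(j\) observed differences over \(L\)
sites, take the maximum-likelihood per-site divergence \(p = j/L\) under a
Jukes–Cantor correction, \(\lambda = -\frac{3}{4}\log(1-\frac{4p}{3})\);
the probability that a site showing a difference experienced exactly one
substitution is then
\(u_j = \lambda e^{-\lambda}/p\) (Poisson hits, conditioned on a visible
difference), and the probability that a \(j\)-step connection is
parsimonious is aggregated over its \(j-1\) inferred intermediates:
\(P_j = u_j^{\,j-1}\), with \(P_1 = 1\) (a single step is always
parsimonious). The limit is the largest \(j\) with \(P_j\) above the
confidence level. The exponent convention is anchored on the published
95% limit of **6 steps for 230 bp** control-region alignments; with it,
57 bp fragments connect to 3 steps and 661 bp fragments to 10, and the
limit is monotone in both fragment length and confidence. The limit is
computed on the full alignment length, indel columns included.

Within one distance level, the components are snapshotted at the level
start; every connection that would re-join components already merged at
the same level is kept but flagged `is_alternative` — the dashed
"alternative mutational connections" of published networks. Ambiguous
loops are therefore retained and flagged, never resolved by extra rules,
and ties in processing order are broken lexicographically by haplotype id
so networks are reproducible. Nested-clade nesting rules are deliberately
out of scope: haplogroup membership is decided on the network directly.

`partition_haplogroups()` labels every sampled haplotype by the seed set
(one per haplogroup) with the strictly shorter shortest-path distance,
over all edges including alternatives; ties and unreachable haplotypes
stay `unassigned` rather than being forced — the fate of genuinely
ambiguous haplotypes in the source system.

## Rarefaction and richness extrapolation

`rarefaction_curve()` is the analytic hypergeometric expectation
\[
E[K_m] = \sum_h \Bigl[1 - \tbinom{n-n_h}{m}\big/\tbinom{n}{m}\Bigr],
\]
with log-space binomial coefficients (overflow-free at \(n \approx 950\)).
`estimate_total_richness()` fits the asymptotic accumulation (Clench /
Michaelis–Menten) model \(K(m) = K_{max}m/(B+m)\) to the curve by least
squares (`nls` with a Michaelis–Menten self-start, bounded `optim` as
fallback) and reports \(K_{max}\) with a standard error from bootstrap
resamples of individuals. **This extrapolation is a methodological
substitution**: the richness-extrapolation procedure originally used with
such data is not fully specified in the accessible record, so the package
fixes a standard, deterministic-given-seed alternative with the same
"total expected richness ± SE" semantics.

Calibration: the Clench asymptote is meaningful when a rare tail of
haplotypes remains partly unsampled (Zipf-like abundance distributions —
the regime matching an observed-27, expected-29 situation). When every
haplotype is already observed the asymptote sits slightly above the
observed count with a misleadingly small bootstrap SE, and under extremely
tail-heavy truths it underestimates; the test suite demonstrates recovery
under a \(1/i^2\) abundance truth and the package documentation says no
more than that.

## Exact binomial tests of ancient composition

`binomial_tail()` and `binomial_point()` are exact log-space summations
(no normal approximation), reliable down to probabilities of order
1e-300. For the headline question — 23 of 24 ancient samples in a
haplogroup whose modern frequency is 24% — the probability of that
composition is the *point* mass \(P(X = 23)\), \(1.01\times10^{-13}\);
the upper tail \(P(X \ge 23)\) is \(1.03\times10^{-13}\). The package
computes both and `compare_ancient_modern()` reports both.

`min_frequency_for_alpha()` inverts the point probability: the smallest
haplogroup-2 frequency \(q\) at which
\(P(X=k\,|\,n,q) = \binom{n}{k}q^k(1-q)^{n-k}\) reaches \(\alpha\), found
by bisection on the increasing branch \(q < k/n\) to \(|\Delta q| <
10^{-6}\). For (24, 23, 0.05) the root is 0.8247 — "at least 82.5%". The
point-mass convention is used here because it is the only one consistent
with that published threshold (the tail crosses 0.05 near 81.7%); the
convention is fixed and stated rather than silently assumed. If even the
maximum over \(q\) (at \(q = k/n\)) is below \(\alpha\), the function
returns `NULL` with a diagnostic.

## The synthetic-data generator

`simulate_dataset()` wraps a hand-written Hudson-style coalescent for one
non-recombining locus: two haplogroup demes that merge (backwards) at
`split_time`, optional symmetric migration, piecewise-constant deme sizes
(constant, or a sudden `factor`-fold expansion at a given time), and
serially sampled ancient tips that enter the genealogy at their age.
Mutations fall on branches as a Poisson process at rate \(\theta/2\) per
lineage per coalescent unit; each is a single-column event — a
transition with probability \(\kappa/(\kappa+2)\), otherwise one of the
two transversions, or (with probability `indel_prob`) a gap toggle.
Time is measured in units of \(N_f\) generations (\(N_f\) the female
effective size), so ancient ages convert via
`age_bp / (gen_time * n_e)`.

Defaults are the study conditions the pipeline was designed around:

| parameter | default | rationale |
|---|---|---|
| `n_modern`, `n_ancient` | 947, 24 | the sample sizes of the motivating dataset |
| `L` | 230 | the fragment every modern sequence shares |
| `theta` | 3 | centres ~27 modern haplotypes, \(H_D\approx0.85\), \(\pi\approx0.02\) at n=947 |
| `demography` | expansion ×100 at 0.6 | star-like within-haplogroup genealogies; negative Fs, smooth mismatch |
| `split_time` | 2.3 | trunk separation \(\approx\theta(split-t_e)\approx5\) steps between haplogroups |
| `hap2_fraction_modern` | 0.24 | modern haplogroup-2 frequency |
| `region_weights` | iberia .10 (fixed hg 1), apennine .05 (fixed hg 2), rest admixed | peninsular fixation; admixed regions get hg 2 at ~0.22 so the overall expectation is 0.24 |
| `ts_tv_ratio` | 6 | with `indel_prob = 0.2`, reproduces the 3 transitions : 1 transversion : 1 indel step mix |
| `ancient_ages_bp` | 20 ages 44,000–15,000 + 4 ages 2,000–1,200 | near-uniform coverage with the 14,000–2,000 B.P. gap unsampled |
| `ancient_hap2_prob` | 23/24 | ancient samples almost all from the minor modern haplogroup |
| `ancient_window` | columns 10–66 | the 57 bp fragment ancient DNA permits |
| `gen_time`, `n_e` | 3 y, 50,000 | 44,000 B.P. ≈ 0.3 coalescent units — ancient tips genuinely inside the genealogy |

A single non-recombining locus has enormous evolutionary variance: across
seeds the realised haplotype number at these defaults ranges roughly
20–35 and \(\pi\) can vary two-fold. The generator is therefore used for
*structural* and *directional* validation — label recovery, frequency
laws, expansion-vs-constant contrasts, internal consistency — not for
matching any single dataset's point estimates.

What the generator does **not** emulate: sequencing or alignment error,
ancient-DNA damage, multi-column indels, rate heterogeneity along the
fragment, spatially explicit structure (locality labels within a region
are arbitrary), selection, recombination. Tests passing on synthetic data
show the machinery is correct under the model's assumptions; they cannot
certify conventions (e.g. gap weighting) chosen differently by other
software on real alignments.

## Numerical and design choices, in one place

* Ewens/Stirling: log-space recurrence + log-sum-exp; exact to double
  precision, validated against exhaustive Chinese-restaurant enumeration
  for \(n \le 8\).
* Mismatch fit: bounded L-BFGS-B, 5 grid starts, tolerance 1e-8; optimiser
  boundary excursions clamped; degenerate single-class vectors short-cut.
* Raggedness p-value: upper tail; Fs p-value: lower tail.
* Bisection roots to \(10^{-7}\), so a plugged-back probability is within
  \(10^{-5}\) of \(\alpha\).
* Network tie-breaks: lexicographic (distance, id-pair); alternative edges
  retained, loops unresolved.
* All Monte-Carlo entry points take an explicit integer seed and restore
  the caller's RNG state; default replicate counts are 1000 (Fs), 500
  (raggedness bootstrap and richness bootstrap).
* Degenerate inputs fail loudly: a single haplotype or \(d=0\) make Fs
  undefined (error), `s/d` is `NULL` at \(d=0\), empty strata are dropped
  with warnings, unassigned samples are excluded with a logged count.

Problem sizes in the shipped test suite are chosen to exercise every code
path at full fidelity while staying comfortably interactive: synthetic
datasets of 25–200 samples (947 for the frequency-law checks, where only
metadata are consumed downstream), 100-seed directional contrasts, a
200-replicate bootstrap-calibration study, and a 100,000-draw rarefaction
resampling oracle.

## Known limitations

* The parsimony-probability formula is a fixed, anchored convention (see
  above); other statistical-parsimony implementations may place the limit
  one step differently at other lengths.
* \(\pi\) uses pairwise-deletion comparable lengths; software that deletes
  columns listwise, or excludes indel columns globally, will differ in the
  third decimal on gappy alignments.
* The Clench richness asymptote is only calibrated for moderately skewed
  abundance distributions (see the rarefaction section).
* The raggedness bootstrap inherits the idealized sudden-expansion model;
  its p-values are approximate for structured or finite-sites data.
* The coalescent generator treats ancient sampling times as exact and
  conversion to coalescent units as known; uncertainty in ages, generation
  time and \(N_f\) is not propagated.
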