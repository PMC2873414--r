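#' Configuration for the synthetic two-haplogroup dataset generator
#'
#' Defaults emulate the structure of the European wolf control-region data
#' the pipeline was built around: ~950 modern 230 bp sequences falling into
#' two haplogroups at unequal frequencies (~76/24), two peninsular regions
#' each fixed for one haplogroup, a recent ~100-fold demographic expansion,
#' a between-haplogroup separation of about five mutational steps with a
#' transition-biased substitution mix including occasional indels, and a
#' small serially sampled ancient subset (ages 44,000-1,200 years B.P.,
#' with the 14,000-2,000 B.P. window unsampled) drawn almost entirely from
#' the minor modern haplogroup.
#'
#' @param n_modern,n_ancient numbers of modern and ancient samples.
#' @param L alignment length in sites.
#' @param theta scaled mutation rate 2*N*mu per locus for the reference deme.
#' @param demography a [demography_constant()] or [demography_expansion()]
#'   descriptor, applied to both haplogroup demes.
#' @param split_time haplogroup-deme split, coalescent units before present.
#' @param migration_rate per-lineage scaled migration rate between demes.
#' @param hap2_fraction_modern expected haplogroup-2 fraction among modern
#'   samples.
#' @param ts_tv_ratio kappa, the transition/transversion rate bias.
#' @param indel_prob per-mutation probability of an indel event (single
#'   column gap toggle).
#' @param ancient_ages_bp ages of the ancient samples, years before present.
#' @param ancient_hap2_prob probability that an ancient sample descends from
#'   the haplogroup-2 deme.
#' @param ancient_window columns retained by [make_ancient_subsample()]
#'   (1-based inclusive), emulating the short ancient fragments.
#' @param gen_time generation time in years (converts ages to generations).
#' @param n_e mitochondrial effective population size of the reference deme
#'   (converts generations to coalescent units).
#' @param region_weights named numeric vector of modern sampling weights for
#'   regions `iberia` (fixed haplogroup 1), `apennine` (fixed haplogroup 2)
#'   and the admixed regions.
#' @param seed integer seed; identical seeds give byte-identical datasets.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_modern = 947, n_ancient = 24, L = 230,
                              theta = 3,
                              demography = demography_expansion(0.6, 100),
                              split_time = 2.3, migration_rate = 0,
                              hap2_fraction_modern = 0.24,
                              ts_tv_ratio = 6, indel_prob = 0.2,
                              ancient_ages_bp = c(
                                round(seq(44000, 15000, length.out = 20)),
                                2000, 1700, 1450, 1200),
                              ancient_hap2_prob = 23 / 24,
                              ancient_window = c(10, 66),
                              gen_time = 3, n_e = 50000,
                              region_weights = c(iberia = 0.10,
                                                 apennine = 0.05,
                                                 central = 0.25,
                                                 eastern = 0.50,
                                                 balkans = 0.10),
                              seed = 1) {
  cfg <- list(n_modern = n_modern, n_ancient = n_ancient, L = L,
              theta = theta, demography = demography,
              split_time = split_time, migration_rate = migration_rate,
              hap2_fraction_modern = hap2_fraction_modern,
              ts_tv_ratio = ts_tv_ratio, indel_prob = indel_prob,
              ancient_ages_bp = ancient_ages_bp,
              ancient_hap2_prob = ancient_hap2_prob,
              ancient_window = ancient_window,
              gen_time = gen_time, n_e = n_e,
              region_weights = region_weights, seed = seed)
  .validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

.validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_modern >= 0, n_ancient >= 0, L >= 1, theta >= 0,
              split_time >= 0, migration_rate >= 0,
              hap2_fraction_modern >= 0, hap2_fraction_modern <= 1,
              ts_tv_ratio >= 0, indel_prob >= 0, indel_prob <= 1,
              gen_time > 0, n_e > 0)
    if (n_modern + n_ancient < 2)
      stop("config error: need at least 2 samples in total")
    if (n_ancient > 0 && length(ancient_ages_bp) == 0)
      stop("config error: n_ancient > 0 but no ancient ages given")
    if (n_ancient == 0 && length(ancient_ages_bp) > 0)
      stop("config error: ancient ages given but n_ancient = 0")
    if (!is.null(ancient_window) &&
        (ancient_window[1L] < 1 || ancient_window[2L] > L ||
         ancient_window[1L] > ancient_window[2L]))
      stop("config error: ancient_window outside [1, L]")
    w <- region_weights
    if (!all(c("iberia", "apennine") %in% names(w)))
      stop("config error: region_weights needs 'iberia' and 'apennine'")
  })
  invisible(cfg)
}

#' Simulate a two-haplogroup mtDNA dataset
#'
#' Draws a structured-coalescent genealogy for two haplogroup demes that
#' split `split_time` coalescent units ago (with optional migration and a
#' shared demography), drops finite-sites mutations at rate `theta/2` per
#' lineage per unit (transition bias `kappa`, occasional single-column gap
#' toggles), and emits the resulting alignment with locality/region/age
#' metadata plus a truth record. Modern samples are assigned to regions and
#' demes so that the realised haplogroup-2 fraction matches
#' `hap2_fraction_modern` in expectation, with the two peninsular regions
#' fixed for one haplogroup each; ancient samples enter the genealogy
#' serially at their ages.
#'
#' @param cfg a [simulation_config()].
#' @return list with `alignment` (a [haplo_alignment()] of all modern +
#'   ancient samples, full length) and `truth` (list: per-sample `samples`
#'   data.frame with the true deme/haplogroup, `tmrca`, `config`, `seed`).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)

  w <- cfg$region_weights / sum(cfg$region_weights)
  mixed <- setdiff(names(w), c("iberia", "apennine"))
  w_mixed <- sum(w[mixed])
  q_mixed <- (cfg$hap2_fraction_modern - w[["apennine"]]) / w_mixed
  q_mixed <- min(max(q_mixed, 0), 1)

  region <- character(0); deme <- integer(0)
  if (cfg$n_modern > 0) {
    region <- sample(names(w), cfg$n_modern, replace = TRUE, prob = w)
    deme <- ifelse(region == "iberia", 1L,
                   ifelse(region == "apennine", 2L, NA_integer_))
    nm <- is.na(deme)
    deme[nm] <- 1L + stats::rbinom(sum(nm), 1L, q_mixed)
  }
  locality <- ifelse(region %in% c("iberia", "apennine"), region,
                     paste0(region, "_", sample(1:2, length(region),
                                                replace = TRUE)))
  ids <- if (cfg$n_modern > 0) paste0("m", seq_len(cfg$n_modern)) else character(0)
  times <- rep(0, cfg$n_modern)
  ages <- rep(NA_real_, cfg$n_modern)

  if (cfg$n_ancient > 0) {
    a_ages <- rep_len(sort(cfg$ancient_ages_bp, decreasing = TRUE),
                      cfg$n_ancient)
    a_deme <- 1L + stats::rbinom(cfg$n_ancient, 1L, cfg$ancient_hap2_prob)
    ids <- c(ids, paste0("a", seq_len(cfg$n_ancient)))
    region <- c(region, rep("ancient_europe", cfg$n_ancient))
    locality <- c(locality, paste0("anc", seq_len(cfg$n_ancient)))
    deme <- c(deme, a_deme)
    times <- c(times, a_ages / (cfg$gen_time * cfg$n_e))
    ages <- c(ages, a_ages)
  }

  tree <- sim_genealogy(times, deme, demography = cfg$demography,
                        split_time = cfg$split_time,
                        migration = cfg$migration_rate)
  seqs <- .evolve_sequences(tree, cfg$L, cfg$theta, cfg$ts_tv_ratio,
                            cfg$indel_prob)
  rownames(seqs) <- ids
  meta <- data.frame(sample_id = ids, locality = locality, region = region,
                     age_bp = ages, stringsAsFactors = FALSE)
  aln <- haplo_alignment(seqs, meta)
  truth <- list(samples = data.frame(sample_id = ids,
                                     haplogroup = as.character(deme),
                                     region = region, age_bp = ages,
                                     stringsAsFactors = FALSE),
                tmrca = max(tree$time), config = cfg, seed = cfg$seed)
  list(alignment = aln, truth = truth)
}

# finite-sites sequence evolution down a genealogy
.evolve_sequences <- function(tree, L, theta, kappa, indel_prob) {
  n_nodes <- length(tree$parent)
  n <- tree$n_tips
  bases <- c("A", "C", "G", "T")
  seqs <- matrix(NA_character_, n_nodes, L)
  ord <- order(tree$time, decreasing = TRUE)    # parents before children
  seqs[ord[1L], ] <- sample(bases, L, replace = TRUE)
  for (v in ord[-1L]) {
    s <- seqs[tree$parent[v], ]
    n_mut <- stats::rpois(1L, theta / 2 * tree$edge_length[v])
    if (n_mut > 0L) s <- .mutate(s, n_mut, kappa, indel_prob)
    seqs[v, ] <- s
  }
  seqs[seq_len(n), , drop = FALSE]
}

.mutate <- function(s, n_mut, kappa, indel_prob) {
  bases <- c("A", "C", "G", "T")
  ts_of <- c(A = "G", G = "A", C = "T", T = "C")
  for (i in seq_len(n_mut)) {
    site <- sample.int(length(s), 1L)
    if (stats::runif(1L) < indel_prob) {
      s[site] <- if (s[site] == "-") sample(bases, 1L) else "-"
    } else {
      cur <- s[site]
      if (cur == "-") next            # substitution falls in a deleted column
      if (stats::runif(1L) < kappa / (kappa + 2)) {
        s[site] <- ts_of[[cur]]
      } else {
        s[site] <- sample(setdiff(bases, c(cur, ts_of[[cur]])), 1L)
      }
    }
  }
  s
}

#' Draw a biased, truncated ancient-style subsample
#'
#' Samples `n` individuals (haplogroup 2 with probability `hap2_bias` per
#' draw, without replacement within haplogroup pools), truncates the
#' alignment to `window`, and attaches ages.
#'
#' @param aln a [haplo_alignment()], e.g. from [simulate_dataset()].
#' @param truth the matching truth record (for the haplogroup pools).
#' @param n subsample size.
#' @param hap2_bias per-draw probability of drawing from haplogroup 2.
#' @param window `c(start, end)` columns to keep, 1-based inclusive.
#' @param seed integer seed.
#' @param ages optional ages (years B.P.) to attach to the subsample,
#'   recycled to length `n`; by default existing ages are kept.
#' @return a [haplo_alignment()] of the subsample.
#' @export
make_ancient_subsample <- function(aln, truth, n, hap2_bias, window,
                                   seed = 1, ages = NULL) {
  stopifnot(inherits(aln, "haplo_alignment"))
  if (n > aln$n) stop("subsample larger than the alignment")
  if (window[1L] < 1 || window[2L] > aln$L || window[1L] > window[2L])
    stop("window [", window[1L], ", ", window[2L],
         "] out of range for L = ", aln$L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lab <- stats::setNames(truth$samples$haplogroup, truth$samples$sample_id)
  pool2 <- rownames(aln$seq)[lab[rownames(aln$seq)] == "2"]
  pool1 <- rownames(aln$seq)[lab[rownames(aln$seq)] == "1"]
  picked <- character(0)
  for (i in seq_len(n)) {
    want2 <- stats::runif(1L) < hap2_bias
    from2 <- if (want2) length(pool2) > 0 else length(pool1) == 0
    if (from2) {
      j <- sample.int(length(pool2), 1L)
      picked <- c(picked, pool2[j]); pool2 <- pool2[-j]
    } else {
      j <- sample.int(length(pool1), 1L)
      picked <- c(picked, pool1[j]); pool1 <- pool1[-j]
    }
  }
  sub <- haplo_alignment(aln$seq[picked, , drop = FALSE],
                         aln$meta[match(picked, aln$meta$sample_id), ])
  sub <- extract_window(sub, window[1L], window[2L])
  if (!is.null(ages)) sub$meta$age_bp <- rep_len(ages, n)
  sub
}
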