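#' Configuration for a full pipeline run
#'
#' Either a FASTA + metadata pair or a [simulation_config()] provides the
#' input alignment. All Monte-Carlo stages are seeded from `seed`.
#'
#' @param fasta,metadata input paths (aligned FASTA; TSV metadata), or NULL
#'   when simulating.
#' @param sim a [simulation_config()], or NULL when reading files.
#' @param out_dir output directory (created if needed).
#' @param seed master seed for all stochastic stages.
#' @param n_reps_fs coalescent replicates for Fu's Fs.
#' @param n_reps_boot parametric-bootstrap replicates for the raggedness test
#'   and bootstrap resamples for the richness SE.
#' @param confidence statistical-parsimony connection confidence.
#' @param strata_key metadata column for frequency strata (default region).
#' @param seeds1,seeds2 seed haplotype ids for haplogroup partitioning; when
#'   NULL they are derived from the simulation truth (majority haplotype of
#'   each true haplogroup) or, for file input, from the most distant
#'   haplotype pair.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, fasta = NULL, metadata = NULL, sim = NULL,
                       seed = 1, n_reps_fs = 1000, n_reps_boot = 500,
                       confidence = 0.95, strata_key = "region",
                       seeds1 = NULL, seeds2 = NULL) {
  if (is.null(sim) && is.null(fasta))
    stop("either `fasta` or `sim` must be given")
  if (!is.null(fasta) && !file.exists(fasta))
    stop("input file does not exist: ", fasta)
  if (!is.null(metadata) && !file.exists(metadata))
    stop("input file does not exist: ", metadata)
  structure(list(fasta = fasta, metadata = metadata, sim = sim,
                 out_dir = out_dir, seed = seed, n_reps_fs = n_reps_fs,
                 n_reps_boot = n_reps_boot, confidence = confidence,
                 strata_key = strata_key, seeds1 = seeds1, seeds2 = seeds2),
            class = "run_config")
}

#' Run the full haplogroup-turnover analysis
#'
#' Orchestrates the pipeline end to end: haplotype collapsing and site
#' classification; diversity, Fu's Fs and mismatch/sudden-expansion
#' statistics; statistical-parsimony network and haplogroup partitioning
#' with between-haplogroup divergence; rarefaction richness; haplogroup
#' frequency tables by stratum and time with the exact binomial
#' ancient-vs-modern comparison. Every output is written under
#' `cfg$out_dir` together with a manifest (input hashes or simulation seed,
#' package and R versions, per-stage runtimes). Deterministic given
#' `cfg$seed`.
#'
#' @param cfg a [run_config()].
#' @return the report bundle (named list of stage results), invisibly.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list()
  manifest <- list(seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("wolfmtdna")),
                   r_version = R.version.string,
                   stages = list())
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr),
                    error = function(e) stop("stage '", name, "' failed: ",
                                             conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    out
  }

  bundle$input <- stage("input", {
    if (!is.null(cfg$sim)) {
      sim <- simulate_dataset(cfg$sim)
      manifest$input <- list(type = "simulated", sim_seed = cfg$sim$seed)
      sim
    } else {
      aln <- read_alignment(cfg$fasta, cfg$metadata)
      hashes <- tools::md5sum(c(cfg$fasta, cfg$metadata))
      manifest$input <- list(type = "files",
                              md5 = as.list(hashes[!is.na(hashes)]))
      list(alignment = aln, truth = NULL)
    }
  })
  aln <- bundle$input$alignment
  truth <- bundle$input$truth

  bundle$haplotypes <- stage("haplotypes", {
    ht <- collapse_haplotypes(aln)
    write_haplotype_table(ht, file.path(cfg$out_dir, "haplotype_table.tsv"))
    sites <- classify_sites(aln)
    utils::write.table(sites$sites,
                       file.path(cfg$out_dir, "variable_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(table = ht, sites = sites)
  })
  ht <- bundle$haplotypes$table

  bundle$stats <- stage("stats", {
    modern <- .modern_subset(aln)
    div <- diversity_summary(modern)
    fs <- fu_fs(modern, n_reps = cfg$n_reps_fs, seed = cfg$seed + 101L)
    mm <- mismatch_distribution(modern, dedup = TRUE)
    fit <- fit_sudden_expansion(mm, n_reps = cfg$n_reps_boot,
                                seed = cfg$seed + 202L)
    utils::write.table(
      data.frame(differences = seq_along(fit$observed) - 1L,
                 observed = fit$observed, expected = fit$expected),
      file.path(cfg$out_dir, "mismatch.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    out <- list(diversity = unclass(div),
                fs = unclass(fs)[c("k_obs", "theta_hat", "s_prime", "fs",
                                   "p_value", "n_reps")],
                mismatch = unclass(fit)[c("tau_hat", "theta0_hat",
                                          "raggedness", "p_value", "n_reps")])
    jsonlite::write_json(out, file.path(cfg$out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    list(diversity = div, fs = fs, mismatch = fit)
  })

  bundle$network <- stage("network", {
    limit <- parsimony_limit(aln$L, cfg$confidence)
    net <- build_network(ht, limit)
    write_network_tsv(net, file.path(cfg$out_dir, "network.tsv"))
    write_network_dot(net, file.path(cfg$out_dir, "network.dot"))
    seeds <- .derive_seeds(cfg, ht, truth)
    assign <- partition_haplogroups(net, seeds$s1, seeds$s2)
    div2 <- group_divergence(aln, assign)
    list(limit = limit, net = net, assignment = assign, divergence = div2)
  })

  bundle$rarefaction <- stage("rarefaction", {
    modern <- .modern_subset(aln)
    counts <- collapse_haplotypes(modern)$haplotypes$total_count
    rc <- estimate_total_richness(counts, n_boot = max(cfg$n_reps_boot, 100),
                                  seed = cfg$seed + 303L)
    write_rarefaction_tsv(rc, file.path(cfg$out_dir, "rarefaction_curve.tsv"))
    jsonlite::write_json(
      list(k_obs = rc$k_obs, k_total_hat = rc$k_total_hat,
           k_total_se = rc$k_total_se, n_boot = rc$n_boot),
      file.path(cfg$out_dir, "richness.json"), auto_unbox = TRUE, digits = NA)
    rc
  })

  bundle$haplogroups <- stage("haplogroups", {
    lab <- bundle$network$assignment$labels[ht$assignment]
    samples <- cbind(aln$meta, label = unname(lab))
    samples$period <- ifelse(is.na(samples$age_bp), "modern", "ancient")
    modern_s <- samples[samples$period == "modern", ]
    by_region <- frequency_table(modern_s, cfg$strata_key)
    utils::write.table(by_region, file.path(cfg$out_dir,
                                            "haplogroup_by_region.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out <- list(by_region = by_region)
    if (any(samples$period == "ancient")) {
      modern_s$stratum_all <- "modern"
      ancient_s <- samples[samples$period == "ancient", ]
      ancient_s$stratum_all <- "ancient"
      ft_modern <- frequency_table(modern_s, "stratum_all")
      ft_ancient <- frequency_table(ancient_s, "stratum_all")
      rep <- compare_ancient_modern(ft_modern, ft_ancient)
      jsonlite::write_json(
        list(modern_p2 = rep$modern_p2, ancient_n = rep$ancient_n,
             ancient_n2 = rep$ancient_n2, prob_point = rep$prob_point,
             prob_tail = rep$prob_tail,
             min_p2_for_alpha = rep$min_p2_for_alpha, alpha = rep$alpha),
        file.path(cfg$out_dir, "ancient_modern_report.json"),
        auto_unbox = TRUE, digits = NA)
      txt <- utils::capture.output(print(rep))
      writeLines(txt, file.path(cfg$out_dir, "ancient_modern_report.txt"))
      out$ancient_modern <- rep
    }
    out
  })

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  bundle$manifest <- manifest
  invisible(bundle)
}

.modern_subset <- function(aln) {
  keep <- !is_ancient(aln)
  if (sum(keep) < 2L) return(aln)
  haplo_alignment(aln$seq[keep, , drop = FALSE],
                  aln$meta[keep, , drop = FALSE])
}

# seed haplotypes for the haplogroup partition: majority haplotype of each
# true group when simulation truth is available, else the most step-distant
# haplotype pair
.derive_seeds <- function(cfg, ht, truth) {
  if (!is.null(cfg$seeds1) && !is.null(cfg$seeds2))
    return(list(s1 = cfg$seeds1, s2 = cfg$seeds2))
  if (!is.null(truth)) {
    lab <- stats::setNames(truth$samples$haplogroup, truth$samples$sample_id)
    hap_of <- ht$assignment
    pick <- function(g, avoid = character(0)) {
      tab <- sort(table(hap_of[names(lab)[lab == g]]), decreasing = TRUE)
      setdiff(names(tab), avoid)[1L]
    }
    s1 <- pick("1")
    return(list(s1 = s1, s2 = pick("2", avoid = s1)))
  }
  pw <- pairwise_steps(ht$rep_seq)$steps
  far <- which(pw == max(pw), arr.ind = TRUE)[1L, ]
  list(s1 = rownames(pw)[far[1L]], s2 = rownames(pw)[far[2L]])
}
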