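#' Collapse aligned sequences into haplotypes
#'
#' Two samples share a haplotype iff their sequences are identical under the
#' package's step convention (zero mutational steps; see [seq_compare()]).
#' Sequences containing N are compared on their N-free columns, and when that
#' comparison is a tie with an existing haplotype the sample is merged into
#' the earliest matching haplotype. Haplotype ids `h1, h2, ...` are assigned
#' in order of first appearance in the input, and the first-seen sequence of
#' each haplotype is kept as its representative.
#'
#' @param aln a [haplo_alignment()].
#' @return an object of class `haplotype_table`: `haplotypes` (data.frame with
#'   `haplotype_id`, `representative`, `total_count`), `counts` (haplotype x
#'   locality matrix), `assignment` (sample id -> haplotype id), `rep_seq`
#'   (representative sequences as a character matrix), `n`, `L`.
#' @export
collapse_haplotypes <- function(aln) {
  stopifnot(inherits(aln, "haplo_alignment"))
  if (aln$n < 1L) stop("empty alignment")
  keys <- apply(aln$seq, 1L, paste0, collapse = "")
  first <- !duplicated(keys)
  ukeys <- keys[first]
  urows <- which(first)

  rep_rows <- integer(0)          # row index of each haplotype representative
  uniq_assign <- integer(length(ukeys))  # haplotype index per unique string
  for (u in seq_along(ukeys)) {
    row <- aln$seq[urows[u], ]
    hit <- 0L
    needs_scan <- any(row == "N") ||
      any(vapply(rep_rows, function(r) any(aln$seq[r, ] == "N"), NA))
    if (needs_scan && length(rep_rows)) {
      for (h in seq_along(rep_rows)) {
        if (seq_steps(row, aln$seq[rep_rows[h], ]) == 0L) { hit <- h; break }
      }
    }
    if (hit == 0L) {
      rep_rows <- c(rep_rows, urows[u])
      hit <- length(rep_rows)
    }
    uniq_assign[u] <- hit
  }
  hap_idx <- uniq_assign[match(keys, ukeys)]
  hap_ids <- paste0("h", seq_along(rep_rows))
  assignment <- stats::setNames(hap_ids[hap_idx], rownames(aln$seq))

  loc <- aln$meta$locality
  counts <- table(factor(hap_ids[hap_idx], levels = hap_ids),
                  factor(loc, levels = sort(unique(loc))))
  counts <- unclass(counts)
  rep_seq <- aln$seq[rep_rows, , drop = FALSE]
  rownames(rep_seq) <- hap_ids
  haplotypes <- data.frame(
    haplotype_id = hap_ids,
    representative = apply(rep_seq, 1L, paste0, collapse = ""),
    total_count = as.integer(rowSums(counts)),
    stringsAsFactors = FALSE)
  structure(list(haplotypes = haplotypes, counts = counts,
                 assignment = assignment, rep_seq = rep_seq,
                 n = aln$n, L = aln$L),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype table:", nrow(x$haplotypes), "haplotypes from", x$n,
      "samples (", ncol(x$counts), "localities )\n")
  invisible(x)
}

#' Write a haplotype table as long-format TSV
#'
#' One row per (haplotype, locality) pair with a positive count.
#' @param ht a [collapse_haplotypes()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(ht, path) {
  stopifnot(inherits(ht, "haplotype_table"))
  long <- as.data.frame(as.table(ht$counts), stringsAsFactors = FALSE)
  names(long) <- c("haplotype_id", "locality", "count")
  long <- long[long$count > 0, ]
  long$representative_sequence <-
    ht$haplotypes$representative[match(long$haplotype_id,
                                       ht$haplotypes$haplotype_id)]
  long <- long[, c("haplotype_id", "representative_sequence",
                   "locality", "count")]
  long <- long[order(match(long$haplotype_id, ht$haplotypes$haplotype_id),
                     long$locality), ]
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify alignment columns
#'
#' A column is variable when at least two distinct non-N states occur, and
#' parsimony-informative when at least two states each occur in two or more
#' samples. The change type is read off the set of state pairs present:
#' purine-purine or pyrimidine-pyrimidine pairs are transitions, base pairs
#' across the two classes transversions, any state against a gap an indel;
#' columns mixing categories are reported as `mixed`.
#'
#' @param aln a [haplo_alignment()].
#' @return an object of class `site_classification` with `sites` (data.frame:
#'   `position`, `parsimony_informative`, `change_type` for each variable
#'   site) plus `variable_sites` and `parsimony_informative_sites` vectors.
#' @export
classify_sites <- function(aln) {
  stopifnot(inherits(aln, "haplo_alignment"))
  purine <- c("A", "G"); pyrimidine <- c("C", "T")
  pos <- integer(0); pi_flag <- logical(0); type <- character(0)
  for (j in seq_len(aln$L)) {
    col <- aln$seq[, j]
    col <- col[col != "N"]
    tab <- table(col)
    if (length(tab) < 2L) next
    states <- names(tab)
    pairs <- utils::combn(states, 2L, simplify = FALSE)
    cats <- unique(vapply(pairs, function(p) {
      if ("-" %in% p) "indel"
      else if (all(p %in% purine) || all(p %in% pyrimidine)) "transition"
      else "transversion"
    }, ""))
    pos <- c(pos, j)
    pi_flag <- c(pi_flag, sum(tab >= 2L) >= 2L)
    type <- c(type, if (length(cats) == 1L) cats else "mixed")
  }
  structure(list(
    sites = data.frame(position = pos, parsimony_informative = pi_flag,
                       change_type = type, stringsAsFactors = FALSE),
    variable_sites = pos,
    parsimony_informative_sites = pos[pi_flag],
    L = aln$L), class = "site_classification")
}

#' @export
print.site_classification <- function(x, ...) {
  cat("sites:", length(x$variable_sites), "variable (",
      length(x$parsimony_informative_sites), "parsimony-informative ) of",
      x$L, "\n")
  if (length(x$variable_sites))
    print(table(x$sites$change_type))
  invisible(x)
}
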