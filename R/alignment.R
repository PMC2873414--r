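#' Aligned mtDNA sequences with per-sample metadata
#'
#' An `haplo_alignment` is the universal input of the pipeline: an equal-length
#' character matrix over the alphabet `A,C,G,T,-,N` (rows = samples, columns =
#' alignment sites) plus a metadata table with one row per sample. Ancient
#' samples carry a radiocarbon age in years before present (`age_bp`); modern
#' samples have `age_bp = NA`.
#'
#' @param seqs character matrix (samples x sites) or a list/vector of
#'   equal-length strings; rownames/names are taken as sample ids.
#' @param meta optional data.frame with columns `sample_id`, `locality`,
#'   `region` and optionally `age_bp`. Samples absent from `meta` get
#'   `locality = region = "unknown"` and `age_bp = NA`.
#' @return an object of class `haplo_alignment` with elements `seq` (character
#'   matrix), `meta` (data.frame), `n` and `L`.
#' @export
haplo_alignment <- function(seqs, meta = NULL) {
  if (is.list(seqs) || (is.character(seqs) && is.null(dim(seqs)))) {
    v <- vapply(seqs, paste0, "", collapse = "")
    lens <- nchar(v)
    if (length(unique(lens)) > 1L) {
      bad <- names(v)[lens != lens[1L]]
      stop("length mismatch: record(s) ", paste(bad, collapse = ", "),
           " differ from the first record's length ", lens[1L])
    }
    ids <- names(v)
    if (is.null(ids)) ids <- paste0("s", seq_along(v))
    seqs <- do.call(rbind, strsplit(toupper(v), "", fixed = TRUE))
    rownames(seqs) <- ids
  }
  seqs[] <- toupper(seqs)
  ids <- rownames(seqs)
  if (is.null(ids)) {
    ids <- paste0("s", seq_len(nrow(seqs)))
    rownames(seqs) <- ids
  }
  if (anyDuplicated(ids))
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (ncol(seqs) < 1L) stop("alignment must have at least one site")
  bad <- !(seqs %in% c("A", "C", "G", "T", "-", "N"))
  dim(bad) <- dim(seqs)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop("illegal character '", seqs[w[1L], w[2L]], "' in record '",
         ids[w[1L]], "' at position ", w[2L],
         " (alphabet is A,C,G,T,-,N)")
  }
  meta <- .complete_metadata(ids, meta)
  structure(list(seq = seqs, meta = meta,
                 n = nrow(seqs), L = ncol(seqs)),
            class = "haplo_alignment")
}

.complete_metadata <- function(ids, meta) {
  out <- data.frame(sample_id = ids, locality = "unknown",
                    region = "unknown", age_bp = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    need <- c("sample_id", "locality", "region")
    miss <- setdiff(need, names(meta))
    if (length(miss))
      stop("metadata lacks required column(s): ", paste(miss, collapse = ", "))
    unknown <- setdiff(meta$sample_id, ids)
    if (length(unknown))
      stop("metadata id(s) not present in the alignment: ",
           paste(unknown, collapse = ", "))
    i <- match(ids, meta$sample_id)
    hit <- !is.na(i)
    out$locality[hit] <- as.character(meta$locality[i[hit]])
    out$region[hit] <- as.character(meta$region[i[hit]])
    if ("age_bp" %in% names(meta)) {
      age <- meta$age_bp[i[hit]]
      if (is.character(age)) {
        age[tolower(trimws(age)) %in% c("", "modern", "na")] <- NA
        age <- as.numeric(age)
      }
      if (any(age < 0, na.rm = TRUE)) stop("age_bp must be non-negative")
      out$age_bp[hit] <- age
    }
  }
  rownames(out) <- NULL
  out
}

#' Read a FASTA alignment (plus optional TSV metadata)
#'
#' Records must be pre-aligned (equal length). The metadata TSV needs columns
#' `sample_id`, `locality`, `region` and may carry `age_bp` (years before
#' present; blank or `"modern"` means a contemporary sample).
#'
#' @param path FASTA file of aligned sequences.
#' @param metadata_path optional TSV file; ids must match the FASTA ids.
#' @return a [haplo_alignment()].
#' @export
read_alignment <- function(path, metadata_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  recs <- ape::read.FASTA(path)
  if (length(recs) == 0L) stop("no sequences in ", path)
  chr <- lapply(as.character(recs), toupper)
  names(chr) <- names(recs)
  meta <- NULL
  if (!is.null(metadata_path)) {
    if (!file.exists(metadata_path)) stop("no such file: ", metadata_path)
    meta <- utils::read.delim(metadata_path, sep = "\t",
                              colClasses = "character",
                              stringsAsFactors = FALSE)
  }
  haplo_alignment(chr, meta)
}

#' Write an alignment back to FASTA (and its metadata to TSV)
#'
#' @param aln a [haplo_alignment()].
#' @param path output FASTA path.
#' @param metadata_path optional output TSV path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, metadata_path = NULL) {
  stopifnot(inherits(aln, "haplo_alignment"))
  lines <- character(2L * aln$n)
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(aln$seq))
  lines[c(FALSE, TRUE)] <- apply(aln$seq, 1L, paste0, collapse = "")
  writeLines(lines, path)
  if (!is.null(metadata_path)) {
    m <- aln$meta
    m$age_bp <- ifelse(is.na(m$age_bp), "modern", format(m$age_bp))
    utils::write.table(m, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Extract a window of alignment columns
#'
#' Used e.g. to cut the short fragment comparable with ancient sequences out
#' of a longer modern alignment. Coordinates are 1-based and inclusive.
#'
#' @param aln a [haplo_alignment()].
#' @param start,end 1-based inclusive column range, `1 <= start <= end <= L`.
#' @return a [haplo_alignment()] of length `end - start + 1` with metadata
#'   preserved.
#' @export
extract_window <- function(aln, start, end) {
  stopifnot(inherits(aln, "haplo_alignment"))
  if (start < 1 || end > aln$L || start > end)
    stop("window [", start, ", ", end, "] out of range for L = ", aln$L)
  haplo_alignment(aln$seq[, start:end, drop = FALSE], aln$meta)
}

#' @export
print.haplo_alignment <- function(x, ...) {
  anc <- sum(!is.na(x$meta$age_bp))
  cat("mtDNA alignment:", x$n, "samples x", x$L, "sites;",
      anc, "ancient,", x$n - anc, "modern\n")
  invisible(x)
}

# TRUE where the sample has a radiocarbon age
is_ancient <- function(aln) !is.na(aln$meta$age_bp)
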