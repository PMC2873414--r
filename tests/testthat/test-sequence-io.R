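test_that("FASTA + metadata round trip preserves sequences and ancient flags", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(">w1", "ACGTACGTAC", ">w2", "ACGTACGTAT", ">w3", "ACGTACGTAC"),
             fa)
  writeLines(c("sample_id\tlocality\tregion\tage_bp",
               "w1\tbialowieza\teastern\tmodern",
               "w2\tcave_a\tancient_europe\t44000"), tsv)
  aln <- read_alignment(fa, tsv)
  expect_equal(aln$n, 3L)
  expect_equal(aln$L, 10L)
  expect_equal(aln$meta$age_bp, c(NA, 44000, NA))
  expect_equal(aln$meta$region[3], "unknown")   # absent from metadata
  out_fa <- withr::local_tempfile(fileext = ".fasta")
  out_tsv <- withr::local_tempfile(fileext = ".tsv")
  write_alignment(aln, out_fa, out_tsv)
  back <- read_alignment(out_fa, out_tsv)
  expect_identical(back$seq, aln$seq)
  expect_equal(back$meta$age_bp, aln$meta$age_bp)
})

test_that("malformed inputs are rejected with informative errors", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGTACGTAC", ">b", "ACGTACGTA"), fa)   # one column short
  expect_error(read_alignment(fa), "length mismatch.*b")
  writeLines(c(">a", "ACGTA", ">a", "ACGTA"), fa)
  expect_error(read_alignment(fa), "duplicate")
  writeLines(c(">a", "ACGTA", ">b", "ACGRA"), fa)            # IUPAC ambiguity
  expect_error(read_alignment(fa), "illegal character 'R' in record 'b' at position 4")
  expect_error(read_alignment("no/such/file.fa"), "no such file")
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGTA"), fa2)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tlocality\tregion", "zz\tx\ty"), tsv)
  expect_error(read_alignment(fa2, tsv), "not present in the alignment")
})

test_that("step counting treats a shared gap run as one indel event", {
  s <- function(a, b) seq_steps(strsplit(a, "")[[1]], strsplit(b, "")[[1]])
  expect_equal(s("AA---TT", "AATTTTT"), 1L)       # 3-column gap run = 1 step
  expect_equal(s("A--AT", "ATTGT"), 2L)           # gap run + substitution
  expect_equal(s("A--AT", "AT-AT"), 1L)           # shared gap col is transparent
  expect_equal(s("A-TA-", "ATTAC"), 2L)           # two separate runs
  expect_equal(s("AANTA", "AAGTA"), 0L)           # N excluded pairwise
  expect_equal(seq_compare(strsplit("AANTA", "")[[1]],
                           strsplit("AAGTA", "")[[1]])$comparable, 4L)
})

test_that("haplotype collapsing matches exhaustive pairwise comparison", {
  # identity case: 4 identical sequences over 2 localities
  a <- aln_fix(rep("ACGT", 4), locality = c("locA", "locA", "locA", "locB"))
  ht <- collapse_haplotypes(a)
  expect_equal(nrow(ht$haplotypes), 1L)
  expect_equal(ht$haplotypes$total_count, 4L)
  expect_equal(as.vector(ht$counts["h1", c("locA", "locB")]), c(3L, 1L))

  # 5-sequence toy, 2 variable sites, 3 distinct patterns
  seqs <- c(a1 = "AACGT", a2 = "AACGT", a3 = "AACGA", a4 = "AGCGT",
            a5 = "AACGA")
  ht2 <- collapse_haplotypes(aln_fix(seqs))
  expect_equal(nrow(ht2$haplotypes), 3L)
  # oracle: brute-force pairwise identity partition
  same <- outer(seqs, seqs, Vectorize(function(x, y) naive_diffs(x, y) == 0))
  expect_equal(length(unique(apply(same, 1, paste, collapse = ""))), 3L)
  # deterministic first-appearance ids
  expect_equal(unname(ht2$assignment), c("h1", "h1", "h2", "h3", "h2"))
})

test_that("sequences containing N merge into the earliest compatible haplotype", {
  a <- aln_fix(c(x = "AATT", y = "AANT", z = "AAGT"))
  ht <- collapse_haplotypes(a)
  expect_equal(unname(ht$assignment), c("h1", "h1", "h2"))
  expect_equal(ht$haplotypes$representative[1], "AATT")
})

test_that("collapsing conserves counts and is idempotent", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(5:25, 1)
    mat <- matrix(sample(c("A", "C", "G", "T"), n * 12, replace = TRUE,
                         prob = c(.55, .15, .15, .15)), n, 12)
    aln <- haplo_alignment(mat)
    ht <- collapse_haplotypes(aln)
    expect_equal(sum(ht$haplotypes$total_count), n)
    expect_equal(sum(ht$counts), n)
    ht2 <- collapse_haplotypes(haplo_alignment(ht$rep_seq))
    expect_equal(nrow(ht2$haplotypes), nrow(ht$haplotypes))
    expect_equal(ht2$haplotypes$representative, ht$haplotypes$representative)
  }
})

test_that("site classification identifies variability, informativeness and change type", {
  a <- aln_fix(c("AAGT", "AAGT", "AGGT", "AAG-"))
  cl <- classify_sites(a)
  expect_equal(cl$variable_sites, c(2L, 4L))
  expect_equal(cl$sites$change_type, c("transition", "indel"))
  expect_false(any(cl$sites$parsimony_informative))

  b <- aln_fix(c("AA", "AA", "GG", "GC"))       # col1 A/G twice each
  cl2 <- classify_sites(b)
  expect_equal(cl2$parsimony_informative_sites, 1L)
  expect_equal(cl2$sites$change_type[1], "transition")
  expect_equal(cl2$sites$change_type[2], "mixed")  # A/G ts + A/C, G/C tv

  c3 <- aln_fix(c("AAAC", "AAAC", "AAAC"))
  expect_length(classify_sites(c3)$variable_sites, 0L)

  # a {A,A,A,C} column is variable, uninformative, transversion
  d4 <- aln_fix(c("A", "A", "A", "C"))
  cl4 <- classify_sites(d4)
  expect_equal(cl4$variable_sites, 1L)
  expect_false(cl4$sites$parsimony_informative[1])
  expect_equal(cl4$sites$change_type[1], "transversion")
})

test_that("window extraction preserves metadata and validates bounds", {
  a <- aln_fix(c(x = paste(rep("ACGTA", 46), collapse = ""),
                 y = paste(rep("ACGTT", 46), collapse = "")),
               age_bp = c(NA, 2700))
  expect_equal(a$L, 230L)
  w <- extract_window(a, 10, 66)
  expect_equal(w$L, 57L)
  expect_equal(w$meta$age_bp, c(NA, 2700))
  expect_identical(extract_window(a, 1, a$L)$seq, a$seq)
  expect_error(extract_window(a, 50, 20), "out of range")
  expect_error(extract_window(a, 0, 57), "out of range")
  expect_error(extract_window(a, 200, 231), "out of range")
})

test_that("windowing to the full length leaves the haplotype partition unchanged", {
  set.seed(7)
  mat <- matrix(sample(c("A", "G"), 15 * 8, replace = TRUE, prob = c(.8, .2)),
                15, 8)
  aln <- haplo_alignment(mat)
  h1 <- collapse_haplotypes(aln)$assignment
  h2 <- collapse_haplotypes(extract_window(aln, 1, 8))$assignment
  expect_identical(h1, h2)
})
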