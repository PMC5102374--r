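aln_from <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(setNames(seqs, paste0("s", seq_along(seqs))))
}

test_that("gap-free alignments are returned unchanged", {
  aln <- aln_from("ACGT", "ACGT", "ACGA")
  res <- trim_alignment_ends(aln)
  expect_equal(as.character(res$alignment), as.character(aln))
  expect_length(res$removed_left, 0)
  expect_length(res$removed_right, 0)
})

test_that("leading columns above the missing threshold are trimmed, strictly", {
  # columns 1-3: 4/5 missing (0.8 > 0.6) -> removed from the left;
  # column 4: 2/5 (0.4) -> scanning stops there
  aln <- aln_from("---ACGTACGT--",
                  "---ACGTACGTAA",
                  "--NACGTACGTAA",
                  "N--ACGTACGTAA",
                  "AAAACGTACGTAA")
  res <- trim_alignment_ends(aln, 0.6)
  expect_equal(res$removed_left, 1:3)
  # right end: last column has 1/5 missing (0.2) -> kept
  expect_length(res$removed_right, 0)
  expect_equal(unique(Biostrings::width(res$alignment)), 10L)

  # a column with exactly 60% missing (3/5) is retained: "more than" is strict
  aln2 <- aln_from("-ACGT", "-ACGT", "NACGT", "AACGT", "AACGT")
  res2 <- trim_alignment_ends(aln2, 0.6)
  expect_length(res2$removed_left, 0)
})

test_that("both ends trim independently and interior columns survive", {
  # interior column 5 is all-gap but must never be removed
  aln <- aln_from("--AC-GT--",
                  "--AC-GT--",
                  "--AC-GT--",
                  "AAAC-GTAA")
  res <- trim_alignment_ends(aln, 0.6)
  expect_equal(res$removed_left, 1:2)
  expect_equal(res$removed_right, 8:9)
  expect_true(grepl("-", as.character(res$alignment[[1L]]), fixed = TRUE))
})

test_that("trimming is idempotent on random gappy alignments", {
  set.seed(14)
  for (i in 1:25) {
    n <- sample(3:8, 1); L <- sample(10:40, 1)
    chars <- matrix(sample(c("A", "C", "G", "T", "-", "N"), n * L, TRUE,
                           prob = c(rep(0.2, 4), 0.15, 0.05)), n, L)
    aln <- Biostrings::DNAStringSet(setNames(apply(chars, 1, paste,
                                                   collapse = ""),
                                             paste0("s", 1:n)))
    res1 <- tryCatch(trim_alignment_ends(aln), error = function(e) NULL)
    if (is.null(res1)) next  # everything-missing alignments legitimately fail
    res2 <- trim_alignment_ends(res1$alignment)
    expect_equal(as.character(res2$alignment),
                 as.character(res1$alignment))
    expect_length(res2$removed_left, 0)
    expect_length(res2$removed_right, 0)
  }
})

test_that("alignment IO validates shape and round-trips", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "AC-GU", ">b", "ACNGT"), path)
  aln <- read_alignment(path)
  expect_equal(as.character(aln[["a"]]), "AC-GT")  # U -> T
  out <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, out)
  expect_equal(as.character(read_alignment(out)), as.character(aln))
  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "AC"), bad)
  expect_error(read_alignment(bad), "differ in length")
})

test_that("percent identity: direct counts, symmetry, bounds", {
  expect_equal(as.numeric(percent_identity("ACGTACGT", "ACGTACGT")), 100)
  expect_equal(as.numeric(percent_identity("AAAA", "AATT")), 50)
  # gap-gap columns excluded; gap-base compared and non-identical
  expect_equal(as.numeric(percent_identity("A-CG--", "AAC---")), 50)
  set.seed(6)
  for (i in 1:10) {
    a <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    ab <- as.numeric(percent_identity(a, b))
    expect_equal(ab, as.numeric(percent_identity(b, a)))
    expect_gte(ab, 0); expect_lte(ab, 100)
  }
  expect_error(percent_identity("", "ACGT"), "empty")
  expect_error(percent_identity("ACG", "ACGT"), "equal-length")
})

test_that("local mode recovers a known substitution load on long sequences", {
  set.seed(8)
  n <- 1500
  a <- sample(c("A", "C", "G", "T"), n, TRUE)
  b <- a
  idx <- sample(n, 39)  # 2.6% substitutions -> 97.4% identity
  for (i in idx) b[i] <- sample(setdiff(c("A", "C", "G", "T"), a[i]), 1)
  pid <- percent_identity(paste(a, collapse = ""), paste(b, collapse = ""),
                          mode = "local")
  expect_equal(as.numeric(pid), 100 * (n - 39) / n, tolerance = 0.003)
  expect_match(attr(pid, "definition"), "local")
})
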