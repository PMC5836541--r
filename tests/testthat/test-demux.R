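test_that("exact and singly-corrupted codewords decode to their sample", {
  cb <- demo_codebook(sprintf("s%02d", 1:6))
  expect_equal(decode_index(cb$index, cb), cb$sample_id)
  # brute force over every single-substitution neighbour of every codeword
  for (i in seq_len(nrow(cb))) {
    cw <- cb$index[i]
    for (pos in 1:9) {
      for (b in setdiff(c("A", "C", "G", "T"), substr(cw, pos, pos))) {
        mut <- cw
        substr(mut, pos, pos) <- b
        expect_equal(decode_index(mut, cb), cb$sample_id[i])
      }
    }
  }
})

test_that("indices far from every codeword stay unassigned", {
  cb <- demo_codebook(c("a", "b"))
  hd <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  # search double mutations of codeword 1 for a probe at distance >= 2
  # from every codeword (must exist for a distance->=3 code)
  probe <- NULL
  bases <- c("A", "C", "G", "T")
  for (p1 in 1:8) for (b1 in setdiff(bases, substr(cb$index[1], p1, p1))) {
    cand <- cb$index[1]
    substr(cand, p1, p1) <- b1
    p2 <- p1 + 1
    for (b2 in setdiff(bases, substr(cb$index[1], p2, p2))) {
      cand2 <- cand
      substr(cand2, p2, p2) <- b2
      if (all(vapply(cb$index, hd, integer(1), x = cand2) >= 2)) {
        probe <- cand2
        break
      }
    }
    if (!is.null(probe)) break
  }
  expect_false(is.null(probe))
  expect_true(is.na(decode_index(probe, cb)))
  expect_true(is.na(decode_index("ACGT", cb)))     # wrong length
})

test_that("barcode mapping tolerates one edit and refuses ambiguity", {
  lib <- tibble::tibble(mutant_id = c("m1", "m2"),
                        uptag = c("ACGTACGTACGTACGTACGT",
                                  "TTGCATGCATGCATGCATGC"))
  expect_equal(map_barcode(lib$uptag, lib), lib$mutant_id)
  # one deletion
  expect_equal(map_barcode(substr(lib$uptag[1], 2, 20), lib), "m1")
  # one substitution (A -> C at position 5)
  sub1 <- lib$uptag[2]; substr(sub1, 5, 5) <- "C"
  expect_equal(map_barcode(sub1, lib), "m2")
  # two edits away: unmapped (second substitution A -> C at position 9)
  sub2 <- sub1; substr(sub2, 9, 9) <- "C"
  expect_true(is.na(map_barcode(sub2, lib)))
  # a read exactly between two barcodes differing at 2 positions
  amb_lib <- tibble::tibble(mutant_id = c("a", "b"),
                            uptag = c("AAAAACCCCC", "AAAAACCCCT"))
  between <- "AAAAACCCCG"   # distance 1 from both
  expect_true(is.na(map_barcode(between, amb_lib)))
  # nearest-distance wins: exact beats distance 1
  expect_equal(map_barcode("AAAAACCCCC", amb_lib), "a")
})

test_that("FASTQ round trip with no errors reproduces counts exactly", {
  lib <- demo_library(8)
  counts <- tibble::tibble(mutant_id = lib$mutant_id,
                           sA = c(5L, 0L, 3L, 1L, 7L, 2L, 0L, 4L),
                           sB = c(1L, 2L, 0L, 0L, 9L, 1L, 3L, 0L))
  cb <- demo_codebook(c("sA", "sB"))
  fq <- emit_fastq(counts, lib, cb, error_rate = 0, seed = 1)
  expect_length(fq, 4 * sum(counts$sA + counts$sB))
  res <- build_counts(fq, cb, lib)
  expect_equal(res$counts, counts)
  expect_equal(res$report$assigned, res$report$total)
})

test_that("read counts are conserved across assignment categories", {
  lib <- demo_library(6)
  cb <- demo_codebook(c("x", "y"))
  counts <- tibble::tibble(mutant_id = lib$mutant_id,
                           x = rep(10L, 6), y = rep(5L, 6))
  fq <- emit_fastq(counts, lib, cb, error_rate = 0.02, seed = 7)
  res <- build_counts(fq, cb, lib)
  r <- res$report
  expect_equal(r$assigned + r$unassigned_index + r$unmapped_barcode, r$total)
  # counting a concatenation equals the sum of counting the parts
  res2 <- build_counts(c(fq, fq), cb, lib)
  expect_equal(as.matrix(res2$counts[-1]), 2 * as.matrix(res$counts[-1]))
})

test_that("one index error plus one barcode error is still recovered", {
  lib <- demo_library(4)
  cb <- demo_codebook(c("s1", "s2"))
  fl <- barseq_flanks()
  read <- paste0(cb$index[1], fl[["U1"]], lib$uptag[2], fl[["U2"]])
  substr(read, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(read, 3, 3))[1]
  bpos <- 9L + nchar(fl[["U1"]]) + 4L  # inside the barcode
  substr(read, bpos, bpos) <- setdiff(c("A", "C", "G", "T"),
                                      substr(read, bpos, bpos))[1]
  fq <- c("@r1", read, "+", strrep("I", nchar(read)))
  res <- build_counts(fq, cb, lib)
  expect_equal(res$counts$s1[2], 1)
  expect_equal(res$report$assigned, 1)
})

test_that("low-rate substitution errors are almost always recovered", {
  # at 0.001/base on ~65-nt reads, >= 99% of reads carry at most one error
  # per segment (binomial bound), so the tolerant matchers recover them
  lib <- demo_library(10)
  cb <- demo_codebook(c("s1", "s2"))
  counts <- tibble::tibble(mutant_id = lib$mutant_id,
                           s1 = rep(300L, 10), s2 = rep(200L, 10))
  fq <- emit_fastq(counts, lib, cb, error_rate = 0.001, seed = 21)
  res <- build_counts(fq, cb, lib)
  expect_gte(res$report$assigned / res$report$total, 0.99)
})

test_that("empty streams and empty tables behave", {
  lib <- demo_library(3)
  cb <- demo_codebook("only")
  empty <- tibble::tibble(mutant_id = lib$mutant_id, only = c(0L, 0L, 0L))
  expect_length(emit_fastq(empty, lib, cb), 0)
  res <- build_counts(character(0), cb, lib)
  expect_equal(sum(as.matrix(res$counts[-1])), 0)
  expect_equal(res$report$total, 0)
})

test_that("duplicate barcodes are rejected at emission and mapping", {
  lib <- tibble::tibble(mutant_id = c("m1", "m2"),
                        uptag = c("ACGTACGTAC", "ACGTACGTAC"))
  cb <- demo_codebook("s")
  counts <- tibble::tibble(mutant_id = c("m1", "m2"), s = c(1L, 1L))
  expect_error(emit_fastq(counts, lib, cb), "duplicate")
  expect_error(map_barcode("ACGTACGTAC", lib), "duplicate")
})

test_that("generated codebooks respect the minimum pairwise distance", {
  cb <- make_index_codebook(sprintf("s%d", 1:20), seed = 5)
  d <- utils::adist(cb$index, cb$index)
  diag(d) <- 99
  expect_gte(min(d), 3)
})
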