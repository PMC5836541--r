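#' Universal flanking sequences of the uptag barcode
#'
#' U1 lies upstream and U2 downstream of the strain-specific uptag in the
#' deletion-collection cassette; sequencing reads emitted by [emit_fastq()]
#' have the layout `index9 + U1 + uptag + U2` (read orientation, 5' to 3').
#'
#' @return Named character vector with elements `U1` and `U2`.
#' @export
barseq_flanks <- function() {
  c(U1 = "GATGTCCACGAGGTCTCT", U2 = "GTCGACCTGCAGCGTACG")
}

#' Random uptag barcode library
#'
#' @param mutant_ids Character vector of mutant ids.
#' @param length Barcode length in nucleotides (default 20, the uptag length).
#' @param min_dist Minimum pairwise Hamming distance enforced between
#'   barcodes (default 3, so single-error-tolerant mapping is unambiguous).
#' @param seed Integer seed.
#' @return Tibble of class `"pf_barcode_library"`: `mutant_id`, `uptag`.
#' @export
random_barcode_library <- function(mutant_ids, length = 20, min_dist = 3,
                                   seed = 1L) {
  seqs <- generate_distant_codes(length(mutant_ids), length, min_dist, seed)
  tibble::new_tibble(
    list(mutant_id = mutant_ids, uptag = seqs),
    class = "pf_barcode_library"
  )
}

#' Sample-index codebook with guaranteed error-correction capacity
#'
#' Generates 9-nt (by default) sample indices whose minimum pairwise Hamming
#' distance is at least `min_dist`; with `min_dist = 3` every single
#' substitution error is correctable.
#'
#' @param sample_ids Character vector of sample ids.
#' @param length Index length (default 9).
#' @param min_dist Minimum pairwise Hamming distance (default 3).
#' @param seed Integer seed.
#' @return Tibble of class `"pf_codebook"`: `sample_id`, `index`.
#' @export
make_index_codebook <- function(sample_ids, length = 9, min_dist = 3,
                                seed = 1L) {
  seqs <- generate_distant_codes(length(sample_ids), length, min_dist, seed)
  tibble::new_tibble(
    list(sample_id = sample_ids, index = seqs),
    class = "pf_codebook"
  )
}

# rejection-samples random DNA words keeping pairwise Hamming distance >= d
generate_distant_codes <- function(n, len, min_dist, seed) {
  set.seed(seed)
  alphabet <- c("A", "C", "G", "T")
  chosen <- matrix(NA_integer_, nrow = 0, ncol = len)
  tries <- 0L
  while (nrow(chosen) < n) {
    tries <- tries + 1L
    if (tries > 200L * n + 1000L)
      stop("could not build a code set with the requested distance", call. = FALSE)
    cand <- sample.int(4L, len, replace = TRUE)
    if (nrow(chosen) == 0L ||
        min(rowSums(chosen != matrix(cand, nrow(chosen), len, byrow = TRUE))) >= min_dist) {
      chosen <- rbind(chosen, cand)
    }
  }
  apply(chosen, 1L, function(i) paste(alphabet[i], collapse = ""))
}

#' Emit BAR-Seq reads for a count table
#'
#' Writes one read per count, of the form `index9 + U1 + uptag + U2`, with
#' independent per-base substitution errors at `error_rate` and constant
#' Phred+33 dummy qualities. The multiset of error-free reads exactly matches
#' the count table.
#'
#' @param counts Count tibble (`mutant_id` + one integer column per sample).
#' @param library A [random_barcode_library()]-style tibble
#'   (`mutant_id`, `uptag`); barcodes must be unique.
#' @param codebook A [make_index_codebook()]-style tibble
#'   (`sample_id`, `index`) covering every sample column.
#' @param error_rate Per-base substitution probability (default 0).
#' @param seed Integer seed (read shuffling and errors).
#' @param path Output FASTQ path (plain or `.gz`); `NULL` returns the lines.
#' @return Invisibly `path`, or the character vector of FASTQ lines when
#'   `path` is `NULL`.
#' @export
emit_fastq <- function(counts, library, codebook, error_rate = 0, seed = 1L,
                       path = NULL) {
  stopifnot(is.data.frame(counts), "mutant_id" %in% names(counts))
  if (anyDuplicated(library$uptag))
    stop("duplicate barcodes in library", call. = FALSE)
  if (error_rate < 0 || error_rate >= 1)
    stop("`error_rate` must be in [0, 1)", call. = FALSE)
  sample_cols <- setdiff(names(counts), "mutant_id")
  if (!all(sample_cols %in% codebook$sample_id))
    stop("codebook is missing indices for some samples", call. = FALSE)
  if (!all(counts$mutant_id %in% library$mutant_id))
    stop("library is missing barcodes for some mutants", call. = FALSE)
  set.seed(seed)
  fl <- barseq_flanks()
  uptag <- library$uptag[match(counts$mutant_id, library$mutant_id)]
  index <- codebook$index[match(sample_cols, codebook$sample_id)]

  reads <- character(0)
  for (j in seq_along(sample_cols)) {
    n <- round(counts[[sample_cols[j]]])
    keep <- n > 0
    if (!any(keep)) next
    reads <- c(reads, rep(paste0(index[j], fl[["U1"]], uptag[keep], fl[["U2"]]),
                          n[keep]))
  }
  if (length(reads) > 0) {
    reads <- sample(reads)
    if (error_rate > 0) reads <- mutate_bases(reads, error_rate)
  }
  qual <- vapply(nchar(reads), function(k) strrep("I", k), character(1))
  lines <- as.vector(rbind(paste0("@read", seq_along(reads)), reads,
                           "+", qual))
  if (length(reads) == 0) lines <- character(0)
  if (is.null(path)) return(lines)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# independent per-base substitutions to a different nucleotide
mutate_bases <- function(reads, rate) {
  alphabet <- c("A", "C", "G", "T")
  lens <- nchar(reads)
  n_err <- stats::rbinom(length(reads), lens, rate)
  hit <- which(n_err > 0)
  for (i in hit) {
    pos <- sample.int(lens[i], n_err[i])
    chars <- strsplit(reads[i], "")[[1]]
    for (p in pos) chars[p] <- sample(setdiff(alphabet, chars[p]), 1)
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Read the sequence lines of a FASTQ file
#' @param path FASTQ path (plain or gzip), or a character vector of FASTQ
#'   lines.
#' @return Character vector of read sequences.
#' @export
read_fastq_seqs <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) {
    con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
    on.exit(close(con))
    readLines(con)
  } else {
    path
  }
  if (length(lines) == 0) return(character(0))
  if (length(lines) %% 4 != 0) {
    warning("FASTQ stream truncated; dropping incomplete trailing record")
    lines <- lines[seq_len(4 * (length(lines) %/% 4))]
  }
  lines[seq(2, length(lines), by = 4)]
}
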