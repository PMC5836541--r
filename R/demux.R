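#' Hamming distances between equal-length sequences and one reference
#'
#' @param x Character vector of sequences.
#' @param ref Single reference sequence; all must share its length.
#' @return Integer vector of mismatch counts (`NA` on length mismatch).
#' @keywords internal
hamming_to <- function(x, ref) {
  len <- nchar(ref)
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(x) & nchar(x) == len
  if (!any(ok)) return(out)
  mism <- integer(sum(ok))
  xs <- x[ok]
  for (k in seq_len(len)) {
    mism <- mism + (substr(xs, k, k) != substr(ref, k, k))
  }
  out[ok] <- mism
  out
}

#' Error-correcting decode of 9-nt sample indices
#'
#' Assigns each observed index to the unique codeword at Hamming distance
#' <= 1. With a codebook of minimum pairwise distance >= 3 this corrects every
#' single substitution error unambiguously. Sequences of the wrong length, at
#' distance >= 2 from every codeword, or (for a degenerate codebook) tied
#' between codewords are returned unassigned (`NA`).
#'
#' @param observed Character vector of observed index sequences.
#' @param codebook A [make_index_codebook()] tibble (`sample_id`, `index`).
#' @return Character vector of sample ids, `NA` where unassigned.
#' @examples
#' cb <- make_index_codebook(c("s1", "s2"), seed = 3)
#' decode_index(cb$index, cb)
#' @export
decode_index <- function(observed, codebook) {
  stopifnot(all(c("sample_id", "index") %in% names(codebook)))
  dmat <- vapply(codebook$index, function(cw) hamming_to(observed, cw),
                 integer(length(observed)))
  dmat <- matrix(dmat, nrow = length(observed))
  assign_nearest(dmat, codebook$sample_id, max_dist = 1)
}

#' Levenshtein-tolerant mapping of uptag barcodes to mutants
#'
#' Maps each observed barcode to the mutant whose uptag is nearest in edit
#' (Levenshtein) distance, provided that distance is <= `max_dist` and the
#' nearest hit is unique; ties at the minimal distance are never guessed and
#' return `NA`. An exact match always beats a distance-1 match.
#'
#' @param observed Character vector of extracted barcode sequences.
#' @param library Barcode library tibble (`mutant_id`, `uptag`).
#' @param max_dist Maximal edit distance (default 1).
#' @return Character vector of mutant ids, `NA` where unmapped.
#' @export
map_barcode <- function(observed, library, max_dist = 1) {
  stopifnot(all(c("mutant_id", "uptag") %in% names(library)))
  if (anyDuplicated(library$uptag))
    stop("duplicate barcodes in library", call. = FALSE)
  out <- rep(NA_character_, length(observed))
  ok <- which(!is.na(observed) & nzchar(observed))
  if (length(ok) == 0) return(out)
  dmat <- utils::adist(observed[ok], library$uptag)
  out[ok] <- assign_nearest(dmat, library$mutant_id, max_dist = max_dist)
  out
}

# nearest-codeword assignment: unique minimum within max_dist, else NA
assign_nearest <- function(dmat, labels, max_dist) {
  n <- nrow(dmat)
  out <- rep(NA_character_, n)
  if (n == 0) return(out)
  dmin <- do.call(pmin, c(as.data.frame(dmat), na.rm = FALSE))
  hit <- which(!is.na(dmin) & dmin <= max_dist)
  for (i in hit) {
    at <- which(dmat[i, ] == dmin[i])
    if (length(at) == 1L) out[i] <- labels[at]
  }
  out
}

# locate U1/U2 flanks (<= 1 mismatch each) and extract the uptag between them;
# the U2 anchor is searched at offsets consistent with a 1-indel barcode
extract_uptag <- function(reads, barcode_lengths) {
  fl <- barseq_flanks()
  u1 <- fl[["U1"]]; u2 <- fl[["U2"]]
  u1_start <- 10L
  u1_end <- u1_start + nchar(u1) - 1L
  tag_start <- u1_end + 1L
  u1_mism <- hamming_to(substr(reads, u1_start, u1_end), u1)
  out <- rep(NA_character_, length(reads))
  lens <- sort(unique(unlist(lapply(barcode_lengths,
                                    function(L) c(L - 1L, L, L + 1L)))))
  lens <- lens[lens >= 1L]
  best_mism <- rep(Inf, length(reads))
  u2n <- nchar(u2)
  for (L in lens) {
    u2_start <- tag_start + L
    u2_obs <- substr(reads, u2_start, u2_start + u2n - 1L)
    # tolerate truncated U2 at the read end: compare over the observed prefix
    cmp_len <- pmin(nchar(u2_obs), u2n)
    mism <- rep(NA_integer_, length(reads))
    for (cl in unique(cmp_len[cmp_len > 0])) {
      idx <- which(cmp_len == cl)
      mism[idx] <- hamming_to(substr(u2_obs[idx], 1, cl), substr(u2, 1, cl))
    }
    good <- !is.na(mism) & mism <= 1 & mism < best_mism
    if (any(good)) {
      out[good] <- substr(reads[good], tag_start, u2_start - 1L)
      best_mism[good] <- mism[good]
    }
  }
  flank_ok <- !is.na(u1_mism) & u1_mism <= 1
  out[!flank_ok] <- NA_character_
  out
}

#' Build a count table from a FASTQ stream
#'
#' Demultiplexes sample indices with single-error Hamming correction, locates
#' the U1/U2 flanks (one mismatch tolerated in each), maps the uptag between
#' them to a mutant within Levenshtein distance 1, and tabulates assigned
#' reads into a mutant x sample count table. Reads with an undecodable index
#' are counted as `unassigned_index`; reads whose index decodes but whose
#' barcode cannot be located or mapped are `unmapped_barcode` (flank-location
#' failures are additionally itemized).
#'
#' @param fastq FASTQ path (plain or gzip) or character vector of FASTQ lines.
#' @param codebook Sample-index codebook (`sample_id`, `index`).
#' @param library Barcode library (`mutant_id`, `uptag`).
#' @return List of class `"pf_demux"`: `counts` (tibble over all library
#'   mutants x codebook samples) and `report` (totals: `total`, `assigned`,
#'   `unassigned_index`, `unmapped_barcode`, `flank_failures`).
#' @export
build_counts <- function(fastq, codebook, library) {
  seqs <- read_fastq_seqs(fastq)
  n_total <- length(seqs)
  mat <- matrix(0L, nrow = nrow(library), ncol = nrow(codebook),
                dimnames = list(library$mutant_id, codebook$sample_id))
  report <- list(total = n_total, assigned = 0L, unassigned_index = 0L,
                 unmapped_barcode = 0L, flank_failures = 0L)
  if (n_total > 0) {
    tab <- table(seqs)
    uniq <- names(tab)
    wt <- as.integer(tab)
    sample_id <- decode_index(substr(uniq, 1, 9), codebook)
    idx_ok <- !is.na(sample_id)
    report$unassigned_index <- sum(wt[!idx_ok])
    tags <- rep(NA_character_, length(uniq))
    tags[idx_ok] <- extract_uptag(uniq[idx_ok],
                                  unique(nchar(library$uptag)))
    flank_fail <- idx_ok & is.na(tags)
    report$flank_failures <- sum(wt[flank_fail])
    mutant_id <- rep(NA_character_, length(uniq))
    mutant_id[!is.na(tags)] <- map_barcode(tags[!is.na(tags)], library)
    assigned <- idx_ok & !is.na(mutant_id)
    report$unmapped_barcode <- sum(wt[idx_ok & !assigned])
    report$assigned <- sum(wt[assigned])
    if (any(assigned)) {
      agg <- stats::aggregate(
        wt[assigned],
        by = list(mutant = mutant_id[assigned], sample = sample_id[assigned]),
        FUN = sum)
      mat[cbind(match(agg$mutant, rownames(mat)),
                match(agg$sample, colnames(mat)))] <- agg$x
    }
  }
  counts <- tibble::tibble(mutant_id = rownames(mat)) |>
    dplyr::bind_cols(tibble::as_tibble(mat))
  structure(list(counts = counts, report = report), class = "pf_demux")
}

#' @export
print.pf_demux <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("<pf_demux> %d reads: %d assigned, %d unassigned index, ",
                     "%d unmapped barcode (%d flank failures)\n"),
              r$total, r$assigned, r$unassigned_index, r$unmapped_barcode,
              r$flank_failures))
  invisible(x)
}
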