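#' Discard poorly covered, poorly correlated samples
#'
#' A sample is discarded when it fails BOTH quality criteria: its total count
#' is below `min_total` AND the mean Pearson correlation of its log mutant
#' frequencies with the other replicates of the same condition and day falls
#' below `min_replicate_correlation`. A deeply sequenced sample is therefore
#' always retained, as is a shallow one that still agrees with its replicates.
#'
#' @param counts Count tibble (`mutant_id` + sample columns).
#' @param samples Sample sheet (`sample_id`, `condition`, `day`, `replicate`).
#' @param min_total Total-count floor (default 300000).
#' @param min_replicate_correlation Correlation floor (default 0.5).
#' @return List: `counts` and `samples` restricted to retained samples, and
#'   `discarded` (tibble of discarded sample ids with their totals and mean
#'   replicate correlations).
#' @export
filter_samples <- function(counts, samples, min_total = 3e5,
                           min_replicate_correlation = 0.5) {
  sample_cols <- setdiff(names(counts), "mutant_id")
  stopifnot(all(sample_cols %in% samples$sample_id))
  totals <- vapply(counts[sample_cols], sum, numeric(1))
  logf <- vapply(counts[sample_cols],
                 function(x) log10(x / max(sum(x), 1) + 1e-9),
                 numeric(nrow(counts)))
  colnames(logf) <- sample_cols
  meta <- samples[match(sample_cols, samples$sample_id), ]
  mean_cor <- vapply(seq_along(sample_cols), function(j) {
    mates <- which(meta$condition == meta$condition[j] &
                     meta$day == meta$day[j] &
                     seq_along(sample_cols) != j)
    if (length(mates) == 0) return(NA_real_)
    mean(stats::cor(logf[, j], logf[, mates, drop = FALSE]))
  }, numeric(1))
  drop <- totals < min_total &
    (!is.na(mean_cor) & mean_cor < min_replicate_correlation)
  if (all(drop)) stop("all samples discarded by quality filters", call. = FALSE)
  discarded <- tibble::tibble(sample_id = sample_cols[drop],
                              total = totals[drop],
                              mean_replicate_cor = mean_cor[drop])
  keep_cols <- c("mutant_id", sample_cols[!drop])
  list(counts = counts[keep_cols],
       samples = samples[samples$sample_id %in% sample_cols[!drop], ],
       discarded = discarded)
}

#' Discard mutants with too few counts overall
#'
#' Keeps mutants whose grand total across all samples is at least
#' `min_total_counts`; a mutant strictly below the threshold is discarded.
#'
#' @param counts Count tibble.
#' @param min_total_counts Grand-total floor (default 2000).
#' @return Filtered count tibble; discarded mutant ids in attribute
#'   `"discarded"`.
#' @export
filter_mutants <- function(counts, min_total_counts = 2000) {
  sample_cols <- setdiff(names(counts), "mutant_id")
  totals <- rowSums(counts[sample_cols])
  keep <- totals >= min_total_counts
  if (!any(keep)) stop("all mutants discarded by the count filter", call. = FALSE)
  out <- counts[keep, ]
  attr(out, "discarded") <- counts$mutant_id[!keep]
  out
}

#' Impute missing day-0 samples from donor populations
#'
#' Replaces each target column by the per-mutant median of the donor columns
#' (all populations grown in the same medium at day 0), rounded to the
#' nearest integer. Non-target columns are never altered.
#'
#' @param counts Count tibble.
#' @param target_samples Sample ids (columns) to overwrite.
#' @param donor_samples Donor sample ids sharing day 0 and growth medium.
#' @return Count tibble with target columns imputed.
#' @export
impute_missing_day0 <- function(counts, target_samples, donor_samples) {
  if (length(donor_samples) == 0)
    stop("no donor samples for day-0 imputation", call. = FALSE)
  stopifnot(all(donor_samples %in% names(counts)),
            all(target_samples %in% names(counts)))
  med <- round(apply(as.matrix(counts[donor_samples]), 1L, stats::median))
  for (s in target_samples) counts[[s]] <- med
  counts
}

#' Normalize a count table
#'
#' Computes median-of-ratios size factors against the geometric-mean
#' pseudo-reference and a variance-stabilized value per entry. The default
#' method is the negative-binomial variance-stabilizing transformation with a
#' locally fitted dispersion trend (via DESeq2); when that fit is infeasible
#' (too few mutants, non-integer counts) the transform falls back to
#' `log2(count / sizefactor + 0.5)`, which is the same monotone log2-like
#' scale without dispersion shrinkage at low counts. Downstream fitness and
#' GLM fitting use the size-factor-scaled counts, so results are invariant to
#' this choice of smooth monotone recalibration. The VST is weakly monotone
#' (it can flatten at the extreme low-count boundary of its fitted dispersion
#' trend); the `scaled` and `log2` scales are strictly monotone.
#'
#' @param counts Count tibble (`mutant_id` + sample columns), no all-zero
#'   samples.
#' @param method `"vst"` (default) or `"log2"`.
#' @return Object of class `"pf_norm"`: `norm` (variance-stabilized tibble),
#'   `scaled` (counts divided by size factors), `size_factors` (named
#'   vector), and `method` (the transform actually applied).
#' @export
normalize_counts <- function(counts, method = c("vst", "log2")) {
  method <- match.arg(method)
  sample_cols <- setdiff(names(counts), "mutant_id")
  mat <- as.matrix(counts[sample_cols])
  rownames(mat) <- counts$mutant_id
  if (any(colSums(mat) == 0))
    stop("all-zero sample column; normalization undefined", call. = FALSE)
  sf <- median_of_ratios_sf(mat)
  if (any(!is.finite(sf) | sf <= 0))
    stop("a sample shares no nonzero mutants with the reference", call. = FALSE)
  scaled <- sweep(mat, 2L, sf, "/")
  vst_mat <- NULL
  if (method == "vst") {
    vst_mat <- try_vst(mat)
    if (is.null(vst_mat)) method <- "log2"
  }
  if (is.null(vst_mat)) vst_mat <- log2(scaled + 0.5)
  as_tb <- function(m) tibble::tibble(mutant_id = counts$mutant_id) |>
    dplyr::bind_cols(tibble::as_tibble(m))
  structure(list(norm = as_tb(vst_mat), scaled = as_tb(scaled),
                 size_factors = stats::setNames(sf, sample_cols),
                 method = method),
            class = "pf_norm")
}

# DESeq2-style median-of-ratios size factors
median_of_ratios_sf <- function(mat) {
  if (requireNamespace("DESeq2", quietly = TRUE)) {
    sf <- try(DESeq2::estimateSizeFactorsForMatrix(mat), silent = TRUE)
    if (!inherits(sf, "try-error")) return(sf)
  }
  log_ref <- rowMeans(log(mat + (mat == 0) * NA), na.rm = TRUE)
  use <- is.finite(log_ref) & rowSums(mat == 0) == 0
  if (!any(use)) return(rep(NA_real_, ncol(mat)))
  apply(mat[use, , drop = FALSE], 2L,
        function(x) exp(stats::median(log(x) - log_ref[use])))
}

try_vst <- function(mat) {
  if (!requireNamespace("DESeq2", quietly = TRUE)) return(NULL)
  im <- round(mat)
  storage.mode(im) <- "integer"
  if (nrow(im) < 50) return(NULL)
  out <- try(suppressMessages(
    DESeq2::varianceStabilizingTransformation(im, blind = TRUE,
                                              fitType = "local")),
    silent = TRUE)
  if (inherits(out, "try-error")) return(NULL)
  out
}

#' @export
print.pf_norm <- function(x, ...) {
  cat(sprintf("<pf_norm> %d mutants x %d samples; transform: %s\n",
              nrow(x$norm), length(x$size_factors), x$method))
  invisible(x)
}
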