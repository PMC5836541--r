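#' Simulate a flow-cytometry event table for a two-strain competition
#'
#' Emulates FACSCalibur-style integer channel data on the 0-1023 scale: FSC
#' and SSC from a single dense Gaussian mode plus a small fraction of
#' scattered outliers, and FL1 (GFP fluorescence) bimodal with weight
#' `mix_fraction` on the GFP-positive mode. Values are rounded and clipped to
#' the instrument range, so modes placed at the range limits produce
#' saturated events.
#'
#' @param n_events Number of events (>= 1).
#' @param mix_fraction Probability that an event is GFP-positive.
#' @param gfp_modes Length-2 FL1 means `c(negative, positive)`, within
#'   0-1023.
#' @param gfp_sd FL1 standard deviation within each mode (default 40).
#' @param scatter_mean,scatter_sd FSC/SSC mode location and spread.
#' @param outlier_fraction Fraction of events with uniform scatter values.
#' @param seed Integer seed.
#' @return Tibble: `FSC`, `SSC`, `FL1` (integers in [0, 1023]); the true
#'   per-event GFP state is kept in attribute `"gfp_true"`.
#' @export
simulate_cytometry <- function(n_events, mix_fraction, gfp_modes = c(200, 800),
                               gfp_sd = 40, scatter_mean = c(450, 380),
                               scatter_sd = 45, outlier_fraction = 0.02,
                               seed = 1L) {
  if (n_events < 1) stop("`n_events` must be >= 1", call. = FALSE)
  if (mix_fraction < 0 || mix_fraction > 1)
    stop("`mix_fraction` must be a probability", call. = FALSE)
  if (any(gfp_modes < 0 | gfp_modes > 1023))
    stop("`gfp_modes` must lie within 0-1023", call. = FALSE)
  set.seed(seed)
  is_out <- stats::runif(n_events) < outlier_fraction
  fsc <- ifelse(is_out, stats::runif(n_events, 0, 1023),
                stats::rnorm(n_events, scatter_mean[1], scatter_sd))
  ssc <- ifelse(is_out, stats::runif(n_events, 0, 1023),
                stats::rnorm(n_events, scatter_mean[2], scatter_sd))
  gfp <- stats::runif(n_events) < mix_fraction
  fl1 <- stats::rnorm(n_events, ifelse(gfp, gfp_modes[2], gfp_modes[1]),
                      gfp_sd)
  clip <- function(x) as.integer(pmin(pmax(round(x), 0), 1023))
  out <- tibble::tibble(FSC = clip(fsc), SSC = clip(ssc), FL1 = clip(fl1))
  attr(out, "gfp_true") <- gfp
  out
}

#' Dynamic density gating of cytometry events
#'
#' Removes saturated events (any channel at the range limits), estimates a
#' two-dimensional Gaussian-kernel density on (FSC, SSC), and keeps the
#' events inside the highest-density region containing `keep_fraction` of
#' events (the upper level set of the density, by event count). Samples with
#' too few input or gated events are rejected with a typed error
#' (`"pf_sample_rejected"`).
#'
#' @param events Tibble with integer columns `FSC`, `SSC`, `FL1`.
#' @param keep_fraction Fraction of (unsaturated) events kept (default 0.4).
#' @param min_events Minimum input events (default 2000).
#' @param min_gated Minimum events after gating; the gated count must be
#'   strictly greater (default 4000).
#' @param grid_n Density grid resolution (default 64).
#' @return The gated event tibble; removed-event bookkeeping in attribute
#'   `"gating"`.
#' @export
gate_events <- function(events, keep_fraction = 0.4, min_events = 2000,
                        min_gated = 4000, grid_n = 64) {
  stopifnot(all(c("FSC", "SSC", "FL1") %in% names(events)))
  if (nrow(events) < min_events)
    stop(structure(class = c("pf_sample_rejected", "error", "condition"),
                   list(message = sprintf("sample rejected: %d events < %d",
                                          nrow(events), min_events),
                        call = NULL)))
  sat <- with(events, FSC >= 1023 | SSC >= 1023 | FL1 >= 1023 |
                FSC <= 0 | SSC <= 0 | FL1 <= 0)
  ok <- events[!sat, ]
  dens <- MASS::kde2d(ok$FSC, ok$SSC, n = grid_n)
  dvals <- interp_grid(dens, ok$FSC, ok$SSC)
  n_keep <- ceiling(keep_fraction * nrow(ok))
  cut <- sort(dvals, decreasing = TRUE)[n_keep]
  keep <- dvals >= cut
  gated <- ok[keep, ]
  if (nrow(gated) <= min_gated)
    stop(structure(class = c("pf_sample_rejected", "error", "condition"),
                   list(message = sprintf("sample rejected: %d gated events <= %d",
                                          nrow(gated), min_gated),
                        call = NULL)))
  attr(gated, "gating") <- list(n_input = nrow(events), n_saturated = sum(sat),
                                n_gated = nrow(gated),
                                density_cut = cut)
  gated
}

# bilinear interpolation of a kde2d grid at points
interp_grid <- function(dens, x, y) {
  ix <- findInterval(x, dens$x, all.inside = TRUE)
  iy <- findInterval(y, dens$y, all.inside = TRUE)
  dx <- (x - dens$x[ix]) / diff(dens$x)[ix]
  dy <- (y - dens$y[iy]) / diff(dens$y)[iy]
  dx <- pmin(pmax(dx, 0), 1); dy <- pmin(pmax(dy, 0), 1)
  z <- dens$z
  z[cbind(ix, iy)] * (1 - dx) * (1 - dy) +
    z[cbind(ix + 1L, iy)] * dx * (1 - dy) +
    z[cbind(ix, iy + 1L)] * (1 - dx) * dy +
    z[cbind(ix + 1L, iy + 1L)] * dx * dy
}

#' Automatic GFP threshold by valley finding
#'
#' Smooths the FL1 distribution with a Gaussian kernel and places the
#' threshold at the deepest density valley between the two largest modes.
#' Unimodal input (control samples containing a single strain) is flagged
#' instead of thresholded.
#'
#' @param fl1 FL1 channel values.
#' @param adjust Kernel bandwidth adjustment passed to [stats::density()].
#' @param min_peak_frac Modes smaller than this fraction of the main peak are
#'   ignored (default 0.05).
#' @return Object of class `"pf_gfp_threshold"`: `threshold` (`NA` when
#'   unimodal), `unimodal` flag, `peaks`, `valleys` (FL1 positions).
#' @export
find_gfp_threshold <- function(fl1, adjust = 1, min_peak_frac = 0.05) {
  if (length(fl1) == 0) stop("empty FL1 input", call. = FALSE)
  d <- stats::density(fl1, adjust = adjust)
  y <- d$y
  n <- length(y)
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
               FALSE)
  is_valley <- c(FALSE, y[2:(n - 1)] < y[1:(n - 2)] & y[2:(n - 1)] <= y[3:n],
                 FALSE)
  peaks <- which(is_peak)
  peaks <- peaks[y[peaks] >= min_peak_frac * max(y[peaks])]
  out <- list(threshold = NA_real_, unimodal = length(peaks) < 2,
              peaks = d$x[peaks], valleys = d$x[which(is_valley)])
  if (!out$unimodal) {
    top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
    between <- which(is_valley)
    between <- between[between > top2[1] & between < top2[2]]
    if (length(between) == 0) {
      seg <- seq(top2[1], top2[2])
      between <- seg[which.min(y[seg])]
    }
    out$threshold <- d$x[between[which.min(y[between])]]
  }
  structure(out, class = "pf_gfp_threshold")
}

#' @export
print.pf_gfp_threshold <- function(x, ...) {
  if (x$unimodal) cat("<pf_gfp_threshold> unimodal FL1 distribution (no threshold)\n")
  else cat(sprintf("<pf_gfp_threshold> threshold at FL1 = %.1f (%d modes)\n",
                   x$threshold, length(x$peaks)))
  invisible(x)
}

#' Classify events as GFP-positive or negative
#' @param fl1 FL1 values.
#' @param threshold Threshold from [find_gfp_threshold()] (or a number).
#' @return Logical vector, `TRUE` for GFP-positive.
#' @export
classify_gfp <- function(fl1, threshold) {
  if (inherits(threshold, "pf_gfp_threshold")) {
    if (threshold$unimodal)
      stop("unimodal threshold object cannot classify; use a control-derived value",
           call. = FALSE)
    threshold <- threshold$threshold
  }
  fl1 > threshold
}

#' Competition fitness from cytometric GFP counts
#'
#' The GFP-negative population is the mutant and the GFP-positive population
#' the wild-type reference; fitness is the same estimator as [fitness_w()]
#' applied to the cytometric frequencies at the beginning and end of the
#' competition.
#'
#' @param counts_b,counts_e Length-2 vectors `c(gfp_neg, gfp_pos)` of event
#'   counts at the beginning and end.
#' @param g Generations between the two time points (default 24).
#' @return Relative fitness w of the mutant.
#' @export
cytometry_fitness <- function(counts_b, counts_e, g = 24) {
  if (any(c(counts_b, counts_e) <= 0))
    stop("all four GFP counts must be positive", call. = FALSE)
  f_b <- counts_b / sum(counts_b)
  f_e <- counts_e / sum(counts_e)
  fitness_w(f_b[1], f_e[1], f_b[2], f_e[2], g = g)
}
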