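#' Coherence connectome
#'
#' Container for a session-wise parcel-by-parcel magnitude-squared coherence
#' matrix: symmetric, entries in \[0, 1\], diagonal fixed to 0 (self-coherence
#' is uninformative and would dominate row-wise top-density selection
#' downstream).
#'
#' @param values P x P numeric matrix in \[0, 1\].
#' @param tr Repetition time (s).
#' @param band Numeric `c(low, high)` passband in Hz.
#' @param n_segments Number of Welch segments averaged.
#' @return A list with class `coherence_matrix`.
#' @export
coherence_matrix <- function(values, tr, band, n_segments) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop_axisflux("coherence matrix not square")
  if (max(abs(values - t(values))) > 1e-10) {
    stop_axisflux("coherence matrix not symmetric")
  }
  if (any(values < -1e-12) || any(values > 1 + 1e-12)) {
    stop_axisflux("coherence entries must lie in [0, 1]")
  }
  values <- pmin(pmax((values + t(values)) / 2, 0), 1)
  diag(values) <- 0
  structure(list(values = values, tr = tr, band = band,
                 n_segments = n_segments),
            class = "coherence_matrix")
}

#' @export
print.coherence_matrix <- function(x, ...) {
  cat(sprintf(
    "coherence_matrix: %d x %d, band %.4f-%.4f Hz, %d segments, density %.3f\n",
    nrow(x$values), ncol(x$values), x$band[1], x$band[2], x$n_segments,
    mean(x$values[upper.tri(x$values)] > 0)))
  invisible(x)
}

#' First eigenvariate of a voxel block
#'
#' Rank-1 temporal summary of a voxels-by-timepoints block: the leading left
#' temporal factor from the SVD of the (column-demeaned) block, unit norm,
#' with its sign fixed so that its mean correlation with the voxel rows is
#' positive.  Used to summarise a region's voxels into one representative
#' series.
#'
#' @param block Voxels x timepoints numeric matrix (>= 2 timepoints).
#' @return Numeric vector of length `timepoints`, unit norm.
#' @export
first_eigenvariate <- function(block) {
  block <- as.matrix(block)
  if (ncol(block) < 2L) stop_axisflux("need >= 2 timepoints")
  if (anyNA(block)) stop_axisflux("block contains missing values")
  if (all(block == 0)) stop_axisflux("degenerate block: all zeros")
  sv <- svd(block, nu = 0, nv = 1)
  v <- sv$v[, 1]
  cr <- block %*% v
  if (sum(cr) < 0) v <- -v
  drop(v)
}

## Welch cross-spectral machinery: Hann-windowed, demeaned, overlapping
## segments; returns the complex segment spectra for all parcels at the
## requested frequency bins, plus the effective number of independent
## averages (each 50%-overlapped segment beyond the first counts 0.5).
welch_segments <- function(series, tr, segment_length, overlap) {
  n <- ncol(series)
  L <- segment_length
  if (n < L) stop_axisflux("series shorter than one Welch segment")
  step <- max(1L, floor(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = step)
  if (length(starts) < 2L) {
    stop_axisflux("insufficient data for coherence df: %d segment(s)",
                  length(starts))
  }
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))  # Hann
  freqs <- (0:(L %/% 2)) / (L * tr)
  d_eff <- 1 + (length(starts) - 1) * (1 - overlap)
  list(starts = starts, window = w, freqs = freqs, d_eff = d_eff, L = L)
}

#' Session coherence connectome
#'
#' Computes the parcel-by-parcel functional connectivity matrix of a session
#' as band-averaged Welch magnitude-squared coherence
#' `|S_xy|^2 / (S_xx S_yy)`: series are band-limited by
#' [modwt_band_series()] over `cfg$scales`, cross-spectra are averaged over
#' Hann-windowed segments (`cfg$segment_length` samples, `cfg$overlap`
#' overlap), and coherence is averaged over the frequency bins inside
#' [passband_edges()].  Edge p-values use the standard Welch null
#' `p = (1 - C)^(d - 1)` with `d` the effective (overlap-corrected) segment
#' count; when `threshold = TRUE` the upper-triangle edges are
#' Benjamini-Hochberg corrected at `cfg$fdr_q` and non-significant edges are
#' set to 0.
#'
#' @param record A [session_record()] (raw; band-limiting is applied here).
#' @param cfg An [analysis_config()].
#' @param threshold Apply edge-level FDR thresholding (default `TRUE`).
#' @return A [coherence_matrix()].
#' @export
session_coherence_fc <- function(record, cfg = analysis_config(),
                                 threshold = TRUE) {
  band <- passband_edges(record$tr, cfg$scales)
  bl <- modwt_band_series(record, cfg$scales)
  x <- bl$series
  p <- nrow(x)
  ws <- welch_segments(x, record$tr, cfg$segment_length, cfg$overlap)
  keep <- which(ws$freqs >= band[1] & ws$freqs <= band[2] & ws$freqs > 0)
  if (!length(keep)) stop_axisflux("no frequency bins inside the passband")
  nseg <- length(ws$starts)

  ## segment spectra: for each kept bin, an nseg x P complex matrix
  Z <- array(0 + 0i, dim = c(nseg, length(keep), p))
  for (s in seq_len(nseg)) {
    seg <- x[, ws$starts[s] + 0:(ws$L - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    seg <- sweep(seg, 2L, ws$window, `*`)
    ft <- t(stats::mvfft(t(seg)))
    Z[s, , ] <- t(ft[, keep, drop = FALSE])
  }

  coh <- matrix(0, p, p)
  for (f in seq_along(keep)) {
    Zf <- Z[, f, ]                       # nseg x P
    S <- crossprod(Conj(Zf), Zf)         # P x P cross-spectra (summed)
    auto <- Re(diag(S))
    msc <- (Mod(S)^2) / (auto %o% auto)
    coh <- coh + Re(msc)
  }
  coh <- coh / length(keep)
  coh <- pmin(pmax((coh + t(coh)) / 2, 0), 1)
  diag(coh) <- 0

  if (threshold) {
    ut <- upper.tri(coh)
    pvals <- (1 - coh[ut])^(ws$d_eff - 1)
    qvals <- bh_adjust(pvals)
    keep_edge <- qvals < cfg$fdr_q
    vals <- coh[ut]
    vals[!keep_edge] <- 0
    coh[ut] <- vals
    coh[lower.tri(coh)] <- t(coh)[lower.tri(coh)]
  }
  coherence_matrix(coh, record$tr, band, nseg)
}
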