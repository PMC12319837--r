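## Maximal-overlap discrete wavelet transform (MODWT) and its multiresolution
## analysis, vectorised across parcels.  Filter: Daubechies least-asymmetric
## length 8 (LA(8)); boundary handling: reflection (series extended to twice
## its length, circular transform, truncation back), which minimises boundary
## leakage on ~900-sample resting-state series.

## LA(8) scaling filter (DWT normalisation); wavelet filter by the quadrature
## mirror relation h_l = (-1)^l g_{L-1-l}.
la8_scaling <- c(
  -0.075765714789273325, -0.02963552764599851, 0.49761866763201545,
   0.80373875180591614,   0.29785779560527736, -0.099219543576847216,
  -0.012603967262037833,  0.032223100604042702
)

modwt_filters <- function() {
  g <- la8_scaling / sqrt(2)
  L <- length(g)
  h <- (-1)^(0:(L - 1)) * rev(g)
  list(g = g, h = h, L = L)
}

## One pyramid step at level j on an N x P matrix V (columns are series).
## W_t = sum_l h_l V_{(t - 2^(j-1) l) mod N}.
modwt_step <- function(V, j, flt) {
  n <- nrow(V)
  tau <- 2^(j - 1)
  W <- matrix(0, n, ncol(V))
  Vout <- matrix(0, n, ncol(V))
  t0 <- seq_len(n) - 1L
  for (l in seq_len(flt$L) - 1L) {
    idx <- ((t0 - tau * l) %% n) + 1L
    W <- W + flt$h[l + 1L] * V[idx, , drop = FALSE]
    Vout <- Vout + flt$g[l + 1L] * V[idx, , drop = FALSE]
  }
  list(W = W, V = Vout)
}

## Inverse pyramid step: reconstruct V_{j-1} from (W_j, V_j).
modwt_istep <- function(W, V, j, flt) {
  n <- nrow(W)
  tau <- 2^(j - 1)
  out <- matrix(0, n, ncol(W))
  t0 <- seq_len(n) - 1L
  for (l in seq_len(flt$L) - 1L) {
    idx <- ((t0 + tau * l) %% n) + 1L
    out <- out + flt$h[l + 1L] * W[idx, , drop = FALSE] +
      flt$g[l + 1L] * V[idx, , drop = FALSE]
  }
  out
}

## MODWT multiresolution detail components, summed over `scales`, for a
## timepoints x P matrix.  Circular transform on the reflection-extended
## series; the first N rows of the reconstruction are returned.
modwt_mra_sum <- function(x, scales) {
  flt <- modwt_filters()
  n <- nrow(x)
  jmax <- max(scales)
  ext <- rbind(x, x[n:1, , drop = FALSE])
  V <- ext
  Ws <- vector("list", jmax)
  for (j in seq_len(jmax)) {
    st <- modwt_step(V, j, flt)
    Ws[[j]] <- st$W
    V <- st$V
  }
  out <- matrix(0, n, ncol(x))
  zero <- matrix(0, nrow(ext), ncol(x))
  for (j in scales) {
    ## detail j: invert from level j down, feeding W only at level j
    D <- modwt_istep(Ws[[j]], zero, j, flt)
    if (j > 1) for (i in (j - 1):1) D <- modwt_istep(zero, D, i, flt)
    out <- out + D[seq_len(n), , drop = FALSE]
  }
  out
}

#' Passband of a dyadic wavelet scale range
#'
#' The union of MODWT detail bands for scales `j_lo..j_hi` at sampling rate
#' `1/tr`: scale `j` covers `[fs/2^(j+1), fs/2^j]`, so the union is
#' `[fs/2^(j_hi+1), fs/2^j_lo]`.  At TR = 0.72 s, scales 3--6 give the
#' canonical low-frequency window of roughly 0.01--0.17 Hz.
#'
#' @param tr Repetition time in seconds.
#' @param scales Integer range of detail scales, e.g. `3:6`.
#' @return Named numeric vector `c(low, high)` in Hz.
#' @export
passband_edges <- function(tr, scales) {
  if (tr <= 0) stop_axisflux("tr must be > 0")
  j_lo <- min(scales); j_hi <- max(scales)
  if (j_lo > j_hi || j_lo < 1) stop_axisflux("invalid scale range")
  fs <- 1 / tr
  c(low = fs / 2^(j_hi + 1), high = fs / 2^j_lo)
}

#' Band-limit a session by MODWT multiresolution details
#'
#' Replaces each parcel's series by the sum of its MODWT multiresolution
#' detail components over the requested scales (LA(8) filter, reflection
#' boundary).  Details carry no DC, so the output of each parcel is
#' approximately zero-mean up to boundary effects.
#'
#' @param record A [session_record()].
#' @param scales Integer range of detail scales (default 3--6).
#' @return A [session_record()] with band-limited series.
#' @export
modwt_band_series <- function(record, scales = 3:6) {
  n <- ncol(record$series)
  need <- 2^(max(scales) + 1)
  if (n < need) {
    stop_axisflux("series too short for scale %d: %d < %d timepoints",
                  max(scales), n, need)
  }
  bl <- t(modwt_mra_sum(t(record$series), scales))
  out <- record
  out$series <- bl
  out
}
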