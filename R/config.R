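#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline with their defaults:
#' gradient parameters (top-row density 0.10, diffusion operator
#' `alpha = 0.5`, diffusion time 0, 10 components), coherence parameters
#' (wavelet scales 3--6, Welch segments of 128 samples with 50% overlap,
#' edge FDR `q = 0.05`), and statistics parameters (1,000 permutations,
#' map/parcel FDR `q = 0.05`, Bonferroni families `0.025/7` within-network
#' and `0.025/21` between-network).
#'
#' @param density Fraction of strongest entries kept per connectome row,
#'   in (0, 1].
#' @param alpha Density-normalisation exponent of the diffusion operator,
#'   in \[0, 1\]; 0.5 discounts sampling density.
#' @param diffusion_time Diffusion time `t`; 0 selects the `lambda/(1-lambda)`
#'   multi-scale eigenvalue weighting.
#' @param n_components Number of embedding components retained.
#' @param scales Integer range of wavelet detail scales forming the passband.
#' @param segment_length,overlap Welch estimator segment length (samples) and
#'   fractional overlap.
#' @param fdr_q Benjamini-Hochberg q threshold (connectome edges and
#'   parcel-wise maps).
#' @param n_perm Number of spin permutations.
#' @param seed Integer seed for all randomised steps.
#' @param alpha_within,alpha_between Bonferroni-corrected thresholds for the
#'   7 within-network and 21 between-network dispersion tests.
#' @param include_sessions,exclude_sessions Optional session id lists applied
#'   by [filter_sessions()]-style subsetting.
#'
#' @return A list with class `analysis_config`.
#' @export
analysis_config <- function(density = 0.10,
                            alpha = 0.5,
                            diffusion_time = 0L,
                            n_components = 10L,
                            scales = 3:6,
                            segment_length = 128L,
                            overlap = 0.5,
                            fdr_q = 0.05,
                            n_perm = 1000L,
                            seed = 1L,
                            alpha_within = 0.025 / 7,
                            alpha_between = 0.025 / 21,
                            include_sessions = NULL,
                            exclude_sessions = NULL) {
  if (!(density > 0 && density <= 1)) stop_axisflux("density must be in (0, 1]")
  if (!(alpha >= 0 && alpha <= 1)) stop_axisflux("alpha must be in [0, 1]")
  if (n_perm < 1) stop_axisflux("n_perm must be >= 1")
  if (length(seed) != 1L || seed != round(seed)) {
    stop_axisflux("seed must be an integer")
  }
  if (!(overlap >= 0 && overlap < 1)) stop_axisflux("overlap must be in [0, 1)")
  if (any(scales < 1) || any(diff(scales) != 1)) {
    stop_axisflux("scales must be a contiguous integer range >= 1")
  }
  structure(
    list(density = density, alpha = alpha,
         diffusion_time = as.integer(diffusion_time),
         n_components = as.integer(n_components),
         scales = as.integer(scales),
         segment_length = as.integer(segment_length), overlap = overlap,
         fdr_q = fdr_q, n_perm = as.integer(n_perm), seed = as.integer(seed),
         alpha_within = alpha_within, alpha_between = alpha_between,
         include_sessions = include_sessions,
         exclude_sessions = exclude_sessions),
    class = "analysis_config"
  )
}

#' @export
print.analysis_config <- function(x, ...) {
  cat(sprintf(paste0(
    "analysis_config: density %.2f, alpha %.2f, t %d, %d components;\n",
    "  scales %d-%d, segments %d @ %.0f%% overlap; q %.3g; %d perms; seed %d\n",
    "  Bonferroni within %.4g, between %.4g\n"),
    x$density, x$alpha, x$diffusion_time, x$n_components,
    min(x$scales), max(x$scales), x$segment_length, 100 * x$overlap,
    x$fdr_q, x$n_perm, x$seed, x$alpha_within, x$alpha_between))
  invisible(x)
}
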