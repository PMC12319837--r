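#' Per-parcel variability of S-A loadings
#'
#' Intra-individual daily variability: the sample standard deviation
#' (denominator S-1) of each parcel's axis loading across sessions.
#'
#' @param axes An [aligned_axes()] with >= 2 sessions.
#' @return A list with class `variability_map`: `values` (P-vector, >= 0),
#'   `n_sessions`, `subject_id`.
#' @export
parcel_sd <- function(axes) {
  if (ncol(axes$loadings) < 2L) stop_axisflux("need >= 2 sessions for SD")
  structure(list(values = apply(axes$loadings, 1L, stats::sd),
                 n_sessions = ncol(axes$loadings),
                 subject_id = axes$subject_id),
            class = "variability_map")
}

#' @export
print.variability_map <- function(x, ...) {
  cat(sprintf("variability_map (%s): %d parcels over %d sessions; median SD %.4g\n",
              x$subject_id, length(x$values), x$n_sessions,
              stats::median(x$values)))
  invisible(x)
}

## Vectorised two-group Levene statistic per parcel: one-way ANOVA on the
## absolute deviations from each group's center (mean for the classic test,
## median for the Brown-Forsythe variant); df (1, S_A + S_B - 2).
levene_rows <- function(ya, yb, center = c("mean", "median")) {
  center <- match.arg(center)
  ctr <- function(y) {
    if (center == "mean") rowMeans(y) else apply(y, 1L, stats::median)
  }
  za <- abs(ya - ctr(ya))
  zb <- abs(yb - ctr(yb))
  na <- ncol(ya); nb <- ncol(yb)
  ma <- rowMeans(za); mb <- rowMeans(zb)
  grand <- (na * ma + nb * mb) / (na + nb)
  ssb <- na * (ma - grand)^2 + nb * (mb - grand)^2
  ssw <- rowSums((za - ma)^2) + rowSums((zb - mb)^2)
  df2 <- na + nb - 2L
  F <- ifelse(ssb == 0, 0, ssb / (ssw / df2))
  F[ssw == 0 & ssb > 0] <- Inf
  p <- ifelse(is.infinite(F), 0, stats::pf(F, 1, df2, lower.tail = FALSE))
  p[F == 0] <- 1
  list(F = F, p = p, df = c(1L, df2))
}

#' Parcel-wise variance comparison between two subjects
#'
#' For each parcel, compares the variance of S-A loadings across sessions
#' between subjects A and B: the difference of sample standard deviations
#' (`diff = SD_A - SD_B`; positive means A more variable) for
#' directionality, and Levene's test for equality of variances (classic
#' mean-centered form by default) for significance, with Benjamini-Hochberg
#' FDR across parcels.
#'
#' @param axesA,axesB [aligned_axes()] on the same parcellation, each with
#'   >= 3 sessions.
#' @param q_threshold FDR threshold (default 0.05).
#' @param center `"mean"` (classic Levene) or `"median"` (Brown-Forsythe).
#' @return A list with class `variance_comparison`: `diff`, `levene_F`, `p`,
#'   `q`, `significant` (all P-vectors), and `df`.
#' @export
variance_comparison <- function(axesA, axesB, q_threshold = 0.05,
                                center = c("mean", "median")) {
  ya <- axesA$loadings; yb <- axesB$loadings
  if (nrow(ya) != nrow(yb)) {
    stop_axisflux("parcellation mismatch: %d vs %d parcels",
                  nrow(ya), nrow(yb))
  }
  if (ncol(ya) < 3L || ncol(yb) < 3L) {
    stop_axisflux("need >= 3 sessions per subject")
  }
  lv <- levene_rows(ya, yb, center = center)
  q <- bh_adjust(lv$p)
  structure(list(diff = apply(ya, 1L, stats::sd) - apply(yb, 1L, stats::sd),
                 levene_F = lv$F, p = lv$p, q = q,
                 significant = q < q_threshold, df = lv$df,
                 q_threshold = q_threshold),
            class = "variance_comparison")
}

#' @export
print.variance_comparison <- function(x, ...) {
  cat(sprintf("variance_comparison: %d parcels, %d significant at q < %.3g\n",
              length(x$diff), sum(x$significant), x$q_threshold))
  invisible(x)
}

#' Decode a variability map against feature maps
#'
#' Spearman correlation between a subject's variability map and each of a
#' set of user-supplied parcel-level feature maps, with a spin-permutation
#' p-value per feature (the subject map is spun, so one null serves all
#' features) and Benjamini-Hochberg FDR across features.  Missing feature
#' values are dropped pairwise.
#'
#' @param map A [variability_map()] (or numeric P-vector).
#' @param features Named list of numeric P-vectors, or a P x F matrix with
#'   column names.
#' @param spins A [spin_index()] on the same parcellation.
#' @param q_threshold FDR threshold across features (default 0.05).
#' @return A data.frame with columns `name`, `spearman_r`, `p_spin`, `q`,
#'   `significant`.
#' @export
decode_map <- function(map, features, spins, q_threshold = 0.05) {
  v <- if (inherits(map, "variability_map")) map$values else as.numeric(map)
  fm <- if (is.list(features)) {
    do.call(cbind, lapply(features, as.numeric))
  } else as.matrix(features)
  if (is.null(colnames(fm))) colnames(fm) <- paste0("feature_", seq_len(ncol(fm)))
  if (nrow(fm) != length(v)) {
    stop_axisflux("feature length %d != map length %d", nrow(fm), length(v))
  }
  if (nrow(spins$index) != length(v)) {
    stop_axisflux("spin index does not match the parcellation")
  }
  sp_cor <- function(x, y) {
    ok <- !is.na(y) & !is.na(x)
    stats::cor(x[ok], y[ok], method = "spearman")
  }
  r_obs <- apply(fm, 2L, sp_cor, x = v)
  spun <- matrix(v[spins$index], nrow = length(v))
  p_spin <- numeric(ncol(fm))
  for (k in seq_len(ncol(fm))) {
    nulls <- apply(spun, 2L, sp_cor, y = fm[, k])
    p_spin[k] <- spin_pvalue(r_obs[k], nulls, two_sided = TRUE)
  }
  q <- bh_adjust(p_spin)
  data.frame(name = colnames(fm), spearman_r = r_obs, p_spin = p_spin,
             q = q, significant = q < q_threshold, row.names = NULL)
}
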