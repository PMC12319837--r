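#' Row-wise density thresholding of a connectome
#'
#' Keeps, in each row, the `ceiling(density * P)` largest entries and zeroes
#' the rest (the "top 10% per seed region" sparsification at the default
#' density of 0.10).  The result is generally asymmetric.  Ties are broken
#' stably towards the lower column index.
#'
#' @param W A [coherence_matrix()] or plain numeric matrix.
#' @param density Fraction of entries kept per row, in (0, 1].
#' @return A P x P matrix with zeroed sub-threshold entries.
#' @export
row_threshold <- function(W, density = 0.10) {
  if (!(density > 0 && density <= 1)) stop_axisflux("density must be in (0, 1]")
  v <- if (inherits(W, "coherence_matrix")) W$values else as.matrix(W)
  p <- ncol(v)
  k <- ceiling(density * p)
  if (k >= p) return(v)
  out <- matrix(0, nrow(v), p)
  for (i in seq_len(nrow(v))) {
    ord <- order(v[i, ], decreasing = TRUE)[seq_len(k)]
    out[i, ord] <- v[i, ord]
  }
  out
}

#' Normalized-angle affinity between connectivity profiles
#'
#' Affinity `a_ij = 1 - acos(rho_ij) / pi` with `rho` the cosine similarity
#' of rows `i` and `j` of the (thresholded) connectome: 1 for identical
#' profiles, 0.5 for orthogonal ones, 0 for anti-parallel ones.
#'
#' @param X P x P (thresholded) matrix; no all-zero rows.
#' @return Symmetric P x P affinity matrix in \[0, 1\] with unit diagonal.
#' @export
affinity_normalized_angle <- function(X) {
  X <- as.matrix(X)
  nrm <- sqrt(rowSums(X^2))
  bad <- which(nrm == 0)
  if (length(bad)) {
    stop_axisflux("all-zero connectivity row(s) at parcel %s",
                  paste(bad, collapse = ", "))
  }
  Xn <- X / nrm
  C <- tcrossprod(Xn)
  C <- pmin(pmax(C, -1), 1)
  A <- 1 - acos(C) / pi
  A <- (A + t(A)) / 2
  diag(A) <- 1
  A
}

## connectivity of the symmetrized support, by breadth-first search
graph_connected <- function(A) {
  adj <- (A + t(A)) > 0
  diag(adj) <- FALSE
  p <- ncol(adj)
  seen <- logical(p)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[1L]
    queue <- queue[-1L]
    nb <- which(adj[i, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Diffusion map embedding
#'
#' Nonlinear spectral embedding of a symmetric non-negative affinity matrix.
#' The affinity is density-normalised, `A_ij / (d_i^alpha d_j^alpha)` with
#' `d` the row sums, made row-stochastic, and eigendecomposed; the trivial
#' constant eigenvector (eigenvalue 1) is dropped.  Components are the
#' eigenvectors scaled by `lambda / (1 - lambda)` at diffusion time 0
#' (multi-scale weighting) or by `lambda^t` otherwise.  Variance explained is
#' reported as each eigenvalue's share of the retained eigenvalue sum.
#'
#' @param A Symmetric non-negative P x P affinity matrix with connected
#'   support.
#' @param alpha Density-normalisation exponent in \[0, 1\].
#' @param diffusion_time Non-negative integer `t`; 0 selects the
#'   `lambda/(1-lambda)` scaling.
#' @param n_components Number of non-trivial components to retain.
#' @return A list with class `embedding_result`: `components` (P x K),
#'   `eigenvalues` (K, descending, < 1), `variance_explained` (K, sums to 1).
#' @export
diffusion_map <- function(A, alpha = 0.5, diffusion_time = 0L,
                          n_components = 10L) {
  A <- as.matrix(A)
  if (max(abs(A - t(A))) > 1e-10) stop_axisflux("affinity must be symmetric")
  if (any(A < 0)) stop_axisflux("affinity must be non-negative")
  if (!graph_connected(A)) stop_axisflux("affinity graph not connected")
  p <- ncol(A)
  d <- rowSums(A)
  At <- A / (d^alpha %o% d^alpha)
  q <- rowSums(At)
  ## symmetric conjugate of the row-stochastic operator M = Q^-1 At:
  ## S = Q^-1/2 At Q^-1/2 shares M's eigenvalues; psi = Q^-1/2 v.
  S <- At / sqrt(q %o% q)
  eg <- eigen(S, symmetric = TRUE)
  lam <- eg$values
  psi <- eg$vectors / sqrt(q)
  ## normalise so the trivial eigenvector is the constant 1 vector
  psi <- psi / psi[1, 1]
  K <- min(n_components, p - 1L)
  lam_k <- lam[2:(K + 1L)]
  psi_k <- psi[, 2:(K + 1L), drop = FALSE]
  ## fix a reproducible sign: largest-magnitude entry positive
  for (k in seq_len(K)) {
    j <- which.max(abs(psi_k[, k]))
    if (psi_k[j, k] < 0) psi_k[, k] <- -psi_k[, k]
  }
  scale_k <- if (diffusion_time == 0) lam_k / (1 - lam_k) else lam_k^diffusion_time
  comps <- sweep(psi_k, 2L, scale_k, `*`)
  lam_pos <- pmax(lam_k, 0)
  ve <- if (sum(lam_pos) > 0) lam_pos / sum(lam_pos) else rep(0, K)
  structure(list(components = comps, eigenvalues = lam_k,
                 variance_explained = ve),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("embedding_result: %d parcels x %d components; lambda_1 %.3f (%.1f%% var)\n",
              nrow(x$components), ncol(x$components), x$eigenvalues[1],
              100 * x$variance_explained[1]))
  invisible(x)
}

#' Orthogonal Procrustes alignment (no scaling)
#'
#' Mean-centers the columns of both matrices, then rotates/reflects `source`
#' by the orthogonal matrix minimising the Frobenius distance to the centered
#' `reference`.  No scaling is applied, so loading dispersion is preserved
#' for the downstream dispersion statistics.
#'
#' @param source,reference P x K matrices of equal shape.
#' @return The aligned, centered P x K source matrix.
#' @export
procrustes_align <- function(source, reference) {
  source <- as.matrix(source); reference <- as.matrix(reference)
  if (!all(dim(source) == dim(reference))) {
    stop_axisflux("shape mismatch: %dx%d vs %dx%d",
                  nrow(source), ncol(source), nrow(reference), ncol(reference))
  }
  Xs <- scale(source, scale = FALSE)
  Xr <- scale(reference, scale = FALSE)
  sv <- svd(crossprod(Xs, Xr))
  Xs %*% (sv$u %*% t(sv$v))
}

#' Aligned per-session S-A axes
#'
#' Container for session-wise sensorimotor-association axis loadings after
#' Procrustes alignment and orientation: `loadings` (P x S), the subject
#' `mean_axis`, per-session Spearman correlation with the mean axis, and the
#' variance explained by each session's own principal component.
#'
#' @param loadings P x S matrix, one aligned axis per session column.
#' @param mean_axis P-vector reference axis.
#' @param session_ids Character vector of length S.
#' @param session_corr Optional S-vector (computed if `NULL`).
#' @param variance_explained_pc1 Optional S-vector.
#' @param subject_id Subject identifier.
#' @return A list with class `aligned_axes`.
#' @export
aligned_axes <- function(loadings, mean_axis = rowMeans(loadings),
                         session_ids = colnames(loadings),
                         session_corr = NULL,
                         variance_explained_pc1 = rep(NA_real_, ncol(loadings)),
                         subject_id = "sub") {
  loadings <- as.matrix(loadings)
  if (is.null(session_ids)) {
    session_ids <- sprintf("ses-%02d", seq_len(ncol(loadings)))
  }
  if (is.null(session_corr)) {
    session_corr <- apply(loadings, 2L, stats::cor, y = mean_axis,
                          method = "spearman")
  }
  structure(list(loadings = loadings, mean_axis = as.numeric(mean_axis),
                 session_ids = as.character(session_ids),
                 session_corr = as.numeric(session_corr),
                 variance_explained_pc1 = as.numeric(variance_explained_pc1),
                 subject_id = subject_id),
            class = "aligned_axes")
}

#' @export
print.aligned_axes <- function(x, ...) {
  cat(sprintf("aligned_axes (%s): %d parcels x %d sessions; median axis-mean r %.3f\n",
              x$subject_id, nrow(x$loadings), ncol(x$loadings),
              stats::median(x$session_corr)))
  invisible(x)
}

embed_connectome <- function(W, cfg) {
  X <- row_threshold(W, cfg$density)
  A <- affinity_normalized_angle(X)
  diffusion_map(A, alpha = cfg$alpha, diffusion_time = cfg$diffusion_time,
                n_components = cfg$n_components)
}

#' Session-wise S-A axes from coherence connectomes
#'
#' The full gradient stage: the mean connectome (across sessions) is embedded
#' to give the subject reference; each session's connectome is embedded with
#' the same parameters and Procrustes-aligned (no scaling) to the reference;
#' the S-A axis is the first aligned component.  The axis is oriented by the
#' association-positive convention: if the mean loading over default-mode
#' parcels is below the mean loading over somatomotor parcels, the sign of
#' the reference and of every session axis is flipped together.
#'
#' @param fcs List of [coherence_matrix()] (or plain matrices), one per
#'   session; names are used as session ids.
#' @param meta A [parcellation_meta()] (supplies network labels for the
#'   orientation anchor).
#' @param cfg An [analysis_config()].
#' @param subject_id Subject identifier stored on the result.
#' @return An [aligned_axes()] object.
#' @export
compute_sa_axes <- function(fcs, meta, cfg = analysis_config(),
                            subject_id = "sub") {
  if (length(fcs) < 2L) stop_axisflux("need >= 2 sessions")
  mats <- lapply(fcs, function(w) {
    if (inherits(w, "coherence_matrix")) w$values else as.matrix(w)
  })
  meanW <- Reduce(`+`, mats) / length(mats)
  ref <- embed_connectome(meanW, cfg)
  ref_c <- scale(ref$components, scale = FALSE)

  S <- length(mats)
  p <- nrow(meta)
  loadings <- matrix(NA_real_, p, S)
  ve1 <- numeric(S)
  for (s in seq_len(S)) {
    em <- embed_connectome(mats[[s]], cfg)
    aligned <- procrustes_align(em$components, ref_c)
    loadings[, s] <- aligned[, 1L]
    ve1[s] <- em$variance_explained[1L]
  }
  mean_axis <- ref_c[, 1L]

  ## association-positive orientation (network anchor, template-free)
  dm <- meta$network == "default_mode"
  sm <- meta$network == "somatomotor"
  if (any(dm) && any(sm) && mean(mean_axis[dm]) < mean(mean_axis[sm])) {
    mean_axis <- -mean_axis
    loadings <- -loadings
  }
  ids <- names(fcs)
  if (is.null(ids)) ids <- sprintf("ses-%02d", seq_len(S))
  colnames(loadings) <- ids
  aligned_axes(loadings, mean_axis, ids,
               variance_explained_pc1 = ve1, subject_id = subject_id)
}

#' Flag outlier sessions
#'
#' Quality control on aligned axes: a session is flagged when its Spearman
#' correlation with the mean axis falls below `corr_threshold`, or when the
#' variance explained by its own first component lies more than
#' `ve_z_threshold` robust standard deviations (MAD) below the median across
#' sessions.  This makes "markedly dissimilar" sessions reproducible to
#' detect rather than excluded by inspection.
#'
#' @param axes An [aligned_axes()] object (>= 3 sessions).
#' @param corr_threshold Minimum Spearman correlation with the mean axis.
#' @param ve_z_threshold Robust z threshold for low variance explained.
#' @return Character vector of flagged session ids (possibly empty).
#' @export
session_qc <- function(axes, corr_threshold = 0.5, ve_z_threshold = 3) {
  if (ncol(axes$loadings) < 3L) stop_axisflux("need >= 3 sessions for QC")
  flag <- axes$session_corr < corr_threshold
  ve <- axes$variance_explained_pc1
  if (!anyNA(ve)) {
    md <- stats::median(ve)
    s <- stats::mad(ve)
    if (s > 0) flag <- flag | (ve < md - ve_z_threshold * s)
  }
  axes$session_ids[flag]
}
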