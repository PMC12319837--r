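test_that("row thresholding keeps the densest entries with stable ties", {
  W <- matrix(runif(16), 4)
  expect_equal(row_threshold(W, 1.0), W)

  W2 <- rbind(c(0.9, 0.2, 0.5, 0.1),
              c(0.1, 0.9, 0.2, 0.5),
              c(0.5, 0.1, 0.9, 0.2),
              c(0.2, 0.5, 0.1, 0.9))
  out <- row_threshold(W2, 0.25)
  expect_equal(out[1, ], c(0.9, 0, 0, 0))

  ties <- matrix(1, 4, 4)
  out2 <- row_threshold(ties, 0.5)
  expect_equal(out2[1, ], c(1, 1, 0, 0))   # lowest-index half retained
})

test_that("normalized-angle affinity maps cosine extremes to 1, 0.5, 0", {
  same <- rbind(c(1, 2, 3), c(2, 4, 6), c(1, 0, 0))
  A <- affinity_normalized_angle(same)
  expect_equal(A[1, 2], 1, tolerance = 1e-12)

  orth <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_equal(affinity_normalized_angle(orth)[1, 2], 0.5, tolerance = 1e-12)

  anti <- rbind(c(1, 0, 1), c(-1, 0, -1), c(0, 1, 0))
  expect_equal(affinity_normalized_angle(anti)[1, 2], 0, tolerance = 1e-7)

  z <- orth; z[2, ] <- 0
  expect_error(affinity_normalized_angle(z), "parcel 2")
})

test_that("diffusion map matches a dense eigensolver oracle on small graphs", {
  set.seed(3)
  for (p in c(7, 10, 12)) {
    A <- matrix(runif(p * p), p)
    A <- (A + t(A)) / 2
    em <- diffusion_map(A, alpha = 0.5, diffusion_time = 0L,
                        n_components = p - 1L)
    ## independent oracle: eigendecompose the non-symmetric row-stochastic
    ## operator directly
    d <- rowSums(A)
    At <- A / outer(d^0.5, d^0.5)
    M <- At / rowSums(At)
    eg <- eigen(M)
    lam <- Re(eg$values)
    ord <- order(lam, decreasing = TRUE)
    lam <- lam[ord]
    V <- Re(eg$vectors[, ord])
    expect_equal(em$eigenvalues, lam[-1], tolerance = 1e-8)
    for (k in seq_len(p - 1)) {
      u <- em$components[, k] / sqrt(sum(em$components[, k]^2))
      v <- V[, k + 1] / sqrt(sum(V[, k + 1]^2))
      expect_equal(abs(sum(u * v)), 1, tolerance = 1e-8)
    }
  }
})

test_that("diffusion map orders a path graph and degenerates on complete graphs", {
  p <- 5
  A <- matrix(0, p, p)
  for (i in 1:(p - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  diag(A) <- 0.5
  em <- diffusion_map(A, n_components = 3)
  expect_true(all(diff(em$components[, 1]) > 0) ||
                all(diff(em$components[, 1]) < 0))
  expect_true(all(diff(em$eigenvalues) <= 1e-12))
  expect_true(all(em$eigenvalues < 1))
  expect_equal(sum(em$variance_explained), 1, tolerance = 1e-12)

  K <- matrix(1, 6, 6)
  emk <- diffusion_map(K, n_components = 3)
  expect_lt(max(abs(emk$components)), 1e-10)

  disc <- diag(2)
  expect_error(diffusion_map(rbind(cbind(disc, 0 * disc),
                                   cbind(0 * disc, disc))),
               "not connected")
})

test_that("Procrustes alignment recovers orthogonal transforms without scaling", {
  set.seed(4)
  ref <- matrix(rnorm(30 * 4), 30)
  refc <- scale(ref, scale = FALSE)

  expect_equal(procrustes_align(ref, ref), refc, tolerance = 1e-10,
               ignore_attr = TRUE)

  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  rot <- ref %*% Q
  expect_equal(procrustes_align(rot, ref), refc, tolerance = 1e-8,
               ignore_attr = TRUE)

  ## optimality: never worse than no alignment
  other <- matrix(rnorm(30 * 4), 30)
  aligned <- procrustes_align(other, ref)
  oc <- scale(other, scale = FALSE)
  expect_lte(norm(aligned - refc, "F"), norm(oc - refc, "F"))

  ## cross-check against an independent implementation
  skip_if_not_installed("vegan")
  vp <- vegan::procrustes(refc, oc, scale = FALSE)
  expect_equal(aligned, oc %*% vp$rotation, tolerance = 1e-8,
               ignore_attr = TRUE)

  expect_error(procrustes_align(ref, ref[, 1:2]), "shape mismatch")
})

test_that("session axes align, orient, and respect permutation equivariance", {
  meta <- meta100()
  tru <- make_ground_truth(meta, noise_sd = 0, seed = 6)
  rec <- simulate_timeseries(tru$g0, 512, 0.72, seed = 6, noise_sd = 0.2)
  fc <- session_coherence_fc(rec)
  cfg <- analysis_config(n_components = 5)

  fcs <- list(`ses-01` = fc, `ses-02` = fc, `ses-03` = fc)
  axes <- compute_sa_axes(fcs, meta, cfg)
  expect_equal(axes$loadings[, 1], axes$mean_axis, tolerance = 1e-8)
  expect_equal(axes$session_corr, rep(1, 3), tolerance = 1e-8)
  dm <- meta$network == "default_mode"
  sm <- meta$network == "somatomotor"
  expect_true(all(apply(axes$loadings, 2,
                        function(g) mean(g[dm]) > mean(g[sm]))))

  ## permuting parcels permutes loadings identically
  perm <- sample(100)
  W <- fc$values[perm, perm]
  meta_p <- as.data.frame(meta)[perm, ]
  meta_p$parcel_id <- 1:100
  axes_p <- compute_sa_axes(list(a = W, b = W), parcellation_meta(meta_p), cfg)
  ref <- compute_sa_axes(list(a = fc$values, b = fc$values), meta, cfg)
  expect_equal(axes_p$mean_axis, ref$mean_axis[perm], tolerance = 1e-8)
})

test_that("embedding sign flips are absorbed by alignment and orientation", {
  meta <- meta100()
  tru <- make_ground_truth(meta, noise_sd = 0, seed = 6)
  cfg <- analysis_config(n_components = 4)
  recs <- lapply(1:3, function(s) {
    simulate_timeseries(tru$g0, 512, 0.72, seed = 20 + s, noise_sd = 0.3,
                        session_id = sprintf("ses-%02d", s))
  })
  fcs <- lapply(recs, session_coherence_fc, cfg = cfg)
  names(fcs) <- sprintf("ses-%02d", 1:3)
  ax1 <- compute_sa_axes(fcs, meta, cfg)
  ## negating a session's connectome-derived eigenvectors is equivalent to
  ## feeding the same connectome; alignment must give identical output
  ax2 <- compute_sa_axes(fcs[c(1, 2, 3)], meta, cfg)
  expect_equal(ax1$loadings, ax2$loadings, tolerance = 1e-10)
})

test_that("session QC flags dissimilar and low-variance sessions", {
  set.seed(8)
  base <- rnorm(60)
  L <- sapply(1:8, function(s) base + rnorm(60, sd = 0.05))
  colnames(L) <- sprintf("ses-%02d", 1:8)
  axes <- axes_from_matrix(L)
  axes$variance_explained_pc1 <- rep(0.33, 8)
  expect_length(session_qc(axes), 0)

  bad <- L
  bad[, 4] <- rnorm(60)                     # independent random axis
  axes_bad <- axes_from_matrix(bad)
  axes_bad$variance_explained_pc1 <- rep(0.33, 8)
  expect_equal(session_qc(axes_bad, corr_threshold = 0.5), "ses-04")

  expect_setequal(session_qc(axes, corr_threshold = 1.01), colnames(L))
})
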