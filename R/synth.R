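#' Synthetic spherical parcellation
#'
#' Builds a parcellation with known geometry for testing and simulation:
#' centroids are placed quasi-uniformly on the unit sphere (a Fibonacci
#' lattice restricted to the left hemisphere, mirrored exactly onto the
#' right), and networks are spatially contiguous patches obtained by
#' nearest-of-k seed points, mirrored across hemispheres.  Deterministic
#' given `seed`.
#'
#' @param n_parcels Even total parcel count (split equally across
#'   hemispheres).
#' @param n_networks Number of networks, between 1 and `n_parcels / 2`;
#'   the first seven take the canonical network names.
#' @param seed Integer seed.
#' @return A [parcellation_meta()] table.
#' @export
make_parcellation <- function(n_parcels = 400L, n_networks = 7L, seed = 1L) {
  if (n_parcels %% 2L != 0L) {
    stop_axisflux("n_parcels must be even, got %d", n_parcels)
  }
  nh <- n_parcels %/% 2L
  if (n_networks < 1L || n_networks > nh) {
    stop_axisflux("n_networks must be in 1..%d", nh)
  }
  ## Fibonacci lattice on the full sphere; the nh most x-negative points
  ## become the left hemisphere, the right is their exact mirror.
  m <- 2L * nh
  i <- seq_len(m) - 1L
  z <- 1 - 2 * (i + 0.5) / m
  r <- sqrt(pmax(0, 1 - z^2))
  az <- pi * (3 - sqrt(5)) * i
  pts <- cbind(x = r * cos(az), y = r * sin(az), z = z)
  left <- pts[order(pts[, "x"])[seq_len(nh)], , drop = FALSE]
  left <- left / sqrt(rowSums(left^2))
  right <- left
  right[, "x"] <- -right[, "x"]

  labels_pool <- if (n_networks <= 7L) {
    AXISFLUX_NETWORKS[seq_len(n_networks)]
  } else {
    c(AXISFLUX_NETWORKS, paste0("network_", 8:n_networks))
  }
  seeds <- with_substream(seed, "parcellation",
                          sample.int(nh, n_networks))
  sim <- left %*% t(left[seeds, , drop = FALSE])
  lab_idx <- max.col(sim, ties.method = "first")
  labels <- labels_pool[lab_idx]

  parcellation_meta(data.frame(
    parcel_id = seq_len(n_parcels),
    hemisphere = rep(c("L", "R"), each = nh),
    network = c(labels, labels),
    x = c(left[, "x"], right[, "x"]),
    y = c(left[, "y"], right[, "y"]),
    z = c(left[, "z"], right[, "z"])
  ))
}

#' Simulate session covariate trajectories
#'
#' Generates hormone-like covariates and Perceived Stress Scale scores over
#' daily sessions with the temporal structure of a dense-sampling design.
#' `design = "cycle"` emulates a menstrual cycle spanning the session range:
#' estradiol (pg/mL) follows a bimodal curve with its dominant ovulatory
#' peak near mid-series and a smaller luteal peak, and progesterone (ng/mL)
#' is near zero in the first (follicular) half and elevated in the second
#' (luteal) half.  `design = "diurnal"` emulates morning salivary sampling:
#' testosterone (pg/mL) and cortisol (ug/dL) as positive AR(1) series.
#' Both designs include integer PSS scores in 0--40.  Deterministic given
#' `seed`.  Means and spreads default to values typical of densely sampled
#' healthy young adults.
#'
#' @param n_sessions Number of daily sessions (>= 3).
#' @param design `"cycle"` or `"diurnal"`.
#' @param seed Integer seed.
#' @param subject_id Subject identifier for the table.
#' @return A [covariate_table()] with one row per session.
#' @export
simulate_covariates <- function(n_sessions, design = c("cycle", "diurnal"),
                                seed = 1L, subject_id = NULL) {
  design <- match.arg(design)
  if (n_sessions < 3L) stop_axisflux("need >= 3 sessions")
  n <- n_sessions
  d <- seq_len(n)
  ids <- sprintf("ses-%02d", d)
  with_substream(seed, paste0("covariates_", design), {
    if (design == "cycle") {
      peak_ovu <- round(n * 13 / 29)          # ovulatory estradiol peak
      peak_lut <- min(n, peak_ovu + round(n * 8 / 29))
      e2 <- 35 + 190 * exp(-(d - peak_ovu)^2 / (2 * 1.5^2)) +
        100 * exp(-(d - peak_lut)^2 / (2 * 3^2)) + stats::rnorm(n, 0, 8)
      e2 <- pmax(e2, 1)
      p4 <- 0.3 + 12 * exp(-(d - 0.72 * n)^2 / (2 * (0.12 * n)^2)) +
        stats::rnorm(n, 0, 0.4)
      p4 <- pmax(p4, 0.05)
      pss <- pmin(pmax(round(stats::rnorm(n, 8.3, 6.6)), 0L), 40L)
      df <- data.frame(subject_id = subject_id %||% "sim-female",
                       session_id = ids, estradiol = e2, progesterone = p4,
                       pss_score = as.integer(pss))
    } else {
      ar1 <- function(n, mu, sd, phi) {
        x <- numeric(n)
        x[1] <- mu + stats::rnorm(1, 0, sd)
        for (t in 2:n) {
          x[t] <- mu + phi * (x[t - 1] - mu) +
            stats::rnorm(1, 0, sd * sqrt(1 - phi^2))
        }
        x
      }
      testo <- pmax(ar1(n, 101.6, 10, 0.5), 1)
      cort <- pmax(ar1(n, 0.50, 0.13, 0.5), 0.02)
      pss <- pmin(pmax(round(stats::rnorm(n, 10.1, 2.1)), 0L), 40L)
      df <- data.frame(subject_id = subject_id %||% "sim-male",
                       session_id = ids, testosterone = testo,
                       cortisol = cort, pss_score = as.integer(pss))
    }
    covariate_table(df)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ground truth for planted simulations
#'
#' Bundles the planted quantities the effect-recovery simulations check
#' against: a smooth latent S-A axis `g0` over the parcellation (a centered
#' random smooth field on the sphere), per-covariate parcel-level loading
#' effects `beta_local` (units: loading change per covariate SD),
#' per-covariate per-network dispersion modulations `gamma_dispersion`, and
#' the session noise SD.
#'
#' @param meta A [parcellation_meta()].
#' @param covariates Character vector of covariate names with planted
#'   effects (may be empty).
#' @param beta_local P x H matrix of loading effects (columns follow
#'   `covariates`); defaults to all zero.
#' @param gamma_dispersion H x (networks) matrix of dispersion modulations;
#'   defaults to all zero.
#' @param noise_sd Session noise SD (>= 0; 0 gives the degenerate
#'   noise-free case).
#' @param seed Integer seed (drives `g0` and downstream noise).
#' @return A list with class `ground_truth`.
#' @export
make_ground_truth <- function(meta, covariates = character(),
                              beta_local = NULL, gamma_dispersion = NULL,
                              noise_sd = 0.1, seed = 1L) {
  p <- nrow(meta)
  networks <- network_levels(meta$network)
  h <- length(covariates)
  if (is.null(beta_local)) beta_local <- matrix(0, p, h)
  beta_local <- as.matrix(beta_local)
  if (h > 0 && (nrow(beta_local) != p || ncol(beta_local) != h)) {
    stop_axisflux("beta_local must be %d x %d", p, h)
  }
  if (is.null(gamma_dispersion)) {
    gamma_dispersion <- matrix(0, h, length(networks))
  }
  gamma_dispersion <- as.matrix(gamma_dispersion)
  if (h > 0 && (nrow(gamma_dispersion) != h ||
                ncol(gamma_dispersion) != length(networks))) {
    stop_axisflux("gamma_dispersion must be %d x %d", h, length(networks))
  }
  if (noise_sd < 0) stop_axisflux("noise_sd must be >= 0")
  if (h > 0) {
    colnames(beta_local) <- covariates
    dimnames(gamma_dispersion) <- list(covariates, networks)
  }
  X <- as.matrix(meta[, c("x", "y", "z")])
  g0 <- with_substream(seed, "g0", {
    centers <- matrix(stats::rnorm(15), 5, 3)
    centers <- centers / sqrt(rowSums(centers^2))
    amps <- stats::rnorm(5)
    ang <- acos(pmin(pmax(X %*% t(centers), -1), 1))
    drop(exp(-ang^2 / (2 * 0.8^2)) %*% amps)
  })
  g0 <- g0 - mean(g0)
  structure(list(g0 = g0, covariates = covariates, beta_local = beta_local,
                 gamma_dispersion = gamma_dispersion, noise_sd = noise_sd,
                 networks = networks, seed = as.integer(seed)),
            class = "ground_truth")
}

#' Simulate session-wise S-A loadings with planted effects
#'
#' The planted model behind the recovery tests: each session's loading
#' vector starts from the latent axis `g0`, receives additive local
#' covariate effects `beta_local %*% z`, is then scaled about each network's
#' median by `1 + gamma %*% z` (the dispersion planting, matching the median
#' definition of the dispersion statistics), and finally receives i.i.d.
#' Gaussian noise.  Covariates are z-scored inside the model so `beta` is in
#' loading units per covariate SD.  With all effects and noise zero, every
#' session equals `g0` exactly.
#'
#' @param meta A [parcellation_meta()].
#' @param truth A [make_ground_truth()] object.
#' @param cov A [covariate_table()] containing every covariate named in
#'   `truth`.
#' @return A list with class `simulated_loadings`: `loadings` (P x S),
#'   `truth`, `session_ids`.
#' @export
simulate_session_loadings <- function(meta, truth, cov) {
  miss <- setdiff(truth$covariates, names(cov))
  if (length(miss)) {
    stop_axisflux("covariate(s) named in ground truth missing from table: %s",
                  paste(miss, collapse = ", "))
  }
  S <- nrow(cov)
  p <- nrow(meta)
  G <- matrix(truth$g0, p, S)
  if (length(truth$covariates)) {
    Z <- zscore_columns(as.data.frame(cov)[truth$covariates])
    G <- G + truth$beta_local %*% t(Z)
    if (any(truth$gamma_dispersion != 0)) {
      for (s in seq_len(S)) {
        for (k in seq_along(truth$networks)) {
          net <- truth$networks[k]
          rows <- meta$network == net
          f <- 1 + sum(truth$gamma_dispersion[, k] * Z[s, ])
          f <- max(f, 0.05)
          med <- stats::median(G[rows, s])
          G[rows, s] <- med + (G[rows, s] - med) * f
        }
      }
    }
  }
  if (truth$noise_sd > 0) {
    G <- G + with_substream(truth$seed, "loading_noise",
                            matrix(stats::rnorm(p * S, 0, truth$noise_sd), p, S))
  }
  colnames(G) <- cov$session_id
  structure(list(loadings = G, truth = truth, session_ids = cov$session_id),
            class = "simulated_loadings")
}

#' Simulate a smooth parcel-level feature map
#'
#' Draws a spatially autocorrelated map over the parcellation as a random
#' mixture of spherical Gaussian bumps.  With `bilateral = TRUE` (default)
#' the map is mirror-symmetric across hemispheres, matching the bilateral
#' structure of real cortical feature maps and of the mirrored-rotation spin
#' null; such maps are the appropriate null ensemble for calibrating
#' spin-permutation tests.
#'
#' @param meta A [parcellation_meta()].
#' @param seed Integer seed.
#' @param width Angular width (radians) of the Gaussian bumps; larger is
#'   smoother.
#' @param n_bumps Number of bumps mixed.
#' @param bilateral Mirror-symmetric across hemispheres (default `TRUE`).
#' @return Numeric P-vector.
#' @export
simulate_smooth_map <- function(meta, seed = 1L, width = 0.3, n_bumps = 25L,
                                bilateral = TRUE) {
  X <- as.matrix(meta[, c("x", "y", "z")])
  with_substream(seed, "smooth_map", {
    ctr <- matrix(stats::rnorm(3 * n_bumps), n_bumps, 3)
    amps <- stats::rnorm(n_bumps)
    if (bilateral) {
      ctr[, 1] <- abs(ctr[, 1])
      X[, 1] <- abs(X[, 1])
    }
    ctr <- ctr / sqrt(rowSums(ctr^2))
    ang <- acos(pmin(pmax(X %*% t(ctr), -1), 1))
    drop(exp(-ang^2 / (2 * width^2)) %*% amps)
  })
}

#' Simulate a session's parcel time series from axis loadings
#'
#' Factor model guaranteeing that coherence connectivity recovers the
#' loading geometry: band-limited latent sources (white noise band-passed to
#' the analysis band) are mixed into parcels with Gaussian weights that
#' decay with the distance between a parcel's loading and each source's
#' center along the axis, plus white observation noise.  Parcels with
#' similar loadings share sources and are therefore coherent in band;
#' distant parcels are not.  Deterministic given `seed`.
#'
#' @param loadings P-vector of axis loadings for this session.
#' @param n_timepoints Number of timepoints (>= 128).
#' @param tr Repetition time in seconds.
#' @param seed Integer seed.
#' @param n_sources Number of latent band-limited sources.
#' @param source_strength Mixing amplitude; 0 gives independent-noise-only
#'   series.
#' @param noise_sd White observation noise SD.
#' @param scales Wavelet scales defining the source band (default 3--6).
#' @param session_id,subject_id Identifiers for the record.
#' @return A [session_record()].
#' @export
simulate_timeseries <- function(loadings, n_timepoints, tr, seed = 1L,
                                n_sources = 12L, source_strength = 1,
                                noise_sd = 0.4, scales = 3:6,
                                session_id = "ses-01", subject_id = "sim") {
  if (n_timepoints < 128L) {
    stop_axisflux("n_timepoints must be >= 128, got %d", n_timepoints)
  }
  p <- length(loadings)
  band <- passband_edges(tr, scales)
  with_substream(seed, paste0("timeseries_", session_id), {
    ## band-limited unit-variance sources via FFT masking of white noise
    freqs <- (0:(n_timepoints - 1)) / (n_timepoints * tr)
    fold <- pmin(freqs, 1 / tr - freqs)
    mask <- fold >= band[1] & fold <= band[2]
    src <- matrix(stats::rnorm(n_timepoints * n_sources), n_timepoints)
    ft <- stats::mvfft(src)
    ft[!mask, ] <- 0
    src <- Re(stats::mvfft(ft, inverse = TRUE)) / n_timepoints
    src <- scale(src)

    ## sources tile the axis at equal quantiles of the loading distribution
    ## (rank position), so every stretch of the axis is equally represented
    ## regardless of how loadings cluster; ties share a rank and therefore a
    ## mixing profile.
    u <- (rank(loadings, ties.method = "average") - 0.5) / p
    centers <- seq(min(u), max(u), length.out = n_sources)
    bw <- 1 / 8
    W <- exp(-outer(u, centers, `-`)^2 / (2 * bw^2))
    W <- W / pmax(sqrt(rowSums(W^2)), 1e-12)
    series <- source_strength * (W %*% t(src)) +
      noise_sd * matrix(stats::rnorm(p * n_timepoints), p)
    session_record(subject_id, session_id, tr, series,
                   time_of_day = "morning")
  })
}
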