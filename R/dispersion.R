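## Canonical pair naming: lexicographic in the fixed seven-network order.
network_pairs <- function(networks) {
  cmb <- utils::combn(networks, 2L)
  paste(cmb[1L, ], cmb[2L, ], sep = "-")
}

#' Within-network dispersion along the S-A axis
#'
#' For each network, the sum of squared (one-dimensional Euclidean)
#' distances between the network's parcel loadings and the network centroid,
#' quantified as the median loading of the network's parcels:
#' `D_w(n) = sum_p (g_p - median_n)^2`.  Larger values mean the network's
#' parcels are more spread out (more segregated) along the axis.
#'
#' @param loadings P-vector of S-A axis loadings.
#' @param labels P-vector of network labels (every network non-empty).
#' @param networks Optional network ordering (default: canonical order of
#'   the labels present).
#' @return Named vector of within-network dispersion, one per network.
#' @export
within_dispersion <- function(loadings, labels, networks = network_levels(labels)) {
  vapply(networks, function(n) {
    g <- loadings[labels == n]
    if (!length(g)) stop_axisflux("empty network '%s'", n)
    sum((g - stats::median(g))^2)
  }, numeric(1))
}

#' Between-network dispersion along the S-A axis
#'
#' For each unordered pair of networks, the (one-dimensional Euclidean)
#' distance between the two network centroids (median loadings):
#' `D_b(n, m) = |median_n - median_m|`.  Pairs follow the fixed canonical
#' network order (21 pairs for seven networks).
#'
#' @inheritParams within_dispersion
#' @return Named vector of between-network dispersion, one per pair.
#' @export
between_dispersion <- function(loadings, labels, networks = network_levels(labels)) {
  med <- vapply(networks, function(n) {
    g <- loadings[labels == n]
    if (!length(g)) stop_axisflux("empty network '%s'", n)
    stats::median(g)
  }, numeric(1))
  cmb <- utils::combn(seq_along(networks), 2L)
  out <- abs(med[cmb[1L, ]] - med[cmb[2L, ]])
  names(out) <- network_pairs(networks)
  out
}

#' Session-wise dispersion series
#'
#' Applies [within_dispersion()] and [between_dispersion()] to every
#' session's aligned S-A axis, giving an S x 7 within-network and an S x 21
#' between-network dispersion table.
#'
#' @param axes An [aligned_axes()] object.
#' @param meta A [parcellation_meta()] supplying the network labels.
#' @return A list with class `dispersion_series`: `within` (S x networks),
#'   `between` (S x pairs), `network_names`, `pair_names`, `session_ids`.
#' @export
dispersion_series <- function(axes, meta) {
  if (nrow(axes$loadings) != nrow(meta)) {
    stop_axisflux("axes and metadata disagree on parcel count")
  }
  networks <- network_levels(meta$network)
  S <- ncol(axes$loadings)
  W <- t(apply(axes$loadings, 2L, within_dispersion,
               labels = meta$network, networks = networks))
  B <- t(apply(axes$loadings, 2L, between_dispersion,
               labels = meta$network, networks = networks))
  rownames(W) <- rownames(B) <- axes$session_ids
  structure(list(within = W, between = B, network_names = networks,
                 pair_names = colnames(B), session_ids = axes$session_ids),
            class = "dispersion_series")
}

#' @export
print.dispersion_series <- function(x, ...) {
  cat(sprintf("dispersion_series: %d sessions x (%d within + %d between)\n",
              nrow(x$within), ncol(x$within), ncol(x$between)))
  invisible(x)
}

#' Covariate effects on network dispersion
#'
#' Fits, for each of the within-network and between-network dispersion
#' measures, the same covariate model used for the local effects (z-scored
#' covariates, per-session random intercept with the documented OLS
#' fallback).  Significance uses Bonferroni family thresholds:
#' `alpha_within` for the 7 within-network tests and `alpha_between` for the
#' 21 between-network tests (defaults 0.025/7 and 0.025/21).  Positive t
#' means increasing segregation with the covariate; negative t means
#' increasing integration.
#'
#' @param series A [dispersion_series()].
#' @param cov A [covariate_table()] matching the series' sessions.
#' @param covariates Character vector of covariate names.
#' @param alpha_within,alpha_between Family significance thresholds.
#' @return A data.frame with columns `measure`, `family`, `covariate`, `t`,
#'   `p`, `bonferroni_significant`, `model_flag`.
#' @export
fit_dispersion_effects <- function(series, cov, covariates,
                                   alpha_within = 0.025 / 7,
                                   alpha_between = 0.025 / 21) {
  fake_axes <- list(session_ids = series$session_ids)
  cov <- match_sessions(fake_axes, cov)
  Z <- zscore_columns(as.data.frame(cov)[covariates])
  colnames(Z) <- covariates
  measures <- cbind(series$within, series$between)
  fam <- c(rep("within", ncol(series$within)),
           rep("between", ncol(series$between)))
  mnames <- c(paste0("within:", colnames(series$within)),
              paste0("between:", colnames(series$between)))
  rows <- list()
  for (m in seq_len(ncol(measures))) {
    r <- fit_effect_model(measures[, m], Z, series$session_ids)
    alpha <- if (fam[m] == "within") alpha_within else alpha_between
    rows[[m]] <- data.frame(
      measure = mnames[m], family = fam[m], covariate = covariates,
      t = unname(r$t), p = unname(r$p),
      bonferroni_significant = unname(r$p) < alpha,
      model_flag = r$flag, row.names = NULL)
  }
  do.call(rbind, rows)
}

#' Spatial specificity of a dispersion effect
#'
#' Tests whether a Bonferroni-surviving dispersion effect is specific to the
#' network topography rather than a spatially global property: for each spin
#' permutation the parcels' network labels are re-derived through the spin
#' index (loadings stay fixed), the dispersion measure is recomputed for
#' every session, the effect model is refit, and the observed t is compared
#' with the null t distribution two-sidedly.  Permutations in which a
#' network involved in the measure receives no parcels are dropped from the
#' null.
#'
#' @param axes An [aligned_axes()] object.
#' @param meta A [parcellation_meta()].
#' @param cov A [covariate_table()].
#' @param measure Measure name as in [fit_dispersion_effects()] output,
#'   e.g. `"within:frontoparietal"` or `"between:visual-somatomotor"`.
#' @param covariate Covariate name whose effect is tested.
#' @param spins A [spin_index()] on the same parcellation.
#' @param covariates Covariate set of the model (defaults to `covariate`
#'   alone).
#' @return A list `(t_obs, p_spin, n_null)`.
#' @export
spin_specificity <- function(axes, meta, cov, measure, covariate, spins,
                             covariates = covariate) {
  stopifnot(covariate %in% covariates)
  networks <- network_levels(meta$network)
  parts <- strsplit(measure, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !parts[1] %in% c("within", "between")) {
    stop_axisflux("unknown measure '%s'", measure)
  }
  fam <- parts[1]
  target <- parts[2]
  involved <- if (fam == "within") target else strsplit(target, "-", fixed = TRUE)[[1]]
  if (!all(involved %in% networks)) {
    stop_axisflux("measure names unknown network(s): %s", target)
  }
  cov_m <- match_sessions(axes, cov)
  Z <- zscore_columns(as.data.frame(cov_m)[covariates])
  colnames(Z) <- covariates

  measure_series <- function(labels) {
    if (fam == "within") {
      apply(axes$loadings, 2L, function(g) {
        x <- g[labels == target]
        if (!length(x)) return(NA_real_)
        sum((x - stats::median(x))^2)
      })
    } else {
      apply(axes$loadings, 2L, function(g) {
        x1 <- g[labels == involved[1]]
        x2 <- g[labels == involved[2]]
        if (!length(x1) || !length(x2)) return(NA_real_)
        abs(stats::median(x1) - stats::median(x2))
      })
    }
  }
  fit_t <- function(y) {
    if (anyNA(y)) return(NA_real_)
    unname(fit_effect_model(y, Z, axes$session_ids)$t[covariate])
  }
  t_obs <- fit_t(measure_series(meta$network))
  t_null <- vapply(seq_len(spins$n_perm), function(j) {
    fit_t(measure_series(meta$network[spins$index[, j]]))
  }, numeric(1))
  ok <- !is.na(t_null)
  list(t_obs = t_obs,
       p_spin = spin_pvalue(t_obs, t_null[ok], two_sided = TRUE),
       n_null = sum(ok))
}
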