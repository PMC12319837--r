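#' @importFrom lmerTest lmer
#' @importFrom lme4 isSingular
NULL

## Align a covariate table to the session order of an aligned_axes object.
match_sessions <- function(axes, cov) {
  idx <- match(axes$session_ids, cov$session_id)
  if (anyNA(idx)) {
    stop_axisflux("sessions missing from covariate table: %s",
                  paste(axes$session_ids[is.na(idx)], collapse = ", "))
  }
  extra <- setdiff(cov$session_id, axes$session_ids)
  if (length(extra)) {
    stop_axisflux("covariate table has sessions not in axes: %s",
                  paste(extra, collapse = ", "))
  }
  cov[idx, , drop = FALSE]
}

## Core single-response fitter shared by the local and dispersion effect
## models: response ~ z-scored covariates with a per-session random
## intercept.  With one observation per session the random-intercept
## variance is not identifiable, so the fallback ladder goes straight to
## OLS (flag "ols_fallback"); with replicated sessions the model is fit by
## REML via lmerTest (Satterthwaite t and p), flagged "boundary_fit" when
## the variance estimate is at the boundary.
fit_effect_model <- function(y, Z, groups) {
  k <- ncol(Z)
  if (!anyDuplicated(groups)) {
    X <- cbind(1, Z)
    fit <- stats::lm.fit(X, y)
    df <- length(y) - ncol(X)
    sigma2 <- max(sum(fit$residuals^2) / df, 1e-300)
    xtxi <- chol2inv(chol(crossprod(X)))
    se <- sqrt(diag(xtxi) * sigma2)
    tval <- fit$coefficients / se
    list(t = tval[-1], p = 2 * stats::pt(-abs(tval[-1]), df),
         flag = "ols_fallback")
  } else {
    dat <- data.frame(y = y, Z, session = factor(groups))
    form <- stats::as.formula(paste(
      "y ~", paste(colnames(Z), collapse = " + "), "+ (1 | session)"))
    fit <- tryCatch(
      suppressMessages(suppressWarnings(lmerTest::lmer(form, data = dat,
                                                       REML = TRUE))),
      error = function(e) NULL)
    if (is.null(fit)) {
      res <- fit_effect_model(y, Z, seq_along(y))
      res$flag <- "ols_fallback"
      return(res)
    }
    co <- stats::coef(summary(fit))
    list(t = co[-1, "t value"], p = co[-1, "Pr(>|t|)"],
         flag = if (lme4::isSingular(fit)) "boundary_fit" else "mixed_ok")
  }
}

## Vectorised OLS over many responses (used for the one-obs-per-session
## design, which is the canonical dense-sampling case).
ols_tmaps <- function(Y, Z) {
  X <- cbind(1, Z)
  S <- nrow(Y); k <- ncol(X)
  xtxi <- chol2inv(chol(crossprod(X)))
  B <- xtxi %*% crossprod(X, Y)
  resid <- Y - X %*% B
  df <- S - k
  sigma2 <- pmax(colSums(resid^2) / df, 1e-300)
  tmat <- matrix(NA_real_, ncol(Z), ncol(Y))
  for (j in seq_len(ncol(Z))) {
    tmat[j, ] <- B[j + 1L, ] / sqrt(xtxi[j + 1L, j + 1L] * sigma2)
  }
  list(t = tmat, p = 2 * stats::pt(-abs(tmat), df), df = df)
}

#' Per-parcel covariate effects on S-A loadings
#'
#' Fits, for every parcel, a model of its session-wise S-A axis loading on
#' the named covariates (jointly, z-scored within subject so effect sizes
#' are per covariate SD), with a per-session random intercept to respect the
#' longitudinal structure.  When each session contributes exactly one
#' observation the random intercept is unidentifiable and the model reduces
#' deterministically to OLS (`model_flags = "ols_fallback"`); replicated
#' sessions are fit by REML via `lmerTest`.  Two-sided t tests per fixed
#' effect; Benjamini-Hochberg FDR across parcels, separately per covariate.
#'
#' @param axes An [aligned_axes()] object.
#' @param cov A [covariate_table()] whose sessions match `axes` exactly.
#' @param covariates Character vector of covariate column names (each
#'   non-constant).
#' @param q_threshold FDR threshold (default 0.05).
#' @return A named list of `effect_map` objects, one per covariate, each
#'   with `covariate`, `t`, `p`, `q`, `significant`, `n_sessions`,
#'   `model_flags`.
#' @export
fit_local_effects <- function(axes, cov, covariates, q_threshold = 0.05) {
  cov <- match_sessions(axes, cov)
  miss <- setdiff(covariates, names(cov))
  if (length(miss)) {
    stop_axisflux("covariate(s) not in table: %s", paste(miss, collapse = ", "))
  }
  Z <- zscore_columns(as.data.frame(cov)[covariates])
  colnames(Z) <- covariates
  Y <- t(axes$loadings)                      # S x P
  S <- nrow(Y); P <- ncol(Y)
  groups <- axes$session_ids

  if (!anyDuplicated(groups)) {
    fit <- ols_tmaps(Y, Z)
    flags <- rep("ols_fallback", P)
    tmat <- fit$t; pmat <- fit$p
  } else {
    tmat <- matrix(NA_real_, length(covariates), P)
    pmat <- matrix(NA_real_, length(covariates), P)
    flags <- character(P)
    for (j in seq_len(P)) {
      r <- fit_effect_model(Y[, j], Z, groups)
      tmat[, j] <- r$t; pmat[, j] <- r$p; flags[j] <- r$flag
    }
  }
  out <- lapply(seq_along(covariates), function(i) {
    q <- bh_adjust(pmat[i, ])
    structure(list(covariate = covariates[i], t = tmat[i, ], p = pmat[i, ],
                   q = q, significant = q < q_threshold, n_sessions = S,
                   model_flags = flags),
              class = "effect_map")
  })
  names(out) <- covariates
  out
}

#' @export
print.effect_map <- function(x, ...) {
  cat(sprintf("effect_map '%s': %d parcels, %d sessions, %d significant (FDR)\n",
              x$covariate, length(x$t), x$n_sessions, sum(x$significant)))
  invisible(x)
}

#' Compare two t-maps across subjects
#'
#' Spearman rank correlation between two unthresholded parcel-wise t-maps,
#' with a two-sided spin-permutation p-value obtained by spinning the first
#' map's t-vector.
#'
#' @param mapA,mapB `effect_map` objects (or numeric vectors) on the same
#'   parcellation.
#' @param spins A [spin_index()].
#' @return A list `(spearman_r, p_spin)`.
#' @export
compare_tmaps <- function(mapA, mapB, spins) {
  ta <- if (inherits(mapA, "effect_map")) mapA$t else as.numeric(mapA)
  tb <- if (inherits(mapB, "effect_map")) mapB$t else as.numeric(mapB)
  if (length(ta) != length(tb)) {
    stop_axisflux("t-map length mismatch: %d vs %d", length(ta), length(tb))
  }
  r <- stats::cor(ta, tb, method = "spearman")
  spun <- matrix(ta[spins$index], nrow = length(ta))
  nulls <- apply(spun, 2L, stats::cor, y = tb, method = "spearman")
  list(spearman_r = r, p_spin = spin_pvalue(r, nulls, two_sided = TRUE))
}

#' Mann-Whitney U comparison of two covariate distributions
#'
#' Two-sided Mann-Whitney U test: exact permutation enumeration when the
#' combined sample size is at most 20 (ties handled by enumeration), and the
#' tie-corrected normal approximation with continuity correction otherwise.
#' Reports the U statistic of the first sample.
#'
#' @param a,b Non-empty numeric vectors.
#' @return A list `(U, p)`.
#' @export
compare_covariate_distributions <- function(a, b) {
  if (!length(a) || !length(b)) stop_axisflux("empty input sample")
  na <- length(a); nb <- length(b)
  rk <- rank(c(a, b))
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (na + nb <= 20L) {
    idx <- utils::combn(na + nb, na)
    u_all <- colSums(matrix(rk[idx], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-12)
  } else {
    n <- na + nb
    ties <- table(rk)
    sigma <- sqrt(na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1))))
    z <- (abs(U - mu) - 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
  }
  list(U = U, p = p)
}
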