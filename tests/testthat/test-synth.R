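test_that("synthetic parcellations are balanced, labelled, and deterministic", {
  meta <- make_parcellation(400, 7, seed = 1)
  expect_equal(sum(meta$hemisphere == "L"), 200)
  expect_equal(sum(meta$hemisphere == "R"), 200)
  expect_setequal(unique(meta$network), network_names())
  expect_true(all(abs(sqrt(meta$x^2 + meta$y^2 + meta$z^2) - 1) < 1e-9))
  ## networks are bilaterally mirrored patches
  expect_equal(meta$network[1:200], meta$network[201:400])

  a <- make_parcellation(10, 2, seed = 1)
  b <- make_parcellation(10, 2, seed = 1)
  expect_identical(a, b)
  expect_error(make_parcellation(9, 2, seed = 1), "even")
})

test_that("cycle covariates peak mid-series; diurnal covariates stay positive", {
  cyc <- simulate_covariates(29, "cycle", seed = 7)
  expect_true(which.max(cyc$estradiol) %in% 12:15)
  expect_true(all(cyc$estradiol > 0) && all(cyc$progesterone > 0))
  ## follicular-luteal contrast: progesterone low early, high late
  expect_lt(mean(cyc$progesterone[1:10]), mean(cyc$progesterone[18:27]))

  diu <- simulate_covariates(20, "diurnal", seed = 7)
  expect_true(all(diu$cortisol > 0) && all(diu$testosterone > 0))

  for (tab in list(cyc, diu)) {
    expect_true(is.integer(tab$pss_score))
    expect_true(all(tab$pss_score >= 0 & tab$pss_score <= 40))
  }
  expect_identical(simulate_covariates(29, "cycle", seed = 7), cyc)
})

test_that("planted loadings degenerate to g0 and recover planted slopes", {
  meta <- meta100()
  cov <- simulate_covariates(29, "cycle", seed = 3)

  tru0 <- make_ground_truth(meta, noise_sd = 0, seed = 4)
  sim0 <- simulate_session_loadings(meta, tru0, cov)
  expect_equal(sim0$loadings, matrix(tru0$g0, 100, 29,
                                     dimnames = list(NULL, cov$session_id)))

  ## beta_local = 1 on one parcel: OLS on the generated matrix recovers
  ## slope 1 within 3 SE
  beta <- matrix(0, 100, 1)
  beta[5, 1] <- 1
  tru <- make_ground_truth(meta, covariates = "estradiol", beta_local = beta,
                           noise_sd = 0.3, seed = 4)
  sim <- simulate_session_loadings(meta, tru, cov)
  z <- as.numeric(scale(cov$estradiol))
  fit <- summary(lm(sim$loadings[5, ] ~ z))
  expect_lt(abs(fit$coefficients["z", "Estimate"] - 1),
            3 * fit$coefficients["z", "Std. Error"])

  ## missing covariate in the table is an error
  expect_error(
    simulate_session_loadings(
      meta, make_ground_truth(meta, covariates = "cortisol", noise_sd = 0.1),
      cov),
    "cortisol")
})

test_that("planted dispersion modulation raises within-network dispersion", {
  meta <- meta100()
  cov <- simulate_covariates(29, "cycle", seed = 3)
  gamma <- matrix(0, 1, 7,
                  dimnames = list("estradiol", network_names()))
  gamma[1, "frontoparietal"] <- 0.3
  tru <- make_ground_truth(meta, covariates = "estradiol",
                           gamma_dispersion = gamma, noise_sd = 0.02,
                           seed = 4)
  sim <- simulate_session_loadings(meta, tru, cov)
  dw <- apply(sim$loadings, 2, function(g) {
    within_dispersion(g, meta$network)[["frontoparietal"]]
  })
  expect_gt(cor(cov$estradiol, dw), 0)
})

test_that("simulated time series are reproducible and coherence tracks loadings", {
  g <- seq(-1, 1, length.out = 20)
  g[2] <- g[1]                              # two parcels with equal loadings
  a <- simulate_timeseries(g, 256, 0.72, seed = 6)
  b <- simulate_timeseries(g, 256, 0.72, seed = 6)
  expect_identical(a$series, b$series)
  expect_error(simulate_timeseries(g, 100, 0.72), ">= 128")

  rec <- simulate_timeseries(g, 900, 0.72, seed = 6, noise_sd = 0.1)
  fc <- session_coherence_fc(rec, threshold = FALSE)
  expect_gt(fc$values[1, 2], 0.8)           # near-identical loadings
  expect_gt(fc$values[1, 2], fc$values[1, 20])  # distant pair is weaker

  noise <- simulate_timeseries(g, 900, 0.72, seed = 6, source_strength = 0)
  fcn <- session_coherence_fc(noise, threshold = FALSE)
  expect_lt(median(fcn$values[upper.tri(fcn$values)]), 0.2)
})

test_that("smooth feature maps are smooth and bilaterally symmetric", {
  meta <- meta100()
  m <- simulate_smooth_map(meta, seed = 11)
  expect_length(m, 100)
  ## mirrored parcels carry identical values
  expect_equal(m[meta$hemisphere == "L"], m[meta$hemisphere == "R"])
  ## spatial autocorrelation: neighbours more similar than random pairs
  X <- as.matrix(meta[, c("x", "y", "z")])
  d <- acos(pmin(pmax(tcrossprod(X), -1), 1))
  ut <- upper.tri(d)
  near <- d[ut] < quantile(d[ut], 0.05)
  dv <- abs(outer(m, m, "-"))[ut]
  expect_lt(mean(dv[near]), mean(dv[!near]))
})
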