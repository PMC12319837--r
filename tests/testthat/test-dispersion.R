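test_that("within- and between-network dispersion match their worked examples", {
  labels <- c("a", "a", "a", "b", "b")
  g <- c(1, 2, 3, 0, 0)
  dw <- within_dispersion(g, labels, networks = c("a", "b"))
  expect_equal(unname(dw), c(2, 0))        # median 2: (1-2)^2 + 0 + (3-2)^2

  g2 <- c(0, 0, 1, 3)
  db <- between_dispersion(g2, c("A", "A", "B", "B"), networks = c("A", "B"))
  expect_equal(unname(db), 2)              # medians 0 and 2

  expect_equal(length(between_dispersion(rnorm(70),
                                         rep(network_names(), 10))), 21)

  same <- within_dispersion(rep(1.5, 5), labels, networks = c("a", "b"))
  expect_true(all(same == 0))
  expect_error(within_dispersion(g, labels, networks = c("a", "zzz")),
               "empty network")
})

test_that("dispersion is translation invariant and scale equivariant", {
  set.seed(11)
  labels <- sample(network_names(), 80, replace = TRUE)
  g <- rnorm(80)
  dw <- within_dispersion(g, labels)
  db <- between_dispersion(g, labels)
  expect_equal(within_dispersion(g + 5, labels), dw, tolerance = 1e-12)
  expect_equal(between_dispersion(g + 5, labels), db, tolerance = 1e-12)
  expect_equal(within_dispersion(3 * g, labels), 9 * dw, tolerance = 1e-12)
  expect_equal(between_dispersion(3 * g, labels), 3 * db, tolerance = 1e-12)
})

test_that("production dispersion equals brute-force loops on random fixtures", {
  set.seed(12)
  for (r in 1:100) {
    n <- sample(20:60, 1)
    k <- sample(2:7, 1)
    networks <- network_names()[1:k]
    labels <- c(networks, sample(networks, n - k, replace = TRUE))
    g <- rnorm(n)
    expect_equal(within_dispersion(g, labels, networks),
                 brute_within(g, labels, networks), tolerance = 1e-12)
    expect_equal(between_dispersion(g, labels, networks),
                 brute_between(g, labels, networks), tolerance = 1e-12)
  }
})

test_that("total sum of squares bounds the within-network sum", {
  set.seed(13)
  for (r in 1:20) {
    labels <- sample(network_names(), 60, replace = TRUE)
    g <- rnorm(60)
    total_about_means <- sum((g - ave(g, labels))^2)
    ## the group-mean SS is the minimum; median centering can only grow it,
    ## and adding between-group spread grows the global total further
    expect_gte(sum((g - mean(g))^2) + 1e-12, total_about_means)
    expect_gte(sum(within_dispersion(g, labels)) + 1e-12, total_about_means)
  }
})

test_that("dispersion series stack sessions deterministically", {
  meta <- meta100()
  set.seed(14)
  L <- matrix(rnorm(100 * 6), 100)
  axes <- axes_from_matrix(L)
  ds <- dispersion_series(axes, meta)
  expect_equal(dim(ds$within), c(6, 7))
  expect_equal(dim(ds$between), c(6, 21))

  same <- dispersion_series(axes_from_matrix(L[, c(1, 1, 1)]), meta)
  expect_equal(same$within[1, ], same$within[3, ])

  perm <- c(3, 1, 2, 6, 5, 4)
  ds_p <- dispersion_series(axes_from_matrix(L[, perm]), meta)
  expect_equal(unname(ds_p$within), unname(ds$within[perm, ]))
})

test_that("dispersion effect models report Bonferroni families and recover planting", {
  meta <- meta100()
  cov <- simulate_covariates(29, "cycle", seed = 15)
  gamma <- matrix(0, 1, 7, dimnames = list("estradiol", network_names()))
  gamma[1, "frontoparietal"] <- 0.35
  tru <- make_ground_truth(meta, covariates = "estradiol",
                           gamma_dispersion = gamma, noise_sd = 0.02,
                           seed = 16)
  sim <- simulate_session_loadings(meta, tru, cov)
  axes <- axes_from_matrix(sim$loadings)
  ds <- dispersion_series(axes, meta)
  eff <- fit_dispersion_effects(ds, cov, "estradiol")

  expect_equal(nrow(eff), 28)
  expect_equal(sum(eff$family == "within"), 7)
  expect_equal(sum(eff$family == "between"), 21)
  hit <- eff[eff$measure == "within:frontoparietal", ]
  expect_gt(hit$t, 0)
  expect_true(hit$bonferroni_significant)

  ## the family thresholds round to the conventional 3-decimal values
  expect_equal(round(0.025 / 7, 3), 0.004)
  expect_equal(round(0.025 / 21, 3), 0.001)
})

test_that("spin specificity separates network-specific from global effects", {
  meta <- meta100()
  spins <- spins100(200)
  cov <- simulate_covariates(24, "cycle", seed = 17)

  gamma <- matrix(0, 1, 7, dimnames = list("estradiol", network_names()))
  gamma[1, "frontoparietal"] <- 0.4
  tru <- make_ground_truth(meta, covariates = "estradiol",
                           gamma_dispersion = gamma, noise_sd = 0.02,
                           seed = 18)
  sim <- simulate_session_loadings(meta, tru, cov)
  axes <- axes_from_matrix(sim$loadings)
  sp <- spin_specificity(axes, meta, cov, "within:frontoparietal",
                         "estradiol", spins)
  expect_lte(sp$p_spin, 0.05)
  expect_gte(sp$p_spin, 1 / (spins$n_perm + 1))

  ## a spatially global effect -- the whole map scaled about its global
  ## median -- survives relabelling and must not look network-specific
  z <- as.numeric(scale(cov$estradiol))
  tru0 <- make_ground_truth(meta, noise_sd = 0.02, seed = 18)
  set.seed(1)
  G <- sapply(seq_len(24), function(s) {
    g <- tru0$g0
    med <- median(g)
    med + (g - med) * (1 + 0.3 * z[s]) + rnorm(100, 0, 0.02)
  })
  colnames(G) <- cov$session_id
  sp_g <- spin_specificity(axes_from_matrix(G), meta, cov,
                           "within:frontoparietal", "estradiol", spins)
  expect_gt(sp_g$p_spin, 0.2)
})
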