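## Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, build(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

meta100 <- function() fixture("meta100", function() make_parcellation(100, 7, seed = 2))
meta40 <- function() fixture("meta40", function() make_parcellation(40, 4, seed = 5))

## small set of spins reused across spatial-null tests
spins100 <- function(n_perm = 200) {
  fixture(paste0("spins100_", n_perm),
          function() generate_spins(meta100(), n_perm, seed = 9))
}

## axes built directly from a loading matrix (bypassing the connectome stage)
axes_from_matrix <- function(loadings, subject_id = "sub") {
  aligned_axes(loadings, subject_id = subject_id)
}

## brute-force dispersion oracles: plain loops, no vectorisation
brute_within <- function(loadings, labels, networks) {
  out <- numeric(length(networks))
  for (k in seq_along(networks)) {
    g <- c()
    for (i in seq_along(loadings)) {
      if (labels[i] == networks[k]) g <- c(g, loadings[i])
    }
    m <- stats::median(g)
    s <- 0
    for (v in g) s <- s + (v - m)^2
    out[k] <- s
  }
  names(out) <- networks
  out
}

brute_between <- function(loadings, labels, networks) {
  med <- numeric(length(networks))
  for (k in seq_along(networks)) {
    med[k] <- stats::median(loadings[labels == networks[k]])
  }
  out <- c()
  nms <- c()
  for (i in seq_along(networks)) {
    for (j in seq_along(networks)) {
      if (j > i) {
        out <- c(out, abs(med[i] - med[j]))
        nms <- c(nms, paste(networks[i], networks[j], sep = "-"))
      }
    }
  }
  names(out) <- nms
  out
}
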