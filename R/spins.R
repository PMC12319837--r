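#' Spin permutation index
#'
#' Holds hemisphere-preserving spherical rotation permutations of parcels:
#' `index[i, j]` names the parcel whose value parcel `i` receives under
#' rotation `j`, so a map `v` is spun as `v[index[, j]]`.  Assignments are
#' nearest-centroid and may be many-to-one, as is standard for parcel-level
#' spin tests.
#'
#' @param index P x n_perm integer matrix.
#' @param n_perm Number of permutations.
#' @param seed Seed used to generate the rotations.
#' @return A list with class `spin_index`.
#' @export
spin_index <- function(index, n_perm = ncol(index), seed = NA_integer_) {
  index <- as.matrix(index)
  storage.mode(index) <- "integer"
  if (any(index < 1L) || any(index > nrow(index))) {
    stop_axisflux("spin index entries must be in 1..P")
  }
  structure(list(index = index, n_perm = as.integer(n_perm),
                 seed = seed),
            class = "spin_index")
}

#' @export
print.spin_index <- function(x, ...) {
  cat(sprintf("spin_index: %d parcels x %d permutations (seed %s)\n",
              nrow(x$index), x$n_perm, format(x$seed)))
  invisible(x)
}

## uniform random rotation in SO(3): QR of a Gaussian matrix with the sign
## of R's diagonal absorbed; a determinant of -1 is corrected by negating
## one column (a measure-preserving map from O(3) \ SO(3) onto SO(3)).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Assign rotated parcel centroids (one rotation)
#'
#' Applies a single 3D rotation to the left-hemisphere centroids and the
#' x-mirrored rotation to the right hemisphere, then maps each original
#' parcel location to its nearest rotated centroid within the same
#' hemisphere.  Exposed so that the identity rotation can be checked to give
#' the identity permutation.
#'
#' @param meta A [parcellation_meta()].
#' @param rotation A 3 x 3 rotation matrix.
#' @return Integer P-vector of parcel assignments.
#' @export
spin_assignment <- function(meta, rotation) {
  X <- as.matrix(meta[, c("x", "y", "z")])
  nrm <- sqrt(rowSums(X^2))
  if (any(abs(nrm - 1) > 1e-9)) stop_axisflux("centroids must be unit norm")
  mirror <- diag(c(-1, 1, 1))
  idx <- integer(nrow(meta))
  for (h in c("L", "R")) {
    rows <- which(meta$hemisphere == h)
    R <- if (h == "L") rotation else mirror %*% rotation %*% mirror
    rot <- X[rows, , drop = FALSE] %*% t(R)
    ## nearest rotated centroid to each original location (cosine = nearest
    ## on the unit sphere)
    sim <- X[rows, , drop = FALSE] %*% t(rot)
    idx[rows] <- rows[max.col(sim, ties.method = "first")]
  }
  idx
}

#' Generate spherical spin permutations
#'
#' Draws `n_perm` uniform random 3D rotations (QR of a Gaussian matrix with
#' determinant corrected to +1), applies each to the left-hemisphere
#' centroids and its x-mirrored counterpart to the right hemisphere (so the
#' null respects bilateral symmetry), and reassigns parcels by nearest
#' centroid within hemisphere.  Deterministic given `seed`.
#'
#' @param meta A [parcellation_meta()] with unit-norm centroids.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return A [spin_index()].
#' @export
generate_spins <- function(meta, n_perm = 1000L, seed = 1L) {
  if (n_perm < 1) stop_axisflux("n_perm must be >= 1")
  idx <- matrix(NA_integer_, nrow(meta), n_perm)
  with_substream(seed, "spins", {
    for (j in seq_len(n_perm)) {
      idx[, j] <- spin_assignment(meta, random_rotation())
    }
  })
  spin_index(idx, n_perm, seed)
}

#' Permutation p-value
#'
#' Exact-style permutation p with the +1 correction, so the smallest
#' attainable value is `1 / (n_perm + 1)` and p is never zero:
#' `p = (1 + #\{|null| >= |observed|\}) / (1 + n_perm)` (two-sided), or the
#' analogous one-sided count.
#'
#' @param observed Observed statistic (scalar).
#' @param null_values Numeric vector of null statistics.
#' @param two_sided Two-sided comparison on magnitudes (default `TRUE`).
#' @return p-value in (0, 1\].
#' @export
spin_pvalue <- function(observed, null_values, two_sided = TRUE) {
  null_values <- null_values[!is.na(null_values)]
  if (!length(null_values)) stop_axisflux("empty null distribution")
  if (two_sided) {
    (1 + sum(abs(null_values) >= abs(observed))) / (1 + length(null_values))
  } else {
    (1 + sum(null_values >= observed)) / (1 + length(null_values))
  }
}
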