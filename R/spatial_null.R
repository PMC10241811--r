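# Spatial-autocorrelation-preserving permutation ("spin") tests for
# map-vs-map correlations on the sphere, vertex-level and parcel-level.

#' Fibonacci sphere lattice
#'
#' Near-uniform unit-sphere vertex coordinates; a synthetic stand-in for a
#' spherical cortical surface projection, so spin tests need no surface
#' files.
#'
#' @param n Number of vertices.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 4L)
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1L)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Haar-uniform random rotation matrix
#'
#' Proper rotation (orthonormal, det = +1) drawn uniformly from SO(3) via QR
#' decomposition of a Gaussian matrix with sign correction.
#'
#' @return 3 x 3 rotation matrix.
#' @export
random_rotation <- function() {
  M <- matrix(stats::rnorm(9L), 3L, 3L)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  # fix the sign ambiguity so Q is Haar-distributed, then ensure det +1
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

# Nearest-neighbour index map for one rotation: entry v is the original
# vertex nearest (greatest dot product = smallest great-circle distance) to
# R %*% coords[v, ]; ties break to the lowest index.
rotation_index <- function(coords, R) {
  D <- (coords %*% t(R)) %*% t(coords)   # D[v, u] = <R x_v, x_u>
  max.col(D, ties.method = "first")
}

#' Spin a vertex-level map
#'
#' Rotates the map on the sphere: the value at vertex v becomes the value of
#' the original vertex nearest to the rotated position of v.
#'
#' @param map Numeric vector per vertex.
#' @param coords n x 3 unit-vector matrix (e.g. [fibonacci_sphere()]).
#' @param R 3 x 3 rotation matrix.
#' @return Rotated map (same length; multiset of values preserved up to
#'   nearest-neighbour duplication).
#' @export
spin_map_vertex <- function(map, coords, R) {
  stopifnot(length(map) == nrow(coords))
  map[rotation_index(coords, R)]
}

#' Spin a parcel-level map
#'
#' Vazquez-Rodriguez adaptation for parcellated data: parcel values are
#' projected to their vertices, rotated at the vertex level, and re-averaged
#' within the original parcels.
#'
#' @param parcel_map Numeric vector, one value per parcel.
#' @param coords n x 3 vertex coordinates.
#' @param labels Integer parcel label per vertex (values `1..n_parcels`,
#'   every parcel nonempty).
#' @param R 3 x 3 rotation matrix.
#' @return Rotated parcel map (length `n_parcels`).
#' @export
spin_map_parcel <- function(parcel_map, coords, labels, R) {
  np <- length(parcel_map)
  if (!all(sort(unique(labels)) %in% seq_len(np)) ||
      length(unique(labels)) != np)
    stop("every parcel 1..n_parcels must own at least one vertex")
  vert <- parcel_map[labels]
  rot <- spin_map_vertex(vert, coords, R)
  as.numeric(tapply(rot, labels, mean))
}

#' Precompute rotation nearest-neighbour maps
#'
#' The expensive part of a spin ensemble depends only on the geometry, so
#' the index maps can be generated once and shared across many tests on the
#' same sphere.
#'
#' @param coords n x 3 vertex coordinates.
#' @param n_perm Number of rotations.
#' @param seed RNG seed.
#' @return n x n_perm integer matrix of vertex reassignment indices.
#' @export
spin_rotation_maps <- function(coords, n_perm, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n_perm), function(k) rotation_index(coords, random_rotation()),
         integer(nrow(coords)))
}

#' Spin permutation test for a map-vs-map correlation
#'
#' Observed statistic: Spearman rho between `map_x` and `map_y`. Null: rho
#' between rotated realizations of `map_x` and the fixed `map_y`. Two-sided
#' p with the add-one convention, `p = (1 + #(|null| >= |obs|)) / (n_perm + 1)`,
#' so p is never 0.
#'
#' @param map_x,map_y Numeric vertex maps on the same sphere (`map_x` is
#'   rotated).
#' @param coords n x 3 vertex coordinates.
#' @param n_perm Ensemble size (default 10000; below 100 warns).
#' @param seed RNG seed for the rotations.
#' @param rot_maps Optional precomputed [spin_rotation_maps()] (overrides
#'   `n_perm`/`seed`).
#' @return List of class `spin_test`: `observed`, `null` (vector), `p`,
#'   `n_perm`.
#' @export
spin_test <- function(map_x, map_y, coords, n_perm = 10000L, seed = NULL,
                      rot_maps = NULL) {
  stopifnot(length(map_x) == length(map_y))
  if (is.null(rot_maps)) {
    if (n_perm < 100L) warning("n_perm < 100 gives a coarse null")
    rot_maps <- spin_rotation_maps(coords, n_perm, seed)
  }
  n_perm <- ncol(rot_maps)
  obs <- spearman(map_x, map_y)
  ry <- rank(map_y)
  null_rho <- apply(rot_maps, 2L, function(idx) {
    stats::cor(rank(map_x[idx]), ry)
  })
  p <- (1 + sum(abs(null_rho) >= abs(obs))) / (n_perm + 1)
  structure(list(observed = obs, null = null_rho, p = p, n_perm = n_perm),
            class = "spin_test")
}

#' @export
print.spin_test <- function(x, ...) {
  cat(sprintf("spin_test: observed rho = %.3f, p_perm = %.4g (%d rotations)\n",
              x$observed, x$p, x$n_perm))
  invisible(x)
}

#' Smooth random map on the sphere
#'
#' White noise smoothed by a Gaussian great-circle kernel: a spatially
#' autocorrelated null fixture for calibration studies.
#'
#' @param coords n x 3 vertex coordinates.
#' @param fwhm_rad Smoothing kernel FWHM in radians.
#' @param kernel Optional precomputed [sphere_smoothing_kernel()]; computing
#'   it once and reusing it makes repeated draws cheap.
#' @return Numeric map of length n, z-scored.
#' @export
smooth_sphere_map <- function(coords, fwhm_rad = 0.5, kernel = NULL) {
  if (is.null(kernel)) kernel <- sphere_smoothing_kernel(coords, fwhm_rad)
  noise <- stats::rnorm(nrow(coords))
  sm <- as.numeric(kernel %*% noise)
  (sm - mean(sm)) / stats::sd(sm)
}

#' Gaussian great-circle smoothing kernel
#'
#' @inheritParams smooth_sphere_map
#' @return n x n kernel matrix.
#' @export
sphere_smoothing_kernel <- function(coords, fwhm_rad = 0.5) {
  sigma <- fwhm_rad / (2 * sqrt(2 * log(2)))
  ang <- acos(pmin(pmax(coords %*% t(coords), -1), 1))
  exp(-ang^2 / (2 * sigma^2))
}
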