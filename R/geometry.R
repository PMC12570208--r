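#' Detector geometry for a flat pixel-array detector
#'
#' Describes a single-panel detector downstream of the sample: pixel counts
#' along the fast and slow readout axes, pixel pitch, sample-detector
#' distance, X-ray wavelength and the beam center in fractional pixel
#' coordinates. All lengths are in meters; reciprocal-space quantities
#' derived from a geometry are in 1/meters.
#'
#' @param n_fast,n_slow integer pixel counts (>= 2).
#' @param pixel_size pixel pitch in meters.
#' @param distance sample-detector distance in meters.
#' @param wavelength X-ray wavelength in meters.
#' @param beam_center length-2 numeric, beam center as (fast, slow)
#'   fractional pixel coordinates; defaults to the detector center.
#' @return an object of class \code{"detector_geometry"}.
#' @examples
#' geom <- detector_geometry(64, 64, 1e-4, 0.1, 1e-10)
#' @export
detector_geometry <- function(n_fast, n_slow, pixel_size, distance, wavelength,
                              beam_center = c((n_fast - 1) / 2, (n_slow - 1) / 2)) {
  check_count(n_fast, "n_fast", min = 2L)
  check_count(n_slow, "n_slow", min = 2L)
  check_positive(pixel_size, "pixel_size")
  check_positive(distance, "distance")
  check_positive(wavelength, "wavelength")
  beam_center <- as.numeric(beam_center)
  if (length(beam_center) != 2L || anyNA(beam_center))
    stop_param("beam_center must be two finite numbers (fast, slow)")
  if (beam_center[1] < 0 || beam_center[1] > n_fast - 1 ||
      beam_center[2] < 0 || beam_center[2] > n_slow - 1)
    stop_param("beam_center lies outside the detector bounds")
  structure(list(n_fast = as.integer(n_fast), n_slow = as.integer(n_slow),
                 pixel_size = pixel_size, distance = distance,
                 wavelength = wavelength, beam_center = beam_center),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf("Detector %d x %d px, pitch %.3g m, distance %.3g m, lambda %.3g m\n",
              x$n_fast, x$n_slow, x$pixel_size, x$distance, x$wavelength))
  cat(sprintf("Beam center (fast, slow) = (%.2f, %.2f)\n",
              x$beam_center[1], x$beam_center[2]))
  invisible(x)
}

#' Angstrom-based convenience constructor
#'
#' Same as [detector_geometry()] but with \code{pixel_size_mm},
#' \code{distance_mm} and \code{wavelength_A} in the units beamline users
#' quote; converted to meters internally.
#'
#' @param n_fast,n_slow pixel counts.
#' @param pixel_size_mm pixel pitch in millimeters.
#' @param distance_mm sample-detector distance in millimeters.
#' @param wavelength_A wavelength in Angstrom.
#' @param ... passed on to [detector_geometry()].
#' @export
detector_geometry_A <- function(n_fast, n_slow, pixel_size_mm, distance_mm,
                                wavelength_A, ...) {
  detector_geometry(n_fast, n_slow, pixel_size_mm * 1e-3, distance_mm * 1e-3,
                    wavelength_A * 1e-10, ...)
}

#' Map detector pixels to reciprocal space (Ewald construction)
#'
#' Computes, for every pixel, the elastic-scattering vector
#' \eqn{q = (s - s_0)/\lambda} where \eqn{s_0} is the unit vector along the
#' incident beam and \eqn{s} the unit vector from the sample to the pixel.
#' All q vectors therefore lie on the Ewald sphere of radius
#' \eqn{1/\lambda} through the origin. A flat-Ewald (small-angle) mode sets
#' the longitudinal component to zero, which is convenient for analytic
#' tests; the curved construction is the default.
#'
#' Pixels are enumerated fast-axis-fastest, matching \code{as.vector()} of an
#' \code{n_fast x n_slow} image matrix.
#'
#' @param geom a [detector_geometry()].
#' @param ewald \code{"curved"} (default) or \code{"flat"}.
#' @return an object of class \code{"qgrid"}: list with \code{q} (P x 3
#'   matrix, 1/m), \code{q_max}, the generating geometry and the mode.
#' @export
pixel_to_q <- function(geom, ewald = c("curved", "flat")) {
  if (!inherits(geom, "detector_geometry")) stop_param("geom must be a detector_geometry")
  ewald <- match.arg(ewald)
  i <- rep(seq_len(geom$n_fast) - 1L, times = geom$n_slow)
  j <- rep(seq_len(geom$n_slow) - 1L, each = geom$n_fast)
  x <- (i - geom$beam_center[1]) * geom$pixel_size
  y <- (j - geom$beam_center[2]) * geom$pixel_size
  lam <- geom$wavelength
  if (ewald == "curved") {
    r <- sqrt(x^2 + y^2 + geom$distance^2)
    q <- cbind(x / (lam * r), y / (lam * r), geom$distance / (lam * r) - 1 / lam)
  } else {
    q <- cbind(x / (lam * geom$distance), y / (lam * geom$distance), 0)
  }
  colnames(q) <- c("qx", "qy", "qz")
  structure(list(q = q, q_max = sqrt(max(rowSums(q^2))), geom = geom,
                 ewald = ewald),
            class = "qgrid")
}

#' Detector geometry matched to a reconstruction grid
#'
#' Convenience constructor for simulation studies: picks the
#' sample-detector distance so the corner of an \code{n_pixels}-square
#' detector reaches \code{margin} times the phantom grid's Nyquist
#' frequency \eqn{1/(2\,voxel)}. This keeps every (rotated) Ewald-sphere
#' sample inside the band representable on the density grid.
#'
#' @param voxel phantom voxel size (m).
#' @param n_pixels detector side in pixels.
#' @param wavelength X-ray wavelength (m), default 1 Angstrom.
#' @param pixel_size pixel pitch (m).
#' @param margin fraction of Nyquist reached at the detector corner.
#' @export
spi_geometry <- function(voxel = 1e-9, n_pixels = 64L, wavelength = 1e-10,
                         pixel_size = 1e-4, margin = 0.9) {
  q_corner <- margin / (2 * voxel)
  if (q_corner * wavelength / 2 >= 1)
    stop_param("wavelength too long to reach the requested resolution")
  theta <- 2 * asin(q_corner * wavelength / 2)
  r_corner <- sqrt(2) * (n_pixels / 2) * pixel_size
  detector_geometry(n_pixels, n_pixels, pixel_size,
                    distance = r_corner / tan(theta), wavelength = wavelength)
}

## ---- quaternions: scalar-first (w, x, y, z), unit norm, active rotations ----

#' Construct a unit quaternion
#'
#' Quaternions are scalar-first numeric vectors \code{c(w, x, y, z)}
#' representing active right-handed rotations. \code{quat()} normalizes its
#' input and canonicalizes the sign so that \code{w >= 0} (q and -q encode
#' the same rotation).
#'
#' @param w,x,y,z components, or a length-4 vector in \code{w}.
#' @export
quat <- function(w, x = NULL, y = NULL, z = NULL) {
  q <- if (is.null(x)) as.numeric(w) else c(w, x, y, z)
  if (length(q) != 4L || anyNA(q)) stop_param("a quaternion needs 4 finite components")
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop_param("zero quaternion cannot be normalized")
  quat_canonical(q / n)
}

#' @rdname quat
#' @param q a quaternion.
#' @export
quat_canonical <- function(q) {
  if (q[1] < 0 || (q[1] == 0 && {
    nz <- which(q != 0); length(nz) > 0 && q[nz[1]] < 0
  })) q <- -q
  q
}

#' @rdname quat
#' @param axis rotation axis (3-vector, need not be unit).
#' @param angle rotation angle in radians.
#' @export
quat_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  quat_canonical(c(cos(angle / 2), sin(angle / 2) * axis))
}

check_unit_quat <- function(q, tol = 1e-9) {
  if (length(q) != 4L || anyNA(q)) stop_param("quaternion must have 4 finite components")
  if (abs(sqrt(sum(q^2)) - 1) > tol)
    stop_param(sprintf("quaternion norm %.3g deviates from 1 beyond tolerance", sqrt(sum(q^2))))
  invisible(q)
}

#' Quaternion composition (Hamilton product)
#'
#' \code{quat_multiply(q2, q1)} is the rotation "first q1, then q2".
#'
#' @param q2,q1 unit quaternions.
#' @export
quat_multiply <- function(q2, q1) {
  w1 <- q1[1]; v1 <- q1[2:4]; w2 <- q2[1]; v2 <- q2[2:4]
  c(w2 * w1 - sum(v2 * v1), w2 * v1 + w1 * v2 + crossprod3(v2, v1))
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix of a unit quaternion
#'
#' @param q unit quaternion, scalar-first.
#' @return 3x3 orthogonal matrix \code{R} with \code{R \%*\% v} the actively
#'   rotated vector.
#' @export
quat_to_matrix <- function(q) {
  check_unit_quat(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Rotate a set of 3-vectors by a quaternion
#'
#' @param q unit quaternion (tolerance 1e-9 on the norm).
#' @param v numeric n x 3 matrix (or length-3 vector) of vectors to rotate.
#' @return rotated vectors, same shape as \code{v}.
#' @export
rotate_vectors <- function(q, v) {
  check_unit_quat(q)
  vec <- is.null(dim(v))
  if (vec) v <- matrix(v, nrow = 1)
  if (ncol(v) != 3L) stop_param("v must be n x 3")
  out <- v %*% t(quat_to_matrix(q))
  if (vec) out <- drop(out)
  out
}

#' Geodesic distance between two rotations
#'
#' Angle (radians) of the relative rotation, with q and -q identified,
#' so the result is in [0, pi].
#'
#' @param q1,q2 unit quaternions.
#' @export
quat_geodesic <- function(q1, q2) {
  d <- min(1, abs(sum(q1 * q2)))
  2 * acos(d)
}

#' Uniform random orientations on SO(3)
#'
#' Draws quaternions uniformly with respect to the Haar measure by
#' normalizing 4-dimensional Gaussian deviates. Deterministic for a fixed
#' seed; the global RNG state is left untouched.
#'
#' @param n number of orientations (>= 1).
#' @param seed integer seed.
#' @return list of \code{n} unit quaternions (canonical sign).
#' @export
random_orientations <- function(n, seed) {
  check_count(n, "n", min = 1L)
  g <- with_local_seed(seed, matrix(stats::rnorm(4 * n), ncol = 4))
  g <- g / sqrt(rowSums(g^2))
  lapply(seq_len(n), function(i) quat_canonical(g[i, ]))
}

#' Deterministic reference orientation sets
#'
#' Reference orientations for slicing/matching. \code{"euler_grid"}
#' enumerates a regular 3D grid of ZYZ Euler angles (the in-plane angles
#' uniform on the circle, the tilt uniform in \eqn{\cos\beta}).
#' \code{"quasi_uniform"} maps a Halton low-discrepancy sequence through the
#' uniform-quaternion construction, giving a reproducible quasi-uniform
#' covering of SO(3) whose nearest-neighbor spacing shrinks as
#' \code{n_ref} grows. \code{"friedel_reduced"} is the same covering
#' restricted to a fundamental domain of the beam-axis Friedel twin
#' (orientations R and Rz(pi) R produce identical flat-Ewald slices of a
#' Friedel-symmetric intensity), so for matching purposes it reaches the
#' angular resolution of a twice-larger full grid.
#'
#' @param n_ref number of orientations (>= 1).
#' @param scheme \code{"quasi_uniform"} (default), \code{"euler_grid"} or
#'   \code{"friedel_reduced"}.
#' @return list of unit quaternions; \code{n_ref = 1} gives the identity.
#' @export
reference_grid <- function(n_ref, scheme = c("quasi_uniform", "euler_grid",
                                             "friedel_reduced")) {
  check_count(n_ref, "n_ref", min = 1L)
  scheme <- match.arg(scheme)
  if (n_ref == 1L) return(list(c(1, 0, 0, 0)))
  if (scheme == "friedel_reduced") {
    qs <- vector("list", n_ref)
    kept <- 0L
    i <- 0L
    while (kept < n_ref) {
      i <- i + 1L
      q <- quat_canonical(shoemake_quat(halton_one(i, 2), halton_one(i, 3),
                                        halton_one(i, 5)))
      tw <- quat_canonical(beam_flip_twin(q))
      # keep the lexicographically smaller twin representative
      d <- q - tw
      first <- which(abs(d) > 1e-12)
      if (length(first) == 0 || d[first[1]] < 0) {
        kept <- kept + 1L
        qs[[kept]] <- q
      }
    }
    return(qs)
  }
  if (scheme == "euler_grid") {
    m <- ceiling(n_ref^(1 / 3))
    alpha <- 2 * pi * (seq_len(m) - 1) / m
    beta <- acos(1 - (2 * seq_len(m) - 1) / m)   # midpoints, uniform in cos
    gamma <- 2 * pi * (seq_len(m) - 0.5) / m
    qs <- vector("list", m^3)
    k <- 0L
    for (a in alpha) for (b in beta) for (g in gamma) {
      k <- k + 1L
      qs[[k]] <- quat_multiply(quat_axis_angle(c(0, 0, 1), a),
                               quat_multiply(quat_axis_angle(c(0, 1, 0), b),
                                             quat_axis_angle(c(0, 0, 1), g)))
    }
    qs <- lapply(qs, quat_canonical)
    qs[seq_len(n_ref)]
  } else {
    qs <- vector("list", n_ref)
    for (i in seq_len(n_ref))
      qs[[i]] <- quat_canonical(shoemake_quat(halton_one(i, 2), halton_one(i, 3),
                                              halton_one(i, 5)))
    qs
  }
}

# Shoemake subgroup-algorithm map from the unit cube to uniform quaternions.
shoemake_quat <- function(u1, u2, u3) {
  s1 <- sqrt(1 - u1); s2 <- sqrt(u1)
  t1 <- 2 * pi * u2; t2 <- 2 * pi * u3
  c(s2 * cos(t2), s1 * sin(t1), s1 * cos(t1), s2 * sin(t2))
}

# Left-composition with the half-turn about the beam (z) axis.
beam_flip_twin <- function(q) c(-q[4], -q[3], q[2], q[1])

halton_one <- function(i, base) {
  f <- 1; r <- 0; k <- i
  while (k > 0) {
    f <- f / base
    r <- r + f * (k %% base)
    k <- k %/% base
  }
  r
}

halton_seq <- function(n, base) vapply(seq_len(n), halton_one, 0, base = base)

## ---- shared parameter checking / seeding helpers ----

stop_param <- function(msg) {
  stop(errorCondition(msg, class = c("spimtip_param_error", "spimtip_error")))
}

stop_format <- function(msg) {
  stop(errorCondition(msg, class = c("spimtip_format_error", "spimtip_error")))
}

stop_numerical <- function(msg) {
  stop(errorCondition(msg, class = c("spimtip_numerical_error", "spimtip_error")))
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop_param(sprintf("%s must be a single integer >= %d", name, min))
  invisible(x)
}

check_positive <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x <= 0)
    stop_param(sprintf("%s must be a single positive number", name))
  invisible(x)
}

# Evaluate expr under a temporary RNG seed, restoring global RNG state.
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
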