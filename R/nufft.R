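## Non-uniform FFT operators (type 1 and type 2) on a cubic grid.
##
## Conventions (fixed throughout the package):
##  * real-space grid nodes sit at x = voxel * (j - M/2), j = 0..M-1 per axis
##    ("centered" storage: array index i corresponds to j = i - 1);
##  * type-2 (uniform -> nonuniform) evaluates
##      f(p) = sum_k F_k exp(-2*pi*1i * p . x_k),
##    type-1 is its adjoint, with exp(+2*pi*1i * p . x_k);
##  * frequencies are in cycles (not radians) per unit length, so a point p
##    is representable iff |p_d| <= 1/(2*voxel) in every axis d;
##  * no 1/N scaling anywhere.
##
## The fast path is Gaussian-kernel gridding on a 2x oversampled fine grid
## with separable spreading in compiled code; the dense direct sums
## (nufft_direct_*) are the reference oracle for small instances.

# Kernel half-width (in fine-grid steps) achieving a requested relative
# tolerance; truncation error of the Gaussian kernel decays as
# exp(-3*pi*m/4) at oversampling ratio 2, plus safety margin (two steps in
# the high-accuracy regime, where deconvolution amplification on small
# grids eats into the bound).
nufft_spread_width <- function(tol) {
  safety <- if (tol < 1e-6) 2L else 1L
  min(16L, max(3L, as.integer(ceiling(-4 * log(tol) / (3 * pi))) + safety))
}

# Nodes in radians per mode-grid step; band check with a tiny slack.
nufft_nodes <- function(points, voxel) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (ncol(points) != 3L) stop_param("points must be an n x 3 matrix")
  xi <- 2 * pi * voxel * points
  bad <- nufft_band_violations(xi, pi * (1 + 1e-9))
  if (length(bad) > 0)
    stop_param(sprintf("points out of the representable band (|q| > 1/(2*voxel)) at indices: %s",
                       paste(bad, collapse = ", ")))
  xi
}

# Per-axis deconvolution factors exp(tau*k^2) * h / sqrt(4*pi*tau) for
# centered modes k = -M/2 .. M/2-1.
nufft_deconv1d <- function(M, tau) {
  h <- pi / M   # fine-grid spacing 2*pi/(2*M)
  k <- seq_len(M) - 1 - M %/% 2
  exp(tau * k^2) * h / sqrt(4 * pi * tau)
}

# Indices into an nf-periodic array holding mode k at position (k mod nf)+1.
mode_wrap_index <- function(M, nf) {
  k <- seq_len(M) - 1 - M %/% 2
  (k %% nf) + 1L
}

#' Type-1 NUFFT: nonuniform samples to a uniform grid (adjoint transform)
#'
#' Computes \eqn{F_k = \sum_p v_p \exp(+2\pi i\, p \cdot x_k)} on the
#' centered cubic grid \eqn{x_k = voxel\,(j - M/2)}, \eqn{j = 0..M-1} per
#' axis, by Gaussian-kernel gridding on a 2x oversampled fine grid. The
#' result matches the dense direct sum to the requested relative tolerance.
#'
#' @param points n x 3 matrix of sample positions (cycles per unit length).
#' @param values complex (or real) sample values, one per point.
#' @param M grid side (>= 4).
#' @param voxel real-space grid spacing.
#' @param tol requested relative accuracy (default 1e-8).
#' @return complex M x M x M array in centered storage.
#' @export
nufft_type1 <- function(points, values, M, voxel = 1, tol = 1e-8) {
  check_count(M, "M", min = 4L)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (is.null(values)) stop_param("samples carry no values")
  if (length(values) != nrow(points))
    stop_param("values length must equal the number of points")
  xi <- nufft_nodes(points, voxel)
  m <- nufft_spread_width(tol)
  tau <- pi * m / (3 * M^2)
  nf <- 2L * as.integer(M)
  g <- if (is.double(values)) nufft_spread3_real(xi, values, nf, m, tau)
       else nufft_spread3(xi, as.complex(values), nf, m, tau)
  G <- stats::fft(g, inverse = TRUE)
  idx <- mode_wrap_index(M, nf)
  d <- nufft_deconv1d(M, tau)
  F <- G[idx, idx, idx]
  F <- F * outer_triple(d, d, d)
  F
}

#' Type-2 NUFFT: uniform grid coefficients to nonuniform samples
#'
#' Evaluates \eqn{f(p) = \sum_k F_k \exp(-2\pi i\, p \cdot x_k)} at
#' arbitrary in-band points; the exact adjoint of [nufft_type1()].
#'
#' @param fvals M x M x M array (real or complex) of grid coefficients in
#'   centered storage; a \code{fourier_volume} is also accepted.
#' @inheritParams nufft_type1
#' @return complex vector, one value per point.
#' @export
nufft_type2 <- function(fvals, points, voxel = 1, tol = 1e-8) {
  if (inherits(fvals, "fourier_volume")) fvals <- fvals$values
  dm <- dim(fvals)
  if (length(dm) != 3L || length(unique(dm)) != 1L)
    stop_param("fvals must be a cubic M x M x M array")
  M <- dm[1]
  if (M < 4L) stop_param("grid side must be >= 4")
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  xi <- nufft_nodes(points, voxel)
  m <- nufft_spread_width(tol)
  tau <- pi * m / (3 * M^2)
  nf <- 2L * as.integer(M)
  d <- nufft_deconv1d(M, tau)
  W <- array(0i, c(nf, nf, nf))
  idx <- mode_wrap_index(M, nf)
  W[idx, idx, idx] <- fvals * outer_triple(d, d, d)
  g <- stats::fft(W)
  nufft_interp3(g, xi, nf, m, tau)
}

outer_triple <- function(a, b, c) {
  M <- length(a)
  array(a, c(M, M, M)) *
    array(rep(b, each = M), c(M, M, M)) *
    array(rep(c, each = M * M), c(M, M, M))
}

#' Dense direct-sum NUFFT oracles
#'
#' Exact \eqn{O(M^3 P)} evaluation of the type-1 and type-2 sums, used as
#' the reference the fast gridding path is tested against. Only suitable
#' for small instances (M <= 16, a few hundred points).
#'
#' @inheritParams nufft_type1
#' @export
nufft_direct_type1 <- function(points, values, M, voxel = 1) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  E <- direct_phase_matrix(points, M, voxel, sign = +1)
  array(as.vector(t(E) %*% as.complex(values)), c(M, M, M))
}

#' @rdname nufft_direct_type1
#' @inheritParams nufft_type2
#' @export
nufft_direct_type2 <- function(fvals, points, voxel = 1) {
  if (inherits(fvals, "fourier_volume")) fvals <- fvals$values
  M <- dim(fvals)[1]
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  E <- direct_phase_matrix(points, M, voxel, sign = -1)
  as.vector(E %*% as.complex(as.vector(fvals)))
}

# P x M^3 matrix of exp(sign * 2*pi*1i * p . x_k), fast axis first.
direct_phase_matrix <- function(points, M, voxel, sign) {
  x1 <- voxel * (seq_len(M) - 1 - M %/% 2)
  xk <- as.matrix(expand.grid(x = x1, y = x1, z = x1))
  exp(sign * 2i * pi * (points %*% t(xk)))
}

## ---- Fourier volumes -------------------------------------------------------

#' Cubic reciprocal-space volume container
#'
#' A cubic array on a Cartesian grid together with its reciprocal voxel
#' size and a role tag: \code{"intensity"} (\eqn{|G|^2}, real and
#' nonnegative with Friedel symmetry), \code{"autocorrelation"} (real-space
#' self-convolution of the density) or \code{"ac_fourier"} / generic
#' complex data. Storage is centered: the zero frequency / zero lag sits at
#' index \code{M/2 + 1} on each axis.
#'
#' @param values cubic M x M x M array, M >= 4.
#' @param voxel_q grid spacing (1/length for reciprocal roles; real-space
#'   lag spacing for the autocorrelation role).
#' @param role one of \code{"intensity"}, \code{"autocorrelation"},
#'   \code{"ac_fourier"}, \code{"generic"}.
#' @param check validate role invariants (default TRUE).
#' @export
fourier_volume <- function(values, voxel_q,
                           role = c("generic", "intensity", "autocorrelation", "ac_fourier"),
                           check = TRUE) {
  role <- match.arg(role)
  dm <- dim(values)
  if (length(dm) != 3L || length(unique(dm)) != 1L || dm[1] < 4L)
    stop_param("values must be a cubic M x M x M array with M >= 4")
  check_positive(voxel_q, "voxel_q")
  if (check && role == "intensity") {
    if (is.complex(values)) {
      if (max(abs(Im(values))) > 1e-8 * max(abs(values), 1e-300))
        stop_param("intensity volume must be real")
      values <- Re(values)
    }
    if (min(values) < -1e-8 * max(abs(values), 1e-300))
      stop_param("intensity volume must be nonnegative")
    fe <- friedel_asymmetry(values)
    if (fe > 1e-8)
      stop_param(sprintf("intensity volume violates Friedel symmetry (rel. asymmetry %.2e)", fe))
  }
  structure(list(values = values, voxel_q = voxel_q, role = role),
            class = "fourier_volume")
}

#' @export
print.fourier_volume <- function(x, ...) {
  cat(sprintf("fourier_volume [%s]: %d^3, voxel_q %.4g\n",
              x$role, dim(x$values)[1], x$voxel_q))
  invisible(x)
}

# Value at -k for centered even-sided storage (the k = -M/2 plane maps to
# itself modulo the grid period).
friedel_mirror <- function(arr) {
  M <- dim(arr)[1]
  ix <- c(1L, seq(M, 2L))
  arr[ix, ix, ix]
}

friedel_asymmetry <- function(arr) {
  s <- max(abs(arr))
  if (s == 0) return(0)
  max(abs(arr - friedel_mirror(arr))) / s
}
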