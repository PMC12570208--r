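## Iterative phase retrieval: error reduction (ER) and hybrid input-output
## (HIO) alternating projections between the Fourier-modulus constraint and
## a real-space support + nonnegativity constraint, with optional
## shrinkwrap support refinement and seeded multi-start.

#' Support constraint specifications
#'
#' \code{support_fixed_sphere} keeps a static spherical support of the
#' given radius (voxels) centered on the grid. \code{support_shrinkwrap}
#' re-estimates the support every \code{interval} iterations by Gaussian
#' blurring of the current density magnitude (sd \code{sigma} voxels) and
#' thresholding at \code{threshold} times its maximum, starting from a
#' generous centered sphere.
#'
#' @param radius sphere radius in voxels.
#' @export
support_fixed_sphere <- function(radius) {
  check_positive(radius, "radius")
  structure(list(type = "fixed_sphere", radius = radius), class = "support_spec")
}

#' @rdname support_fixed_sphere
#' @param sigma blur standard deviation in voxels.
#' @param threshold relative threshold on the blurred magnitude.
#' @param interval iterations between support updates.
#' @param init_radius initial sphere radius in voxels (default M/4 at run time).
#' @export
support_shrinkwrap <- function(sigma = 1.5, threshold = 0.12, interval = 20L,
                               init_radius = NULL) {
  check_positive(sigma, "sigma")
  if (threshold <= 0 || threshold >= 1) stop_param("threshold must be in (0, 1)")
  check_count(interval, "interval", min = 1L)
  structure(list(type = "shrinkwrap", sigma = sigma, threshold = threshold,
                 interval = as.integer(interval), init_radius = init_radius),
            class = "support_spec")
}

#' Phase-retrieval configuration
#'
#' @param schedule list of stages, each a list with \code{method}
#'   (\code{"hybrid_input_output"} or \code{"error_reduction"}),
#'   \code{iterations} (>= 1) and, for HIO, \code{beta} in (0, 1.5).
#' @param support a [support_fixed_sphere()] or [support_shrinkwrap()].
#' @param seed integer seed for the random initial phases.
#' @param n_starts number of seeded starts; the result with the lowest
#'   final Fourier error is kept.
#' @export
phasing_config <- function(schedule = list(
                             list(method = "hybrid_input_output", iterations = 100L, beta = 0.9),
                             list(method = "error_reduction", iterations = 50L)),
                           support = support_shrinkwrap(), seed = 1L, n_starts = 4L) {
  for (st in schedule) {
    if (!st$method %in% c("hybrid_input_output", "error_reduction"))
      stop_param(sprintf("unknown phasing method '%s'", st$method))
    check_count(st$iterations, "iterations", min = 1L)
    if (st$method == "hybrid_input_output") {
      beta <- st$beta %||% 0.9
      if (beta <= 0 || beta >= 1.5) stop_param("beta must be in (0, 1.5)")
    }
  }
  if (!inherits(support, "support_spec")) stop_param("support must be a support_spec")
  check_count(n_starts, "n_starts", min = 1L)
  structure(list(schedule = schedule, support = support, seed = as.integer(seed),
                 n_starts = as.integer(n_starts)),
            class = "phasing_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Recover a real, nonnegative, compactly supported density from intensities
#'
#' Alternating-projection phase retrieval on the oversampled intensity
#' volume: the Fourier-domain projection replaces the modulus by
#' \eqn{\sqrt{I}} keeping the phase; the object-domain constraint enforces
#' support and nonnegativity (ER projects, HIO feeds back with parameter
#' beta). The input is Friedel-symmetrized and clipped to be nonnegative
#' before the square root. Initial phases are uniform random from the seed;
#' with \code{n_starts > 1} the best final Fourier error wins.
#'
#' @param intensity a [fourier_volume()] holding \eqn{|G|^2} (role
#'   \code{"intensity"} or \code{"generic"}).
#' @param cfg a [phasing_config()].
#' @param oversample linear oversampling factor of the intensity relative
#'   to the object support (must be >= 2 for retrieval to be well posed).
#' @param init optional [density_model()] used as the initial object
#'   estimate instead of random phases (single start).
#' @return a \code{phasing_result}: \code{density} (a [density_model()]),
#'   \code{fourier_error} history of the winning start, and
#'   \code{support_fraction}.
#' @export
phase_retrieve <- function(intensity, cfg = phasing_config(), oversample = 2L,
                           init = NULL) {
  if (!inherits(intensity, "fourier_volume")) stop_param("intensity must be a fourier_volume")
  if (oversample < 2) stop_param("intensity must be oversampled by at least 2 for phasing")
  I <- intensity$values
  if (is.complex(I)) I <- Re(I)
  I <- (I + friedel_mirror(I)) / 2
  I[I < 0] <- 0
  M <- dim(I)[1]
  voxel <- 1 / (M * intensity$voxel_q)
  # target modulus in density units (the forward map carries voxel^3), so
  # the true density is an exact fixed point of the projections
  A <- sqrt(ifftshift3(I)) / voxel^3
  anorm <- sqrt(sum(A^2))
  if (anorm == 0) {
    zero <- density_model(array(0, c(M, M, M)), voxel)
    return(structure(list(density = zero, fourier_error = 0,
                          support_fraction = 0), class = "phasing_result"))
  }
  seeds <- cfg$seed + seq_len(if (is.null(init)) cfg$n_starts else 1L) - 1L
  best <- NULL
  for (s in seeds) {
    run <- phase_retrieve_single(A, anorm, M, cfg, s, init, voxel)
    if (is.null(best) || utils::tail(run$err, 1) < utils::tail(best$err, 1)) best <- run
  }
  rho <- fftshift3(best$g)              # object centered on the output grid
  mask <- fftshift3(best$mask)
  rho[!mask | rho < 0] <- 0
  structure(list(density = density_model(rho, voxel, support_mask = mask),
                 fourier_error = best$err,
                 support_fraction = mean(mask)),
            class = "phasing_result")
}

# One seeded phase-retrieval run in the wrapped (FFT-native) domain.
phase_retrieve_single <- function(A, anorm, M, cfg, seed, init, voxel) {
  sup <- cfg$support
  radius <- if (sup$type == "fixed_sphere") sup$radius else sup$init_radius %||% (M / 4)
  mask <- ifftshift3(sphere_mask(M, radius))
  g <- if (is.null(init)) {
    phi <- with_local_seed(seed, array(stats::runif(M^3, 0, 2 * pi), c(M, M, M)))
    g0 <- Re(stats::fft(A * exp(1i * phi), inverse = TRUE)) / M^3
    g0[!mask | g0 < 0] <- 0     # start inside the object constraint set, so
    g0                          # the ER error is non-increasing from step one
  } else {
    g0 <- ifftshift3(init$rho)
    # bring the init onto the modulus scale (densities may be normalized
    # arbitrarily between generations; HIO must not mix scales)
    n0 <- sqrt(sum(Mod(stats::fft(g0))^2))
    if (n0 > 0) g0 <- g0 * (anorm / n0)
    g0
  }
  err <- numeric(0)
  total_it <- 0L
  for (stage in cfg$schedule) {
    beta <- stage$beta %||% 0.9
    hio <- stage$method == "hybrid_input_output"
    for (it in seq_len(stage$iterations)) {
      total_it <- total_it + 1L
      G <- stats::fft(g)
      modG <- Mod(G)
      err <- c(err, sqrt(sum((modG - A)^2)) / anorm)
      if (!all(is.finite(G)))
        stop_numerical(sprintf("non-finite Fourier iterate at iteration %d", total_it))
      phase <- ifelse(modG > 0, G / modG, 1 + 0i)
      gm <- Re(stats::fft(A * phase, inverse = TRUE)) / M^3
      viol <- !mask | gm < 0
      if (hio) {
        gn <- gm
        gn[viol] <- g[viol] - beta * gm[viol]
        g <- gn
      } else {
        gm[viol] <- 0
        g <- gm
      }
      if (sup$type == "shrinkwrap" && total_it %% sup$interval == 0) {
        blur <- gaussian_blur3(pmax(g, 0), sup$sigma)
        mask <- blur >= sup$threshold * max(blur)
      }
    }
  }
  # final object-domain projection so the constraints hold exactly
  g[!mask | g < 0] <- 0
  G <- stats::fft(g)
  err <- c(err, sqrt(sum((Mod(G) - A)^2)) / anorm)
  list(g = g, mask = mask, err = err)
}

sphere_mask <- function(M, radius) {
  ax <- seq_len(M) - 1 - M / 2
  r2 <- outer_triple_real(ax^2, rep(1, M), rep(1, M)) +
        outer_triple_real(rep(1, M), ax^2, rep(1, M)) +
        outer_triple_real(rep(1, M), rep(1, M), ax^2)
  r2 <= radius^2
}

# Periodic Gaussian blur (sd sigma voxels) via the FFT transfer function.
gaussian_blur3 <- function(x, sigma) {
  M <- dim(x)[1]
  k <- c(0:(M / 2), (-M / 2 + 1):(-1)) / M
  t1 <- exp(-2 * pi^2 * sigma^2 * k^2)
  Re(stats::fft(stats::fft(x) * outer_triple_real(t1, t1, t1), inverse = TRUE)) / M^3
}

#' @export
print.phasing_result <- function(x, ...) {
  cat(sprintf("phasing_result: %d^3 density, final Fourier error %.4g, support %.1f%%\n",
              dim(x$density$rho)[1], utils::tail(x$fourier_error, 1),
              100 * x$support_fraction))
  invisible(x)
}

#' Align two densities over translations and centro-inversion
#'
#' Phase retrieval determines a density only up to a (cyclic) translation
#' and a centro-inversion twin. This maximizes the normalized
#' cross-correlation over all cyclic shifts of \code{b} (and of its
#' inverted copy) via FFT correlation.
#'
#' @param a,b [density_model()] objects on identical grids.
#' @return list with \code{correlation} (in [-1, 1]), \code{shift} (the
#'   cyclic shift to apply to \code{b} to best match \code{a}) and
#'   \code{inverted}.
#' @export
align_densities <- function(a, b) {
  if (!inherits(a, "density_model") || !inherits(b, "density_model"))
    stop_param("a and b must be density_model objects")
  if (!identical(dim(a$rho), dim(b$rho))) stop_param("grid shapes differ")
  M <- dim(a$rho)[1]
  ac <- a$rho - mean(a$rho)
  bc <- b$rho - mean(b$rho)
  na <- sqrt(sum(ac^2)); nb <- sqrt(sum(bc^2))
  if (na == 0 || nb == 0) stop_param("zero-variance density cannot be aligned")
  Fa <- stats::fft(ac)
  score <- function(bcand) {
    cc <- Re(stats::fft(Fa * Conj(stats::fft(bcand)), inverse = TRUE)) / M^3
    i <- which.max(cc)
    idx <- as.integer(arrayInd(i, dim(cc))) - 1L
    list(corr = cc[i] / (na * nb), shift = idx)
  }
  s1 <- score(bc)
  binv <- invert_density(bc)
  s2 <- score(binv)
  if (s2$corr > s1$corr) {
    list(correlation = s2$corr, shift = wrap_shift(s2$shift, M), inverted = TRUE)
  } else {
    list(correlation = s1$corr, shift = wrap_shift(s1$shift, M), inverted = FALSE)
  }
}

# shift reported in (-M/2, M/2]
wrap_shift <- function(s, M) {
  s <- s %% M
  ifelse(s > M / 2, s - M, s)
}

# centro-inversion about the grid origin (index 1), cyclic
invert_density <- function(x) {
  M <- dim(x)[1]
  ix <- c(1L, seq(M, 2L))
  x[ix, ix, ix]
}

#' Best aligned correlation between two densities
#'
#' Convenience wrapper around [align_densities()] returning only the
#' correlation coefficient.
#' @inheritParams align_densities
#' @export
aligned_correlation <- function(a, b) align_densities(a, b)$correlation
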