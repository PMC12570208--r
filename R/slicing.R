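## Reference slicing and exhaustive orientation (and conformation) matching.

#' Reference slices of a model at a set of orientations
#'
#' Evaluates the model's 3D diffraction intensity on the detector's
#' Ewald-sphere q-grid rotated into each reference orientation's particle
#' frame, via a type-2 NUFFT applied to the autocorrelation volume.
#' Negative numerical residues are clipped to zero and the clipped mass is
#' recorded in the \code{clipped_mass} attribute.
#'
#' @param model_fourier a [fourier_volume()] with role
#'   \code{"autocorrelation"} (real-space lag grid).
#' @param orientations list of unit quaternions.
#' @param qgrid a [pixel_to_q()] grid.
#' @param conformation conformation index tag carried along (default 1).
#' @param nufft_tol NUFFT accuracy of the slicing transform.
#' @return a \code{reference_set}: list with \code{orientations},
#'   \code{slices} (pixels x n_ref matrix, nonnegative) and
#'   \code{conformation}.
#' @export
compute_slices <- function(model_fourier, orientations, qgrid, conformation = 1L,
                           nufft_tol = 1e-6) {
  if (!inherits(model_fourier, "fourier_volume") ||
      model_fourier$role != "autocorrelation")
    stop_param("model_fourier must be a fourier_volume with role 'autocorrelation'")
  if (length(orientations) == 0) stop_param("orientations must be nonempty")
  if (!inherits(qgrid, "qgrid")) stop_param("qgrid must come from pixel_to_q()")
  voxel <- model_fourier$voxel_q          # lag spacing for the AC role
  npix <- nrow(qgrid$q)
  n_ref <- length(orientations)
  pts <- matrix(0, npix * n_ref, 3)
  for (i in seq_len(n_ref)) {
    Rm <- quat_to_matrix(orientations[[i]])
    pts[(i - 1) * npix + seq_len(npix), ] <- qgrid$q %*% Rm
  }
  vals <- Re(nufft_type2(model_fourier$values, pts, voxel, tol = nufft_tol)) * voxel^3
  slices <- matrix(vals, npix, n_ref)
  clipped <- -sum(slices[slices < 0])
  slices[slices < 0] <- 0
  structure(list(orientations = orientations, slices = slices,
                 conformation = as.integer(conformation)),
            class = "reference_set", clipped_mass = clipped)
}

#' Assign each pattern its best (orientation, conformation) pair
#'
#' Exhaustively evaluates a distance between every image and every
#' reference slice of every conformation, returning the argmin per image.
#' \code{weighted_l2} is \eqn{\sum_p w_p (I_p - s R_p)^2} with the
#' closed-form optimal scale \eqn{s = \sum w I R / \sum w R^2} (or the
#' known per-image fluence when \code{scale = "known"}); weights default to
#' \code{1/max(I_p, 1)}, the approximate inverse variance of Poisson
#' counts. \code{poisson_nll} is
#' \eqn{\sum_p [s R_p - I_p \log(s R_p + \epsilon)]} with the
#' maximum-likelihood scale (analytic for the tiny log guard). Ties are
#' broken by lowest orientation index, then lowest conformation index.
#'
#' @param stack a \code{pattern_stack}.
#' @param refs a \code{reference_set} or list of them (one per conformation).
#' @param metric \code{"weighted_l2"} (default) or \code{"poisson_nll"}.
#' @param weights \code{"inv_poisson"} (default) or \code{"uniform"}.
#' @param scale \code{"fitted"} (default) or \code{"known"} (use the
#'   stack's recorded fluence).
#' @param eps floor inside the Poisson log guard.
#' @return a \code{match_result} data frame: one row per image with
#'   \code{orientation} (index), \code{conformation}, \code{distance},
#'   \code{scale}.
#' @export
match_orientations <- function(stack, refs, metric = c("weighted_l2", "poisson_nll"),
                               weights = c("inv_poisson", "uniform"),
                               scale = c("fitted", "known"), eps = 1e-12) {
  metric <- match.arg(metric)
  weights <- match.arg(weights)
  scale <- match.arg(scale)
  if (inherits(refs, "reference_set")) refs <- list(refs)
  d <- dim(stack$images)
  npix <- d[1] * d[2]
  D <- d[3]
  for (rs in refs)
    if (nrow(rs$slices) != npix)
      stop_param("reference slices do not match the detector shape")
  I <- matrix(stack$images, npix, D)
  W <- if (weights == "inv_poisson") 1 / pmax(I, 1) else matrix(1, npix, D)
  best <- list(dist = rep(Inf, D), ori = rep(NA_integer_, D),
               conf = rep(NA_integer_, D), scale = rep(NA_real_, D))
  for (ci in seq_along(refs)) {
    R <- refs[[ci]]$slices
    res <- switch(metric,
      weighted_l2 = dist_weighted_l2(I, W, R,
                                     known = if (scale == "known") stack$fluence),
      poisson_nll = dist_poisson_nll(I, R, eps,
                                     known = if (scale == "known") stack$fluence))
    # argmin over orientations for this conformation (which.min: lowest index on ties)
    oi <- max.col(-res$dist, ties.method = "first")
    di <- res$dist[cbind(seq_len(D), oi)]
    si <- res$scale[cbind(seq_len(D), oi)]
    upd <- di < best$dist |
      (di == best$dist & (oi < best$ori | (oi == best$ori & ci < best$conf)))
    upd[is.na(upd)] <- FALSE
    best$dist[upd] <- di[upd]; best$ori[upd] <- oi[upd]
    best$conf[upd] <- ci; best$scale[upd] <- si[upd]
  }
  out <- data.frame(image = seq_len(D), orientation = best$ori,
                    conformation = best$conf, distance = best$dist,
                    scale = best$scale)
  class(out) <- c("match_result", "data.frame")
  out
}

# Weighted L2 with per-image weights; returns D x n_ref distance and scale.
dist_weighted_l2 <- function(I, W, R, known = NULL) {
  WI2 <- colSums(W * I^2)                      # D
  cross <- crossprod(W * I, R)                 # D x n_ref
  denom <- crossprod(W, R^2)                   # D x n_ref
  if (is.null(known)) {
    s <- cross / pmax(denom, 1e-300)
    dist <- WI2 - cross^2 / pmax(denom, 1e-300)
  } else {
    s <- matrix(known, nrow(cross), ncol(cross))
    dist <- WI2 - 2 * s * cross + s^2 * denom
  }
  # guard tiny negative round-off
  dist[dist < 0] <- 0
  list(dist = dist, scale = s)
}

# Poisson negative log-likelihood, computed in closed form. For the
# tiny log-guard eps the optimal scale is analytic (d/ds = 0 gives
# s = sum of counts over positive-slice pixels / sum of the slice), and
# log(s R + eps) splits into log(s) + log(R) on R > 0 pixels and log(eps)
# on R = 0 pixels (the eps correction on positive pixels is below machine
# precision at these scales), so the whole D x n_ref table reduces to two
# matrix products. All-zero reference slices are skipped (distance Inf)
# and flagged.
dist_poisson_nll <- function(I, R, eps, known = NULL) {
  D <- ncol(I); n_ref <- ncol(R)
  zero_ref <- colSums(R) == 0
  if (any(zero_ref))
    warning(sprintf("%d all-zero reference slice(s) skipped under poisson_nll",
                    sum(zero_ref)))
  pos <- R > 0
  logR <- array(0, dim(R))
  logR[pos] <- log(R[pos])
  sumR <- colSums(R)
  Ipos <- crossprod(I, pos)            # D x n_ref: counts on R > 0 pixels
  Izero <- colSums(I) - Ipos           # counts on R = 0 pixels
  ILogR <- crossprod(I, logR)          # D x n_ref
  s <- if (is.null(known)) {
    pmax(sweep(Ipos, 2, pmax(sumR, 1e-300), "/"), 1e-12)
  } else matrix(known, D, n_ref)
  dist <- sweep(s, 2, sumR, "*") - Ipos * log(s) - ILogR - Izero * log(eps)
  dist[, zero_ref] <- Inf
  s[, zero_ref] <- NA_real_
  list(dist = dist, scale = s)
}

#' Orientation assignment accuracy against simulation truth
#'
#' Fraction of images whose assigned reference orientation matches the true
#' orientation within \code{tol_deg} degrees of geodesic distance, counting
#' the Friedel twin (a half-turn about the beam axis composed on the left)
#' as correct.
#'
#' @param result a \code{match_result}.
#' @param refs a \code{reference_set} or list of them.
#' @param true_orientations list of true quaternions (e.g.
#'   \code{stack$true_orientation}).
#' @param tol_deg angular tolerance in degrees.
#' @export
matching_accuracy <- function(result, refs, true_orientations, tol_deg = 1) {
  if (inherits(refs, "reference_set")) refs <- list(refs)
  flip <- quat_axis_angle(c(0, 0, 1), pi)
  tol <- tol_deg * pi / 180
  ok <- vapply(seq_len(nrow(result)), function(i) {
    qa <- refs[[result$conformation[i]]]$orientations[[result$orientation[i]]]
    qt <- true_orientations[[i]]
    qf <- quat_multiply(flip, qt)
    min(quat_geodesic(qa, qt), quat_geodesic(qa, qf)) <= tol
  }, TRUE)
  mean(ok)
}
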