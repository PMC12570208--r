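## Autocorrelation merging: Tikhonov-regularized normal equations of the
## slicing (type-2 NUFFT) operator, applied via Cartesian-FFT convolution
## on a 2x-embedded Toeplitz grid and solved by a residual-minimizing
## conjugate-direction (conjugate residual) iteration.

#' Set up the NUFFT normal equations for autocorrelation recovery
#'
#' For the linear model \eqn{I(q_p) = \sum_k x_k e^{-2\pi i q_p x_k}}
#' (a type-2 NUFFT of the autocorrelation grid), the normal equations
#' \eqn{(A^H A + \lambda I)x = A^H b} have a Toeplitz system matrix: its
#' action is a convolution with the type-1 NUFFT of unit weights on a
#' 2M-padded grid, and the right-hand side is the type-1 NUFFT of the data.
#' Friedel symmetrization (augmenting every sample with its \eqn{-q}
#' mirror) is applied by construction, which makes both volumes real.
#'
#' @param samples list with \code{points} (P x 3, 1/length) and real
#'   \code{values} (oriented intensity data).
#' @param M autocorrelation grid side (>= 8).
#' @param lambda Tikhonov parameter (>= 0).
#' @param voxel real-space lag grid spacing.
#' @param nufft_tol NUFFT accuracy of the two type-1 transforms.
#' @param friedel augment samples with Friedel mirrors (default TRUE).
#' @return a \code{normal_equations} object: \code{rhs} (M^3), \code{kernel}
#'   (2M^3), its FFT, \code{lambda} and bookkeeping fields.
#' @export
setup_normal_equations <- function(samples, M, lambda = 0, voxel = 1,
                                   nufft_tol = 1e-6, friedel = TRUE) {
  check_count(M, "M", min = 8L)
  if (lambda < 0) stop_param("lambda must be >= 0")
  pts <- samples$points
  vals <- samples$values
  if (is.null(vals)) stop_param("samples carry no values")
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  if (nrow(pts) == 0) stop_param("samples are empty")
  if (length(vals) != nrow(pts)) stop_param("values length must match points")
  rhs <- nufft_type1(pts, as.double(vals), M, voxel, tol = nufft_tol)
  kernel <- nufft_type1(pts, rep(1.0, nrow(pts)), 2L * M, voxel, tol = nufft_tol)
  if (friedel) {
    rhs <- 2 * Re(rhs)
    kernel <- 2 * Re(kernel)
  } else {
    rhs <- Re(rhs)      # data are real; imaginary residue is NUFFT noise
    kernel <- Re(kernel)
  }
  M2 <- 2L * M
  kw <- array(0, c(M2, M2, M2))
  idx2 <- mode_wrap_index(M2, M2)
  kw[idx2, idx2, idx2] <- kernel
  structure(list(rhs = rhs, kernel = kernel,
                 kernel_fft = stats::fft(kw),
                 lambda = lambda, M = as.integer(M), voxel = voxel,
                 n_samples = nrow(pts) * (1L + friedel),
                 points = pts, values = as.double(vals),
                 nufft_tol = nufft_tol),
            class = "normal_equations")
}

#' Apply the regularized normal-equation operator
#'
#' Computes \eqn{(A^H A + \lambda I)x} by zero-embedding \code{x} into the
#' 2M Toeplitz grid, multiplying by the kernel's Fourier transform, and
#' cropping back; exact (to NUFFT tolerance) and self-adjoint.
#'
#' @param ne a \code{normal_equations} object.
#' @param x real M^3 array.
#' @param lambda override of the Tikhonov parameter (default \code{ne$lambda}).
#' @export
apply_system <- function(ne, x, lambda = ne$lambda) {
  if (!inherits(ne, "normal_equations")) stop_param("ne must be normal_equations")
  M <- ne$M
  if (length(dim(x)) != 3L || any(dim(x) != M))
    stop_param("x shape does not match the normal equations grid")
  M2 <- 2L * M
  xw <- array(0, c(M2, M2, M2))
  idx <- mode_wrap_index(M, M2)
  xw[idx, idx, idx] <- x
  z <- Re(stats::fft(stats::fft(xw) * ne$kernel_fft, inverse = TRUE)) / M2^3
  z[idx, idx, idx] + lambda * x
}

#' Solve the normal equations for the autocorrelation volume
#'
#' Conjugate-direction iteration (the residual-minimizing conjugate
#' residual variant, so the residual norm is non-increasing) on the
#' symmetric positive-definite operator of [apply_system()], zero initial
#' guess, stopping at relative residual \code{tol} or \code{max_iter}.
#'
#' @param ne a \code{normal_equations} object.
#' @param tol relative residual stopping tolerance.
#' @param max_iter iteration cap.
#' @param x0 optional initial guess (e.g. the previous generation's
#'   solution); default zero.
#' @return a \code{merge_solution}: the recovered autocorrelation (a
#'   [fourier_volume()]), \code{lambda_used}, \code{data_misfit}
#'   (\eqn{\|Ax - b\|} over the samples), \code{solution_norm},
#'   \code{cg_iterations}, \code{converged}, \code{residual_history}.
#' @export
solve_autocorrelation <- function(ne, tol = 1e-6, max_iter = 500L, x0 = NULL) {
  if (!inherits(ne, "normal_equations")) stop_param("ne must be normal_equations")
  check_positive(tol, "tol")
  b <- ne$rhs
  bnorm <- sqrt(sum(b^2))
  x <- if (is.null(x0)) array(0, dim(b)) else x0
  history <- numeric(0)
  iters <- 0L
  if (bnorm > 0) {
    r <- if (is.null(x0)) b else b - apply_system(ne, x)
    if (!is.null(x0) && sqrt(sum(r^2)) > bnorm) {   # unhelpful warm start
      x <- array(0, dim(b))
      r <- b
    }
    p <- r
    Ar <- apply_system(ne, r)
    Ap <- Ar
    rAr <- sum(r * Ar)
    repeat {
      rn <- sqrt(sum(r^2))
      history <- c(history, rn / bnorm)
      if (rn / bnorm <= tol || iters >= max_iter) break
      alpha <- rAr / sum(Ap * Ap)
      if (!is.finite(alpha))
        stop_numerical(sprintf("non-finite step in merge solver at iteration %d", iters))
      x <- x + alpha * p
      r <- r - alpha * Ap
      Ar <- apply_system(ne, r)
      rArn <- sum(r * Ar)
      beta <- rArn / rAr
      rAr <- rArn
      p <- r + beta * p
      Ap <- Ar + beta * Ap
      iters <- iters + 1L
      if (!all(is.finite(x)))
        stop_numerical(sprintf("non-finite iterate in merge solver at iteration %d", iters))
    }
  }
  pred <- Re(nufft_type2(x, ne$points, ne$voxel, tol = ne$nufft_tol))
  misfit <- sqrt(sum((pred - ne$values)^2))
  ac <- fourier_volume(x / ne$voxel^3, voxel_q = ne$voxel, role = "autocorrelation")
  structure(list(autocorrelation = ac, lambda_used = ne$lambda,
                 data_misfit = misfit, solution_norm = sqrt(sum(x^2)),
                 cg_iterations = iters,
                 converged = length(history) > 0 && utils::tail(history, 1) <= tol,
                 residual_history = history),
            class = "merge_solution")
}

#' @export
print.merge_solution <- function(x, ...) {
  cat(sprintf("merge_solution: %d^3 AC, lambda %.3g, misfit %.4g, |x| %.4g, %d iterations%s\n",
              dim(x$autocorrelation$values)[1], x$lambda_used, x$data_misfit,
              x$solution_norm, x$cg_iterations,
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Tikhonov hyper-parameter sweep with L-curve selection
#'
#' Runs [solve_autocorrelation()] for each candidate \eqn{\lambda} (the
#' expensive type-1 setup is shared) and selects the solution at the corner
#' of the (log data misfit, log solution norm) curve by maximum curvature;
#' with fewer than three candidates, or a degenerate curve, it falls back
#' to the smallest \eqn{\lambda} whose misfit is within 5\% of the minimum.
#' The selection is invariant to the ordering of \code{lambdas}.
#'
#' @inheritParams setup_normal_equations
#' @param lambdas numeric vector of Tikhonov parameters; \code{NULL} means
#'   \code{lambdas_rel} times the kernel zero lag (the mean eigenvalue of
#'   \eqn{A^H A}).
#' @param lambdas_rel relative grid used when \code{lambdas} is NULL.
#' @param tol,max_iter passed to [solve_autocorrelation()].
#' @return the selected \code{merge_solution}; all candidates are attached
#'   as attribute \code{"sweep"}.
#' @export
hyperparameter_sweep <- function(samples, M, lambdas = NULL, tol = 1e-6,
                                 max_iter = 500L, voxel = 1, nufft_tol = 1e-6,
                                 friedel = TRUE, lambdas_rel = 10^seq(-6, -1, by = 1),
                                 x0 = NULL) {
  ne <- setup_normal_equations(samples, M, 0, voxel, nufft_tol, friedel)
  t0 <- kernel_zero_lag(ne)
  if (is.null(lambdas)) lambdas <- t0 * lambdas_rel
  if (length(lambdas) == 0) stop_param("lambdas must be nonempty")
  ord <- order(lambdas)
  sols <- vector("list", length(lambdas))
  errs <- character(0)
  for (i in ord) {
    ne$lambda <- lambdas[i]
    sols[[i]] <- tryCatch(solve_autocorrelation(ne, tol, max_iter, x0 = x0),
                          spimtip_numerical_error = function(e) {
                            errs <<- c(errs, conditionMessage(e)); NULL
                          })
  }
  ok <- which(!vapply(sols, is.null, TRUE))
  if (length(ok) == 0)
    stop_numerical(paste("all merge solves failed:", paste(errs, collapse = "; ")))
  pick <- ok[lcurve_select(vapply(sols[ok], `[[`, 0, "data_misfit"),
                           vapply(sols[ok], `[[`, 0, "solution_norm"),
                           lambdas[ok])]
  out <- sols[[pick]]
  attr(out, "sweep") <- data.frame(
    lambda = lambdas[ok],
    data_misfit = vapply(sols[ok], `[[`, 0, "data_misfit"),
    solution_norm = vapply(sols[ok], `[[`, 0, "solution_norm"),
    iterations = vapply(sols[ok], function(s) s$cg_iterations, 0L))
  out
}

kernel_zero_lag <- function(ne) {
  M2 <- dim(ne$kernel)[1]
  ne$kernel[M2 / 2 + 1, M2 / 2 + 1, M2 / 2 + 1]
}

# Corner of the L-curve by maximum discrete curvature in sorted-lambda
# order; fallback: smallest lambda with misfit within 5% of the minimum.
lcurve_select <- function(misfit, norm, lambdas) {
  o <- order(lambdas)
  fallback <- function() {
    cand <- which(misfit <= 1.05 * min(misfit))
    cand[which.min(lambdas[cand])]
  }
  if (length(lambdas) < 3) return(fallback())
  x <- log(pmax(misfit[o], 1e-300))
  y <- log(pmax(norm[o], 1e-300))
  n <- length(x)
  curv <- rep(NA_real_, n)
  for (i in 2:(n - 1)) {
    dx1 <- x[i] - x[i - 1]; dy1 <- y[i] - y[i - 1]
    dx2 <- x[i + 1] - x[i]; dy2 <- y[i + 1] - y[i]
    cross <- dx1 * dy2 - dy1 * dx2
    denom <- sqrt((dx1^2 + dy1^2) * (dx2^2 + dy2^2) * ((dx1 + dx2)^2 + (dy1 + dy2)^2))
    if (denom > 0) curv[i] <- abs(cross) / denom
  }
  if (all(is.na(curv))) return(fallback())
  o[which.max(curv)]
}
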