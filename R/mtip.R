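## The multi-tiered iterative phasing (M-TIP) generation loop:
## slice -> match orientations/conformations -> merge autocorrelation ->
## phase, repeated from a randomized first pass until the density models
## converge.

#' M-TIP reconstruction configuration
#'
#' @param grid_n Shannon channels per dimension of the object (the object
#'   support fits an N-cube of this side); the working reciprocal grid has
#'   side \code{oversample * grid_n}.
#' @param voxel real-space voxel size (m) of the reconstruction grid.
#' @param n_ref number of reference orientations for slicing/matching.
#' @param ref_scheme [reference_grid()] scheme.
#' @param n_conformations number of density models K maintained.
#' @param metric matching metric, see [match_orientations()].
#' @param n_generations_max maximum number of generations.
#' @param convergence_tol stop when the maximum aligned relative density
#'   change across conformations falls below this (strict inequality).
#' @param seed master seed: initial random orientations/conformation
#'   assignment and phasing starts all derive from it.
#' @param oversample linear oversampling of the intensity grid (>= 2).
#' @param lambdas_rel Tikhonov sweep grid, relative to the kernel zero lag
#'   (the mean eigenvalue of the unregularized system).
#' @param merge_tol,merge_max_iter merge solver controls.
#' @param nufft_tol NUFFT accuracy used inside the loop.
#' @param warm_start reuse the previous generation's merge solution and
#'   density as initial guesses (faster, but adds hysteresis to the loop).
#' @param phasing list of phasing controls: \code{hio_iterations},
#'   \code{er_iterations}, \code{beta}, \code{n_starts},
#'   \code{shrinkwrap_sigma}, \code{shrinkwrap_threshold},
#'   \code{shrinkwrap_interval}.
#' @export
mtip_config <- function(grid_n = 32L, voxel = 1e-9, n_ref = 400L,
                        ref_scheme = "quasi_uniform", n_conformations = 1L,
                        metric = "weighted_l2", n_generations_max = 12L,
                        convergence_tol = 0.02, seed = 1L, oversample = 2L,
                        lambdas_rel = c(1e-4, 1e-3, 1e-2), merge_tol = 1e-3,
                        merge_max_iter = 25L, nufft_tol = 1e-3,
                        warm_start = TRUE, phasing = list()) {
  check_count(grid_n, "grid_n", min = 8L)
  check_count(n_ref, "n_ref", min = 1L)
  check_count(n_conformations, "n_conformations", min = 1L)
  check_count(n_generations_max, "n_generations_max", min = 1L)
  check_count(oversample, "oversample", min = 2L)
  if (!is.infinite(convergence_tol)) check_positive(convergence_tol, "convergence_tol")
  ph_def <- list(hio_iterations = 100L, er_iterations = 30L, beta = 0.9,
                 n_starts = 2L, shrinkwrap_sigma = 1.5,
                 shrinkwrap_threshold = 0.12, shrinkwrap_interval = 20L)
  unknown <- setdiff(names(phasing), names(ph_def))
  if (length(unknown) > 0)
    stop_param(paste("unknown phasing option(s):", paste(unknown, collapse = ", ")))
  ph_def[names(phasing)] <- phasing
  structure(list(grid_n = as.integer(grid_n), voxel = voxel,
                 n_ref = as.integer(n_ref), ref_scheme = ref_scheme,
                 n_conformations = as.integer(n_conformations), metric = metric,
                 n_generations_max = as.integer(n_generations_max),
                 convergence_tol = convergence_tol, seed = as.integer(seed),
                 oversample = as.integer(oversample), lambdas_rel = lambdas_rel,
                 merge_tol = merge_tol, merge_max_iter = as.integer(merge_max_iter),
                 nufft_tol = nufft_tol, warm_start = isTRUE(warm_start),
                 phasing = ph_def),
            class = "mtip_config")
}

#' Reconstruct particle density models from a diffraction pattern stack
#'
#' Runs the full M-TIP loop. Generation 0 assigns random orientations
#' (and, for K > 1, uniform random conformations) to the patterns, merges
#' and phases once to obtain starting models; each later generation
#' recomputes reference slices from the current models, reassigns each
#' image the (orientation, conformation) pair minimizing the matching
#' metric, merges each conformation's fluence-normalized samples with a
#' Tikhonov sweep, and phases each merged volume (warm-started from the
#' previous density). The loop stops when the maximum aligned relative
#' density change falls below \code{convergence_tol}, or at
#' \code{n_generations_max}.
#'
#' @param stack a \code{pattern_stack} (from [simulate_patterns()] or
#'   [read_pattern_stack()]).
#' @param geom a [detector_geometry()]; defaults to the stack's.
#' @param config an [mtip_config()].
#' @param log optional [event_log()] for weather-plot diagnostics.
#' @param checkpoint_dir optional directory; per-generation densities
#'   (MRC), assignments (TSV) and history (TSV) are written there.
#' @param init_densities optional list of K [density_model()] starting
#'   models (e.g. read back from a checkpoint, or built by
#'   [split_conformations()] for staged K > 1 initialization); when given,
#'   the randomized generation-0 pass is skipped and the loop starts by
#'   slicing these models.
#' @param verbose print one line per generation.
#' @return an object of class \code{"mtip"}: densities (list of
#'   [density_model()]), assignments, per-generation history, convergence
#'   flag; see [summary.mtip()].
#' @export
mtip <- function(stack, geom = stack$geom, config = mtip_config(), log = NULL,
                 checkpoint_dir = NULL, init_densities = NULL, verbose = FALSE) {
  if (!inherits(stack, "pattern_stack")) stop_param("stack must be a pattern_stack")
  if (!inherits(config, "mtip_config")) stop_param("config must be an mtip_config")
  d <- dim(stack$images)
  if (d[1] != geom$n_fast || d[2] != geom$n_slow)
    stop_param("stack image shape does not match the detector geometry")
  D <- d[3]
  K <- config$n_conformations
  M <- config$oversample * config$grid_n
  voxel <- config$voxel
  qgrid <- pixel_to_q(geom)
  npix <- nrow(qgrid$q)
  I <- matrix(stack$images, npix, D)
  note <- function(w, lab, gen) if (!is.null(log)) record_event(log, w, lab, gen)

  # generation 0: random orientations + uniform random conformations
  init <- with_local_seed(config$seed, {
    list(ori = random_orientations(D, seed = config$seed + 1L),
         conf = if (K > 1) sample.int(K, D, replace = TRUE) else rep(1L, D))
  })
  totals <- colSums(I)
  scale0 <- totals / mean(totals)           # fluence surrogate for the first pass
  assigned_q <- init$ori
  conf <- init$conf
  scales <- pmax(scale0, 1e-12)
  densities <- vector("list", K)
  prev_x <- vector("list", K)               # CG warm starts per conformation
  history <- data.frame()
  refs_q <- reference_grid(config$n_ref, config$ref_scheme)
  converged <- FALSE
  assignments <- NULL
  gen_start <- 0L
  if (!is.null(init_densities)) {
    if (length(init_densities) != K)
      stop_param("init_densities must provide one model per conformation")
    densities <- lapply(init_densities, function(m) {
      tot <- sum(m$rho) * m$voxel^3
      if (tot > 0) m$rho <- m$rho / tot
      m
    })
    gen_start <- 1L
  }

  for (gen in gen_start:config$n_generations_max) {
    if (gen > 0) {
      # slice current models and reassign (orientation, conformation)
      refs <- vector("list", K)
      for (k in seq_len(K)) {
        ack <- density_ac(densities[[k]])
        refs[[k]] <- compute_slices(ack, refs_q, qgrid, conformation = k,
                                    nufft_tol = config$nufft_tol)
        note(k, "slice", gen)
      }
      assignments <- match_orientations(stack, refs, metric = config$metric)
      note(0, "match", gen)
      assigned_q <- lapply(seq_len(D), function(i)
        refs_q[[assignments$orientation[i]]])
      conf <- assignments$conformation
      # merge normalization uses the robust per-image totals estimate of the
      # relative fluence, not the matching's fitted scale: the fitted scale
      # is conditional on the assigned slice, so assignment errors would
      # otherwise distort the merged volume
      scales <- pmax(scale0, 1e-12)
      conf <- reseed_empty_conformations(conf, assignments$distance, K, verbose)
    }

    prev <- densities
    for (k in seq_len(K)) {
      sel <- which(conf == k)
      pts <- matrix(0, npix * length(sel), 3)
      for (ii in seq_along(sel)) {
        i <- sel[ii]
        pts[(ii - 1) * npix + seq_len(npix), ] <-
          qgrid$q %*% quat_to_matrix(assigned_q[[i]])
      }
      vals <- as.vector(sweep(I[, sel, drop = FALSE], 2, scales[sel], "/"))
      sol <- hyperparameter_sweep(
        list(points = pts, values = vals), M,
        lambdas = NULL, tol = config$merge_tol,
        max_iter = config$merge_max_iter, voxel = voxel,
        nufft_tol = config$nufft_tol, lambdas_rel = config$lambdas_rel,
        x0 = if (config$warm_start) prev_x[[k]])
      prev_x[[k]] <- sol$autocorrelation$values * voxel^3
      note(k, "merge", gen)
      iv <- intensity_from_ac(sol$autocorrelation, voxel)
      ivv <- iv$values
      ivv[ivv < 0] <- 0
      iv <- fourier_volume(ivv, iv$voxel_q, role = "intensity", check = FALSE)
      ph <- config$phasing
      cfg_ph <- phasing_config(
        schedule = list(
          list(method = "hybrid_input_output",
               iterations = ph$hio_iterations, beta = ph$beta),
          list(method = "error_reduction", iterations = ph$er_iterations)),
        support = support_shrinkwrap(ph$shrinkwrap_sigma, ph$shrinkwrap_threshold,
                                     ph$shrinkwrap_interval),
        seed = config$seed + 100L * k + gen, n_starts = ph$n_starts)
      pr <- phase_retrieve(iv, cfg_ph, oversample = config$oversample,
                           init = if (config$warm_start && gen > 0) prev[[k]])
      dk <- pr$density
      tot <- sum(dk$rho) * dk$voxel^3
      if (tot > 0) dk$rho <- dk$rho / tot   # unit integrated density: keeps
      densities[[k]] <- dk                  # every stage's magnitudes O(1)
      note(k, "phase", gen)
    }

    change <- if (gen == 0) NA_real_ else max(vapply(seq_len(K), function(k)
      aligned_rel_change(prev[[k]], densities[[k]]), 0))
    row <- data.frame(generation = gen,
                      total_distance = if (is.null(assignments)) NA_real_
                                       else sum(assignments$distance),
                      density_change = change)
    row[paste0("n_conf", seq_len(K))] <- as.list(tabulate(conf, K))
    history <- rbind(history, row)
    if (verbose)
      cat(sprintf("generation %d: distance %.4g, change %.4g, counts %s\n",
                  gen, row$total_distance, change,
                  paste(unlist(row[-(1:3)]), collapse = "/")))
    if (!is.null(checkpoint_dir))
      write_checkpoint(checkpoint_dir, gen, densities, assignments, history, refs_q)
    state <- structure(list(densities = densities, assignments = assignments,
                            generation = gen, history = history,
                            reference_orientations = refs_q,
                            config = config, converged = FALSE,
                            stack_dim = d, geom = geom),
                       class = "mtip")
    if (gen >= 1 && check_convergence(state, config$convergence_tol)) {
      converged <- TRUE
      break
    }
  }
  state$converged <- converged
  state
}

#' @rdname mtip
#' @export
run_mtip <- mtip

# AC volume of a (possibly oversampled-grid) density estimate, no extra
# padding: the shrinkwrapped support occupies at most half the grid.
density_ac <- function(model) {
  M <- dim(model$rho)[1]
  G <- stats::fft(model$rho) * model$voxel^3
  I <- fftshift3(Re(G * Conj(G)))
  ac_from_intensity(fourier_volume(I, 1 / (M * model$voxel), "intensity", check = FALSE),
                    model$voxel)
}

aligned_rel_change <- function(old, new) {
  if (is.null(old)) return(Inf)
  al <- align_densities(old, new)
  shifted <- cyclic_shift3(new$rho, al$shift, al$inverted)
  sqrt(sum((shifted - old$rho)^2) / max(sum(old$rho^2), 1e-300))
}

cyclic_shift3 <- function(x, shift, inverted = FALSE) {
  if (inverted) x <- invert_density(x)
  M <- dim(x)[1]
  ix <- function(s) ((seq_len(M) - 1 - s) %% M) + 1
  x[ix(shift[1]), ix(shift[2]), ix(shift[3])]
}

# A conformation that lost (nearly) all of its images is re-seeded with the
# worst-matching half of the largest conformation's images: with hard argmin
# assignment the K models can collapse onto one state early on, and the
# worst-matching images of the surviving model are precisely the ones most
# likely to belong to the missing state.
reseed_empty_conformations <- function(conf, dist, K, verbose = FALSE,
                                       min_frac = 0.05) {
  for (k in seq_len(K)) {
    if (sum(conf == k) >= min_frac * length(conf) / K) next
    big <- which.max(tabulate(conf, K))
    if (big == k) next
    pool <- which(conf == big)
    worst <- pool[order(dist[pool], decreasing = TRUE)]
    take <- worst[seq_len(floor(length(worst) / 2))]
    conf[take] <- k
    if (verbose)
      message(sprintf("conformation %d nearly empty; re-seeded with %d images from conformation %d",
                      k, length(take), big))
  }
  conf
}

#' Seed K conformation models from a converged single-model fit
#'
#' Staged initialization for multi-conformation reconstruction: hard
#' argmin assignment started from a random 50/50 split collapses onto the
#' mixture-average model (both models stay identical, so the likelihood
#' cannot tell states apart). Splitting *after* a K = 1 fit has converged
#' works because the orientations are then trustworthy: each random
#' disjoint subset merges to the average model plus small-sample noise
#' whose only systematic component is the conformational difference, and
#' the matching loop amplifies exactly that component.
#'
#' @param fit a converged K = 1 \code{mtip} object.
#' @param stack the pattern stack the fit was computed from.
#' @param K number of conformation models to seed (>= 2).
#' @param seed seed for the random split.
#' @return list of K [density_model()] objects for [mtip()]'s
#'   \code{init_densities}.
#' @export
split_conformations <- function(fit, stack, K = 2L, seed = 1L) {
  if (!inherits(fit, "mtip")) stop_param("fit must be an mtip object")
  if (is.null(fit$assignments)) stop_param("fit carries no orientation assignments")
  check_count(K, "K", min = 2L)
  config <- fit$config
  geom <- fit$geom
  qgrid <- pixel_to_q(geom)
  npix <- nrow(qgrid$q)
  D <- fit$stack_dim[3]
  M <- config$oversample * config$grid_n
  voxel <- config$voxel
  I <- matrix(stack$images, npix, D)
  totals <- colSums(I)
  scales <- pmax(totals / mean(totals), 1e-12)
  refs_q <- fit$reference_orientations
  groups <- with_local_seed(seed, sample(rep_len(seq_len(K), D)))
  out <- vector("list", K)
  for (k in seq_len(K)) {
    sel <- which(groups == k)
    pts <- matrix(0, npix * length(sel), 3)
    for (ii in seq_along(sel)) {
      i <- sel[ii]
      pts[(ii - 1) * npix + seq_len(npix), ] <-
        qgrid$q %*% quat_to_matrix(refs_q[[fit$assignments$orientation[i]]])
    }
    vals <- as.vector(sweep(I[, sel, drop = FALSE], 2, scales[sel], "/"))
    sol <- hyperparameter_sweep(list(points = pts, values = vals), M,
                                lambdas = NULL, tol = config$merge_tol,
                                max_iter = config$merge_max_iter, voxel = voxel,
                                nufft_tol = config$nufft_tol,
                                lambdas_rel = config$lambdas_rel)
    iv <- intensity_from_ac(sol$autocorrelation, voxel)
    ivv <- iv$values
    ivv[ivv < 0] <- 0
    iv <- fourier_volume(ivv, iv$voxel_q, role = "intensity", check = FALSE)
    ph <- config$phasing
    cfg_ph <- phasing_config(
      schedule = list(
        list(method = "hybrid_input_output", iterations = ph$hio_iterations,
             beta = ph$beta),
        list(method = "error_reduction", iterations = ph$er_iterations)),
      support = support_shrinkwrap(ph$shrinkwrap_sigma, ph$shrinkwrap_threshold,
                                   ph$shrinkwrap_interval),
      seed = config$seed + 1000L * k, n_starts = ph$n_starts)
    pr <- phase_retrieve(iv, cfg_ph, oversample = config$oversample,
                         init = fit$densities[[1]])
    out[[k]] <- pr$density
  }
  out
}

#' Convergence test on the reconstruction state
#'
#' TRUE when the latest generation's maximum aligned relative density
#' change is strictly below \code{tol}.
#'
#' @param state an \code{mtip} object (generation >= 1).
#' @param tol convergence tolerance.
#' @export
check_convergence <- function(state, tol) {
  if (state$generation < 1) stop_param("convergence needs at least one generation")
  ch <- utils::tail(state$history$density_change, 1)
  is.finite(ch) && ch < tol
}

write_checkpoint <- function(dir, gen, densities, assignments, history, refs_q) {
  gd <- file.path(dir, sprintf("generation_%03d", gen))
  dir.create(gd, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(densities))
    write_mrc(densities[[k]], file.path(gd, sprintf("density_conf%d.mrc", k)))
  if (!is.null(assignments)) {
    tab <- assignments
    utils::write.table(tab, file.path(gd, "assignments.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  utils::write.table(history, file.path(dir, "history.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(gd)
}

## ---- S3 methods ------------------------------------------------------------

#' @export
print.mtip <- function(x, ...) {
  cat(sprintf("M-TIP reconstruction: %d conformation(s), %d image(s), generation %d%s\n",
              length(x$densities), x$stack_dim[3], x$generation,
              if (x$converged) " (converged)" else ""))
  for (k in seq_along(x$densities)) {
    n <- sum(x$assignments$conformation == k)
    cat(sprintf("  conformation %d: %d images, total density %.4g\n", k,
                if (is.null(x$assignments)) NA_integer_ else n,
                sum(x$densities[[k]]$rho) * x$densities[[k]]$voxel^3))
  }
  invisible(x)
}

#' Summary of an M-TIP reconstruction
#'
#' @param object an \code{mtip} object.
#' @param truth optional [density_model()] or list of them; when given,
#'   aligned correlations against the truth are reported.
#' @param ... unused.
#' @export
summary.mtip <- function(object, truth = NULL, ...) {
  out <- list(generation = object$generation, converged = object$converged,
              history = object$history,
              counts = tabulate(object$assignments$conformation,
                                length(object$densities)))
  if (!is.null(truth)) {
    if (inherits(truth, "density_model")) truth <- list(truth)
    M <- dim(object$densities[[1]]$rho)[1]
    emb <- lapply(truth, function(tm) embed_density(tm, M))
    out$truth_correlation <- outer(
      seq_along(object$densities), seq_along(emb),
      Vectorize(function(k, j) aligned_correlation(emb[[j]], object$densities[[k]])))
  }
  class(out) <- "summary.mtip"
  out
}

#' @export
print.summary.mtip <- function(x, ...) {
  cat(sprintf("M-TIP after %d generation(s)%s\n", x$generation,
              if (x$converged) ", converged" else ""))
  cat("images per conformation:", paste(x$counts, collapse = ", "), "\n")
  if (!is.null(x$truth_correlation)) {
    cat("aligned correlation with truth (rows = reconstructions):\n")
    print(round(x$truth_correlation, 4))
  }
  cat("history:\n")
  print(x$history, row.names = FALSE)
  invisible(x)
}

# Embed an N^3 truth model into the corner of the M^3 working grid (the
# alignment search absorbs the placement).
embed_density <- function(model, M) {
  N <- dim(model$rho)[1]
  if (N == M) return(model)
  if (N > M) stop_param("truth grid larger than the working grid")
  arr <- array(0, c(M, M, M))
  arr[seq_len(N), seq_len(N), seq_len(N)] <- model$rho
  density_model(arr, model$voxel)
}

#' @export
plot.mtip <- function(x, ...) {
  h <- x$history[x$history$generation >= 1, , drop = FALSE]
  if (nrow(h) == 0) stop_param("nothing to plot before generation 1")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$generation, h$total_distance, type = "b", pch = 19,
                 xlab = "generation", ylab = "summed matching distance",
                 main = "orientation matching")
  graphics::plot(h$generation, h$density_change, type = "b", pch = 19, log = "y",
                 xlab = "generation", ylab = "aligned relative density change",
                 main = "model convergence")
  invisible(x)
}

#' Simulate patterns from a fitted reconstruction
#'
#' Draws patterns from the reconstructed density models, mirroring the
#' original stack's geometry: a parametric-bootstrap check of the fit.
#'
#' @param object an \code{mtip} object.
#' @param nsim number of patterns.
#' @param seed integer seed.
#' @param noise a [noise_spec()]; defaults to Poisson with the object's seed.
#' @param ... unused.
#' @export
simulate.mtip <- function(object, nsim = 100, seed = 1L, noise = NULL, ...) {
  K <- length(object$densities)
  oris <- random_orientations(nsim, seed)
  confs <- with_local_seed(seed + 1L, sample.int(K, nsim, replace = TRUE))
  if (is.null(noise)) noise <- noise_spec(seed = seed + 2L)
  simulate_patterns(object$densities, object$geom, oris, confs, noise = noise)
}

#' Per-image matching residuals of a reconstruction
#'
#' @param object an \code{mtip} object.
#' @param ... unused.
#' @return numeric vector of final matching distances (NA before the first
#'   matching pass).
#' @export
residuals.mtip <- function(object, ...) {
  if (is.null(object$assignments)) return(rep(NA_real_, object$stack_dim[3]))
  object$assignments$distance
}

#' @importFrom stats simulate residuals
NULL
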