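# Tiny reconstruction instance shared across the loop tests.
tiny_mtip_setup <- function(D = 24, seed = 42) {
  ph <- tiny_phantom(N = 16)
  geom <- tiny_geometry(n_pixels = 16)
  fl <- fluence_for_photons(ph, geom, 3000)
  stack <- simulate_patterns(ph, geom, random_orientations(D, seed = 2),
                             noise = noise_spec(fluence_mean = fl, seed = seed))
  list(ph = ph, geom = geom, stack = stack)
}

tiny_cfg <- function(...) {
  mtip_config(grid_n = 16, n_ref = 40, n_generations_max = 2, seed = 9,
              phasing = list(n_starts = 1, hio_iterations = 30, er_iterations = 10),
              merge_max_iter = 15, ...)
}

test_that("an infinite convergence tolerance stops after exactly one generation", {
  s <- tiny_mtip_setup()
  fit <- mtip(s$stack, s$geom, tiny_cfg(convergence_tol = Inf))
  expect_equal(fit$generation, 1L)
  expect_true(fit$converged)
  expect_equal(nrow(fit$history), 2L)      # generations 0 and 1
})

test_that("the loop is deterministic for a fixed configuration and seed", {
  s <- tiny_mtip_setup()
  f1 <- mtip(s$stack, s$geom, tiny_cfg())
  f2 <- mtip(s$stack, s$geom, tiny_cfg())
  expect_identical(f1$densities[[1]]$rho, f2$densities[[1]]$rho)
  expect_identical(f1$assignments, f2$assignments)
  expect_identical(f1$history, f2$history)
})

test_that("convergence is a strict-inequality test on the aligned density change", {
  state <- structure(list(generation = 3L,
                          history = data.frame(generation = 0:3,
                                               density_change = c(NA, 1, 0.5, 0.01))),
                     class = "mtip")
  expect_true(check_convergence(state, 0.02))
  state$history$density_change[4] <- 0.02   # exactly at tol: not converged
  expect_false(check_convergence(state, 0.02))
  state$history$density_change[4] <- 0      # identical densities
  expect_true(check_convergence(state, 1e-12))
  state$generation <- 0L
  expect_error(check_convergence(state, 0.02), "generation")
  # a perturbation of magnitude 10*tol is seen as unconverged by the metric
  ph <- tiny_phantom(N = 16)
  tol <- 0.01
  pert <- ph$rho * (1 + 10 * tol * 2 * (array(runif(16^3), dim(ph$rho)) > 0.5))
  ch <- spimtip:::aligned_rel_change(ph, density_model(pert, ph$voxel))
  expect_gt(ch, tol)
})

test_that("one generation from true orientations is a fixed point of the loop", {
  ph <- tiny_phantom(N = 16)
  geom <- tiny_geometry(n_pixels = 24)
  refs_q <- reference_grid(60)
  D <- 180                                   # ~10 samples per Shannon voxel
  idx <- rep(seq_along(refs_q), length.out = D)
  oris <- lapply(idx, function(i) refs_q[[i]])
  stack <- clean_stack(ph, geom, oris)
  # merge at the true orientations and compare with the exact autocorrelation
  sm <- merge_samples(stack)
  sol <- hyperparameter_sweep(sm, M = 32, lambdas = NULL, tol = 1e-6,
                              max_iter = 200, voxel = ph$voxel, nufft_tol = 1e-6,
                              lambdas_rel = c(1e-6, 1e-4, 1e-2))
  ex <- exact_autocorrelation(ph, 2)
  expect_lt(rel_l2(sol$autocorrelation$values, ex$values), 0.05)
  # re-matching against slices of that merged model keeps the assignments
  refs <- compute_slices(sol$autocorrelation, refs_q, pixel_to_q(geom),
                         nufft_tol = 1e-8)
  res <- match_orientations(stack, refs)
  expect_equal(matching_accuracy(res, refs, stack$true_orientation, tol_deg = 1), 1)
})

test_that("empty conformations are re-seeded from the largest one", {
  conf <- rep(1L, 10)
  dist <- c(5, 1, 9, 2, 8, 3, 7, 4, 6, 0)
  out <- spimtip:::reseed_empty_conformations(conf, dist, K = 2)
  expect_equal(sum(out == 2), 5)
  expect_true(all(which(out == 2) %in% order(dist, decreasing = TRUE)[1:5]))
})

test_that("reconstruction methods expose the fit: print, summary, residuals, simulate", {
  s <- tiny_mtip_setup()
  fit <- mtip(s$stack, s$geom, tiny_cfg())
  expect_output(print(fit), "M-TIP reconstruction")
  sm <- summary(fit, truth = s$ph)
  expect_s3_class(sm, "summary.mtip")
  expect_true(all(dim(sm$truth_correlation) == c(1, 1)))
  expect_gte(sm$truth_correlation[1, 1], -1)
  expect_output(print(sm), "aligned correlation")
  expect_length(residuals(fit), dim(s$stack$images)[3])
  boot <- simulate(fit, nsim = 5, seed = 3)
  expect_s3_class(boot, "pattern_stack")
  expect_equal(dim(boot$images), c(16, 16, 5))
  pf <- file.path(tempdir(), "mtip-hist.png")
  png(pf); plot(fit); dev.off()
  expect_true(file.exists(pf))
})

test_that("checkpoints contain densities, assignments and history", {
  s <- tiny_mtip_setup()
  ck <- file.path(tempdir(), "ckpt-test")
  fit <- mtip(s$stack, s$geom, tiny_cfg(convergence_tol = Inf), checkpoint_dir = ck)
  expect_true(file.exists(file.path(ck, "generation_001", "density_conf1.mrc")))
  expect_true(file.exists(file.path(ck, "generation_001", "assignments.tsv")))
  hist <- read.table(file.path(ck, "history.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(hist), 2)
  m <- read_mrc(file.path(ck, "generation_001", "density_conf1.mrc"))
  expect_equal(dim(m$rho), dim(fit$densities[[1]]$rho))
})
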