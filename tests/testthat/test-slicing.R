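# Independently coded brute-force matcher (triple loop) used as the oracle
# for match_orientations.
make_refs <- function(model, geom, n_ref, conformation = 1L, tol = 1e-8) {
  ac <- exact_autocorrelation(model, 2)
  compute_slices(ac, reference_grid(n_ref), pixel_to_q(geom),
                 conformation = conformation, nufft_tol = tol)
}

test_that("slices are nonnegative, Friedel-degenerate, and radial for symmetric models", {
  geom <- detector_geometry(16, 16, 1e-4, 0.1, 1e-10, beam_center = c(7.5, 7.5))
  # single centered Gaussian: spherically symmetric intensity
  N <- 16
  ax <- (seq_len(N) - 1 - N / 2)
  r2 <- spimtip:::outer_triple_real(ax^2, rep(1, N), rep(1, N)) +
        spimtip:::outer_triple_real(rep(1, N), ax^2, rep(1, N)) +
        spimtip:::outer_triple_real(rep(1, N), rep(1, N), ax^2)
  ph <- density_model(exp(-r2 / (2 * 2^2)), 1e-9)
  ac <- exact_autocorrelation(ph, 2)
  qg <- pixel_to_q(geom)
  rs <- compute_slices(ac, list(c(1, 0, 0, 0)), qg, nufft_tol = 1e-10)
  expect_true(all(rs$slices >= 0))
  # identity orientation: swapping (fast, slow) pixel coordinates preserves
  # |q| for this centered geometry, so the slice must be symmetric
  img <- matrix(rs$slices[, 1], 16, 16)
  expect_lt(max(abs(img - t(img))) / max(img), 1e-9)
  # identical slices for q and its beam-axis half-turn composition (flat Ewald)
  qgf <- pixel_to_q(geom, ewald = "flat")
  phA <- tiny_phantom(N = 16)
  acA <- exact_autocorrelation(phA, 2)
  q0 <- quat(rnorm(4))
  qF <- quat_multiply(q0, quat_axis_angle(c(0, 0, 1), pi))
  two <- compute_slices(acA, list(q0, qF), qgf, nufft_tol = 1e-10)
  expect_equal(two$slices[, 1], two$slices[, 2], tolerance = 1e-8)
  # zero autocorrelation -> zero slices
  zac <- fourier_volume(array(0, c(32, 32, 32)), ac$voxel_q, "autocorrelation")
  expect_true(all(compute_slices(zac, list(q0), qg)$slices == 0))
})

test_that("a noiseless pattern self-matches its generating orientation with zero distance", {
  ph <- tiny_phantom(N = 16)
  geom <- tiny_geometry(n_pixels = 16)
  refs <- make_refs(ph, geom, 20)
  truth_idx <- c(3L, 17L, 9L)
  stack <- clean_stack(ph, geom, refs$orientations[truth_idx], nufft_tol = 1e-10)
  res <- match_orientations(stack, refs)
  expect_identical(res$orientation, truth_idx)
  expect_equal(res$scale, rep(1, 3), tolerance = 1e-5)
  expect_lt(max(res$distance) / sum(stack$images[, , 1]^2), 1e-10)
})

test_that("matching agrees with the brute-force triple-loop oracle", {
  pair <- make_phantom(phantom_spec("two_conformations", seed = 3), 16, 1e-9)
  geom <- tiny_geometry(n_pixels = 16)
  refs <- list(make_refs(pair[[1]], geom, 20, 1L), make_refs(pair[[2]], geom, 20, 2L))
  fl <- fluence_for_photons(pair[[1]], geom, 2000)
  oris <- random_orientations(10, seed = 21)
  stack <- simulate_patterns(pair, geom, oris,
                             conformation_ids = rep(1:2, 5),
                             noise = noise_spec(fluence_mean = fl, seed = 5))
  res <- match_orientations(stack, refs)
  I <- matrix(stack$images, 256, 10)
  W <- 1 / pmax(I, 1)
  bf <- brute_force_match(I, W, refs)
  expect_identical(res$orientation, bf$orientation)
  expect_identical(res$conformation, bf$conformation)
  expect_equal(res$distance, bf$distance, tolerance = 1e-10)
  expect_equal(res$scale, bf$scale, tolerance = 1e-10)
  # the reported distance is the minimum over all evaluated pairs
  for (ci in 1:2) {
    d <- spimtip:::dist_weighted_l2(I, W, refs[[ci]]$slices)$dist
    expect_true(all(res$distance <= d + 1e-9 * abs(d)))
  }
})

test_that("fitted-scale matching is invariant to a global fluence change", {
  ph <- tiny_phantom(N = 16)
  geom <- tiny_geometry(n_pixels = 16)
  refs <- make_refs(ph, geom, 25)
  oris <- random_orientations(8, seed = 31)
  s1 <- clean_stack(ph, geom, oris)
  s2 <- s1; s2$images <- s1$images * 2
  r1 <- match_orientations(s1, refs)
  r2 <- match_orientations(s2, refs)
  expect_identical(r1$orientation, r2$orientation)
})

test_that("augmenting the reference set with the truth never increases the metric", {
  ph <- tiny_phantom(N = 16)
  geom <- tiny_geometry(n_pixels = 16)
  ac <- exact_autocorrelation(ph, 2)
  qg <- pixel_to_q(geom)
  oris_true <- random_orientations(5, seed = 41)
  stack <- clean_stack(ph, geom, oris_true)
  base <- reference_grid(20)
  r0 <- match_orientations(stack, compute_slices(ac, base, qg))
  r1 <- match_orientations(stack, compute_slices(ac, c(base, oris_true), qg))
  expect_true(all(r1$distance <= r0$distance + 1e-9 * r0$distance))
})

test_that("poisson_nll matching works and flags all-zero reference slices", {
  # a sharp-blob phantom so the ten reference slices are genuinely distinct
  ph <- make_phantom(phantom_spec(blob_sigma = 1e-9, seed = 7), 16, 1e-9)
  geom <- tiny_geometry(n_pixels = 16)
  refs <- make_refs(ph, geom, 10)
  fl <- fluence_for_photons(ph, geom, 3000)
  oris <- lapply(c(2L, 8L), function(i) refs$orientations[[i]])
  stack <- simulate_patterns(ph, geom, oris,
                             noise = noise_spec(poisson = FALSE, fluence_jitter_cv = 0,
                                                fluence_mean = fl))
  res <- match_orientations(stack, refs, metric = "poisson_nll")
  expect_equal(matching_accuracy(res, refs,
                                 lapply(c(2L, 8L), function(i) refs$orientations[[i]]),
                                 tol_deg = 1), 1)
  # closed-form table equals the direct per-pair likelihood evaluation
  I <- matrix(stack$images, 256, 2)
  got <- spimtip:::dist_poisson_nll(I, refs$slices, eps = 1e-12)
  for (i in 1:2) for (j in c(1, 4, 9)) {
    r <- refs$slices[, j]
    sdir <- sum(I[r > 0, i]) / sum(r)
    ddir <- sum(sdir * r - I[, i] * log(sdir * r + 1e-12))
    expect_equal(got$dist[i, j], ddir, tolerance = 1e-8)
    expect_equal(got$scale[i, j], sdir, tolerance = 1e-8)
  }
  refs_z <- refs
  refs_z$slices[, 5] <- 0
  expect_warning(match_orientations(stack, refs_z, metric = "poisson_nll"),
                 "all-zero")
})

test_that("matching accuracy counts Friedel twins as correct", {
  ph <- tiny_phantom(N = 16)
  geom <- tiny_geometry(n_pixels = 16)
  refs <- make_refs(ph, geom, 30)
  flip <- quat_axis_angle(c(0, 0, 1), pi)
  truth <- lapply(c(4L, 12L), function(i) refs$orientations[[i]])
  truth_flipped <- lapply(truth, function(q) quat_multiply(flip, q))
  stack <- clean_stack(ph, geom, truth)
  res <- match_orientations(stack, refs)
  expect_equal(matching_accuracy(res, refs, truth), 1)
  expect_equal(matching_accuracy(res, refs, truth_flipped), 1)
})
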