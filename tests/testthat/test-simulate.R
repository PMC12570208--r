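test_that("phantoms are nonnegative, supported, and reproducible", {
  ph <- tiny_phantom(N = 16)
  expect_s3_class(ph, "density_model")
  expect_true(all(ph$rho >= 0))
  expect_gt(sum(ph$rho) * ph$voxel^3, 0)
  expect_true(all(ph$rho[!ph$support_mask] == 0))
  expect_identical(ph$rho, tiny_phantom(N = 16)$rho)
  # degenerate two-conformation pair: zero shift gives identical models
  pair0 <- make_phantom(phantom_spec("two_conformations", conformation_shift = 0,
                                     seed = 3), N = 16, voxel = 1e-9)
  expect_identical(pair0[[1]]$rho, pair0[[2]]$rho)
  pair <- make_phantom(phantom_spec("two_conformations", seed = 3), N = 16,
                       voxel = 1e-9)
  expect_gt(max(abs(pair[[1]]$rho - pair[[2]]$rho)), 0)
})

test_that("intensity volumes satisfy the zero-frequency and Friedel identities", {
  ph <- tiny_phantom(N = 16)
  expect_error(density_to_intensity(ph, oversample = 1), "oversample")
  iv <- density_to_intensity(ph, 2)
  M <- dim(iv$values)[1]
  expect_equal(M, 32L)
  c0 <- M / 2 + 1
  expect_equal(iv$values[c0, c0, c0], (sum(ph$rho) * ph$voxel^3)^2,
               tolerance = 1e-10)
  expect_lt(spimtip:::friedel_asymmetry(iv$values), 1e-10)
  zero <- density_model(array(0, c(16, 16, 16)), 1e-9)
  expect_true(all(density_to_intensity(zero, 2)$values == 0))
})

test_that("the exact autocorrelation matches direct-correlation oracles", {
  ph <- tiny_phantom(N = 12)
  ac <- exact_autocorrelation(ph, 2)
  M <- dim(ac$values)[1]; c0 <- M / 2 + 1
  expect_equal(ac$values[c0, c0, c0], sum(ph$rho^2) * ph$voxel^3, tolerance = 1e-10)
  # a nonzero lag checked by explicit shifted-product summation
  lag <- c(2, -1, 3)
  padded <- array(0, c(M, M, M))
  padded[1:12, 1:12, 1:12] <- ph$rho
  sh <- spimtip:::cyclic_shift3(padded, lag)
  expect_equal(ac$values[c0 + lag[1], c0 + lag[2], c0 + lag[3]],
               sum(padded * sh) * ph$voxel^3, tolerance = 1e-8)
  # centro-symmetrized phantom -> centro-symmetric autocorrelation
  rho_cs <- (padded + spimtip:::invert_density(padded)) / 2
  ac_cs <- spimtip:::density_ac(density_model(rho_cs, ph$voxel))
  expect_lt(max(abs(ac_cs$values - spimtip:::friedel_mirror(ac_cs$values))) /
              max(ac_cs$values), 1e-8)
  zero <- density_model(array(0, c(12, 12, 12)), 1e-9)
  expect_true(all(exact_autocorrelation(zero, 2)$values == 0))
})

test_that("noiseless patterns equal the continuous intensity at rotated Ewald points", {
  ph <- tiny_phantom(N = 12)
  geom <- tiny_geometry(n_pixels = 16)
  oris <- random_orientations(2, seed = 5)
  stack <- clean_stack(ph, geom, oris)
  qg <- pixel_to_q(geom)
  for (i in 1:2) {
    pts <- qg$q %*% quat_to_matrix(oris[[i]])
    G <- nufft_direct_type2(ph$rho * ph$voxel^3, pts, ph$voxel)
    expect_lt(max(abs(as.vector(stack$images[, , i]) - Re(G * Conj(G)))) /
                max(abs(G)^2), 1e-7)
  }
})

test_that("Poisson noise has the right mean and dispersion; background adds a plane", {
  geom <- detector_geometry(16, 16, 1e-4, 0.1, 1e-10)
  zero <- density_model(array(0, c(8, 8, 8)), 1e-9)
  b0 <- 5
  stack <- simulate_patterns(zero, geom, random_orientations(2000, 1),
                             noise = noise_spec(poisson = TRUE, fluence_jitter_cv = 0,
                                                background_slope = c(b0, 0, 0),
                                                seed = 77))
  means <- apply(stack$images, c(1, 2), mean)
  expect_true(all(abs(means - b0) < 4 * sqrt(b0 / 2000)))
  vmr <- apply(stack$images, c(1, 2), var) / means
  expect_lt(abs(mean(vmr) - 1), 0.05)
  expect_true(all(stack$images == round(stack$images)))
  expect_error(
    simulate_patterns(zero, geom, random_orientations(2, 1),
                      noise = noise_spec(background_slope = c(-1, 0, 0))),
    "negative")
})

test_that("stacks are bitwise reproducible and scale linearly with fluence", {
  ph <- tiny_phantom(N = 12)
  geom <- tiny_geometry(n_pixels = 16)
  oris <- random_orientations(40, seed = 2)
  fl <- fluence_for_photons(ph, geom, 500)
  ns <- noise_spec(fluence_mean = fl, seed = 9)
  s1 <- simulate_patterns(ph, geom, oris, noise = ns)
  s2 <- simulate_patterns(ph, geom, oris, noise = ns)
  expect_identical(s1$images, s2$images)
  expect_identical(s1$fluence, s2$fluence)
  # expected photons scale linearly in fluence_mean (noise off: exact)
  a <- simulate_patterns(ph, geom, oris,
                         noise = noise_spec(poisson = FALSE, fluence_jitter_cv = 0,
                                            fluence_mean = fl))
  b <- simulate_patterns(ph, geom, oris,
                         noise = noise_spec(poisson = FALSE, fluence_jitter_cv = 0,
                                            fluence_mean = 3 * fl))
  expect_equal(sum(b$images) / sum(a$images), 3, tolerance = 1e-12)
  expect_equal(mean(apply(s1$images, 3, sum)), 500, tolerance = 0.2)
})

test_that("noise-free simulation is orientation-equivariant", {
  ph <- tiny_phantom(N = 12)
  geom <- tiny_geometry(n_pixels = 16)
  q1 <- quat(rnorm(4))
  R <- quat_axis_angle(c(1, 2, -1), 0.7)
  s1 <- clean_stack(ph, geom, list(quat_multiply(q1, R)))
  # sampling the R-rotated particle-frame grid under orientation q1
  qg <- pixel_to_q(geom)
  pts <- (qg$q %*% quat_to_matrix(q1)) %*% quat_to_matrix(R)
  G <- nufft_type2(ph$rho * ph$voxel^3, pts, ph$voxel, tol = 1e-8)
  expect_lt(max(abs(as.vector(s1$images[, , 1]) - Re(G * Conj(G)))) /
              max(Mod(G)^2), 1e-8)
})
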