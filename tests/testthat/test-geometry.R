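test_that("invalid detector parameters are rejected with the offending field named", {
  expect_error(detector_geometry(1, 64, 1e-4, 0.1, 1e-10), "n_fast")
  expect_error(detector_geometry(64, 64, -1e-4, 0.1, 1e-10), "pixel_size")
  expect_error(detector_geometry(64, 64, 1e-4, 0, 1e-10), "distance")
  expect_error(detector_geometry(64, 64, 1e-4, 0.1, 1e-10, beam_center = c(100, 0)),
               "beam_center")
})

test_that("the beam-center pixel maps to q = 0 and mirror pixels to opposite q", {
  geom <- detector_geometry(64, 64, 1e-4, 0.1, 1e-10, beam_center = c(32, 32))
  qg <- pixel_to_q(geom)
  center <- 33 + 32 * 64            # fast-major index of pixel (32, 32)
  expect_equal(unname(qg$q[center, ]), c(0, 0, 0), tolerance = 1e-15)
  # pixels symmetric about the beam center: (32+5, 32-3) vs (32-5, 32+3)
  p1 <- (32 + 5 + 1) + (32 - 3) * 64
  p2 <- (32 - 5 + 1) + (32 + 3) * 64
  expect_equal(sqrt(sum(qg$q[p1, ]^2)), sqrt(sum(qg$q[p2, ]^2)), tolerance = 1e-12)
  expect_equal(qg$q[p1, 1:2], -qg$q[p2, 1:2], tolerance = 1e-12)
})

test_that("corner pixel magnitude matches the scattering-angle oracle", {
  geom <- detector_geometry(64, 64, 1e-4, 0.1, 1e-10, beam_center = c(31.5, 31.5))
  qg <- pixel_to_q(geom)
  corner <- 64 * 64                 # pixel (63, 63)
  r <- sqrt(2) * 31.5 * 1e-4        # in-plane distance to the beam center
  theta <- atan(r / 0.1)
  expect_equal(sqrt(sum(qg$q[corner, ]^2)), 2 * sin(theta / 2) / 1e-10,
               tolerance = 1e-12)
})

test_that("every curved-Ewald q vector lies on the Ewald sphere", {
  geom <- detector_geometry(48, 40, 2e-4, 0.15, 1.5e-10, beam_center = c(20, 25))
  qg <- pixel_to_q(geom)
  k0 <- 1 / geom$wavelength
  radii <- sqrt(qg$q[, 1]^2 + qg$q[, 2]^2 + (qg$q[, 3] + k0)^2)
  expect_lt(max(abs(radii - k0)) / k0, 1e-9)
  flat <- pixel_to_q(geom, ewald = "flat")
  expect_true(all(flat$q[, 3] == 0))
})

test_that("quaternion rotations match the rotation-matrix oracle and preserve products", {
  expect_equal(rotate_vectors(c(1, 0, 0, 0), c(0.3, -1, 2)), c(0.3, -1, 2))
  q90 <- quat_axis_angle(c(0, 0, 1), pi / 2)
  expect_equal(rotate_vectors(q90, c(1, 0, 0)), c(0, 1, 0), tolerance = 1e-12)
  set.seed(4)
  for (i in 1:10) {
    q1 <- quat(rnorm(4)); q2 <- quat(rnorm(4))
    v <- matrix(rnorm(15), 5, 3)
    seq2 <- rotate_vectors(q2, rotate_vectors(q1, v))
    comp <- rotate_vectors(quat_multiply(q2, q1), v)
    expect_equal(seq2, comp, tolerance = 1e-12)
    oracle <- v %*% t(quat_to_matrix(q1)) %*% t(quat_to_matrix(q2))
    expect_equal(seq2, oracle, tolerance = 1e-12)
    # inner products preserved
    g1 <- tcrossprod(v)
    g2 <- tcrossprod(rotate_vectors(q1, v))
    expect_equal(g1, g2, tolerance = 1e-12)
  }
  expect_error(rotate_vectors(c(1, 1, 0, 0), c(1, 0, 0)), "norm")
})

test_that("random orientations are seeded, unit, and uniform in the trace moment", {
  expect_error(random_orientations(0, 1), "n")
  a <- random_orientations(25, 123)
  b <- random_orientations(25, 123)
  expect_identical(a, b)
  expect_length(random_orientations(1, 5), 1)
  expect_equal(sqrt(sum(random_orientations(1, 5)[[1]]^2)), 1, tolerance = 1e-12)
  qs <- random_orientations(10000, 99)
  traces <- vapply(qs, function(q) sum(diag(quat_to_matrix(q))), 0)
  # uniform SO(3): E[tr R] = 0, Var[tr R] = 1 (tr R = 1 + 2 cos(angle))
  expect_lt(abs(mean(traces)), 3 * sd(traces) / sqrt(length(traces)))
})

test_that("reference grids are deterministic coverings that refine with n_ref", {
  expect_error(reference_grid(10, scheme = "banana"))
  expect_identical(reference_grid(1, "euler_grid"), list(c(1, 0, 0, 0)))
  expect_identical(reference_grid(64, "quasi_uniform"), reference_grid(64, "quasi_uniform"))
  g8 <- reference_grid(8, "euler_grid")
  expect_length(g8, 8)
  for (q in g8) expect_equal(sqrt(sum(q^2)), 1, tolerance = 1e-12)
  dmin <- outer(seq_along(g8), seq_along(g8), Vectorize(function(i, j)
    if (i == j) Inf else quat_geodesic(g8[[i]], g8[[j]])))
  expect_gt(min(dmin), 1e-6)        # no duplicates after q = -q identification

  max_nn <- function(qs) {
    n <- length(qs)
    nn <- rep(Inf, n)
    for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
      nn[i] <- min(nn[i], quat_geodesic(qs[[i]], qs[[j]]))
    max(nn)
  }
  for (scheme in c("quasi_uniform", "euler_grid"))
    expect_lt(max_nn(reference_grid(500, scheme)), max_nn(reference_grid(50, scheme)))
})
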