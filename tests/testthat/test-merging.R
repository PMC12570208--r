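# Small shared instance: 200 in-band points, M = 8.
small_instance <- function(seed = 3, P = 200, M = 8, voxel = 1.5) {
  set.seed(seed)
  list(points = matrix(runif(3 * P, -1, 1), ncol = 3) / (2 * voxel),
       values = rnorm(P)^2, M = M, voxel = voxel)
}

dense_operator <- function(inst) {
  E <- spimtip:::direct_phase_matrix(inst$points, inst$M, inst$voxel, -1)
  list(AhA = Re(Conj(t(E)) %*% E), Ahb = Re(as.vector(Conj(t(E)) %*% inst$values)))
}

test_that("normal-equation setup: linearity of the rhs and the kernel zero lag", {
  inst <- small_instance()
  ne <- setup_normal_equations(inst[c("points", "values")], inst$M, 0.1,
                               inst$voxel, nufft_tol = 1e-10, friedel = FALSE)
  expect_equal(spimtip:::kernel_zero_lag(ne), 200, tolerance = 1e-7)
  z <- setup_normal_equations(list(points = inst$points, values = rep(0, 200)),
                              inst$M, 0.1, inst$voxel, nufft_tol = 1e-10,
                              friedel = FALSE)
  expect_equal(max(abs(z$rhs)), 0, tolerance = 1e-12)
  expect_identical(z$kernel, ne$kernel)             # kernel ignores the values
  dbl <- setup_normal_equations(list(points = inst$points, values = 2 * inst$values),
                                inst$M, 0.1, inst$voxel, nufft_tol = 1e-10,
                                friedel = FALSE)
  expect_equal(dbl$rhs, 2 * ne$rhs, tolerance = 1e-12)
  expect_error(setup_normal_equations(list(points = inst$points[0, , drop = FALSE],
                                           values = numeric(0)), 8), "empty")
})

test_that("apply_system equals the dense normal matrix and is self-adjoint", {
  inst <- small_instance()
  lam <- 0.7
  ne <- setup_normal_equations(inst[c("points", "values")], inst$M, lam,
                               inst$voxel, nufft_tol = 1e-10, friedel = FALSE)
  dn <- dense_operator(inst)
  set.seed(5)
  x <- array(rnorm(inst$M^3), rep(inst$M, 3))
  y <- array(rnorm(inst$M^3), rep(inst$M, 3))
  Ax <- apply_system(ne, x)
  expect_lt(max(abs(Ax - array(dn$AhA %*% as.vector(x) + lam * as.vector(x),
                               rep(inst$M, 3)))) / max(abs(Ax)), 1e-7)
  expect_equal(apply_system(ne, array(0, rep(inst$M, 3))),
               array(0, rep(inst$M, 3)))
  expect_lt(abs(sum(Ax * y) - sum(x * apply_system(ne, y))) / abs(sum(Ax * y)), 1e-8)
  # large lambda dominates: top eigenvalue by power iteration
  v <- x / sqrt(sum(x^2))
  for (i in 1:30) {
    w <- apply_system(ne, v, lambda = 0)
    v <- w / sqrt(sum(w^2))
  }
  top <- sum(v * apply_system(ne, v, lambda = 0))
  big <- 100 * top
  dev <- apply_system(ne, x, lambda = big) - big * x
  expect_lt(sqrt(sum(dev^2)) / (big * sqrt(sum(x^2))), 0.01)
})

test_that("the merge solver matches a dense direct solve and behaves on zero data", {
  inst <- small_instance()
  lam <- 0.5
  ne <- setup_normal_equations(inst[c("points", "values")], inst$M, lam,
                               inst$voxel, nufft_tol = 1e-10, friedel = FALSE)
  dn <- dense_operator(inst)
  xd <- solve(dn$AhA + lam * diag(inst$M^3), dn$Ahb)
  sol <- solve_autocorrelation(ne, tol = 1e-10, max_iter = 500)
  xs <- as.vector(sol$autocorrelation$values) * inst$voxel^3
  expect_lt(max(abs(xs - xd)) / max(abs(xd)), 1e-6)
  expect_true(sol$converged)
  expect_lte(sol$cg_iterations, 500)
  # residual history is non-increasing (residual-minimizing iteration)
  expect_true(all(diff(sol$residual_history) <= 1e-10))
  zne <- setup_normal_equations(list(points = inst$points, values = rep(0, 200)),
                                inst$M, lam, inst$voxel)
  zsol <- solve_autocorrelation(zne, tol = 1e-8)
  expect_true(all(zsol$autocorrelation$values == 0))
  expect_lte(zsol$cg_iterations, 1)
})

test_that("the hyper-parameter sweep selects stably and order-independently", {
  inst <- small_instance()
  lams <- c(2, 0.02, 0.2)
  one <- hyperparameter_sweep(inst[c("points", "values")], inst$M, lambdas = 0.2,
                              tol = 1e-8, max_iter = 300, voxel = inst$voxel)
  ne <- setup_normal_equations(inst[c("points", "values")], inst$M, 0.2, inst$voxel)
  ref <- solve_autocorrelation(ne, tol = 1e-8, max_iter = 300)
  expect_equal(one$autocorrelation$values, ref$autocorrelation$values,
               tolerance = 1e-12)
  s1 <- hyperparameter_sweep(inst[c("points", "values")], inst$M, lambdas = lams,
                             tol = 1e-8, max_iter = 300, voxel = inst$voxel)
  s2 <- hyperparameter_sweep(inst[c("points", "values")], inst$M,
                             lambdas = rev(lams), tol = 1e-8, max_iter = 300,
                             voxel = inst$voxel)
  expect_equal(s1$lambda_used, s2$lambda_used)
  expect_equal(s1$autocorrelation$values, s2$autocorrelation$values)
  # continuity in lambda: 1% change in lambda moves the solution < 2%
  sa <- solve_autocorrelation(setup_normal_equations(
    inst[c("points", "values")], inst$M, 0.2, inst$voxel), tol = 1e-10, 500)
  sb <- solve_autocorrelation(setup_normal_equations(
    inst[c("points", "values")], inst$M, 0.202, inst$voxel), tol = 1e-10, 500)
  expect_lt(rel_l2(sb$autocorrelation$values, sa$autocorrelation$values), 0.02)
})

test_that("Friedel symmetrization equals explicit sample mirroring", {
  inst <- small_instance(P = 120)
  ne1 <- setup_normal_equations(inst[c("points", "values")], inst$M, 0,
                                inst$voxel, nufft_tol = 1e-10, friedel = TRUE)
  aug <- list(points = rbind(inst$points, -inst$points),
              values = c(inst$values, inst$values))
  ne2 <- setup_normal_equations(aug, inst$M, 0, inst$voxel,
                                nufft_tol = 1e-10, friedel = FALSE)
  expect_equal(ne1$rhs, ne2$rhs, tolerance = 1e-7)
  expect_equal(ne1$kernel, ne2$kernel, tolerance = 1e-7)
})
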