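test_that("spherical harmonic basis is orthonormal to high degree", {
  # Gauss-Legendre x uniform-phi quadrature over the sphere
  gl <- 48
  # nodes/weights via eigenvalue method (Golub-Welsch), independent of the basis code
  beta <- (1:(gl - 1)) / sqrt(4 * (1:(gl - 1))^2 - 1)
  J <- diag(0, gl); J[cbind(1:(gl - 1), 2:gl)] <- beta; J[cbind(2:gl, 1:(gl - 1))] <- beta
  eg <- eigen(J, symmetric = TRUE)
  x <- eg$values; w <- 2 * eg$vectors[1, ]^2
  np <- 96
  ph <- (0:(np - 1)) * 2 * pi / np
  theta <- rep(acos(x), each = np); phi <- rep(ph, times = gl)
  wt <- rep(w, each = np) * (2 * pi / np)
  B <- spharm_basis(theta, phi, 12)
  G <- crossprod(B, B * wt)
  expect_lt(max(abs(G - diag(ncol(B)))), 1e-12)
})

test_that("radial parameterization follows the angle conventions", {
  pts <- rbind(c(2, 0, 0), c(0, 0, 3), c(-1, 0, 0), c(0, 2, 0), c(0, -2, 0),
               c(0, 0, -1))
  par <- parameterize_surface(pts, center = c(0, 0, 0))
  expect_equal(par$theta[1], 0)                       # +z pole
  expect_equal(c(par$theta[2], par$phi[2]), c(pi / 2, 0))  # +x equator
  expect_equal(par$theta[3], pi)
  expect_equal(c(par$theta[4], par$phi[4]), c(pi / 2, pi / 2))
  expect_equal(par$r[2], 3)
})

test_that("uniform sphere samples parameterize uniformly (area-bin chi-square)", {
  set.seed(4)
  u <- matrix(rnorm(3 * 4000), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  par <- parameterize_surface(5 * u, center = c(0, 0, 0))
  # equal-area bins: uniform in cos(theta) x phi
  bins <- table(cut(cos(par$theta), seq(-1, 1, length.out = 5)),
                cut(par$phi, seq(0, 2 * pi, length.out = 5)))
  p <- suppressWarnings(stats::chisq.test(as.vector(bins)))$p.value
  expect_gt(p, 0.01)
})

test_that("parameterization flags exterior centres and direction collisions", {
  set.seed(5)
  u <- matrix(rnorm(3 * 200), ncol = 3); u <- u / sqrt(rowSums(u^2))
  expect_error(parameterize_surface(u, center = c(5, 0, 0)), "convex hull")
  dup <- rbind(u, u[1, ] * 0.5)   # same direction, different radius
  expect_warning(parameterize_surface(dup, center = c(0, 0, 0)), "collision")
})

test_that("ellipsoid fits concentrate energy in degree 1 and reconstruct exactly", {
  s <- ellipsoid_surface(c(4, 3, 2), diag(3), n_points = 1200)
  desc <- fit_spharm(s, L = 31)
  deg <- rep(0:31, times = 2 * (0:31) + 1)
  energy <- rowSums(desc$coeffs^2)
  expect_lt(sum(energy[deg >= 2]) / sum(energy), 0.01)
  expect_lt(desc$fit_residual, 1e-3)

  sphere <- ellipsoid_surface(c(5, 5, 5), diag(3), n_points = 1200)
  dsph <- fit_spharm(sphere, L = 31)
  esph <- rowSums(dsph$coeffs^2)
  expect_lt(sum(esph[deg >= 2]) / sum(esph), 1e-10)

  rec <- reconstruct(desc, 48)
  expect_lt(hausdorff(s, rec), 0.3)   # sampling-density limited
})

test_that("fit_spharm validates its preconditions", {
  s <- ellipsoid_surface(c(2, 1.5, 1), diag(3), n_points = 30)
  expect_error(fit_spharm(s, L = 10), "decrease L")
  flat <- cbind(0, matrix(rnorm(40), ncol = 2))
  expect_error(fit_spharm(flat, L = 2), "degenerate")
})

test_that("translation changes the centre but not the coefficients", {
  set.seed(8)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  s <- ellipsoid_surface(c(3, 2, 1.5), R, n_points = 400)
  d0 <- fit_spharm(s, L = 6)
  d1 <- fit_spharm(sweep(s, 2, c(10, -4, 2), `+`), L = 6)
  expect_equal(d1$center, d0$center + c(10, -4, 2), tolerance = 1e-8)
  expect_equal(d1$coeffs, d0$coeffs, tolerance = 1e-6)
})

test_that("zero coefficients reconstruct to the centre point", {
  d <- structure(list(order = 3, coeffs = matrix(0, 16, 3), center = c(1, 2, 3),
                      fit_residual = 0), class = "spharm_descriptor")
  rec <- reconstruct(d, 8)
  expect_true(all(abs(sweep(rec, 2, c(1, 2, 3))) < 1e-12))
  # determinism on a fixed grid
  d2 <- fit_spharm(ellipsoid_surface(c(3, 2, 2), diag(3), n_points = 300), L = 5)
  expect_identical(reconstruct(d2, 16), reconstruct(d2, 16))
})

test_that("hausdorff agrees with the naive oracle and its axioms", {
  expect_equal(hausdorff(rbind(c(0, 0, 0)), rbind(c(0, 0, 3))), 3)
  A <- matrix(rnorm(3 * 40), ncol = 3)
  expect_lt(hausdorff(A, A), 1e-6)
  for (s in 1:5) {
    set.seed(400 + s)
    A <- matrix(rnorm(3 * 25), ncol = 3)
    B <- matrix(rnorm(3 * 30), ncol = 3)
    expect_equal(hausdorff(A, B), oracle_hausdorff(A, B), tolerance = 1e-7)
    expect_equal(hausdorff(A, B), hausdorff(B, A))
  }
  # dense samples of unit spheres with centres 1 apart are ~1 apart
  u1 <- ellipsoid_surface(c(1, 1, 1), n_points = 3000)
  u2 <- sweep(u1, 2, c(1, 0, 0), `+`)
  expect_equal(hausdorff(u1, u2), 1, tolerance = 0.05)
  expect_error(hausdorff(A[0, , drop = FALSE], B), "non-empty")
})

test_that("reconstruction error is non-increasing in the fitted order", {
  # voxelized ellipsoid surface (boundary-voxel centres) at 0.25 um
  shp <- c(38, 38, 38); vs <- rep(0.25, 3)
  ctr <- (shp - 1) / 2 * vs
  m <- orgeval:::ellipsoid_mask(shp, vs, ctr, c(4, 3, 2), diag(3))
  s <- orgeval:::voxel_coords_um(orgeval:::boundary_voxels(m), vs)
  h <- vapply(c(1, 3, 7, 15), function(L) {
    d <- fit_spharm(s, L = L)
    hausdorff(s, reconstruct(d, 64))
  }, numeric(1))
  # non-increasing up to a sliver (1% of a voxel edge) of discretization jitter
  expect_true(all(diff(h) <= 0.01 * 0.25))
  # an eccentric ellipsoid is fitted far better at high order than order 0
  e <- ellipsoid_surface(c(4, 2, 1), diag(3), n_points = 500)
  h0 <- hausdorff(e, reconstruct(fit_spharm(e, L = 0, normalize = "radial"), 32))
  h8 <- hausdorff(e, reconstruct(fit_spharm(e, L = 8, normalize = "radial"), 32))
  expect_gt(h0, h8)
})

test_that("spharm_qc passes synthetic ellipsoidal organelles and handles edge cases", {
  cfg <- simulate_config(
    image_shape = c(56, 80, 80), voxel_size = c(0.25, 0.25, 0.25),
    cell_axes_um = c(5, 7, 8),
    organelles = list(org1 = list(lambda = 6, mean_axes = c(1.0, 0.8, 0.7),
                                  axis_sd = 0.1, elongation = 1.2,
                                  elongation_shift = 0, radial_beta = c(2, 2)))
  )
  sim <- simulate_cell(cfg, seed = 61, render = FALSE)
  obj <- extract_objects(label_mask(sim$record$organelle_masks$org1,
                                    sim$record$voxel_size))
  qc <- spharm_qc(obj, L = 31, voxel_size = sim$record$voxel_size)
  expect_identical(nrow(qc), nrow(obj))
  expect_true(all(qc$pass))
  expect_true(all(qc$l_used <= 31))
  expect_identical(nrow(spharm_qc(list(), L = 31)), 0L)
})

test_that("descriptor tidiers report the coefficient layout", {
  d <- fit_spharm(ellipsoid_surface(c(3, 2, 2), diag(3), n_points = 300), L = 4)
  td <- tidy(d)
  expect_identical(nrow(td), 3L * 25L)
  expect_identical(sort(unique(td$l)), 0:4)
  gl <- glance(d)
  expect_gt(gl$energy_degree1, 0.99)
})
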