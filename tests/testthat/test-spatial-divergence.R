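# helper: build a cell_record with an axis-aligned ellipsoidal cell/nucleus
make_ellipsoid_record <- function(axes = c(5, 8, 10), scale = 0.4,
                                  shape = c(28, 40, 48), vs = 0.5,
                                  rotate_about_z = 0) {
  ctr <- (shape - 1) / 2 * vs
  R <- orgeval:::rot_about_z(rotate_about_z)
  cell <- orgeval:::ellipsoid_mask(shape, rep(vs, 3), ctr, axes, R)
  nuc <- orgeval:::ellipsoid_mask(shape, rep(vs, 3), ctr, axes * scale, R)
  list(record = cell_record(cell, nuc, voxel_size = vs), center = ctr, R = R)
}

test_that("align_cell recovers an applied in-plane rotation", {
  base <- make_ellipsoid_record(axes = c(3, 5, 9))
  R0 <- align_cell(base$record)
  # major axis (x, third coordinate) maps to the first aligned coordinate
  expect_equal(abs(R0[1, ]), c(0, 0, 1), tolerance = 0.05)

  rot <- make_ellipsoid_record(axes = c(3, 5, 9), rotate_about_z = pi / 2)
  R1 <- align_cell(rot$record)
  # after a 90-degree turn the major axis lies along y (second coordinate)
  expect_equal(abs(R1[1, ]), c(0, 1, 0), tolerance = 0.05)
  ang <- acos(min(1, abs(sum(R1[1, ] * c(0, 1, 0)))))
  expect_lt(ang * 180 / pi, 2)

  sph <- make_ellipsoid_record(axes = c(6, 6, 6))
  expect_warning(Rs <- align_cell(sph$record), "spherical")
  expect_identical(Rs, diag(3))
})

test_that("normalized radius hits its endpoints and midpoints", {
  er <- make_ellipsoid_record(axes = c(5, 8, 10))
  rec <- er$record; ctr <- er$center
  nuc_ctr <- colMeans(orgeval:::voxel_coords_um(
    orgeval:::mask_indices(rec$nuclear_mask), rec$voxel_size))

  p0 <- normalize_position(nuc_ctr, rec)
  expect_equal(p0$r, 0)

  # along +x: boundary at ctr + (0,0,10); midpoint of the ray at r ~ 0.5
  pb <- normalize_position(ctr + c(0, 0, 9.7), rec)
  expect_gt(pb$r, 0.93)
  pm <- normalize_position(ctr + c(0, 0, 5), rec)
  expect_equal(pm$r, 0.5, tolerance = 0.05)
  # angles in the aligned frame: +x direction is the major axis
  rot <- align_cell(rec)
  pm2 <- normalize_position(ctr + c(0, 0, 5), rec, rot)
  expect_equal(pm2$theta, 0, tolerance = 0.05)

  expect_error(normalize_position(ctr + c(0, 0, 30), rec), "outside")
})

test_that("normalized positions are invariant to rigid motion of the record", {
  er <- make_ellipsoid_record(axes = c(4, 6, 8), shape = c(40, 40, 40))
  rec1 <- er$record
  target <- er$center + c(2, 3, 4)
  p1 <- normalize_position(target, rec1)

  # translate the whole record by whole voxels
  sh <- c(3L, -2L, 4L)
  shift_arr <- function(a, sh) {
    d <- dim(a); out <- array(if (is.logical(a)) FALSE else 0L, d)
    src <- list(seq_len(d[1]) - sh[1], seq_len(d[2]) - sh[2], seq_len(d[3]) - sh[3])
    ok <- lapply(seq_len(3), function(i) src[[i]] >= 1 & src[[i]] <= d[i])
    out[ok[[1]], ok[[2]], ok[[3]]] <-
      a[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
    out
  }
  rec2 <- cell_record(shift_arr(rec1$cell_mask, sh), shift_arr(rec1$nuclear_mask, sh),
                      voxel_size = rec1$voxel_size)
  p2 <- normalize_position(target + sh * 0.5, rec2)
  expect_equal(p2$r, p1$r, tolerance = 1e-6)
  expect_equal(p2$theta, p1$theta, tolerance = 1e-6)

  # rotation of the record (90 degrees in-plane): the radius is unchanged
  er3 <- make_ellipsoid_record(axes = c(4, 6, 8), shape = c(40, 40, 40),
                               rotate_about_z = pi / 2)
  target3 <- er3$center + as.numeric(er3$R %*% c(2, 3, 4))
  p3 <- normalize_position(target3, er3$record)
  expect_equal(p3$r, p1$r, tolerance = 0.02)
})

test_that("kernel densities integrate to one over the ball", {
  set.seed(23)
  pos <- tibble::tibble(bx = 0, by = 0, bz = 0)
  den <- fit_density(pos, bandwidth = 0.15, grid_size = 24)
  expect_equal(sum(den$values) * den$vol_element, 1, tolerance = 1e-3)
  # single point at the origin: density maximal at the innermost node
  expect_lt(max(sqrt(rowSums(den$coords[which.max(den$values), , drop = FALSE]^2))),
            0.1)
  many <- matrix(runif(300, -0.5, 0.5), ncol = 3)
  den2 <- fit_density(many, bandwidth = 0.2, grid_size = 24)
  expect_equal(sum(den2$values) * den2$vol_element, 1, tolerance = 1e-3)
  expect_error(fit_density(many[0, ]), "at least one")
})

test_that("spatial KL matches the hand-computed two-cell example", {
  two_cell <- function(p) {
    structure(list(values = p / 0.5, coords = matrix(0, 2, 3), grid_size = 2L,
                   bandwidth = 0.15, vol_element = 0.5, n_points = 2L),
              class = "spatial_density")
  }
  P <- two_cell(c(0.8, 0.2)); Q <- two_cell(c(0.5, 0.5))
  expect_equal(spatial_kl(P, Q), 0.8 * log(1.6) + 0.2 * log(0.4), tolerance = 1e-12)
  expect_equal(spatial_kl(P, Q), 0.1927, tolerance = 1e-3)
  expect_equal(spatial_kl(Q, P), 0.2231, tolerance = 1e-3)
  expect_equal(spatial_kl(P, P), 0)
  expect_gte(spatial_kl(Q, P), 0)
  expect_error(spatial_kl(P, two_cell(c(0.5, 0.5))[c(1, 2)]), "spatial_density")
})

test_that("same-generator samples have smaller KL than different generators", {
  set.seed(24)
  draw <- function(n, spread) matrix(rnorm(n * 3, 0, spread), ncol = 3) * 0.4
  A1 <- fit_density(draw(150, 0.5), grid_size = 20)
  A2 <- fit_density(draw(150, 0.5), grid_size = 20)
  B <- fit_density(sweep(draw(150, 0.5), 2, c(0.4, 0, 0), `+`), grid_size = 20)
  expect_lt(spatial_kl(A1, A2), spatial_kl(A1, B))
})
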