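#' Configuration for the synthetic 3D cell generator
#'
#' Describes one study condition: an ellipsoidal cell with a concentric
#' scaled nucleus, per-channel organelle populations (ellipsoidal
#' instances with controlled size, elongation and radial placement), and a
#' rendering model (Gaussian PSF blur, background, additive noise). The
#' elongation shift `delta` multiplies the major/minor axis ratio and is
#' the single contrast knob used for shape-sensitivity studies; `delta = 0`
#' leaves the population at its base shape distribution. Radial placement
#' draws a Beta(a, b) shell fraction between the nuclear surface and the
#' cell boundary along a uniform random direction, so the configured Beta
#' is exactly the distribution the bookkeeping records.
#'
#' @param image_shape `(z, y, x)` voxel counts.
#' @param voxel_size um per voxel, `(dz, dy, dx)`.
#' @param cell_axes_um Cell semi-axes `(z, y, x)`, um.
#' @param cell_axis_jitter SD of the per-cell Gaussian jitter on each
#'   semi-axis, um.
#' @param nucleus_scale Nucleus semi-axes as a fraction of the cell's.
#' @param organelles Named list; each element a list with `lambda` (Poisson
#'   mean instance count), `mean_axes` (semi-axes um, major first),
#'   `axis_sd` (SD of axis jitter), `elongation` (base major-axis
#'   multiplier), `elongation_shift` (delta), `radial_beta` (`c(a, b)`).
#' @param psf_sd Gaussian PSF standard deviation, um.
#' @param background Constant background intensity (0-1 scale).
#' @param noise_sd SD of additive Gaussian noise.
#' @param min_gap_vox Minimum voxel separation enforced between organelle
#'   instances (keeps instances resolvable after PSF blur).
#' @return A `synthetic_config` list.
#' @export
simulate_config <- function(image_shape = c(32, 48, 48),
                            voxel_size = c(0.5, 0.5, 0.5),
                            cell_axes_um = c(6, 9, 11),
                            cell_axis_jitter = 0.3,
                            nucleus_scale = 0.45,
                            organelles = default_organelles(),
                            psf_sd = 0.4,
                            background = 0.05,
                            noise_sd = 0.02,
                            min_gap_vox = 2L) {
  stopifnot(length(image_shape) == 3L, all(image_shape >= 8),
            nucleus_scale > 0, nucleus_scale < 1,
            cell_axis_jitter >= 0, psf_sd >= 0, noise_sd >= 0)
  for (org in organelles) {
    stopifnot(org$lambda >= 0, all(org$mean_axes > 0), org$axis_sd >= 0,
              all(org$radial_beta > 0))
  }
  structure(
    list(image_shape = as.integer(image_shape),
         voxel_size = check_voxel_size(voxel_size),
         cell_axes_um = as.numeric(cell_axes_um),
         cell_axis_jitter = cell_axis_jitter,
         nucleus_scale = nucleus_scale,
         organelles = organelles,
         psf_sd = psf_sd, background = background, noise_sd = noise_sd,
         min_gap_vox = as.integer(min_gap_vox)),
    class = "synthetic_config"
  )
}

default_organelles <- function() {
  list(
    orgA = list(lambda = 8, mean_axes = c(1.3, 0.95, 0.85), axis_sd = 0.12,
                elongation = 1.2, elongation_shift = 0, radial_beta = c(2, 2)),
    orgB = list(lambda = 6, mean_axes = c(1.3, 0.9, 0.8), axis_sd = 0.12,
                elongation = 1.5, elongation_shift = 0, radial_beta = c(2, 5)),
    orgC = list(lambda = 6, mean_axes = c(1.2, 0.9, 0.8), axis_sd = 0.1,
                elongation = 1.1, elongation_shift = 0, radial_beta = c(5, 2))
  )
}

# rotation about the z axis (first coordinate), mixing (y, x)
rot_about_z <- function(angle) {
  ca <- cos(angle); sa <- sin(angle)
  matrix(c(1, 0, 0,
           0, ca, -sa,
           0, sa, ca), 3, 3, byrow = TRUE)
}

# uniform random 3D rotation (QR of a Gaussian matrix, det fixed to +1)
random_rotation <- function() {
  qd <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qd)
  Q <- Q %*% diag(sign(diag(qr.R(qd))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

# ellipsoid radius along unit direction u for axes a and rotation R
ellipsoid_radius <- function(u, axes, R) {
  v <- as.numeric(t(R) %*% u)
  1 / sqrt(sum((v / axes)^2))
}

# voxelize an ellipsoid into an existing-size array; returns logical array
ellipsoid_mask <- function(image_shape, voxel_size, center_um, axes, R) {
  lo <- pmax(floor((center_um - max(axes)) / voxel_size) + 1, 1)
  hi <- pmin(ceiling((center_um + max(axes)) / voxel_size) + 1, image_shape)
  out <- array(FALSE, image_shape)
  if (any(lo > hi)) return(out)
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  g <- as.matrix(expand.grid(z = zi, y = yi, x = xi))
  p <- sweep(voxel_coords_um(g, voxel_size), 2, center_um)
  q <- p %*% R             # rows: t(R) %*% p
  inside <- rowSums(sweep(q, 2, axes, `/`)^2) <= 1
  out[g[inside, , drop = FALSE]] <- TRUE
  out
}

# 26-neighbourhood binary dilation (repeated `times` times), computed on
# the foreground bounding box only
dilate26 <- function(mask, times = 1L) {
  if (times < 1L || !any(mask)) return(mask)
  d <- dim(mask)
  idx <- mask_indices(mask)
  lo <- pmax(apply(idx, 2, min) - times, 1)
  hi <- pmin(apply(idx, 2, max) + times, d)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  ds <- dim(sub)
  for (t in seq_len(times)) {
    pad <- array(FALSE, ds + 2L)
    pad[2:(ds[1] + 1), 2:(ds[2] + 1), 2:(ds[3] + 1)] <- sub
    acc <- array(FALSE, ds)
    for (dz in 0:2) for (dy in 0:2) for (dx in 0:2) {
      acc <- acc | pad[dz + 1:ds[1], dy + 1:ds[2], dx + 1:ds[3]]
    }
    sub <- acc
  }
  out <- mask
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
  out
}

# separable Gaussian blur with renormalized (mass-preserving) edges
gauss_blur3d <- function(arr, sd_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sd_vox[ax]
    if (s <= 0) next
    n <- d[ax]
    K <- exp(-outer(seq_len(n), seq_len(n), `-`)^2 / (2 * s^2))
    K <- K / rowSums(K)
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    a2 <- aperm(arr, perm)
    m <- matrix(a2, n)
    a2 <- array(K %*% m, dim(a2))
    arr <- aperm(a2, order(perm))
  }
  arr
}

#' Simulate one synthetic cell and its rendered intensity channels
#'
#' Builds an ellipsoidal cell mask (jittered semi-axes, random in-plane
#' orientation — adherent cells are flat, so only the about-z angle is
#' randomized), a concentric scaled nucleus, and per-channel organelle
#' instances: randomly oriented ellipsoids placed at Beta-distributed shell
#' fractions between nucleus and membrane, rejection-sampled to stay inside
#' the cell, outside the nucleus and disjoint from all other instances.
#' Intensity channels are the instance masks blurred with a Gaussian PSF,
#' rescaled to unit peak, plus constant background and Gaussian noise
#' (clipped to `[0, 1]`).
#'
#' Identical `config` and `seed` give bit-identical output; the caller's
#' RNG state is untouched.
#'
#' @param config A [simulate_config()].
#' @param seed Integer seed.
#' @param cell_id Identifier stamped on the record and bookkeeping rows.
#' @param render Render intensity channels (default `TRUE`); `FALSE` skips
#'   the PSF/noise stage (masks and bookkeeping only), which is cheaper for
#'   purely geometric studies and does not change the mask RNG stream.
#' @return A list: `record` ([cell_record()]), `truth`
#'   ([multichannel_image()], `NULL` when `render = FALSE`), and `objects`,
#'   a ground-truth tibble with one row per placed instance (`organelle`,
#'   `instance`, true `axes`, `rotation`, Beta draw `s_shell`, realized
#'   fractional radius `r_true`, `centroid` um).
#' @export
simulate_cell <- function(config, seed = 1L, cell_id = 1L, render = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(seed, {
    shp <- config$image_shape; vs <- config$voxel_size
    center <- (shp - 1) / 2 * vs
    cell_axes <- pmax(config$cell_axes_um + rnorm(3, 0, config$cell_axis_jitter), 1)
    Rcell <- rot_about_z(runif(1, 0, 2 * pi))
    cell <- ellipsoid_mask(shp, vs, center, cell_axes, Rcell)
    nucleus <- ellipsoid_mask(shp, vs, center, cell_axes * config$nucleus_scale, Rcell)

    occupied <- array(FALSE, shp)
    org_masks <- list()
    book <- list()
    for (cn in names(config$organelles)) {
      org <- config$organelles[[cn]]
      n_inst <- rpois(1, org$lambda)
      labels <- array(0L, shp)
      placed <- 0L
      while (placed < n_inst) {
        rejections <- 0L
        repeat {
          if (rejections >= 1000L) {
            abort(sprintf(
              "could not place %s instance %d after 1000 rejections; use smaller organelle sizes.",
              cn, placed + 1L))
          }
          axes <- pmax(org$mean_axes + rnorm(3, 0, org$axis_sd), 0.3)
          # volume-preserving elongation: the major/minor ratio is multiplied
          # by elongation * (1 + delta) while the volume stays fixed
          ratio <- org$elongation * (1 + (org$elongation_shift %||% 0))
          axes <- axes * c(ratio^(2 / 3), ratio^(-1 / 3), ratio^(-1 / 3))
          Rorg <- random_rotation()
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          R_cell_dir <- ellipsoid_radius(u, cell_axes, Rcell)
          r_nuc_dir <- ellipsoid_radius(u, cell_axes * config$nucleus_scale, Rcell)
          margin <- ellipsoid_radius(u, axes, Rorg)   # extent along the ray
          lo <- r_nuc_dir + margin; hi <- R_cell_dir - margin
          s <- rbeta(1, org$radial_beta[1], org$radial_beta[2])
          if (hi <= lo) { rejections <- rejections + 1L; next }
          rho <- lo + s * (hi - lo)
          cen <- center + rho * u
          m <- ellipsoid_mask(shp, vs, cen, axes, Rorg)
          nvox <- sum(m)
          if (nvox < 4L || any(m & !cell) || any(m & nucleus) || any(m & occupied)) {
            rejections <- rejections + 1L
            next
          }
          placed <- placed + 1L
          labels[m] <- placed
          occupied <- occupied | dilate26(m, config$min_gap_vox)
          book[[length(book) + 1L]] <- tibble::tibble(
            cell_id = cell_id, organelle = cn, instance = placed,
            axes = list(axes), rotation = list(Rorg),
            s_shell = s, rho_um = rho, r_true = rho / R_cell_dir,
            centroid = list(cen), n_voxels = nvox
          )
          break
        }
      }
      org_masks[[cn]] <- labels
    }

    truth <- NULL
    if (render) {
      channels <- array(0, c(length(org_masks), shp))
      for (j in seq_along(org_masks)) {
        ch <- gauss_blur3d(array(as.numeric(org_masks[[j]] > 0), shp),
                           rep(config$psf_sd, 3) / vs)
        if (max(ch) > 0) ch <- ch / max(ch)
        ch <- ch + config$background
        if (config$noise_sd > 0) ch <- ch + rnorm(length(ch), 0, config$noise_sd)
        channels[j, , , ] <- pmin(pmax(ch, 0), 1)
      }
      truth <- multichannel_image(channels, names(org_masks), voxel_size = vs)
    }

    list(
      record = cell_record(cell, nucleus, org_masks, voxel_size = vs,
                           cell_id = cell_id),
      truth = truth,
      objects = if (length(book)) dplyr::bind_rows(book) else tibble::tibble()
    )
  })
}

#' Simulate an independent population of synthetic cells
#'
#' Cells are generated with per-cell seeds derived deterministically from
#' `seed`; the pooled bookkeeping table carries every instance's true axes,
#' orientation, shell draw and realized fractional radius, making each
#' downstream metric testable as parameter recovery.
#'
#' @inheritParams simulate_cell
#' @param n_cells Number of cells (`>= 1`).
#' @return A list: `records`, `truths` (parallel lists) and `objects`
#'   (bookkeeping tibble over all cells).
#' @export
simulate_population <- function(config, n_cells, seed = 1L, render = TRUE) {
  stopifnot(n_cells >= 1)
  cell_seeds <- with_seed(seed, sample.int(.Machine$integer.max %/% 2, n_cells))
  cells <- lapply(seq_len(n_cells), function(i) {
    simulate_cell(config, seed = cell_seeds[i], cell_id = i, render = render)
  })
  list(records = lapply(cells, `[[`, "record"),
       truths = lapply(cells, `[[`, "truth"),
       objects = dplyr::bind_rows(lapply(cells, `[[`, "objects")))
}

#' Emulate a model prediction by degrading a ground-truth image
#'
#' Reproduces the two failure modes the exclusivity metrics measure: loss
#' of sharpness (Gaussian blur) and inter-organelle confusion (each channel
#' mixed with the mean of the others). With `blur_sd = 0`,
#' `crosstalk = 0`, `noise_sd = 0` the truth is returned unchanged.
#'
#' @param truth A [multichannel_image()].
#' @param blur_sd Added Gaussian blur SD, um.
#' @param crosstalk Mixing fraction in `[0, 1)`: each output channel is
#'   `(1 - crosstalk) * channel + crosstalk * mean(other channels)`.
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed Seed for the noise.
#' @return A [multichannel_image()] of the same shape.
#' @export
simulate_prediction <- function(truth, blur_sd = 0, crosstalk = 0,
                                noise_sd = 0, seed = NULL) {
  stopifnot(inherits(truth, "mc_image"), blur_sd >= 0,
            crosstalk >= 0, crosstalk < 1)
  d <- dim(truth$data)
  out <- array(0, d)
  blurred <- array(0, d)
  for (j in seq_len(d[1])) {
    ch <- array(truth$data[j, , , ], d[2:4])
    if (blur_sd > 0) ch <- gauss_blur3d(ch, rep(blur_sd, 3) / truth$voxel_size)
    blurred[j, , , ] <- ch
  }
  if (crosstalk > 0 && d[1] > 1L) {
    for (j in seq_len(d[1])) {
      others <- colMeans(blurred[-j, , , , drop = FALSE])
      out[j, , , ] <- (1 - crosstalk) * blurred[j, , , ] + crosstalk * others
    }
  } else {
    out <- blurred
  }
  if (noise_sd > 0) {
    out <- out + with_seed(seed, array(rnorm(length(out), 0, noise_sd), d))
  }
  multichannel_image(out, truth$channel_names, truth$voxel_size)
}

#' Analytic surface samples of a generated ellipsoidal instance
#'
#' Samples the true (un-voxelized) surface of a bookkeeping row's
#' ellipsoid at quasi-uniform directions — the reference surface for
#' SPHARM parameter-recovery studies.
#'
#' @param axes Semi-axes um (major first).
#' @param rotation 3x3 orientation matrix.
#' @param center Centre um (`(z, y, x)`), default origin.
#' @param n_points Number of surface samples.
#' @return `n_points x 3` matrix of um coordinates.
#' @export
ellipsoid_surface <- function(axes, rotation = diag(3), center = c(0, 0, 0),
                              n_points = 240) {
  i <- seq_len(n_points) - 0.5
  z <- 1 - 2 * i / n_points
  rr <- sqrt(pmax(1 - z^2, 0))
  ga <- pi * (1 + sqrt(5)) * i
  u <- cbind(z, rr * cos(ga), rr * sin(ga))
  sweep(u %*% diag(axes) %*% t(rotation), 2, center, `+`)
}
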