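# Independent brute-force oracles used to freeze expected values.
# These deliberately share no code with the package implementation.

# per-pixel sort oracle for all three exclusivity metrics
oracle_exclusivity <- function(data, region = NULL) {
  nc <- dim(data)[1]
  m <- t(matrix(data, nrow = nc))
  if (!is.null(region)) m <- m[as.vector(region != 0), , drop = FALSE]
  n <- nrow(m)
  margins <- numeric(n)
  amax <- integer(n)
  for (i in seq_len(n)) {
    v <- m[i, ]
    s <- sort(v, decreasing = TRUE)
    margins[i] <- s[1] - s[2]
    amax[i] <- which(v == max(v))[1]   # lowest index on ties
  }
  per <- rep(NA_real_, nc)
  pair <- matrix(NA_real_, nc, nc)
  for (o in seq_len(nc)) {
    sel <- amax == o
    if (!any(sel)) next
    per[o] <- mean(margins[sel])
    for (j in seq_len(nc)) {
      if (j != o) pair[o, j] <- mean(m[sel, o] - m[sel, j])
    }
  }
  occ <- tabulate(amax, nc) / n
  list(overall = mean(margins), per_organelle = per, pairwise = pair,
       occupancy = occ)
}

# exhaustive neighbour-enumeration oracle for the k-NN purity score
oracle_purity_score <- function(points, labels, k) {
  points <- as.matrix(points)
  n <- nrow(points)
  m <- sum(labels == 1)
  q <- m / n
  tot <- 0
  for (i in seq_len(n)) {
    d <- sqrt(rowSums((points - matrix(points[i, ], n, ncol(points),
                                       byrow = TRUE))^2))
    cand <- setdiff(seq_len(n), i)
    nn <- cand[order(d[cand], cand)][seq_len(k)]
    p <- mean(labels[nn] == 1)
    t1 <- if (p == 0) 0 else p * log(p / q)
    t2 <- if (p == 1) 0 else (1 - p) * log((1 - p) / (1 - q))
    tot <- tot + t1 + t2
  }
  tot / n
}

# naive double-loop Hausdorff for small sets
oracle_hausdorff <- function(A, B) {
  dmat <- outer(seq_len(nrow(A)), seq_len(nrow(B)), Vectorize(function(i, j) {
    sqrt(sum((A[i, ] - B[j, ])^2))
  }))
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

random_mc_image <- function(nc = 4, shape = c(8, 16, 16), seed = 1) {
  set.seed(seed)
  multichannel_image(array(runif(nc * prod(shape)), c(nc, shape)),
                     voxel_size = c(0.5, 0.5, 0.5))
}

# the worked 3-channel, 2-pixel example used across the exclusivity tests
example_image <- function() {
  multichannel_image(array(c(0.9, 0.5, 0.1, 0.2, 0.7, 0.6), c(3, 1, 1, 2)))
}

# small synthetic config for fast generator tests
small_config <- function(...) {
  simulate_config(
    image_shape = c(28, 40, 40),
    cell_axes_um = c(5, 7, 8),
    organelles = list(
      org1 = list(lambda = 5, mean_axes = c(1.0, 0.8, 0.7), axis_sd = 0.1,
                  elongation = 1.2, elongation_shift = 0, radial_beta = c(2, 2))
    ),
    ...
  )
}

# organelle set with a shared elongation shift / radial profile
shifted_organelles <- function(delta = 0, beta = NULL) {
  orgs <- orgeval:::default_organelles()
  lapply(orgs, function(o) {
    o$elongation_shift <- delta
    if (!is.null(beta)) o$radial_beta <- beta
    o
  })
}

# pooled SPHARM coefficient matrix for a generated population, fitted on
# analytic surface samples of the bookkeeping ellipsoids
population_shape_matrix <- function(delta, seed, n_cells = 4, L = 8,
                                    n_points = 160) {
  cfg <- simulate_config(organelles = shifted_organelles(delta))
  pop <- simulate_population(cfg, n_cells, seed = seed, render = FALSE)
  descs <- purrr::map2(pop$objects$axes, pop$objects$rotation, function(a, R) {
    fit_spharm(ellipsoid_surface(a, R, c(0, 0, 0), n_points = n_points), L = L)
  })
  spharm_matrix(descs, L = L)
}

# normalized positions of every generated object in a population
population_positions <- function(config, n_cells, seed) {
  pop <- simulate_population(config, n_cells, seed = seed, render = FALSE)
  out <- lapply(seq_along(pop$records), function(i) {
    rec <- pop$records[[i]]
    rot <- suppressWarnings(align_cell(rec))
    obj <- pop$objects[pop$objects$cell_id == i, ]
    dplyr::bind_rows(lapply(obj$centroid, normalize_position,
                            record = rec, rotation = rot))
  })
  list(positions = dplyr::bind_rows(out), objects = pop$objects)
}
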