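#' Embed two object populations in a common PCA shape space
#'
#' Principal component analysis is fitted on the pooled coefficient matrix
#' of both populations (so both are reduced in the same basis) and each
#' object is projected on the first `n_components` components (default 3).
#' A deterministic sign convention is applied: within each component the
#' loading of largest magnitude is made positive.
#'
#' @param x Numeric descriptor matrix (objects x features), e.g. from
#'   [spharm_matrix()]; rows of both populations stacked.
#' @param labels Integer/factor vector with exactly two values; coded so
#'   population 1 is the first value encountered (conventionally the
#'   synthetic set) and population 2 the second (the real set).
#' @param n_components Number of retained components.
#' @param fit_on `"pooled"` (default) fits the PCA on all objects;
#'   `"population2"` fits on the second population only and projects both.
#' @return An object of class `shape_embedding`: `points`
#'   (`(m+n) x n_components`), `labels` (1/2), `m`, `n`,
#'   `explained_variance` (fractions) and `loadings`.
#' @export
pca_embed <- function(x, labels, n_components = 3, fit_on = c("pooled", "population2")) {
  fit_on <- match.arg(fit_on)
  x <- as.matrix(x)
  lab <- normalize_labels(labels)
  if (nrow(x) != length(lab)) abort("`labels` must have one entry per row of `x`.")
  if (nrow(x) < n_components + 1) abort("need more objects than components.")
  fit_rows <- if (fit_on == "pooled") seq_len(nrow(x)) else which(lab == 2L)
  pc <- prcomp(x[fit_rows, , drop = FALSE], center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(k)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  }
  pts <- sweep(x, 2, pc$center) %*% rot
  ev <- pc$sdev^2
  shape_embedding(pts, lab,
                  explained_variance = ev[seq_len(k)] / sum(ev),
                  loadings = rot)
}

normalize_labels <- function(labels) {
  u <- unique(labels)
  if (length(u) != 2L) abort("`labels` must take exactly two values.")
  as.integer(ifelse(labels == u[1], 1L, 2L))
}

#' Construct a shape embedding directly from coordinates
#'
#' @param points `(m+n) x d` coordinate matrix.
#' @param labels Two-valued population labels (recoded to 1/2 in order of
#'   first appearance).
#' @param explained_variance,loadings Optional PCA metadata.
#' @return A `shape_embedding` object.
#' @export
shape_embedding <- function(points, labels, explained_variance = NULL, loadings = NULL) {
  points <- as.matrix(points)
  lab <- normalize_labels(labels)
  if (nrow(points) != length(lab)) abort("`labels` must have one entry per point.")
  m <- sum(lab == 1L); n <- sum(lab == 2L)
  if (m < 1L || n < 1L) abort("both populations must be non-empty.")
  structure(list(points = points, labels = lab, m = m, n = n,
                 explained_variance = explained_variance, loadings = loadings),
            class = "shape_embedding")
}

#' @export
print.shape_embedding <- function(x, ...) {
  cat(sprintf("<shape_embedding> %d + %d points in %d dimension(s)\n",
              x$m, x$n, ncol(x$points)))
  if (!is.null(x$explained_variance)) {
    cat("explained variance:", paste(signif(x$explained_variance, 3), collapse = ", "), "\n")
  }
  invisible(x)
}

# k-nearest-neighbour index matrix (self excluded, ties by point index)
knn_index_matrix <- function(points, k) {
  n <- nrow(points)
  if (k < 1 || k > n - 1) abort(sprintf("k must be in [1, %d].", n - 1))
  D <- as.matrix(dist(points))
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(D[i, -i], seq_len(n)[-i])[seq_len(k)]
    idx[i, ] <- seq_len(n)[-i][ord]
  }
  idx
}

purity_score_from_p <- function(p_i, q) {
  term <- function(p, qq) ifelse(p == 0, 0, p * log(p / qq))
  mean(term(p_i, q) + term(1 - p_i, 1 - q))
}

#' k-NN purity divergence between two embedded populations
#'
#' For each object in the pooled embedding, the purity `p_i` is the fraction
#' of its `k` nearest neighbours (Euclidean, self excluded, distance ties
#' broken by point index) that belong to population 1. The score is the
#' average KL divergence, in nats, of the Bernoulli(`p_i`) neighbourhood
#' composition from the reference mixing fraction `q = m/(m+n)`:
#' `mean( p_i log(p_i/q) + (1-p_i) log((1-p_i)/(1-q)) )` with the
#' `0 log 0 = 0` convention. Zero iff every neighbourhood is as mixed as
#' the pooled sample; large when the populations separate.
#'
#' @param emb A [shape_embedding()].
#' @param k Neighbourhood size, `1 <= k <= m+n-1`.
#' @return Scalar score (nats), `>= 0`.
#' @export
knn_purity_score <- function(emb, k) {
  stopifnot(inherits(emb, "shape_embedding"))
  idx <- knn_index_matrix(emb$points, k)
  is1 <- emb$labels == 1L
  p_i <- rowMeans(matrix(is1[idx], nrow = nrow(idx)))
  purity_score_from_p(p_i, emb$m / (emb$m + emb$n))
}

#' Purity divergence over a ladder of neighbourhood sizes
#'
#' Small `k` is sensitive to local sampling noise (scores biased upward);
#' very large `k` spans both populations and washes sensitivity out. The
#' default ladder brackets `k = 8`, the reference value for shape
#' comparisons.
#'
#' @inheritParams knn_purity_score
#' @param ks Neighbourhood sizes to evaluate.
#' @param n_permutations If `> 0`, a permutation p-value is computed per k.
#' @param seed Seed for the permutations.
#' @return An object of class `divergence_result`; see
#'   [tidy.divergence_result()].
#' @export
k_sweep <- function(emb, ks = c(2, 4, 8, 16, 32), n_permutations = 0, seed = NULL) {
  stopifnot(inherits(emb, "shape_embedding"))
  ks <- as.integer(ks)
  scores <- vapply(ks, function(k) knn_purity_score(emb, k), numeric(1))
  p_values <- rep(NA_real_, length(ks))
  if (n_permutations > 0) {
    for (i in seq_along(ks)) {
      p_values[i] <- permutation_test(emb, ks[i], n_permutations = n_permutations,
                                      seed = seed)$p_value
    }
  }
  structure(
    list(score_by_k = tibble::tibble(k = ks, score = scores, p_value = p_values),
         q = emb$m / (emb$m + emb$n), m = emb$m, n = emb$n,
         n_permutations = n_permutations, seed = seed),
    class = "divergence_result"
  )
}

#' @export
print.divergence_result <- function(x, ...) {
  cat(sprintf("<divergence_result> m = %d, n = %d (q = %.3f)\n", x$m, x$n, x$q))
  print(x$score_by_k)
  invisible(x)
}

#' Permutation test for the purity divergence
#'
#' Population labels are randomly permuted (sizes preserved)
#' `n_permutations` times and the score recomputed; neighbour indices are
#' fixed by geometry, so only purities are recomputed per permutation. The
#' p-value uses the add-one estimator
#' `p = (1 + #[permuted >= observed]) / (n_permutations + 1)`, which is
#' never exactly zero at finite permutations.
#'
#' @inheritParams knn_purity_score
#' @param n_permutations At least 19.
#' @param seed Integer seed; fixed seed gives an identical p-value.
#' @return A list: `p_value`, `observed`, `permuted` (scores), `k`,
#'   `n_permutations`, `seed`.
#' @export
permutation_test <- function(emb, k, n_permutations = 199, seed = NULL) {
  stopifnot(inherits(emb, "shape_embedding"))
  if (n_permutations < 19) abort("use at least 19 permutations.")
  idx <- knn_index_matrix(emb$points, k)
  q <- emb$m / (emb$m + emb$n)
  score_for <- function(lab) {
    p_i <- rowMeans(matrix(lab[idx] == 1L, nrow = nrow(idx)))
    purity_score_from_p(p_i, q)
  }
  observed <- score_for(emb$labels)
  permuted <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) score_for(sample(emb$labels)), numeric(1))
  })
  list(p_value = (1 + sum(permuted >= observed)) / (n_permutations + 1),
       observed = observed, permuted = permuted, k = k,
       n_permutations = n_permutations, seed = seed)
}

#' Linear regression of object shape on cell position
#'
#' Ordinary least squares of each object's first shape principal component
#' on its three position coordinates; the coefficient of determination
#' measures how much organelle shape is explained by where the organelle
#' sits in the cell. A constant response yields `R^2 = 0` by definition.
#'
#' @param positions `n x 3` matrix of per-object (normalized) positions.
#' @param pc1 Numeric vector: first principal component of the shape
#'   descriptors, one per object.
#' @return Scalar `R^2` in `[0, 1]`.
#' @export
shape_position_regression <- function(positions, pc1) {
  positions <- as.matrix(positions)
  if (nrow(positions) != length(pc1)) abort("`positions` and `pc1` must align.")
  if (nrow(positions) < 5L) abort("need at least 5 objects.")
  if (isTRUE(all.equal(var(pc1), 0)) || var(pc1) == 0) return(0)
  fit <- lm(pc1 ~ positions)
  summary(fit)$r.squared
}
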