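test_that("pooled PCA embedding has the documented properties", {
  set.seed(12)
  # data in an exact 3-D affine subspace: 3 components explain everything
  basis <- matrix(rnorm(30), 10, 3)
  x <- matrix(rnorm(60 * 3), 60, 3) %*% t(basis)
  emb <- pca_embed(x, rep(c(1, 2), 30), n_components = 3)
  expect_gt(sum(emb$explained_variance), 1 - 1e-10)
  # determinism incl. the sign convention
  emb2 <- pca_embed(x, rep(c(1, 2), 30), n_components = 3)
  expect_identical(emb$points, emb2$points)
  # isotropic cloud: roughly equal variance fractions
  y <- matrix(rnorm(3000 * 3), ncol = 3)
  embi <- pca_embed(y, rep(c(1, 2), 1500))
  expect_lt(diff(range(embi$explained_variance)), 0.05)
  expect_error(pca_embed(x[1:3, ], c(1, 2, 1), n_components = 3), "more objects")
  expect_error(shape_embedding(x, rep(1, 60)), "two values")
})

test_that("purity score is exact on symmetric and separated configurations", {
  ang <- (0:7) * 2 * pi / 8
  oct <- cbind(cos(ang), sin(ang))
  # pairwise-alternating labels: each vertex has one neighbour per population,
  # so every purity equals the reference purity and the score vanishes
  expect_equal(knn_purity_score(shape_embedding(oct, c(1, 1, 2, 2, 1, 1, 2, 2)), 2),
               0, tolerance = 1e-14)
  # strictly alternating labels: both neighbours are the opposite population
  expect_equal(knn_purity_score(shape_embedding(oct, rep(c(1, 2), 4)), 2),
               log(2), tolerance = 1e-14)
  # fully separated equal clusters: every purity is 0 or 1
  set.seed(13)
  for (sz in c(10, 25)) {
    pts <- rbind(matrix(rnorm(sz * 3), sz), matrix(rnorm(sz * 3, 100), sz))
    emb <- shape_embedding(pts, rep(c(1, 2), each = sz))
    for (k in c(2, sz - 1)) {
      expect_equal(knn_purity_score(emb, k), log(2), tolerance = 1e-12)
      expect_equal(knn_purity_score(emb, k),
                   oracle_purity_score(pts, rep(c(1, 2), each = sz), k),
                   tolerance = 1e-12)
    }
  }
})

test_that("purity score matches the exhaustive oracle on all small configurations", {
  set.seed(14)
  for (trial in 1:40) {
    n_tot <- sample(4:12, 1)
    d <- sample(1:3, 1)
    pts <- matrix(rnorm(n_tot * d), n_tot, d)
    m <- sample(seq_len(n_tot - 1), 1)
    labels <- sample(rep(c(1, 2), c(m, n_tot - m)))
    emb <- shape_embedding(pts, labels)
    # recoding: shape_embedding calls the first-seen value population 1
    lab1 <- labels == labels[1]
    for (k in unique(pmin(c(1, 3, n_tot - 1), n_tot - 1))) {
      expect_equal(knn_purity_score(emb, k),
                   oracle_purity_score(pts, ifelse(lab1, 1, 2), k),
                   tolerance = 1e-12)
    }
  }
})

test_that("six specified 1-D points match the hand-enumerated oracle", {
  pts <- matrix(c(0, 1, 2.5, 3, 7, 7.5), ncol = 1)
  labels <- c(1, 1, 2, 1, 2, 2)
  emb <- shape_embedding(pts, labels)
  expect_equal(knn_purity_score(emb, 3), oracle_purity_score(pts, labels, 3),
               tolerance = 1e-14)
})

test_that("score is non-negative and symmetric under label exchange", {
  set.seed(15)
  for (trial in 1:10) {
    pts <- matrix(rnorm(30 * 2), 30)
    labels <- sample(rep(c(1, 2), c(12, 18)))
    emb_a <- shape_embedding(pts, labels)
    emb_b <- shape_embedding(pts, 3 - labels)
    # force the same 1/2 coding on the swapped labels
    emb_b$labels <- 3L - emb_a$labels
    emb_b$m <- emb_a$n; emb_b$n <- emb_a$m
    s <- knn_purity_score(emb_a, 5)
    expect_gte(s, 0)
    expect_equal(s, knn_purity_score(emb_b, 5), tolerance = 1e-12)
  }
})

test_that("well-mixed samples score at the finite-k reference floor, far from separation", {
  # At fixed k the null score does not vanish with n: neighbour labels of a
  # well-mixed sample approach independent Bernoulli(q) draws, so the score
  # converges to the Binomial(k, q) KL floor. The discriminating property is
  # that this floor sits far below the fully separated value log(2).
  set.seed(16)
  k <- 8
  term <- function(p, q) {
    ifelse(p == 0, 0, p * log(p / q)) + ifelse(p == 1, 0, (1 - p) * log((1 - p) / (1 - q)))
  }
  floor_k <- sum(stats::dbinom(0:k, k, 0.5) * term((0:k) / k, 0.5))
  for (n in c(50, 200, 800)) {
    med <- stats::median(vapply(1:10, function(b) {
      pts <- matrix(rnorm(2 * n * 3), 2 * n, 3)
      knn_purity_score(shape_embedding(pts, rep(c(1, 2), each = n)), k)
    }, numeric(1)))
    expect_lt(abs(med - floor_k), 0.4 * floor_k)
    expect_lt(med, 0.2 * log(2))
  }
})

test_that("k_sweep records scores per k and keeps the reference k available", {
  set.seed(17)
  pts <- matrix(rnorm(80 * 3), 80)
  emb <- shape_embedding(pts, rep(c(1, 2), each = 40))
  dv <- k_sweep(emb)
  expect_identical(dv$score_by_k$k, c(2L, 4L, 8L, 16L, 32L))
  expect_true(8L %in% dv$score_by_k$k)
  expect_true(all(dv$score_by_k$score >= 0))
  single <- k_sweep(emb, ks = 8)
  expect_identical(nrow(single$score_by_k), 1L)
  expect_error(knn_purity_score(emb, 0), "k must be")
  expect_error(knn_purity_score(emb, 80), "k must be")
  td <- tidy(dv)
  expect_identical(names(td), c("k", "score", "p_value"))
  expect_identical(glance(dv)$m, 40L)
})

test_that("permutation test is reproducible and flags separated clusters", {
  set.seed(18)
  pts <- rbind(matrix(rnorm(30 * 3), 30), matrix(rnorm(30 * 3, 50), 30))
  emb <- shape_embedding(pts, rep(c(1, 2), each = 30))
  r1 <- permutation_test(emb, 8, n_permutations = 199, seed = 17)
  r2 <- permutation_test(emb, 8, n_permutations = 199, seed = 17)
  expect_identical(r1$p_value, r2$p_value)
  expect_equal(r1$p_value, 1 / 200)
  expect_error(permutation_test(emb, 8, n_permutations = 10), "19")
})

test_that("shape-position regression matches its analytic cases", {
  set.seed(19)
  pos <- matrix(runif(500 * 3), 500)
  expect_equal(shape_position_regression(pos, rep(2.5, 500)), 0)
  pc1 <- pos %*% c(1, -2, 0.5) + 3
  expect_equal(suppressWarnings(shape_position_regression(pos, as.vector(pc1))),
               1, tolerance = 1e-12)
  r2 <- shape_position_regression(pos, rnorm(500))
  expect_lt(r2, 0.05)
  expect_error(shape_position_regression(pos[1:3, ], rnorm(3)), "at least 5")
})
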