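test_that("multichannel_signal validates its invariants", {
  expect_error(multichannel_signal(matrix(c(1, NA), 1), fs = 10), "missing")
  expect_error(multichannel_signal(matrix(1:4, 2), fs = -1), "positive")
  sig <- multichannel_signal(matrix(rnorm(20), 2), fs = 10)
  expect_s3_class(sig, "multichannel_signal")
  expect_equal(length(sig$channel_names), 2)
})

test_that("embedding preserves the number of time points and is deterministic", {
  set.seed(1)
  sig <- multichannel_signal(matrix(rnorm(8 * 400), 8), fs = 100)
  for (m in c("pca", "spectral")) {
    tr <- embed_signal(sig, embedding_config(m, n_dims = 3, seed = 7))
    expect_equal(nrow(tr$states), 400)
    expect_equal(ncol(tr$states), 3)
    tr2 <- embed_signal(sig, embedding_config(m, n_dims = 3, seed = 7))
    expect_identical(tr$states, tr2$states)
  }
  expect_error(embed_signal(sig, embedding_config("lle")), "not available")
  lor <- simulate_attractor("lorenz", n = 300, seed = 2)
  tr <- embed_signal(t(lor$states), embedding_config("pca", n_dims = 2))
  expect_equal(nrow(tr$states), 300)
})

test_that("umap embedding runs and is reproducible given its seed", {
  set.seed(3)
  sig <- multichannel_signal(matrix(rnorm(6 * 300), 6), fs = 100)
  cfg <- embedding_config("umap", n_dims = 2, seed = 7)
  a <- embed_signal(sig, cfg)
  b <- embed_signal(sig, cfg)
  expect_equal(dim(a$states), c(300, 2))
  expect_identical(a$states, b$states)
})

test_that("cross-entropy matches hand-computed values and obeys Gibbs' inequality", {
  # p uniform over T = 4, q = (1/2, 1/4, 1/8, 1/8):
  # -sum p log q = (1/4)(1 + 2 + 3 + 3) log 2
  emb <- matrix(1, 4, 1)
  orig <- matrix(c(1 / 2, 1 / 4, 1 / 8, 1 / 8), nrow = 1)
  expect_equal(cross_entropy(orig, emb), 2.25 * log(2), tolerance = 1e-12)

  # p = q: the score is the Shannon entropy of p
  v <- c(0.4, 0.3, 0.2, 0.1)
  h <- -sum(v * log(v))
  expect_equal(cross_entropy(matrix(v, 1), matrix(v, 4, 1)), h,
               tolerance = 1e-12)

  # Gibbs: C(p, q) >= H(p) with equality iff p = q
  set.seed(4)
  for (i in 1:10) {
    p <- runif(6); q <- runif(6)
    hp <- -sum(p / sum(p) * log(p / sum(p)))
    ce <- cross_entropy(matrix(q, 1), matrix(p, 6, 1))
    expect_gte(ce, hp - 1e-12)
  }
  expect_error(cross_entropy(matrix(c(0, 1), 1), matrix(1, 2, 1)),
               "zero-norm")
  expect_error(cross_entropy(matrix(1:4, 1), matrix(1, 3, 1)), "time points")
})

test_that("cross-entropy ranks candidate embeddings like a direct recomputation", {
  set.seed(5)
  orig <- matrix(rnorm(5 * 100), 5)
  emb_a <- matrix(rnorm(100 * 2), 100)
  emb_b <- matrix(rnorm(100 * 2, sd = 3), 100)
  ce <- function(em) {
    p <- sqrt(rowSums(em^2)); q <- sqrt(colSums(orig^2))
    p <- p / sum(p); q <- q / sum(q)
    -sum(p * log(q))
  }
  got <- c(cross_entropy(orig, emb_a), cross_entropy(orig, emb_b))
  want <- c(ce(emb_a), ce(emb_b))
  expect_equal(got, want, tolerance = 1e-12)
  expect_identical(order(got), order(want))
})

test_that("tessellation generators recover separated blob means", {
  set.seed(6)
  blob1 <- matrix(rnorm(100, mean = 0), ncol = 2)
  blob2 <- matrix(rnorm(100, mean = 10), ncol = 2)
  tess <- fit_tessellation(rbind(blob1, blob2), k = 2, seed = 1)
  g <- tess$generators[order(tess$generators[, 1]), ]
  expect_equal(g[1, ], colMeans(blob1), tolerance = 0.5)
  expect_equal(g[2, ], colMeans(blob2), tolerance = 0.5)
  # determinism
  tess2 <- fit_tessellation(rbind(blob1, blob2), k = 2, seed = 1)
  expect_identical(tess$generators, tess2$generators)
})

test_that("k equal to the number of distinct points makes every point a generator", {
  pts <- matrix(c(0, 0, 1, 0, 0, 1, 2, 2), ncol = 2, byrow = TRUE)
  tess <- fit_tessellation(pts, k = 4, seed = 1)
  expect_equal(nrow(tess$generators), 4)
  expect_setequal(apply(tess$generators, 1, paste, collapse = ","),
                  apply(pts, 1, paste, collapse = ","))
  expect_error(fit_tessellation(rbind(pts, pts), k = 5), "distinct")
})

test_that("symbolize agrees with a brute-force nearest-generator loop", {
  set.seed(7)
  pts <- matrix(rnorm(200 * 3), ncol = 3)
  tess <- fit_tessellation(pts, k = 6, seed = 2)
  sym <- symbolize(pts, tess)
  brute <- integer(200)
  for (t in 1:200) {
    d <- apply(tess$generators, 1, function(g) sum((pts[t, ] - g)^2))
    brute[t] <- which.min(d)
  }
  expect_identical(sym$symbols, tess$arrangement[brute])
})

test_that("symbolize respects the tie rule and zero-distance states", {
  tess <- structure(list(generators = rbind(c(0, 0), c(2, 0), c(5, 5)),
                         K = 3L, arrangement = 1:3),
                    class = "tessellation")
  # exactly at generator 3
  expect_equal(symbolize(rbind(c(5, 5)), tess)$symbols, 3L)
  # equidistant between generators 1 and 2 -> lowest raw index wins
  expect_equal(symbolize(rbind(c(1, 0)), tess)$symbols, 1L)
})

test_that("permuting the arrangement permutes symbols but not the time partition", {
  set.seed(8)
  pts <- matrix(rnorm(100 * 2), ncol = 2)
  tess <- fit_tessellation(pts, k = 4, seed = 3)
  s1 <- symbolize(pts, tess)
  perm <- c(3L, 1L, 4L, 2L)
  tess2 <- tess
  tess2$arrangement <- perm
  s2 <- symbolize(pts, tess2)
  expect_identical(s2$symbols, perm[s1$symbols])
  # the partition of time indices is unchanged, cells just wear new labels
  for (k in 1:4)
    expect_identical(which(s1$symbols == k), which(s2$symbols == perm[k]))
})

test_that("davies_bouldin matches the brute-force reference on random labelings", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(30:200, 1)
    pts <- matrix(rnorm(n * 2), ncol = 2)
    labels <- sample.int(sample(2:6, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(davies_bouldin(pts, labels),
                 brute_davies_bouldin(pts, as.integer(factor(labels))),
                 tolerance = 1e-9)
  }
  expect_error(davies_bouldin(matrix(rnorm(10), 5), rep(1, 5)), "2 non-empty")
})

test_that("davies_bouldin separates good from bad k on fixed blobs", {
  set.seed(10)
  pts <- rbind(matrix(rnorm(100, 0), ncol = 2),
               matrix(rnorm(100, 12), ncol = 2))
  good <- rep(1:2, each = 50)
  bad <- rep(1:2, 50)
  expect_lt(davies_bouldin(pts, good), davies_bouldin(pts, bad))
  # well-separated singleton-dispersion clusters give an index near 0
  tight <- rbind(matrix(rep(c(0, 0), 10), ncol = 2, byrow = TRUE),
                 matrix(rep(c(50, 50), 10), ncol = 2, byrow = TRUE))
  expect_lt(davies_bouldin(tight, rep(1:2, each = 10)), 1e-10)
})

test_that("stabilization rule handles flat and elbow curves", {
  expect_equal(stabilization_point(2:10, rep(1, 9)), 2)
  curve <- c(10, 9, 8, 7, 6, 5, 4, 4, 4, 4, 4)
  expect_equal(stabilization_point(2:12, curve), 8)
  expect_error(stabilization_point(c(3, 2), c(1, 1)), "increasing")
})

test_that("subspace selection recovers the generative blob count", {
  ks <- vapply(1:10, function(s) {
    set.seed(s)
    pts <- do.call(rbind, lapply(1:5, function(m)
      matrix(rnorm(120, mean = 10 * m), ncol = 2)))
    select_num_subspaces(pts, k_min = 2, k_max = 20, seed = s)$k
  }, numeric(1))
  expect_true(all(ks == 5))
})
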