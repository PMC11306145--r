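test_that("recurrence sets enumerate the worked example correctly", {
  p <- fractal_params(2)
  sym <- c(1L, 2L, 1L, 1L)
  emb <- ifs_project(sym, p)
  lvl1 <- recurrence_sets(sym, emb, 1)
  expect_equal(lvl1[["1"]]$times, c(1L, 3L, 4L))
  expect_equal(lvl1[["2"]]$times, 2L)
  lvl2 <- recurrence_sets(sym, emb, 2)
  expect_equal(lvl2[["1_2"]]$times, 3L)   # current 1, previous 2
  expect_equal(lvl2[["1_1"]]$times, 4L)
  expect_equal(lvl2[["2_1"]]$times, 2L)
  expect_equal(lvl2[["2_2"]]$cardinality, 0L)
  lvl0 <- recurrence_sets(sym, emb, 0)
  expect_equal(lvl0$phi$times, 1:4)
  expect_error(recurrence_sets(sym, emb, 4), "exceeds")
})

test_that("recurrence sets partition the eligible times at every level", {
  set.seed(1)
  for (rep in 1:5) {
    K <- sample(2:5, 1)
    L <- sample(50:150, 1)
    sym <- rand_symbols(L, K)
    emb <- ifs_project(sym, fractal_params(K))
    for (N in 0:3) {
      cl <- recurrence_sets(sym, emb, N)
      all_times <- sort(unname(unlist(lapply(cl, `[[`, "times"))))
      expect_equal(all_times, seq.int(max(N, 1), L))  # level 0 -> 1..L
      if (N == 0) expect_equal(all_times, 1:L)
      # disjoint by construction: total count equals union size
      expect_equal(sum(vapply(cl, `[[`, integer(1), "cardinality")),
                   length(all_times))
      # brute-force membership check against a direct scan
      pick <- sample(length(cl), 1)
      expect_identical(cl[[pick]]$times,
                       brute_cluster_times(sym, cl[[pick]]$pattern))
    }
  }
})

test_that("scaled pair distances follow the alpha^N adjustment", {
  cl <- list(pattern = 1L, times = 1:2,
             addresses = rbind(c(0, 0), c(3, 4)), cardinality = 2L)
  expect_equal(scaled_pair_distances(cl, alpha = 0.5, level = 1), 10)
  cl3 <- list(pattern = 1L, times = 1:3,
              addresses = rbind(c(0, 0), c(1, 0), c(0, 1)), cardinality = 3L)
  expect_length(scaled_pair_distances(cl3, 0.5, 0), 3)  # m(m-1)/2
  cl1 <- list(pattern = 1L, times = 1L, addresses = rbind(c(0, 0)),
              cardinality = 1L)
  expect_error(scaled_pair_distances(cl1, 0.5, 1), "fewer than 2")
  # identical addresses give zero distance
  cl0 <- list(pattern = 1L, times = 1:2,
              addresses = rbind(c(1, 1), c(1, 1)), cardinality = 2L)
  expect_equal(scaled_pair_distances(cl0, 0.9, 2), 0)
})

test_that("HRR follows each convention on the worked example", {
  p <- fractal_params(2)
  sym <- c(1L, 2L, 1L, 1L)
  emb <- ifs_project(sym, p)
  cl <- recurrence_sets(sym, emb, 1)[["1"]]
  expect_equal(hrqa_metrics(cl, p$alpha, 1, L = 4,
                            hrr = "as_printed")[["HRR"]], 3 / 16)
  expect_equal(hrqa_metrics(cl, p$alpha, 1, L = 4,
                            hrr = "squared")[["HRR"]], 9 / 16)
  expect_equal(hrqa_metrics(cl, p$alpha, 1, L = 4,
                            hrr = "proportion")[["HRR"]], 3 / 4)
})

test_that("degenerate distance distributions hit the histogram bounds", {
  # all pairwise distances equal -> single occupied bin
  cl <- list(pattern = 1L, times = 1:2,
             addresses = rbind(c(0, 0), c(1, 0)), cardinality = 2L)
  m <- hrqa_metrics(cl, 0.5, 0, L = 10, B = 10)
  expect_equal(m[["HVar"]], 0)
  expect_equal(m[["HENT"]], 0)
  expect_equal(m[["HGini"]], 0)
  # distances uniform across B bins -> entropy ln B, Gini 1 - 1/B:
  # the perfect ruler 0, 1, 4, 6 has pairwise distances exactly 1..6,
  # one per bin when B = 6
  cl2 <- list(pattern = 1L, times = 1:4,
              addresses = cbind(c(0, 1, 4, 6), 0), cardinality = 4L)
  m2 <- hrqa_metrics(cl2, 1, 0, L = 10, B = 6)
  expect_equal(m2[["HENT"]], log(6), tolerance = 1e-12)
  expect_equal(m2[["HGini"]], 1 - 1 / 6, tolerance = 1e-12)
})

test_that("all seven metrics match the brute-force reference", {
  set.seed(2)
  for (rep in 1:25) {
    K <- sample(2:4, 1)
    L <- sample(10:30, 1)
    sym <- rand_symbols(L, K)
    p <- fractal_params(K, 0.99)
    emb <- ifs_project(sym, p)
    for (hrr in c("squared", "as_printed", "proportion")) {
      for (N in 0:2) {
        cl <- recurrence_sets(sym, emb, N)
        pick <- sample(length(cl), min(3, length(cl)))
        for (i in pick) {
          got <- hrqa_metrics(cl[[i]], p$alpha, N, L = L, hrr = hrr)
          want <- brute_hrqa(sym, K, p$alpha, cl[[i]]$pattern, hrr = hrr)
          expect_equal(got, want, tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("moment inequality and histogram bounds hold on random clusters", {
  set.seed(3)
  B <- 10
  for (rep in 1:10) {
    sym <- rand_symbols(100, 3)
    p <- fractal_params(3)
    emb <- ifs_project(sym, p)
    for (N in 0:2) {
      for (cl in recurrence_sets(sym, emb, N)) {
        m <- hrqa_metrics(cl, p$alpha, N, L = 100, B = B)
        expect_gte(m[["HENT"]], 0)
        expect_lte(m[["HENT"]], log(B) + 1e-12)
        expect_gte(m[["HGini"]], 0)
        expect_lte(m[["HGini"]], 1 - 1 / B + 1e-12)
        if (m[["HVar"]] > 0)
          expect_gte(m[["HKurtosis"]], m[["HSkew"]]^2 + 1 - 1e-9)
      }
    }
  }
})

test_that("metric scaling behaves under a uniform distance rescaling", {
  # scaling all addresses by c scales HMean by c, HVar by c^2 and leaves
  # the shape metrics and histogram functionals unchanged
  set.seed(4)
  sym <- rand_symbols(60, 3)
  p <- fractal_params(3)
  emb <- ifs_project(sym, p)
  cl <- recurrence_sets(sym, emb, 1)[["2"]]
  stopifnot(cl$cardinality >= 3)
  scaled <- cl
  scaled$addresses <- cl$addresses * 7
  m1 <- hrqa_metrics(cl, p$alpha, 1, L = 60)
  m2 <- hrqa_metrics(scaled, p$alpha, 1, L = 60)
  expect_equal(m2[["HMean"]], 7 * m1[["HMean"]], tolerance = 1e-12)
  expect_equal(m2[["HVar"]], 49 * m1[["HVar"]], tolerance = 1e-12)
  for (nm in c("HSkew", "HKurtosis", "HENT", "HGini"))
    expect_equal(m2[[nm]], m1[[nm]], tolerance = 1e-10)
})

test_that("feature vector has the combinatorial length and stable naming", {
  set.seed(5)
  fv <- feature_vector(rand_symbols(50, 3), K = 3, max_level = 1)
  expect_length(fv, 7 * (1 + 3))
  expect_identical(names(fv)[1:7],
                   c("HRR", "HMean", "HVar", "HSkew", "HKurtosis",
                     "HENT", "HGini"))
  expect_true("HRR_2" %in% names(fv))
  fv2 <- feature_vector(rand_symbols(100, 4), K = 4, max_level = 2)
  expect_length(fv2, 7 * (1 + 4 + 16))
  # level-2 names read from previous to current state
  expect_true(all(c("HRR_1_1", "HGini_4_3") %in% names(fv2)))
  expect_false(anyNA(fv2))
})

test_that("level-0 HRR and cluster cardinalities are invariant under relabeling", {
  set.seed(6)
  for (rep in 1:5) {
    K <- 4
    sym <- rand_symbols(80, K)
    perm <- sample(K)
    p <- fractal_params(K)
    emb1 <- ifs_project(sym, p)
    emb2 <- ifs_project(perm[sym], p)
    fv1 <- feature_vector(sym, emb1, K = K, max_level = 1)
    fv2 <- feature_vector(perm[sym], emb2, K = K, max_level = 1)
    expect_equal(fv1[["HRR"]], fv2[["HRR"]])
    # cardinality of cluster k maps to cluster perm[k] (HRR is a
    # cardinality functional, so HRR_k must transport along the permutation)
    for (k in 1:K)
      expect_equal(fv1[[paste0("HRR_", k)]],
                   fv2[[paste0("HRR_", perm[k])]])
  }
})
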