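test_that("contraction factor matches its closed form and bounds", {
  expect_equal(contraction_factor(4, 1 - 1e-12),
               sin(pi / 4) / (1 + sin(pi / 4)), tolerance = 1e-9)
  expect_equal(contraction_factor(45, 0.99),
               0.99 * sin(pi / 45) / (1 + sin(pi / 45)), tolerance = 1e-15)
  expect_lt(contraction_factor(2, 1e-9), 1e-8)  # tau -> 0 forces alpha -> 0
  expect_error(contraction_factor(1, 0.5), "at least 2")
  expect_error(contraction_factor(5, 1.2), "between 0 and 1")
  p <- fractal_params(45, 0.99)
  expect_equal(p$alpha, contraction_factor(45, 0.99))
})

test_that("IFS projection satisfies its exact recurrence", {
  set.seed(1)
  for (K in c(2, 5, 9)) {
    p <- fractal_params(K, 0.9)
    sym <- rand_symbols(50, K)
    emb <- ifs_project(sym, p)
    expect_equal(emb$addresses, brute_ifs(sym, K, p$alpha),
                 tolerance = 1e-12, ignore_attr = TRUE)
    # first address is the unit vector of the first symbol
    k1 <- sym[1]
    expect_equal(unname(emb$addresses[1, ]),
                 c(cos(2 * pi * k1 / K), sin(2 * pi * k1 / K)),
                 tolerance = 1e-12)
  }
  expect_error(ifs_project(c(1, 7), fractal_params(4)), "1\\.\\.K")
})

test_that("a constant sequence converges to the geometric-series fixed point", {
  p <- fractal_params(6, 0.99)
  emb <- ifs_project(rep(4L, 100), p)
  fixed <- c(cos(2 * pi * 4 / 6), sin(2 * pi * 4 / 6)) / (1 - p$alpha)
  expect_equal(unname(emb$addresses[100, ]), fixed, tolerance = 1e-8)
})

test_that("addresses obey the contraction bound and first-level discs are disjoint", {
  set.seed(2)
  for (K in c(2, 5, 45, 100)) {
    p <- fractal_params(K, 0.99)
    r <- p$alpha / (1 - p$alpha)
    for (rep in 1:10) {
      sym <- rand_symbols(300, K)
      A <- ifs_project(sym, p)$addresses
      expect_lte(max(sqrt(rowSums(A^2))), 1 / (1 - p$alpha) + 1e-12)
      # every address sits within alpha/(1-alpha) of its symbol's anchor
      anchors <- cbind(cos(2 * pi * sym / K), sin(2 * pi * sym / K))
      expect_lte(max(sqrt(rowSums((A - anchors)^2))), r + 1e-12)
    }
    # disc disjointness: anchors are 2 sin(pi/K) apart, discs have radius r
    expect_lt(2 * r, 2 * sin(pi / K))
  }
})

test_that("addresses sharing a symbol history are close (prefix property)", {
  set.seed(3)
  K <- 4
  p <- fractal_params(K, 0.99)
  sym <- rand_symbols(400, K)
  A <- ifs_project(sym, p)$addresses
  for (n in 1:3) {
    bound <- 2 * p$alpha^n / (1 - p$alpha)
    idx <- seq(n, 400)
    hist_key <- vapply(idx, function(t)
      paste(sym[(t - n + 1):t], collapse = ","), character(1))
    for (key in unique(hist_key)[1:min(5, length(unique(hist_key)))]) {
      ts <- idx[hist_key == key]
      if (length(ts) < 2) next
      pairs <- utils::combn(ts, 2)
      dmax <- max(sqrt(rowSums((A[pairs[1, ], , drop = FALSE] -
                                A[pairs[2, ], , drop = FALSE])^2)))
      expect_lte(dmax, bound + 1e-12)
    }
  }
})

test_that("box-counting dimension recovers known dimensions", {
  set.seed(4)
  sq <- cbind(runif(10000), runif(10000))
  expect_equal(box_counting_dimension(sq)$dimension, 2, tolerance = 0.1)
  seg <- cbind(runif(10000), 0.5)
  expect_equal(box_counting_dimension(seg)$dimension, 1, tolerance = 0.1)
  # a repeated single point occupies one box at every scale
  pt <- matrix(rep(c(0.3, 0.7), 20), ncol = 2, byrow = TRUE)
  expect_equal(box_counting_dimension(pt)$dimension, 0)
  expect_error(box_counting_dimension(cbind(1:5, 1:5)), "at least 10")
  bc <- box_counting_dimension(sq)
  expect_true(all(diff(bc$table$epsilon) < 0))
  expect_true(all(diff(bc$table$xi) >= 0))
})

test_that("structured dynamics yield a sparser fractal than i.i.d. noise", {
  # qualitative contrast between a chaotic attractor and randomness:
  # random sequences spread addresses over more boxes at equal L and K
  set.seed(5)
  K <- 10
  p <- fractal_params(K, 0.99)
  lor <- simulate_attractor("lorenz", n = 4000, seed = 11)
  tess <- fit_tessellation(lor$states, K, seed = 1)
  sym_lor <- symbolize(lor$states, tess)
  sym_rnd <- rand_symbols(4000, K)
  d_lor <- box_counting_dimension(ifs_project(sym_lor, p)$addresses)$dimension
  d_rnd <- box_counting_dimension(ifs_project(sym_rnd, p)$addresses)$dimension
  expect_gt(d_rnd, d_lor)
})
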