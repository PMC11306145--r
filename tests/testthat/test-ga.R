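test_that("ga_fitness is the composition of relabel, project and box count", {
  set.seed(1)
  K <- 4
  p <- fractal_params(K, 0.99)
  sym <- rand_symbols(500, K)
  ident <- ga_fitness(1:K, sym, p)
  direct <- box_counting_dimension(ifs_project(sym, p)$addresses)$dimension
  expect_equal(ident, direct)
  expect_error(ga_fitness(c(1, 1, 2, 3), sym, p), "permutation")
})

test_that("ga_fitness matches brute-force recomputation for both K = 2 arrangements", {
  set.seed(2)
  p <- fractal_params(2, 0.9)
  sym <- rand_symbols(300, 2)
  for (arr in list(1:2, 2:1)) {
    relab <- arr[sym]
    want <- box_counting_dimension(brute_ifs(relab, 2, p$alpha))$dimension
    expect_equal(ga_fitness(arr, sym, p), want, tolerance = 1e-12)
  }
})

test_that("fitness is nearly invariant across arrangements of an i.i.d. sequence", {
  set.seed(3)
  K <- 5
  p <- fractal_params(K, 0.99)
  sym <- rand_symbols(3000, K)
  fits <- vapply(1:20, function(i) ga_fitness(sample(K), sym, p), numeric(1))
  expect_lt(diff(range(fits)), 0.15)
})

test_that("elitist GA finds the exhaustive optimum for small K", {
  set.seed(4)
  for (K in c(2, 3)) {
    p <- fractal_params(K, 0.99)
    perms <- all_perms(K)
    for (rep in 1:10) {
      sym <- rand_symbols(200, K)
      best_brute <- max(vapply(perms, ga_fitness, numeric(1),
                               symbols = sym, params = p))
      opt <- optimize_labels(sym, p, ga_config(pool_size = 12, ga_iter = 10,
                                               seed = rep))
      expect_equal(opt$fitness, best_brute, tolerance = 1e-12)
      expect_false(is.unsorted(opt$history))  # elitism: never decreases
    }
  }
})

test_that("GA terminates early on a flat fitness landscape and keeps honest books", {
  # constant sequences give the same (zero-extent) fractal under every
  # arrangement, so fitness is flat and the convergence check must fire
  sym <- rep(1:2, each = 50)[c(rep(1, 99), 2)]  # nearly constant
  p <- fractal_params(2, 0.9)
  cfg <- ga_config(pool_size = 8, ga_iter = 100, conv_window = 5, seed = 1)
  opt <- optimize_labels(rep(c(1L, 2L), 50), p, cfg)
  expect_lt(opt$generations, 100)
  expect_lte(length(opt$history), cfg$ga_iter)
  expect_equal(max(opt$history), opt$fitness)
  expect_true(setequal(opt$arrangement, 1:2))
})

test_that("optimize_labels is deterministic given the seed", {
  set.seed(6)
  sym <- rand_symbols(300, 4)
  p <- fractal_params(4, 0.99)
  cfg <- ga_config(pool_size = 10, ga_iter = 5, seed = 42)
  a <- optimize_labels(sym, p, cfg)
  b <- optimize_labels(sym, p, cfg)
  expect_identical(a$arrangement, b$arrangement)
  expect_identical(a$history, b$history)
})

test_that("ga_config validates its fields", {
  expect_error(ga_config(pool_size = 10, slt = 20), "exceed")
  expect_error(ga_config(pm = 1.5), "pm")
  expect_error(ga_config(ga_iter = 0), "ga_iter")
  expect_equal(ga_config(paper_scale = TRUE)$pool_size, 50000L)
})
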