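#' Genetic-algorithm configuration for label-arrangement optimization
#'
#' The fractal encoding is sensitive to how subspace labels `1:K` are
#' assigned to Voronoi cells; with 45 subspaces there are `45! ~ 1.2e56`
#' arrangements, so an exhaustive search is impossible and a permutation
#' genetic algorithm is used instead.
#'
#' @param pool_size Population size per generation. The desk default is
#'   200; `paper_scale = TRUE` restores the 50,000-strong pool used at full
#'   study scale (a compute choice, not part of the method definition).
#' @param slt Number of top arrangements kept for reproduction (elitism);
#'   defaults to 20% of the pool.
#' @param pm Mutation probability per offspring (random swap).
#' @param ga_iter Maximum number of generations.
#' @param conv_window,conv_tol Early stopping: stop when the best fitness
#'   improves by less than `conv_tol` over `conv_window` consecutive
#'   generations.
#' @param seed Integer seed; the optimization is deterministic given it.
#' @param paper_scale If `TRUE`, set `pool_size` to 50,000.
#' @return An object of class `"ga_config"`.
#' @export
ga_config <- function(pool_size = 200, slt = NULL, pm = 0.1, ga_iter = 100,
                      conv_window = 10, conv_tol = 1e-4, seed = 1,
                      paper_scale = FALSE) {
  if (paper_scale) pool_size <- 50000
  pool_size <- as.integer(pool_size)
  if (is.null(slt)) slt <- max(2L, as.integer(round(pool_size * 0.2)))
  slt <- as.integer(slt)
  if (pool_size < 2) stop("`pool_size` must be at least 2")
  if (slt > pool_size) stop("`slt` cannot exceed `pool_size`")
  if (pm < 0 || pm > 1) stop("`pm` must lie in [0, 1]")
  if (ga_iter < 1) stop("`ga_iter` must be at least 1")
  structure(list(pool_size = pool_size, slt = slt, pm = pm,
                 ga_iter = as.integer(ga_iter),
                 conv_window = as.integer(conv_window), conv_tol = conv_tol,
                 seed = as.integer(seed)),
            class = "ga_config")
}

check_permutation <- function(arrangement, K) {
  arrangement <- as.integer(arrangement)
  if (length(arrangement) != K || !setequal(arrangement, seq_len(K)))
    stop("`arrangement` must be a permutation of 1..K")
  arrangement
}

#' Fitness of a label arrangement
#'
#' Relabels the symbol sequence through the arrangement, projects it with
#' the chaos-game encoding, and returns the box-counting dimension of the
#' resulting address cloud. Arrangements that let structured dynamics
#' occupy a richer fractal score higher.
#'
#' @param arrangement A permutation of `1:K` mapping raw cell index to
#'   category label.
#' @param symbols A `"symbol_sequence"` or integer vector.
#' @param params A [fractal_params()] object.
#' @param ... Passed to [box_counting_dimension()].
#' @return The fractal dimension (single numeric).
#' @export
ga_fitness <- function(arrangement, symbols, params, ...) {
  sq <- as_symbols(symbols, K = params$K)
  arrangement <- check_permutation(arrangement, params$K)
  relabeled <- arrangement[sq$symbols]
  emb <- ifs_project(relabeled, params)
  box_counting_dimension(emb$addresses, ...)$dimension
}

# order crossover (OX): copy a random slice from parent a, fill the rest
# in parent b's order
ox_crossover <- function(a, b) {
  K <- length(a)
  cut <- sort(sample.int(K, 2))
  child <- integer(K)
  slice <- cut[1]:cut[2]
  child[slice] <- a[slice]
  child[-slice] <- b[!(b %in% a[slice])]
  child
}

swap_mutate <- function(p) {
  idx <- sample.int(length(p), 2)
  p[idx] <- p[rev(idx)]
  p
}

#' Optimize the subspace label arrangement
#'
#' Elitist permutation genetic algorithm maximizing the fractal dimension
#' of the chaos-game encoding (see [ga_fitness()]): random initial pool,
#' truncation selection of the top `slt` arrangements, order crossover and
#' swap mutation to refill the pool, with the elite carried over unchanged
#' so the best fitness never decreases. Fitness values are cached across
#' generations.
#'
#' @param symbols A `"symbol_sequence"` or integer vector.
#' @param params A [fractal_params()] object.
#' @param cfg A [ga_config()].
#' @param ... Passed to [box_counting_dimension()] via [ga_fitness()].
#' @return An object of class `"label_optimization"`: `arrangement` (best
#'   permutation), `fitness`, per-generation best-fitness `history`, and
#'   `generations` actually run.
#' @examples
#' set.seed(1)
#' p <- fractal_params(3, 0.99)
#' opt <- optimize_labels(sample(3, 200, TRUE), p,
#'                        ga_config(pool_size = 20, ga_iter = 10, seed = 1))
#' opt$fitness
#' @export
optimize_labels <- function(symbols, params, cfg = ga_config(), ...) {
  stopifnot(inherits(cfg, "ga_config"))
  sq <- as_symbols(symbols, K = params$K)
  K <- params$K
  set.seed(cfg$seed)
  pool <- replicate(cfg$pool_size, sample.int(K), simplify = FALSE)
  cache <- new.env(parent = emptyenv())
  eval_fit <- function(p) {
    key <- paste(p, collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- ga_fitness(p, sq, params, ...)
    cache[[key]] <- f
    f
  }
  history <- numeric(0)
  best <- NULL
  best_fit <- -Inf
  gen <- 0L
  for (iter in seq_len(cfg$ga_iter)) {
    gen <- iter
    fitness <- vapply(pool, eval_fit, numeric(1))
    ord <- order(fitness, decreasing = TRUE)
    if (fitness[ord[1]] > best_fit) {
      best_fit <- fitness[ord[1]]
      best <- pool[[ord[1]]]
    }
    history <- c(history, best_fit)
    w <- cfg$conv_window
    if (length(history) > w &&
        history[length(history)] - history[length(history) - w] < cfg$conv_tol)
      break
    elite <- pool[ord[seq_len(min(cfg$slt, length(pool)))]]
    n_off <- cfg$pool_size - length(elite)
    offspring <- vector("list", n_off)
    for (i in seq_len(n_off)) {
      parents <- sample.int(length(elite), 2, replace = length(elite) < 2)
      child <- ox_crossover(elite[[parents[1]]], elite[[parents[2]]])
      if (stats::runif(1) < cfg$pm) child <- swap_mutate(child)
      offspring[[i]] <- child
    }
    pool <- c(elite, offspring)
  }
  structure(list(arrangement = best, fitness = best_fit, history = history,
                 generations = gen),
            class = "label_optimization")
}

#' @export
print.label_optimization <- function(x, ...) {
  cat(sprintf("<label_optimization> best fitness %.4f after %d generations\n",
              x$fitness, x$generations))
  invisible(x)
}
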