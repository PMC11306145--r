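#' Fit a Voronoi tessellation of the state space
#'
#' Segments the state space into `k` subspaces by k-means: the cluster
#' centroids are the Voronoi generators (a k-means partition is exactly the
#' Voronoi tessellation of its centroids). The label `arrangement` starts as
#' the identity permutation and can later be replaced by an optimized one
#' (see [optimize_labels()]).
#'
#' @param points A `T x d` matrix of states or a `"trajectory"`.
#' @param k Number of subspaces (2 <= k <= number of distinct points).
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param nstart,iter_max Passed to [stats::kmeans()].
#' @return An object of class `"tessellation"` with `generators` (`k x d`),
#'   `K` and `arrangement` (a permutation of `1:k`).
#' @examples
#' pts <- rbind(matrix(rnorm(50, 0), , 2), matrix(rnorm(50, 6), , 2))
#' fit_tessellation(pts, k = 2, seed = 1)$generators
#' @export
fit_tessellation <- function(points, k, seed = 1, nstart = 10,
                             iter_max = 100) {
  pts <- as_state_matrix(points)
  k <- as.integer(k)
  if (k < 2) stop("`k` must be at least 2")
  if (nrow(pts) < k) stop("`k` exceeds the number of points")
  n_distinct <- nrow(unique(pts))
  if (k > n_distinct) stop("`k` exceeds the number of distinct points")
  set.seed(seed)
  if (k == n_distinct) {
    # degenerate partition: every distinct point is its own generator
    generators <- unname(unique(pts))
  } else {
    # Hartigan-Wong's Quick-TRANSfer stage struggles on very large
    # structured clouds; MacQueen converges cleanly there
    alg <- if (nrow(pts) > 20000) "MacQueen" else "Hartigan-Wong"
    km <- stats::kmeans(pts, centers = k, nstart = nstart,
                        iter.max = iter_max, algorithm = alg)
    generators <- unname(km$centers)
  }
  structure(list(generators = generators, K = k,
                 arrangement = seq_len(k)),
            class = "tessellation")
}

#' @export
print.tessellation <- function(x, ...) {
  cat(sprintf("<tessellation> K = %d subspaces in %d dims\n",
              x$K, ncol(x$generators)))
  invisible(x)
}

# squared distances from each row of `pts` to each generator
generator_dist2 <- function(pts, gen) {
  outer(rowSums(pts^2), rep(1, nrow(gen))) +
    outer(rep(1, nrow(pts)), rowSums(gen^2)) - 2 * pts %*% t(gen)
}

#' Symbolize a trajectory with a tessellation
#'
#' Assigns each state to its nearest Voronoi generator and maps the raw cell
#' index through the tessellation's label `arrangement`, converting the
#' trajectory into the categorical sequence whose transition dynamics the
#' recurrence analysis quantifies. Ties are broken toward the lowest raw
#' cell index for determinism.
#'
#' @param traj A `"trajectory"` or `T x d` matrix.
#' @param tess A `"tessellation"` with matching dimensionality.
#' @return An object of class `"symbol_sequence"` with integer `symbols` in
#'   `1:K`, plus `K` and the sequence length `L`.
#' @examples
#' tess <- structure(list(generators = rbind(c(0, 0), c(4, 0)), K = 2L,
#'                        arrangement = 1:2), class = "tessellation")
#' symbolize(rbind(c(0.1, 0), c(3.9, 0), c(4, 1)), tess)$symbols
#' @export
symbolize <- function(traj, tess) {
  pts <- as_state_matrix(traj)
  stopifnot(inherits(tess, "tessellation"))
  if (ncol(pts) != ncol(tess$generators))
    stop("trajectory dimension does not match tessellation generators")
  d2 <- generator_dist2(pts, tess$generators)
  raw <- max.col(-d2, ties.method = "first")
  new_symbol_sequence(tess$arrangement[raw], tess$K)
}

new_symbol_sequence <- function(symbols, K) {
  symbols <- as.integer(symbols)
  K <- as.integer(K)
  if (length(symbols) < 1L) stop("empty symbol sequence")
  if (any(symbols < 1L | symbols > K))
    stop("symbols must lie in 1..K")
  structure(list(symbols = symbols, K = K, L = length(symbols)),
            class = "symbol_sequence")
}

#' @export
print.symbol_sequence <- function(x, ...) {
  cat(sprintf("<symbol_sequence> L = %d, K = %d\n", x$L, x$K))
  invisible(x)
}

as_symbols <- function(x, K = NULL) {
  if (inherits(x, "symbol_sequence")) return(x)
  if (is.null(K)) K <- max(x)
  new_symbol_sequence(x, K)
}

#' Davies-Bouldin index
#'
#' Cluster-quality score used to choose the number of subspaces: for each
#' cluster pair the ratio of summed within-cluster scatters to
#' between-centroid distance is formed, and the index is the mean over
#' clusters of the worst ratio. Lower values indicate tighter, better
#' separated clusters.
#'
#' @param points A numeric matrix of observations (rows).
#' @param labels Integer cluster assignment, one per row.
#' @return The Davies-Bouldin index (single numeric).
#' @export
davies_bouldin <- function(points, labels) {
  pts <- as_state_matrix(points)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("at least 2 non-empty clusters are required")
  cent <- matrix(0, k, ncol(pts))
  scatter <- numeric(k)
  for (g in seq_len(k)) {
    sub <- pts[labels == g, , drop = FALSE]
    cent[g, ] <- colMeans(sub)
    scatter[g] <- mean(sqrt(rowSums(sweep(sub, 2, cent[g, ])^2)))
  }
  M <- as.matrix(stats::dist(cent))
  R <- outer(scatter, scatter, `+`) / M
  diag(R) <- -Inf
  mean(apply(R, 1, max))
}

#' Stabilization point of a quality curve
#'
#' Given index values over an increasing grid of `k`, returns the smallest
#' `k` after which the relative improvement per step falls below
#' `tolerance`. Used by [select_num_subspaces()] on the (smoothed)
#' Davies-Bouldin curve.
#'
#' @param k Increasing numeric grid.
#' @param values Index values on the grid (lower = better).
#' @param tolerance Relative per-step improvement threshold (default 0.01).
#' @return The stabilizing `k` (the last grid point if none stabilizes).
#' @examples
#' stabilization_point(2:12, c(10, 8, 6, 4, 2, 1, 1, 1, 1, 1, 1) / 10)
#' @export
stabilization_point <- function(k, values, tolerance = 0.01) {
  if (length(k) != length(values) || length(k) < 2)
    stop("`k` and `values` must be equal-length vectors of length >= 2")
  if (is.unsorted(k, strictly = TRUE)) stop("`k` must be strictly increasing")
  # work on the running minimum so a noisy uptick never masquerades as
  # stabilization and later re-descents still count as improvement
  best <- cummin(values)
  denom <- pmax(abs(best[-length(best)]), .Machine$double.eps)
  improvement <- (best[-length(best)] - best[-1]) / denom
  idx <- which(improvement < tolerance)
  if (length(idx) == 0) k[length(k)] else k[idx[1]]
}

#' Select the number of Voronoi subspaces
#'
#' Sweeps a grid of candidate subspace counts, scores each k-means
#' tessellation with the Davies-Bouldin index, smooths the curve with a
#' local polynomial (loess) fit, and returns the smallest `k` at which the
#' smoothed curve stabilizes (per-step relative improvement below
#' `tolerance`).
#'
#' @param points A `T x d` matrix or `"trajectory"`.
#' @param k_min,k_max,step Grid of candidate counts (defaults 10..100 by 1).
#' @param smoothing `"loess"` (default) or `"none"`.
#' @param span Loess span.
#' @param tolerance Stabilization threshold on the relative improvement.
#' @param nstart Random restarts per k-means fit; separated clusters need
#'   several restarts to avoid local optima that corrupt the index curve.
#' @param seed Seed for the k-means fits.
#' @return An object of class `"subspace_selection"`: `k` (the selected
#'   count) plus the full `grid`, raw `index` and `smoothed` curves.
#' @examples
#' set.seed(1)
#' pts <- do.call(rbind, lapply(1:3, function(m) matrix(rnorm(60, 8 * m), , 2)))
#' select_num_subspaces(pts, k_min = 2, k_max = 8)$k
#' @export
select_num_subspaces <- function(points, k_min = 10, k_max = 100, step = 1,
                                 smoothing = c("loess", "none"), span = 0.5,
                                 tolerance = 0.01, nstart = 20, seed = 1) {
  smoothing <- match.arg(smoothing)
  pts <- as_state_matrix(points)
  if (k_min < 2) stop("`k_min` must be at least 2")
  if (k_max > nrow(pts)) stop("`k_max` exceeds the number of points")
  grid <- seq.int(k_min, k_max, by = step)
  if (length(grid) < 2) stop("the k grid must contain at least 2 values")
  index <- vapply(grid, function(k) {
    set.seed(seed + k)
    km <- stats::kmeans(pts, centers = k, nstart = nstart, iter.max = 100)
    davies_bouldin(pts, km$cluster)
  }, numeric(1))
  smoothed <- index
  # a fitted curve only makes sense on long grids; short sweeps with a
  # sharp minimum would be blurred by it
  if (smoothing == "loess" && length(grid) >= 25) {
    fit <- try(stats::loess(index ~ grid, span = span, degree = 2),
               silent = TRUE)
    if (!inherits(fit, "try-error")) smoothed <- stats::fitted(fit)
  }
  k_star <- stabilization_point(grid, smoothed, tolerance)
  structure(list(k = k_star, grid = grid, index = index, smoothed = smoothed,
                 tolerance = tolerance),
            class = "subspace_selection")
}

#' @export
print.subspace_selection <- function(x, ...) {
  cat(sprintf("<subspace_selection> k* = %d (grid %d..%d)\n",
              x$k, min(x$grid), max(x$grid)))
  invisible(x)
}
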