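#' Embedding configuration
#'
#' Settings for projecting a multichannel signal into a low-dimensional
#' state space. The nonlinear dimensionality-reduction step itself is
#' delegated to established implementations: uwot (UMAP), Rtsne (t-SNE),
#' vegan (Isomap) and a Laplacian-eigenmap spectral embedding; "pca" is a
#' fast linear baseline. UMAP with `n_dims = 4`, `n_neighbors = 5`,
#' `min_dist = 0.1`, `spread = 1` is the reference configuration for
#' 62-lead EEG.
#'
#' @param method One of `"umap"`, `"pca"`, `"isomap"`, `"spectral"`,
#'   `"tsne"`, `"lle"`. `"lle"` is recognized but not available.
#' @param n_dims Embedding dimension (>= 2; default 4).
#' @param n_neighbors Neighborhood size for umap/isomap/spectral.
#' @param min_dist,spread UMAP layout parameters.
#' @param perplexity t-SNE perplexity.
#' @param seed Integer seed; embeddings are deterministic given the seed.
#' @return An object of class `"embedding_config"`.
#' @export
embedding_config <- function(method = c("umap", "pca", "isomap", "spectral",
                                        "tsne", "lle"),
                             n_dims = 4, n_neighbors = 5, min_dist = 0.1,
                             spread = 1.0, perplexity = 30, seed = 1) {
  method <- match.arg(method)
  if (!is.numeric(n_dims) || n_dims < 2) stop("`n_dims` must be >= 2")
  if (n_neighbors < 1) stop("`n_neighbors` must be positive")
  if (min_dist <= 0 || spread <= 0 || perplexity <= 0)
    stop("embedding hyperparameters must be positive")
  if (method == "tsne" && n_dims > 3)
    stop("t-SNE (Rtsne) supports at most 3 output dimensions")
  structure(list(method = method, n_dims = as.integer(n_dims),
                 n_neighbors = as.integer(n_neighbors), min_dist = min_dist,
                 spread = spread, perplexity = perplexity,
                 seed = as.integer(seed)),
            class = "embedding_config")
}

new_trajectory <- function(states, fs = NA_real_, source = NULL) {
  states <- as.matrix(states)
  if (nrow(states) < 2L) stop("a trajectory needs at least 2 states")
  colnames(states) <- paste0("x", seq_len(ncol(states)))
  structure(list(states = states, fs = fs, source = source),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d states x %d dims\n",
              nrow(x$states), ncol(x$states)))
  invisible(x)
}

as_state_matrix <- function(x) {
  if (inherits(x, "trajectory")) x$states
  else if (inherits(x, "multichannel_signal")) t(x$data)
  else as.matrix(x)
}

# Fit an embedder on pooled samples and return an object that can also
# transform new samples (only pca and umap support out-of-sample mapping).
fit_embedder <- function(X, cfg) {
  set.seed(cfg$seed)
  switch(cfg$method,
    pca = {
      p <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = cfg$n_dims)
      list(method = "pca", center = p$center, rotation = p$rotation,
           transform = function(newX)
             sweep(newX, 2, p$center) %*% p$rotation)
    },
    umap = {
      m <- uwot::umap(X, n_components = cfg$n_dims,
                      n_neighbors = cfg$n_neighbors, min_dist = cfg$min_dist,
                      spread = cfg$spread, n_threads = 1, n_sgd_threads = 0,
                      ret_model = TRUE)
      list(method = "umap", model = m,
           transform = function(newX)
             uwot::umap_transform(newX, m, n_threads = 1))
    },
    stop(sprintf("embedding method '%s' does not support out-of-sample mapping; use 'pca' or 'umap'",
                 cfg$method))
  )
}

#' Embed a multichannel signal into a low-dimensional state space
#'
#' Maps each time sample (one column of the channels-by-samples matrix) to a
#' point in a `n_dims`-dimensional state space, producing the trajectory
#' whose geometry the recurrence analysis quantifies. The number of time
#' points is preserved and results are deterministic given `cfg$seed`.
#'
#' @param signal A [multichannel_signal()] or a channels-by-samples matrix.
#' @param cfg An [embedding_config()].
#' @return A `"trajectory"` object with a `T x n_dims` `states` matrix.
#' @details Isomap, spectral embedding and t-SNE have no natural
#'   out-of-sample extension and operate on the full sample; they also build
#'   pairwise structures of size `T^2`, so are practical only for windows of
#'   a few thousand samples.
#' @examples
#' sig <- multichannel_signal(matrix(rnorm(6 * 300), 6), fs = 100)
#' tr <- embed_signal(sig, embedding_config("pca", n_dims = 2))
#' dim(tr$states)
#' @export
embed_signal <- function(signal, cfg = embedding_config()) {
  X <- if (inherits(signal, "multichannel_signal")) t(signal$data)
       else t(as.matrix(signal))
  fs <- if (inherits(signal, "multichannel_signal")) signal$fs else NA_real_
  n <- nrow(X)
  if (n <= cfg$n_neighbors && cfg$method %in% c("umap", "isomap", "spectral"))
    stop("too few samples for the chosen method and neighborhood size")
  set.seed(cfg$seed)
  states <- switch(cfg$method,
    pca = {
      if (cfg$n_dims > ncol(X))
        stop("`n_dims` exceeds the number of channels for pca")
      stats::prcomp(X, center = TRUE, rank. = cfg$n_dims)$x
    },
    umap = uwot::umap(X, n_components = cfg$n_dims,
                      n_neighbors = cfg$n_neighbors, min_dist = cfg$min_dist,
                      spread = cfg$spread, n_threads = 1, n_sgd_threads = 0),
    isomap = {
      fit <- vegan::isomap(stats::dist(X), ndim = cfg$n_dims,
                           k = cfg$n_neighbors)
      fit$points[, seq_len(cfg$n_dims), drop = FALSE]
    },
    spectral = spectral_embed(X, cfg$n_dims, cfg$n_neighbors),
    tsne = {
      if (n - 1 < 3 * cfg$perplexity)
        stop("too few samples for the chosen t-SNE perplexity")
      Rtsne::Rtsne(X, dims = cfg$n_dims, perplexity = cfg$perplexity,
                   check_duplicates = FALSE, pca = TRUE)$Y
    },
    lle = stop("locally linear embedding is not available in this build"),
    stop(sprintf("unknown embedding method '%s'", cfg$method))
  )
  new_trajectory(states, fs = fs)
}

# Laplacian eigenmap on a symmetrized kNN graph: embed with the
# eigenvectors of the random-walk-normalized graph Laplacian belonging to
# the smallest nonzero eigenvalues.
spectral_embed <- function(X, n_dims, n_neighbors) {
  n <- nrow(X)
  nn <- FNN::get.knn(X, k = n_neighbors)
  i <- rep(seq_len(n), each = n_neighbors)
  j <- as.vector(t(nn$nn.index))
  A <- matrix(0, n, n)
  A[cbind(i, j)] <- 1
  A <- pmax(A, t(A))                     # symmetrize
  d <- pmax(rowSums(A), .Machine$double.eps)
  L <- diag(n) - A / d                   # random-walk Laplacian
  # smallest-magnitude eigenpairs of the symmetrized problem
  Ls <- (L + t(L)) / 2
  e <- RSpectra::eigs_sym(Ls, k = n_dims + 1, which = "SM")
  ord <- order(e$values)
  vecs <- e$vectors[, ord, drop = FALSE]
  vecs[, 2:(n_dims + 1), drop = FALSE]   # drop the constant eigenvector
}

#' Cross-entropy between a signal and its embedding
#'
#' Scores how much of the original signal's information an embedding
#' retains by comparing the per-sample Euclidean norm profiles of the
#' embedded trajectory (`p`) and the original multichannel signal (`q`):
#' `C = -sum_t p_t log q_t`. Lower is better; the method and dimensionality
#' with the lowest cross-entropy retains the original signal best.
#'
#' @param original The original signal ([multichannel_signal()] or
#'   channels-by-samples matrix).
#' @param embedded The embedded `"trajectory"` (or `T x d` matrix).
#' @param normalize If `TRUE` (default), both norm sequences are rescaled to
#'   sum to one over time so the score is a proper cross-entropy between
#'   distributions; then `C >= H(p)` with equality iff `p = q`.
#' @param raw If `TRUE`, skip normalization entirely and evaluate the
#'   literal norm-based sum (useful only for ranking).
#' @return A single numeric score (natural-log units).
#' @examples
#' sig <- multichannel_signal(matrix(rnorm(5 * 200), 5), fs = 100)
#' tr <- embed_signal(sig, embedding_config("pca", n_dims = 2))
#' cross_entropy(sig, tr)
#' @export
cross_entropy <- function(original, embedded, normalize = TRUE, raw = FALSE) {
  qmat <- if (inherits(original, "multichannel_signal")) t(original$data)
          else t(as.matrix(original))
  pmat <- as_state_matrix(embedded)
  if (nrow(qmat) != nrow(pmat))
    stop("`original` and `embedded` must cover the same time points")
  p <- sqrt(rowSums(pmat^2))
  q <- sqrt(rowSums(qmat^2))
  if (raw) return(-sum(p * log(q)))
  if (normalize) {
    if (any(q == 0) || any(p == 0))
      stop("zero-norm sample encountered; input is degenerate for normalized cross-entropy")
    p <- p / sum(p)
    q <- q / sum(q)
  } else if (any(q == 0)) {
    stop("zero-norm sample in `original`")
  }
  -sum(p * log(q))
}
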