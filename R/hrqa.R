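#' Multilevel heterogeneous recurrence sets
#'
#' Partitions time indices by their recent category history. A level-N
#' pattern is the tuple `(k1, ..., kN)` with `k1` the current category,
#' `k2` the previous one, and so on; the cluster for a pattern collects
#' every time `t >= N` whose trailing history matches it, together with the
#' corresponding chaos-game addresses. Level 0 is the single whole-sequence
#' cluster. For fixed N the clusters are exhaustive and pairwise disjoint
#' over `{N, ..., L}` (1-based), so level-1 cardinalities sum to `L` and
#' level-2 cardinalities to `L - 1`.
#'
#' @param symbols A `"symbol_sequence"` or integer vector.
#' @param embedding The `"fractal_embedding"` generated from the same
#'   symbols (addresses are attached to each cluster).
#' @param level Transition level N (>= 0, < L).
#' @return A named list of clusters, one per pattern (all `K^N` patterns,
#'   empty ones included), each a list with `pattern`, `times`,
#'   `addresses`, `cardinality`. Names join the pattern as
#'   `"k1_k2_..._kN"` (current first); the level-0 cluster is named
#'   `"phi"`.
#' @examples
#' p <- fractal_params(2)
#' emb <- ifs_project(c(1, 2, 1, 1), p)
#' sapply(recurrence_sets(c(1, 2, 1, 1), emb, 1), `[[`, "cardinality")
#' @export
recurrence_sets <- function(symbols, embedding, level) {
  sq <- as_symbols(symbols,
                   K = if (inherits(embedding, "fractal_embedding"))
                     embedding$params$K else NULL)
  stopifnot(inherits(embedding, "fractal_embedding"))
  if (nrow(embedding$addresses) != sq$L)
    stop("embedding and symbols have different lengths")
  level <- as.integer(level)
  if (level < 0) stop("`level` must be non-negative")
  if (level >= sq$L) stop("`level` exceeds the sequence length minus one")
  K <- sq$K
  A <- embedding$addresses
  if (level == 0L) {
    cl <- list(phi = list(pattern = integer(0), times = seq_len(sq$L),
                          addresses = A, cardinality = sq$L))
    return(cl)
  }
  ts <- seq.int(level, sq$L)
  # lexicographic pattern code: (k1-1)*K^(N-1) + ... + (kN-1)*K^0 + 1
  code <- rep(0L, length(ts))
  for (j in seq_len(level)) {
    code <- code * K + (sq$symbols[ts - j + 1L] - 1L)
  }
  code <- code + 1L
  patterns <- as.matrix(expand.grid(rev(lapply(seq_len(level),
                                               function(i) seq_len(K)))))
  patterns <- patterns[, rev(seq_len(level)), drop = FALSE]  # k1 varies slowest
  members <- split(ts, factor(code, levels = seq_len(K^level)))
  out <- vector("list", K^level)
  for (i in seq_len(K^level)) {
    tt <- members[[i]]
    out[[i]] <- list(pattern = as.integer(patterns[i, ]), times = tt,
                     addresses = A[tt, , drop = FALSE],
                     cardinality = length(tt))
  }
  names(out) <- apply(patterns, 1, paste, collapse = "_")
  out
}

#' Scaled pairwise address distances of a recurrence cluster
#'
#' Euclidean distances between all unordered pairs of addresses in one
#' cluster, rescaled by `alpha^N` so that clusters at different transition
#' levels are measured on a comparable scale (level-N clusters live in
#' copies of the fractal shrunk by `alpha^N`).
#'
#' @param cluster One cluster from [recurrence_sets()] (needs
#'   `cardinality >= 2`).
#' @param alpha Contraction factor of the encoding.
#' @param level Transition level N of the cluster.
#' @return A numeric vector of `m(m-1)/2` scaled distances.
#' @export
scaled_pair_distances <- function(cluster, alpha, level) {
  if (cluster$cardinality < 2)
    stop("cluster has fewer than 2 members; pairwise distances are undefined")
  as.numeric(stats::dist(cluster$addresses)) / alpha^level
}

hrqa_metric_names <- c("HRR", "HMean", "HVar", "HSkew", "HKurtosis",
                       "HENT", "HGini")

#' Heterogeneous recurrence quantification metrics for one cluster
#'
#' Computes the seven HRQA metrics of a recurrence cluster: the recurrence
#' rate HRR, the first four standardized moments (HMean, HVar, HSkew,
#' HKurtosis) of the scaled pairwise address distances, and two histogram
#' functionals of those distances over `B` equal bins on `[0, max d]` —
#' Shannon entropy HENT and the Gini impurity HGini.
#'
#' @param cluster One cluster from [recurrence_sets()].
#' @param alpha Contraction factor.
#' @param level Transition level N.
#' @param L Length of the observed symbol sequence.
#' @param B Number of histogram bins (default 10).
#' @param hrr HRR convention: `"squared"` (default) counts recurrent pairs,
#'   `C^2/L^2`; `"as_printed"` is `C/L^2`; `"proportion"` is `C/L`.
#' @return A named numeric vector of the 7 metrics.
#' @details Degenerate clusters yield finite fill values rather than NaN:
#'   an empty cluster gives all zeros; a singleton gives its HRR with all
#'   distance-based metrics 0; zero variance sets HSkew and HKurtosis to 0.
#'   Zero distances are counted in the first histogram bin so the bin
#'   probabilities always sum to one. Moments use the number of pairs as
#'   denominator (population moments over the pair multiset), and the
#'   histogram probabilities are normalized per unordered pair, which is
#'   equivalent to doubling counts under the ordered-pair normalizer.
#' @examples
#' p <- fractal_params(2)
#' emb <- ifs_project(c(1, 2, 1, 1), p)
#' cl <- recurrence_sets(c(1, 2, 1, 1), emb, 1)[["1"]]
#' hrqa_metrics(cl, p$alpha, 1, L = 4)
#' @export
hrqa_metrics <- function(cluster, alpha, level, L, B = 10,
                         hrr = c("squared", "as_printed", "proportion")) {
  hrr <- match.arg(hrr)
  if (B < 2) stop("`B` must be at least 2")
  m <- cluster$cardinality
  hrr_val <- switch(hrr,
                    squared = m^2 / L^2,
                    as_printed = m / L^2,
                    proportion = m / L)
  out <- stats::setNames(numeric(7), hrqa_metric_names)
  out["HRR"] <- hrr_val
  if (m < 2) {
    if (m == 0) out["HRR"] <- 0
    return(out)
  }
  d <- scaled_pair_distances(cluster, alpha, level)
  npairs <- length(d)
  mu <- sum(d) / npairs
  v <- sum((d - mu)^2) / npairs
  out["HMean"] <- mu
  out["HVar"] <- v
  if (v > 0) {
    out["HSkew"] <- sum((d - mu)^3) / (npairs * v^1.5)
    out["HKurtosis"] <- sum((d - mu)^4) / (npairs * v^2)
  }
  maxd <- max(d)
  if (maxd == 0) {
    pr <- 1  # point mass: single occupied bin
  } else {
    b <- ceiling(d * B / maxd)
    b[b < 1L] <- 1L   # zeros fall in the first bin
    b[b > B] <- B     # guard against floating-point spill
    pr <- tabulate(b, nbins = B) / npairs
  }
  out["HENT"] <- -sum(pr[pr > 0] * log(pr[pr > 0]))
  out["HGini"] <- 1 - sum(pr^2)
  out
}

#' Full multilevel HRQA feature vector of a window
#'
#' Concatenates the seven HRQA metrics over every transition pattern from
#' level 0 up to `max_level`, in a stable order (level, then lexicographic
#' pattern, then metric). With `K` categories the vector has length
#' `7 * (1 + K + K^2 + ... + K^max_level)`; for `K = 45`, `max_level = 2`
#' that is 14,497 features.
#'
#' @param symbols A `"symbol_sequence"` or integer vector.
#' @param embedding The matching `"fractal_embedding"`; built automatically
#'   from `symbols` and `params` when omitted.
#' @param K Number of categories (taken from `params` if missing).
#' @param max_level Highest transition level (default 2).
#' @param B Histogram bins for HENT/HGini.
#' @param hrr HRR convention, see [hrqa_metrics()].
#' @param params Optional [fractal_params()]; defaults to
#'   `fractal_params(K)`.
#' @return A named numeric vector. Level-0 names are the bare metric names;
#'   level-1 names append the category (`"HRR_3"`); level-2 names read in
#'   transition order from previous to current state (`"HRR_2_5"` is the
#'   transition from subspace 2 to subspace 5). Note the internal pattern
#'   tuples store the current state first, so a pattern `(k1 = 5, k2 = 2)`
#'   becomes the feature suffix `"_2_5"`.
#' @examples
#' length(feature_vector(sample(3, 50, TRUE), K = 3, max_level = 1))  # 28
#' @export
feature_vector <- function(symbols, embedding = NULL, K = NULL,
                           max_level = 2, B = 10,
                           hrr = c("squared", "as_printed", "proportion"),
                           params = NULL) {
  hrr <- match.arg(hrr)
  if (is.null(params)) {
    if (is.null(K)) {
      if (inherits(symbols, "symbol_sequence")) K <- symbols$K
      else if (!is.null(embedding)) K <- embedding$params$K
      else stop("supply `K` or `params`")
    }
    params <- fractal_params(K)
  }
  K <- params$K
  sq <- as_symbols(symbols, K = K)
  if (is.null(embedding)) embedding <- ifs_project(sq, params)
  alpha <- embedding$params$alpha
  pieces <- vector("list", max_level + 1)
  for (N in 0:max_level) {
    clusters <- recurrence_sets(sq, embedding, N)
    vals <- vapply(clusters, hrqa_metrics, numeric(7), alpha = alpha,
                   level = N, L = sq$L, B = B, hrr = hrr)
    # vals: 7 x K^N matrix; interleave so metrics stay grouped per pattern
    v <- as.numeric(vals)
    if (N == 0) {
      names(v) <- hrqa_metric_names
    } else {
      suffix <- vapply(clusters, function(cl)
        paste(rev(cl$pattern), collapse = "_"), character(1))
      names(v) <- paste(rep(hrqa_metric_names, length(clusters)),
                        rep(suffix, each = 7), sep = "_")
    }
    pieces[[N + 1]] <- v
  }
  out <- unlist(pieces, use.names = TRUE)
  structure(out, K = K, max_level = max_level, B = B, hrr = hrr,
            tau = params$tau, alpha = alpha)
}
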