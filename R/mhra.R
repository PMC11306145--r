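#' Fit a multilevel heterogeneous recurrence analysis model
#'
#' End-to-end fitting front-end for the three-phase methodology:
#' \enumerate{
#'   \item \strong{Embedding} — recordings are cut into windows and every
#'     time sample is mapped into a low-dimensional state space (the
#'     embedder is fit once on pooled training samples and frozen, so that
#'     features are comparable across windows and prediction uses the same
#'     map).
#'   \item \strong{Recurrence quantification} — the pooled states are
#'     segmented into `K` Voronoi subspaces, the subspace label arrangement
#'     is optimized by a genetic algorithm maximizing the fractal dimension
#'     of the chaos-game encoding, and each window is reduced to its
#'     multilevel HRQA feature vector.
#'   \item \strong{Classification} — per-class LASSO stability selection
#'     followed by one-vs-all ensemble models.
#' }
#' Everything is fit on the supplied recordings only, so holding out
#' recordings before calling `mhra()` yields a leakage-free evaluation.
#'
#' @param x List of [multichannel_signal()] recordings.
#' @param labels Class labels, one per recording; defaults to the signals'
#'   own `label` fields.
#' @param window_s,overlap Windowing, see [window_signal()].
#' @param embedding An [embedding_config()]; only `"pca"` and `"umap"`
#'   support the frozen out-of-sample mapping `predict()` needs.
#' @param K Number of Voronoi subspaces; `NULL` selects it with
#'   [select_num_subspaces()] over `k_range`.
#' @param k_range Grid endpoints for the subspace-count selection.
#' @param tau Scaling control of the fractal encoding (default 0.99).
#' @param arrangement `"optimize"` (genetic algorithm, default) or
#'   `"identity"`.
#' @param ga A [ga_config()] for the arrangement optimization.
#' @param max_level Highest transition level quantified (default 2).
#' @param B Histogram bins for the entropy/Gini metrics.
#' @param hrr HRR convention, see [hrqa_metrics()].
#' @param select Run LASSO stability selection per class (default `TRUE`).
#' @param selection_runs,stability Passed to [lasso_select()].
#' @param method,grid,preset,cv_folds Passed to [train_ova()].
#' @param tess_max_points Pooled states are subsampled to at most this many
#'   points for the k-means tessellation fit.
#' @param ga_max_symbols The arrangement is optimized on at most this many
#'   pooled symbols (the fractal dimension stabilizes with a few thousand
#'   addresses).
#' @param seed Integer seed governing every stochastic step.
#' @return An object of class `"mhra"` with the frozen embedder,
#'   tessellation, fractal parameters, training `features`, `labels`,
#'   `groups`, selection reports and fitted one-vs-all models. Methods:
#'   [print.mhra()], [summary.mhra()], [predict.mhra()], [plot.mhra()].
#' @examples
#' \donttest{
#' recs <- generate_surrogate_eeg(n_per_class = 2, n_channels = 8,
#'                                fs = 100, duration = 40, seed = 1)
#' fit <- mhra(recs, K = 4, embedding = embedding_config("pca", n_dims = 3),
#'             select = FALSE, method = "random_forest", seed = 1)
#' fit
#' }
#' @export
mhra <- function(x, labels = NULL, window_s = 20, overlap = 0,
                 embedding = embedding_config("pca"), K = NULL,
                 k_range = c(10, 100), tau = 0.99,
                 arrangement = c("optimize", "identity"),
                 ga = ga_config(pool_size = 40, ga_iter = 15),
                 max_level = 2, B = 10,
                 hrr = c("squared", "as_printed", "proportion"),
                 select = TRUE, selection_runs = 10, stability = 1.0,
                 method = "random_forest", grid = NULL, preset = "desk",
                 cv_folds = 10, tess_max_points = 100000,
                 ga_max_symbols = 5000, seed = 1) {
  arrangement <- match.arg(arrangement)
  hrr <- match.arg(hrr)
  cl <- match.call()
  if (inherits(x, "multichannel_signal")) x <- list(x)
  stopifnot(all(vapply(x, inherits, logical(1), "multichannel_signal")))
  if (is.null(labels))
    labels <- vapply(x, function(s) as.character(s$label %||% NA_character_),
                     character(1))
  if (anyNA(labels)) stop("every recording needs a label")

  # phase 1: windows and the frozen state-space embedding
  windows <- list(); win_labels <- character(); groups <- character()
  for (i in seq_along(x)) {
    w <- window_signal(x[[i]], window_s = window_s, overlap = overlap)
    windows <- c(windows, w)
    win_labels <- c(win_labels, rep(labels[i], length(w)))
    groups <- c(groups, rep(x[[i]]$id %||% sprintf("rec%03d", i),
                            length(w)))
  }
  pooled <- do.call(rbind, lapply(windows, function(w) t(w$data)))
  set.seed(seed)
  fit_rows <- if (nrow(pooled) > tess_max_points)
    sort(sample(nrow(pooled), tess_max_points)) else seq_len(nrow(pooled))
  cfg <- embedding
  cfg$seed <- seed
  embedder <- fit_embedder(pooled[fit_rows, , drop = FALSE], cfg)
  trajs <- lapply(windows, function(w) embedder$transform(t(w$data)))
  states <- do.call(rbind, trajs)

  # phase 2: tessellation, arrangement, HRQA features
  set.seed(seed + 1L)
  st_rows <- if (nrow(states) > tess_max_points)
    sort(sample(nrow(states), tess_max_points)) else seq_len(nrow(states))
  if (is.null(K)) {
    selK <- select_num_subspaces(states[st_rows, , drop = FALSE],
                                 k_min = k_range[1], k_max = k_range[2],
                                 seed = seed)
    K <- selK$k
  } else selK <- NULL
  tess <- fit_tessellation(states[st_rows, , drop = FALSE], K, seed = seed)
  params <- fractal_params(K, tau)
  opt <- NULL
  if (arrangement == "optimize") {
    pooled_sym <- symbolize(states[seq_len(min(nrow(states),
                                               ga_max_symbols)), ,
                                   drop = FALSE], tess)
    ga$seed <- seed
    opt <- optimize_labels(pooled_sym, params, ga)
    tess$arrangement <- opt$arrangement
  }
  features <- t(vapply(trajs, function(tr) {
    sym <- symbolize(tr, tess)
    feature_vector(sym, K = K, max_level = max_level, B = B, hrr = hrr,
                   params = params)
  }, numeric(7 * sum(K^(0:max_level)))))

  # phase 3: selection and one-vs-all ensembles
  classes <- sort(unique(win_labels))
  sel <- NULL
  if (select) {
    sel <- lapply(stats::setNames(classes, classes), function(cc)
      lasso_select(features, win_labels, cc, runs = selection_runs,
                   stability = stability, seed = seed))
    sel <- lapply(sel, function(s)
      if (length(s$selected) == 0) colnames(features) else s)
  }
  models <- train_ova(features, win_labels, selection = sel,
                      method = method, grid = grid, preset = preset,
                      cv_folds = cv_folds, seed = seed)

  structure(list(call = cl, embedding = cfg, embedder = embedder,
                 window_s = window_s, overlap = overlap,
                 example_symbols = symbolize(trajs[[1]], tess),
                 tessellation = tess, params = params,
                 subspace_selection = selK, optimization = opt,
                 max_level = max_level, B = B, hrr = hrr,
                 features = features, labels = win_labels, groups = groups,
                 selection = sel, models = models, classes = classes,
                 seed = seed),
            class = "mhra")
}

#' @export
print.mhra <- function(x, ...) {
  cat("Multilevel heterogeneous recurrence analysis model\n\n")
  cat("Call: "); print(x$call)
  cat(sprintf("\n%d training windows (%d classes: %s)\n",
              nrow(x$features), length(x$classes),
              paste(x$classes, collapse = ", ")))
  cat(sprintf("embedding: %s to %d dims; K = %d subspaces; tau = %g (alpha = %.4f)\n",
              x$embedding$method, x$embedding$n_dims, x$params$K,
              x$params$tau, x$params$alpha))
  cat(sprintf("%d HRQA features per window (levels 0..%d); classifier: %s\n",
              ncol(x$features), x$max_level, x$models$method))
  invisible(x)
}

#' Summarize a fitted MHRA model
#'
#' @param object A fitted `"mhra"` object.
#' @param ... Unused.
#' @return `object`, invisibly, after printing a summary of the state
#'   space, arrangement optimization, and feature selection.
#' @export
summary.mhra <- function(object, ...) {
  print(object)
  if (!is.null(object$optimization))
    cat(sprintf("\narrangement optimized: fractal dimension %.4f after %d generations\n",
                object$optimization$fitness,
                object$optimization$generations))
  if (!is.null(object$selection)) {
    cat("\nfeatures retained by stability selection:\n")
    for (cl in object$classes) {
      s <- object$selection[[cl]]
      n <- if (inherits(s, "selection_report")) length(s$selected)
           else length(s)
      cat(sprintf("  %-12s %d\n", cl, n))
    }
  }
  cat("\nclass distribution of training windows:\n")
  print(table(object$labels))
  invisible(object)
}

#' Predict emotions/classes for new recordings
#'
#' Applies the frozen embedding, tessellation and label arrangement to new
#' recordings, extracts their multilevel HRQA feature vectors, and scores
#' them with the fitted one-vs-all ensembles.
#'
#' @param object A fitted `"mhra"` object.
#' @param newdata A [multichannel_signal()] or list of them.
#' @param type `"class"` (argmax over per-class scores), `"score"` (the
#'   per-class score matrix) or `"features"` (the HRQA feature matrix).
#' @param ... Unused.
#' @return A data frame with one row per window (`group`, `label` if known,
#'   `predicted`), or the requested matrix for `type != "class"`.
#' @export
predict.mhra <- function(object, newdata,
                         type = c("class", "score", "features"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "multichannel_signal")) newdata <- list(newdata)
  windows <- list(); labs <- character(); grp <- character()
  for (i in seq_along(newdata)) {
    w <- window_signal(newdata[[i]], window_s = object$window_s,
                       overlap = object$overlap)
    windows <- c(windows, w)
    labs <- c(labs, rep(as.character(newdata[[i]]$label %||% NA_character_),
                        length(w)))
    grp <- c(grp, rep(newdata[[i]]$id %||% sprintf("new%03d", i),
                      length(w)))
  }
  K <- object$params$K
  features <- t(vapply(windows, function(w) {
    tr <- object$embedder$transform(t(w$data))
    sym <- symbolize(tr, object$tessellation)
    feature_vector(sym, K = K, max_level = object$max_level, B = object$B,
                   hrr = object$hrr, params = object$params)
  }, numeric(7 * sum(K^(0:object$max_level)))))
  if (type == "features") return(features)
  scores <- predict(object$models, features, type = "score")
  if (type == "score") return(scores)
  data.frame(group = grp, label = labs,
             predicted = object$classes[max.col(scores,
                                                ties.method = "first")],
             stringsAsFactors = FALSE)
}

#' Plot the fractal encoding of a fitted MHRA model
#'
#' Scatter plot of the chaos-game addresses of the first training window —
#' the fractal whose multilevel cluster geometry the HRQA metrics quantify.
#'
#' @param x A fitted `"mhra"` object.
#' @param ... Passed to [plot.fractal_embedding()].
#' @return `x`, invisibly.
#' @export
plot.mhra <- function(x, ...) {
  emb <- ifs_project(x$example_symbols, x$params)
  plot(emb, main = sprintf("chaos-game encoding, K = %d", x$params$K), ...)
  invisible(x)
}
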