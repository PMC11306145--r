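#' Contraction factor of the chaos-game encoding
#'
#' The iterated-function-system encoding places one anchor on the unit
#' circle per category and contracts the running address toward it. The
#' contraction factor
#' \deqn{\alpha = \tau \sin(\pi/K) / (1 + \sin(\pi/K))}
#' with `0 < tau < 1` guarantees that the K first-level address clusters
#' (discs of radius `alpha/(1-alpha)` around anchors `2 sin(pi/K)` apart)
#' remain pairwise disjoint, so category membership stays decodable from
#' the fractal geometry.
#'
#' @param K Number of categories (>= 2).
#' @param tau Scaling control in (0, 1); default 0.99.
#' @return The contraction factor `alpha` in (0, 1).
#' @examples
#' contraction_factor(45, 0.99)
#' @export
contraction_factor <- function(K, tau = 0.99) {
  if (!is.numeric(K) || K < 2) stop("`K` must be at least 2")
  if (!is.numeric(tau) || tau <= 0 || tau >= 1)
    stop("`tau` must lie strictly between 0 and 1")
  s <- sin(pi / K)
  tau * s / (1 + s)
}

#' Fractal encoding parameters
#'
#' @param K Number of categories.
#' @param tau Scaling control in (0, 1); default 0.99.
#' @return An object of class `"fractal_params"` with `K`, `tau` and the
#'   derived contraction factor `alpha`.
#' @seealso [contraction_factor()]
#' @export
fractal_params <- function(K, tau = 0.99) {
  structure(list(K = as.integer(K), tau = tau,
                 alpha = contraction_factor(K, tau)),
            class = "fractal_params")
}

#' @export
print.fractal_params <- function(x, ...) {
  cat(sprintf("<fractal_params> K = %d, tau = %g, alpha = %.6f\n",
              x$K, x$tau, x$alpha))
  invisible(x)
}

#' Project a symbol sequence into the IFS fractal plane
#'
#' Applies the chaos-game recurrence
#' \deqn{I_t = \alpha I_{t-1} + (\cos 2\pi k_t/K, \sin 2\pi k_t/K), \quad I_0 = (0,0)}
#' so each time point receives a 2-D address that encodes its entire
#' category history: addresses sharing the same last n symbols lie within
#' `2 alpha^n / (1 - alpha)` of each other, which is what makes multilevel
#' transition patterns readable off the fractal.
#'
#' @param symbols A `"symbol_sequence"` or integer vector with values in
#'   `1:K`.
#' @param params A [fractal_params()] object (its `K` must cover the
#'   symbols).
#' @return An object of class `"fractal_embedding"`: `addresses` (`L x 2`
#'   matrix of `(Ix, Iy)`), `params` and the generating `symbols`.
#' @examples
#' p <- fractal_params(4)
#' ifs_project(c(1, 2, 1, 1), p)$addresses
#' @export
ifs_project <- function(symbols, params) {
  stopifnot(inherits(params, "fractal_params"))
  sq <- as_symbols(symbols, K = params$K)
  if (sq$K > params$K || any(sq$symbols > params$K))
    stop("symbol outside 1..K for the given parameters")
  k <- sq$symbols
  theta <- 2 * pi * k / params$K
  # the recurrence is a first-order linear filter driven by the anchors
  Ix <- as.numeric(stats::filter(cos(theta), params$alpha,
                                 method = "recursive"))
  Iy <- as.numeric(stats::filter(sin(theta), params$alpha,
                                 method = "recursive"))
  structure(list(addresses = cbind(Ix = Ix, Iy = Iy), params = params,
                 symbols = sq),
            class = "fractal_embedding")
}

#' @export
print.fractal_embedding <- function(x, ...) {
  cat(sprintf("<fractal_embedding> %d addresses, K = %d, alpha = %.4f\n",
              nrow(x$addresses), x$params$K, x$params$alpha))
  invisible(x)
}

#' @export
plot.fractal_embedding <- function(x, cex = 0.2, pch = 16, asp = 1, ...) {
  graphics::plot(x$addresses, cex = cex, pch = pch, asp = asp,
                 xlab = "Ix", ylab = "Iy", ...)
  invisible(x)
}

#' Box-counting (Minkowski) dimension of a 2-D point cloud
#'
#' Covers the cloud with square boxes of decreasing side length, counts the
#' occupied boxes `xi(eps)` at each scale, and estimates the dimension as
#' the least-squares slope of `log xi` versus `log(1/eps)` over the fitted
#' scale range. The grid is anchored at the bounding-box corner for
#' determinism.
#'
#' @param points An `L x 2` matrix, or a `"fractal_embedding"`.
#' @param epsilons Optional decreasing vector of box side lengths; defaults
#'   to the bounding-square side halved `n_scales` times.
#' @param n_scales Number of default dyadic scales (default 10).
#' @param fit_range Indices of scales entering the regression. The default
#'   `"auto"` keeps scales that are neither trivially coarse (one box) nor
#'   saturated (more than `max_occupancy` boxes per point), since both ends
#'   of the log-log curve flatten and bias the slope.
#' @param max_occupancy Saturation guard for the automatic fit range.
#' @return A list of class `"box_dimension"`: `dimension`, the `(epsilon,
#'   xi)` `table`, and the `fit_range` used. A zero-extent cloud (all
#'   points identical) has dimension 0 by convention.
#' @examples
#' sq <- cbind(runif(5000), runif(5000))
#' box_counting_dimension(sq)$dimension  # close to 2
#' @export
box_counting_dimension <- function(points, epsilons = NULL, n_scales = 10,
                                   fit_range = "auto", max_occupancy = 0.2) {
  pts <- if (inherits(points, "fractal_embedding")) points$addresses
         else as.matrix(points)
  if (nrow(pts) < 10) stop("at least 10 points are required")
  if (ncol(pts) != 2) stop("`points` must be a two-column matrix")
  lo <- apply(pts, 2, min)
  side <- max(apply(pts, 2, max) - lo)
  if (side == 0) {
    tab <- data.frame(epsilon = NA_real_, xi = 1L)
    return(structure(list(dimension = 0, table = tab, fit_range = integer()),
                     class = "box_dimension"))
  }
  if (is.null(epsilons)) epsilons <- side / 2^seq_len(n_scales)
  if (any(epsilons <= 0) || is.unsorted(rev(epsilons), strictly = TRUE))
    stop("`epsilons` must be strictly decreasing and positive")
  xi <- vapply(epsilons, function(eps) {
    nbox <- ceiling(side / eps)
    ix <- pmin(floor((pts[, 1] - lo[1]) / eps), nbox - 1)
    iy <- pmin(floor((pts[, 2] - lo[2]) / eps), nbox - 1)
    length(unique(ix * nbox + iy))
  }, numeric(1))
  n <- length(epsilons)
  if (identical(fit_range, "auto")) {
    keep <- which(xi > 1 & xi <= max_occupancy * nrow(pts))
    if (length(keep) < 3) keep <- if (n > 4) 2:(n - 1) else seq_len(n)
  } else {
    keep <- as.integer(fit_range)
  }
  if (length(keep) < 3)
    stop("fit range must contain at least 3 scales")
  fit <- stats::lm(log(xi[keep]) ~ log(1 / epsilons[keep]))
  structure(list(dimension = unname(stats::coef(fit)[2]),
                 table = data.frame(epsilon = epsilons, xi = xi),
                 fit_range = keep),
            class = "box_dimension")
}

#' @export
print.box_dimension <- function(x, ...) {
  cat(sprintf("<box_dimension> %.4f over %d scales\n",
              x$dimension, nrow(x$table)))
  invisible(x)
}
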