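#' Simulate a canonical dynamical system
#'
#' Generates reference trajectories for exercising the recurrence pipeline:
#' the Lorenz and Roessler attractors (4th-order Runge-Kutta integration
#' via deSolve, transient burn-in discarded) and an i.i.d. Gaussian
#' "random" system. Structured attractors occupy a more distinctive
#' chaos-game fractal than random dynamics, which is the qualitative
#' contrast the package's tests lean on.
#'
#' @param kind `"random"`, `"lorenz"` or `"rossler"`.
#' @param n Number of retained samples (>= 100).
#' @param dt Integration step (default 0.01).
#' @param params Named list of system parameters. Defaults: Lorenz
#'   `sigma = 10, rho = 28, beta = 8/3`; Roessler `a = 0.2, b = 0.2,
#'   c = 5.7`.
#' @param init Initial state (length 3); a small seeded perturbation of
#'   `(1, 1, 1)` by default.
#' @param burn_in Integration steps discarded before sampling (default
#'   1000).
#' @param seed Integer seed.
#' @return A `"trajectory"` with an `n x 3` `states` matrix.
#' @examples
#' tr <- simulate_attractor("lorenz", n = 500, seed = 7)
#' max(abs(tr$states))  # bounded
#' @export
simulate_attractor <- function(kind = c("random", "lorenz", "rossler"),
                               n = 10000, dt = 0.01, params = NULL,
                               init = NULL, burn_in = 1000, seed = 1) {
  kind <- match.arg(kind)
  if (n < 100) stop("`n` must be at least 100")
  if (dt <= 0) stop("`dt` must be positive")
  set.seed(seed)
  if (kind == "random") {
    states <- matrix(stats::rnorm(3 * n), n, 3)
    return(new_trajectory(states, fs = 1 / dt, source = kind))
  }
  if (is.null(init)) init <- c(1, 1, 1) + stats::rnorm(3, sd = 0.1)
  deriv <- switch(kind,
    lorenz = {
      p <- utils::modifyList(list(sigma = 10, rho = 28, beta = 8 / 3),
                             as.list(params))
      function(t, y, parms)
        list(c(p$sigma * (y[2] - y[1]),
               y[1] * (p$rho - y[3]) - y[2],
               y[1] * y[2] - p$beta * y[3]))
    },
    rossler = {
      p <- utils::modifyList(list(a = 0.2, b = 0.2, c = 5.7),
                             as.list(params))
      function(t, y, parms)
        list(c(-y[2] - y[3],
               y[1] + p$a * y[2],
               p$b + y[3] * (y[1] - p$c)))
    })
  times <- seq(0, dt * (burn_in + n - 1), by = dt)
  sol <- deSolve::rk4(y = init, times = times, func = deriv, parms = NULL)
  states <- unname(sol[(burn_in + 1):(burn_in + n), -1, drop = FALSE])
  if (anyNA(states) || any(!is.finite(states)))
    stop("divergent integration: reduce `dt` or check parameters")
  new_trajectory(states, fs = 1 / dt, source = kind)
}

#' Generate labeled surrogate multichannel recordings
#'
#' Builds synthetic multi-lead recordings whose classes differ in their
#' underlying transition dynamics but not in amplitude, emulating the shape
#' of a 62-lead EEG dataset. Each recording mixes (i) the standardized
#' coordinates of a class-specific driving system (an attractor or i.i.d.
#' noise) and (ii) shared band-limited oscillations with random phases,
#' through seeded random mixing matrices, then adds independent Gaussian
#' sensor noise at the requested signal-to-noise ratio. Because mixing
#' matrices and oscillation amplitudes are common across classes, any
#' separability must come from the recurrence structure of the dynamics.
#'
#' @param classes Named list of class specifications; each element is a
#'   list with at least `kind` (passed to [simulate_attractor()]).
#' @param n_per_class Recordings per class.
#' @param n_channels Number of channels (default 62).
#' @param fs Sampling rate in Hz (default 200).
#' @param duration Recording length in seconds.
#' @param osc_freqs Frequencies (Hz) of the shared oscillatory components
#'   (defaults to theta/alpha/beta tones at 6, 10 and 20 Hz).
#' @param snr_db Per-channel signal-to-noise ratio in dB (`Inf` for clean
#'   mixtures).
#' @param seed Integer seed; the whole dataset is deterministic given it.
#' @return A list of [multichannel_signal()] objects with `label` set to
#'   the class name and `id` to a unique recording identifier.
#' @examples
#' recs <- generate_surrogate_eeg(n_per_class = 1, n_channels = 4,
#'                                duration = 2, fs = 100, seed = 1)
#' sapply(recs, function(r) r$label)
#' @export
generate_surrogate_eeg <- function(classes = list(lorenz = list(kind = "lorenz"),
                                                  random = list(kind = "random")),
                                   n_per_class = 5, n_channels = 62,
                                   fs = 200, duration = 60,
                                   osc_freqs = c(6, 10, 20), snr_db = 10,
                                   seed = 1) {
  if (length(classes) < 2) stop("at least 2 classes are required")
  if (is.null(names(classes)) || any(names(classes) == ""))
    stop("`classes` must be a named list")
  if (!is.finite(snr_db) && snr_db != Inf) stop("`snr_db` must be finite or Inf")
  n <- round(fs * duration)
  set.seed(seed)
  # mixing matrices shared across classes: discrimination must come from
  # the dynamics, not from the spatial patterns or amplitudes
  A <- matrix(stats::rnorm(n_channels * 3), n_channels, 3)
  Bmix <- matrix(stats::rnorm(n_channels * length(osc_freqs)),
                 n_channels, length(osc_freqs))
  out <- list()
  rec_seed <- 0L
  for (cl in names(classes)) {
    spec <- classes[[cl]]
    for (r in seq_len(n_per_class)) {
      rec_seed <- rec_seed + 1L
      drive <- simulate_attractor(kind = spec$kind, n = n,
                                  dt = spec$dt %||% 0.01,
                                  params = spec$params,
                                  seed = seed * 1000L + rec_seed)
      Z <- scale(drive$states)            # unit-variance coordinates
      phases <- stats::runif(length(osc_freqs), 0, 2 * pi)
      tgrid <- seq_len(n) / fs
      osc <- vapply(seq_along(osc_freqs),
                    function(i) sin(2 * pi * osc_freqs[i] * tgrid + phases[i]),
                    numeric(n))
      clean <- A %*% t(Z) + Bmix %*% t(osc)
      if (is.finite(snr_db)) {
        sd_noise <- sqrt(apply(clean, 1, stats::var) / 10^(snr_db / 10))
        noise <- matrix(stats::rnorm(n_channels * n), n_channels, n) * sd_noise
        clean <- clean + noise
      }
      out[[length(out) + 1L]] <-
        multichannel_signal(clean, fs = fs, label = cl,
                            id = sprintf("%s_%02d", cl, r))
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
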