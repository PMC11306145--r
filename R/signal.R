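#' Construct a multichannel signal
#'
#' Bundles a channels-by-samples numeric matrix with its sampling rate,
#' channel names and an optional class label. This is the raw-input container
#' used throughout the package (e.g. a 62-lead EEG recording).
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_names Optional character vector, one name per channel.
#' @param label Optional class tag (e.g. an emotion label).
#' @param id Optional recording identifier used for group-aware splitting.
#' @return An object of class `"multichannel_signal"` with elements
#'   `data`, `fs`, `channel_names`, `label`, `id`.
#' @examples
#' x <- multichannel_signal(matrix(rnorm(4 * 100), 4), fs = 100)
#' x
#' @export
multichannel_signal <- function(data, fs, channel_names = NULL, label = NULL,
                                id = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be a numeric matrix")
  if (anyNA(data) || any(!is.finite(data)))
    stop("`data` contains missing or non-finite values")
  if (nrow(data) < 1L) stop("at least one channel is required")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  if (is.null(channel_names)) {
    channel_names <- if (!is.null(rownames(data))) rownames(data)
    else paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data))
    stop("`channel_names` must have one entry per channel")
  structure(
    list(data = data, fs = fs, channel_names = channel_names,
         label = label, id = id),
    class = "multichannel_signal"
  )
}

#' @export
print.multichannel_signal <- function(x, ...) {
  cat(sprintf("<multichannel_signal> %d channels x %d samples @ %g Hz",
              nrow(x$data), ncol(x$data), x$fs))
  if (!is.null(x$label)) cat(sprintf("  label: %s", x$label))
  if (!is.null(x$id)) cat(sprintf("  id: %s", x$id))
  cat("\n")
  invisible(x)
}

#' Split a signal into fixed-length windows
#'
#' Cuts a recording into windows of `window_s` seconds, optionally
#' overlapping. Any trailing remainder shorter than one window is dropped.
#'
#' @param signal A [multichannel_signal()].
#' @param window_s Window length in seconds (default 20, matching the
#'   windowing used for EEG feature extraction).
#' @param overlap Fraction of overlap between consecutive windows in
#'   `[0, 1)`; 0 gives contiguous non-overlapping windows.
#' @return A list of `multichannel_signal` windows inheriting `fs`, `label`
#'   and `id` from the parent recording.
#' @examples
#' x <- multichannel_signal(matrix(rnorm(2 * 1200), 2), fs = 20)
#' length(window_signal(x, window_s = 20))  # 3 windows
#' @export
window_signal <- function(signal, window_s = 20, overlap = 0) {
  stopifnot(inherits(signal, "multichannel_signal"))
  if (!is.numeric(window_s) || window_s <= 0) stop("`window_s` must be > 0")
  if (!is.numeric(overlap) || overlap < 0 || overlap >= 1)
    stop("`overlap` must be in [0, 1)")
  w <- round(signal$fs * window_s)
  n <- ncol(signal$data)
  if (n < w) stop("signal shorter than one window")
  step <- max(1L, round(w * (1 - overlap)))
  starts <- seq.int(1L, n - w + 1L, by = step)
  lapply(starts, function(s) {
    multichannel_signal(signal$data[, s:(s + w - 1L), drop = FALSE],
                        fs = signal$fs, channel_names = signal$channel_names,
                        label = signal$label, id = signal$id)
  })
}
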