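#' Read a multichannel signal from delimited text
#'
#' @param path CSV/TSV file of numbers.
#' @param fs Sampling rate in Hz.
#' @param orientation `"channels_x_samples"` (canonical) or
#'   `"samples_x_channels"` (transposed on read).
#' @param header Does the file carry a header row?
#' @param sep Field separator (`","` default; use `"\t"` for TSV).
#' @param label,id Optional class tag and recording identifier.
#' @return A [multichannel_signal()].
#' @export
read_signal_csv <- function(path, fs,
                            orientation = c("channels_x_samples",
                                            "samples_x_channels"),
                            header = FALSE, sep = ",", label = NULL,
                            id = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  m <- as.matrix(utils::read.table(path, header = header, sep = sep))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at row %d, column %d of %s",
                 bad[1], bad[2], path))
  }
  if (orientation == "samples_x_channels") m <- t(m)
  multichannel_signal(unname(m), fs = fs, label = label, id = id)
}

#' Write a trajectory as CSV
#'
#' Columns: `t` (sample index) then `x1..xd`.
#'
#' @param traj A `"trajectory"` (or `T x d` matrix).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  st <- as_state_matrix(traj)
  df <- data.frame(t = seq_len(nrow(st)), st)
  colnames(df) <- c("t", paste0("x", seq_len(ncol(st))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a symbol sequence as CSV
#'
#' @param symbols A `"symbol_sequence"` or integer vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_symbols_csv <- function(symbols, path) {
  sq <- as_symbols(symbols)
  utils::write.csv(data.frame(t = seq_len(sq$L), symbol = sq$symbols),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a feature matrix with a provenance sidecar
#'
#' The features go to `path` as CSV (window metadata columns first); a JSON
#' sidecar `<path>.json` records the parameters that produced them (K, tau,
#' alpha, B, conventions, arrangement, seeds) for full provenance.
#'
#' @param features Numeric matrix with named HRQA columns.
#' @param path Output CSV path.
#' @param labels,groups Optional per-row metadata columns.
#' @param meta Named list stored in the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path, labels = NULL, groups = NULL,
                               meta = list()) {
  df <- as.data.frame(features, check.names = FALSE)
  if (!is.null(groups)) df <- cbind(group = groups, df)
  if (!is.null(labels)) df <- cbind(label = labels, df)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Convert a delimited signal file to the canonical layout
#'
#' Reads a delimited numeric matrix, optionally transposes it to the
#' canonical channels-by-samples layout, rejects missing values with the
#' offending location, and writes the canonical CSV plus a JSON manifest
#' (orientation, sampling rate, channel names, content hash).
#'
#' @param input Input delimited file.
#' @param out Output CSV path; the manifest goes to `<out>.json`.
#' @param transpose Set when the input is samples-by-channels.
#' @param fs Sampling rate recorded in the manifest.
#' @param sep Field separator of the input.
#' @param header Does the input carry a header row?
#' @return `out`, invisibly.
#' @export
convert_signal <- function(input, out, transpose = FALSE, fs = NA_real_,
                           sep = ",", header = FALSE) {
  if (!file.exists(input)) stop(sprintf("file not found: %s", input))
  m <- as.matrix(utils::read.table(input, header = header, sep = sep))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at row %d, column %d of %s",
                 bad[1], bad[2], input))
  }
  if (transpose) m <- t(m)
  utils::write.table(m, out, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  manifest <- list(orientation = "channels_x_samples", fs = fs,
                   n_channels = nrow(m), n_samples = ncol(m),
                   channel_names = paste0("ch", seq_len(nrow(m))),
                   content_hash = unname(tools::md5sum(out)))
  jsonlite::write_json(manifest, paste0(out, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out)
}

default_run_config <- function() {
  list(
    window_s = 20, overlap = 0,
    embedding_method = "umap", n_dims = 4, n_neighbors = 5,
    min_dist = 0.1, spread = 1.0,
    k_min = 10, k_max = 100, K = NULL,
    tau = 0.99, B = 10, hrr = "squared", max_level = 2,
    ga_pool = 200, ga_iter = 100, ga_pm = 0.1, ga_slt = NULL,
    selection_runs = 30, stability = 1.0,
    method = "xgboost", preset = "desk", split = 0.9, repeats = 30,
    cv_folds = 10, seed = 1
  )
}

validate_run_config <- function(cfg) {
  check <- function(ok, key, msg)
    if (!ok) stop(sprintf("invalid config value for `%s`: %s", key, msg),
                  call. = FALSE)
  check(cfg$tau > 0 && cfg$tau < 1, "tau", "must lie strictly in (0, 1)")
  check(cfg$window_s > 0, "window_s", "must be positive")
  check(cfg$overlap >= 0 && cfg$overlap < 1, "overlap", "must be in [0, 1)")
  check(cfg$n_dims >= 2, "n_dims", "must be at least 2")
  check(cfg$B >= 2, "B", "must be at least 2")
  check(cfg$max_level >= 0, "max_level", "must be non-negative")
  check(cfg$stability > 0 && cfg$stability <= 1, "stability",
        "must be in (0, 1]")
  check(cfg$split > 0 && cfg$split < 1, "split", "must be in (0, 1)")
  check(cfg$hrr %in% c("squared", "as_printed", "proportion"), "hrr",
        "unknown convention")
  check(cfg$embedding_method %in% c("umap", "pca", "isomap", "spectral",
                                    "tsne", "lle"),
        "embedding_method", "unknown method")
  invisible(cfg)
}

#' Load and validate a YAML run configuration
#'
#' Reads a YAML file of pipeline settings, fills every missing key with its
#' documented default (an empty file therefore yields the full default
#' configuration: 20-s windows, tau = 0.99, 4 embedding dimensions, B = 10
#' histogram bins, ...), rejects unknown keys, and bounds-checks each value
#' with an error naming the offending key. Provenance (package version,
#' timestamp and a hash of the resolved settings) is attached as
#' attributes so the YAML fields round-trip unchanged.
#'
#' @param path YAML file (may be empty).
#' @return A named list of class `"run_config"`.
#' @seealso [write_run_config()]
#' @export
load_validate_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- default_run_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, user, keep.null = TRUE)
  validate_run_config(cfg)
  tmp <- tempfile()
  yaml::write_yaml(cfg, tmp)
  structure(cfg,
            class = c("run_config", "list"),
            version = as.character(utils::packageVersion("mhra")),
            timestamp = format(Sys.time(), tz = "UTC"),
            config_hash = unname(tools::md5sum(tmp)))
}

#' Write a run configuration to YAML
#'
#' @param cfg A `"run_config"` (or plain named list).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  attributes(cfg) <- list(names = names(cfg))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
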