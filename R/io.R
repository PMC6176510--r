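#' Read a multichannel recording
#'
#' CSV recordings are samples x channels with a header row of channel names.
#' The sampling rate comes from `sampling_rate`, or from a
#' `<path>.rate` sidecar containing a single number.  Seizure intervals are
#' read from an optional CSV sidecar with columns
#' `recording_id, start_sample, end_sample` (half-open, 0-based).
#'
#' @param path Signal file path.
#' @param format `"csv"` or `"edf"` (EDF requires an external reader, not
#'   bundled; requesting it raises an informative error).
#' @param intervals_path Optional seizure-interval sidecar CSV.
#' @param sampling_rate Sampling rate in Hz; required for CSV unless the
#'   `.rate` sidecar exists.
#' @return A [recording()].
#' @export
read_recording <- function(path, format = c("csv", "edf"),
                           intervals_path = NULL, sampling_rate = NULL) {
  format <- match.arg(format)
  if (format == "edf")
    stop("EDF reader unavailable: no EDF backend is installed; ",
         "convert to CSV (samples x channels with header)")
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("recording needs a header and data rows")
  header <- gsub("^\"|\"$", "", strsplit(lines[1L], ",", fixed = TRUE)[[1L]])
  n_ch <- length(header)
  rows <- strsplit(lines[-1L], ",", fixed = TRUE)
  widths <- lengths(rows)
  if (any(widths != n_ch))
    stop(sprintf("ragged CSV: row %d has %d fields, expected %d",
                 which(widths != n_ch)[1L] + 1L,
                 widths[widths != n_ch][1L], n_ch))
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop(sprintf("non-numeric cell in data row %d", (bad - 1L) %/% n_ch + 2L))
  }
  # file rows are samples, so the row-major unlist is column-major
  # channels x samples
  signal <- matrix(vals, nrow = n_ch)
  rownames(signal) <- header
  if (is.null(sampling_rate)) {
    rate_file <- paste0(path, ".rate")
    if (file.exists(rate_file)) {
      sampling_rate <- as.numeric(readLines(rate_file)[1L])
    } else {
      stop("missing sampling rate: pass sampling_rate= or provide ", rate_file)
    }
  }
  intervals <- data.frame(start = integer(0), end = integer(0))
  if (!is.null(intervals_path)) {
    iv <- utils::read.csv(intervals_path)
    intervals <- data.frame(start = as.integer(iv$start_sample),
                            end = as.integer(iv$end_sample))
  }
  recording(signal, sampling_rate, intervals)
}

#' Write a recording to CSV
#'
#' Samples x channels with a channel-name header, plus a `.rate` sidecar and,
#' when intervals are present, an `_intervals.csv` sidecar.
#'
#' @param rec A [recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  df <- as.data.frame(t(rec$signal))
  names(df) <- rownames(rec$signal) %||% paste0("ch", seq_len(nrow(rec$signal)))
  utils::write.csv(df, path, row.names = FALSE)
  writeLines(format(rec$sampling_rate), paste0(path, ".rate"))
  if (nrow(rec$seizure_intervals) > 0L) {
    iv <- data.frame(recording_id = basename(path),
                     start_sample = rec$seizure_intervals$start,
                     end_sample = rec$seizure_intervals$end)
    utils::write.csv(iv, sub("\\.csv$", "_intervals.csv", path),
                     row.names = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a feature archive
#'
#' Serializes synchronization-matrix features, labels, channel names and a
#' configuration fingerprint to a single binary archive (RDS).
#'
#' @param path Output path.
#' @param features Windows x n^2 feature matrix.
#' @param labels 0/1 vector.
#' @param channel_names Channel labels.
#' @param fingerprint Named list describing how the features were computed
#'   (window size, AP settings, ...).
#' @return `path`, invisibly.
#' @export
write_features <- function(path, features, labels, channel_names,
                           fingerprint = list()) {
  stopifnot(nrow(features) == length(labels))
  saveRDS(list(features = features, labels = labels,
               channel_names = channel_names, fingerprint = fingerprint),
          path)
  invisible(path)
}

#' Read a feature archive
#'
#' @param path Archive written by [write_features()].
#' @param expect_fingerprint Optional fingerprint to compare against; any
#'   mismatch logs a warning (the archive is still returned).
#' @return List with `features`, `labels`, `channel_names`, `fingerprint`.
#' @export
read_features <- function(path, expect_fingerprint = NULL) {
  obj <- readRDS(path)
  if (!is.null(expect_fingerprint) &&
      !identical(obj$fingerprint[names(expect_fingerprint)],
                 expect_fingerprint))
    warning("feature archive fingerprint mismatch: archive was computed ",
            "with different settings")
  obj
}

#' Write a synchronization matrix to CSV
#'
#' Square numeric CSV with channel names as header row and first column.
#'
#' @param sync A `sync_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sync_matrix <- function(sync, path) {
  df <- as.data.frame(sync$values)
  names(df) <- sync$channel_names
  utils::write.csv(cbind(channel = sync$channel_names, df), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a synchronization matrix from CSV
#'
#' @param path CSV written by [write_sync_matrix()].
#' @return A `sync_matrix`.
#' @export
read_sync_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  ch <- as.character(df[[1L]])
  values <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(values) <- list(ch, ch)
  structure(list(values = values, n = length(ch), channel_names = ch),
            class = "sync_matrix")
}

#' Serialize trained classifier parameters
#'
#' @param params A `clfcnn_params`.
#' @param path Output path (RDS archive of shapes, flat arrays and config).
#' @return `path`, invisibly.
#' @export
write_model <- function(params, path) {
  saveRDS(params, path)
  invisible(path)
}

#' Load classifier parameters written by [write_model()]
#'
#' @param path Archive path.
#' @return A `clfcnn_params`.
#' @export
read_model <- function(path) {
  readRDS(path)
}
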