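# Record containers and I/O: single-lead ECG traces, 6-axis IMU streams,
# rate conversion, fixed-length windowing and per-sample label expansion.

#' Working sampling rate for all models (Hz)
#'
#' Every model in the package operates at 250 Hz; records at other rates must
#' be passed through [resample_ecg()] first.
#' @export
WORKING_FS <- 250

#' Single-lead ECG record
#'
#' @param samples Numeric vector of voltages in mV.
#' @param fs Sampling rate in Hz (> 0).
#' @param lead Lead label, e.g. `"V2"` or `"MLV2"`.
#' @param beat_labels Optional data.frame with columns `index` (0-based sample
#'   index of the R-peak) and `cls` (annotation symbol, e.g. `"N"`, `"V"`,
#'   `"S"`, `"F"`). Indices must be strictly increasing and within the record.
#' @param rhythm_label Optional record-level diagnosis class (e.g. `"MI"`).
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, lead = "V2", beat_labels = NULL,
                       rhythm_label = NULL) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (any(!is.finite(samples)))
    stop("samples must all be finite")
  if (!is.null(beat_labels)) {
    beat_labels <- as.data.frame(beat_labels)
    stopifnot(all(c("index", "cls") %in% names(beat_labels)))
    beat_labels$index <- as.integer(beat_labels$index)
    beat_labels$cls <- as.character(beat_labels$cls)
    if (nrow(beat_labels)) {
      if (any(diff(beat_labels$index) <= 0))
        stop("beat indices must be strictly increasing")
      if (any(beat_labels$index < 0L | beat_labels$index >= length(samples)))
        stop("beat index out of range")
    }
  }
  structure(list(samples = samples, fs = fs, lead = lead,
                 beat_labels = beat_labels, rhythm_label = rhythm_label),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples @ %g Hz (%.1f s), lead %s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$lead))
  if (!is.null(x$beat_labels))
    cat(sprintf("  %d annotated beats\n", nrow(x$beat_labels)))
  if (!is.null(x$rhythm_label))
    cat(sprintf("  rhythm label: %s\n", x$rhythm_label))
  invisible(x)
}

#' Six-axis IMU record
#'
#' @param acc n-by-3 matrix of accelerations (m s^-2).
#' @param gyro n-by-3 matrix of angular velocities (deg s^-1).
#' @param fs Sampling rate in Hz.
#' @param activity Optional activity class label.
#' @return An object of class `imu_record`.
#' @export
imu_record <- function(acc, gyro, fs, activity = NULL) {
  acc <- as.matrix(acc); gyro <- as.matrix(gyro)
  if (ncol(acc) != 3L || ncol(gyro) != 3L)
    stop("acc and gyro must each have 3 columns")
  if (nrow(acc) != nrow(gyro))
    stop("acc and gyro must have equal length")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  colnames(acc) <- c("ax", "ay", "az")
  colnames(gyro) <- c("gx", "gy", "gz")
  structure(list(acc = acc, gyro = gyro, fs = fs, activity = activity),
            class = "imu_record")
}

#' @export
print.imu_record <- function(x, ...) {
  cat(sprintf("<imu_record> %d samples @ %g Hz (%.1f s)%s\n",
              nrow(x$acc), x$fs, nrow(x$acc) / x$fs,
              if (is.null(x$activity)) "" else paste0(", activity: ", x$activity)))
  invisible(x)
}

#' Annotation class scheme
#'
#' The 9-class per-sample label space used by the segmentation network:
#' 0 background/normal, 1 MI, 2 HF, 3 AR (record-level rhythm classes),
#' 4 FB, 5 SVEB, 6 VEB, 7 paced/other-ectopic (beat classes), 8 unknown/noise.
#' Classes 7 and 8 round out the 9-dimensional output; only the first seven
#' are produced by the synthetic generator.
#'
#' @return Named integer vector mapping class name to index.
#' @export
ecg_class_scheme <- function() {
  c(background = 0L, MI = 1L, HF = 2L, AR = 3L, FB = 4L,
    SVEB = 5L, VEB = 6L, paced = 7L, unknown = 8L)
}

# Beat annotation symbols -> scheme class names. "N" stays background: normal
# beats do not claim samples away from a record-level rhythm class.
beat_symbol_map <- function() {
  c(N = "background", L = "background", R = "background",
    V = "VEB", E = "VEB", S = "SVEB", A = "SVEB", a = "SVEB", J = "SVEB",
    F = "FB", `/` = "paced", f = "paced", Q = "unknown", `?` = "unknown")
}

#' Read an ECG record from CSV or WFDB
#'
#' CSV dialect: one header line, columns `time_s,voltage_mV`; an optional
#' label sidecar `<path>.labels.csv` with columns `sample_index,symbol` is
#' mapped onto `beat_labels`. WFDB records (`.hea`/`.dat`, formats 16 and 212)
#' keep their native sampling rate; `.atr` annotations, when present, are
#' mapped onto `beat_labels` with unknown symbols recorded as `"unknown"`.
#'
#' @param path Path to the `.csv` file or the WFDB record prefix (with or
#'   without `.hea`).
#' @param format `"auto"` (by extension), `"csv"` or `"wfdb"`.
#' @param channel Signal channel to extract from multi-lead WFDB records.
#' @return An [ecg_record()].
#' @export
read_ecg <- function(path, format = c("auto", "csv", "wfdb"), channel = 1L) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path)) "csv" else "wfdb"
  if (format == "csv") read_ecg_csv(path) else read_wfdb(path, channel)
}

read_ecg_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  d <- read.csv(path)
  if (!all(c("time_s", "voltage_mV") %in% names(d)))
    stop("CSV must have columns time_s,voltage_mV")
  dt <- diff(d$time_s)
  fs <- 1 / median(dt)
  beats <- NULL
  sidecar <- paste0(sub("\\.csv$", "", path), ".labels.csv")
  if (file.exists(sidecar)) {
    lab <- read.csv(sidecar)
    beats <- data.frame(index = as.integer(lab$sample_index),
                        cls = as.character(lab$symbol))
  }
  ecg_record(d$voltage_mV, fs = round(fs, 6), beat_labels = beats)
}

#' Write an ECG record to CSV (plus label sidecar)
#'
#' @param rec An [ecg_record()].
#' @param path Output `.csv` path; beats go to `<path>.labels.csv`.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(rec, path) {
  n <- length(rec$samples)
  d <- data.frame(time_s = (seq_len(n) - 1) / rec$fs,
                  voltage_mV = rec$samples)
  write.csv(d, path, row.names = FALSE)
  if (!is.null(rec$beat_labels) && nrow(rec$beat_labels)) {
    write.csv(data.frame(sample_index = rec$beat_labels$index,
                         symbol = rec$beat_labels$cls),
              paste0(sub("\\.csv$", "", path), ".labels.csv"),
              row.names = FALSE)
  }
  invisible(path)
}

#' Resample an ECG record
#'
#' Polyphase FIR resampling (anti-aliasing on downsampling) via
#' [signal::resample()]. Beat indices are rescaled by the same rate ratio.
#'
#' @param rec An [ecg_record()].
#' @param fs_target Target rate in Hz.
#' @return A new [ecg_record()] at `fs_target`.
#' @export
resample_ecg <- function(rec, fs_target) {
  stopifnot(inherits(rec, "ecg_record"), fs_target > 0)
  if (length(rec$samples) == 0L) stop("cannot resample an empty record")
  if (isTRUE(all.equal(fs_target, rec$fs))) return(rec)
  pq <- rational_ratio(fs_target / rec$fs)
  y <- signal::resample(rec$samples, p = pq[1], q = pq[2])
  n_out <- round(length(rec$samples) * fs_target / rec$fs)
  if (length(y) > n_out) y <- y[seq_len(n_out)]
  if (length(y) < n_out) y <- c(y, rep(y[length(y)], n_out - length(y)))
  beats <- rec$beat_labels
  if (!is.null(beats) && nrow(beats)) {
    beats$index <- pmin(as.integer(round(beats$index * fs_target / rec$fs)),
                        n_out - 1L)
    beats <- beats[!duplicated(beats$index), , drop = FALSE]
  }
  ecg_record(y, fs = fs_target, lead = rec$lead, beat_labels = beats,
             rhythm_label = rec$rhythm_label)
}

# Best small-denominator rational approximation to x (continued fractions).
rational_ratio <- function(x, max_den = 10000L) {
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L; r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < 1e-12) break
    if (abs(r - a) < 1e-12) break
    r <- 1 / (r - a)
  }
  c(as.integer(p1), as.integer(q1))
}

#' Expand beat and rhythm labels into a per-sample class vector
#'
#' Each annotated non-normal beat paints its class over a symmetric
#' neighborhood of ±300 ms around the R-peak; a record-level rhythm class
#' paints every sample not claimed by a beat class; everything else is
#' background. Precedence: beat class > rhythm class > background.
#'
#' @param rec An [ecg_record()] at any rate.
#' @param class_scheme Named integer map from class name to index; see
#'   [ecg_class_scheme()].
#' @param neighborhood_ms Half-width of the painted beat neighborhood (ms).
#' @return Integer vector of class indices, one per sample.
#' @export
expand_labels <- function(rec, class_scheme = ecg_class_scheme(),
                          neighborhood_ms = 300) {
  n <- length(rec$samples)
  y <- rep(class_scheme[["background"]], n)
  if (!is.null(rec$rhythm_label)) {
    if (!rec$rhythm_label %in% names(class_scheme))
      stop("unmapped rhythm symbol: ", rec$rhythm_label)
    y[] <- class_scheme[[rec$rhythm_label]]
  }
  beats <- rec$beat_labels
  if (!is.null(beats) && nrow(beats)) {
    half <- as.integer(round(neighborhood_ms / 1000 * rec$fs))
    smap <- beat_symbol_map()
    for (i in seq_len(nrow(beats))) {
      sym <- beats$cls[i]
      cls_name <- if (sym %in% names(smap)) smap[[sym]]
        else if (sym %in% names(class_scheme)) sym
        else stop("unmapped annotation symbol: ", sym)
      if (cls_name == "background") next
      lo <- max(0L, beats$index[i] - half)
      hi <- min(n - 1L, beats$index[i] + half)
      y[(lo + 1L):(hi + 1L)] <- class_scheme[[cls_name]]
    }
  }
  as.integer(y)
}

#' Cut a record into fixed-length labeled windows
#'
#' Windows are half-open sample ranges `[start, start + L)` with
#' `L = win_s * fs`; the trailing partial window is dropped. With the default
#' 8 s at 250 Hz each window holds 2000 samples. The per-sample label vector
#' comes from [expand_labels()].
#'
#' @param rec An [ecg_record()] at the working rate.
#' @param win_s Window length in seconds.
#' @param stride_s Stride in seconds (defaults to `win_s`: non-overlapping).
#' @param class_scheme Label map passed to [expand_labels()].
#' @return List of `labeled_window` objects, each `list(x, y)` with equal
#'   lengths.
#' @export
make_windows <- function(rec, win_s = 8, stride_s = win_s,
                         class_scheme = ecg_class_scheme()) {
  stopifnot(inherits(rec, "ecg_record"))
  L <- as.integer(round(win_s * rec$fs))
  step <- as.integer(round(stride_s * rec$fs))
  n <- length(rec$samples)
  if (n < L) {
    warning("record shorter than one window; returning empty list")
    return(list())
  }
  y_all <- expand_labels(rec, class_scheme)
  starts <- seq(0L, n - L, by = step)
  lapply(starts, function(s) {
    idx <- (s + 1L):(s + L)
    structure(list(x = rec$samples[idx], y = y_all[idx], start = s),
              class = "labeled_window")
  })
}

#' Write / read a window dataset cache
#'
#' Plain-text cache of a labeled window set: `x.csv` (one window per row),
#' `y.csv` (integer labels, same shape) and `meta.json` (fs, class names,
#' optional per-window group labels).
#'
#' @param ds Dataset list with fields `x` (n-by-L numeric matrix), `y`
#'   (n-by-L integer matrix), `fs`, `class_names`, and optionally `group`.
#' @param dir Directory to write into (created if needed).
#' @return `dir`, invisibly (writer); the dataset list (reader).
#' @export
write_window_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(ds$x, file.path(dir, "x.csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  write.table(ds$y, file.path(dir, "y.csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  meta <- list(fs = ds$fs, class_names = ds$class_names)
  if (!is.null(ds$group)) meta$group <- ds$group
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_window_dataset
#' @export
read_window_dataset <- function(dir) {
  x <- as.matrix(read.csv(file.path(dir, "x.csv"), header = FALSE))
  y <- as.matrix(read.csv(file.path(dir, "y.csv"), header = FALSE))
  dimnames(x) <- dimnames(y) <- NULL
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  out <- list(x = x, y = matrix(as.integer(y), nrow(y), ncol(y)),
              fs = meta$fs, class_names = meta$class_names)
  if (!is.null(meta$group)) out$group <- meta$group
  out
}

#' Read / write an IMU record as CSV
#'
#' Columns `t,ax,ay,az,gx,gy,gz` with one header line.
#' @param path CSV path.
#' @param rec An [imu_record()].
#' @return An [imu_record()] (reader); `path` invisibly (writer).
#' @export
read_imu_csv <- function(path) {
  d <- read.csv(path)
  fs <- 1 / median(diff(d$t))
  imu_record(as.matrix(d[, c("ax", "ay", "az")]),
             as.matrix(d[, c("gx", "gy", "gz")]), fs = round(fs, 6))
}

#' @rdname read_imu_csv
#' @export
write_imu_csv <- function(rec, path) {
  n <- nrow(rec$acc)
  d <- data.frame(t = (seq_len(n) - 1) / rec$fs, rec$acc, rec$gyro)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
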