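# End-to-end monitoring loop: fuse ECG vitals, beat annotations and activity
# classification into one timestamped event per 8 s window, with debounced
# alert flags. Runs in deterministic replay mode over recorded (or synthetic)
# streams; the same inputs and checkpoints always produce byte-identical
# session logs.

#' Run the streaming monitor over time-aligned ECG and IMU sources
#'
#' Emits one event per 8 s ECG window: mean heart rate and latest
#' respiratory-rate estimate in the window, beat annotations (when an
#' annotation model is supplied), the dominant activity class (when an
#' activity model and IMU stream are supplied), and alert flags.
#' `abnormal_beat` is raised when a beat in the window is annotated
#' FB/SVEB/VEB; `fall` when a fall is classified. Alerts are debounced: one
#' alert per contiguous run of abnormal windows.
#'
#' @param ecg An [ecg_record()] at 250 Hz.
#' @param imu Optional [imu_record()] aligned to the same clock.
#' @param models List with optional entries `annotation` (`ecg_seq2seq`) and
#'   `activity` (`activity_resnet`).
#' @param win_s Event cadence in seconds.
#' @param out Optional path; events are appended as JSON lines.
#' @return Data.frame of events: `t` (window end, s), `hr`, `rr`,
#'   `n_beats`, `beat_classes`, `activity`, `alerts`.
#' @export
run_monitor <- function(ecg, imu = NULL, models = list(), win_s = 8,
                        out = NULL) {
  stopifnot(inherits(ecg, "ecg_record"))
  if (abs(ecg$fs - WORKING_FS) > 1e-9)
    stop("monitor requires ECG at ", WORKING_FS, " Hz")
  dur <- length(ecg$samples) / ecg$fs
  n_win <- floor(dur / win_s)
  if (n_win < 1) stop("need at least one full window")

  beats <- suppressWarnings(detect_qrs(ecg))
  hr_series <- if (nrow(beats) >= 3) estimate_hr(beats) else NULL
  rr_series <- if (dur >= 30 && nrow(beats) >= 20)
    tryCatch(estimate_rr(ecg, beats), error = function(e) NULL) else NULL
  ann <- if (!is.null(models$annotation))
    annotate(models$annotation, ecg, beats) else NULL
  acts <- if (!is.null(models$activity) && !is.null(imu))
    classify_stream(models$activity, imu) else NULL

  prev_alerts <- character(0)
  events <- vector("list", n_win)
  for (k in seq_len(n_win)) {
    t0 <- (k - 1) * win_s; t1 <- k * win_s
    hr <- if (!is.null(hr_series)) {
      sel <- hr_series$t >= t0 & hr_series$t < t1
      if (any(sel)) mean(hr_series$hr[sel]) else NA_real_
    } else NA_real_
    rr <- if (!is.null(rr_series)) {
      sel <- rr_series$t <= t1
      if (any(sel)) tail(rr_series$rr[sel], 1) else NA_real_
    } else NA_real_
    in_win <- beats$time_s >= t0 & beats$time_s < t1
    beat_cls <- if (!is.null(ann) && !is.null(ann$beat_annotations)) {
      ba <- ann$beat_annotations
      ba$class_name[ba$time_s >= t0 & ba$time_s < t1]
    } else character(0)
    activity <- if (!is.null(acts)) {
      sel <- acts$t >= t0 & acts$t < t1
      if (any(sel)) names(which.max(table(acts$class[sel]))) else NA_character_
    } else NA_character_

    cur <- character(0)
    if (any(beat_cls %in% c("FB", "SVEB", "VEB"))) cur <- c(cur, "abnormal_beat")
    if (!is.null(acts)) {
      sel <- acts$t >= t0 & acts$t < t1
      if (any(acts$class[sel] == "fall")) cur <- c(cur, "fall")
    }
    alerts <- setdiff(cur, prev_alerts)   # debounce contiguous runs
    prev_alerts <- cur
    events[[k]] <- list(t = t1, hr = hr, rr = rr,
                        n_beats = sum(in_win),
                        beat_classes = beat_cls,
                        activity = activity, alerts = alerts)
  }
  if (!is.null(out)) {
    con <- file(out, open = "w")
    on.exit(close(con))
    for (ev in events)
      writeLines(jsonlite::toJSON(ev, auto_unbox = TRUE, digits = NA,
                                  null = "null"), con)
  }
  data.frame(
    t = vapply(events, `[[`, 0, "t"),
    hr = vapply(events, `[[`, 0, "hr"),
    rr = vapply(events, `[[`, 0, "rr"),
    n_beats = vapply(events, `[[`, 0L, "n_beats"),
    beat_classes = vapply(events, function(e)
      paste(e$beat_classes, collapse = ","), ""),
    activity = vapply(events, `[[`, "", "activity"),
    alerts = vapply(events, function(e) paste(e$alerts, collapse = ","), ""))
}
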