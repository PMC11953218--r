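#' Single-subject averaged evoked response
#'
#' One subject x condition trial-averaged TEP: a channels x timepoints matrix
#' (microvolts) with its sampling rate and the time of the first sample
#' relative to the TMS pulse.
#'
#' @param subject_id Subject label.
#' @param waveform Pulse waveform, `"monophasic"` or `"biphasic"`.
#' @param direction Induced current direction, `"PA"`, `"AP"` or `"LM"`.
#' @param data Numeric matrix, channels x timepoints (uV). Row order must
#'   match the montage it is used with.
#' @param srate Sampling rate (samples/s), > 0.
#' @param t0_offset Time of the first sample relative to the pulse (ms).
#' @return A `tep_evoked` object.
#' @export
subject_evoked <- function(subject_id, waveform, direction, data, srate, t0_offset) {
  waveform <- match.arg(waveform, .waveforms)
  direction <- match.arg(direction, .directions)
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data))) {
    abort(paste0("evoked data must be finite numeric (subject ", subject_id, ")"))
  }
  if (!is.numeric(srate) || length(srate) != 1 || srate <= 0) abort("srate must be > 0")
  storage.mode(data) <- "double"
  structure(list(subject_id = as.character(subject_id), waveform = waveform,
                 direction = direction, data = data, srate = as.numeric(srate),
                 t0_offset = as.numeric(t0_offset)),
            class = "tep_evoked")
}

#' @export
print.tep_evoked <- function(x, ...) {
  tt <- evoked_times(x)
  cat(sprintf("<tep_evoked> %s / %s_%s: %d ch x %d samples, %.6g Hz, [%.6g, %.6g] ms\n",
              x$subject_id, x$waveform, x$direction, nrow(x$data), ncol(x$data),
              x$srate, tt[1], tt[length(tt)]))
  invisible(x)
}

#' Time axis of an evoked record
#' @param ev A `tep_evoked`.
#' @return Numeric vector of sample times (ms relative to the pulse).
#' @export
evoked_times <- function(ev) {
  ev$t0_offset + (seq_len(ncol(ev$data)) - 1) * 1000 / ev$srate
}

#' Multi-subject evoked dataset
#'
#' A validated collection of [subject_evoked()] records covering a complete
#' 2 (pulse waveform) x 3 (current direction) within-subject crossing, with a
#' shared montage, sampling rate and time axis.
#'
#' @param montage A [tep_montage()].
#' @param records List of `tep_evoked` records.
#' @param analysis_window Length-2 numeric, half-open `[start, end)` window
#'   (ms) used by downstream analyses. Default `c(5, 400)`.
#' @return A `tep_dataset` object.
#' @export
tep_dataset <- function(montage, records, analysis_window = c(5, 400)) {
  stopifnot(inherits(montage, "tep_montage"))
  if (length(records) == 0) abort("no records")
  for (r in records) {
    if (!inherits(r, "tep_evoked")) abort("records must be tep_evoked objects")
    if (nrow(r$data) != n_channels(montage)) {
      abort(sprintf("record %s %s_%s has %d rows but montage has %d channels",
                    r$subject_id, r$waveform, r$direction, nrow(r$data),
                    n_channels(montage)))
    }
  }
  srates <- vapply(records, `[[`, 1.0, "srate")
  t0s <- vapply(records, `[[`, 1.0, "t0_offset")
  ns <- vapply(records, function(r) ncol(r$data), 1L)
  if (length(unique(srates)) > 1 || length(unique(t0s)) > 1 || length(unique(ns)) > 1) {
    abort("all records must share srate, t0_offset and sample count")
  }
  key <- vapply(records, function(r) paste(r$subject_id, r$waveform, r$direction), "")
  if (anyDuplicated(key)) abort("duplicate subject x condition records")
  subjects <- unique(vapply(records, `[[`, "", "subject_id"))
  missing <- character(0)
  for (s in subjects) for (w in .waveforms) for (d in .directions) {
    if (!any(key == paste(s, w, d))) missing <- c(missing, sprintf("%s missing (%s, %s)", s, w, d))
  }
  if (length(missing)) abort(paste0("incomplete design: ", paste(missing, collapse = "; ")))
  structure(list(montage = montage, records = records,
                 analysis_window = as.numeric(analysis_window),
                 subjects = subjects),
            class = "tep_dataset")
}

#' @export
print.tep_dataset <- function(x, ...) {
  cat(sprintf("<tep_dataset> %d subjects x 6 conditions, %d channels, %.6g Hz, window [%g, %g) ms\n",
              length(x$subjects), n_channels(x$montage),
              x$records[[1]]$srate, x$analysis_window[1], x$analysis_window[2]))
  invisible(x)
}

#' Fetch one record from a dataset
#' @param dataset A `tep_dataset`.
#' @param subject_id,waveform,direction Record coordinates.
#' @return A `tep_evoked`.
#' @export
get_record <- function(dataset, subject_id, waveform, direction) {
  for (r in dataset$records) {
    if (r$subject_id == subject_id && r$waveform == waveform && r$direction == direction) return(r)
  }
  abort(sprintf("no record for %s %s_%s", subject_id, waveform, direction))
}

#' Apply a function to every record of a dataset
#' @noRd
map_records <- function(dataset, f) {
  dataset$records <- lapply(dataset$records, f)
  dataset
}

#' Crop an evoked record to a time window
#'
#' Retains samples with `start <= t < end` (half-open window, ms relative to
#' the pulse); `t0_offset` is updated to the first retained sample.
#'
#' @param ev A [subject_evoked()] record or a [tep_dataset()].
#' @param window_ms Length-2 numeric `c(start, end)`.
#' @return Object of the same class, cropped.
#' @export
crop_evoked <- function(ev, window_ms) {
  if (inherits(ev, "tep_dataset")) {
    return(map_records(ev, function(r) crop_evoked(r, window_ms)))
  }
  stopifnot(inherits(ev, "tep_evoked"))
  tt <- evoked_times(ev)
  eps <- 1e-9
  keep <- which(tt >= window_ms[1] - eps & tt < window_ms[2] - eps)
  if (length(keep) == 0) abort(sprintf("empty window [%g, %g)", window_ms[1], window_ms[2]))
  ev$data <- ev$data[, keep, drop = FALSE]
  ev$t0_offset <- tt[keep[1]]
  ev
}

#' Downsample an evoked record
#'
#' Integer-stride decimation when `target_srate` divides `srate` exactly (the
#' first retained sample is the first input sample, so the time axis is
#' preserved); otherwise polyphase resampling through the signal package.
#' Upsampling is refused. The input is assumed already low-pass filtered
#' below the target Nyquist frequency.
#'
#' @param ev A [subject_evoked()] record or a [tep_dataset()].
#' @param target_srate New sampling rate (samples/s), `<= srate`.
#' @return Object of the same class at the new rate.
#' @export
downsample_evoked <- function(ev, target_srate) {
  if (inherits(ev, "tep_dataset")) {
    return(map_records(ev, function(r) downsample_evoked(r, target_srate)))
  }
  stopifnot(inherits(ev, "tep_evoked"))
  if (target_srate > ev$srate) abort("no upsampling: target_srate exceeds srate")
  if (target_srate == ev$srate) return(ev)
  ratio <- ev$srate / target_srate
  if (abs(ratio - round(ratio)) < 1e-9) {
    idx <- seq(1, ncol(ev$data), by = round(ratio))
    ev$data <- ev$data[, idx, drop = FALSE]
  } else {
    if (!requireNamespace("signal", quietly = TRUE)) {
      abort("non-integer decimation needs the signal package")
    }
    fr <- .rat_approx(target_srate / ev$srate)
    ev$data <- t(apply(ev$data, 1, function(x) signal::resample(x, fr[1], fr[2])))
  }
  ev$srate <- target_srate
  ev
}

.rat_approx <- function(x, max_den = 1000) {
  best <- c(1L, 1L); err <- Inf
  for (q in 1:max_den) {
    p <- round(x * q)
    if (p < 1) next
    e <- abs(x - p / q)
    if (e < err) { err <- e; best <- c(p, q) }
    if (err < 1e-12) break
  }
  best
}

#' Per-condition grand averages
#'
#' Mean across subjects of each condition's records (optionally after
#' per-subject GFP normalization with [normalize_by_gfp()]), cropped to the
#' analysis window.
#'
#' @param dataset A [tep_dataset()].
#' @param window Analysis window (ms); default the dataset's.
#' @param normalize Divide each subject's record by its mean GFP over the
#'   window first (default `TRUE`, the convention for topographic analyses).
#' @return Named list of channels x timepoints matrices, one per condition
#'   (names as in [tep_conditions()]), with attributes `times` and `srate`.
#' @export
grand_averages <- function(dataset, window = dataset$analysis_window, normalize = TRUE) {
  out <- list()
  times <- NULL
  for (w in .waveforms) for (d in .directions) {
    mats <- lapply(dataset$subjects, function(s) {
      r <- get_record(dataset, s, w, d)
      if (normalize) r <- normalize_by_gfp(r, window)
      r <- crop_evoked(r, window)
      if (is.null(times)) times <<- evoked_times(r)
      r$data
    })
    out[[condition_label(w, d)]] <- Reduce(`+`, mats) / length(mats)
  }
  attr(out, "times") <- times
  attr(out, "srate") <- dataset$records[[1]]$srate
  out
}
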