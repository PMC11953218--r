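#' Write an evoked dataset to disk
#'
#' One delimited text matrix file per subject x condition record (channels x
#' timepoints, no header; full double precision, so a read round-trip is
#' bit-exact) plus a `manifest.csv` with columns `subject_id, waveform,
#' direction, path, srate, t0_offset` and a montage file.
#'
#' @param dataset A [tep_dataset()].
#' @param dir Output directory (created if needed).
#' @return Path of the manifest, invisibly.
#' @export
write_evoked_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(dataset$records, function(r) {
    fn <- sprintf("%s_%s_%s.csv", r$subject_id, r$waveform, r$direction)
    # readr emits shortest round-trippable doubles, so reads are bit-exact
    readr::write_csv(as.data.frame(r$data), file.path(dir, fn),
                     col_names = FALSE)
    tibble(subject_id = r$subject_id, waveform = r$waveform,
           direction = r$direction, path = fn,
           srate = r$srate, t0_offset = r$t0_offset)
  })
  manifest <- bind_rows(rows)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  write_montage(dataset$montage, file.path(dir, "montage.txt"))
  invisible(file.path(dir, "manifest.csv"))
}

#' Load an evoked dataset from a manifest
#'
#' Reads the manifest (columns `subject_id, waveform, direction, path`, plus
#' optional `srate` and `t0_offset` which otherwise default to arguments) and
#' the per-record matrix files it points to, validates channel counts against
#' the montage and the completeness of the 2 x 3 design, and returns a
#' [tep_dataset()]. Any violation is a structured error naming the offending
#' record.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param montage_path Path to the montage file ([read_montage()] format).
#' @param srate,t0_offset Fallbacks when the manifest lacks those columns.
#' @param analysis_window Analysis window passed to [tep_dataset()].
#' @return A [tep_dataset()].
#' @export
load_dataset <- function(manifest_path, montage_path, srate = NULL,
                         t0_offset = NULL, analysis_window = c(5, 400)) {
  if (!file.exists(manifest_path)) abort(paste0("manifest not found: ", manifest_path))
  montage <- read_montage(montage_path)
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE)
  need <- c("subject_id", "waveform", "direction", "path")
  if (!all(need %in% names(manifest))) {
    abort(paste0("manifest must have columns: ", paste(need, collapse = ", ")))
  }
  base <- dirname(manifest_path)
  records <- purrr::pmap(manifest, function(subject_id, waveform, direction, path, ...) {
    extra <- list(...)
    fp <- if (file.exists(path)) path else file.path(base, path)
    if (!file.exists(fp)) abort(paste0("matrix file not found: ", path))
    mat <- as.matrix(data.table::fread(fp, header = FALSE))
    dimnames(mat) <- NULL
    if (nrow(mat) != n_channels(montage)) {
      abort(sprintf("channel-count mismatch in %s: %d rows, montage has %d channels",
                    path, nrow(mat), n_channels(montage)))
    }
    subject_evoked(subject_id, waveform, direction, mat,
                   srate = extra$srate %||% srate %||%
                     abort("srate neither in manifest nor supplied"),
                   t0_offset = extra$t0_offset %||% t0_offset %||%
                     abort("t0_offset neither in manifest nor supplied"))
  })
  tep_dataset(montage, records, analysis_window = analysis_window)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
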