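#' Global field power
#'
#' GFP at a timepoint is the spatial standard deviation of the
#' average-referenced scalp map: `sqrt(mean((v - mean(v))^2))` across
#' channels. A reference-free measure of momentary response strength.
#'
#' @param x A numeric vector (one map), a channels x timepoints matrix, or a
#'   [subject_evoked()] record.
#' @return For a vector, a single GFP value; otherwise a tibble with columns
#'   `time` (ms; sample index if no time axis is known) and `gfp` (uV).
#' @examples
#' compute_gfp(c(1, -1, 1, -1))  # 1
#' @export
compute_gfp <- function(x) {
  if (inherits(x, "tep_evoked")) {
    g <- gfp_of_matrix(x$data)
    return(tibble(time = evoked_times(x), gfp = g))
  }
  if (is.matrix(x)) {
    if (nrow(x) < 2) abort("GFP needs at least 2 channels")
    return(tibble(time = seq_len(ncol(x)), gfp = gfp_of_matrix(x)))
  }
  if (length(x) < 2) abort("GFP needs at least 2 channels")
  sqrt(mean((x - mean(x))^2))
}

gfp_of_matrix <- function(mat) {
  if (nrow(mat) < 2) abort("GFP needs at least 2 channels")
  centered <- sweep(mat, 2, colMeans(mat))
  sqrt(colMeans(centered^2))
}

#' Normalize an evoked record by its mean GFP
#'
#' Divides all channels by the record's mean GFP over the analysis window, so
#' the normalized record has mean GFP exactly 1 there. This removes
#' between-subject amplitude differences before topographic analyses while
#' preserving the spatial pattern and the relative GFP time course.
#'
#' @param ev A [subject_evoked()] record.
#' @param window Window (ms, half-open) over which the mean GFP is taken.
#' @return The normalized `tep_evoked`.
#' @export
normalize_by_gfp <- function(ev, window = c(5, 400)) {
  stopifnot(inherits(ev, "tep_evoked"))
  g <- gfp_of_matrix(crop_evoked(ev, window)$data)
  mg <- mean(g)
  if (mg <= 0) abort("zero mean GFP in window; cannot normalize")
  ev$data <- ev$data / mg
  ev
}
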