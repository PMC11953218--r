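#' Electrode montage
#'
#' A montage is the ordered set of scalp electrodes an evoked dataset is
#' recorded from: unique channel labels (10-10 nomenclature) plus a 3-D
#' position per channel on a unit sphere (arbitrary units; only the relative
#' geometry is used, e.g. for the spatially smooth synthetic template maps
#' and for topographic plotting).
#'
#' @param channel_names Character vector of unique channel labels.
#' @param positions Numeric matrix, one row per channel, 3 columns (x, y, z).
#' @return A `tep_montage` object: list with `channel_names` and `positions`.
#' @examples
#' m <- montage_1010_74()
#' n_channels(m)
#' @export
tep_montage <- function(channel_names, positions) {
  channel_names <- as.character(channel_names)
  positions <- as.matrix(positions)
  if (length(channel_names) < 3) {
    abort("a montage needs at least 3 channels")
  }
  if (anyDuplicated(channel_names)) {
    abort(paste0("duplicate channel names: ",
                 paste(unique(channel_names[duplicated(channel_names)]), collapse = ", ")))
  }
  if (nrow(positions) != length(channel_names) || ncol(positions) != 3) {
    abort("`positions` must be a (n_channels x 3) matrix")
  }
  if (!all(is.finite(positions))) abort("montage positions must be finite")
  storage.mode(positions) <- "double"
  rownames(positions) <- channel_names
  structure(list(channel_names = channel_names, positions = positions),
            class = "tep_montage")
}

#' @export
print.tep_montage <- function(x, ...) {
  cat("<tep_montage> ", n_channels(x), " channels: ",
      paste(head(x$channel_names, 6), collapse = ", "),
      if (n_channels(x) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Number of channels in a montage
#' @param m A `tep_montage`.
#' @return Integer channel count.
#' @export
n_channels <- function(m) length(m$channel_names)

# nominal 10-10 arc angles: `ap` is the angle (degrees) from the vertex along
# the midline (anterior positive), `lat` the angle from the midline along the
# coronal arc (left positive). Idealized geometry, not digitized positions.
.row_ap <- c(Fp = 72, AF = 54, F = 36, FT = 18, FC = 18, T = 0, C = 0,
             TP = -18, CP = -18, P = -36, PO = -54, O = -72, I = -90)

.label_angles <- function(label) {
  row <- sub("[0-9z]+$", "", label)
  num <- sub("^[A-Za-z]+?(?=[0-9z]+$)", "", label, perl = TRUE)
  ap <- .row_ap[[row]]
  if (num == "z") {
    lat <- 0
  } else {
    k <- as.integer(num)
    lat <- c(`1` = 18, `2` = 18, `3` = 36, `4` = 36, `5` = 54, `6` = 54,
             `7` = 72, `8` = 72, `9` = 90, `10` = 90)[[as.character(k)]]
    if (k %% 2 == 0) lat <- -lat  # even numbers on the right
  }
  c(ap = ap, lat = lat)
}

#' Idealized 74-channel 10-10 montage
#'
#' Standard 10-10 labels with positions computed from nominal arc angles on a
#' unit sphere (vertex at Cz). This reconstructs the layout of a 74-electrode
#' TMS-EEG cap; it is an idealized spherical geometry, not digitized
#' coordinates.
#'
#' @return A [tep_montage()] with 74 channels.
#' @export
montage_1010_74 <- function() {
  labels <- c(
    "Fp1", "Fpz", "Fp2",
    "AF7", "AF3", "AFz", "AF4", "AF8",
    "F9", "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8", "F10",
    "FT9", "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8", "FT10",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "TP10",
    "P9", "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8", "P10",
    "PO9", "PO7", "PO3", "POz", "PO4", "PO8", "PO10",
    "O9", "O1", "Oz", "O2", "O10",
    "Iz")
  pos <- t(vapply(labels, function(lb) {
    a <- .label_angles(lb)
    ap <- a[["ap"]] * pi / 180
    lat <- a[["lat"]] * pi / 180
    # tilt from vertex toward the front by `ap`, then toward the left by `lat`
    c(sin(ap), cos(ap) * sin(lat), cos(ap) * cos(lat))
  }, numeric(3)))
  tep_montage(labels, pos)
}

#' Read / write a montage file
#'
#' Plain-text electrode position file: one channel per line, whitespace- or
#' comma-separated columns `label x y z` (Cartesian, unit sphere). A header
#' line is detected and skipped if the coordinate fields are non-numeric.
#'
#' @param path File path.
#' @return `read_montage()` returns a [tep_montage()]; `write_montage()`
#'   returns `path` invisibly.
#' @export
read_montage <- function(path) {
  if (!file.exists(path)) abort(paste0("montage file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[,[:space:]]+")
  bad <- vapply(fields, length, 1L) < 4
  if (any(bad)) abort(paste0("montage file: line(s) with fewer than 4 fields: ",
                             paste(which(bad), collapse = ", ")))
  num <- suppressWarnings(vapply(fields, function(f) as.numeric(f[2]), 1.0))
  if (is.na(num[1]) && length(fields) > 1) { # header row
    fields <- fields[-1]
    num <- num[-1]
  }
  if (anyNA(num)) abort("montage file: non-numeric coordinates")
  labels <- vapply(fields, `[[`, "", 1L)
  pos <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
  tep_montage(labels, pos)
}

#' @param m A `tep_montage`.
#' @rdname read_montage
#' @export
write_montage <- function(m, path) {
  stopifnot(inherits(m, "tep_montage"))
  lines <- sprintf("%s %.17g %.17g %.17g", m$channel_names,
                   m$positions[, 1], m$positions[, 2], m$positions[, 3])
  writeLines(c("label x y z", lines), path)
  invisible(path)
}

#' Great-circle-free chordal distances between electrodes
#' @noRd
montage_dist <- function(m) {
  as.matrix(stats::dist(m$positions))
}
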