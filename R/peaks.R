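#' Built-in M1-TEP component definitions
#'
#' The six canonical motor-cortex TEP components with their measurement
#' windows (time of interest, closed interval, ms) and four-electrode
#' regions of interest. Windows are non-overlapping by construction
#' (touching decimals, e.g. 24.9/25). Users may pass an edited copy of this
#' table to the extraction functions.
#'
#' @return Tibble with `component`, `polarity` (`"negative"`/`"positive"`),
#'   `toi_start`, `toi_end` (ms), `roi` (list column of channel labels).
#' @export
tep_components <- function() {
  tibble(
    component = c("N15", "P30", "N45", "P60", "N100", "P180"),
    polarity = c("negative", "positive", "negative", "positive",
                 "negative", "positive"),
    toi_start = c(7, 25, 38, 55, 90, 170),
    toi_end = c(24.9, 37.9, 54.9, 74.9, 129.9, 219.9),
    roi = list(c("C3", "CP3", "CP1", "CP5"),
               c("Cz", "FCz", "C1", "FC1"),
               c("F4", "FC4", "FC2", "F2"),
               c("C3", "CP3", "CP1", "CP5"),
               c("FCz", "C1", "FC1", "FC3"),
               c("F2", "FCz", "FC2", "C2"))
  )
}

check_component <- function(comp) {
  need <- c("component", "polarity", "toi_start", "toi_end", "roi")
  if (!all(need %in% names(comp))) {
    abort(paste0("component table needs columns: ", paste(need, collapse = ", ")))
  }
  first <- toupper(substr(comp$component, 1, 1))
  want <- ifelse(comp$polarity == "negative", "N", "P")
  if (any(first != want)) {
    abort("component polarity must match the leading letter of its name")
  }
  invisible(comp)
}

#' Extract a component's peak amplitude and latency from one record
#'
#' The ROI trace is the unweighted mean of the ROI channels. The amplitude
#' is the signed extremum of that trace within the (closed) time of
#' interest — minimum for negative components, maximum for positive — and
#' the latency is the time of that extremum. Boundary samples are eligible
#' (components can be absent or polarity-inverted in individual subjects, so
#' no local-peak requirement is imposed); among equal extrema, the earliest
#' timepoint wins.
#'
#' @param ev A [subject_evoked()] record.
#' @param comp One row of a [tep_components()]-style table.
#' @param montage The montage giving `ev`'s channel order.
#' @return One-row tibble: `subject_id`, `waveform`, `direction`,
#'   `component`, `amplitude` (uV), `latency` (ms).
#' @export
extract_peak <- function(ev, comp, montage) {
  check_component(comp)
  roi <- comp$roi[[1]]
  idx <- match(roi, montage$channel_names)
  if (anyNA(idx)) {
    abort(paste0("ROI channels missing from montage: ",
                 paste(roi[is.na(idx)], collapse = ", ")))
  }
  tt <- evoked_times(ev)
  eps <- 1e-9
  sel <- which(tt >= comp$toi_start - eps & tt <= comp$toi_end + eps)
  if (length(sel) == 0) {
    abort(sprintf("TOI [%g, %g] outside the epoch [%g, %g]",
                  comp$toi_start, comp$toi_end, tt[1], tt[length(tt)]))
  }
  trace <- colMeans(ev$data[idx, sel, drop = FALSE])
  if (all(is.na(trace))) abort("all-NaN ROI trace")
  i <- if (comp$polarity == "negative") which.min(trace) else which.max(trace)
  tibble(subject_id = ev$subject_id, waveform = ev$waveform,
         direction = ev$direction, component = comp$component,
         amplitude = trace[i], latency = tt[sel][i])
}

#' Peak table for a whole dataset
#'
#' Applies [extract_peak()] to every record x component and returns the long
#' peaks table the statistical layer consumes.
#'
#' @param dataset A [tep_dataset()].
#' @param components A [tep_components()]-style table (default the built-in).
#' @return Tibble: `subject_id`, `waveform`, `direction`, `condition`,
#'   `component`, `amplitude`, `latency`.
#' @export
extract_peaks <- function(dataset, components = tep_components()) {
  check_component(components)
  purrr::map_dfr(dataset$records, function(r) {
    purrr::map_dfr(seq_len(nrow(components)), function(i) {
      extract_peak(r, components[i, ], dataset$montage)
    })
  }) %>%
    mutate(condition = condition_label(.data$waveform, .data$direction),
           .after = "direction")
}

#' Screen peak values for group-level outliers
#'
#' A subject is flagged for a component if, in any condition, their
#' amplitude or latency deviates from the group mean of that
#' condition-component cell by strictly more than `z` standard deviations
#' (single pass on the full group's mean/SD). Exclusion applies per
#' component, across all of its conditions.
#'
#' @param peaks Long peaks table from [extract_peaks()].
#' @param z SD threshold (default 2.5).
#' @return The peaks table with an added logical `excluded` column, plus a
#'   `flags` attribute (tibble `subject_id`, `component`, `reason`).
#' @export
screen_peak_outliers <- function(peaks, z = 2.5) {
  if (length(unique(peaks$subject_id)) < 3) abort("outlier screening needs >= 3 subjects")
  long <- peaks %>%
    tidyr::pivot_longer(c("amplitude", "latency"),
                        names_to = "measure", values_to = "value") %>%
    group_by(.data$condition, .data$component, .data$measure) %>%
    mutate(zscore = {
      s <- sd(.data$value)
      if (is.na(s) || s == 0) rep(0, n()) else (.data$value - mean(.data$value)) / s
    }) %>%
    ungroup()
  flags <- long %>%
    filter(abs(.data$zscore) > z) %>%
    mutate(reason = sprintf("%s %s in %s: z = %.2f", .data$component,
                            .data$measure, .data$condition, .data$zscore)) %>%
    select(dplyr::all_of(c("subject_id", "component", "reason")))
  out <- peaks %>%
    left_join(flags %>% distinct(.data$subject_id, .data$component) %>%
                mutate(excluded = TRUE),
              by = c("subject_id", "component")) %>%
    mutate(excluded = !is.na(.data$excluded))
  attr(out, "flags") <- flags
  out
}

#' Choose a normalizing transform for a variable
#'
#' Evaluates no transform, square root, base-ten logarithm and inverse
#' (shifting the data to strict positivity first where the transform
#' requires it; the shift is recorded) and selects the candidate with the
#' highest Shapiro-Wilk W. If no candidate reaches Shapiro-Wilk p > .05 the
#' result carries `no_transform_normalizes = TRUE`, signalling the robust
#' (trimmed-means) analysis path.
#'
#' @param values Numeric vector, n >= 8, non-constant.
#' @param label Variable label carried through to the result.
#' @return A `transform_choice`: tibble of all candidates (`transform`, `W`,
#'   `p`, `shift`) with attributes `chosen`, `no_transform_normalizes`,
#'   `label`.
#' @export
choose_transform <- function(values, label = "value") {
  values <- values[is.finite(values)]
  if (length(values) < 8) abort("need n >= 8 for transform selection")
  if (sd(values) == 0) abort("constant input: no transform applicable")
  shift_pos <- function(x) if (min(x) <= 0) -min(x) + 1e-3 * max(1, diff(range(x))) else 0
  cands <- list(
    none = function(x) list(y = x, shift = 0),
    sqrt = function(x) { s <- shift_pos(x); list(y = sqrt(x + s), shift = s) },
    log10 = function(x) { s <- shift_pos(x); list(y = log10(x + s), shift = s) },
    inverse = function(x) { s <- shift_pos(x); list(y = 1 / (x + s), shift = s) }
  )
  rows <- purrr::imap_dfr(cands, function(f, nm) {
    tr <- f(values)
    if (sd(tr$y) == 0 || !all(is.finite(tr$y))) {
      return(tibble(transform = nm, W = NA_real_, p = NA_real_, shift = tr$shift))
    }
    sw <- shapiro.test(tr$y)
    tibble(transform = nm, W = unname(sw$statistic), p = sw$p.value, shift = tr$shift)
  })
  ok <- which(!is.na(rows$W))
  chosen <- rows$transform[ok[which.max(rows$W[ok])]]
  structure(rows, class = c("transform_choice", class(rows)),
            chosen = chosen, label = label,
            no_transform_normalizes = !any(rows$p[ok] > 0.05))
}

#' Apply a chosen transform
#' @param values Numeric vector.
#' @param choice A `transform_choice` from [choose_transform()].
#' @return Transformed values.
#' @export
apply_transform <- function(values, choice) {
  nm <- attr(choice, "chosen")
  s <- choice$shift[match(nm, choice$transform)]
  switch(nm,
         none = values,
         sqrt = sqrt(values + s),
         log10 = log10(values + s),
         inverse = 1 / (values + s))
}
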