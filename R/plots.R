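#' GFP traces per condition
#'
#' Butterfly-free summary of the evoked response strength: the grand-average
#' GFP time course for each of the six conditions.
#'
#' @param dataset A [tep_dataset()].
#' @param window Time window (ms); defaults to the full epoch.
#' @param normalize GFP-normalize subjects before averaging.
#' @return A ggplot object.
#' @export
plot_gfp <- function(dataset, window = NULL, normalize = FALSE) {
  r0 <- dataset$records[[1]]
  tt <- evoked_times(r0)
  window <- window %||% c(tt[1], tt[length(tt)] + 1e-6)
  ga <- grand_averages(dataset, window = window, normalize = normalize)
  df <- purrr::imap_dfr(ga, function(m, cond) {
    tibble(condition = cond, time = attr(ga, "times"), gfp = gfp_of_matrix(m))
  }) %>%
    tidyr::separate_wider_delim("condition", "_",
                                names = c("waveform", "direction"),
                                cols_remove = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$gfp,
                                   colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~waveform, ncol = 1) +
    ggplot2::labs(x = "time (ms)", y = "GFP (µV)",
                  title = "Grand-average global field power") +
    ggplot2::theme_minimal()
}

#' Template map topographies
#'
#' Simple flat-projected scalp maps of a template set (azimuthal projection
#' of the electrode positions, interpolation-free point maps).
#'
#' @param templates Channels x K template matrix (rownames = channel labels
#'   when available).
#' @param montage A [tep_montage()] giving the positions.
#' @return A ggplot object.
#' @export
plot_templates <- function(templates, montage) {
  pos <- montage$positions
  # azimuthal equidistant projection from the vertex
  th <- acos(pmin(pmax(pos[, 3], -1), 1))
  ph <- atan2(pos[, 2], pos[, 1])
  df <- purrr::map_dfr(seq_len(ncol(templates)), function(k) {
    tibble(class = colnames(templates)[k] %||% paste0("class", k),
           x = th * cos(ph), y = th * sin(ph), w = templates[, k])
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$w)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::facet_wrap(~class) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Microstate template maps", colour = "weight") +
    ggplot2::theme_void()
}

#' Class-sequence bars per condition
#'
#' The per-condition microstate label sequence as coloured bars over time,
#' with the GFP trace overlaid — the standard way to show which template
#' occupies which part of the evoked response.
#'
#' @param seg An `ms_segmentation` fitted on a dataset (so it carries
#'   per-condition labels).
#' @return A ggplot object.
#' @export
plot_class_sequence <- function(seg) {
  if (is.null(seg$condition_labels)) {
    abort("segmentation carries no per-condition labels (was it fit on a dataset?)")
  }
  df <- seg$condition_labels %>% mutate(class = factor(.data$class))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$gfp)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$class), width = 1.2) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~condition, ncol = 1, strip.position = "right") +
    ggplot2::labs(x = "time (ms)", y = "GFP", fill = "class",
                  title = "Microstate class sequences") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ms_segmentation <- function(object, ...) plot_class_sequence(object)

#' @export
autoplot.tct_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$p)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.05, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "time (ms)", y = "p (randomization)",
                  title = "Topographic consistency test") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ms_cv <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$K, .data$mean_test_gev)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$selected_k, linetype = 2) +
    ggplot2::labs(y = "mean test-set GEV",
                  title = "Cross-validated map-count selection") +
    ggplot2::theme_minimal()
}

#' Feature box plots
#'
#' Distribution of a microstate feature across subjects, per class and
#' condition.
#'
#' @param features Tibble from [microstate_features()].
#' @param feature `"auc"`, `"duration"`, or `"onset"`.
#' @return A ggplot object.
#' @export
plot_features <- function(features, feature = c("auc", "duration", "onset")) {
  feature <- match.arg(feature)
  ggplot2::ggplot(features,
                  ggplot2::aes(factor(.data$class), .data[[feature]],
                               fill = .data$direction)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~waveform, ncol = 1) +
    ggplot2::labs(x = "microstate class", y = feature) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
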