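#' Assemble a run configuration
#'
#' Collects every tunable of the end-to-end analysis with its default:
#' analysis window 5-400 ms, downsampling to 960 Hz, automatic map-count
#' selection over 3-12 by 50-iteration cross-validation (or a fixed K),
#' 250 segmentation restarts, 5000 randomizations for the topographic
#' consistency test, signed-polarity labelling, +-2.5 SD peak screening and
#' chi-square(.99) Mahalanobis screening.
#'
#' @param manifest,montage Paths for [load_dataset()] (omit when passing a
#'   dataset to [run_pipeline()] directly).
#' @param window Analysis window (ms).
#' @param downsample_to Target sampling rate (Hz); `NULL` to keep as-is.
#' @param k Number of microstate maps, or `"auto"` for cross-validated
#'   selection.
#' @param k_range Candidate range for the automatic selection.
#' @param restarts,n_perm,cv_iter Algorithm sizes.
#' @param polarity `"signed"` or `"ignore"`.
#' @param peak_z Peak outlier threshold (SD).
#' @param components Component table (default [tep_components()]).
#' @param exclude_mahalanobis Drop subjects flagged by the Mahalanobis
#'   screen before the microstate stages (default TRUE).
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param out_dir Output directory for tables (`NULL`: nothing written).
#' @return A `run_config` list.
#' @export
run_config <- function(manifest = NULL, montage = NULL, window = c(5, 400),
                       downsample_to = 960, k = "auto", k_range = c(3, 12),
                       restarts = 250, n_perm = 5000, cv_iter = 50,
                       polarity = c("signed", "ignore"), peak_z = 2.5,
                       components = tep_components(),
                       exclude_mahalanobis = TRUE, seed = 1,
                       out_dir = NULL) {
  structure(list(manifest = manifest, montage = montage, window = window,
                 downsample_to = downsample_to, k = k, k_range = k_range,
                 restarts = restarts,
                 n_perm = n_perm, cv_iter = cv_iter,
                 polarity = match.arg(polarity), peak_z = peak_z,
                 components = components,
                 exclude_mahalanobis = exclude_mahalanobis,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Run the full TEP analysis pipeline
#'
#' load -> window/downsample -> Mahalanobis screen -> peaks (+ outlier
#' screen, transform choice) -> topographic consistency -> map-count
#' selection -> segmentation -> features -> statistics (rmANOVAs on peak and
#' microstate features, onset mixed model). Every stage is seeded from the
#' master seed, logged with its wall time, and its tabular outputs are
#' written to `out_dir` when configured, so identical configurations produce
#' byte-identical tables.
#'
#' @param config A [run_config()].
#' @param dataset Optionally, an in-memory [tep_dataset()] (skips loading).
#' @return A `tep_run` list: `dataset`, `screen`, `peaks`, `transforms`,
#'   `tct`, `cv`, `segmentation`, `features`, `stats`, `log`.
#' @export
run_pipeline <- function(config, dataset = NULL) {
  stopifnot(inherits(config, "run_config"))
  log <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
    log[[name]] <<- tibble(stage = name,
                           seconds = as.numeric(Sys.time() - t0, units = "secs"))
    out
  }
  seed <- config$seed

  dataset <- stage("load", {
    if (is.null(dataset)) {
      dataset <- load_dataset(config$manifest, config$montage,
                              analysis_window = config$window)
    }
    dataset$analysis_window <- config$window
    if (!is.null(config$downsample_to) &&
        config$downsample_to < dataset$records[[1]]$srate) {
      dataset <- downsample_evoked(dataset, config$downsample_to)
    }
    dataset
  })

  screen <- stage("mahalanobis_screen", {
    if (length(dataset$subjects) >= 5) mahalanobis_outliers(dataset, config$window)
    else NULL
  })
  analysis_data <- dataset
  if (config$exclude_mahalanobis && !is.null(screen) && any(screen$flagged)) {
    drop <- screen$subject_id[screen$flagged]
    keep <- setdiff(dataset$subjects, drop)
    if (length(keep) >= 4) {
      analysis_data$records <- Filter(function(r) r$subject_id %in% keep,
                                      dataset$records)
      analysis_data$subjects <- keep
    }
  }

  peaks <- stage("peaks", {
    extract_peaks(dataset, config$components) %>%
      screen_peak_outliers(z = config$peak_z)
  })
  transforms <- stage("transforms", {
    peaks %>%
      filter(!.data$excluded) %>%
      tidyr::pivot_longer(c("amplitude", "latency"),
                          names_to = "measure", values_to = "v") %>%
      group_by(.data$component, .data$measure) %>%
      summarise(choice = list(tryCatch(choose_transform(.data$v),
                                       error = function(e) NULL)),
                .groups = "drop")
  })

  tct_res <- stage("tct", {
    set.seed(seed + 1L)
    tct(analysis_data, window = config$window, n_perm = config$n_perm)
  })

  cv <- NULL
  k <- config$k
  if (identical(k, "auto")) {
    cv <- stage("cross_validation", {
      cross_validate_k(analysis_data, k_range = config$k_range,
                       n_iter = config$cv_iter,
                       seed = seed + 2L, window = config$window,
                       polarity = config$polarity)
    })
    k <- cv$selected_k
  }

  seg <- stage("segmentation", {
    ms_segment(analysis_data, K = k, restarts = config$restarts,
               seed = seed + 3L, polarity = config$polarity,
               window = config$window)
  })
  features <- stage("features", {
    microstate_features(analysis_data, seg$templates, window = config$window,
                        polarity = config$polarity)
  })

  stats_res <- stage("stats", {
    ms_stats <- purrr::map_dfr(c("auc", "duration"), function(feat) {
      purrr::map_dfr(sort(unique(features$class)), function(cl) {
        d <- features %>% filter(.data$class == cl)
        a <- rm_anova_2x3(d, value = feat)
        as_tibble(a) %>% mutate(feature = feat, class = cl, .before = 1)
      })
    })
    onset <- tryCatch(onset_mixed_model(features), error = function(e) NULL)
    peak_stats <- purrr::map_dfr(unique(peaks$component), function(cp) {
      d <- peaks %>% filter(.data$component == cp, !.data$excluded)
      purrr::map_dfr(c("amplitude", "latency"), function(me) {
        a <- tryCatch(rm_anova_2x3(d, value = me), error = function(e) NULL)
        if (is.null(a)) return(tibble())
        as_tibble(a) %>% mutate(component = cp, measure = me, .before = 1)
      })
    })
    list(peak_anovas = peak_stats, microstate_anovas = ms_stats, onset = onset)
  })

  run <- structure(list(dataset = dataset, screen = screen, peaks = peaks,
                        transforms = transforms, tct = tct_res, cv = cv,
                        segmentation = seg, features = features,
                        stats = stats_res, config = config,
                        log = bind_rows(log)),
                   class = "tep_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' @export
print.tep_run <- function(x, ...) {
  cat(sprintf("<tep_run> %d subjects; K = %d, GEV = %.3f; %d peak rows; %d feature rows\n",
              length(x$dataset$subjects), x$segmentation$K, x$segmentation$gev,
              nrow(x$peaks), nrow(x$features)))
  invisible(x)
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) readr::write_csv(df, file.path(dir, name))
  wr(run$peaks, "peaks.csv")
  wr(run$features, "features.csv")
  wr(as_tibble(run$tct), "tct.csv")
  wr(run$segmentation$condition_labels, "label_sequences.csv")
  tmpl <- as.data.frame(run$segmentation$templates)
  tmpl$channel <- rownames(run$segmentation$templates)
  wr(as_tibble(tmpl), "templates.csv")
  if (!is.null(run$cv)) wr(run$cv$curve, "cv_curve.csv")
  if (!is.null(run$screen)) wr(as_tibble(run$screen), "mahalanobis.csv")
  wr(run$stats$peak_anovas, "peak_anovas.csv")
  wr(run$stats$microstate_anovas, "microstate_anovas.csv")
  if (!is.null(run$stats$onset)) wr(run$stats$onset$contrasts, "onset_contrasts.csv")
  wr(run$log, "run_log.csv")
  invisible(dir)
}
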