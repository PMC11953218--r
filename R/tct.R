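#' Topographic consistency test
#'
#' Randomization test asking, per timepoint and condition, whether subjects
#' share a common scalp topography. The observed statistic is the GFP of the
#' across-subject mean map. The null distribution is built by independently
#' shuffling each subject's channel order (producing random topographies with
#' each subject's amplitude spectrum intact), re-averaging, and recomputing
#' the mean-map GFP, `n_perm` times. p uses the add-one rule:
#' `p = (1 + #null >= observed) / (1 + n_perm)`, so it is never zero.
#'
#' @param dataset A [tep_dataset()] (the test runs per condition) or a list
#'   of subject matrices (channels x timepoints), treated as one group.
#' @param window Analysis window (ms); defaults to the dataset's.
#' @param n_perm Number of channel-shuffling randomizations (default 5000).
#' @param seed Integer seed.
#' @param normalize GFP-normalize each subject record first (datasets only).
#' @return A `tct_result`: tibble with `condition`, `time`, `observed`,
#'   `null_mean`, `null_sd`, `p`; attributes `n_perm`, `seed`, and
#'   `low_perm` flag when `n_perm < 100`.
#' @export
tct <- function(dataset, window = NULL, n_perm = 5000, seed = NULL,
                normalize = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  low_perm <- n_perm < 100
  if (low_perm) warn("n_perm < 100: p-values are coarse")
  run_one <- function(mats, cond, times) {
    if (length(mats) < 2) abort("TCT needs >= 2 subjects")
    res <- cpp_tct(mats, n_perm)
    tibble(condition = cond, time = times, observed = res$observed,
           null_mean = res$null_mean, null_sd = res$null_sd, p = res$p)
  }
  if (inherits(dataset, "tep_dataset")) {
    window <- window %||% dataset$analysis_window
    out <- purrr::map_dfr(tep_conditions(), function(cond) {
      wd <- strsplit(cond, "_")[[1]]
      times <- NULL
      mats <- lapply(dataset$subjects, function(s) {
        r <- get_record(dataset, s, wd[1], wd[2])
        if (normalize) r <- normalize_by_gfp(r, window)
        r <- crop_evoked(r, window)
        times <<- evoked_times(r)
        r$data
      })
      run_one(mats, cond, times)
    })
  } else {
    mats <- lapply(dataset, as.matrix)
    out <- run_one(mats, "group", seq_len(ncol(mats[[1]])))
  }
  structure(out, class = c("tct_result", class(out)),
            n_perm = n_perm, seed = seed, low_perm = low_perm)
}

#' @export
glance.tct_result <- function(x, ...) {
  x %>% group_by(.data$condition) %>%
    summarise(frac_sig = mean(.data$p < 0.05), min_p = min(.data$p),
              .groups = "drop") %>%
    mutate(n_perm = attr(x, "n_perm"))
}

#' Mahalanobis-distance subject screening
#'
#' Flags subjects whose overall topographic pattern deviates from the group.
#' Each subject is represented by the concatenation of their condition-average
#' maps over the analysis window; the feature space is reduced by principal
#' components retaining at least `var_keep` of the variance (at most
#' `n_subjects - 2` dimensions), and the Mahalanobis distance to the group
#' centroid is computed there. Subjects beyond the chi-square `1 - alpha`
#' quantile for the retained dimension are flagged.
#'
#' @param dataset A [tep_dataset()], >= 5 subjects.
#' @param window Analysis window (ms).
#' @param var_keep Minimum variance fraction retained by the PCA (default 0.9).
#' @param alpha Flagging tail probability (default 0.01).
#' @param normalize GFP-normalize records first.
#' @return Tibble sorted by decreasing distance: `subject_id`, `dist2`
#'   (squared Mahalanobis distance), `rank`, `flagged`; attributes
#'   `threshold` and `n_dim`.
#' @export
mahalanobis_outliers <- function(dataset, window = dataset$analysis_window,
                                 var_keep = 0.9, alpha = 0.01, normalize = TRUE) {
  n <- length(dataset$subjects)
  if (n < 5) abort("outlier screening needs >= 5 subjects")
  feats <- t(vapply(dataset$subjects, function(s) {
    unlist(lapply(.waveforms, function(w) lapply(.directions, function(d) {
      r <- get_record(dataset, s, w, d)
      if (normalize) r <- normalize_by_gfp(r, window)
      as.vector(crop_evoked(r, window)$data)
    })), use.names = FALSE)
  }, numeric(6 * n_channels(dataset$montage) *
               ncol(crop_evoked(dataset$records[[1]], window)$data))))
  X <- scale(feats, center = TRUE, scale = FALSE)
  sv <- svd(X, nu = n, nv = 0)
  lambda <- sv$d^2 / (n - 1)
  cum <- cumsum(lambda) / sum(lambda)
  d <- min(max(which(cum >= var_keep)[1], 1L), n - 2L)
  if (any(lambda[seq_len(d)] < .Machine$double.eps * lambda[1])) {
    abort("singular covariance after reduction; use fewer dimensions (lower var_keep)")
  }
  scores <- sv$u[, seq_len(d), drop = FALSE] %*% diag(sv$d[seq_len(d)], d)
  dist2 <- rowSums(sweep(scores^2, 2, lambda[seq_len(d)], "/"))
  thr <- qchisq(1 - alpha, df = d)
  out <- tibble(subject_id = dataset$subjects, dist2 = dist2) %>%
    arrange(dplyr::desc(.data$dist2)) %>%
    mutate(rank = dplyr::row_number(), flagged = .data$dist2 > thr)
  structure(out, threshold = thr, n_dim = d)
}
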