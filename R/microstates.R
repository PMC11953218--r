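#' Microstate segmentation by modified k-means
#'
#' Clusters scalp topographies into `K` template maps with the modified
#' k-means used for evoked-potential microstate analysis: per restart, `K`
#' templates are seeded from observed timepoints, each timepoint is labelled
#' with the template it correlates best with (signed spatial Pearson
#' correlation by default), templates are refined as the normalized mean of
#' their members, and the configuration with the highest global explained
#' variance (GEV) across all restarts is retained. GEV is the GFP^2-weighted
#' mean squared spatial correlation between each map and its assigned
#' template.
#'
#' @param x A [tep_dataset()] (its per-condition grand averages over the
#'   analysis window, GFP-normalized per subject, are concatenated) or a
#'   channels x timepoints matrix of maps.
#' @param K Number of template maps (default 6).
#' @param restarts Random restarts (default 250).
#' @param seed Integer seed for restart seeding (optional).
#' @param max_iter Maximum label/update iterations per restart.
#' @param polarity `"signed"` (evoked convention, default) labels by signed
#'   correlation; `"ignore"` uses absolute correlation.
#' @param window Analysis window (ms); defaults to the dataset's.
#' @param normalize GFP-normalize subjects before grand-averaging (datasets
#'   only).
#' @param seed_labelings Optional integer matrix (restarts x timepoints,
#'   classes `1..K`) of initial labelings to start restarts from instead of
#'   timepoint seeds (used for exhaustive small-instance audits).
#' @return An `ms_segmentation`: list with `templates` (channels x K,
#'   zero-mean unit-norm columns), `gev`, per-condition `labels` tibbles
#'   (datasets only), `restart_gev`, and provenance (`K`, `restarts`, `seed`,
#'   `polarity`, iterations).
#' @export
ms_segment <- function(x, K = 6, restarts = 250, seed = NULL, max_iter = 100,
                       polarity = c("signed", "ignore"),
                       window = NULL, normalize = TRUE, seed_labelings = NULL) {
  polarity <- match.arg(polarity)
  ga <- NULL
  if (inherits(x, "tep_dataset")) {
    window <- window %||% x$analysis_window
    ga <- grand_averages(x, window = window, normalize = normalize)
    mat <- do.call(cbind, ga)
    times <- attr(ga, "times")
    srate <- attr(ga, "srate")
  } else {
    mat <- as.matrix(x)
    times <- seq_len(ncol(mat))
    srate <- NA_real_
  }
  if (K < 1) abort("K must be >= 1")
  if (K > ncol(mat)) abort("K exceeds number of timepoints")
  Tn <- ncol(mat)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(seed_labelings)) {
    # k-means++-style seeding from data timepoints: first seed drawn with
    # probability ~ GFP^2, later seeds ~ GFP^2 x (1 - best r^2 so far), so
    # restarts start from strong, mutually dissimilar maps
    U <- sweep(mat, 2, colMeans(mat))
    nrm <- sqrt(colSums(U^2))
    w <- nrm^2
    U <- sweep(U, 2, pmax(nrm, .Machine$double.eps), "/")
    seed_idx <- t(vapply(seq_len(restarts), function(i) {
      sel <- integer(K)
      m2 <- rep(0, Tn)
      for (k in seq_len(K)) {
        prob <- if (k == 1) w else w * pmax(1 - m2, 0)
        if (sum(prob) <= 0) prob <- rep(1, Tn)
        sel[k] <- sample.int(Tn, 1, prob = prob)
        m2 <- pmax(m2, as.vector(crossprod(U[, sel[k]], U))^2)
      }
      sel
    }, integer(K))) - 1L
    if (K == 1) seed_idx <- matrix(seed_idx, ncol = 1)
    seed_lab <- matrix(0L, 0, 0)
  } else {
    seed_idx <- matrix(0L, 0, 0)
    seed_lab <- as.matrix(seed_labelings) - 1L
    if (ncol(seed_lab) != Tn) abort("seed_labelings must have one column per timepoint")
  }
  fit <- cpp_modkmeans(mat, K, seed_idx, seed_lab, max_iter,
                       polarity == "ignore")
  templates <- fit$templates
  colnames(templates) <- paste0("class", seq_len(K))
  if (inherits(x, "tep_dataset")) rownames(templates) <- x$montage$channel_names
  labels_all <- fit$labels + 1L
  res <- structure(list(
    templates = templates, gev = fit$gev,
    labels = labels_all, times = times, srate = srate,
    restart_gev = as.numeric(fit$restart_gev),
    restart_iter = as.integer(fit$restart_iter),
    K = K, restarts = if (is.null(seed_labelings)) restarts else nrow(seed_lab),
    seed = seed, polarity = polarity, window = window
  ), class = "ms_segmentation")
  if (!is.null(ga)) {
    nt <- length(times)
    res$condition_labels <- purrr::imap(ga, function(m, cond) {
      i <- which(names(ga) == cond)
      idx <- ((i - 1) * nt + 1):(i * nt)
      tibble(condition = cond, time = times, class = labels_all[idx],
             gfp = gfp_of_matrix(m))
    }) %>% bind_rows()
  }
  res
}

#' @export
print.ms_segmentation <- function(x, ...) {
  cat(sprintf("<ms_segmentation> K = %d, GEV = %.4f (%d restarts, polarity %s)\n",
              x$K, x$gev, x$restarts, x$polarity))
  invisible(x)
}

#' @export
glance.ms_segmentation <- function(x, ...) {
  tibble(K = x$K, gev = x$gev, restarts = x$restarts,
         polarity = x$polarity,
         mean_iterations = mean(x$restart_iter))
}

#' @export
tidy.ms_segmentation <- function(x, ...) {
  as_tibble(as.data.frame(x$templates)) %>%
    mutate(channel = rownames(x$templates) %||% paste0("ch", dplyr::row_number())) %>%
    tidyr::pivot_longer(-dplyr::all_of("channel"), names_to = "class",
                        values_to = "weight")
}

#' Backfit template maps to an evoked record
#'
#' Labels every timepoint of a record with the template it correlates best
#' with (same polarity rule as segmentation; ties go to the lowest class
#' index). Timepoints whose best absolute correlation falls below 0.5 are
#' counted as low-confidence.
#'
#' @param templates Channels x K template matrix (e.g. from
#'   [ms_segment()]`$templates`).
#' @param ev A [subject_evoked()] record or channels x timepoints matrix.
#' @param window Analysis window (ms), applied if `ev` is a record.
#' @param polarity `"signed"` or `"ignore"`.
#' @return An `ms_labels` object: tibble with `time`, `class`, `corr`, `gfp`
#'   plus attributes `srate` and `low_confidence` (fraction with max |r| <
#'   0.5).
#' @export
ms_backfit <- function(templates, ev, window = c(5, 400),
                       polarity = c("signed", "ignore")) {
  polarity <- match.arg(polarity)
  if (inherits(ev, "tep_evoked")) {
    ev <- crop_evoked(ev, window)
    mat <- ev$data
    times <- evoked_times(ev)
    srate <- ev$srate
  } else {
    mat <- as.matrix(ev)
    times <- seq_len(ncol(mat))
    srate <- NA_real_
  }
  R <- cpp_spatial_corr(templates, mat)
  score <- if (polarity == "ignore") abs(R) else R
  cls <- apply(score, 2, which.max)   # which.max: first max -> lowest index
  rbest <- R[cbind(cls, seq_along(cls))]
  out <- tibble(time = times, class = as.integer(cls), corr = rbest,
                gfp = gfp_of_matrix(mat))
  structure(out, class = c("ms_labels", class(out)),
            srate = srate, K = nrow(R),
            low_confidence = mean(abs(rbest) < 0.5))
}

#' Microstate features of a labelled sequence
#'
#' Per class: AUC (sum of GFP over the timepoints labelled with the class,
#' times the sample step, ms*uV), duration (number of labelled timepoints
#' times the sample step, ms) and onset (time of the first labelled sample,
#' `NA` if the class never occurs). Durations sum to the labelled span and
#' AUCs to the total GFP area exactly.
#'
#' @param labels An `ms_labels` object from [ms_backfit()], or a tibble with
#'   columns `time`, `class`, `gfp`.
#' @param K Number of classes (defaults to the labels' `K` attribute or the
#'   maximum observed class).
#' @return Tibble with `class`, `auc`, `duration`, `onset`.
#' @export
ms_features <- function(labels, K = NULL) {
  K <- K %||% attr(labels, "K") %||% max(labels$class)
  srate <- attr(labels, "srate")
  dt <- if (!is.null(srate) && is.finite(srate)) 1000 / srate else
    stats::median(diff(labels$time))
  purrr::map_dfr(seq_len(K), function(k) {
    sel <- labels$class == k
    tibble(class = k,
           auc = sum(labels$gfp[sel]) * dt,
           duration = sum(sel) * dt,
           onset = if (any(sel)) labels$time[which(sel)[1]] else NA_real_)
  })
}

#' Subject-level microstate feature table
#'
#' Backfits a set of group template maps to every subject x condition record
#' (GFP-normalized by default, matching the segmentation input) and extracts
#' AUC, duration and onset per class — the long-format table the statistical
#' layer consumes.
#'
#' @param dataset A [tep_dataset()].
#' @param templates Channels x K template matrix.
#' @inheritParams ms_backfit
#' @param normalize GFP-normalize each record before backfitting.
#' @return Tibble: `subject_id`, `waveform`, `direction`, `condition`,
#'   `class`, `auc`, `duration`, `onset`.
#' @export
microstate_features <- function(dataset, templates,
                                window = dataset$analysis_window,
                                polarity = c("signed", "ignore"),
                                normalize = TRUE) {
  polarity <- match.arg(polarity)
  purrr::map_dfr(dataset$records, function(r) {
    if (normalize) r <- normalize_by_gfp(r, window)
    lab <- ms_backfit(templates, r, window = window, polarity = polarity)
    ms_features(lab, K = ncol(templates)) %>%
      mutate(subject_id = r$subject_id, waveform = r$waveform,
             direction = r$direction,
             condition = condition_label(r$waveform, r$direction),
             .before = 1)
  })
}

#' Cross-validated selection of the number of microstate maps
#'
#' For each candidate `K`, subjects are repeatedly split into a learning and
#' a test half; templates are fit on the learning half's concatenated
#' condition grand-averages and their GEV when backfit to the test half's
#' grand-averages is recorded. The curve is the mean test GEV per `K`;
#' `selected_k` is the smallest `K` whose curve value reaches within
#' `plateau_tol` (relative) of the curve maximum — the "first K on the
#' plateau" rule.
#'
#' @param dataset A [tep_dataset()], >= 4 subjects.
#' @param k_range Length-2 integer range of `K` (default `c(3, 12)`).
#' @param n_iter Number of random split iterations (default 50).
#' @param restarts k-means restarts per fit (default 3; with the
#'   residual-weighted seeding a handful of restarts per fit suffices inside
#'   the cross-validation loop, unlike a final segmentation).
#' @param plateau_tol Relative plateau tolerance (default 0.01).
#' @param seed Integer seed.
#' @param max_iter,polarity,window,normalize Passed to the segmentation.
#' @return An `ms_cv` object: `curve` tibble (`K`, `mean_test_gev`),
#'   `selected_k`, `unreliable` flag (max curve < 0.5), `n_iter`, `seed`.
#' @export
cross_validate_k <- function(dataset, k_range = c(3, 12), n_iter = 50,
                             restarts = 3, plateau_tol = 0.01, seed = NULL,
                             max_iter = 20, polarity = c("signed", "ignore"),
                             window = dataset$analysis_window, normalize = TRUE) {
  polarity <- match.arg(polarity)
  subjects <- dataset$subjects
  n <- length(subjects)
  if (n < 4) abort("cross-validation needs >= 4 subjects")
  ks <- seq(k_range[1], k_range[2])
  # per-subject normalized, cropped condition matrices, computed once
  cache <- list()
  for (s in subjects) for (w in .waveforms) for (d in .directions) {
    r <- get_record(dataset, s, w, d)
    if (normalize) r <- normalize_by_gfp(r, window)
    cache[[paste(s, w, d)]] <- crop_evoked(r, window)$data
  }
  if (max(ks) >= ncol(cache[[1]]) * 6) abort("k_max too large for the data")
  if (max(ks) >= n_channels(dataset$montage)) abort("k_max must be below the channel count")
  half_ga <- function(subs) {
    do.call(cbind, lapply(.waveforms, function(w) {
      do.call(cbind, lapply(.directions, function(d) {
        Reduce(`+`, lapply(subs, function(s) cache[[paste(s, w, d)]])) / length(subs)
      }))
    }))
  }
  if (!is.null(seed)) set.seed(seed)
  ev <- matrix(NA_real_, n_iter, length(ks))
  for (i in seq_len(n_iter)) {
    learn <- sample(subjects, floor(n / 2))
    test <- setdiff(subjects, learn)
    Xl <- half_ga(learn)
    Xt <- half_ga(test)
    wt <- colSums(sweep(Xt, 2, colMeans(Xt))^2)
    Ut <- sweep(Xt, 2, colMeans(Xt))
    nrm <- sqrt(colSums(Ut^2))
    Ut <- sweep(Ut, 2, pmax(nrm, .Machine$double.eps), "/")
    for (j in seq_along(ks)) {
      fit <- ms_segment(Xl, K = ks[j], restarts = restarts, max_iter = max_iter,
                        polarity = polarity)
      R <- crossprod(fit$templates, Ut)
      score <- if (polarity == "ignore") abs(R) else R
      rbest <- R[cbind(max.col(t(score), ties.method = "first"), seq_len(ncol(R)))]
      ev[i, j] <- sum(wt * rbest^2) / sum(wt)
    }
  }
  curve <- tibble(K = ks, mean_test_gev = colMeans(ev))
  mx <- max(curve$mean_test_gev)
  sel <- curve$K[which(curve$mean_test_gev >= (1 - plateau_tol) * mx)[1]]
  structure(list(curve = curve, selected_k = sel,
                 unreliable = mx < 0.5, n_iter = n_iter, seed = seed,
                 plateau_tol = plateau_tol),
            class = "ms_cv")
}

#' @export
print.ms_cv <- function(x, ...) {
  cat(sprintf("<ms_cv> selected K = %d over K in [%d, %d] (%d iterations%s)\n",
              x$selected_k, min(x$curve$K), max(x$curve$K), x$n_iter,
              if (x$unreliable) "; UNRELIABLE: low explained variance" else ""))
  invisible(x)
}

#' @export
tidy.ms_cv <- function(x, ...) x$curve

#' Match estimated templates to reference maps
#'
#' Finds the class permutation maximizing the total absolute spatial
#' correlation between estimated and reference templates (exhaustive over
#' permutations for K <= 8, greedy beyond). Used to assess template recovery
#' up to sign and permutation.
#'
#' @param est,ref Channels x K matrices.
#' @return Tibble with `ref_class`, `est_class`, `abs_corr`.
#' @export
match_templates <- function(est, ref) {
  K <- ncol(ref)
  A <- abs(crossprod(unitize_maps(est), unitize_maps(ref)))  # est x ref
  if (K <= 8 && ncol(est) == K) {
    perms <- all_perms(K)
    sc <- vapply(perms, function(p) sum(A[cbind(p, seq_len(K))]), 1.0)
    p <- perms[[which.max(sc)]]
  } else {
    p <- integer(K)
    used <- rep(FALSE, nrow(A))
    for (j in order(-apply(A, 2, max))) {
      cand <- which.max(ifelse(used, -Inf, A[, j]))
      p[j] <- cand
      used[cand] <- TRUE
    }
  }
  tibble(ref_class = seq_len(K), est_class = p,
         abs_corr = A[cbind(p, seq_len(K))])
}

unitize_maps <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  n <- sqrt(colSums(m^2))
  sweep(m, 2, pmax(n, .Machine$double.eps), "/")
}

all_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- list()
  for (p in sub) for (i in 0:(n - 1L)) {
    out[[length(out) + 1L]] <- append(p, n, after = i)
  }
  out
}
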