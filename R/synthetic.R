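#' Random smooth template maps
#'
#' Draws `K` spatially smooth random scalp maps: Gaussian channel noise
#' smoothed by a squared-exponential kernel over the electrode positions,
#' then average-referenced (zero mean) and unit-L2-normalized. Maps are
#' redrawn until every pair satisfies `|spatial correlation| <= 1 -
#' min_separation`. Smooth random fields stand in for dipolar topographies:
#' clustering only ever sees the topography vectors, so spatial smoothness
#' (not forward-model realism) is what matters.
#'
#' @param montage A [tep_montage()].
#' @param K Number of maps, `<=` channel count.
#' @param seed Integer seed (optional).
#' @param min_separation In `[0, 1)`: required pairwise separation (default
#'   0.5, i.e. `|r| <= 0.5`).
#' @param smoothness Kernel length scale in unit-sphere chord units
#'   (default 0.7).
#' @param max_tries Redraw budget per map before erroring.
#' @return Channels x K matrix (zero-mean unit-norm columns), with attributes
#'   `seed` and `min_separation`.
#' @export
make_template_maps <- function(montage, K, seed = NULL, min_separation = 0.5,
                               smoothness = 0.7, max_tries = 500) {
  if (K > n_channels(montage)) abort("K exceeds channel count")
  if (min_separation < 0 || min_separation >= 1) abort("min_separation must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  D <- montage_dist(montage)
  L <- exp(-D^2 / (2 * smoothness^2))
  maps <- matrix(NA_real_, n_channels(montage), 0)
  tries <- 0
  while (ncol(maps) < K) {
    m <- L %*% rnorm(n_channels(montage))
    m <- m - mean(m)
    nm <- sqrt(sum(m^2))
    if (nm < .Machine$double.eps) next
    m <- m / nm
    ok <- ncol(maps) == 0 || all(abs(crossprod(maps, m)) <= 1 - min_separation)
    if (ok) {
      maps <- cbind(maps, m)
    } else {
      tries <- tries + 1
      if (tries > max_tries) {
        abort(sprintf("could not draw %d maps at separation %.2f after %d retries",
                      K, min_separation, max_tries))
      }
    }
  }
  colnames(maps) <- paste0("class", seq_len(K))
  rownames(maps) <- montage$channel_names
  attr(maps, "seed") <- seed
  attr(maps, "min_separation") <- min_separation
  maps
}

#' GFP envelope of a simulated TEP
#'
#' Sum of Gaussian bumps describing the target GFP time course (uV). The
#' defaults place bumps at the canonical M1-TEP component latencies
#' (15/30/45/60/100/180 ms) with widths and peak amplitudes of plausible
#' magnitude for suprathreshold motor-cortex stimulation, plus a broad
#' low-amplitude late slow wave (300 ms) so that, as in recorded TEPs, the
#' field does not vanish in the late part of the epoch.
#'
#' @param centers,widths,peaks Numeric vectors (ms, ms, uV); widths > 0,
#'   peaks >= 0.
#' @return A `gfp_envelope` tibble with columns `center_ms`, `width_ms`,
#'   `peak_uv`.
#' @export
gfp_envelope <- function(centers = c(15, 30, 45, 60, 100, 180, 300),
                         widths = c(4, 5, 6, 8, 15, 25, 60),
                         peaks = c(4, 5, 4, 5, 6, 4, 2)) {
  if (any(widths <= 0)) abort("envelope widths must be > 0")
  if (any(peaks < 0)) abort("envelope peaks must be >= 0")
  structure(tibble(center_ms = centers, width_ms = widths, peak_uv = peaks),
            class = c("gfp_envelope", "tbl_df", "tbl", "data.frame"))
}

#' Evaluate a GFP envelope at times `t` (ms)
#' @param env A [gfp_envelope()].
#' @param t Numeric vector of times (ms).
#' @return Numeric vector of envelope values (uV).
#' @export
eval_envelope <- function(env, t) {
  out <- numeric(length(t))
  for (i in seq_len(nrow(env))) {
    out <- out + env$peak_uv[i] * exp(-(t - env$center_ms[i])^2 / (2 * env$width_ms[i]^2))
  }
  out
}

#' Microstate segment plan
#'
#' Ordered, contiguous class segments for one condition: class `classes[i]`
#' occupies `[onsets[i], onsets[i] + durations[i])` ms.
#'
#' @param classes Integer class indices.
#' @param onsets,durations ms; segments must be non-overlapping and ordered.
#' @return Tibble `class`, `onset_ms`, `duration_ms`.
#' @export
segment_plan <- function(classes, onsets, durations) {
  if (any(durations <= 0)) abort("segment durations must be > 0")
  ends <- onsets + durations
  if (any(diff(onsets) <= 0) || any(onsets[-1] < ends[-length(ends)] - 1e-9)) {
    abort("segments must be ordered and non-overlapping")
  }
  tibble(class = as.integer(classes), onset_ms = onsets, duration_ms = durations)
}

#' Default and order-swapped segment plans
#'
#' `default_segment_plan()` tiles the 5-400 ms analysis window with six
#' classes in order, with boundaries roughly tracking the component
#' latencies. `swap_segment_plans()` returns two plans identical except that
#' classes 1 and 2 exchange their temporal slots (`delta` ms apart) — the
#' ground truth for onset-order swap analyses.
#'
#' @return A [segment_plan()] tibble (or a list of two, `plan_a`/`plan_b`).
#' @export
default_segment_plan <- function() {
  segment_plan(1:6,
               onsets = c(5, 25, 45, 70, 120, 220),
               durations = c(20, 20, 25, 50, 100, 180))
}

#' @param delta Onset difference (ms) between the swapped classes.
#' @rdname default_segment_plan
#' @export
swap_segment_plans <- function(delta = 60) {
  # classes 1 and 2 exchange their slots between the two plans; others fixed
  p1 <- segment_plan(c(1, 2, 3, 4, 5, 6),
                     onsets = c(5, 5 + delta, 125, 170, 220, 300),
                     durations = c(delta, 60, 45, 50, 80, 100))
  p2 <- segment_plan(c(2, 1, 3, 4, 5, 6),
                     onsets = c(5, 5 + delta, 125, 170, 220, 300),
                     durations = c(delta, 60, 45, 50, 80, 100))
  list(plan_a = p1, plan_b = p2)
}

#' Simulate a multi-subject TEP dataset with known microstate structure
#'
#' Each subject x condition record is built as: for every timepoint inside a
#' planned segment, `envelope(t) * scale_subj * sqrt(n_ch) * map_class`,
#' where `map_class` is the subject's (optionally spatially perturbed) copy
#' of the true template, so the noiseless GFP equals `envelope(t) *
#' scale_subj` exactly inside segments; plus Gaussian sensor noise
#' everywhere. Segment boundaries are jittered per subject and condition.
#'
#' @param n_subjects Number of subjects.
#' @param montage A [tep_montage()].
#' @param templates True maps (channels x K, zero-mean unit-norm), e.g. from
#'   [make_template_maps()].
#' @param plans Named list of [segment_plan()]s, one per condition label (or
#'   a single plan used for all six conditions).
#' @param envelope A [gfp_envelope()].
#' @param srate Sampling rate (default 960).
#' @param epoch Epoch span `c(start, end)` ms (default `c(-200, 400)`).
#' @param noise_sd Sensor noise SD (uV; default 0).
#' @param amp_sdlog Log-SD of the lognormal per-subject amplitude scale
#'   (default 0.2).
#' @param latency_jitter_sd Per-subject, per-condition SD (ms) of segment
#'   boundary jitter (default 3).
#' @param spatial_noise Fraction of a random smooth map mixed into each
#'   subject's templates (default 0.1).
#' @param seed Integer seed (the whole dataset is reproducible from it).
#' @param analysis_window Stored on the dataset (default `c(5, 400)`).
#' @return List with `dataset` (a [tep_dataset()]) and `truth` (a
#'   `tep_ground_truth`: true templates, plans, subject parameters, realized
#'   per-record onsets/durations, `noise_sd`, `seed`).
#' @export
simulate_tep_dataset <- function(n_subjects, montage, templates, plans,
                                 envelope = gfp_envelope(), srate = 960,
                                 epoch = c(-200, 400), noise_sd = 0,
                                 amp_sdlog = 0.2, latency_jitter_sd = 3,
                                 spatial_noise = 0.1, seed = NULL,
                                 analysis_window = c(5, 400)) {
  if (n_subjects < 1) abort("n_subjects must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  conds <- tep_conditions()
  if (inherits(plans, "data.frame")) plans <- setNames(rep(list(plans), 6), conds)
  if (!all(conds %in% names(plans))) abort("plans must cover all six conditions")
  K <- ncol(templates)
  for (p in plans) if (any(p$class > K)) abort("plan classes exceed template count")
  nch <- n_channels(montage)
  dt <- 1000 / srate
  nsamp <- floor((epoch[2] - epoch[1]) * srate / 1000)
  times <- epoch[1] + (seq_len(nsamp) - 1) * dt
  D <- montage_dist(montage)
  L <- exp(-D^2 / (2 * 0.7^2))
  subj_ids <- sprintf("S%02d", seq_len(n_subjects))

  subj_scale <- exp(rnorm(n_subjects, 0, amp_sdlog))
  subj_templates <- lapply(seq_len(n_subjects), function(i) {
    if (spatial_noise <= 0) return(templates)
    pert <- apply(templates, 2, function(m) {
      r <- L %*% rnorm(nch); r <- r - mean(r); r <- r / sqrt(sum(r^2))
      v <- m + spatial_noise * r
      v <- v - mean(v); v / sqrt(sum(v^2))
    })
    pert
  })

  records <- list()
  realized <- list()
  for (i in seq_len(n_subjects)) {
    for (cond in conds) {
      wd <- strsplit(cond, "_")[[1]]
      plan <- plans[[cond]]
      ons <- plan$onset_ms
      ends <- ons + plan$duration_ms
      bounds <- c(ons, ends[length(ends)])
      if (latency_jitter_sd > 0) {
        jb <- bounds + c(rnorm(length(bounds) - 1, 0, latency_jitter_sd), 0)
        # keep boundaries ordered, inside the window, segments >= 2 samples
        jb[1] <- max(jb[1], analysis_window[1])
        for (k in 2:length(jb)) jb[k] <- max(jb[k], jb[k - 1] + 2 * dt)
        jb <- pmin(jb, bounds[length(bounds)])
        for (k in (length(jb) - 1):1) jb[k] <- min(jb[k], jb[k + 1] - 2 * dt)
        bounds <- jb
      }
      mat <- matrix(0, nch, nsamp)
      env <- eval_envelope(envelope, times)
      for (sgi in seq_len(nrow(plan))) {
        sel <- times >= bounds[sgi] - 1e-9 & times < bounds[sgi + 1] - 1e-9
        if (!any(sel)) next
        mp <- subj_templates[[i]][, plan$class[sgi]]
        mat[, sel] <- outer(mp * sqrt(nch), env[sel] * subj_scale[i])
      }
      if (noise_sd > 0) mat <- mat + matrix(rnorm(nch * nsamp, 0, noise_sd), nch, nsamp)
      records[[length(records) + 1]] <-
        subject_evoked(subj_ids[i], wd[1], wd[2], mat, srate, epoch[1])
      realized[[length(realized) + 1]] <-
        tibble(subject_id = subj_ids[i], condition = cond,
               class = plan$class,
               onset_ms = bounds[-length(bounds)],
               duration_ms = diff(bounds))
    }
  }
  dataset <- tep_dataset(montage, records, analysis_window = analysis_window)
  truth <- structure(list(
    templates = templates, plans = plans,
    subject_params = tibble(subject_id = subj_ids, amp_scale = subj_scale,
                            spatial_noise = spatial_noise,
                            latency_jitter_sd = latency_jitter_sd),
    realized_segments = bind_rows(realized),
    envelope = envelope, noise_sd = noise_sd, seed = seed
  ), class = "tep_ground_truth")
  list(dataset = dataset, truth = truth)
}

#' Replace one subject's records with a deviant version
#'
#' Utility for validating the Mahalanobis subject screen: corrupts one
#' subject by scrambling their channel order (`"scramble_channels"`, one
#' permutation shared across that subject's records), flipping polarity
#' (`"flip_polarity"`), or replacing the data with white sensor noise of the
#' group's amplitude (`"pure_noise"`).
#'
#' @param dataset A [tep_dataset()].
#' @param subject_id Subject to corrupt.
#' @param mode One of `"scramble_channels"`, `"flip_polarity"`, `"pure_noise"`.
#' @param seed Integer seed.
#' @return The modified [tep_dataset()].
#' @export
make_deviant_subject <- function(dataset, subject_id,
                                 mode = c("scramble_channels", "flip_polarity",
                                          "pure_noise"),
                                 seed = NULL) {
  mode <- match.arg(mode)
  if (!subject_id %in% dataset$subjects) {
    abort(paste0("unknown subject: ", subject_id))
  }
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(n_channels(dataset$montage))
  group_sd <- sd(unlist(lapply(dataset$records[1:min(6, length(dataset$records))],
                               function(r) as.vector(r$data))))
  dataset$records <- lapply(dataset$records, function(r) {
    if (r$subject_id != subject_id) return(r)
    r$data <- switch(mode,
      scramble_channels = r$data[perm, , drop = FALSE],
      flip_polarity = -r$data,
      pure_noise = matrix(rnorm(length(r$data), 0, group_sd),
                          nrow(r$data), ncol(r$data)))
    r
  })
  dataset
}

#' Bundled synthetic fixtures
#'
#' Named dataset configurations used throughout the tests and examples:
#' \describe{
#'   \item{clean6}{27 subjects, 74 channels, 6 well-separated true maps
#'     occupying the same contiguous segments in all six conditions,
#'     component-latency GFP envelope, sensor SNR ~ 5 (`snr` adjustable).}
#'   \item{swapAB}{As clean6, but classes 1 and 2 swap their order of
#'     appearance between monophasic and biphasic conditions (onset
#'     difference 60 ms), boundary jitter 10 ms.}
#'   \item{swapnull}{The swapAB geometry with identical plans in all
#'     conditions (no swap); the matched null for power/type-I studies.}
#'   \item{deviant1}{clean6 with subject S01's channels scrambled.}
#'   \item{nullflat}{Pure sensor noise, no topographic structure (20
#'     subjects, 1000-sample window) for calibration of the topographic
#'     consistency test.}
#' }
#'
#' @param name Fixture name.
#' @param seed Integer seed.
#' @param n_subjects Override the fixture's subject count.
#' @param snr Signal-to-noise ratio: mean in-window noiseless GFP divided by
#'   the sensor noise SD (clean6/swapAB/deviant1; default 5).
#' @param dir If non-NULL, the dataset is also written there with
#'   [write_evoked_dataset()] (plus `ground_truth_segments.csv`).
#' @return List with `dataset` and `truth` (NULL for `nullflat`).
#' @export
make_fixture <- function(name = c("clean6", "swapAB", "swapnull", "deviant1",
                                  "nullflat"),
                         seed = 1, n_subjects = NULL, snr = 5, dir = NULL) {
  name <- match.arg(name)
  montage <- montage_1010_74()
  env <- gfp_envelope()
  noise_for <- function(snr) {
    tt <- seq(5, 400, by = 1000 / 960)
    mean(eval_envelope(env, tt)) / snr
  }
  out <- switch(name,
    clean6 = ,
    deviant1 = {
      sim <- simulate_tep_dataset(
        n_subjects %||% 27, montage,
        make_template_maps(montage, 6, seed = seed, min_separation = 0.5),
        default_segment_plan(), env, noise_sd = noise_for(snr),
        seed = seed + 1000L)
      if (name == "deviant1") {
        sim$dataset <- make_deviant_subject(sim$dataset, "S01",
                                            "scramble_channels", seed = seed + 2000L)
        sim$truth$deviant <- "S01"
      }
      sim
    },
    swapAB = ,
    swapnull = {
      sp <- swap_segment_plans(delta = 60)
      plans <- setNames(vector("list", 6), tep_conditions())
      for (cond in tep_conditions()) {
        mono <- startsWith(cond, "monophasic")
        plans[[cond]] <- if (name == "swapAB" && !mono) sp$plan_b else sp$plan_a
      }
      simulate_tep_dataset(
        n_subjects %||% 27, montage,
        make_template_maps(montage, 6, seed = seed, min_separation = 0.5),
        plans, env, noise_sd = noise_for(snr),
        latency_jitter_sd = 10, seed = seed + 1000L)
    },
    nullflat = {
      n <- n_subjects %||% 20
      set.seed(seed)
      nsamp <- 1000
      srate <- 960
      records <- list()
      for (i in seq_len(n)) for (w in .waveforms) for (d in .directions) {
        records[[length(records) + 1]] <- subject_evoked(
          sprintf("S%02d", i), w, d,
          matrix(rnorm(74 * nsamp), 74, nsamp), srate, 0)
      }
      win <- c(0, nsamp * 1000 / srate)
      list(dataset = tep_dataset(montage, records, analysis_window = win),
           truth = NULL)
    })
  if (!is.null(dir)) {
    write_evoked_dataset(out$dataset, dir)
    if (!is.null(out$truth)) {
      readr::write_csv(out$truth$realized_segments,
                       file.path(dir, "ground_truth_segments.csv"))
    }
  }
  out
}
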