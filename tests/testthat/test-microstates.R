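test_that("noiseless segmentation attains GEV 1 and recovers the true maps", {
  sim <- tiny_sim(n_subjects = 2, nch = 12, K = 3, seed = 51)
  seg <- ms_segment(sim$dataset, K = 3, restarts = 30, seed = 52)
  expect_equal(seg$gev, 1, tolerance = 1e-9)
  mt <- match_templates(seg$templates, sim$truth$templates)
  expect_true(all(mt$abs_corr >= 0.999))
  # retained GEV dominates every restart (maximization audit)
  expect_true(all(seg$restart_gev <= seg$gev + 1e-12))
})

test_that("K = 1 segmentation is the normalized dominant pattern, reproducibly", {
  sim <- tiny_sim(n_subjects = 1, nch = 8, K = 2, seed = 61, noise_sd = 0.2)
  X <- crop_evoked(sim$dataset$records[[1]], c(5, 200))$data
  s1 <- ms_segment(X, K = 1, restarts = 5, seed = 3)
  s2 <- ms_segment(X, K = 1, restarts = 5, seed = 3)
  expect_identical(s1$templates, s2$templates)
  expect_equal(sum(s1$templates^2), 1, tolerance = 1e-12)
  expect_true(all(s1$labels == 1))
  expect_true(s1$gev > 0 && s1$gev <= 1)
})

test_that("segmentation is invariant to global amplitude rescaling", {
  sim <- tiny_sim(n_subjects = 1, nch = 10, K = 3, seed = 71, noise_sd = 0.3)
  X <- crop_evoked(sim$dataset$records[[1]], c(5, 200))$data
  a <- ms_segment(X, K = 3, restarts = 20, seed = 5)
  b <- ms_segment(5 * X, K = 3, restarts = 20, seed = 5)
  expect_equal(a$templates, b$templates, tolerance = 1e-9)
  expect_identical(a$labels, b$labels)
  expect_equal(a$gev, b$gev, tolerance = 1e-12)
})

test_that("GEV is non-decreasing in K under exhaustive restarts", {
  set.seed(77)
  X <- matrix(rnorm(3 * 7), 3, 7)
  gev_k <- vapply(1:3, function(K) {
    labs <- as.matrix(expand.grid(rep(list(seq_len(K)), 7)))
    ms_segment(X, K = K, seed_labelings = labs, max_iter = 50)$gev
  }, 1.0)
  expect_true(all(diff(gev_k) >= -1e-12))
})

test_that("backfitting labels by best correlation with documented tie handling", {
  m <- small_montage(10)
  tm <- make_template_maps(m, 3, seed = 81)
  # record built from template 3 only
  mat <- outer(tm[, 3], rep(1, 20)) * rep(2, 20) + 0
  lab <- ms_backfit(tm, mat)
  expect_true(all(lab$class == 3))
  expect_equal(lab$corr, rep(1, 20), tolerance = 1e-9)

  # a map orthogonal to all templates: tie on |r| ~ 0 -> lowest index, flagged
  Q <- qr.Q(qr(cbind(tm, rnorm(10))))
  orth <- Q[, 4] - mean(Q[, 4])
  lab2 <- ms_backfit(tm, outer(orth, rep(1, 5)))
  expect_gt(attr(lab2, "low_confidence"), 0.99)
})

test_that("noiseless swapped-order conditions backfit to the planned sequences", {
  m <- small_montage(12)
  tm <- make_template_maps(m, 3, seed = 91, min_separation = 0.4)
  pa <- segment_plan(c(1, 2, 3), onsets = c(5, 65, 125), durations = c(60, 60, 70))
  pb <- segment_plan(c(2, 1, 3), onsets = c(5, 65, 125), durations = c(60, 60, 70))
  plans <- setNames(rep(list(pa), 6), tep_conditions())
  plans$biphasic_PA <- pb
  env <- gfp_envelope(centers = c(30, 90, 160), widths = c(15, 15, 20),
                      peaks = c(4, 4, 3))
  sim <- simulate_tep_dataset(1, m, tm, plans, env, srate = 500,
                              epoch = c(-50, 200), amp_sdlog = 0,
                              latency_jitter_sd = 0, spatial_noise = 0,
                              seed = 92, analysis_window = c(5, 195))
  for (cond in c("monophasic_PA", "biphasic_PA")) {
    wd <- strsplit(cond, "_")[[1]]
    r <- get_record(sim$dataset, "S01", wd[1], wd[2])
    lab <- ms_backfit(tm, r, window = c(5, 195))
    ft <- ms_features(lab, K = 3)
    plan <- sim$truth$plans[[cond]]
    truth_onset <- plan$onset_ms[order(plan$class)]
    # onsets must match the plan within one sample
    expect_true(all(abs(ft$onset - truth_onset) <= 1000 / 500 + 1e-9),
                info = cond)
  }
})

test_that("microstate features obey their arithmetic and conservation laws", {
  lab <- tibble::tibble(time = seq(0, by = 1000 / 960, length.out = 100),
                        class = rep(2L, 100), gfp = rep(1, 100))
  attr(lab, "srate") <- 960
  attr(lab, "K") <- 3
  ft <- ms_features(lab)
  expect_equal(ft$duration[2], 100 * 1000 / 960)
  expect_equal(ft$auc[2], 100 * 1000 / 960)
  expect_equal(ft$onset[2], 0)
  # absent classes
  expect_equal(ft$duration[c(1, 3)], c(0, 0))
  expect_true(all(is.na(ft$onset[c(1, 3)])))

  # interleaved classes conserve total duration and GFP area
  lab2 <- tibble::tibble(time = seq(0, by = 2, length.out = 50),
                         class = rep(c(1L, 2L), 25),
                         gfp = runif(50, 0.5, 2))
  attr(lab2, "srate") <- 500
  ft2 <- ms_features(lab2, K = 2)
  expect_equal(sum(ft2$duration), 50 * 2)
  expect_equal(sum(ft2$auc), sum(lab2$gfp) * 2)
})

test_that("cross-validation recovers the true map count on clean small data", {
  sim <- tiny_sim(n_subjects = 6, nch = 12, K = 3, seed = 101, noise_sd = 0.15)
  cv <- cross_validate_k(sim$dataset, k_range = c(2, 6), n_iter = 10, seed = 102,
                         window = c(5, 200))
  expect_equal(cv$selected_k, 3)
  expect_false(cv$unreliable)
  expect_equal(nrow(cv$curve), 5)
  expect_true(all(is.finite(cv$curve$mean_test_gev)))
})

test_that("Mahalanobis screening ranks deviants first and respects symmetry", {
  sim <- tiny_sim(n_subjects = 8, nch = 16, K = 3, seed = 111, noise_sd = 0.2,
                  spatial = 0.1)
  dev <- make_deviant_subject(sim$dataset, "S05", "scramble_channels", seed = 4)
  sc <- mahalanobis_outliers(dev, window = c(5, 200))
  expect_equal(sc$subject_id[1], "S05")

  # duplicated subjects get equal distances: copy S02's data onto S01
  ds <- sim$dataset
  for (i in seq_along(ds$records)) {
    r <- ds$records[[i]]
    if (r$subject_id == "S01") {
      src <- get_record(sim$dataset, "S02", r$waveform, r$direction)
      ds$records[[i]]$data <- src$data
    }
  }
  sc2 <- mahalanobis_outliers(ds, window = c(5, 200))
  d12 <- sc2$dist2[match(c("S01", "S02"), sc2$subject_id)]
  expect_equal(d12[1], d12[2], tolerance = 1e-8)

  small <- tiny_sim(n_subjects = 3, nch = 8, K = 2, seed = 112)
  expect_error(mahalanobis_outliers(small$dataset), ">= 5")
})
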