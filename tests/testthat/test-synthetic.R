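test_that("template maps are zero-mean, unit-norm, separated and seed-deterministic", {
  m <- montage_1010_74()
  tm <- make_template_maps(m, 6, seed = 1, min_separation = 0.5)
  expect_equal(dim(tm), c(74, 6))
  expect_equal(unname(colMeans(tm)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(colSums(tm^2)), rep(1, 6), tolerance = 1e-12)
  R <- crossprod(tm)
  expect_true(all(abs(R[upper.tri(R)]) <= 0.5))

  tm2 <- make_template_maps(m, 6, seed = 1, min_separation = 0.5)
  expect_identical(tm, tm2)

  one <- make_template_maps(m, 1, seed = 2)
  expect_equal(sum(one^2), 1, tolerance = 1e-12)
  expect_equal(mean(one), 0, tolerance = 1e-12)

  # unsatisfiable separation errors out after bounded retries
  expect_error(make_template_maps(small_montage(4), 4, seed = 3,
                                  min_separation = 0.999, max_tries = 10),
               "could not draw")
})

test_that("simulation is bit-deterministic in its seed", {
  a <- tiny_sim(n_subjects = 2, seed = 21, noise_sd = 0.4, jitter = 2,
                spatial = 0.1)
  b <- tiny_sim(n_subjects = 2, seed = 21, noise_sd = 0.4, jitter = 2,
                spatial = 0.1)
  for (i in seq_along(a$dataset$records)) {
    expect_identical(a$dataset$records[[i]]$data, b$dataset$records[[i]]$data)
  }
  expect_identical(a$truth$realized_segments, b$truth$realized_segments)
})

test_that("noiseless records realize the planned topographies and GFP envelope", {
  sim <- tiny_sim(n_subjects = 1, nch = 10, K = 3, seed = 31)
  r <- sim$dataset$records[[1]]
  tt <- evoked_times(r)
  g <- gfp_of_matrix(r$data)
  env <- eval_envelope(sim$truth$envelope, tt)
  plan <- sim$truth$plans[[1]]
  for (i in seq_len(nrow(plan))) {
    sel <- which(tt >= plan$onset_ms[i] & tt < plan$onset_ms[i] + plan$duration_ms[i])
    # instantaneous maps are exactly proportional to the segment's template
    U <- sweep(r$data[, sel, drop = FALSE], 2, colMeans(r$data[, sel, drop = FALSE]))
    rr <- crossprod(sim$truth$templates[, plan$class[i]], U) /
      sqrt(colSums(U^2))
    expect_equal(unname(as.vector(rr)), rep(1, length(sel)), tolerance = 1e-9)
    # GFP equals the envelope (unit subject scale)
    expect_equal(g[sel], env[sel], tolerance = 1e-9)
  }
})

test_that("doubling the envelope peaks doubles the noiseless GFP everywhere", {
  m <- small_montage(8)
  tm <- make_template_maps(m, 2, seed = 5)
  plan <- segment_plan(1:2, onsets = c(5, 80), durations = c(75, 100))
  env1 <- gfp_envelope(centers = c(30, 120), widths = c(12, 20), peaks = c(3, 4))
  env2 <- gfp_envelope(centers = c(30, 120), widths = c(12, 20), peaks = c(6, 8))
  s1 <- simulate_tep_dataset(1, m, tm, plan, env1, srate = 500,
                             epoch = c(-50, 200), amp_sdlog = 0,
                             latency_jitter_sd = 0, spatial_noise = 0, seed = 9)
  s2 <- simulate_tep_dataset(1, m, tm, plan, env2, srate = 500,
                             epoch = c(-50, 200), amp_sdlog = 0,
                             latency_jitter_sd = 0, spatial_noise = 0, seed = 9)
  g1 <- gfp_of_matrix(s1$dataset$records[[1]]$data)
  g2 <- gfp_of_matrix(s2$dataset$records[[1]]$data)
  expect_equal(g2, 2 * g1, tolerance = 1e-12)
})

test_that("deviant-subject modes corrupt exactly one subject as described", {
  sim <- tiny_sim(n_subjects = 3, nch = 16, K = 3, seed = 41, noise_sd = 0.1)
  ds <- sim$dataset

  flip <- make_deviant_subject(ds, "S02", "flip_polarity")
  r0 <- get_record(ds, "S02", "monophasic", "PA")
  r1 <- get_record(flip, "S02", "monophasic", "PA")
  expect_identical(r1$data, -r0$data)
  expect_identical(get_record(flip, "S01", "monophasic", "PA")$data,
                   get_record(ds, "S01", "monophasic", "PA")$data)

  scr <- make_deviant_subject(ds, "S02", "scramble_channels", seed = 6)
  r2 <- get_record(scr, "S02", "monophasic", "PA")
  # scrambled topographies decorrelate from the originals
  hi <- which(gfp_of_matrix(r0$data) > 1)
  U0 <- sweep(r0$data[, hi], 2, colMeans(r0$data[, hi]))
  U2 <- sweep(r2$data[, hi], 2, colMeans(r2$data[, hi]))
  rr <- colSums(U0 * U2) / sqrt(colSums(U0^2) * colSums(U2^2))
  expect_lt(mean(abs(rr)), 0.5)

  expect_error(make_deviant_subject(ds, "S99", "pure_noise"), "unknown subject")
})

test_that("fixture catalog returns the documented configurations", {
  fx <- make_fixture("clean6", seed = 2, n_subjects = 5)
  expect_equal(length(fx$dataset$subjects), 5)
  expect_equal(length(fx$dataset$records), 30)
  expect_equal(ncol(fx$truth$templates), 6)

  sw <- make_fixture("swapAB", seed = 2, n_subjects = 4)
  pa <- sw$truth$plans[["monophasic_PA"]]
  pb <- sw$truth$plans[["biphasic_PA"]]
  expect_equal(pa$class[1:2], c(1L, 2L))
  expect_equal(pb$class[1:2], c(2L, 1L))
  expect_equal(pa$onset_ms, pb$onset_ms)

  nf <- make_fixture("nullflat", seed = 2, n_subjects = 5)
  expect_null(nf$truth)
  expect_equal(ncol(nf$dataset$records[[1]]$data), 1000)

  expect_error(make_fixture("nope", seed = 1))
})
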