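# builds a record whose ROI channels carry a Gaussian bump of the requested
# peak and latency (other channels flat unless given an offset)
bump_record <- function(montage, comp, peak_uv, center_ms, srate = 960,
                        epoch = c(-200, 400), other_offset = 0) {
  tt <- epoch[1] + (seq_len(floor(diff(epoch) * srate / 1000)) - 1) * 1000 / srate
  mat <- matrix(other_offset, n_channels(montage), length(tt))
  idx <- match(comp$roi[[1]], montage$channel_names)
  bump <- peak_uv * exp(-(tt - center_ms)^2 / (2 * 5^2))
  for (i in idx) mat[i, ] <- bump
  subject_evoked("S1", "monophasic", "PA", mat, srate, epoch[1])
}

test_that("every built-in component's peak is recovered exactly from a bump", {
  m <- montage_1010_74()
  comps <- tep_components()
  centers <- c(15, 30, 45, 60, 100, 180)
  for (i in seq_len(nrow(comps))) {
    comp <- comps[i, ]
    sgn <- if (comp$polarity == "negative") -1 else 1
    ev <- bump_record(m, comp, sgn * 6, centers[i])
    pk <- extract_peak(ev, comp, m)
    tt <- evoked_times(ev)
    near <- tt[which.min(abs(tt - centers[i]))]
    expect_equal(pk$amplitude, sgn * 6 * exp(-(near - centers[i])^2 / 50),
                 tolerance = 1e-9)
    expect_lte(abs(pk$latency - centers[i]), 1000 / 960)   # within one sample
    expect_true(pk$latency >= comp$toi_start && pk$latency <= comp$toi_end)
  }
})

test_that("flat traces, ramps and ties follow the documented extremum rules", {
  m <- montage_1010_74()
  comps <- tep_components()
  n15 <- comps[comps$component == "N15", ]
  p30 <- comps[comps$component == "P30", ]

  flat <- bump_record(m, n15, 0, 15)
  pk <- extract_peak(flat, n15, m)
  expect_equal(pk$amplitude, 0)
  tt <- evoked_times(flat)
  expect_equal(pk$latency, tt[which(tt >= n15$toi_start)[1]])  # first TOI sample

  # monotonically rising ramp: positive peak at the TOI's last sample
  ramp <- flat
  ramp$data[match(p30$roi[[1]], m$channel_names), ] <-
    matrix(rep(seq_len(ncol(ramp$data)), each = 4), 4)
  pk2 <- extract_peak(ramp, p30, m)
  sel <- which(tt >= p30$toi_start & tt <= p30$toi_end)
  expect_equal(pk2$latency, tt[sel[length(sel)]])

  # two equal maxima: earliest wins
  twin <- flat
  tr <- numeric(ncol(twin$data))
  sel2 <- which(tt >= p30$toi_start & tt <= p30$toi_end)
  tr[sel2[3]] <- 5; tr[sel2[7]] <- 5
  twin$data[match(p30$roi[[1]], m$channel_names), ] <-
    matrix(rep(tr, each = 4), 4)
  expect_equal(extract_peak(twin, p30, m)$latency, tt[sel2[3]])

  # TOI outside the epoch errors
  short <- crop_evoked(flat, c(100, 150))
  expect_error(extract_peak(short, p30, m), "outside the epoch")
})

test_that("peak extraction ignores constant shifts on non-ROI channels", {
  m <- montage_1010_74()
  p30 <- tep_components()[2, ]
  a <- bump_record(m, p30, 6, 30, other_offset = 0)
  b <- bump_record(m, p30, 6, 30, other_offset = 17.3)
  expect_equal(extract_peak(a, p30, m)$amplitude,
               extract_peak(b, p30, m)$amplitude)
})

test_that("opposite-polarity responses yield the signed extremum", {
  m <- montage_1010_74()
  n15 <- tep_components()[1, ]
  inv <- bump_record(m, n15, +4, 15)     # positive bump for a negative component
  pk <- extract_peak(inv, n15, m)
  # minimum of a positive bump within the TOI: small or "wrong-signed" value
  expect_lt(pk$amplitude, 4)
  expect_gte(pk$amplitude, 0)
})

test_that("outlier screening flags strictly beyond 2.5 SD, per component", {
  base <- expand.grid(subject_id = sprintf("s%02d", 1:31),
                      waveform = "monophasic", direction = "PA",
                      stringsAsFactors = FALSE)
  base$condition <- "monophasic_PA"
  base$component <- "P30"
  base$amplitude <- qnorm(ppoints(31))   # no chance flags among the rest
  base$latency <- 30
  base$amplitude[1] <- 10
  out <- screen_peak_outliers(tibble::as_tibble(base))
  expect_true(all(out$excluded[out$subject_id == "s01"]))
  expect_false(any(out$excluded[out$subject_id != "s01"]))

  # all equal: no flags
  eq <- base; eq$amplitude <- 1; eq$latency <- 30
  expect_false(any(screen_peak_outliers(tibble::as_tibble(eq))$excluded))

  # a value exactly at 2.5 SD is NOT flagged (strict inequality)
  x <- c(2, seq(-1, 1, length.out = 20))
  f <- function(a) { y <- c(a, x[-1]); (y[1] - mean(y)) / sd(y) - 2.5 }
  a_star <- uniroot(f, c(1, 100), tol = 1e-12)$root - 1e-9  # at/just under 2.5
  ex <- base[1:21, ]
  ex$amplitude <- c(a_star, x[-1])
  ex$latency <- 30
  z <- (a_star - mean(ex$amplitude)) / sd(ex$amplitude)
  expect_equal(z, 2.5, tolerance = 1e-6)
  expect_false(any(screen_peak_outliers(tibble::as_tibble(ex))$excluded))

  expect_error(screen_peak_outliers(tibble::as_tibble(base[1:2, ])), ">= 3")
})

test_that("transform selection maximizes Shapiro-Wilk W and flags failures", {
  set.seed(7)
  ln <- exp(rnorm(60, 1, 0.8))
  ch <- choose_transform(ln)
  expect_equal(attr(ch, "chosen"), "log10")
  expect_false(attr(ch, "no_transform_normalizes"))

  gs <- rnorm(60)
  expect_equal(attr(choose_transform(gs), "chosen"), "none")

  heavy <- rcauchy(200)
  ch2 <- choose_transform(heavy)
  expect_true(attr(ch2, "no_transform_normalizes"))

  expect_error(choose_transform(rep(1, 20)), "constant")
  expect_error(choose_transform(rnorm(5)), "n >= 8")
})
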