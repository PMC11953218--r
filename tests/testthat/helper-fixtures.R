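# Small in-code fixtures shared across test files. Everything is generated
# at test time; nothing is read from disk.

# tiny montage: nch points spread on the upper hemisphere
small_montage <- function(nch = 12) {
  stopifnot(nch >= 3)
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(nch) - 1
  z <- 1 - i / (2 * nch)          # stay on the upper half
  r <- sqrt(pmax(1 - z^2, 0))
  tep_montage(paste0("E", seq_len(nch)),
              cbind(r * cos(golden * i), r * sin(golden * i), z))
}

# small noiseless-capable simulated dataset for fast structural tests
tiny_sim <- function(n_subjects = 3, nch = 12, K = 3, seed = 1,
                     noise_sd = 0, jitter = 0, spatial = 0,
                     srate = 400, epoch = c(-50, 200),
                     plan = NULL, window = c(5, 200)) {
  m <- small_montage(nch)
  tm <- make_template_maps(m, K, seed = seed, min_separation = 0.4)
  plan <- plan %||% segment_plan(seq_len(K),
                                 onsets = seq(5, by = 60, length.out = K),
                                 durations = rep(60, K))
  env <- gfp_envelope(centers = c(20, 60, 120), widths = c(10, 15, 25),
                      peaks = c(4, 5, 3))
  simulate_tep_dataset(n_subjects, m, tm, plan, envelope = env,
                       srate = srate, epoch = epoch, noise_sd = noise_sd,
                       amp_sdlog = 0, latency_jitter_sd = jitter,
                       spatial_noise = spatial, seed = seed + 7,
                       analysis_window = window)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# long 2x3 within-subject table with iid N(mu, 1) cells
random_design_table <- function(n = 10, mu = 0) {
  d <- expand.grid(subject_id = sprintf("s%02d", seq_len(n)),
                   waveform = c("monophasic", "biphasic"),
                   direction = c("PA", "AP", "LM"),
                   stringsAsFactors = FALSE)
  d$value <- rnorm(nrow(d)) + mu
  tibble::as_tibble(d)
}
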