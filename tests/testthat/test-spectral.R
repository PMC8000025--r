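test_that("taper spec enforces the concentration bound and the fs/N grid", {
  expect_error(taper_spec(k = 4, tw = 2), "2\\*TW - 1")
  s <- multitaper_power(array(rnorm(2 * 1 * 512), c(2, 1, 512)), fs = 1017.375)
  expect_equal(diff(s$freqs)[1], 1017.375 / 512) # ~1.99 Hz resolution
  expect_equal(length(s$freqs), 257)
  expect_equal(taper_half_bandwidth(taper_spec(), fs = 1017.375),
               2 / (512 / 1017.375))
})

test_that("multitaper power of white noise is flat and Parseval-consistent with a periodogram", {
  set.seed(7)
  ntr <- 200; n <- 256; fs <- 1000
  ep <- array(rnorm(ntr * n), c(ntr, 1, n))
  s <- multitaper_power(ep, fs, taper_spec(3, 2, n))
  expect_true(all(s$values >= 0))
  # integrated PSD ~ variance (Parseval)
  expect_equal(sum(s$values) * fs / n, 1, tolerance = 0.05)
  # plain periodogram oracle: mean one-sided PSD over trials
  pg <- rowMeans(vapply(seq_len(ntr), function(tr) {
    x <- ep[tr, 1, ]; x <- x - mean(x)
    p <- Mod(fft(x)[1:(n / 2 + 1)])^2 / (n * fs)
    p[2:(n / 2)] <- 2 * p[2:(n / 2)]
    p
  }, numeric(n / 2 + 1)))
  expect_equal(mean(s$values), mean(pg), tolerance = 0.05)
  # flat: no band stands out
  ba <- band_average(s)
  expect_lt(max(ba) / min(ba), 1.15)
  # all-zero input gives zero power
  expect_true(all(multitaper_power(array(0, c(2, 1, 64)), fs)$values == 0))
})

test_that("power is invariant to per-trial mean offsets", {
  set.seed(8)
  ep <- array(rnorm(10 * 2 * 128), c(10, 2, 128))
  ep2 <- ep + array(rep(rnorm(10, sd = 50), 2 * 128), c(10, 2, 128))
  expect_equal(multitaper_power(ep2, 1000)$values,
               multitaper_power(ep, 1000)$values, tolerance = 1e-10)
})

test_that("baseline z-normalization follows the (S - mean)/SD formula", {
  set.seed(9)
  base <- multitaper_power(array(rnorm(40 * 1 * 128), c(40, 1, 128)), 1000,
                           taper_spec(3, 2, 128), keep_trials = TRUE)
  mu <- apply(base$values, c(2, 3), mean)
  sdv <- apply(base$values, c(2, 3), sd)
  pw <- multitaper_power(array(rnorm(40 * 1 * 128), c(40, 1, 128)), 1000,
                         taper_spec(3, 2, 128))
  pw$values <- mu + 2 * sdv # exactly two baseline SDs above the mean
  z <- normalize_to_baseline(pw, base)
  expect_equal(as.vector(z$values), rep(2, length(z$freqs)))
  expect_equal(z$normalization, "baseline_z")
  # identical power and baseline mean -> ~0
  pw$values <- mu
  expect_equal(max(abs(normalize_to_baseline(pw, base)$values)), 0)
  # zero baseline SD is an error naming the frequency
  base$values[, , 3] <- 1
  expect_error(normalize_to_baseline(pw, base), "zero baseline SD at")
})

test_that("baseline spectra on a shorter window are interpolated onto the analysis grid", {
  set.seed(10)
  base <- multitaper_power(array(rnorm(30 * 1 * 234), c(30, 1, 234)), 1017.375,
                           taper_spec(3, 2, 234), keep_trials = TRUE)
  pw <- multitaper_power(array(rnorm(30 * 1 * 512), c(30, 1, 512)), 1017.375)
  z <- normalize_to_baseline(pw, base)
  expect_equal(length(z$freqs), 257)
  expect_true(all(is.finite(z$values)))
})

test_that("coherence is bounded, symmetric, and matches the independent-noise bias oracle", {
  set.seed(11)
  ntr <- 500; n <- 256; fs <- 1000
  ep <- array(rnorm(ntr * 2 * n), c(ntr, 2, n))
  co <- coherence(ep, rbind(c(1, 2), c(2, 1)), fs, taper_spec(3, 2, n))
  expect_true(all(co$values >= 0 & co$values <= 1))
  expect_equal(co$values[1, ], co$values[2, ]) # C_ij = C_ji exactly
  # magnitude-squared coherence of independent Gaussians: E[C] ~ 1/(K n_trials)
  expect_equal(mean(co$values), 1 / (3 * ntr), tolerance = 0.2)
  # identical signals -> coherence 1 everywhere
  ep[, 2, ] <- ep[, 1, ]
  co1 <- coherence(ep[1:20, , , drop = FALSE], rbind(c(1, 2)), fs, taper_spec(3, 2, n))
  expect_equal(as.vector(co1$values), rep(1, n / 2 + 1), tolerance = 1e-9)
  expect_error(coherence(ep[1, , , drop = FALSE], rbind(c(1, 2)), fs,
                         taper_spec(1, 1, n)), "degenerate")
})

test_that("a shared oscillator produces a coherence peak at its frequency", {
  s <- generate_session(generator_config(
    n_trials_per_condition = 30, n_channels = 2, probes = "V1",
    n_samples = 512, seed = 12,
    oscillators = list(oscillator(center = 40, bw = 6, amplitude = 12)),
    couplings = list()))
  co <- coherence(s$lfp, rbind(c(1, 2)), s$fs)
  pk <- find_peak_frequency(structure(list(freqs = co$freqs, values = co$values),
                                      class = "spectral_result"), c(10, 100))
  expect_equal(pk$peak_hz, 40, tolerance = 4)
})

test_that("sliding windows tile the span end-aligned to the event", {
  set.seed(13)
  fs <- 1017.375
  ep <- array(rnorm(4 * 1 * 1024), c(4, 1, 1024)) # 1,006.5-ms span
  tf <- sliding_spectrogram(ep, fs, taper_spec(3, 2, 512), step_ms = 20)
  expect_equal(dim(tf$values)[1], 26)
  expect_equal(diff(tf$times), rep(20, 25))
  expect_equal(max(tf$times), -1000 * 512 / fs / 2) # last window ends at t = 0
  # step equal to span - window gives exactly two windows
  tf2 <- sliding_spectrogram(ep, fs, taper_spec(3, 2, 512),
                             step_ms = 1000 * 512 / fs)
  expect_equal(dim(tf2$values)[1], 2)
  expect_error(sliding_spectrogram(ep[, , 1:400, drop = FALSE], fs,
                                   taper_spec(3, 2, 512)), "span shorter")
})

test_that("window spectra of stationary input are statistically identical", {
  set.seed(14)
  ep <- array(rnorm(60 * 1 * 768), c(60, 1, 768))
  tf <- sliding_spectrogram(ep, 1017.375, taper_spec(3, 2, 256), step_ms = 40)
  ba <- band_average(tf) # time x band x unit
  rel_sd <- apply(ba[, , 1], 2, sd) / apply(ba[, , 1], 2, mean)
  expect_true(all(rel_sd < 0.1))
})

test_that("band averaging respects edge conventions", {
  freqs <- one_sided_freqs <- seq(0, 100, by = 1)
  sr <- structure(list(freqs = freqs, values = matrix(5, 1, length(freqs))),
                  class = "spectral_result")
  ba <- band_average(sr, band_set())
  expect_true(all(ba == 5)) # constant spectrum -> constant band means
  v <- matrix(0, 1, length(freqs)); v[1, freqs == 10] <- 7
  sr$values <- v
  ba <- band_average(sr, band_set())
  expect_true(ba[1, "alpha"] > 0 && all(ba[1, colnames(ba) != "alpha"] == 0))
  # a grid point exactly at 8 Hz belongs to alpha, not theta
  v[] <- 0; v[1, freqs == 8] <- 3
  sr$values <- v
  ba <- band_average(sr, band_set())
  expect_equal(unname(ba[1, "theta"]), 0)
  expect_gt(ba[1, "alpha"], 0)
  expect_error(band_average(sr, band_set(narrow = c(10.2, 10.4))), "no grid frequencies")
})

test_that("peak localization handles ties, edges, and flat spectra", {
  freqs <- seq(0, 100, by = 2)
  mk <- function(vals) structure(list(freqs = freqs, values = matrix(vals, 1)),
                                 class = "spectral_result")
  # two equal maxima -> lower frequency wins
  y <- rep(1, length(freqs)); y[freqs == 30] <- 5; y[freqs == 40] <- 5
  pk <- find_peak_frequency(mk(y), c(20, 50), smooth = FALSE)
  expect_equal(pk$peak_hz, 30)
  # monotone spectrum -> band edge with no interior peak
  pk2 <- find_peak_frequency(mk(freqs / 10), c(20, 50), smooth = FALSE)
  expect_equal(pk2$peak_hz, 50)
  expect_false(pk2$interior)
  # flat spectrum -> flagged, no peak
  pk3 <- find_peak_frequency(mk(rep(2, length(freqs))), c(20, 50))
  expect_true(pk3$flat)
  expect_true(is.na(pk3$peak_hz))
})

test_that("an injected 40-Hz oscillator is localized to within one frequency bin", {
  s <- generate_session(generator_config(
    n_trials_per_condition = 40, n_channels = 1, probes = "V1",
    n_samples = 512, seed = 15,
    oscillators = list(oscillator(center = 40, bw = 6, amplitude = 15)),
    couplings = list(), evoked = NULL))
  pw <- multitaper_power(s$lfp, s$fs)
  pk <- find_peak_frequency(pw, c(25, 50))
  expect_equal(pk$peak_hz, 40, tolerance = 1017.375 / 512 + 1e-9)
})
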