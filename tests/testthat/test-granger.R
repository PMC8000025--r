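fs0 <- 1017.375

test_that("multi-trial VAR fitting recovers known coefficients", {
  A <- array(0, c(2, 2, 2))
  A[, , 1] <- matrix(c(0.5, 0.3, 0, 0.4), 2, 2, byrow = TRUE)
  A[, , 2] <- matrix(c(-0.2, 0, 0.1, -0.15), 2, 2, byrow = TRUE)
  ep <- simulate_var(A, n_trials = 100, n_samples = 512, seed = 21)
  m <- fit_var(ep, order = 2)
  expect_lt(max(abs(m$A - A)), 0.05)
  expect_lt(max(abs(m$Sigma - diag(2))), 0.05)
  expect_lt(m$spectral_radius, 1)
})

test_that("white noise selects a minimal order and the sample covariance", {
  set.seed(22)
  ep <- array(rnorm(50 * 2 * 256), c(50, 2, 256))
  m <- fit_var(ep, p_max = 8)
  expect_lte(m$order, 2)
  expect_lt(max(abs(m$Sigma - diag(2))), 0.05)
  expect_lt(max(abs(m$A)), 0.05)
})

test_that("degenerate inputs raise explicit errors", {
  set.seed(23)
  ep <- array(rnorm(10 * 2 * 128), c(10, 2, 128))
  dup <- array(0, c(10, 3, 128))
  dup[, 1:2, ] <- ep
  dup[, 3, ] <- ep[, 1, ] # exact copy channel
  expect_error(fit_var(dup, order = 2), "singular|collinear")
  expect_error(fit_var(ep[1:2, , 1:20, drop = FALSE], order = 10), "guard-ratio")
})

test_that("spectral cGC is nonnegative and its frequency average matches the fitted time-domain GC", {
  A <- array(0, c(2, 2, 1))
  A[1, 1, 1] <- 0.5; A[2, 1, 1] <- 0.4; A[2, 2, 1] <- 0.7
  ep <- simulate_var(A, n_trials = 60, n_samples = 512, seed = 24)
  g <- conditional_spectral_gc(ep, x = 1, y = 2, fs = fs0)
  expect_true(all(g$cgc >= 0))
  # Geweke integral identity of the decomposition itself
  expect_equal(spectral_gc_mean(g), g$gc_time, tolerance = 1e-3)
  expect_gt(g$gc_time, 0.05)
})

test_that("cGC is invariant to a common positive rescaling of all channels", {
  A <- array(0, c(2, 2, 1))
  A[1, 1, 1] <- 0.5; A[2, 1, 1] <- 0.4; A[2, 2, 1] <- 0.7
  ep <- simulate_var(A, n_trials = 20, n_samples = 256, seed = 25)
  g1 <- conditional_spectral_gc(ep, 1, 2, fs = fs0, order = 2)
  g2 <- conditional_spectral_gc(ep * 37.5, 1, 2, fs = fs0, order = 2)
  expect_equal(g1$cgc, g2$cgc, tolerance = 1e-8)
})

test_that("independent channels stay below the shuffle threshold at most frequencies", {
  set.seed(26)
  ep <- array(rnorm(30 * 2 * 256), c(30, 2, 256))
  thr <- suppressWarnings(shuffle_null_threshold(ep, x = 1, y = 2, fs = fs0,
                                                 n_shuffles = 60, seed = 5))
  frac_below <- mean(thr$observed$cgc[1, ] <= thr$per_frequency)
  expect_gt(frac_below, 0.7)
  expect_true(all(thr$per_frequency >= 0))
})

test_that("conditioning on the relay removes chain-induced causality", {
  A <- array(0, c(3, 3, 1))
  A[1, 1, 1] <- 0.5            # x
  A[2, 1, 1] <- 0.5; A[2, 2, 1] <- 0.5 # z driven by x
  A[3, 2, 1] <- 0.5; A[3, 3, 1] <- 0.3 # y driven by z only
  ep <- simulate_var(A, n_trials = 40, n_samples = 512, seed = 27)
  thr_u <- suppressWarnings(shuffle_null_threshold(ep, x = 1, y = 3, fs = fs0,
                                                   n_shuffles = 60, seed = 6))
  g_c <- suppressWarnings(conditional_spectral_gc(ep, x = 1, y = 3, z = 2, fs = fs0))
  expect_gt(spectral_gc_mean(thr_u$observed), thr_u$mean)   # pairwise flow detected
  # conditioning on the relay collapses the apparent flow by orders of magnitude
  expect_lt(spectral_gc_mean(g_c), 0.05 * spectral_gc_mean(thr_u$observed))
})

test_that("shuffle thresholds guard their preconditions", {
  set.seed(28)
  ep <- array(rnorm(2 * 2 * 64), c(2, 2, 64))
  expect_error(shuffle_null_threshold(ep, 1, 2, fs = fs0), "at least 3 trials")
  ep2 <- array(rnorm(10 * 2 * 256), c(10, 2, 256))
  expect_error(shuffle_null_threshold(ep2, 1, 2, fs = fs0, n_shuffles = 10),
               "at least 20")
  expect_warning(shuffle_null_threshold(ep2, 1, 2, fs = fs0, n_shuffles = 25,
                                        order = 1),
                 "fewer than 100 shuffles")
})

test_that("pairwise cGC enumerates every ordered derivation pair in scope", {
  s <- generate_session(generator_config(
    n_trials_per_condition = 10, n_channels = 3, probes = c("V1", "V4"),
    n_samples = 256, seed = 29,
    oscillators = list(oscillator(center = 30, bw = 10, amplitude = 6)),
    couplings = list()))
  b <- bipolar_rereference(s)
  res <- suppressWarnings(pairwise_cgc(b, scope = "within", order = 2,
                                       conditioning_cap = 2))
  expect_named(res, c("RF", "OUT"))
  expect_equal(nrow(res$RF$cgc), 2 * 1) # 2 derivations -> 2 ordered pairs
  prs <- res$RF$pairs
  expect_true(all(paste(prs[, 1], prs[, 2]) %in% c("1 2", "2 1")))
  res_b <- suppressWarnings(pairwise_cgc(b, scope = "between", order = 2,
                                         conditioning_cap = 2))
  expect_equal(nrow(res_b$RF$cgc), 2 * 2 * 2) # all cross-probe ordered pairs
})
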