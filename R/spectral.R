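#' Slepian taper specification
#'
#' @param k Number of tapers (default 3). Must satisfy `k <= 2*tw - 1`, the
#'   usual leakage bound for Slepian families.
#' @param tw Time-bandwidth product (default 2).
#' @param n Window length in samples (default 512).
#' @return A `taper_spec`.
#' @export
taper_spec <- function(k = 3, tw = 2, n = 512) {
  stopifnot(n > 0, tw > 0, k >= 1)
  if (k > 2 * tw - 1)
    stop(sprintf("k = %d exceeds 2*TW - 1 = %g: tapers beyond that are poorly concentrated", k, 2 * tw - 1))
  structure(list(k = as.integer(k), tw = tw, n = as.integer(n)), class = "taper_spec")
}

.taper_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) sequences
#'
#' Computed as the leading eigenvectors of the standard symmetric
#' tridiagonal matrix whose eigenvectors are the DPSS (Percival & Walden).
#' Tapers are unit-energy; symmetric tapers have positive mean and
#' antisymmetric tapers start positive.
#'
#' @param n Sequence length.
#' @param k Number of sequences.
#' @param tw Time-bandwidth product.
#' @return An n x k matrix, one taper per column, ordered by concentration.
#' @export
dpss_tapers <- function(n, k, tw) {
  key <- sprintf("%d_%d_%g", n, k, tw)
  hit <- get0(key, envir = .taper_cache)
  if (!is.null(hit)) return(hit)
  W <- tw / n
  t0 <- 0:(n - 1)
  A <- matrix(0, n, n)
  diag(A) <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * W)
  off <- t0[-1] * (n - t0[-1]) / 2
  A[cbind(2:n, 1:(n - 1))] <- off
  A[cbind(1:(n - 1), 2:n)] <- off
  ev <- eigen(A, symmetric = TRUE)
  V <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    s <- sum(V[, j])
    if (abs(s) < 1e-8) s <- sum(V[seq_len(ceiling(n / 2)), j])
    if (s < 0) V[, j] <- -V[, j]
  }
  assign(key, V, envir = .taper_cache)
  V
}

one_sided_freqs <- function(n, fs) seq(0, floor(n / 2)) * fs / n

# Tapered FFTs for a channel: returns complex array [freq(one-sided) x taper x trial].
# x: samples x trials, already demeaned per trial.
tapered_fft <- function(x, V) {
  n <- nrow(x); nf <- floor(n / 2) + 1
  out <- array(0i, c(nf, ncol(V), ncol(x)))
  for (j in seq_len(ncol(V))) {
    X <- stats::mvfft(x * V[, j])
    out[, j, ] <- X[seq_len(nf), , drop = FALSE]
  }
  out
}

as_epoch_array <- function(epochs) {
  if (is.matrix(epochs)) {
    array(epochs, c(nrow(epochs), 1, ncol(epochs)))
  } else if (length(dim(epochs)) == 3) epochs
  else stop("epochs must be a [trial x channel x sample] array or a [trial x sample] matrix")
}

#' Multitaper spectral power
#'
#' Per-trial means are removed, each trial-channel is tapered by K Slepian
#' sequences, and squared FFT magnitudes are averaged over tapers (and
#' optionally over trials). Output is a one-sided power spectral density:
#' `sum(values) * fs/N` approximates the signal variance.
#'
#' @param epochs Array trial x channel x sample (or trial x sample matrix).
#' @param fs Sampling rate in Hz.
#' @param taper A [taper_spec()]; `taper$n` must equal the epoch length.
#' @param keep_trials If TRUE, return per-trial spectra
#'   (trial x channel x freq) instead of the trial average.
#' @return A `spectral_result`: list with `freqs` (Hz, spacing fs/N),
#'   `values` (channel x freq, or trial x channel x freq), `normalization`
#'   ("raw"), `fs`, `taper`.
#' @export
multitaper_power <- function(epochs, fs, taper = taper_spec(n = dim(as_epoch_array(epochs))[3]),
                             keep_trials = FALSE) {
  ep <- as_epoch_array(epochs)
  n <- dim(ep)[3]
  if (taper$n != n) stop("epoch length does not match taper$n")
  V <- dpss_tapers(n, taper$k, taper$tw)
  freqs <- one_sided_freqs(n, fs)
  nf <- length(freqs)
  scale <- rep(2 / fs, nf)
  scale[1] <- 1 / fs
  if (n %% 2 == 0) scale[nf] <- 1 / fs
  n_trial <- dim(ep)[1]; n_chan <- dim(ep)[2]
  vals <- array(0, c(n_trial, n_chan, nf))
  for (ch in seq_len(n_chan)) {
    x <- t(ep[, ch, , drop = TRUE])
    if (n_trial == 1) x <- matrix(ep[1, ch, ], ncol = 1)
    x <- sweep(x, 2, colMeans(x))
    Xf <- tapered_fft(x, V)
    p <- apply(Mod(Xf)^2, c(1, 3), mean) # average tapers -> freq x trial
    vals[, ch, ] <- t(p * scale)
  }
  values <- if (keep_trials) vals else apply(vals, c(2, 3), mean)
  structure(list(freqs = freqs, values = values,
                 normalization = "raw", fs = fs, taper = taper,
                 unit = "channel"),
            class = "spectral_result")
}

#' Baseline z-normalization of spectral power
#'
#' z(f) = (S(f) - mean over trials of baseline power) / SD over trials of
#' baseline power, per channel and frequency. When the baseline was
#' estimated on a shorter window its frequency grid is linearly
#' interpolated onto the analysis grid.
#'
#' @param power A `spectral_result` from [multitaper_power()] (trial
#'   averaged or per-trial).
#' @param baseline A `spectral_result` with `keep_trials = TRUE`
#'   (trial x channel x freq) from the baseline window.
#' @return A `spectral_result` with `normalization = "baseline_z"`.
#' @export
normalize_to_baseline <- function(power, baseline) {
  stopifnot(inherits(power, "spectral_result"), inherits(baseline, "spectral_result"))
  if (length(dim(baseline$values)) != 3)
    stop("baseline must carry per-trial spectra (keep_trials = TRUE)")
  mu <- apply(baseline$values, c(2, 3), mean)
  sdv <- apply(baseline$values, c(2, 3), stats::sd)
  same_grid <- length(baseline$freqs) == length(power$freqs) &&
    all(abs(baseline$freqs - power$freqs) < 1e-9)
  if (!same_grid) {
    mu <- t(apply(mu, 1, function(r) stats::approx(baseline$freqs, r, xout = power$freqs, rule = 2)$y))
    sdv <- t(apply(sdv, 1, function(r) stats::approx(baseline$freqs, r, xout = power$freqs, rule = 2)$y))
  }
  bad <- which(sdv == 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("zero baseline SD at %g Hz (channel %d)",
                 power$freqs[bad[1, 2]], bad[1, 1]))
  v <- power$values
  if (length(dim(v)) == 3) {
    for (tr in seq_len(dim(v)[1])) v[tr, , ] <- (v[tr, , ] - mu) / sdv
  } else {
    v <- (v - mu) / sdv
  }
  out <- power
  out$values <- v
  out$normalization <- "baseline_z"
  out
}

#' Multitaper spectral coherence
#'
#' Magnitude-squared coherence C_ij(f) = |S_ij(f)|^2 / (S_i(f) S_j(f)),
#' with cross- and auto-spectra averaged jointly over tapers and trials
#' before forming the ratio. Values lie in [0, 1]; the estimator needs at
#' least two taper-trial samples (a single taper of a single trial is
#' identically 1).
#'
#' @param epochs Array trial x channel x sample.
#' @param pairs Two-column matrix of channel index pairs.
#' @param fs Sampling rate in Hz.
#' @param taper A [taper_spec()].
#' @return A `spectral_result` with `values` pair x freq and `pairs`.
#' @export
coherence <- function(epochs, pairs, fs, taper = taper_spec(n = dim(as_epoch_array(epochs))[3])) {
  ep <- as_epoch_array(epochs)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  n <- dim(ep)[3]; n_trial <- dim(ep)[1]
  if (taper$n != n) stop("epoch length does not match taper$n")
  if (n_trial * taper$k < 2)
    stop("coherence needs at least 2 taper-trial samples (single trial, single taper is degenerate)")
  V <- dpss_tapers(n, taper$k, taper$tw)
  freqs <- one_sided_freqs(n, fs)
  chans <- sort(unique(as.vector(pairs)))
  Xf <- vector("list", max(chans))
  for (ch in chans) {
    x <- t(ep[, ch, , drop = TRUE])
    if (n_trial == 1) x <- matrix(ep[1, ch, ], ncol = 1)
    x <- sweep(x, 2, colMeans(x))
    ft <- tapered_fft(x, V)
    dim(ft) <- c(length(freqs), taper$k * n_trial)
    Xf[[ch]] <- ft
  }
  vals <- matrix(0, nrow(pairs), length(freqs))
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    Sij <- rowMeans(Xf[[i]] * Conj(Xf[[j]]))
    Si <- rowMeans(Mod(Xf[[i]])^2)
    Sj <- rowMeans(Mod(Xf[[j]])^2)
    vals[p, ] <- Mod(Sij)^2 / (Si * Sj)
  }
  rownames(vals) <- paste(pairs[, 1], pairs[, 2], sep = "-")
  structure(list(freqs = freqs, values = vals, pairs = pairs,
                 normalization = "raw", fs = fs, taper = taper,
                 unit = "pair"),
            class = "spectral_result")
}

#' Sliding-window time-frequency map
#'
#' Applies [multitaper_power()] (or [coherence()]) in windows of
#' `taper$n` samples stepped every `step_ms`, right-aligned so that the
#' last window ends at the final sample of the epoch (time 0 at the
#' alignment event; window-center times are negative).
#'
#' @param epochs Array trial x channel x sample spanning the full analysis
#'   span (e.g. 1024 samples for a 1,006.5-ms span at 1017.375 Hz).
#' @param fs Sampling rate in Hz.
#' @param taper A [taper_spec()] defining the window length.
#' @param step_ms Window step in ms (default 20).
#' @param pairs Optional pair matrix; when given, coherence is computed
#'   instead of power.
#' @return A `timefreq_map`: `times` (window centers, ms, 0 = epoch end),
#'   `freqs`, `values` (time x freq x unit), `window` (samples), `step_ms`.
#' @export
sliding_spectrogram <- function(epochs, fs, taper = taper_spec(), step_ms = 20,
                                pairs = NULL) {
  ep <- as_epoch_array(epochs)
  n_total <- dim(ep)[3]
  win <- taper$n
  if (n_total < win) stop("span shorter than the analysis window")
  win_ms <- 1000 * win / fs
  span_ms <- 1000 * n_total / fs
  nw <- floor((span_ms - win_ms) / step_ms) + 1
  step_samp <- step_ms * fs / 1000
  times <- numeric(nw)
  vals <- NULL
  for (k in seq_len(nw)) {
    end <- n_total - round((nw - k) * step_samp)
    idx <- (end - win + 1):end
    sub <- ep[, , idx, drop = FALSE]
    res <- if (is.null(pairs)) multitaper_power(sub, fs, taper)
           else coherence(sub, pairs, fs, taper)
    if (is.null(vals))
      vals <- array(0, c(nw, length(res$freqs), nrow(res$values)))
    vals[k, , ] <- t(res$values)
    times[k] <- -( (nw - k) * step_ms + win_ms / 2 )
  }
  structure(list(times = times, freqs = one_sided_freqs(win, fs),
                 values = vals, window = win, step_ms = step_ms, fs = fs,
                 taper = taper, measure = if (is.null(pairs)) "power" else "coherence"),
            class = "timefreq_map")
}

#' Canonical frequency bands
#'
#' theta 4-8, alpha 8-13, beta 13-25, low gamma 25-50, high gamma 50-80 Hz.
#' Lower edges are inclusive and upper edges exclusive, except the last
#' band, whose upper edge is inclusive.
#'
#' @param ... Optional named `c(lo, hi)` overrides replacing the default set.
#' @return A `band_set` (named list of intervals).
#' @export
band_set <- function(...) {
  bands <- list(...)
  if (!length(bands)) {
    bands <- list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 25),
                  low_gamma = c(25, 50), high_gamma = c(50, 80))
  }
  lo <- vapply(bands, `[`, numeric(1), 1)
  hi <- vapply(bands, `[`, numeric(1), 2)
  stopifnot(all(hi > lo), !is.unsorted(lo), all(lo[-1] >= hi[-length(hi)]))
  structure(bands, class = "band_set")
}

band_mask <- function(freqs, band, last = FALSE, fs = NULL, n = NULL) {
  m <- if (last) freqs >= band[1] & freqs <= band[2]
       else freqs >= band[1] & freqs < band[2]
  m & freqs > 0 & freqs < max(freqs) # DC and Nyquist excluded
}

#' Average spectral values within frequency bands
#'
#' Arithmetic mean over grid frequencies falling in each band (lower edge
#' inclusive, upper edge exclusive; the last band is upper-inclusive). DC
#' and Nyquist bins are excluded.
#'
#' @param result A `spectral_result`, `gc_result`, or `timefreq_map`.
#' @param bands A [band_set()].
#' @return For a `spectral_result` or `gc_result`, a unit x band matrix;
#'   for a `timefreq_map`, a time x band x unit array.
#' @export
band_average <- function(result, bands = band_set()) {
  stopifnot(inherits(bands, "band_set"))
  if (inherits(result, "gc_result"))
    result <- list(freqs = result$freqs, values = result$cgc)
  freqs <- result$freqs
  nb <- length(bands)
  masks <- lapply(seq_len(nb), function(b) band_mask(freqs, bands[[b]], last = b == nb))
  empty <- vapply(masks, function(m) !any(m), logical(1))
  if (any(empty))
    stop(sprintf("band '%s' contains no grid frequencies", names(bands)[which(empty)[1]]))
  if (inherits(result, "timefreq_map")) {
    v <- result$values # time x freq x unit
    out <- array(0, c(dim(v)[1], nb, dim(v)[3]),
                 dimnames = list(NULL, names(bands), NULL))
    for (b in seq_len(nb))
      out[, b, ] <- apply(v[, masks[[b]], , drop = FALSE], c(1, 3), mean)
    return(out)
  }
  v <- result$values
  if (length(dim(v)) == 3) { # per-trial spectra
    out <- array(0, c(dim(v)[1], dim(v)[2], nb),
                 dimnames = list(NULL, NULL, names(bands)))
    for (b in seq_len(nb))
      out[, , b] <- apply(v[, , masks[[b]], drop = FALSE], c(1, 2), mean)
    return(out)
  }
  out <- vapply(seq_len(nb), function(b) rowMeans(v[, masks[[b]], drop = FALSE]),
                numeric(nrow(v)))
  out <- matrix(out, nrow = nrow(v), dimnames = list(rownames(v), names(bands)))
  out
}

#' Locate the spectral peak within a band
#'
#' Returns, per unit, the frequency of the maximum within the band after
#' optional 3-bin moving-average smoothing. Ties resolve to the lower
#' frequency. A spectrum that is flat within tolerance is flagged with
#' `flat = TRUE` (no peak); a maximum sitting on a band edge is flagged
#' `interior = FALSE`.
#'
#' @param result A `spectral_result` (unit x freq values).
#' @param band `c(lo, hi)` in Hz.
#' @param smooth Apply 3-bin moving-average smoothing first (default TRUE).
#' @param tol Flatness tolerance relative to the mean magnitude (default 1e-10).
#' @return data.frame with `unit`, `peak_hz` (NA when flat), `interior`,
#'   `flat`.
#' @export
find_peak_frequency <- function(result, band, smooth = TRUE, tol = 1e-10) {
  stopifnot(inherits(result, "spectral_result"), length(band) == 2)
  m <- result$freqs >= band[1] & result$freqs <= band[2]
  if (!any(m)) stop("band contains no grid frequencies")
  f <- result$freqs[m]
  v <- result$values[, m, drop = FALSE]
  out <- lapply(seq_len(nrow(v)), function(u) {
    y <- v[u, ]
    if (smooth && length(y) >= 3) {
      y <- stats::filter(y, rep(1 / 3, 3), sides = 2)
      y[1] <- v[u, 1:2] |> mean()
      y[length(y)] <- mean(v[u, (length(y) - 1):length(y)])
      y <- as.numeric(y)
    }
    rng <- max(y) - min(y)
    if (rng <= tol * max(abs(mean(y)), 1e-300))
      return(data.frame(unit = u, peak_hz = NA_real_, interior = FALSE, flat = TRUE))
    i <- which.max(y) # which.max takes the first (lowest-frequency) maximum
    data.frame(unit = u, peak_hz = f[i], interior = i > 1 && i < length(y), flat = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.spectral_result <- function(x, ...) {
  nd <- dim(x$values)
  cat(sprintf("<spectral_result> %s, %s units x %d freqs (%.2f-%.2f Hz), normalization %s\n",
              x$unit %||% "channel",
              paste(nd[-length(nd)], collapse = " x "),
              length(x$freqs), min(x$freqs), max(x$freqs), x$normalization))
  invisible(x)
}

#' @export
print.timefreq_map <- function(x, ...) {
  cat(sprintf("<timefreq_map> %s, %d windows x %d freqs x %d units, step %g ms\n",
              x$measure, dim(x$values)[1], dim(x$values)[2], dim(x$values)[3], x$step_ms))
  invisible(x)
}
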