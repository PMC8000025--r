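#' Band-limited oscillator specification
#'
#' One latent narrowband source: Gaussian white noise band-pass filtered
#' (4th-order Butterworth) around a per-condition center frequency, mixed
#' into channels with a depth-amplitude profile. Condition labels are
#' `RF`, `OUT1`, `OUT2`.
#'
#' @param center Center frequency in Hz.
#' @param bw Bandwidth in Hz (default 10).
#' @param amplitude Overall amplitude in µV (default 10).
#' @param depth_profile Per-channel mixing weights (length = total channel
#'   count of the session); NULL = all channels of `probe` (or all probes)
#'   at weight 1.
#' @param probe Restrict the default profile to one probe ("V1"/"V4").
#' @param cond_gain Named per-condition amplitude gains
#'   (default all 1).
#' @param cond_offset Named per-condition center-frequency offsets in Hz
#'   (default all 0).
#' @param baseline_gain Amplitude gain in the pre-stimulus baseline window
#'   (default 0.3): spontaneous narrowband activity is weaker than driven.
#' @return An `oscillator_spec` list.
#' @export
oscillator <- function(center, bw = 10, amplitude = 10, depth_profile = NULL,
                       probe = NULL,
                       cond_gain = c(RF = 1, OUT1 = 1, OUT2 = 1),
                       cond_offset = c(RF = 0, OUT1 = 0, OUT2 = 0),
                       baseline_gain = 0.3) {
  stopifnot(center > 0, bw > 0, amplitude >= 0, all(is.finite(cond_gain)))
  structure(list(center = center, bw = bw, amplitude = amplitude,
                 depth_profile = depth_profile, probe = probe,
                 cond_gain = cond_gain, cond_offset = cond_offset,
                 baseline_gain = baseline_gain),
            class = "oscillator_spec")
}

#' Directed lagged coupling specification
#'
#' A finite-lag linear term: at each time step the mean of the source
#' channels, `lag` samples back, is added to every target channel with the
#' given gain, so the latent system is exactly a vector autoregression.
#'
#' @param from Source channel indices (global, across probes).
#' @param to Target channel indices.
#' @param lag Lag in samples (>= 1).
#' @param gain Coupling gain.
#' @param cond_gain Named per-condition multipliers on `gain`.
#' @return A `coupling_spec` list.
#' @export
coupling <- function(from, to, lag = 2, gain = 0.3,
                     cond_gain = c(RF = 1, OUT1 = 1, OUT2 = 1)) {
  stopifnot(lag >= 1, is.finite(gain), length(from) >= 1, length(to) >= 1,
            !any(from %in% to) || gain == 0 || TRUE)
  structure(list(from = as.integer(from), to = as.integer(to),
                 lag = as.integer(lag), gain = gain, cond_gain = cond_gain),
            class = "coupling_spec")
}

#' Synthetic laminar-recording generator configuration
#'
#' Defines the study conditions emulated by [generate_session()]: two
#' 16-contact probes (V1, V4) at 150-µm spacing sampled at 1017.375 Hz,
#' three attention conditions (RF, OUT1, OUT2), band-limited oscillators
#' with condition-dependent gain and peak location, directed lagged
#' couplings, 1/f background noise, and a stimulus-evoked granular sink
#' whose potentials are produced by the same disc-source forward model
#' that the iCSD stage inverts.
#'
#' @param n_trials_per_condition Trials per condition (default 100).
#' @param n_channels Contacts per probe (default 16).
#' @param probes Probe area labels (default c("V1", "V4")).
#' @param spacing Contact spacing in µm (default 150).
#' @param fs Sampling rate in Hz (default 1017.375).
#' @param n_samples Samples per emitted epoch (default 512, 503.25 ms).
#' @param n_baseline Samples in the baseline tensor (default 234:
#'   -200 ms to +30 ms around stimulus onset).
#' @param oscillators List of [oscillator()] specs.
#' @param couplings List of [coupling()] specs.
#' @param noise List: `exponent` of the 1/f spectrum (default 1), `sd`
#'   (µV, default 20), `sd_white` white floor (default 2).
#' @param evoked List or NULL: `sink_channel` (within-probe index),
#'   `amplitude` (CSD units), `latency_ms`, `width_ms`, plus the return
#'   current geometry `source_offset` (contacts) and balance; used when
#'   `epoch_alignment = "stimulus_onset"`.
#' @param conduction List: disc radius `R` µm (500) and conductivity
#'   `sigma` S/m (0.4) for the evoked forward model.
#' @param epoch_alignment One of "pre_dimming" (default), "cue_onset",
#'   "stimulus_onset". Condition effects apply except at
#'   "stimulus_onset" epochs before the cue; the evoked response is added
#'   only for "stimulus_onset".
#' @param attention_onset_sample Optional sample index after which
#'   condition gains ramp in (100-ms raised-cosine ramp); NULL = whole
#'   epoch.
#' @param mua_latency_ms Per-probe minimum MUA-envelope latency (default
#'   30); the generator emits an envelope whose latency grows by
#'   `mua_latency_slope` ms per contact away from the evoked sink channel.
#' @param mua_latency_slope ms per contact (default 3).
#' @param seed Master seed (default 1).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_trials_per_condition = 100,
                             n_channels = 16,
                             probes = c("V1", "V4"),
                             spacing = 150,
                             fs = 1017.375,
                             n_samples = 512,
                             n_baseline = 234,
                             oscillators = default_oscillators(),
                             couplings = default_couplings(n_channels, length(probes)),
                             noise = list(exponent = 1, sd = 20, sd_white = 2),
                             evoked = list(sink_channel = NULL, amplitude = 1,
                                           latency_ms = 35, width_ms = 12,
                                           source_offset = 2),
                             conduction = list(R = 500, sigma = 0.4),
                             epoch_alignment = c("pre_dimming", "cue_onset", "stimulus_onset"),
                             attention_onset_sample = NULL,
                             mua_latency_ms = 30,
                             mua_latency_slope = 3,
                             seed = 1) {
  epoch_alignment <- match.arg(epoch_alignment)
  stopifnot(fs > 0, n_samples > 0, n_trials_per_condition >= 1,
            n_channels >= 1, spacing > 0, n_baseline >= 16)
  gains <- unlist(lapply(couplings, `[[`, "gain"))
  if (length(gains) && any(!is.finite(gains))) stop("coupling gains must be finite")
  if (!is.null(evoked)) {
    stopifnot(evoked$latency_ms >= 0,
              evoked$latency_ms < 1000 * n_samples / fs)
    # nominal granular contact when unspecified
    evoked$sink_channel <- evoked$sink_channel %||% (ceiling(n_channels / 2) + 1)
    stopifnot(evoked$sink_channel >= 1, evoked$sink_channel <= n_channels)
  }
  structure(list(
    n_trials_per_condition = as.integer(n_trials_per_condition),
    n_channels = as.integer(n_channels), probes = probes,
    spacing = spacing, fs = fs, n_samples = as.integer(n_samples),
    n_baseline = as.integer(n_baseline),
    oscillators = oscillators, couplings = couplings, noise = noise,
    evoked = evoked, conduction = conduction,
    epoch_alignment = epoch_alignment,
    attention_onset_sample = attention_onset_sample,
    mua_latency_ms = mua_latency_ms, mua_latency_slope = mua_latency_slope,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Default oscillator set
#'
#' An alpha source whose power drops with attention to the RF and a
#' low-gamma source whose peak sits ~4 Hz higher and is stronger under
#' attend-RF, mirroring the condition-dependent spectral structure of
#' attention experiments.
#' @export
default_oscillators <- function() {
  list(
    oscillator(center = 10, bw = 6, amplitude = 12,
               cond_gain = c(RF = 0.8, OUT1 = 1, OUT2 = 1)),
    oscillator(center = 33, bw = 8, amplitude = 10,
               cond_gain = c(RF = 1.3, OUT1 = 1, OUT2 = 1),
               cond_offset = c(RF = 4, OUT1 = 0, OUT2 = 0))
  )
}

#' Default coupling set
#'
#' A feedforward V1-granular to V4-granular coupling and a weaker
#' V4-infragranular to V1-supragranular feedback coupling.
#' @export
default_couplings <- function(n_channels = 16, n_probes = 2) {
  if (n_probes < 2) return(list())
  g <- ceiling(n_channels / 2) + 1 # nominal granular contact
  list(
    coupling(from = g, to = n_channels + g, lag = 2, gain = 0.35),
    coupling(from = 2 * n_channels - 2, to = max(1, g - 3), lag = 3, gain = 0.2)
  )
}

pink_noise <- function(n, exponent, sd_target, n_series = 1) {
  # spectral shaping of white noise: amplitude ~ f^(-exponent/2)
  w <- matrix(stats::rnorm(n * n_series), n, n_series)
  X <- stats::mvfft(w)
  f <- c(1, seq_len(n - 1)) # avoid DC blowup; bin index as frequency proxy
  shape <- f^(-exponent / 2)
  shape[1] <- 0
  X <- X * shape
  x <- Re(stats::mvfft(X, inverse = TRUE)) / n
  x <- sweep(x, 2, apply(x, 2, stats::sd), "/") * sd_target
  x
}

bp_filter_coefs <- function(center, bw, fs) {
  lo <- max(0.5, center - bw / 2) / (fs / 2)
  hi <- min(fs / 2 - 1, center + bw / 2) / (fs / 2)
  signal::butter(2, c(lo, hi), type = "pass") # 4th-order band-pass
}

narrowband_noise <- function(n, center, bw, fs) {
  bf <- bp_filter_coefs(center, bw, fs)
  pad <- 300
  x <- stats::rnorm(n + 2 * pad)
  y <- signal::filtfilt(bf, x)
  y <- y[(pad + 1):(pad + n)]
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

coupling_companion_radius <- function(couplings, n_ch, cond_gains) {
  lags <- vapply(couplings, `[[`, integer(1), "lag")
  p <- max(lags)
  A <- array(0, c(n_ch, n_ch, p))
  for (i in seq_along(couplings)) {
    cp <- couplings[[i]]
    g <- cp$gain * cond_gains[i]
    A[cp$to, cp$from, cp$lag] <- A[cp$to, cp$from, cp$lag] + g / length(cp$from)
  }
  comp <- matrix(0, n_ch * p, n_ch * p)
  for (k in seq_len(p)) comp[1:n_ch, ((k - 1) * n_ch + 1):(k * n_ch)] <- A[, , k]
  if (p > 1) comp[(n_ch + 1):(n_ch * p), 1:(n_ch * (p - 1))] <- diag(n_ch * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Generate a synthetic two-probe laminar session
#'
#' Builds trial-epoched LFPs with known ground truth: latent narrowband
#' oscillators with depth-weighted mixing and condition-dependent
#' gain/peak location, directed lagged couplings (the latent system is a
#' stable VAR; an unstable specification is rejected), 1/f noise, and -
#' for stimulus-onset-aligned epochs - an evoked potential obtained by
#' pushing the configured CSD sink/source profile through
#' [forward_potentials()], plus a stimulus-locked MUA-envelope tensor
#' with a known shortest-latency channel. Identical config and seed give
#' bit-identical output; trial content does not depend on trial order.
#'
#' @param config A [generator_config()].
#' @return A `session_recording`: list with `lfp`
#'   (trial x channel x sample, µV), `baseline`
#'   (trial x channel x n_baseline), `condition` (factor RF/OUT1/OUT2),
#'   `probe_of_channel`, `fs`, `spacing`, `epoch_alignment`, `mua`
#'   (stimulus-onset epochs only), `referencing = "monopolar"`, and
#'   `ground_truth` (the config).
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  conds <- c("RF", "OUT1", "OUT2")
  n_probe <- length(cfg$probes)
  n_ch <- cfg$n_channels * n_probe
  n_tr <- cfg$n_trials_per_condition * 3
  ns <- cfg$n_samples
  probe_of_channel <- rep(cfg$probes, each = cfg$n_channels)

  # stability of the coupling-only lag operator, per condition
  if (length(cfg$couplings)) {
    for (cond in conds) {
      cg <- vapply(cfg$couplings, function(cp) unname(cp$cond_gain[cond] %||% 1), numeric(1))
      r <- coupling_companion_radius(cfg$couplings, n_ch, cg)
      if (r >= 1) {
        worst <- which.max(vapply(cfg$couplings, function(cp) abs(cp$gain), numeric(1)))
        stop(sprintf(
          "unstable coupling specification (spectral radius %.3f >= 1 in condition %s); largest gain: channels [%s] -> [%s], lag %d, gain %.3f",
          r, cond, paste(cfg$couplings[[worst]]$from, collapse = ","),
          paste(cfg$couplings[[worst]]$to, collapse = ","),
          cfg$couplings[[worst]]$lag, cfg$couplings[[worst]]$gain))
      }
    }
  }

  # evoked potential template (per probe), via the forward model
  evoked_lfp <- NULL
  if (!is.null(cfg$evoked) && cfg$epoch_alignment == "stimulus_onset") {
    ev <- cfg$evoked
    prof <- numeric(cfg$n_channels)
    prof[ev$sink_channel] <- -ev$amplitude
    off <- ev$source_offset %||% 2
    ret <- ev$sink_channel + c(-off, off)
    ret <- ret[ret >= 1 & ret <= cfg$n_channels]
    prof[ret] <- prof[ret] + ev$amplitude / length(ret) # balanced return currents
    tt <- (seq_len(ns) - 1) / cfg$fs * 1000
    wave <- exp(-0.5 * ((tt - ev$latency_ms) / (ev$width_ms / 2))^2)
    pot <- forward_potentials(prof, cfg$spacing, cfg$conduction$R, cfg$conduction$sigma)
    evoked_lfp <- outer(pot, wave) # channel(in-probe) x sample
  }

  # ramped condition gain envelope
  ramp <- rep(1, ns)
  if (!is.null(cfg$attention_onset_sample)) {
    ramp <- numeric(ns)
    a <- cfg$attention_onset_sample
    w <- round(0.1 * cfg$fs)
    idx <- seq_len(ns)
    ramp[idx >= a + w] <- 1
    mid <- idx >= a & idx < a + w
    ramp[mid] <- 0.5 * (1 - cos(pi * (idx[mid] - a) / w))
  }

  seeds <- derive_seeds(cfg$seed, n_tr)
  lfp <- array(0, c(n_tr, n_ch, ns))
  baseline <- array(0, c(n_tr, n_ch, cfg$n_baseline))
  condition <- factor(rep(conds, each = cfg$n_trials_per_condition), levels = conds)
  lags <- if (length(cfg$couplings)) vapply(cfg$couplings, `[[`, integer(1), "lag") else integer(0)

  # per-oscillator channel profiles
  profs <- lapply(cfg$oscillators, function(osc) {
    if (!is.null(osc$depth_profile)) {
      stopifnot(length(osc$depth_profile) == n_ch)
      osc$depth_profile
    } else if (!is.null(osc$probe)) {
      as.numeric(probe_of_channel == osc$probe)
    } else rep(1, n_ch)
  })

  for (tr in seq_len(n_tr)) {
    cond <- as.character(condition[tr])
    lfp_tr <- with_seed(seeds[tr], {
      x <- t(pink_noise(ns, cfg$noise$exponent, cfg$noise$sd, n_ch)) +
        matrix(stats::rnorm(n_ch * ns, sd = cfg$noise$sd_white), n_ch, ns)
      for (k in seq_along(cfg$oscillators)) {
        osc <- cfg$oscillators[[k]]
        apply_cond <- cfg$epoch_alignment != "stimulus_onset"
        g_cond <- if (apply_cond) unname(osc$cond_gain[cond] %||% 1) else 1
        f_off <- if (apply_cond) unname(osc$cond_offset[cond] %||% 0) else 0
        s <- narrowband_noise(ns, osc$center + f_off, osc$bw, cfg$fs)
        gain_t <- osc$amplitude * (1 + (g_cond - 1) * ramp)
        x <- x + outer(profs[[k]], s * gain_t)
      }
      if (length(cfg$couplings)) {
        maxlag <- max(lags)
        cps <- lapply(cfg$couplings, function(cp) {
          g <- cp$gain * unname(cp$cond_gain[cond] %||% 1)
          list(from = cp$from, to = cp$to, lag = cp$lag, g = g / length(cp$from))
        })
        for (t in (maxlag + 1):ns) {
          for (cp in cps) {
            x[cp$to, t] <- x[cp$to, t] + cp$g * sum(x[cp$from, t - cp$lag])
          }
        }
      }
      if (!is.null(evoked_lfp)) {
        for (p in seq_len(n_probe)) {
          idx <- ((p - 1) * cfg$n_channels) + seq_len(cfg$n_channels)
          x[idx, ] <- x[idx, ] + evoked_lfp
        }
      }
      bl <- t(pink_noise(cfg$n_baseline, cfg$noise$exponent, cfg$noise$sd, n_ch)) +
        matrix(stats::rnorm(n_ch * cfg$n_baseline, sd = cfg$noise$sd_white), n_ch, cfg$n_baseline)
      for (k in seq_along(cfg$oscillators)) {
        osc <- cfg$oscillators[[k]]
        s <- narrowband_noise(cfg$n_baseline, osc$center, osc$bw, cfg$fs)
        bl <- bl + outer(profs[[k]], s) * osc$amplitude * osc$baseline_gain
      }
      list(x = x, bl = bl)
    })
    lfp[tr, , ] <- lfp_tr$x
    baseline[tr, , ] <- lfp_tr$bl
  }

  mua <- NULL
  if (cfg$epoch_alignment == "stimulus_onset") {
    sink_ch <- if (!is.null(cfg$evoked)) cfg$evoked$sink_channel else ceiling(cfg$n_channels / 2)
    lat_ms <- cfg$mua_latency_ms +
      cfg$mua_latency_slope * abs(seq_len(cfg$n_channels) - sink_ch)
    onset <- round(0.02 * cfg$fs) # envelope epoch includes 20 ms pre-onset
    n_mua <- ns
    mua <- with_seed(cfg$seed + 1L, {
      m <- array(stats::rexp(n_tr * n_ch * n_mua, rate = 10), c(n_tr, n_ch, n_mua))
      tt <- ((seq_len(n_mua) - onset) / cfg$fs) * 1000
      for (p in seq_len(n_probe)) {
        for (ch in seq_len(cfg$n_channels)) {
          gch <- (p - 1) * cfg$n_channels + ch
          resp <- 2 * pmax(0, 1 - exp(-(tt - lat_ms[ch]) / 10)) * (tt >= lat_ms[ch])
          m[, gch, ] <- sweep(m[, gch, , drop = FALSE], 3, resp, "+")
        }
      }
      attr(m, "onset_sample") <- onset
      attr(m, "latency_ms") <- lat_ms
      m
    })
  }

  structure(list(
    lfp = lfp, baseline = baseline, condition = condition,
    probe_of_channel = probe_of_channel, fs = cfg$fs, spacing = cfg$spacing,
    epoch_alignment = cfg$epoch_alignment, mua = mua,
    referencing = "monopolar", ground_truth = cfg
  ), class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  d <- dim(x$lfp)
  cat(sprintf("<session_recording> %d trials x %d channels x %d samples @ %.3f Hz (%s, %s)\n",
              d[1], d[2], d[3], x$fs, x$epoch_alignment, x$referencing))
  print(table(x$condition))
  invisible(x)
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> %d trials/condition, %d x %d channels, %d samples @ %.3f Hz, %d oscillators, %d couplings, seed %d\n",
              x$n_trials_per_condition, length(x$probes), x$n_channels,
              x$n_samples, x$fs, length(x$oscillators), length(x$couplings), x$seed))
  invisible(x)
}
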