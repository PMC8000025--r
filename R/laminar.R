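#' Spline inverse current-source density (iCSD)
#'
#' Estimates the CSD depth profile from laminar potentials by inverting the
#' disc-source conduction matrix built under cubic-spline depth
#' interpolation of the CSD (C-hat = F^-1 Phi), then smooths the estimate
#' along depth with a Gaussian filter (reflection padding at the ends).
#' Conductivity scales the magnitude of the estimate but not its spatial
#' profile.
#'
#' @param potentials Matrix depth x time of potentials (superficial row
#'   first), or a vector for a single time point.
#' @param spacing Contact spacing in µm (default 150).
#' @param R Disc radius in µm (default 500).
#' @param sigma Conductivity in S/m (default 0.4).
#' @param smooth_sd Gaussian depth-smoothing SD in µm (default 200); 0
#'   disables smoothing.
#' @param times Optional time grid in ms for the columns.
#' @return A `csd_profile`: list with `depths` (mm, increasing with depth
#'   below the first contact), `times` (ms), `csd` (smoothed, depth x time;
#'   sinks negative), `csd_raw` (pre-smoothing) and `smooth_sd`.
#' @export
compute_icsd <- function(potentials, spacing = 150, R = 500, sigma = 0.4,
                         smooth_sd = 200, times = NULL) {
  phi <- as.matrix(potentials)
  if (!all(is.finite(phi))) stop("non-finite potentials")
  n <- nrow(phi)
  if (n < 4) stop("spline iCSD needs at least 4 depths")
  depths_um <- seq(0, by = spacing, length.out = n)
  Fm <- csd_forward_matrix(depths_um, R, sigma)
  kap <- kappa(Fm, exact = FALSE)
  if (!is.finite(kap) || kap > 1e10) stop("ill-conditioned conduction matrix")
  csd_raw <- solve(Fm, phi)
  csd <- if (smooth_sd > 0) gaussian_depth_smooth(csd_raw, spacing, smooth_sd) else csd_raw
  structure(list(
    depths = depths_um / 1000,
    times = times %||% seq_len(ncol(phi)),
    csd = csd, csd_raw = csd_raw,
    smooth_sd = smooth_sd
  ), class = "csd_profile")
}

# Gaussian smoothing along depth (rows), reflection padding at the edges.
gaussian_depth_smooth <- function(x, spacing, sd_um) {
  x <- as.matrix(x)
  n <- nrow(x)
  # kernel half-width clamped to the grid so reflection padding always fits
  half <- max(1L, min(ceiling(3 * sd_um / spacing), n - 1L))
  g <- stats::dnorm(seq(-half, half) * spacing, sd = sd_um)
  g <- g / sum(g)
  # reflect rows at both ends
  top <- x[half:1, , drop = FALSE]
  bot <- x[n:(n + 1 - half), , drop = FALSE]
  xp <- rbind(top, x, bot)
  nh <- nrow(top)
  out <- matrix(0, n, ncol(x))
  for (k in seq_along(g)) {
    off <- k - half - 1L
    out <- out + g[k] * xp[nh + seq_len(n) + off, , drop = FALSE]
  }
  dimnames(out) <- dimnames(x)
  out
}

#' Detect the earliest current sink across laminae
#'
#' For each depth, the sink onset is the first time (inside the search
#' window) at which the smoothed CSD falls below
#' `-threshold * max(|sink peak|)`, where the sink peak is the most negative
#' CSD value in the window across all depths. The depth with the earliest
#' onset identifies the granular (layer IV) reference channel; ties are
#' broken toward the larger sink amplitude.
#'
#' @param csd A `csd_profile` from [compute_icsd()].
#' @param window Search window in ms, `c(from, to)` (default c(20, 100)).
#' @param threshold Fraction of the global peak sink (default 0.25).
#' @return List with `channel` (depth index), `onset_ms`, and `onsets_ms`
#'   per depth (NA where the threshold is never crossed).
#' @export
detect_earliest_sink <- function(csd, window = c(20, 100), threshold = 0.25) {
  stopifnot(inherits(csd, "csd_profile"), length(window) == 2, threshold > 0)
  sel <- which(csd$times >= window[1] & csd$times <= window[2])
  if (!length(sel)) stop("search window outside the CSD time grid")
  m <- csd$csd[, sel, drop = FALSE]
  peak_sink <- min(m)
  if (peak_sink >= 0) stop("no sink detected: CSD never negative in the search window")
  thr <- -threshold * abs(peak_sink)
  onsets <- apply(m, 1, function(row) {
    i <- which(row < thr)[1]
    if (is.na(i)) NA_real_ else csd$times[sel[i]]
  })
  if (all(is.na(onsets))) stop("no sink detected: no depth crosses the onset threshold")
  best <- which(onsets == min(onsets, na.rm = TRUE))
  if (length(best) > 1) { # tie: larger sink amplitude wins
    amp <- apply(m[best, , drop = FALSE], 1, min)
    best <- best[which.min(amp)]
  }
  list(channel = best[1], onset_ms = onsets[best[1]], onsets_ms = onsets)
}

#' Multiunit-envelope response latency per channel
#'
#' Latency is the first post-onset time at which the trial-averaged envelope
#' exceeds its pre-onset baseline mean by `k` baseline SDs. The channel with
#' the shortest latency marks the input layer.
#'
#' @param mua Array trial x channel x sample of nonnegative envelopes, or a
#'   channel x sample matrix of trial-averaged envelopes.
#' @param onset_sample Stimulus-onset sample index.
#' @param k Criterion in baseline SDs (default 3).
#' @param fs Sampling rate in Hz (default 1017.375), for ms conversion.
#' @return List with `latency_ms` per channel (NA if the criterion is never
#'   reached) and `channel`, the argmin.
#' @export
mua_latency <- function(mua, onset_sample, k = 3, fs = 1017.375) {
  if (length(dim(mua)) == 3) {
    if (any(mua < 0)) stop("envelope must be nonnegative")
    avg <- apply(mua, c(2, 3), mean)
  } else {
    avg <- as.matrix(mua)
    if (any(avg < 0)) stop("envelope must be nonnegative")
  }
  ns <- ncol(avg)
  stopifnot(onset_sample > 2, onset_sample < ns)
  base <- avg[, seq_len(onset_sample - 1), drop = FALSE]
  mu <- rowMeans(base)
  sdv <- apply(base, 1, stats::sd)
  lat <- vapply(seq_len(nrow(avg)), function(ch) {
    thr <- mu[ch] + k * sdv[ch]
    post <- avg[ch, onset_sample:ns]
    i <- which(post > thr)[1]
    if (is.na(i)) NA_real_ else (i - 1) / fs * 1000
  }, numeric(1))
  if (all(is.na(lat))) stop("no channel reaches the latency criterion")
  list(latency_ms = lat, channel = which.min(lat))
}

#' Assign laminar compartment labels from depth relative to layer IV
#'
#' Depths are in mm relative to the reference (layer IV) channel, positive
#' toward the cortical surface. Area-specific ranges: in V1, supragranular
#' at 0.25 to 1 mm above, granular within 0.25 mm, infragranular at 0.25 to
#' 0.75 mm below; in V4 the granular half-width is 0.1 mm (supragranular
#' 0.1 to 1 mm above, infragranular 0.1 to 0.75 mm below). Outer bounds are
#' closed; contacts outside all ranges are `unassigned`.
#'
#' @param depths_mm Signed depths in mm relative to the reference channel.
#' @param area `"V1"` or `"V4"`.
#' @return Character vector of labels: `supragranular`, `granular`,
#'   `infragranular`, or `unassigned`.
#' @export
assign_compartments <- function(depths_mm, area = c("V1", "V4")) {
  area <- match.arg(area)
  g_half <- if (area == "V1") 0.25 else 0.1
  vapply(depths_mm, function(d) {
    if (abs(d) < g_half) "granular"
    else if (d >= g_half && d <= 1) "supragranular"
    else if (d <= -g_half && d >= -0.75) "infragranular"
    else "unassigned"
  }, character(1))
}

#' Align one probe to layer IV
#'
#' Combines the earliest CSD sink and, when a multiunit envelope is
#' supplied, the shortest MUA-envelope latency. When the two criteria
#' disagree, the CSD sink wins and a warning is issued.
#'
#' @param csd A `csd_profile` for the probe (contact-ordered, superficial
#'   first).
#' @param area `"V1"` or `"V4"`.
#' @param spacing Contact spacing in µm.
#' @param mua Optional trial x channel x sample MUA-envelope array.
#' @param onset_sample Stimulus-onset sample for `mua`.
#' @param ... Passed to [detect_earliest_sink()].
#' @return A `laminar_alignment`: list with `reference_channel`, `depth_mm`
#'   per contact (positive = superficial), `compartment` labels, and `area`.
#' @export
align_probe <- function(csd, area = c("V1", "V4"), spacing = 150,
                        mua = NULL, onset_sample = NULL, ...) {
  area <- match.arg(area)
  sink <- detect_earliest_sink(csd, ...)
  ref <- sink$channel
  if (!is.null(mua)) {
    stopifnot(!is.null(onset_sample))
    ml <- mua_latency(mua, onset_sample)
    if (ml$channel != ref) {
      warning(sprintf(
        "CSD sink (channel %d) and MUA latency (channel %d) disagree; using the CSD sink",
        ref, ml$channel))
    }
  }
  n <- length(csd$depths)
  depth_mm <- (ref - seq_len(n)) * spacing / 1000 # positive above reference
  structure(list(
    reference_channel = ref,
    depth_mm = depth_mm,
    compartment = assign_compartments(depth_mm, area),
    area = area
  ), class = "laminar_alignment")
}

#' @export
print.laminar_alignment <- function(x, ...) {
  cat(sprintf("<laminar_alignment> area %s, reference channel %d (layer IV)\n",
              x$area, x$reference_channel))
  print(data.frame(channel = seq_along(x$depth_mm),
                   depth_mm = x$depth_mm, compartment = x$compartment),
        row.names = FALSE)
  invisible(x)
}

#' @export
print.csd_profile <- function(x, ...) {
  cat(sprintf("<csd_profile> %d depths x %d times, smoothing SD %g um\n",
              nrow(x$csd), ncol(x$csd), x$smooth_sd))
  invisible(x)
}
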