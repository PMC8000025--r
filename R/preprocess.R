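#' Epoch extraction specification
#'
#' @param offset Start offset in samples relative to the recording's
#'   alignment event (0 = first sample).
#' @param length Window length in samples (default 512: 503.25 ms at
#'   1017.375 Hz).
#' @return An `epoch_spec`.
#' @export
epoch_spec <- function(offset = 0, length = 512) {
  stopifnot(length > 0, offset >= 0)
  structure(list(offset = as.integer(offset), length = as.integer(length)),
            class = "epoch_spec")
}

#' Extract a fixed window from every trial
#'
#' Pure slicing: per-trial windows of exactly `spec$length` samples
#' starting `spec$offset` samples into the epoch. No filtering or
#' detrending happens here; per-trial mean removal is done by the spectral
#' and GC estimators at consumption time.
#'
#' @param recording A `session_recording`.
#' @param spec An [epoch_spec()].
#' @return A `session_recording` with the windowed `lfp` (baseline and
#'   metadata carried over).
#' @export
epoch <- function(recording, spec) {
  stopifnot(inherits(recording, "session_recording"), inherits(spec, "epoch_spec"))
  ns <- dim(recording$lfp)[3]
  from <- spec$offset + 1L
  to <- spec$offset + spec$length
  if (to > ns) {
    stop(sprintf("epoch window [%d, %d] exceeds the %d available samples (all %d trials affected)",
                 from, to, ns, dim(recording$lfp)[1]))
  }
  out <- recording
  out$lfp <- recording$lfp[, , from:to, drop = FALSE]
  out
}

#' Bipolar re-referencing of adjacent contacts
#'
#' Improves spatial specificity by first-differencing neighboring contacts
#' within each probe, superficial minus deep: derivation
#' `d_i = v_i - v_(i+1)`, assigned to the midpoint depth of its parents.
#' Derivations never span probes; any signal common to all contacts of a
#' probe cancels exactly.
#'
#' @param recording A `session_recording` (monopolar).
#' @return A `bipolar_recording` (also a `session_recording`) with
#'   `n_channels - 1` derivations per probe, `parent_channels`, and
#'   `derivation_midpoint` (in contact units, 1-based from the superficial
#'   end of each probe).
#' @export
bipolar_rereference <- function(recording) {
  stopifnot(inherits(recording, "session_recording"))
  if (identical(recording$referencing, "bipolar"))
    stop("recording is already bipolar re-referenced")
  probes <- unique(recording$probe_of_channel)
  keep_from <- integer(0); keep_to <- integer(0)
  for (p in probes) {
    idx <- which(recording$probe_of_channel == p)
    if (length(idx) < 2)
      stop(sprintf("probe %s has a single contact: bipolar derivation undefined", p))
    keep_from <- c(keep_from, idx[-length(idx)])
    keep_to <- c(keep_to, idx[-1])
  }
  out <- recording
  out$lfp <- recording$lfp[, keep_from, , drop = FALSE] -
    recording$lfp[, keep_to, , drop = FALSE]
  if (!is.null(recording$baseline)) {
    out$baseline <- recording$baseline[, keep_from, , drop = FALSE] -
      recording$baseline[, keep_to, , drop = FALSE]
  }
  out$mua <- NULL
  out$probe_of_channel <- recording$probe_of_channel[keep_from]
  out$parent_channels <- cbind(superficial = keep_from, deep = keep_to)
  # midpoint position within the probe, in contact units
  within <- ave(seq_along(keep_from), recording$probe_of_channel[keep_from],
                FUN = seq_along)
  out$derivation_midpoint <- within + 0.5
  out$referencing <- "bipolar"
  class(out) <- c("bipolar_recording", "session_recording")
  out
}

#' Write a session container to disk
#'
#' Serializes the recording (lfp, baseline, condition, probe metadata,
#' fs/spacing/seed attributes) as a single versioned RDS container with a
#' format tag, readable by [read_session()].
#'
#' @param recording A `session_recording`.
#' @param path Output file path.
#' @export
write_session <- function(recording, path) {
  stopifnot(inherits(recording, "session_recording"))
  obj <- unclass(recording)
  obj$.format <- "laminarGC-session"
  obj$.format_version <- 1L
  obj$.classes <- class(recording)
  saveRDS(obj, path)
  invisible(path)
}

#' Read a session container
#'
#' @param path Path written by [write_session()].
#' @return A `session_recording`.
#' @export
read_session <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$.format, "laminarGC-session"))
    stop("not a laminarGC session container")
  cls <- obj$.classes
  obj$.format <- obj$.format_version <- obj$.classes <- NULL
  structure(obj, class = cls)
}
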