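#' Behavioral bookkeeping: percent correct
#'
#' Percentage of correctly completed trials among trials where fixation was
#' maintained (fixation breaks are excluded from the denominator before
#' calling this).
#'
#' @param n_correct Number of correct trials.
#' @param n_total Number of completed (fixation-held) trials.
#' @return Percent correct, in percentage points.
#' @examples
#' percent_correct(95, 100)
#' @export
percent_correct <- function(n_correct, n_total) {
  stopifnot(is.numeric(n_correct), is.numeric(n_total), all(n_total > 0),
            all(n_correct >= 0), all(n_correct <= n_total))
  100 * n_correct / n_total
}

#' Number of distinct task conditions
#'
#' The attention task crosses the cue color (which of the three stimuli is
#' relevant), the dimming order of the three stimuli, and the grating drift
#' direction; each full cycle samples every combination.
#'
#' @param n_cue_colors Number of cue colors (default 3).
#' @param n_dimming_orders Number of dimming orders of the three stimuli
#'   (default `factorial(3)` = 6).
#' @param n_motion_directions Number of grating drift directions (default 2).
#' @return Total number of conditions per cycle.
#' @export
task_condition_count <- function(n_cue_colors = 3,
                                 n_dimming_orders = 6,
                                 n_motion_directions = 2) {
  n_cue_colors * n_dimming_orders * n_motion_directions
}

#' Duration of an analysis window in milliseconds
#'
#' @param n_samples Window length in samples.
#' @param fs Sampling rate in Hz.
#' @return Duration in ms.
#' @examples
#' window_duration_ms(512, 1017.375) # 503.25 ms
#' @export
window_duration_ms <- function(n_samples, fs) {
  stopifnot(n_samples > 0, fs > 0)
  1000 * n_samples / fs
}

#' Multitaper half-bandwidth
#'
#' Half-bandwidth W = TW / T of a Slepian taper family, where T = N / fs is
#' the window duration. Power within +/- W of a frequency is concentrated by
#' the tapers.
#'
#' @param taper A [taper_spec()].
#' @param fs Sampling rate in Hz.
#' @return Half-bandwidth in Hz.
#' @export
taper_half_bandwidth <- function(taper, fs) {
  stopifnot(inherits(taper, "taper_spec"), fs > 0)
  taper$tw * fs / taper$n
}

# Derive a stream of per-unit RNG seeds from a master seed, so content of
# unit i does not depend on how many units precede it being consumed.
derive_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1, n >= 0)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master_seed %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

# Evaluate an expression under a local RNG seed without disturbing the
# caller's RNG state.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
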