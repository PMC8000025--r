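#' Pool the two attend-away conditions
#'
#' Draws an equal number of trials (the smaller condition's count) from
#' OUT1 and OUT2 without replacement, seeded, and concatenates them into a
#' single attend-OUT trial set.
#'
#' @param trials_out1,trials_out2 Trial indices of the two conditions.
#' @param seed RNG seed.
#' @return Integer vector of pooled trial indices (length `2 * min(n1, n2)`).
#' @export
pool_attend_out <- function(trials_out1, trials_out2, seed = 1) {
  if (!length(trials_out1) || !length(trials_out2))
    stop("both OUT conditions must be non-empty")
  k <- min(length(trials_out1), length(trials_out2))
  with_seed(seed, {
    c(sample(trials_out1, k), sample(trials_out2, k))
  })
}

#' Attentional modulation index
#'
#' MI = (F_RF - F_OUT) / (F_RF + F_OUT), elementwise. For nonnegative
#' measures the MI lies in \[-1, 1\]; where both inputs are zero the index
#' is undefined and returned as NA.
#'
#' @param f_rf,f_out Nonnegative measures (any congruent shape).
#' @return MI with the shape of the inputs.
#' @export
modulation_index <- function(f_rf, f_out) {
  stopifnot(length(f_rf) == length(f_out))
  denom <- f_rf + f_out
  mi <- (f_rf - f_out) / denom
  mi[denom == 0] <- NA_real_
  mi
}

#' Two-sided Wilcoxon signed-rank tests with FDR control
#'
#' One paired test per row of `diffs`; Benjamini-Hochberg step-up is
#' applied within each test family (typically a frequency band). Tests
#' with fewer than 5 non-tied (nonzero) pairs are skipped and flagged.
#'
#' @param diffs Matrix test x n of paired differences (or a vector for a
#'   single test).
#' @param family Factor of length nrow(diffs) grouping tests into FDR
#'   families (default: one family).
#' @param q FDR level (default 0.05).
#' @return data.frame with `test`, `family`, `n_effective`, `p`, `q_value`,
#'   `significant`, `skipped`.
#' @export
wilcoxon_fdr <- function(diffs, family = NULL, q = 0.05) {
  if (is.vector(diffs)) diffs <- matrix(diffs, nrow = 1)
  nt <- nrow(diffs)
  family <- factor(family %||% rep("all", nt))
  stopifnot(length(family) == nt)
  p <- rep(NA_real_, nt); neff <- integer(nt)
  for (i in seq_len(nt)) {
    d <- diffs[i, ]
    d <- d[is.finite(d)]
    d <- d[d != 0]
    neff[i] <- length(d)
    if (length(d) < 5) next # skipped: too few non-tied pairs
    p[i] <- suppressWarnings(stats::wilcox.test(d, mu = 0, alternative = "two.sided")$p.value)
  }
  qv <- rep(NA_real_, nt)
  for (f in levels(family)) {
    sel <- which(family == f & !is.na(p))
    if (length(sel)) qv[sel] <- stats::p.adjust(p[sel], method = "BH")
  }
  data.frame(test = seq_len(nt), family = family, n_effective = neff,
             p = p, q_value = qv,
             significant = !is.na(qv) & qv <= q,
             skipped = is.na(p))
}

#' Dominance-direction matrix for directed GC
#'
#' For each contact pair (X, Y), tests across sessions whether cGC is
#' stronger X to Y or Y to X (two-sided Wilcoxon signed-rank on the
#' directional difference, BH-corrected across pairs within the band).
#' Significant pairs receive the session-mean cGC of the dominant
#' direction, signed so that entry (i, j) > 0 means i to j dominates
#' (and entry (j, i) carries the same strength with negative sign);
#' non-significant pairs are 0.
#'
#' @param cgc Array session x n x n of band-averaged directed cGC
#'   (`cgc[s, i, j]` = session s, direction i to j). At least 5 sessions.
#' @param q FDR level (default 0.05).
#' @return A `dominance_matrix`: list with `matrix` (n x n signed
#'   strengths), `tests` (the [wilcoxon_fdr()] table with pair indices),
#'   `q`.
#' @export
dominance_matrix <- function(cgc, q = 0.05) {
  stopifnot(length(dim(cgc)) == 3, dim(cgc)[2] == dim(cgc)[3])
  n_ses <- dim(cgc)[1]; n <- dim(cgc)[2]
  if (n_ses < 5) stop("dominance testing needs at least 5 sessions")
  prs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  diffs <- t(apply(prs, 1, function(ij) cgc[, ij[1], ij[2]] - cgc[, ij[2], ij[1]]))
  tests <- wilcoxon_fdr(diffs, q = q)
  tests$from <- prs[, 1]; tests$to <- prs[, 2]
  M <- matrix(0, n, n)
  for (k in which(tests$significant)) {
    i <- prs[k, 1]; j <- prs[k, 2]
    d_mean <- mean(cgc[, i, j] - cgc[, j, i])
    if (d_mean > 0) {
      s <- mean(cgc[, i, j]); M[i, j] <- s; M[j, i] <- -s
    } else {
      s <- mean(cgc[, j, i]); M[j, i] <- s; M[i, j] <- -s
    }
  }
  structure(list(matrix = M, tests = tests, q = q), class = "dominance_matrix")
}

#' @export
print.dominance_matrix <- function(x, ...) {
  ns <- sum(x$tests$significant)
  cat(sprintf("<dominance_matrix> %d x %d contacts, %d significant pair(s) at q <= %g\n",
              nrow(x$matrix), ncol(x$matrix), ns, x$q))
  invisible(x)
}

#' Normalize band-averaged cGC to the per-group maximum
#'
#' Divides each group's five band values by that group's maximum across
#' the bands, so the strongest band maps to 1. Groups (rows) are
#' normalized independently (e.g. per monkey, separately for within-area
#' and between-area pools).
#'
#' @param band_values Numeric vector (one group) or matrix group x band.
#' @return Same shape, each group scaled to max 1.
#' @export
normalize_cgc <- function(band_values) {
  v <- if (is.null(dim(band_values))) matrix(band_values, 1,
         dimnames = list(NULL, names(band_values))) else as.matrix(band_values)
  mx <- apply(v, 1, max)
  if (any(mx == 0)) stop("zero maximum cGC in a normalization group")
  out <- sweep(v, 1, mx, "/")
  if (is.null(dim(band_values))) drop(out) else out
}

#' Pool contact-level directed values into laminar compartments
#'
#' Arithmetic mean of directed contact-pair values grouped by (source
#' compartment, target compartment); `unassigned` contacts are excluded.
#' Empty compartment combinations are returned as NA and flagged.
#'
#' @param values Matrix n x n of directed contact-pair values
#'   (`values[i, j]` = i to j; the diagonal is ignored).
#' @param from_compartments Compartment label per source contact.
#' @param to_compartments Compartment label per target contact (defaults
#'   to `from_compartments` for within-probe pooling).
#' @return 3 x 3 matrix (supragranular, granular, infragranular) of
#'   pooled means, with attribute `n` giving pair counts.
#' @export
compartment_pool <- function(values, from_compartments,
                             to_compartments = from_compartments) {
  stopifnot(nrow(values) == length(from_compartments),
            ncol(values) == length(to_compartments))
  comps <- c("supragranular", "granular", "infragranular")
  out <- matrix(NA_real_, 3, 3, dimnames = list(comps, comps))
  nmat <- matrix(0L, 3, 3, dimnames = list(comps, comps))
  same <- identical(from_compartments, to_compartments) &&
    nrow(values) == ncol(values)
  for (a in comps) for (b in comps) {
    ia <- which(from_compartments == a); ib <- which(to_compartments == b)
    if (!length(ia) || !length(ib)) next
    v <- values[ia, ib, drop = FALSE]
    if (same) { # drop self-pairs on the diagonal of the full matrix
      for (r in seq_along(ia)) for (cc in seq_along(ib))
        if (ia[r] == ib[cc]) v[r, cc] <- NA
    }
    v <- v[is.finite(v)]
    if (!length(v)) next
    out[a, b] <- mean(v)
    nmat[a, b] <- length(v)
  }
  if (any(is.na(out)))
    attr(out, "empty") <- which(is.na(out), arr.ind = TRUE)
  attr(out, "n") <- nmat
  out
}

#' Spectrogram modulation index (SMI)
#'
#' The attentional modulation index applied per (time, frequency, unit)
#' cell of two sliding-window maps. Maps must share grids. By default the
#' SMI is computed on raw (nonnegative) power maps; baseline z-scored maps
#' can be negative, making the ratio ill-behaved, so they are refused
#' unless `allow_negative = TRUE`.
#'
#' @param tf_rf,tf_out `timefreq_map`s for attend-RF and pooled attend-OUT.
#' @param allow_negative Permit maps with negative values (default FALSE).
#' @return A `timefreq_map` with `measure = "smi"`.
#' @export
smi <- function(tf_rf, tf_out, allow_negative = FALSE) {
  stopifnot(inherits(tf_rf, "timefreq_map"), inherits(tf_out, "timefreq_map"))
  if (!identical(dim(tf_rf$values), dim(tf_out$values)) ||
      max(abs(tf_rf$times - tf_out$times)) > 1e-9 ||
      max(abs(tf_rf$freqs - tf_out$freqs)) > 1e-9)
    stop("time-frequency grids do not match")
  if (!allow_negative && (min(tf_rf$values) < 0 || min(tf_out$values) < 0))
    stop("SMI expects nonnegative (raw power) maps; set allow_negative = TRUE to override")
  out <- tf_rf
  out$values <- array(modulation_index(tf_rf$values, tf_out$values),
                      dim(tf_rf$values))
  out$measure <- "smi"
  out
}

#' Repeated-measures ANOVA across the three attention conditions
#'
#' Single-factor (condition) repeated-measures ANOVA on a session x
#' condition table, used as a secondary check on the RF/OUT1/OUT2 triplet
#' before pooling the OUT conditions.
#'
#' @param values Matrix session x 3 (columns RF, OUT1, OUT2).
#' @return List with `F`, `df`, `p`.
#' @export
attention_anova <- function(values) {
  stopifnot(ncol(values) == 3, nrow(values) >= 3)
  df <- data.frame(
    y = as.vector(values),
    cond = factor(rep(colnames(values) %||% c("RF", "OUT1", "OUT2"),
                      each = nrow(values))),
    subj = factor(rep(seq_len(nrow(values)), times = 3)))
  fit <- stats::aov(y ~ cond + Error(subj / cond), data = df)
  tab <- summary(fit)[["Error: subj:cond"]][[1]]
  list(F = tab["cond", "F value"], df = c(tab["cond", "Df"], tab["Residuals", "Df"]),
       p = tab["cond", "Pr(>F)"])
}
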