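#' Fit a vector autoregression across trials
#'
#' Per-trial demeaned multi-trial least squares: lag-stacked covariances
#' are pooled across trials and solved in one normal-equation system. When
#' `order` is NULL the order is chosen by the selection criterion over
#' `1:p_max` on a common sample range, then the model is refit at the
#' selected order on all usable samples.
#'
#' @param epochs Array trial x dim x sample (or dim x sample matrix for a
#'   single trial).
#' @param order Fixed model order, or NULL for criterion-based selection.
#' @param p_max Largest order considered (default 20).
#' @param criterion "bic" (default) or "aic".
#' @param guard_ratio Minimum ratio of pooled regression rows to p*dim^2
#'   (default 10); a violation is an error.
#' @return A `var_model`: `order`, `A` (dim x dim x order), `Sigma`
#'   (innovation covariance), `n_obs`, `spectral_radius`, `criterion`
#'   table, `ridge_applied`.
#' @export
fit_var <- function(epochs, order = NULL, p_max = 20, criterion = c("bic", "aic"),
                    guard_ratio = 10) {
  criterion <- match.arg(criterion)
  if (is.matrix(epochs)) epochs <- array(epochs, c(1, nrow(epochs), ncol(epochs)))
  n_tr <- dim(epochs)[1]; d <- dim(epochs)[2]; ns <- dim(epochs)[3]
  # per-trial, per-channel demeaning
  mu <- apply(epochs, c(1, 2), mean)
  epochs <- sweep(epochs, c(1, 2), mu)

  crit_tab <- NULL
  if (is.null(order)) {
    p_max <- min(p_max, ns - d - 2)
    G <- matrix(0, d * (p_max + 1), d * (p_max + 1))
    nr <- 0
    for (tr in seq_len(n_tr)) {
      xm <- if (d == 1) matrix(epochs[tr, 1, ], ncol = 1) else t(epochs[tr, , ])
      E <- stats::embed(xm, p_max + 1)
      G <- G + crossprod(E)
      nr <- nr + nrow(E)
    }
    crit <- vapply(seq_len(p_max), function(p) {
      yi <- seq_len(d); xi <- d + seq_len(d * p)
      XtX <- G[xi, xi, drop = FALSE]
      B <- tryCatch(solve(XtX, G[xi, yi, drop = FALSE]),
                    error = function(e) NULL)
      if (is.null(B)) return(NA_real_)
      S <- (G[yi, yi] - crossprod(G[xi, yi, drop = FALSE], B)) / nr
      ld <- determinant(S, logarithm = TRUE)
      if (ld$sign <= 0) return(NA_real_)
      k <- p * d^2
      as.numeric(ld$modulus) + k * (if (criterion == "bic") log(nr) else 2) / nr
    }, numeric(1))
    if (all(is.na(crit))) stop("singular covariance at every candidate order (duplicated or collinear channels?)")
    order <- which.min(crit)
    crit_tab <- data.frame(order = seq_len(p_max), criterion = crit)
  }
  p <- as.integer(order)
  stopifnot(p >= 1, p < ns)

  XtX <- matrix(0, d * p, d * p); XtY <- matrix(0, d * p, d)
  YtY <- matrix(0, d, d); nr <- 0
  for (tr in seq_len(n_tr)) {
    xm <- if (d == 1) matrix(epochs[tr, 1, ], ncol = 1) else t(epochs[tr, , ])
    E <- stats::embed(xm, p + 1)
    Y <- E[, seq_len(d), drop = FALSE]
    X <- E[, d + seq_len(d * p), drop = FALSE]
    XtX <- XtX + crossprod(X); XtY <- XtY + crossprod(X, Y)
    YtY <- YtY + crossprod(Y); nr <- nr + nrow(E)
  }
  if (nr / (p * d^2) < guard_ratio)
    stop(sprintf("guard-ratio violation: %d pooled samples for p*dim^2 = %d (ratio %.1f < %g)",
                 nr, p * d^2, nr / (p * d^2), guard_ratio))
  B <- tryCatch(solve(XtX, XtY), error = function(e)
    stop("singular lag covariance (duplicated or collinear channels?)"))
  Sigma <- (YtY - crossprod(XtY, B)) / (nr - d * p)
  Sigma <- (Sigma + t(Sigma)) / 2
  ridge_applied <- FALSE
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / max(min(ev), .Machine$double.eps) > 1e12) {
    Sigma <- Sigma + diag(1e-8 * sum(diag(Sigma)) / d, d)
    ridge_applied <- TRUE
    ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("innovation covariance not positive definite")
  }
  A <- array(0, c(d, d, p))
  for (k in seq_len(p)) A[, , k] <- t(B[(k - 1) * d + seq_len(d), , drop = FALSE])
  comp <- matrix(0, d * p, d * p)
  for (k in seq_len(p)) comp[seq_len(d), (k - 1) * d + seq_len(d)] <- A[, , k]
  if (p > 1) comp[(d + 1):(d * p), seq_len(d * (p - 1))] <- diag(d * (p - 1))
  sr <- max(Mod(eigen(comp, only.values = TRUE)$values))
  if (sr >= 1)
    stop(sprintf("unstable VAR fit (companion spectral radius %.4f >= 1)", sr))
  structure(list(order = p, A = A, Sigma = Sigma, n_obs = nr, dim = d,
                 spectral_radius = sr, criterion = crit_tab,
                 ridge_applied = ridge_applied),
            class = "var_model")
}

#' Simulate trials from a VAR process
#'
#' Draws independent trials from the VAR defined by coefficient array `A`
#' and innovation covariance `Sigma`, discarding a burn-in so trials start
#' from the stationary distribution.
#'
#' @param A Coefficient array dim x dim x order.
#' @param Sigma Innovation covariance (default identity).
#' @param n_trials,n_samples Trial count and samples per trial.
#' @param burn Burn-in samples discarded per trial (default 200).
#' @param seed RNG seed.
#' @return Array trial x dim x sample.
#' @export
simulate_var <- function(A, Sigma = diag(dim(A)[1]), n_trials, n_samples,
                         burn = 200, seed = 1) {
  d <- dim(A)[1]; p <- dim(A)[3]
  L <- chol(Sigma)
  with_seed(seed, {
    out <- array(0, c(n_trials, d, n_samples))
    for (tr in seq_len(n_trials)) {
      n <- n_samples + burn
      e <- matrix(stats::rnorm(n * d), n, d) %*% L
      x <- matrix(0, d, n)
      for (t in (p + 1):n) {
        acc <- e[t, ]
        for (k in seq_len(p)) acc <- acc + A[, , k] %*% x[, t - k]
        x[, t] <- acc
      }
      out[tr, , ] <- x[, (burn + 1):n]
    }
    out
  })
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("<var_model> dim %d, order %d, %d pooled samples, spectral radius %.3f\n",
              x$dim, x$order, x$n_obs, x$spectral_radius))
  invisible(x)
}

# Autocovariance sequence Gamma_0..Gamma_q of a stable VAR, via the
# companion-form Lyapunov equation (doubling iteration) and the Yule-Walker
# extension for lags >= p.
var_autocov <- function(A, Sigma, q) {
  d <- dim(A)[1]; p <- dim(A)[3]
  M <- matrix(0, d * p, d * p)
  for (k in seq_len(p)) M[1:d, (k - 1) * d + 1:d] <- A[, , k]
  if (p > 1) M[(d + 1):(d * p), 1:(d * (p - 1))] <- diag(d * (p - 1))
  S <- matrix(0, d * p, d * p); S[1:d, 1:d] <- Sigma
  X <- S; Mk <- M
  for (i in 1:60) {
    X <- X + Mk %*% X %*% t(Mk)
    Mk <- Mk %*% Mk
    if (max(abs(Mk)) < 1e-300) break
  }
  G <- array(0, c(d, d, q + 1))
  for (k in 0:min(q, p - 1)) G[, , k + 1] <- X[1:d, k * d + 1:d]
  if (q >= p) for (k in p:q) {
    acc <- matrix(0, d, d)
    for (j in seq_len(p)) acc <- acc + A[, , j] %*% G[, , k - j + 1]
    G[, , k + 1] <- acc
  }
  G
}

# Whittle's multivariate Levinson-Durbin recursion: AR(q) coefficients and
# innovation covariance of the process with autocovariances G.
whittle_ar <- function(G, q) {
  d <- dim(G)[1]
  A <- array(0, c(d, d, q)); B <- array(0, c(d, d, q))
  V <- matrix(G[, , 1], d, d); Vb <- V
  for (n in seq_len(q)) {
    D <- matrix(G[, , n + 1], d, d)
    if (n > 1) for (k in 1:(n - 1)) D <- D - A[, , k] %*% G[, , n - k + 1]
    An <- D %*% solve(Vb)
    Bn <- t(D) %*% solve(V)
    if (n > 1) {
      Aold <- A; Bold <- B
      for (k in 1:(n - 1)) {
        A[, , k] <- Aold[, , k] - An %*% Bold[, , n - k]
        B[, , k] <- Bold[, , k] - Bn %*% Aold[, , n - k]
      }
    }
    A[, , n] <- An; B[, , n] <- Bn
    V <- (diag(d) - An %*% Bn) %*% V
    Vb <- (diag(d) - Bn %*% An) %*% Vb
  }
  list(A = A, V = (V + t(V)) / 2)
}

# Transfer function H(f) = (I - sum_k A_k e^{-i 2 pi f k / fs})^{-1} for a
# coefficient array, returned as a list of complex matrices per frequency.
transfer_from_coefs <- function(A, freqs, fs) {
  d <- dim(A)[1]; p <- dim(A)[3]
  Z <- exp(outer(seq_len(p), -1i * 2 * pi * freqs / fs))  # p x nf
  Aflat <- matrix(A, d * d, p)
  AfAll <- Aflat %*% Z                                    # d^2 x nf
  lapply(seq_along(freqs), function(i) {
    solve(diag(d) - matrix(AfAll[, i], d, d))
  })
}

var_transfer <- function(model, freqs, fs) transfer_from_coefs(model$A, freqs, fs)

# Marginal (reduced) model of the first mr variables of a fitted VAR,
# derived from the model's own autocovariance by Whittle factorization.
# The marginal of a VAR is VARMA, i.e. AR(infinity); q lags approximate it,
# with q chosen from the fitted spectral radius up to q_max.
reduced_from_model <- function(full, mr, q_max = 64) {
  sr <- min(max(full$spectral_radius, 0.5), 0.995)
  q <- min(q_max, max(full$order, ceiling(log(1e-7) / log(sr))))
  G <- var_autocov(full$A, full$Sigma, q)
  whittle_ar(array(G[seq_len(mr), seq_len(mr), ], c(mr, mr, dim(G)[3])), q)
}

# Geweke conditional spectral GC from a fitted full model; the reduced
# model on (target, conditioning...) is the full model's own marginal.
# Ordering inside the full model must be (target, conditioning..., source).
cgc_from_model <- function(full, mr, freqs, fs, q_max = 64) {
  m <- full$dim
  red <- reduced_from_model(full, mr, q_max)
  Sf <- full$Sigma; Sr <- red$V
  zidx <- if (mr > 1) 2:mr else integer(0)
  # normalize full innovations: partial out the target's innovation from the
  # others, then partial the conditioning set out of the source
  P1 <- diag(m)
  P1[-1, 1] <- -Sf[-1, 1] / Sf[1, 1]
  S1 <- P1 %*% Sf %*% t(P1)
  P <- P1
  if (length(zidx)) {
    P2 <- diag(m)
    P2[(mr + 1):m, zidx] <- -S1[(mr + 1):m, zidx, drop = FALSE] %*%
      solve(S1[zidx, zidx, drop = FALSE])
    P <- P2 %*% P1
  }
  Pinv <- solve(P)
  # reduced model normalization (conditioning innovations vs target)
  PR <- diag(mr)
  if (mr > 1) PR[-1, 1] <- -Sr[-1, 1] / Sr[1, 1]
  PRinv <- solve(PR)
  H <- var_transfer(full, freqs, fs)
  G <- transfer_from_coefs(red$A, freqs, fs)
  num <- Sr[1, 1]
  syy <- Sf[1, 1]
  f <- vapply(seq_along(freqs), function(i) {
    Ht <- H[[i]] %*% Pinv
    Ge <- diag(m) + 0i
    Ge[seq_len(mr), seq_len(mr)] <- G[[i]] %*% PRinv
    Q1 <- solve(Ge, Ht)[1, 1]
    log(num / (Mod(Q1)^2 * syy))
  }, numeric(1))
  n_clip <- sum(f < 0)
  f[f < 0] <- 0
  list(f = f, n_clipped = n_clip, gc_time = log(Sr[1, 1] / Sf[1, 1]),
       q_reduced = dim(red$A)[3])
}

#' Conditional spectral Granger causality for one directed pair
#'
#' Geweke-style conditional GC from channel `x` to channel `y` given the
#' conditioning set `z`, on the fs/N frequency grid: a full VAR is fit on
#' (y, z, x); the reduced model on (y, z) is the full model's own marginal,
#' obtained from its autocovariance sequence by Whittle factorization (the
#' marginal of a VAR is ARMA, so refitting it as a low-order VAR biases the
#' GC level upward); the spectral decomposition of the reduced innovations
#' through the full model yields f_{x->y|z}(f). Values are nonnegative by
#' construction; small negative numerical artifacts are clipped at 0 and
#' counted (a warning is raised when more than 1% of bins clip). With `z`
#' empty this is the unconditional (pairwise) spectral GC.
#'
#' @param epochs Array trial x channel x sample.
#' @param x Source channel index.
#' @param y Target channel index.
#' @param z Conditioning channel indices (default none).
#' @param fs Sampling rate in Hz.
#' @param order Fixed VAR order of the full model, or NULL for BIC
#'   selection over 1:p_max.
#' @param p_max Order-selection bound (default 20).
#' @param q_max Lag cap for the derived reduced model (default 64).
#' @param freqs Frequency grid (default the one-sided fs/N grid of the
#'   epoch length).
#' @return A `gc_result`: `freqs`, `cgc` (1 x nfreq matrix), `pairs`,
#'   `conditioning`, `gc_time` (time-domain conditional GC), `n_clipped`,
#'   `orders` (full VAR order and derived reduced-model lag count), `fs`.
#' @export
conditional_spectral_gc <- function(epochs, x, y, z = integer(0), fs,
                                    order = NULL, p_max = 20, q_max = 64,
                                    freqs = NULL) {
  ep <- as_epoch_array(epochs)
  x <- as.integer(x); y <- as.integer(y); z <- as.integer(z)
  if (x == y || x %in% z || y %in% z)
    stop("source, target and conditioning set must be disjoint")
  freqs <- freqs %||% one_sided_freqs(dim(ep)[3], fs)
  full <- fit_var(ep[, c(y, z, x), , drop = FALSE], order = order[1],
                  p_max = p_max)
  res <- cgc_from_model(full, mr = 1 + length(z), freqs, fs, q_max = q_max)
  if (res$n_clipped > 0.01 * length(freqs))
    warning(sprintf("%d of %d spectral GC bins were negative and clipped",
                    res$n_clipped, length(freqs)))
  structure(list(freqs = freqs, cgc = matrix(res$f, 1), fs = fs,
                 pairs = cbind(from = x, to = y),
                 conditioning = list(z), gc_time = res$gc_time,
                 n_clipped = res$n_clipped,
                 orders = c(full = full$order, reduced = res$q_reduced),
                 threshold = NULL),
            class = "gc_result")
}

#' Frequency-averaged spectral GC (Geweke integral)
#'
#' Mean of the spectral GC over the two-sided frequency grid (interior
#' one-sided bins counted twice), which for a well-specified stable model
#' approximates the time-domain GC.
#'
#' @param gc A `gc_result`.
#' @return Numeric, one value per directed pair.
#' @export
spectral_gc_mean <- function(gc) {
  stopifnot(inherits(gc, "gc_result"))
  v <- gc$cgc
  nf <- ncol(v)
  w <- c(1, rep(2, nf - 2), 1)
  as.numeric(v %*% w) / sum(w)
}

#' Trial-shuffle null threshold for conditional GC
#'
#' Destroys the source-target association while preserving all marginal
#' statistics: for each shuffle, the source channel's trial order is
#' permuted relative to the target (the conditioning set stays with the
#' target) and the conditional spectral GC is recomputed with the same
#' model order as the observed fit. Returns the given percentile of the
#' null per frequency, per band, and for the grid-mean statistic.
#'
#' @param epochs Array trial x channel x sample.
#' @param x,y,z Source, target, conditioning channel indices.
#' @param fs Sampling rate in Hz.
#' @param n_shuffles Number of trial permutations (default 200; at least
#'   20, with a warning below 100).
#' @param percentile Null percentile (default 95).
#' @param seed RNG seed for the permutations.
#' @param order VAR order(s) used for every shuffle; NULL selects by BIC
#'   on the observed data and reuses those orders.
#' @param bands A [band_set()] for band-averaged thresholds.
#' @return List with `per_frequency` (vector over freqs), `band` (named
#'   vector), `mean` (scalar), `freqs`, `n_shuffles`, and the observed
#'   `observed` `gc_result`.
#' @export
shuffle_null_threshold <- function(epochs, x, y, z = integer(0), fs,
                                   n_shuffles = 200, percentile = 95,
                                   seed = 1, order = NULL,
                                   bands = band_set()) {
  ep <- as_epoch_array(epochs)
  n_tr <- dim(ep)[1]
  if (n_tr < 3) stop("shuffle null needs at least 3 trials")
  if (n_shuffles < 20) stop("n_shuffles must be at least 20 for a usable 95th percentile")
  if (n_shuffles < 100) warning("fewer than 100 shuffles: the 95th percentile is noisy")
  freqs <- one_sided_freqs(dim(ep)[3], fs)
  obs <- conditional_spectral_gc(ep, x, y, z, fs, order = order)
  p_full <- unname(obs$orders["full"])
  nf <- length(freqs)
  nb <- length(bands)
  masks <- lapply(seq_len(nb), function(b) band_mask(freqs, bands[[b]], last = b == nb))
  null_f <- matrix(0, n_shuffles, nf)
  perms <- with_seed(seed, replicate(n_shuffles, sample.int(n_tr), simplify = FALSE))
  sub <- ep[, c(y, z, x), , drop = FALSE]
  m <- dim(sub)[2]
  for (s in seq_len(n_shuffles)) {
    shuf <- sub
    shuf[, m, ] <- sub[perms[[s]], m, ]
    full <- fit_var(shuf, order = p_full)
    null_f[s, ] <- cgc_from_model(full, mr = m - 1, freqs, fs)$f
  }
  pr <- percentile / 100
  band_null <- vapply(seq_len(nb), function(b) rowMeans(null_f[, masks[[b]], drop = FALSE]),
                      numeric(n_shuffles))
  wts <- c(1, rep(2, nf - 2), 1)
  list(per_frequency = apply(null_f, 2, stats::quantile, probs = pr, names = FALSE),
       band = stats::setNames(apply(band_null, 2, stats::quantile, probs = pr, names = FALSE),
                              names(bands)),
       mean = stats::quantile(as.numeric(null_f %*% wts) / sum(wts), probs = pr, names = FALSE),
       freqs = freqs, n_shuffles = n_shuffles, observed = obs)
}

# Conditioning set for a directed pair: remaining derivations of the same
# probe (within) or of both probes (between), capped by retaining the
# nearest by depth.
conditioning_set <- function(i, j, channels, positions, cap = 8) {
  rest <- setdiff(channels, c(i, j))
  if (length(rest) > cap) {
    dist <- pmin(abs(positions[rest] - positions[i]), abs(positions[rest] - positions[j]))
    rest <- rest[order(dist)][seq_len(cap)]
  }
  sort(rest)
}

#' Conditional GC over all directed contact pairs
#'
#' Iterates every ordered pair of derivations in scope; each pair is
#' conditioned on the remaining derivations of its probe (within-probe
#' scope) or of both probes (between-probe scope), capped at
#' `conditioning_cap` nearest-by-depth derivations. One `gc_result` per
#' requested condition; OUT1/OUT2 trials are pooled with
#' [pool_attend_out()] and RF trials are subsampled to the pooled size so
#' both conditions use equal trial counts.
#'
#' @param recording A `bipolar_recording` (aligned, bipolar-referenced).
#' @param scope "within" (default) or "between" probes.
#' @param conditions Character vector out of "RF", "OUT" (default both).
#' @param conditioning_cap Maximum conditioning-set size (default 8).
#' @param order Fixed VAR order(s) passed to [conditional_spectral_gc()].
#' @param seed Seed for OUT pooling / RF balancing.
#' @param probe Restrict within-probe scope to one probe label (default:
#'   first probe).
#' @return Named list of `gc_result` (one per condition), each with
#'   `cgc` pair x freq and `pairs`.
#' @export
pairwise_cgc <- function(recording, scope = c("within", "between"),
                         conditions = c("RF", "OUT"), conditioning_cap = 8,
                         order = NULL, seed = 1, probe = NULL) {
  scope <- match.arg(scope)
  stopifnot(inherits(recording, "bipolar_recording"))
  pc <- recording$probe_of_channel
  pos <- recording$derivation_midpoint
  if (scope == "within") {
    probe <- probe %||% unique(pc)[1]
    chans <- which(pc == probe)
    prs <- expand.grid(from = chans, to = chans)
    prs <- prs[prs$from != prs$to, ]
  } else {
    pr_labels <- unique(pc)
    stopifnot(length(pr_labels) == 2)
    a <- which(pc == pr_labels[1]); b <- which(pc == pr_labels[2])
    prs <- rbind(expand.grid(from = a, to = b), expand.grid(from = b, to = a))
    chans <- c(a, b)
  }
  # equal-trial-count conditions
  idx_rf <- which(recording$condition == "RF")
  pooled_out <- pool_attend_out(which(recording$condition == "OUT1"),
                                which(recording$condition == "OUT2"), seed = seed)
  idx_rf <- with_seed(seed + 1L, sample(idx_rf, min(length(idx_rf), length(pooled_out))))
  trial_sets <- list(RF = sort(idx_rf), OUT = sort(pooled_out))[conditions]
  freqs <- one_sided_freqs(dim(recording$lfp)[3], recording$fs)
  out <- lapply(trial_sets, function(trs) {
    cgc <- matrix(0, nrow(prs), length(freqs))
    conds <- vector("list", nrow(prs))
    gct <- numeric(nrow(prs))
    for (k in seq_len(nrow(prs))) {
      i <- prs$from[k]; j <- prs$to[k]
      zset <- conditioning_set(i, j, chans, pos, conditioning_cap)
      r <- tryCatch(
        conditional_spectral_gc(recording$lfp[trs, , , drop = FALSE],
                                x = i, y = j, z = zset, fs = recording$fs,
                                order = order),
        error = function(e) stop(sprintf("pair %d->%d: %s", i, j, conditionMessage(e))))
      cgc[k, ] <- r$cgc
      conds[[k]] <- zset
      gct[k] <- r$gc_time
    }
    structure(list(freqs = freqs, cgc = cgc, fs = recording$fs,
                   pairs = as.matrix(prs), conditioning = conds,
                   gc_time = gct, n_clipped = NA, threshold = NULL),
              class = "gc_result")
  })
  out
}

#' @export
print.gc_result <- function(x, ...) {
  cat(sprintf("<gc_result> %d directed pair(s) x %d freqs (%.2f-%.2f Hz)\n",
              nrow(x$cgc), length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}
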