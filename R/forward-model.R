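#' Potential of a uniform current disc
#'
#' Closed-form potential generated at axial distance `dist` by a planar disc
#' of radius `R` carrying uniform current-source density, per unit CSD and
#' unit disc thickness, in an infinite isotropic medium of conductivity
#' `sigma`:
#' \deqn{\phi(d) = \frac{\sqrt{d^2 + R^2} - |d|}{2\sigma}.}
#'
#' @param dist Axial distance(s) from the disc plane, in µm.
#' @param R Disc radius in µm (default 500).
#' @param sigma Tissue conductivity in S/m (default 0.4).
#' @return Potential per unit current-source density, same length as `dist`.
#'   With CSD in µA/mm^3, distances in µm and `sigma` in S/m the result is
#'   in nV per µm of source thickness.
#' @export
disc_potential_kernel <- function(dist, R = 500, sigma = 0.4) {
  stopifnot(R > 0, sigma > 0)
  (sqrt(dist^2 + R^2) - abs(dist)) / (2 * sigma)
}

#' Disc-source forward matrix under cubic-spline CSD interpolation
#'
#' Builds the conduction matrix F mapping CSD values at the electrode depths
#' to potentials at the same depths, assuming the CSD varies along depth as
#' the natural cubic spline through the electrode values and that each
#' infinitesimal depth slab is a uniform disc of radius `R`. Column j is the
#' potential profile of the spline cardinal basis function of electrode j,
#' obtained by numerical quadrature along depth.
#'
#' @param depths Electrode depths in µm, strictly monotone.
#' @param R Disc radius in µm.
#' @param sigma Conductivity in S/m.
#' @param n_sub Quadrature subintervals per electrode gap (default 20).
#' @return A length(depths) x length(depths) matrix F with Phi = F %*% C.
#' @export
csd_forward_matrix <- function(depths, R = 500, sigma = 0.4, n_sub = 20) {
  n <- length(depths)
  stopifnot(n >= 4, R > 0, sigma > 0, n_sub >= 2)
  d <- diff(depths)
  if (any(d == 0)) stop("duplicate electrode depths")
  if (any(d < 0) && any(d > 0)) stop("electrode depths must be monotone")
  if (all(d < 0)) depths <- rev(depths) # computed symmetric in ordering
  # fine depth grid across the electrode span
  fine <- unique(unlist(lapply(seq_len(n - 1), function(i) {
    seq(depths[i], depths[i + 1], length.out = n_sub + 1)
  })))
  # trapezoid weights on the (non-uniform-safe) fine grid
  h <- diff(fine)
  w <- c(h / 2, 0) + c(0, h / 2)
  # kernel: potential at electrode i from unit CSD slab at fine point m
  Kmat <- outer(depths, fine, function(zi, zs) disc_potential_kernel(zi - zs, R, sigma))
  # cardinal spline basis evaluated on the fine grid
  B <- vapply(seq_len(n), function(j) {
    e <- numeric(n); e[j] <- 1
    stats::spline(depths, e, xout = fine, method = "natural")$y
  }, numeric(length(fine)))
  Kmat %*% (B * w)
}

#' Forward-model potentials from a CSD depth profile
#'
#' Pushes per-depth CSD amplitudes through the disc-source forward model
#' Phi = F . C, with F from [csd_forward_matrix()]. This is the exact matrix
#' inverted by [compute_icsd()], so the two form a round trip on the spline
#' span.
#'
#' @param csd_amplitudes Numeric vector (one value per depth) or matrix
#'   (depth x time) of CSD values.
#' @param spacing Electrode spacing in µm (default 150).
#' @param R Disc radius in µm (default 500).
#' @param sigma Conductivity in S/m (default 0.4).
#' @return Potentials with the same shape as `csd_amplitudes`.
#' @export
forward_potentials <- function(csd_amplitudes, spacing = 150, R = 500, sigma = 0.4) {
  x <- as.matrix(csd_amplitudes)
  if (!all(is.finite(x))) stop("non-finite CSD input")
  n <- nrow(x)
  Fm <- csd_forward_matrix(seq(0, by = spacing, length.out = n), R, sigma)
  out <- Fm %*% x
  if (is.vector(csd_amplitudes)) drop(out) else out
}
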