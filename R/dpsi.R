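# dPSI: difference in inclusion between two groups on a discrete grid.
#
# With per-group PSI densities P1, P2 on a shared B-bin grid, the
# independence distribution of dPSI = Psi2 - Psi1 lives on the 2B-1 grid of
# bin-index differences; the posterior multiplies it by a three-component
# mixture prior (spike at 0, broader centered component, uniform slab) and
# renormalizes.

#' dPSI grid
#' @param B number of PSI bins; the dPSI grid has `2B - 1` points with
#'   centers `(-(B-1)..(B-1))/B`.
#' @return list with `centers` and bin `width`.
#' @export
dpsi_grid <- function(B = 40L) {
  list(B = B, centers = seq(-(B - 1), B - 1) / B, width = 1 / B)
}

#' Independence distribution of dPSI
#'
#' Discrete cross-correlation of two PSI densities:
#' `P_ind(d) = sum_{j - i = d} P1(i) P2(j)`.
#'
#' @param p1,p2 PSI densities on the same B-bin grid (sum to 1).
#' @return density over the `2B - 1` dPSI bins (sums to 1).
#' @export
dpsi_independent <- function(p1, p2) {
  B <- length(p1)
  if (length(p2) != B) stop("PSI densities must share the same grid")
  out <- numeric(2 * B - 1)
  for (d in seq(-(B - 1), B - 1)) {
    i <- max(1, 1 - d):min(B, B - d)
    out[d + B] <- sum(p1[i] * p2[i + d])
  }
  out / sum(out)
}

#' Three-component mixture prior on dPSI
#'
#' A spike concentrated near 0, a broader centered component, and a uniform
#' slab, discretized on the dPSI grid.  Shapes are Beta distributions of
#' `(dPSI + 1)/2` with equal shape parameters, hence symmetric about 0.
#'
#' @param weights mixture weights `(spike, center, slab)`, summing to 1.
#' @param spike_shape Beta shape of the spike (default 5000: about 95% of the
#'   spike mass within |dPSI| < 0.02).
#' @param center_shape Beta shape of the centered component (default 50:
#'   about 95% within |dPSI| < 0.20).
#' @param B number of PSI bins.
#' @return object of class `dpsi_prior`: density on the dPSI grid plus the
#'   parameters used.
#' @export
dpsi_prior <- function(weights = c(spike = 0.25, center = 0.50, slab = 0.25),
                       spike_shape = 5000, center_shape = 50, B = 40L) {
  stopifnot(length(weights) == 3, all(weights >= 0),
            abs(sum(weights) - 1) < 1e-9)
  grid <- dpsi_grid(B)
  comp <- function(a) {
    d <- stats::dbeta((grid$centers + 1) / 2, a, a) / 2
    d / sum(d)
  }
  dens <- weights[1] * comp(spike_shape) + weights[2] * comp(center_shape) +
    weights[3] * rep(1 / length(grid$centers), length(grid$centers))
  structure(list(density = dens / sum(dens), grid = grid, weights = weights,
                 spike_shape = spike_shape, center_shape = center_shape),
            class = "dpsi_prior")
}

#' Uniform prior on dPSI (identity for the posterior update)
#' @param B number of PSI bins.
#' @return a `dpsi_prior` with uniform density.
#' @export
dpsi_prior_uniform <- function(B = 40L) {
  grid <- dpsi_grid(B)
  n <- length(grid$centers)
  structure(list(density = rep(1 / n, n), grid = grid,
                 weights = c(spike = 0, center = 0, slab = 1),
                 spike_shape = NA, center_shape = NA),
            class = "dpsi_prior")
}

#' dPSI posterior
#'
#' Pointwise product of the independence distribution and the prior,
#' renormalized; reports the posterior mean and the confidence
#' `P(|dPSI| > C)` for any threshold C.
#'
#' @param p_ind density from [dpsi_independent()].
#' @param prior a `dpsi_prior` on the same grid.
#' @return object of class `dpsi_posterior` with `density`, `centers`,
#'   `e_dpsi`.
#' @export
dpsi_posterior <- function(p_ind, prior) {
  if (length(p_ind) != length(prior$density))
    stop("dPSI grids do not match")
  dens <- p_ind * prior$density
  s <- sum(dens)
  if (s <= 0) stop("degenerate prior/data: posterior has zero mass")
  dens <- dens / s
  structure(list(density = dens, centers = prior$grid$centers,
                 width = prior$grid$width,
                 e_dpsi = sum(dens * prior$grid$centers)),
            class = "dpsi_posterior")
}

#' Posterior probability of a change exceeding C
#' @param post a `dpsi_posterior`.
#' @param C change threshold in \[0, 1).
#' @return `P(|dPSI| > C)`.
#' @export
prob_change <- function(post, C = 0.2) {
  stopifnot(inherits(post, "dpsi_posterior"))
  sum(post$density[abs(post$centers) > C + 1e-12])
}

#' @export
print.dpsi_posterior <- function(x, ...) {
  cat(sprintf("dPSI posterior: E[dPSI] = %.4f, P(|dPSI|>0.2) = %.4f\n",
              x$e_dpsi, prob_change(x, 0.2)))
  invisible(x)
}
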