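# Inversion of measured network observables onto the model's parameter
# space: parametric (c2 -> (<k>, N_g/N)) curves at fixed c1, nearest-curve
# matching, and regime classification against the critical line.

#' Default rate grids for curve construction and phase diagrams
#'
#' `c1`: 7 log-spaced values over `[1e-2, 1e1]`; `c2`: 25 log-spaced values
#' over `[1e-5, 1e-1]`. The `c2` span brackets the percolation transition
#' at the default system size (`L = 1000` the interior `<s>` maximum sits
#' near `c2 ~ 1e-4..1e-3` across this `c1` range). They are configuration,
#' not results.
#'
#' @return list with elements `c1` and `c2`.
#' @export
default_rate_grids <- function() {
  list(c1 = 10^seq(-2, 1, length.out = 7),
       c2 = 10^seq(-5, -1, length.out = 25))
}

#' Parametric observable curves at fixed c1
#'
#' For every `c1` in the grid, runs the model along the `c2` grid and
#' records `(<k>, N_g/N)` so that observations can be matched back to model
#' coordinates. Curve points closer to each other than `tol` in z-scored
#' observable space (an injectivity failure, which would make the inversion
#' ambiguous) trigger a warning naming the colliding cells.
#'
#' @param c1_grid,c2_grid rate grids (>= 3 points each).
#' @param params template `ff_params`.
#' @param tol injectivity tolerance in z-scored observable distance.
#' @return `phase_diagram` data.frame with class `param_curves` prepended.
#' @export
build_curves <- function(c1_grid, c2_grid, params, tol = 1e-3) {
  diagram <- phase_diagram(c1_grid, c2_grid, params)
  zk <- as.vector(scale(diagram$mean_k))
  zg <- as.vector(scale(diagram$ng_over_n))
  n <- nrow(diagram)
  if (n <= 2000L) {     # quadratic check only at desk scale
    d2 <- outer(zk, zk, `-`)^2 + outer(zg, zg, `-`)^2
    diag(d2) <- Inf
    coll <- which(d2 < tol^2, arr.ind = TRUE)
    coll <- coll[coll[, 1L] < coll[, 2L], , drop = FALSE]
    if (nrow(coll) > 0L) {
      i <- coll[1L, 1L]; j <- coll[1L, 2L]
      warning(sprintf(
        "curves are not injective at tolerance %g: (c1=%.4g, c2=%.4g) and (c1=%.4g, c2=%.4g) coincide (%d colliding pairs)",
        tol, diagram$c1[i], diagram$c2[i], diagram$c1[j], diagram$c2[j],
        nrow(coll)))
    }
  }
  class(diagram) <- c("param_curves", class(diagram))
  diagram
}

#' Match observed (mean degree, giant fraction) to model coordinates
#'
#' Finds the nearest curve point under Euclidean distance in z-scored
#' observable space (each axis standardized over all curve points, so the
#' `[1,3]` range of `<k>` does not dominate the `(0,1]` range of `N_g/N`),
#' then interpolates `c2` linearly between the winning point and its better
#' neighbour along the winning `c1` curve.
#'
#' @param obs_k observed mean degree in `[1, 3]`.
#' @param obs_ng observed giant-cluster fraction in `(0, 1]`.
#' @param curves a `param_curves` object.
#' @param reject_dist z-scored distance above which the observation is
#'   declared out of model range.
#' @param weights relative weights of the (degree, giant-fraction) axes
#'   after standardization. The default weighs both equally, appropriate
#'   for model-side observables; when the degree estimate carries a known
#'   bias (image skeletons inflate pixel degree through rasterization
#'   crossings) the degree axis should be down-weighted.
#' @return list of class `match_result`: `c1_hat`, `c2_hat`, `distance`,
#'   `out_of_range`.
#' @export
match_parameters <- function(obs_k, obs_ng, curves, reject_dist = 1.0,
                             weights = c(1, 1)) {
  stopifnot(nrow(curves) > 0L, obs_k >= 1, obs_k <= 3, obs_ng > 0, obs_ng <= 1,
            length(weights) == 2L, all(weights >= 0), any(weights > 0))
  mu_k <- mean(curves$mean_k); s_k <- sd(curves$mean_k)
  mu_g <- mean(curves$ng_over_n); s_g <- sd(curves$ng_over_n)
  zk <- weights[1L] * (curves$mean_k - mu_k) / s_k
  zg <- weights[2L] * (curves$ng_over_n - mu_g) / s_g
  ok <- weights[1L] * (obs_k - mu_k) / s_k
  og <- weights[2L] * (obs_ng - mu_g) / s_g
  d <- sqrt((zk - ok)^2 + (zg - og)^2)
  i <- which.min(d)
  c1_hat <- curves$c1[i]

  # interpolate c2 between the winner and its nearer neighbour on the curve
  on_curve <- which(curves$c1 == c1_hat)
  on_curve <- on_curve[order(curves$c2[on_curve])]
  j <- match(i, on_curve)
  cands <- c(j - 1L, j + 1L)
  cands <- cands[cands >= 1L & cands <= length(on_curve)]
  c2_hat <- curves$c2[i]
  dist_best <- d[i]
  if (length(cands)) {
    jn <- cands[which.min(d[on_curve[cands]])]
    k2 <- on_curve[jn]
    # orthogonal projection of the observation on the segment i -> k2
    v <- c(zk[k2] - zk[i], zg[k2] - zg[i])
    wv <- c(ok - zk[i], og - zg[i])
    t <- sum(v * wv) / sum(v * v)
    t <- min(max(t, 0), 1)
    if (is.finite(t)) {
      lc2 <- (1 - t) * log(curves$c2[i]) + t * log(curves$c2[k2])
      c2_hat <- exp(lc2)
      dist_best <- sqrt(sum((wv - t * v)^2))
    }
  }
  structure(
    list(c1_hat = c1_hat, c2_hat = c2_hat, distance = dist_best,
         out_of_range = dist_best > reject_dist),
    class = "match_result")
}

#' Classify the percolation regime of a matched network
#'
#' Compares the matched `c2_hat` to the critical `c2*(c1_hat)` interpolated
#' from the critical line: within `band` log10 units the network is
#' `"critical"`, below it `"subcritical"`, above it `"supercritical"`. The
#' band width is a reporting convention comparable to the grid spacing.
#'
#' @param match a `match_result`.
#' @param critline a `critical_line`.
#' @param band half-width of the critical band in log10 units.
#' @return one of `"subcritical"`, `"critical"`, `"supercritical"`,
#'   `"unclassified"` (c1 outside the critical line's support).
#' @export
classify_regime <- function(match, critline, band = 0.25) {
  c2s <- critical_c2(critline, match$c1_hat)
  if (is.na(c2s)) return("unclassified")
  dl <- log10(match$c2_hat / c2s)
  if (abs(dl) <= band) "critical" else if (dl < 0) "subcritical" else "supercritical"
}
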