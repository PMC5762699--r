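# Distributional and complexity statistics of skeleton networks: cluster-mass
# CCDFs and their collapse onto a common power law, mass entropy and the
# critical binarization threshold, finite-size scaling of the giant cluster,
# box-counting fractal dimension, and the Lempel-Ziv complexity z-score
# against randomized skeletons.

#' Complementary cumulative distribution of cluster masses
#'
#' `P(s)` is the fraction of clusters whose mass is at least `s`, evaluated
#' at every distinct observed mass, so `P` is non-increasing with
#' `P(min mass) = 1`. The per-mass probability `p(s)` and the mean mass
#' `<s>` are carried along.
#'
#' @param masses vector of positive integer cluster masses.
#' @return data.frame of class `mass_distribution` with columns `mass`,
#'   `pdf`, `ccdf`; attribute `mean_mass`.
#' @export
ccdf <- function(masses) {
  if (length(masses) == 0L) stop("ccdf: no masses")
  stopifnot(all(masses >= 1))
  tab <- table(masses)
  s <- as.numeric(names(tab))
  p <- as.numeric(tab) / length(masses)
  out <- data.frame(mass = s, pdf = p, ccdf = rev(cumsum(rev(p))))
  attr(out, "mean_mass") <- mean(masses)
  class(out) <- c("mass_distribution", class(out))
  out
}

#' Collapse mass distributions and fit the power-law exponent
#'
#' Each distribution's support is rescaled by its mean mass `<s>`; the
#' rescaled points are pooled and the tail exponent is obtained by least
#' squares on `log P` versus `log(s/<s>)` restricted to `fit_range`. For a
#' CCDF decaying as `P(s) ~ s^(1 - gamma)` the fitted slope is `1 - gamma`,
#' so `gamma = 1 - slope`.
#'
#' @param distributions a `mass_distribution` or list of them.
#' @param fit_range range of normalized mass `s/<s>` used for the fit.
#' @return list of class `exponent_fit`: `gamma`, `slope`, `r_squared`,
#'   `n_points`, `fit_range`.
#' @export
collapse_and_fit_exponent <- function(distributions, fit_range = c(0.05, 5)) {
  if (inherits(distributions, "mass_distribution"))
    distributions <- list(distributions)
  if (length(distributions) == 0L) stop("no distributions supplied")
  x <- numeric(0); y <- numeric(0)
  for (d in distributions) {
    ms <- attr(d, "mean_mass")
    x <- c(x, d$mass / ms)
    y <- c(y, d$ccdf)
  }
  keep <- x >= fit_range[1] & x <= fit_range[2] & y > 0
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 5L)
    stop("fewer than 5 pooled support points in the fit range")
  fit <- lm(log(y) ~ log(x))
  slope <- unname(coef(fit)[2L])
  structure(
    list(gamma = 1 - slope,
         slope = slope,
         r_squared = summary(fit)$r.squared,
         n_points = length(x),
         fit_range = fit_range),
    class = "exponent_fit")
}

#' Shannon entropy of the cluster-mass partition
#'
#' Clusters are grouped by distinct mass `i`; `p_i` is the fraction of all
#' skeleton pixels that belong to clusters of mass `i`, and
#' `H = -sum p_i log(p_i)` (natural log). H is zero when all mass sits in a
#' single mass class and maximal when total mass is split evenly across
#' classes.
#'
#' @param masses vector of positive cluster masses.
#' @return non-negative entropy value.
#' @export
mass_entropy <- function(masses) {
  if (length(masses) == 0L) stop("mass_entropy: no masses")
  tot <- tapply(masses, masses, sum)   # pixels per mass class
  p <- as.numeric(tot) / sum(masses)
  -sum(p * log(p))
}

#' Critical threshold of a threshold profile
#'
#' The threshold at which the cluster-mass entropy `H` (method
#' `"entropy_max"`) or the cluster count `N_c` (method `"nc_max"`) attains
#' its global maximum; ties and plateaus resolve to the lowest threshold.
#' If the maximum sits on the boundary of the sweep the result carries
#' attribute `interior_peak = FALSE`.
#'
#' @param profile a `threshold_profile` from [threshold_sweep()].
#' @param method `"entropy_max"` (default) or `"nc_max"`.
#' @return critical threshold `th*` with attribute `interior_peak`.
#' @export
critical_threshold <- function(profile, method = c("entropy_max", "nc_max")) {
  method <- match.arg(method)
  col <- if (method == "entropy_max") "entropy" else "n_c"
  ok <- !is.na(profile[[col]])
  if (sum(ok) < 3L) stop("critical_threshold: fewer than 3 usable thresholds")
  th <- profile$th[ok]
  v <- profile[[col]][ok]
  i <- which.max(v)   # first index at ties -> lower th
  structure(th[i], interior_peak = (i > 1L && i < length(v)))
}

#' Finite-size scaling of the giant-cluster fraction
#'
#' Samples square subwindows of geometrically increasing area, averages
#' `N_g/N` of the clusters restricted to each window over random placements,
#' and fits the scaling slope of `log(N_g/N)` against `log(area)`. A network
#' dominated by one spanning cluster gives slope near 0; scattered
#' unit-mass clusters give slope near -1.
#'
#' @param skel logical skeleton matrix.
#' @param n_scales number of window sizes (>= 3), halving from the full frame.
#' @param n_placements random placements per window size.
#' @param seed integer seed for placements.
#' @return list of class `scaling_result`: `areas`, `ng_over_n`,
#'   `scaling_slope`, `n_skipped` (empty windows).
#' @export
finite_size_scaling <- function(skel, n_scales = 5L, n_placements = 20L,
                                seed = 1L) {
  stopifnot(is.matrix(skel), is.logical(skel))
  if (!any(skel)) stop("finite_size_scaling: empty skeleton")
  if (n_scales < 3L) stop("need at least 3 scales")
  side0 <- min(dim(skel))
  sides <- pmax(4L, as.integer(round(side0 / 2^(seq_len(n_scales) - 1L))))
  sides <- unique(sides)
  vals <- numeric(0); areas <- numeric(0); n_skipped <- 0L
  withr::with_seed(seed, {
    for (s in sides) {
      acc <- numeric(0)
      for (p in seq_len(n_placements)) {
        r0 <- if (nrow(skel) > s) sample.int(nrow(skel) - s, 1L) else 0L
        c0 <- if (ncol(skel) > s) sample.int(ncol(skel) - s, 1L) else 0L
        win <- skel[(r0 + 1L):(r0 + s), (c0 + 1L):(c0 + s), drop = FALSE]
        if (!any(win)) { n_skipped <- n_skipped + 1L; next }
        cl <- label_clusters(win)
        acc <- c(acc, cl$giant_mass / cl$n_pixels)
      }
      if (length(acc)) {
        vals <- c(vals, mean(acc))
        areas <- c(areas, as.numeric(s)^2)
      }
    }
  })
  if (length(areas) < 3L) stop("too few non-empty window scales")
  fit <- lm(log(vals) ~ log(areas))
  structure(
    list(areas = areas, ng_over_n = vals,
         scaling_slope = unname(coef(fit)[2L]),
         n_skipped = n_skipped),
    class = "scaling_result")
}

#' Box-counting fractal dimension of a skeleton
#'
#' Counts occupied boxes at dyadic box sizes `eps = 1, 2, 4, ...` and fits
#' `-slope` of `log N(eps)` versus `log eps`. The pattern is first cropped
#' to its occupied bounding box, anchoring the box grid to the pattern so
#' the estimate is exactly translation invariant. Scales with fewer than 4
#' occupied boxes or with `eps` above half the bounding box are excluded
#' from the fit to avoid the saturation plateau.
#'
#' @param skel logical matrix with at least 2 occupied pixels.
#' @return fractal dimension, with attributes `eps` and `counts`.
#' @export
fractal_dimension <- function(skel) {
  stopifnot(is.matrix(skel), is.logical(skel))
  occ <- which(skel, arr.ind = TRUE)
  if (nrow(occ) < 2L) stop("fractal_dimension: need at least 2 occupied pixels")
  ri <- occ[, 1L] - min(occ[, 1L])   # crop to bounding box
  ci <- occ[, 2L] - min(occ[, 2L])
  ext <- max(max(ri), max(ci)) + 1L
  eps <- 2^(0:floor(log2(ext)))
  counts <- vapply(eps, function(e) {
    b <- (ri %/% e) * (max(ci) %/% e + 1) + (ci %/% e)
    length(unique(b))
  }, numeric(1))
  keep <- counts >= 4 & eps <= ext / 2
  if (sum(keep) < 2L) stop("fractal_dimension: degenerate box-count range")
  fit <- lm(log(counts[keep]) ~ log(eps[keep]))
  structure(-unname(coef(fit)[2L]), eps = eps, counts = counts)
}

#' Lempel-Ziv complexity z-score against randomized skeletons
#'
#' The skeleton is flattened row-major into a binary sequence and its
#' Lempel-Ziv (1976) production complexity `K` is computed. The null
#' ensemble redistributes the occupied pixels uniformly over the frame
#' (occupancy count preserved); with mean `mu_R` and standard deviation
#' `sigma_R` of the null complexities, the normalized complexity is
#' `z = (K - mu_R) / sigma_R`. Setting `eq3_literal = TRUE` divides by the
#' variance `sigma_R^2` instead.
#'
#' @param skel logical skeleton matrix.
#' @param n_rand number of randomized versions (>= 2; 1000 for final runs).
#' @param seed integer seed for the null ensemble.
#' @param eq3_literal divide by variance instead of standard deviation.
#' @return list of class `complexity_result`: `K`, `mu_R`, `sigma_R`, `z`,
#'   `n_randomizations`, `degenerate` (`TRUE` when `sigma_R == 0`).
#' @export
complexity_zscore <- function(skel, n_rand = 1000L, seed = 1L,
                              eq3_literal = FALSE) {
  stopifnot(is.matrix(skel), is.logical(skel))
  if (!any(skel)) stop("complexity_zscore: empty skeleton")
  if (n_rand < 2L) stop("need at least 2 randomizations")
  n <- length(skel)
  n_occ <- sum(skel)
  seq0 <- as.integer(t(skel))   # row-major flattening
  K <- lz76_cpp(seq0)
  Kr <- numeric(n_rand)
  withr::with_seed(seed, {
    for (i in seq_len(n_rand)) {
      r <- integer(n)
      r[sample.int(n, n_occ)] <- 1L
      Kr[i] <- lz76_cpp(r)
    }
  })
  mu <- mean(Kr); sdev <- sd(Kr)
  degenerate <- sdev == 0
  denom <- if (eq3_literal) sdev^2 else sdev
  structure(
    list(K = K, mu_R = mu, sigma_R = sdev,
         z = if (degenerate) NA_real_ else (K - mu) / denom,
         n_randomizations = n_rand,
         degenerate = degenerate),
    class = "complexity_result")
}
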