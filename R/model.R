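# Agent-based fission/fusion kinetics: parameter container, propensities,
# Gillespie replicates, steady-state observables, phase diagram and its
# critical line.

#' Parameters of the fission/fusion model
#'
#' A population of `L` dimers whose tips merge into nodes of degree at most
#' three. Tip-to-tip fusion/fission carry rates `a1`/`b1` and tip-to-side
#' fusion/fission `a2`/`b2`; the model is controlled through the relative
#' rates `c1 = a1/b1` and `c2 = a2/b2` with `b1 = 1` defining the time unit
#' and `b2 = (3/2) b1`. A run executes `n_events` reactions (default `3L`,
#' enough for the degree populations to become stationary) and is repeated
#' `n_reps` times with independent random streams.
#'
#' @param L number of dimers (edges), >= 1.
#' @param c1 relative tip-to-tip fusion rate `a1/b1` (>= 0).
#' @param c2 relative tip-to-side fusion rate `a2/b2` (>= 0).
#' @param b1 tip-to-tip fission rate (time unit).
#' @param b2 tip-to-side fission rate; defaults to `1.5 * b1`.
#' @param n_events Gillespie reactions per replicate; default `3 * L`.
#' @param n_reps replicates; default 100.
#' @param seed integer master seed.
#' @return list of class `ff_params`.
#' @export
model_params <- function(L, c1, c2, b1 = 1, b2 = 1.5 * b1,
                         n_events = 3L * L, n_reps = 100L, seed = 1L) {
  stopifnot(L >= 1, c1 >= 0, c2 >= 0, b1 >= 0, b2 >= 0,
            n_events >= 1, n_reps >= 1)
  structure(list(L = as.integer(L), c1 = c1, c2 = c2, b1 = b1, b2 = b2,
                 n_events = as.integer(n_events), n_reps = as.integer(n_reps),
                 seed = as.integer(seed)),
            class = "ff_params")
}

#' Reaction propensities from degree populations
#'
#' Mass-action forms with `a_i = c_i * b_i`:
#' `A1 = a1 n1 (n1 - 1) / 2` (tip-to-tip fusion over unordered pairs),
#' `B1 = b1 n2`, `A2 = a2 n1 n2`, `B2 = b2 n3`.
#'
#' @param n1,n2,n3 counts of degree-1, -2 and -3 nodes.
#' @param params an `ff_params` object.
#' @return named numeric vector `c(A1, B1, A2, B2)`.
#' @export
propensities <- function(n1, n2, n3, params) {
  a1 <- params$c1 * params$b1
  a2 <- params$c2 * params$b2
  c(A1 = a1 * n1 * (n1 - 1) / 2,
    B1 = params$b1 * n2,
    A2 = a2 * n1 * n2,
    B2 = params$b2 * n3)
}

#' Run one replicate of the fission/fusion dynamics
#'
#' Starts from `L` disconnected dimers (`2L` degree-1 nodes), executes
#' `n_events` Gillespie reactions and measures the final network: degree
#' populations, connected components of the node graph (sizes in nodes),
#' mean degree, giant-cluster fraction and mean cluster size excluding the
#' giant. If every channel's propensity vanishes before `n_events` the state
#' is absorbing; the run stops there and is flagged.
#'
#' @param params an `ff_params` object.
#' @param record_trace record `(n1, n2, n3)` after every event.
#' @param return_edges return the dimer edge list (node ids) of the final
#'   network, for embedding or export.
#' @param seed seed for this replicate; defaults to `params$seed`.
#' @return list with the final-state observables (see above).
#' @export
simulate_fission_fusion <- function(params, record_trace = FALSE,
                                    return_edges = FALSE,
                                    seed = params$seed) {
  withr::with_seed(seed,
    simulate_ff_cpp(params$L, params$c1, params$c2, params$b1, params$b2,
                    params$n_events, record_trace, return_edges))
}

#' Steady-state observables averaged over replicates
#'
#' Repeats [simulate_fission_fusion()] `n_reps` times with sub-seeds split
#' from the master seed and one measurement at the end of each replicate,
#' returning across-replicate means and standard deviations of the mean
#' degree `<k>`, the giant fraction `<N_g/N>` and the mean cluster size
#' excluding the giant `<s>`.
#'
#' @param params an `ff_params` object.
#' @return list of class `ff_observables` with `mean_k`, `ng_over_n`,
#'   `mean_s`, their `sd_*` counterparts, `n_reps`, `n_absorbed`.
#' @export
run_model <- function(params) {
  k <- ng <- s <- numeric(params$n_reps)
  absorbed <- logical(params$n_reps)
  for (r in seq_len(params$n_reps)) {
    res <- simulate_fission_fusion(params, seed = split_seed(params$seed, r))
    k[r] <- res$mean_k
    ng[r] <- res$ng_over_n
    s[r] <- res$mean_s_excl_giant
    absorbed[r] <- res$absorbed
  }
  structure(
    list(mean_k = mean(k), sd_k = sd(k),
         ng_over_n = mean(ng), sd_ng = sd(ng),
         mean_s = mean(s, na.rm = TRUE), sd_s = sd(s, na.rm = TRUE),
         n_reps = params$n_reps, n_absorbed = sum(absorbed)),
    class = "ff_observables")
}

#' Phase diagram over a grid of relative rates
#'
#' Runs [run_model()] on every `(c1, c2)` grid cell with a cell-specific
#' sub-seed, returning one row per cell in long format.
#'
#' @param c1_grid,c2_grid rate grids (each >= 3 points for the critical
#'   line to be extractable).
#' @param params template `ff_params`; its `c1`/`c2` are overridden cell by
#'   cell.
#' @return data.frame of class `phase_diagram` with columns `c1`, `c2`,
#'   `mean_k`, `sd_k`, `ng_over_n`, `sd_ng`, `mean_s`, `sd_s`.
#' @export
phase_diagram <- function(c1_grid, c2_grid, params) {
  stopifnot(length(c1_grid) >= 3L, length(c2_grid) >= 3L)
  grid <- expand.grid(c2 = sort(c2_grid), c1 = sort(c1_grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- params
    p$c1 <- grid$c1[i]
    p$seed <- split_seed(params$seed, cell_stream(grid$c1[i], grid$c2[i]))
    p$c2 <- grid$c2[i]
    obs <- run_model(p)
    rows[[i]] <- data.frame(c1 = p$c1, c2 = p$c2,
                            mean_k = obs$mean_k, sd_k = obs$sd_k,
                            ng_over_n = obs$ng_over_n, sd_ng = obs$sd_ng,
                            mean_s = obs$mean_s, sd_s = obs$sd_s)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("phase_diagram", class(out))
  out
}

# deterministic stream id for a grid cell, independent of sweep order
cell_stream <- function(c1, c2) {
  h <- sum(utf8ToInt(sprintf("%.10g_%.10g", c1, c2)) *
             seq_len(nchar(sprintf("%.10g_%.10g", c1, c2))))
  h %% 100000L
}

#' Critical line of the phase diagram
#'
#' For each `c1`, locates the interior maximum of the mean cluster size
#' `<s>` (excluding the giant) along the `c2` grid — the percolation
#' signature — and refines it by a quadratic fit in `log(c2)` through the
#' maximum and its two neighbours. A reference curve `c2* = alpha * c1^beta`
#' is fitted to the refined points by least squares on logs. `c1` values
#' whose `<s>` maximum sits on the grid boundary are omitted.
#'
#' @param diagram a `phase_diagram`.
#' @return data.frame of class `critical_line` with columns `c1`, `c2_star`;
#'   attributes `alpha`, `beta`, `omitted` (boundary-max `c1` values).
#' @export
critical_line <- function(diagram) {
  out <- list(); omitted <- numeric(0)
  for (c1v in sort(unique(diagram$c1))) {
    d <- diagram[diagram$c1 == c1v, ]
    d <- d[order(d$c2), ]
    ok <- is.finite(d$mean_s)
    d <- d[ok, ]
    if (nrow(d) < 3L) { omitted <- c(omitted, c1v); next }
    i <- which.max(d$mean_s)
    if (i == 1L || i == nrow(d)) { omitted <- c(omitted, c1v); next }
    lx <- log(d$c2[(i - 1L):(i + 1L)])
    ly <- d$mean_s[(i - 1L):(i + 1L)]
    qf <- lm(ly ~ lx + I(lx^2))
    b <- coef(qf)
    x_star <- if (is.finite(b[3L]) && b[3L] < 0) -b[2L] / (2 * b[3L]) else lx[2L]
    # keep the refinement inside the bracketing interval
    x_star <- min(max(x_star, lx[1L]), lx[3L])
    out[[length(out) + 1L]] <- data.frame(c1 = c1v, c2_star = exp(x_star))
  }
  if (!length(out)) stop("no interior <s> maximum on any c1 slice")
  res <- do.call(rbind, out)
  fit <- if (nrow(res) >= 2L) lm(log(res$c2_star) ~ log(res$c1)) else NULL
  attr(res, "alpha") <- if (!is.null(fit)) exp(unname(coef(fit)[1L])) else NA
  attr(res, "beta") <- if (!is.null(fit)) unname(coef(fit)[2L]) else NA
  attr(res, "omitted") <- omitted
  class(res) <- c("critical_line", class(res))
  res
}

#' Interpolate the critical line at a given c1
#'
#' Log-log linear interpolation between tabulated `(c1, c2*)` points.
#'
#' @param critline a `critical_line`.
#' @param c1 query value; must lie within the tabulated `c1` range.
#' @return interpolated `c2*`, or `NA` outside the support.
#' @export
critical_c2 <- function(critline, c1) {
  if (c1 < min(critline$c1) || c1 > max(critline$c1)) return(NA_real_)
  exp(stats::approx(log(critline$c1), log(critline$c2_star), xout = log(c1))$y)
}
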