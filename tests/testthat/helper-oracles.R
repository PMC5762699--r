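# Independent brute-force oracles used to cross-check the implementation.

# recursive-free flood fill over 8-neighbourhoods; returns sorted cluster
# masses of a logical matrix
flood_fill_masses <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  seen <- matrix(FALSE, nr, nc)
  masses <- integer(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!m[r, c] || seen[r, c]) next
    size <- 0L
    stack <- list(c(r, c)); seen[r, c] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            m[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
    masses <- c(masses, size)
  }
  sort(masses)
}

# direct-counting CCDF oracle: fraction of masses >= s for each distinct s
ccdf_by_counting <- function(masses) {
  s <- sort(unique(masses))
  vapply(s, function(x) mean(masses >= x), numeric(1))
}

# entropy of the mass partition evaluated directly from its definition
entropy_by_definition <- function(masses) {
  h <- 0
  for (i in unique(masses)) {
    p <- sum(masses[masses == i]) / sum(masses)
    h <- h - p * log(p)
  }
  h
}

# number of 8-connected components (via the package-independent flood fill)
n_components8 <- function(m) length(flood_fill_masses(m))

# exact stationary distribution of the embedded jump chain of the
# tip-to-tip-only dynamics for L = 2 (states indexed by the number of
# degree-2 nodes, n2 = 0, 1, 2), from the mass-action propensities
jump_chain_stationary_L2 <- function(c1, b1 = 1) {
  a1 <- c1 * b1
  rate_up <- function(n2) { n1 <- 4 - 2 * n2; a1 * n1 * (n1 - 1) / 2 }
  rate_dn <- function(n2) b1 * n2
  P <- matrix(0, 3, 3)
  for (n2 in 0:2) {
    up <- rate_up(n2); dn <- rate_dn(n2); tot <- up + dn
    if (n2 < 2) P[n2 + 1, n2 + 2] <- up / tot
    if (n2 > 0) P[n2 + 1, n2] <- dn / tot
  }
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

# draw n cluster masses from p(s) proportional to s^(-gamma) on 1..smax
sample_power_law <- function(n, gamma, smax) {
  p <- (1:smax)^(-gamma)
  sample.int(smax, n, replace = TRUE, prob = p / sum(p))
}
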