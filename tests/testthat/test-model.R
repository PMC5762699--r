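test_that("propensities take the mass-action forms", {
  p <- model_params(L = 10, c1 = 2, c2 = 3, b1 = 1, b2 = 1.5)
  expect_equal(propensities(4, 1, 0, p),
               c(A1 = 12, B1 = 1, A2 = 18, B2 = 0))
  # fresh dimers: no fission channels, no tip-to-side fusion
  expect_equal(unname(propensities(2 * p$L, 0, 0, p)[2:4]), c(0, 0, 0))
  # no free tips: both fusion channels closed
  expect_equal(unname(propensities(0, 5, 2, p)[c(1, 3)]), c(0, 0))
  expect_equal(p$b2, 1.5 * p$b1)
})

test_that("the initial state is L disjoint dimers", {
  r1 <- mitonet:::simulate_ff_cpp(1L, 1, 1, 1, 1.5, 0L)
  expect_equal(r1$n_nodes, 2L)
  expect_equal(r1$n_components, 1L)
  expect_equal(r1$mean_k, 1)

  r0 <- mitonet:::simulate_ff_cpp(15000L, 0.5, 0.01, 1, 1.5, 0L)
  expect_equal(r0$n1, 30000L)
  expect_equal(r0$n2 + r0$n3, 0L)
  expect_equal(r0$n1 + 2 * r0$n2 + 3 * r0$n3, 30000L)
})

test_that("tip conservation holds after every one of 1e5 mixed-rate events", {
  r <- simulate_fission_fusion(model_params(L = 1000, c1 = 0.5, c2 = 0.05,
                                            n_events = 1e5, n_reps = 1, seed = 3),
                               record_trace = TRUE)
  tr <- r$trace
  expect_true(all(tr[, 1] + 2 * tr[, 2] + 3 * tr[, 3] == 2000L))
  # node count changes by exactly +/- 1 per event
  n <- rowSums(tr)
  expect_true(all(abs(diff(n)) == 1L))
  # graph-side and count-side mean degree agree
  expect_equal(r$mean_k, (r$n1 + 2 * r$n2 + 3 * r$n3) / r$n_nodes)
  expect_equal(sum(r$cluster_sizes), r$n_nodes)
})

test_that("pure fusion and pure fission reach their limiting states", {
  # c1 = c2 = 0: nothing ever fuses; every component is one dimer
  r <- simulate_fission_fusion(model_params(L = 10, c1 = 0, c2 = 0, n_reps = 1))
  expect_true(r$absorbed)
  expect_equal(r$mean_k, 1)
  expect_equal(r$n_components, 10L)
  expect_equal(r$ng_over_n, 2 / 20)

  # with fission vastly dominating, the chain spends almost all its time
  # at or next to the all-dimer state (monotone drainage of fused nodes)
  pr <- model_params(L = 50, c1 = 1e-5, c2 = 1e-5, n_events = 2e4,
                     n_reps = 1, seed = 5)
  drained <- simulate_fission_fusion(pr, record_trace = TRUE)
  frac_fused <- mean(drained$trace[, 2] + drained$trace[, 3] > 1)
  expect_lt(frac_fused, 0.1)

  # saturating tip-to-tip fusion drives <k> to 2 (chains and rings)
  obs <- run_model(model_params(L = 1000, c1 = 1e4, c2 = 0, n_reps = 5, seed = 6))
  expect_lt(abs(obs$mean_k - 2), 0.05)
})

test_that("fixed seeds give bit-identical observables", {
  p <- model_params(L = 200, c1 = 1, c2 = 0.01, n_reps = 3, seed = 42)
  expect_identical(run_model(p), run_model(p))
  expect_identical(simulate_fission_fusion(p, return_edges = TRUE),
                   simulate_fission_fusion(p, return_edges = TRUE))
})

test_that("Gillespie occupancies match the exact L = 2 jump-chain solution", {
  # with c2 = 0 and L = 2 the state space is n2 in {0,1,2}; the exact
  # stationary distribution of the embedded chain is (1/4, 1/2, 1/4)
  pi_exact <- jump_chain_stationary_L2(c1 = 1)
  expect_equal(pi_exact, c(0.25, 0.5, 0.25), tolerance = 1e-12)

  r <- simulate_fission_fusion(model_params(L = 2, c1 = 1, c2 = 0,
                                            n_events = 1e5, n_reps = 1, seed = 7),
                               record_trace = TRUE)
  burn <- 1000
  n2 <- r$trace[-(1:burn), 2]
  obs <- tabulate(n2 + 1L, nbins = 3)
  n <- sum(obs)
  # visit frequencies within 3 Monte-Carlo standard errors
  for (s in 1:3) {
    se <- sqrt(pi_exact[s] * (1 - pi_exact[s]) / n)
    expect_lt(abs(obs[s] / n - pi_exact[s]), 3 * se + 1e-9)
  }
  chi2 <- sum((obs - n * pi_exact)^2 / (n * pi_exact))
  expect_lt(chi2, qchisq(0.99, df = 2))
})

test_that("the phase diagram is cell-independent and has the critical line", {
  p <- model_params(L = 300, c1 = 1, c2 = 1, n_reps = 5, seed = 8)
  c1g <- c(0.05, 0.1, 0.2)
  c2g <- 10^seq(-4, -1, length.out = 7)
  d1 <- phase_diagram(c1g, c2g, p)
  d2 <- phase_diagram(c1g, rev(c2g), p)       # shuffled sweep order
  expect_equal(d1, d2)
  expect_equal(nrow(d1), 21L)

  cl <- critical_line(d1)
  expect_true(all(cl$c2_star >= min(c2g) & cl$c2_star <= max(c2g)))
  expect_true(all(is.finite(cl$c2_star)))
})
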