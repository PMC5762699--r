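test_that("ccdf matches hand examples and the counting oracle", {
  d <- ccdf(c(1, 1, 2, 4))
  expect_equal(d$mass, c(1, 2, 4))
  expect_equal(d$ccdf, c(1, 0.5, 0.25))
  expect_equal(ccdf(5)$ccdf, 1)
  expect_error(ccdf(integer(0)), "no masses")

  set.seed(11)
  masses <- sample_power_law(1000, gamma = 2, smax = 1000)
  d <- ccdf(masses)
  expect_equal(d$ccdf, ccdf_by_counting(masses), tolerance = 1e-15)
  expect_equal(attr(d, "mean_mass"), mean(masses))
})

test_that("ccdf is non-increasing with P(min mass) = 1 on random inputs", {
  set.seed(12)
  for (i in 1:25) {
    masses <- sample.int(50, sample(1:200, 1), replace = TRUE)
    d <- ccdf(masses)
    expect_true(all(diff(d$ccdf) <= 0))
    expect_equal(d$ccdf[1], 1)
    expect_equal(sum(d$pdf), 1)
  }
})

test_that("collapsed-CCDF fit recovers known exponents", {
  # an exact power law P = x^(-1) has slope -1, hence gamma = 2
  exact <- data.frame(mass = 1:100, pdf = NA_real_, ccdf = (1:100)^(-1))
  attr(exact, "mean_mass") <- 1
  class(exact) <- c("mass_distribution", class(exact))
  fit <- collapse_and_fit_exponent(exact, fit_range = c(0.05, 100))
  expect_equal(fit$gamma, 2, tolerance = 0.01)

  # pooling two copies of the same distribution changes nothing
  fit2 <- collapse_and_fit_exponent(list(exact, exact), fit_range = c(0.05, 100))
  expect_equal(fit2$gamma, fit$gamma)

  # seeded samples from p(s) ~ s^-1.5
  set.seed(13)
  dists <- lapply(1:10, function(i) ccdf(sample_power_law(2000, 1.5, 1e4)))
  fit3 <- collapse_and_fit_exponent(dists)
  expect_lt(abs(fit3$gamma - 1.5), 0.15)

  expect_error(collapse_and_fit_exponent(ccdf(c(1, 2))), "5 pooled")
})

test_that("mass entropy follows its definition and is maximal at even split", {
  expect_equal(mass_entropy(c(2, 2)), 0)
  expect_equal(mass_entropy(c(1, 1, 2)), log(2))
  expect_equal(mass_entropy(c(1, 2, 3)),
               -sum(c(1, 2, 3) / 6 * log(c(1, 2, 3) / 6)))

  set.seed(14)
  for (i in 1:30) {
    masses <- sample.int(30, sample(2:50, 1), replace = TRUE)
    expect_equal(mass_entropy(masses), entropy_by_definition(masses),
                 tolerance = 1e-12)
  }

  # for k mass classes of equal total mass, H = log(k) is the maximum
  for (k in 2:4) {
    classes <- 1:k
    # class i repeated prod/i times, so every class carries equal total mass
    masses_even <- unlist(lapply(classes, function(i) rep(i, prod(classes) / i)))
    expect_equal(mass_entropy(masses_even), log(k), tolerance = 1e-12)
    masses_uneven <- unlist(lapply(classes, function(i) rep(i, i)))
    expect_lte(mass_entropy(masses_uneven), log(k))
  }
})

test_that("critical threshold picks the global maximum, ties to lower th", {
  prof <- data.frame(th = c(0.1, 0.2, 0.3), n_c = c(5L, 9L, 2L),
                     entropy = c(0.1, 0.9, 0.3))
  expect_equal(as.numeric(critical_threshold(prof)), 0.2)
  expect_equal(as.numeric(critical_threshold(prof, "nc_max")), 0.2)
  expect_true(attr(critical_threshold(prof), "interior_peak"))

  mono <- data.frame(th = c(0.1, 0.2, 0.3), n_c = 1:3,
                     entropy = c(0.9, 0.5, 0.1))
  expect_equal(as.numeric(critical_threshold(mono)), 0.1)
  expect_false(attr(critical_threshold(mono), "interior_peak"))

  tie <- data.frame(th = c(0.1, 0.2, 0.3), n_c = c(1L, 5L, 5L),
                    entropy = c(0.2, 0.8, 0.8))
  expect_equal(as.numeric(critical_threshold(tie)), 0.2)

  allna <- data.frame(th = 1:3 / 10, n_c = NA_integer_, entropy = NA_real_)
  expect_error(critical_threshold(allna), "usable")
})

test_that("finite-size scaling separates spanning from scattered patterns", {
  # one frame-spanning cluster: N_g/N = 1 at every scale, slope ~ 0
  grid <- matrix(FALSE, 128, 128)
  grid[seq(1, 128, by = 8), ] <- TRUE
  grid[, seq(1, 128, by = 8)] <- TRUE
  sc <- finite_size_scaling(grid, seed = 5)
  expect_equal(sc$ng_over_n, rep(1, length(sc$areas)))
  expect_lt(abs(sc$scaling_slope), 1e-9)

  # isolated unit clusters on a jittered sparse grid: N_g/N ~ 1/occupied,
  # so the slope against area is close to -1
  set.seed(6)
  sparse <- matrix(FALSE, 256, 256)
  centres <- expand.grid(r = seq(4, 252, by = 8), c = seq(4, 252, by = 8))
  keep <- runif(nrow(centres)) < 0.5
  sparse[as.matrix(centres[keep, ])] <- TRUE
  sc2 <- finite_size_scaling(sparse, n_scales = 5, n_placements = 40, seed = 7)
  expect_lt(abs(sc2$scaling_slope + 1), 0.15)

  expect_error(finite_size_scaling(matrix(FALSE, 8, 8)), "empty")
})

test_that("box-counting dimension is calibrated and translation invariant", {
  expect_equal(as.numeric(fractal_dimension(matrix(TRUE, 256, 256))), 2,
               tolerance = 0.05)
  line <- matrix(FALSE, 256, 256); line[100, ] <- TRUE
  expect_equal(as.numeric(fractal_dimension(line)), 1, tolerance = 0.05)
  sp <- make_fixture_skeleton("sierpinski")
  expect_equal(as.numeric(fractal_dimension(sp)), log(3) / log(2),
               tolerance = 0.05)

  big <- matrix(FALSE, 300, 300)
  big[1:256, 1:256] <- sp
  shifted <- matrix(FALSE, 300, 300)
  shifted[8:263, 12:267] <- sp
  expect_equal(as.numeric(fractal_dimension(big)),
               as.numeric(fractal_dimension(shifted)), tolerance = 1e-9)

  expect_error(fractal_dimension(matrix(FALSE, 4, 4)), "2 occupied")
})

test_that("complexity z-score behaves under the null and flags degeneracy", {
  # a skeleton that is itself a uniform scatter stays within |z| <= 3
  set.seed(8)
  scatter <- matrix(FALSE, 64, 64)
  scatter[sample.int(64 * 64, 400)] <- TRUE
  z <- complexity_zscore(scatter, n_rand = 200, seed = 9)
  expect_lt(abs(z$z), 3)
  expect_gt(z$sigma_R, 0)

  # a full frame is invariant under occupancy-preserving randomization:
  # sigma_R = 0 is flagged rather than producing a z
  full <- matrix(TRUE, 16, 16)
  zf <- complexity_zscore(full, n_rand = 5, seed = 10)
  expect_true(zf$degenerate)
  expect_true(is.na(zf$z))
  expect_equal(zf$mu_R, zf$K)

  # an ordered pattern is far less complex than its randomizations
  stripes <- matrix(FALSE, 64, 64); stripes[seq(1, 64, 4), ] <- TRUE
  zs <- complexity_zscore(stripes, n_rand = 100, seed = 11)
  expect_lt(zs$z, -3)

  expect_error(complexity_zscore(matrix(FALSE, 8, 8)), "empty")
})
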