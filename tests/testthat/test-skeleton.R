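unclass_mat <- function(x) { attributes(x) <- list(dim = dim(x)); x }

test_that("binarize applies a strict threshold and validates input", {
  img <- matrix(c(0.2, 0.05, 0.5, 0.9), 2, 2)
  expect_identical(binarize(img, 0.3), matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2))
  expect_false(any(binarize(img, 1.0)))
  expect_true(all(binarize(matrix(0.5, 3, 3), 0.15)))
  expect_error(binarize(img, 1.2), "threshold")
  expect_error(binarize(img, -0.1), "threshold")
})

test_that("skeletonize thins a thick bar to a single path and is idempotent", {
  bw <- matrix(FALSE, 26, 30)
  bw[10:12, 5:24] <- TRUE
  sk <- skeletonize(bw)
  deg <- classify_degrees(sk)
  expect_equal(sum(deg == 1L), 2L)              # exactly two endpoints
  no_2x2 <- !any(sk[-1, -1] & sk[-nrow(sk), -1] &
                 sk[-1, -ncol(sk)] & sk[-nrow(sk), -ncol(sk)])
  expect_true(no_2x2)
  expect_identical(unclass_mat(skeletonize(unclass_mat(sk))), unclass_mat(sk))
  # empty in, empty out
  expect_false(any(skeletonize(matrix(FALSE, 5, 5))))
})

test_that("a rendered T of three thick bars thins to one branch point", {
  bw <- matrix(FALSE, 40, 40)
  bw[19:21, 5:35] <- TRUE    # horizontal bar
  bw[5:21, 19:21] <- TRUE    # vertical bar meeting it
  deg <- classify_degrees(skeletonize(bw))
  expect_equal(sum(deg == 3L), 1L)
})

test_that("cluster labelling follows 8-connectivity with mass bookkeeping", {
  expect_equal(label_clusters(make_fixture_skeleton("diag2"))$n_clusters, 1L)
  expect_equal(label_clusters(make_fixture_skeleton("diag2"))$masses, 2L)

  two <- matrix(FALSE, 3, 5); two[2, 1] <- TRUE; two[2, 4] <- TRUE
  cl <- label_clusters(two)
  expect_equal(cl$n_clusters, 2L)
  expect_equal(cl$masses, c(1L, 1L))

  cl2 <- label_clusters(make_fixture_skeleton("two_components"))
  expect_equal(cl2$n_clusters, 2L)
  expect_equal(sort(cl2$masses), c(3L, 7L))
  expect_equal(cl2$giant_mass, 7L)
  expect_equal(cl2$n_pixels, 10L)
})

test_that("labelling agrees with a brute-force flood fill on random grids", {
  set.seed(101)
  for (i in 1:100) {
    m <- matrix(runif(32 * 32) < runif(1, 0.1, 0.6), 32, 32)
    cl <- label_clusters(m)
    expect_identical(sort(cl$masses), as.integer(flood_fill_masses(m)))
    expect_equal(sum(cl$masses), sum(m))   # mass conservation
  }
})

test_that("thinning preserves the number of 8-connected components", {
  set.seed(202)
  for (i in 1:40) {
    m <- matrix(runif(32 * 32) < runif(1, 0.2, 0.7), 32, 32)
    expect_equal(label_clusters(skeletonize(m))$n_clusters, n_components8(m))
  }
})

test_that("degree classification clamps to {1,2,3} and matches fixtures", {
  d <- classify_degrees(make_fixture_skeleton("line3"))
  expect_equal(d[d > 0], c(1L, 2L, 1L))

  dt <- classify_degrees(make_fixture_skeleton("tjunction"))
  expect_equal(sort(dt[dt > 0]), c(1L, 1L, 1L, 2L, 2L, 2L, 3L))

  iso <- matrix(FALSE, 3, 3); iso[2, 2] <- TRUE
  expect_equal(classify_degrees(iso)[2, 2], 1L)    # m = 0 clamps to 1

  # a plus-shaped crossing has m = 4 at the centre: clamps to 3
  pc <- classify_degrees(make_fixture_skeleton("plus_cross"))
  expect_equal(pc[5, 5], 3L)

  set.seed(303)
  for (i in 1:20) {
    m <- matrix(runif(64) < 0.4, 8, 8)
    dd <- classify_degrees(m)
    expect_true(all(dd[m] %in% 1:3))
    expect_true(all(dd[!m] == 0L))
  }
})

test_that("mean degree averages over all occupied pixels", {
  expect_equal(mean_degree(classify_degrees(make_fixture_skeleton("line3"))), 4 / 3)
  # diamond ring: 4 pixels, each with exactly two (diagonal) neighbours
  ring <- matrix(FALSE, 5, 5)
  ring[cbind(c(1, 2, 2, 3), c(2, 1, 3, 2))] <- TRUE
  expect_equal(mean_degree(classify_degrees(ring)), 2)
  expect_equal(mean_degree(classify_degrees(make_fixture_skeleton("tjunction"))),
               12 / 7)
  expect_error(mean_degree(classify_degrees(matrix(FALSE, 3, 3))), "empty")
})

test_that("segments are typed by terminal degrees with the stated mass rule", {
  l3 <- make_fixture_skeleton("line3")
  seg <- extract_segments(l3)
  expect_equal(seg$type, "1-1")
  expect_equal(seg$mass, 3L)

  tj <- make_fixture_skeleton("tjunction")
  seg <- extract_segments(tj)
  expect_equal(seg$type, rep("1-3", 3))
  expect_equal(seg$mass, rep(2L, 3))
  expect_equal(sum(seg$mass), sum(tj) - 1L)  # branch pixel in no segment

  ring <- matrix(FALSE, 5, 5)
  ring[cbind(c(1, 2, 2, 3), c(2, 1, 3, 2))] <- TRUE
  seg <- extract_segments(ring)
  expect_equal(nrow(seg), 0L)
  expect_equal(attr(seg, "n_cycles"), 1L)
})

test_that("threshold sweep records all statistics and conserves mass", {
  # a rendered blob stays one cluster below its intensity
  img <- matrix(0, 64, 64)
  img[20:40, 20:40] <- 0.5
  prof <- threshold_sweep(img, c(0.1, 0.2, 0.3))
  expect_s3_class(prof, "threshold_profile")
  expect_equal(prof$n_c, rep(1L, 3))
  expect_error(threshold_sweep(img, c(0.1, 0.2)), "3 thresholds")
  expect_error(threshold_sweep(img, c(0.2, 0.1, 0.3)), "increasing")

  # empty-skeleton thresholds become NA rows
  prof2 <- threshold_sweep(img, c(0.1, 0.4, 0.9))
  expect_true(is.na(prof2$n_c[3]))

  # conservation: sum of cluster masses equals occupied pixels at each th
  set.seed(404)
  noisy <- matrix(runif(64 * 64), 64, 64)
  for (th in c(0.3, 0.6, 0.9)) {
    cl <- label_clusters(skeletonize(binarize(noisy, th)))
    expect_equal(sum(cl$masses), cl$n_pixels)
  }
})

test_that("image IO round-trips and normalizes by bit depth", {
  img <- matrix(runif(64 * 48), 64, 48)
  tf <- tempfile(fileext = ".png")
  write_grayscale_image(img, tf, params = list(seed = 1))
  back <- read_grayscale_image(tf)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 1 / 255)   # 8-bit quantization only
  expect_true(file.exists(paste0(tf, ".json")))

  tf2 <- tempfile(fileext = ".tif")
  write_grayscale_image(img, tf2)
  expect_lt(max(abs(read_grayscale_image(tf2) - img)), 1 / 65535 + 1e-9)
  expect_error(read_grayscale_image("no_such_file.png"), "not found")
})

test_that("the default balanced image shows the expected sweep signatures", {
  ph <- phenotype_presets(1000L)$balanced

  # with camera noise: cluster count is non-monotone with an interior peak
  img <- generate_model_image(ph, render_params(seed = 11L))
  prof <- threshold_sweep(img)
  i <- which.max(prof$n_c)
  expect_gt(i, 1); expect_lt(i, nrow(prof))
  expect_true(any(diff(prof$n_c) > 0) && any(diff(prof$n_c) < 0))

  # the network's own mean degree decreases with threshold; asserted on a
  # noise-free render because the shared camera-dust band at low
  # thresholds carries no network signal
  img0 <- generate_model_image(ph, render_params(seed = 11L, noise_sd = 0))
  prof0 <- threshold_sweep(img0)
  k <- prof0$mean_k[!is.na(prof0$mean_k)]
  expect_true(all(diff(k) <= 0.05))
})
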