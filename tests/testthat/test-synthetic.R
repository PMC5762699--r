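test_that("fixture catalogue matches its documented ground truth", {
  expect_error(make_fixture_skeleton("nope"), "line3.*tjunction.*diag2")
  expect_equal(sum(make_fixture_skeleton("line3")), 3L)
  expect_equal(sum(make_fixture_skeleton("tjunction")), 7L)
  expect_equal(sum(make_fixture_skeleton("diag2")), 2L)
  expect_equal(sum(make_fixture_skeleton("plus_cross")), 13L)
  sp <- make_fixture_skeleton("sierpinski")
  expect_equal(dim(sp), c(256L, 256L))
  expect_equal(sum(sp), 3^8)   # order-8 Sierpinski triangle
})

test_that("rendering is bit-identical under a fixed seed", {
  ph <- phenotype_spec("balanced", c1 = 0.1, c2 = 3e-4, L = 50L)
  rp <- render_params(image_size = c(256L, 256L), seed = 9L)
  expect_identical(generate_model_image(ph, rp), generate_model_image(ph, rp))
})

test_that("with no fusion every dimer renders as its own cluster", {
  ph <- phenotype_spec("fragmented", c1 = 0, c2 = 0, L = 30L)
  rp <- render_params(line_width_px = 1L, psf_sigma_px = 0, noise_sd = 0,
                      image_size = c(512L, 512L), seed = 21L)
  img <- generate_model_image(ph, rp, brightness_spread = 0)
  cl <- label_clusters(skeletonize(binarize(img, 0.15)))
  expect_equal(cl$n_clusters, 30L)
})

test_that("a single tubule survives the full pipeline as one open path", {
  ph <- phenotype_spec("fragmented", c1 = 0, c2 = 0, L = 1L)
  rp <- render_params(psf_sigma_px = 1.0, noise_sd = 0.02,
                      image_size = c(128L, 128L), seed = 5L)
  img <- generate_model_image(ph, rp, brightness_spread = 0)
  sk <- despeckle(skeletonize(binarize(img, 0.15)))
  cl <- label_clusters(sk)
  expect_equal(cl$n_clusters, 1L)
  deg <- classify_degrees(sk)
  expect_equal(sum(deg == 1L), 2L)
})

test_that("intensity histogram is bimodal at the stated modes", {
  ph <- phenotype_spec("balanced", c1 = 0.1, c2 = 3e-4, L = 300L)
  # no PSF: the optics legitimately dim thin-tube cores, so the mode test
  # addresses the noise model alone
  rp <- render_params(psf_sigma_px = 0, image_size = c(512L, 512L), seed = 2L)
  img <- generate_model_image(ph, rp, brightness_spread = 0)
  expect_gte(min(img), 0); expect_lte(max(img), 1)
  breaks <- seq(0, 1, by = 0.01)
  h <- hist(img, breaks = breaks, plot = FALSE)
  bg_mode <- h$mids[which.max(h$counts)]
  expect_lt(abs(bg_mode - 0), rp$noise_sd + 0.011)
  # overlapping tubules saturate and clip to 1; the detector-saturation
  # spike is not the foreground mode
  fg <- h$counts * (h$mids > 0.35 & h$mids < 0.98)
  fg_mode <- h$mids[which.max(fg)]
  expect_lt(abs(fg_mode - rp$foreground_intensity), rp$noise_sd + 0.011)
})

test_that("raising the tip-to-side rate raises the recovered giant fraction", {
  ph_lo <- phenotype_spec("fragmented", c1 = 0.1, c2 = 6e-5, L = 150L)
  ph_hi <- phenotype_spec("hyperfused", c1 = 0.1, c2 = 1.5e-3, L = 150L)
  ng <- function(ph, seed) {
    rp <- render_params(image_size = c(384L, 384L), seed = seed)
    sk <- despeckle(skeletonize(binarize(generate_model_image(ph, rp), 0.15)))
    cl <- label_clusters(sk)
    cl$giant_mass / cl$n_pixels
  }
  seeds <- 1:20
  ng_lo <- vapply(seeds, function(s) ng(ph_lo, s), numeric(1))
  ng_hi <- vapply(seeds, function(s) ng(ph_hi, s), numeric(1))
  expect_gt(mean(ng_hi), mean(ng_lo))
})

test_that("over-dense networks are rejected with a density message", {
  ph <- phenotype_spec("balanced", c1 = 0.1, c2 = 3e-4, L = 5000L)
  rp <- render_params(image_size = c(64L, 64L))
  expect_error(generate_model_image(ph, rp), "dense")
})

test_that("phenotype presets keep the documented rate ordering", {
  pr <- phenotype_presets()
  expect_lt(pr$fragmented$c2, pr$balanced$c2)
  expect_lt(pr$balanced$c2, pr$hyperfused$c2)
  expect_equal(pr$fragmented$c1, pr$hyperfused$c1)
  expect_error(phenotype_spec("odd", 1, 1), "arg")
})
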