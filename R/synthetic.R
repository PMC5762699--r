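# Synthetic pseudo-confocal images: the fission/fusion simulator supplies a
# network, each connected component is embedded in the plane as curvilinear
# polylines, stroked at finite width, blurred by a Gaussian PSF and
# corrupted with additive background noise. Also provides small hand-built
# fixture skeletons with known ground truth.

#' Rendering parameters for synthetic images
#'
#' Defaults emulate a widefield/spinning-disk micrograph of fluorescently
#' labelled mitochondria: tubules about 3 px wide, a PSF of 1.5 px, additive
#' Gaussian background noise of 0.05 intensity units, foreground intensity
#' 0.7 on a 1024 x 1024 frame.
#'
#' @param line_width_px stroke width in pixels (>= 1).
#' @param psf_sigma_px Gaussian point-spread sigma in pixels (0 disables).
#' @param noise_sd additive Gaussian noise standard deviation (0 disables).
#' @param foreground_intensity tubule intensity in (0, 1].
#' @param image_size `(rows, cols)`.
#' @param seed master integer seed; simulation, embedding and noise draw
#'   from sub-seeds split from it.
#' @return list of class `render_params`.
#' @export
render_params <- function(line_width_px = 3L, psf_sigma_px = 1.5,
                          noise_sd = 0.05, foreground_intensity = 0.7,
                          image_size = c(1024L, 1024L), seed = 1L) {
  stopifnot(line_width_px >= 1, psf_sigma_px >= 0, noise_sd >= 0,
            foreground_intensity > 0, foreground_intensity <= 1,
            length(image_size) == 2L, all(image_size >= 16))
  structure(list(line_width_px = as.integer(line_width_px),
                 psf_sigma_px = psf_sigma_px, noise_sd = noise_sd,
                 foreground_intensity = foreground_intensity,
                 image_size = as.integer(image_size),
                 seed = as.integer(seed)),
            class = "render_params")
}

#' Phenotype specification for synthetic networks
#'
#' Bundles the relative fusion rates `(c1, c2)` and system size `L` under a
#' phenotype label. See [phenotype_presets()] for the built-in fragmented /
#' balanced / hyperfused conditions.
#'
#' @param label one of `"fragmented"`, `"balanced"`, `"hyperfused"`.
#' @param c1,c2 positive relative rates.
#' @param L number of dimers.
#' @return list of class `phenotype_spec`.
#' @export
phenotype_spec <- function(label, c1, c2, L = 1000L) {
  label <- match.arg(label, c("fragmented", "balanced", "hyperfused"))
  stopifnot(c1 >= 0, c2 >= 0, L >= 1)
  structure(list(label = label, c1 = c1, c2 = c2, L = as.integer(L)),
            class = "phenotype_spec")
}

#' Built-in phenotype presets
#'
#' Three conditions mirroring fragmentation (oxidative stress), balance
#' (control) and hyperfusion (fusion-protein over-expression). All share
#' `c1 = 0.1`; the balanced preset sits at the critical tip-to-side rate
#' `c2*` located from the model's own `<s>` maximum at `L = 1000`
#' (see the package vignette), and the perturbed presets sit a factor 5
#' below and above it — roughly half a decade, matching how far the
#' perturbed conditions sit from the critical line on the model's phase
#' diagram — placing them clearly in the subcritical and supercritical
#' regimes.
#'
#' @param L number of dimers per network.
#' @return named list of three `phenotype_spec` objects.
#' @export
phenotype_presets <- function(L = 1000L) {
  c2_star <- 3e-4   # critical c2 at c1 = 0.1, L = 1000 (see vignette)
  list(
    fragmented = phenotype_spec("fragmented", c1 = 0.1, c2 = c2_star / 5, L = L),
    balanced   = phenotype_spec("balanced",   c1 = 0.1, c2 = c2_star,     L = L),
    hyperfused = phenotype_spec("hyperfused", c1 = 0.1, c2 = c2_star * 5, L = L)
  )
}

#' Render a simulated fission/fusion network as a grayscale image
#'
#' Runs one replicate of the fission/fusion dynamics at the phenotype's
#' `(c1, c2, L)`, embeds every connected component in the plane (each dimer
#' becomes a bounded-turning random-walk polyline of fixed step length;
#' cycle-closing dimers become straight chords), strokes the polylines at
#' `line_width_px`, convolves with the Gaussian PSF, adds noise and clips to
#' `[0, 1]`. Components are placed uniformly at random; a placement that
#' would bring a component within `gap_px` pixels of previously placed
#' foreground is redrawn (bounded retries), so distinct model clusters stay
#' distinct in the rendered image.
#'
#' @param phenotype a `phenotype_spec`.
#' @param render a `render_params`.
#' @param gap_px minimum clearance between distinct components, in pixels.
#' @param dimer_steps random-walk steps per dimer (step length 4 px).
#' @param brightness_spread mean of the exponential spread of per-component
#'   log-brightness (0 renders every component at `foreground_intensity`;
#'   the default 0.3 emulates variable fluorophore loading).
#' @return numeric matrix in `[0, 1]` with attributes `phenotype`,
#'   `render_params`.
#' @export
generate_model_image <- function(phenotype, render = render_params(),
                                 gap_px = 4L, dimer_steps = 3L,
                                 brightness_spread = 0.3) {
  stopifnot(inherits(phenotype, "phenotype_spec"),
            inherits(render, "render_params"))
  nr <- render$image_size[1L]; nc <- render$image_size[2L]
  if (phenotype$L * 30 > nr * nc)
    stop("network too dense to embed: ", phenotype$L, " dimers exceed ",
         "~1 dimer per 30 px^2 in a ", nr, "x", nc, " frame")

  sim <- simulate_fission_fusion(
    model_params(L = phenotype$L, c1 = phenotype$c1, c2 = phenotype$c2,
                 n_reps = 1L, seed = split_seed(render$seed, 1L)),
    return_edges = TRUE, seed = split_seed(render$seed, 1L))

  occ <- matrix(FALSE, nr, nc)
  img <- matrix(0, nr, nc)
  withr::with_seed(split_seed(render$seed, 2L), {
    comps <- split_components(sim$edges)
    comps <- comps[order(vapply(comps, nrow, 1L), decreasing = TRUE)]
    for (comp in comps) {
      placed <- FALSE
      for (attempt in seq_len(200L)) {
        # a crowded frame is handled by gently shrinking the component's
        # layout on successive retries rather than giving up
        polylines <- embed_component(comp, nr, nc,
                                     step_px = 4, n_steps = dimer_steps,
                                     max_turn = pi / 6,
                                     scale_mult = 0.97^((attempt - 1L) %/% 10L))
        px <- do.call(rbind, polylines)
        hit <- stroke_pixels(px, nr, nc,
                             radius = render$line_width_px / 2 + gap_px)
        if (any(occ[hit])) next
        # fluorophore loading varies between mitochondria: per-dimer
        # brightness with mode at foreground_intensity and an exponential
        # left tail, so tubules fade out gradually across the threshold
        # sweep (thresholding then removes bonds one by one) instead of
        # whole clusters vanishing at once. Fluorescence is additive, so
        # overlapping tubules and junctions render brighter, as fused
        # tangles do in real micrographs (clipped to [0,1] at the end).
        for (pl in polylines) {
          core <- stroke_pixels(pl, nr, nc, radius = render$line_width_px / 2)
          occ[core] <- TRUE
          b <- if (brightness_spread > 0)
            exp(-stats::rexp(1, 1 / brightness_spread)) else 1
          img[core] <- img[core] + render$foreground_intensity * b
        }
        placed <- TRUE
        break
      }
      if (!placed)
        stop("component embedding failed after 200 retries; the frame is ",
             "too crowded at this dimer density (L = ", phenotype$L, ")")
    }
  })
  if (render$psf_sigma_px > 0)
    img <- as.matrix(EBImage::gblur(img, sigma = render$psf_sigma_px))
  if (render$noise_sd > 0) {
    # noise rides on a dark pedestal of one noise_sd, as on a real camera;
    # below the pedestal the frame binarizes to a single lacy cluster, the
    # regime real micrographs show at very low thresholds
    withr::with_seed(split_seed(render$seed, 3L), {
      img <- img + render$noise_sd +
        matrix(rnorm(nr * nc, 0, render$noise_sd), nr, nc)
    })
  }
  img <- pmin(pmax(img, 0), 1)
  attr(img, "phenotype") <- phenotype
  attr(img, "render_params") <- render
  img
}

# group the dimer edge list into connected components; returns a list of
# 2-column matrices (one edge list per component)
split_components <- function(edges) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  memb <- igraph::components(g)$membership
  split.data.frame(edges, memb[edges[, 1L]])
}

# lay out one component. Single dimers become bounded-turning random walks
# from a uniform start; larger components get a force-directed
# (Fruchterman-Reingold) layout scaled to the target tubule length, randomly
# rotated and placed uniformly in the frame, with each dimer drawn as a
# jittered curvilinear polyline between its node positions. Returns a list
# of 2-column matrices of sample points (row, col) at 0.5 px spacing, one
# per dimer.
embed_component <- function(edges, nr, nc, step_px, n_steps, max_turn,
                            scale_mult = 1) {
  margin <- 8
  target_len <- step_px * n_steps
  nodes <- unique(as.vector(edges))
  id <- setNames(seq_along(nodes), nodes)
  el <- cbind(id[as.character(edges[, 1L])], id[as.character(edges[, 2L])])

  if (nrow(el) == 1L && el[1L, 1L] != el[1L, 2L]) {
    start <- c(runif(1, margin, nr - margin), runif(1, margin, nc - margin))
    w <- turning_walk(start, step_px, n_steps, max_turn, nr, nc, margin)
    return(list(densify_polyline(w)))
  }

  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  xy <- igraph::layout_with_fr(g)
  d <- sqrt(rowSums((xy[el[, 1L], , drop = FALSE] -
                     xy[el[, 2L], , drop = FALSE])^2))
  d <- d[d > 0]
  sc <- if (length(d)) target_len / max(mean(d), 1e-6) else 1
  xy <- xy * sc
  a <- runif(1, 0, 2 * pi)
  xy <- xy %*% matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2L)
  # expand dense layouts until tubule coverage of the bounding box is
  # moderate, so the PSF does not merge parallel tubules into blobs
  w <- diff(range(xy[, 1L])); h <- diff(range(xy[, 2L]))
  dens <- nrow(el) * target_len * 3 / max(w * h, 1)
  if (is.finite(dens) && dens > 0.12) xy <- xy * sqrt(dens / 0.12)
  xy <- xy * scale_mult
  w <- diff(range(xy[, 1L])); h <- diff(range(xy[, 2L]))
  shrink <- 0.999 * min(1, (nr - 2 * margin) / max(w, 1e-6),
                        (nc - 2 * margin) / max(h, 1e-6))
  xy <- xy * shrink
  runif_safe <- function(lo, hi) if (hi > lo) runif(1, lo, hi) else (lo + hi) / 2
  off <- c(runif_safe(margin - min(xy[, 1L]), nr - margin - max(xy[, 1L])),
           runif_safe(margin - min(xy[, 2L]), nc - margin - max(xy[, 2L])))
  xy <- sweep(xy, 2L, off, "+")

  lapply(seq_len(nrow(el)), function(e) {
    p <- xy[el[e, 1L], ]; q <- xy[el[e, 2L], ]
    if (el[e, 1L] == el[e, 2L]) {
      # dimer bent into a loop: small lobe anchored at the node
      ang <- runif(1, 0, 2 * pi)
      r <- target_len / (2 * pi) * 2
      ctr <- p + r * c(cos(ang), sin(ang))
      t <- seq(ang + pi, ang + 3 * pi, length.out = 9L)
      pts <- rbind(p, t(ctr + r * rbind(cos(t[-c(1L, 9L)]), sin(t[-c(1L, 9L)]))), p)
    } else {
      mid <- (p + q) / 2
      perp <- c(q[2L] - p[2L], p[1L] - q[1L])
      nl <- sqrt(sum(perp^2))
      if (nl > 0) perp <- perp / nl
      amp <- runif(1, -0.25, 0.25) * sqrt(sum((q - p)^2))
      pts <- rbind(p, mid + amp * perp, q)
    }
    pts[, 1L] <- pmin(pmax(pts[, 1L], 2), nr - 1)
    pts[, 2L] <- pmin(pmax(pts[, 2L], 2), nc - 1)
    densify_polyline(pts)
  })
}

# bounded-turning random walk from `start`: fixed step, heading increment
# uniform in [-max_turn, max_turn], reflected off the frame margins
turning_walk <- function(start, step_px, n_steps, max_turn, nr, nc, margin) {
  out <- matrix(NA_real_, n_steps + 1L, 2L)
  out[1L, ] <- start
  heading <- runif(1, 0, 2 * pi)
  p <- start
  for (i in seq_len(n_steps)) {
    heading <- heading + runif(1, -max_turn, max_turn)
    q <- p + step_px * c(cos(heading), sin(heading))
    if (q[1L] < margin || q[1L] > nr - margin) {
      heading <- pi - heading + runif(1, -max_turn, max_turn)
      q <- p + step_px * c(cos(heading), sin(heading))
    }
    if (q[2L] < margin || q[2L] > nc - margin) {
      heading <- -heading + runif(1, -max_turn, max_turn)
      q <- p + step_px * c(cos(heading), sin(heading))
    }
    q[1L] <- min(max(q[1L], 2), nr - 1)
    q[2L] <- min(max(q[2L], 2), nc - 1)
    out[i + 1L, ] <- q
    p <- q
  }
  out
}

# resample a polyline at ~0.5 px spacing
densify_polyline <- function(v) {
  if (nrow(v) == 1L) return(v)
  segs <- lapply(seq_len(nrow(v) - 1L), function(i) {
    a <- v[i, ]; b <- v[i + 1L, ]
    n <- max(2L, ceiling(sqrt(sum((b - a)^2)) / 0.5))
    cbind(seq(a[1L], b[1L], length.out = n), seq(a[2L], b[2L], length.out = n))
  })
  do.call(rbind, segs)
}

# linear pixel indices covered when stamping a disc of `radius` at each
# polyline sample point
stroke_pixels <- function(pts, nr, nc, radius) {
  r0 <- floor(radius)
  offs <- expand.grid(dr = -r0:r0, dc = -r0:r0)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2 | (r0 == 0), , drop = FALSE]
  if (nrow(offs) == 0L) offs <- data.frame(dr = 0L, dc = 0L)
  rr <- outer(round(pts[, 1L]), offs$dr, `+`)
  cc <- outer(round(pts[, 2L]), offs$dc, `+`)
  keep <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  unique((cc[keep] - 1L) * nr + rr[keep])
}

#' Hand-built fixture skeletons with known ground truth
#'
#' Available fixtures: `"line3"` (3 collinear pixels, one cluster of mass
#' 3), `"tjunction"` (branch point with three 2-pixel arms; 7 pixels, one
#' degree-3 pixel), `"diag2"` (two diagonally adjacent pixels; one cluster
#' under 8-connectivity), `"sierpinski"` (order-8 Sierpinski triangle on a
#' 256 x 256 grid, box-counting dimension log 3 / log 2), `"plus_cross"`
#' (four arms meeting at one pixel) and `"two_components"` (`line3` and
#' `tjunction` far apart; clusters of mass 3 and 7).
#'
#' @param name fixture identifier.
#' @return logical matrix of class `mito_skeleton`.
#' @export
make_fixture_skeleton <- function(name) {
  fixtures <- c("line3", "tjunction", "diag2", "sierpinski",
                "plus_cross", "two_components")
  if (!is.character(name) || length(name) != 1L || !(name %in% fixtures))
    stop("unknown fixture '", name, "'; available: ",
         paste(fixtures, collapse = ", "))
  m <- switch(name,
    line3 = {
      x <- matrix(FALSE, 5L, 5L); x[3L, 2:4] <- TRUE; x
    },
    tjunction = {
      # arms leave the centre up, down-left and down-right so that no two
      # arm pixels are mutually 8-adjacent: degrees are exactly (3; 2,2,2;
      # 1,1,1)
      x <- matrix(FALSE, 9L, 9L)
      x[5L, 5L] <- TRUE                      # centre, degree 3
      x[3:4, 5L] <- TRUE                     # up arm
      x[6L, 4L] <- TRUE; x[7L, 3L] <- TRUE   # down-left arm
      x[6L, 6L] <- TRUE; x[7L, 7L] <- TRUE   # down-right arm
      x
    },
    diag2 = {
      x <- matrix(FALSE, 4L, 4L); x[1L, 1L] <- TRUE; x[2L, 2L] <- TRUE; x
    },
    sierpinski = {
      i <- 0:255
      outer(i, i, function(a, b) bitwAnd(a, b) == 0L)
    },
    plus_cross = {
      x <- matrix(FALSE, 9L, 9L)
      x[5L, 2:8] <- TRUE; x[2:8, 5L] <- TRUE; x
    },
    two_components = {
      x <- matrix(FALSE, 20L, 20L)
      x[3L, 2:4] <- TRUE                       # line3 in one corner
      x[14L, 14L] <- TRUE                      # tjunction centre
      x[12:13, 14L] <- TRUE                    # up arm
      x[15L, 13L] <- TRUE; x[16L, 12L] <- TRUE # down-left arm
      x[15L, 15L] <- TRUE; x[16L, 16L] <- TRUE # down-right arm
      x
    })
  class(m) <- c("mito_skeleton", class(m))
  m
}
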