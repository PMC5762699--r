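# Image -> skeleton pipeline: binarize at an intensity threshold, thin to a
# one-pixel trace, label 8-connected clusters, classify pixel degrees, and
# decompose the trace into typed segments.

#' Read a grayscale image, normalized to [0, 1]
#'
#' Reads TIFF (8/16-bit) or PNG images. Intensities are normalized by the
#' image bit depth (8-bit maps 255 to 1), not by the per-image maximum, so
#' binarization thresholds are absolute across images. Multi-channel images
#' are reduced to their first channel.
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @return numeric matrix with values in `[0, 1]`.
#' @export
read_grayscale_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format '", ext, "' for ", path)
  )
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  if (length(img) == 0L) stop("empty image: ", path)
  # readTIFF/readPNG already divide by the dtype maximum
  storage.mode(img) <- "double"
  if (anyNA(img) || any(!is.finite(img))) stop("non-finite pixels in ", path)
  pmin(pmax(img, 0), 1)
}

#' Write a grayscale image with a parameter sidecar
#'
#' Writes 8-bit PNG or 16-bit TIFF. If `params` is given, a JSON sidecar
#' `<path>.json` records it for provenance.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param path output path (`.png`, `.tif`/`.tiff`).
#' @param params optional list serialized alongside the image.
#' @return `path`, invisibly.
#' @export
write_grayscale_image <- function(img, path, params = NULL) {
  stopifnot(is.matrix(img), min(img) >= 0, max(img) <= 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 16L),
    stop("unsupported image format '", ext, "'")
  )
  if (!is.null(params)) {
    jsonlite::write_json(params, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Binarize a normalized image at a threshold
#'
#' A pixel is foreground iff its intensity strictly exceeds `th`.
#'
#' @param img numeric matrix with values in `[0, 1]`.
#' @param th threshold in `[0, 1]`.
#' @return logical matrix.
#' @export
binarize <- function(img, th) {
  stopifnot(is.matrix(img))
  if (!is.numeric(th) || length(th) != 1L || is.na(th) || th < 0 || th > 1)
    stop("threshold must be a single value in [0, 1]")
  img > th
}

#' Thin a binary image to a one-pixel skeleton
#'
#' Iterative morphological thinning to convergence. Only 8-simple pixels with
#' at least two occupied neighbours are removed, so thinning preserves both
#' endpoints and the number of connected components, and the result contains
#' no fully occupied 2x2 block.
#'
#' @param bw logical matrix (foreground = `TRUE`).
#' @param threshold optional threshold recorded on the result.
#' @return object of class `mito_skeleton`: logical matrix with attribute
#'   `threshold`.
#' @export
skeletonize <- function(bw, threshold = NA_real_) {
  stopifnot(is.matrix(bw), is.logical(bw))
  out <- thin_skeleton_cpp(bw)
  attr(out, "threshold") <- threshold
  class(out) <- c("mito_skeleton", class(out))
  out
}

#' Label 8-connected clusters of a skeleton
#'
#' A cluster is a maximal set of occupied pixels in which each pixel touches
#' at least one other through any of its eight nearest neighbours. Cluster
#' mass is the pixel count.
#'
#' @param skel logical matrix (typically a `mito_skeleton`).
#' @return a list of class `cluster_set` with elements `labels` (integer
#'   matrix, 0 = background), `masses` (integer vector, one entry per
#'   cluster), `n_clusters`, `n_pixels` and `giant_mass`.
#' @export
label_clusters <- function(skel) {
  stopifnot(is.matrix(skel), is.logical(skel))
  lab <- label_components8_cpp(unclass_matrix(skel))
  n_cl <- max(lab)
  masses <- if (n_cl > 0L) tabulate(lab[lab > 0L], nbins = n_cl) else integer(0)
  structure(
    list(labels = lab,
         masses = masses,
         n_clusters = n_cl,
         n_pixels = sum(masses),
         giant_mass = if (n_cl > 0L) max(masses) else 0L),
    class = "cluster_set")
}

unclass_matrix <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' Classify the degree of every skeleton pixel
#'
#' Counts the occupied 8-neighbours `m` of each occupied pixel and assigns
#' degree `k = 1` (endpoint, including isolated pixels with `m = 0`),
#' `k = 2` (tube interior) or `k = 3` (branch point; any `m >= 3` is treated
#' as a branch point since rasterization can produce spurious 4-crossings).
#'
#' @param skel logical matrix, already thinned.
#' @return integer matrix: degree in `{1,2,3}` on occupied pixels, 0 elsewhere.
#' @export
classify_degrees <- function(skel) {
  stopifnot(is.matrix(skel), is.logical(skel))
  nr <- nrow(skel); nc <- ncol(skel)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- skel
  m <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    m <- m + pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  deg <- pmin(pmax(m, 1L), 3L)
  deg[!skel] <- 0L
  storage.mode(deg) <- "integer"
  deg
}

#' Mean degree of a skeleton
#'
#' Arithmetic mean of the per-pixel degree over all occupied pixels.
#'
#' @param dmap integer degree matrix from [classify_degrees()].
#' @return value in `[1, 3]`.
#' @export
mean_degree <- function(dmap) {
  occ <- dmap > 0L
  if (!any(occ)) stop("mean_degree: empty skeleton")
  mean(dmap[occ])
}

#' Decompose a skeleton into typed segments
#'
#' Segments are maximal paths of degree-2 pixels between terminal pixels of
#' degree 1 or 3. Segment mass counts the interior degree-2 pixels plus any
#' degree-1 terminals; branch-point (degree-3) pixels are shared by up to
#' three segments and are not counted in any segment's mass. The segment type
#' records the terminal degrees: `"1-1"` (free tube), `"1-3"` (dangling
#' branch) or `"3-3"` (internal link). Isolated rings have no terminal and
#' yield no segment; their count is returned in the `n_cycles` attribute.
#'
#' @param skel logical skeleton matrix.
#' @param dmap degree matrix from [classify_degrees()]; computed if missing.
#' @return data.frame with columns `type` and `mass`, attribute `n_cycles`.
#' @export
extract_segments <- function(skel, dmap = NULL) {
  if (is.null(dmap)) dmap <- classify_degrees(skel)
  nr <- nrow(skel); nc <- ncol(skel)
  occ_idx <- which(skel)
  type <- character(0); mass <- integer(0)

  if (length(occ_idx)) {
    deg_of <- dmap[occ_idx]
    index_of <- integer(nr * nc); index_of[occ_idx] <- seq_along(occ_idx)
    visited_px <- logical(length(occ_idx))   # degree-1/2 pixels consumed
    offs <- as.integer(c(-1, 1, -nr, nr, -nr - 1, -nr + 1, nr - 1, nr + 1))

    neighbours <- function(p) {
      r <- (p - 1L) %% nr + 1L
      cands <- p + offs
      keep <- rep(TRUE, 8L)
      if (r == 1L) keep[c(1L, 5L, 7L)] <- FALSE
      if (r == nr) keep[c(2L, 6L, 8L)] <- FALSE
      cands <- cands[keep]
      cands <- cands[cands >= 1L & cands <= nr * nc]
      cands[skel[cands]]
    }

    walk <- function(from, into) {
      # follow degree-2 pixels from terminal `from` through `into`;
      # returns c(interior_count, terminal_pixel)
      n_int <- 0L
      prev <- from; cur <- into
      while (dmap[cur] == 2L) {
        visited_px[index_of[cur]] <<- TRUE
        n_int <- n_int + 1L
        nb <- neighbours(cur)
        nxt <- nb[nb != prev]
        if (length(nxt) == 0L) break             # 2-pixel stub: cur ends it
        # diagonal shortcuts can make both a terminal and the next interior
        # pixel adjacent; prefer an unvisited degree-2 continuation
        if (length(nxt) > 1L) {
          d2 <- nxt[dmap[nxt] == 2L & !visited_px[index_of[nxt]]]
          nxt <- if (length(d2)) d2[1L] else nxt[dmap[nxt] != 2L][1L]
        }
        prev <- cur; cur <- nxt
        if (cur == from) break                   # closed loop back to start
      }
      c(n_int, cur)
    }

    terminals <- occ_idx[deg_of != 2L]
    for (t in terminals) {
      for (nb in neighbours(t)) {
        if (dmap[nb] == 2L) {
          if (visited_px[index_of[nb]]) next
          res <- walk(t, nb)
          end <- res[2L]
          if (end == t) { # loop attached to t (t must be a branch point)
            type <- c(type, paste(dmap[t], dmap[t], sep = "-"))
            mass <- c(mass, res[1L])
            next
          }
        } else {
          # direct terminal-terminal adjacency: count once
          if (nb < t) next
          res <- c(0L, nb)
          end <- nb
        }
        end <- res[2L]
        dt <- sort(c(dmap[t], dmap[end]))
        type <- c(type, paste(dt[1L], dt[2L], sep = "-"))
        mass <- c(mass, res[1L] + sum(dmap[t] == 1L) + sum(dmap[end] == 1L))
      }
      visited_px[index_of[t]] <- TRUE
    }

    # isolated single pixels: degree-1 with no neighbours => mass-1 segment
    singles <- occ_idx[deg_of == 1L]
    for (p in singles) {
      if (length(neighbours(p)) == 0L) {
        type <- c(type, "1-1"); mass <- c(mass, 1L)
      }
    }

    n_cycles <- 0L
    for (p in occ_idx[deg_of == 2L]) {
      if (!visited_px[index_of[p]]) {
        res <- walk(p, p) # consume the loop: walk marks visited
        nb <- neighbours(p)
        for (q in nb) if (dmap[q] == 2L && !visited_px[index_of[q]]) {
          walk(p, q)
        }
        visited_px[index_of[p]] <- TRUE
        n_cycles <- n_cycles + 1L
      }
    }
  } else {
    n_cycles <- 0L
  }

  out <- data.frame(type = type, mass = mass, stringsAsFactors = FALSE)
  attr(out, "n_cycles") <- n_cycles
  out
}

#' Remove sub-resolution specks from a skeleton
#'
#' Drops 8-connected clusters smaller than `min_px` pixels. Specks below
#' the diffraction-limited tubule scale are camera noise, not organelles;
#' removing them before computing network statistics is the usual
#' despeckling step of fluorescence image pipelines.
#'
#' @param skel logical skeleton matrix.
#' @param min_px minimum cluster mass kept (1 keeps everything).
#' @return logical matrix of the same class.
#' @export
despeckle <- function(skel, min_px = 4L) {
  if (min_px <= 1L || !any(skel)) return(skel)
  cl <- label_clusters(skel)
  small <- which(cl$masses < min_px)
  if (length(small)) {
    out <- skel & !(matrix(cl$labels %in% small, nrow(skel), ncol(skel)))
    attributes(out) <- attributes(skel)
    return(out)
  }
  skel
}

#' Sweep the binarization threshold and profile the network
#'
#' For each threshold runs binarize -> skeletonize -> despeckle -> label ->
#' degrees and records the cluster count `N_c`, mean cluster mass `<s>`,
#' mean degree `<k>`, giant-cluster fraction `N_g/N` and the cluster-mass
#' entropy `H`. Thresholds yielding an empty skeleton are recorded as `NA`
#' rows.
#'
#' @param img normalized grayscale matrix.
#' @param thresholds increasing vector of at least 3 thresholds.
#' @param keep_masses if `TRUE`, attach the per-threshold cluster-mass lists
#'   as the `masses` attribute (a named list).
#' @param min_cluster_px despeckling cutoff passed to [despeckle()]; set to
#'   1 to keep every cluster.
#' @return data.frame of class `threshold_profile` with columns `th`, `n_c`,
#'   `mean_s`, `mean_k`, `ng_over_n`, `entropy`.
#' @export
threshold_sweep <- function(img, thresholds = default_thresholds(),
                            keep_masses = FALSE, min_cluster_px = 4L) {
  stopifnot(is.matrix(img))
  if (length(thresholds) < 3L) stop("need at least 3 thresholds")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  rows <- vector("list", length(thresholds))
  mass_lists <- if (keep_masses) vector("list", length(thresholds))
  for (i in seq_along(thresholds)) {
    th <- thresholds[i]
    sk <- despeckle(skeletonize(binarize(img, th), threshold = th),
                    min_cluster_px)
    if (!any(sk)) {
      rows[[i]] <- data.frame(th = th, n_c = NA_integer_, mean_s = NA_real_,
                              mean_k = NA_real_, ng_over_n = NA_real_,
                              entropy = NA_real_)
      next
    }
    cl <- label_clusters(sk)
    dmap <- classify_degrees(sk)
    rows[[i]] <- data.frame(
      th = th,
      n_c = cl$n_clusters,
      mean_s = mean(cl$masses),
      mean_k = mean_degree(dmap),
      ng_over_n = cl$giant_mass / cl$n_pixels,
      entropy = mass_entropy(cl$masses))
    if (keep_masses) mass_lists[[i]] <- cl$masses
  }
  out <- do.call(rbind, rows)
  class(out) <- c("threshold_profile", class(out))
  if (keep_masses) {
    names(mass_lists) <- formatC(thresholds, format = "g")
    attr(out, "masses") <- mass_lists
  }
  out
}

#' Default binarization threshold grid
#'
#' 0.02 to 0.60 in steps of 0.02; single-threshold analyses default to 0.15.
#' @return numeric vector.
#' @export
default_thresholds <- function() seq(0.02, 0.60, by = 0.02)
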