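# End-to-end drivers: per-image analysis (threshold sweep plus all
# distributional and complexity statistics) and the full synthetic study
# (generate phenotypes, analyze, build curves, match, classify).

#' Analysis configuration
#'
#' Collects every tunable of the pipeline in one serializable document.
#' Defaults mirror the reference analysis conditions (single-threshold
#' statistics at 0.15, 1000 randomizations, simulator at `L = 15000` with
#' `3L` events and 100 replicates); `desk_scale = TRUE` substitutes the
#' reduced conditions used for routine runs and tests (`L = 1000`, 20
#' replicates, 200 randomizations, 384 px complexity frames).
#'
#' @param thresholds binarization sweep grid.
#' @param reference_th single threshold for distribution-level statistics.
#' @param fit_range normalized-mass fit window for the exponent.
#' @param n_randomizations complexity null-ensemble size.
#' @param L,n_reps simulator size and replicate count.
#' @param c1_grid,c2_grid rate grids for curves and phase diagram.
#' @param seed master seed.
#' @param min_cluster_px despeckling cutoff for skeleton statistics.
#' @param complexity_frame frame side (px) for complexity evaluation;
#'   skeletons larger than this are centre-cropped first.
#' @param desk_scale use reduced problem sizes.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(thresholds = default_thresholds(),
                            reference_th = 0.15,
                            fit_range = c(0.05, 5),
                            n_randomizations = if (desk_scale) 200L else 1000L,
                            L = if (desk_scale) 1000L else 15000L,
                            n_reps = if (desk_scale) 20L else 100L,
                            c1_grid = default_rate_grids()$c1,
                            c2_grid = default_rate_grids()$c2,
                            seed = 1L,
                            min_cluster_px = 4L,
                            complexity_frame = if (desk_scale) 128L else 256L,
                            desk_scale = TRUE) {
  structure(list(thresholds = thresholds, reference_th = reference_th,
                 fit_range = fit_range,
                 n_randomizations = as.integer(n_randomizations),
                 L = as.integer(L), n_reps = as.integer(n_reps),
                 c1_grid = c1_grid, c2_grid = c2_grid,
                 seed = as.integer(seed),
                 min_cluster_px = as.integer(min_cluster_px),
                 complexity_frame = as.integer(complexity_frame),
                 desk_scale = isTRUE(desk_scale)),
            class = "analysis_config")
}

#' Analyze one image end to end
#'
#' Runs the threshold sweep, then at the reference threshold computes the
#' cluster-mass distribution, collapsed-exponent fit across the sweep,
#' entropy-based critical threshold, fractal dimension, finite-size scaling
#' and Lempel-Ziv complexity z-score. If `out_dir` is given, writes the
#' per-threshold profile as CSV and the summary (plus cluster masses) as
#' JSON, with the configuration alongside.
#'
#' @param img grayscale matrix or path to a TIFF/PNG file.
#' @param config an `analysis_config`.
#' @param out_dir optional output directory (created if needed).
#' @param name stem for output files.
#' @return list of class `image_summary`: `profile`, `th_star_entropy`,
#'   `th_star_nc`, `gamma`, `fractal_dim`, `scaling_slope`, `lz_z`,
#'   `mean_k_ref`, `ng_over_n_ref`, `masses_ref`.
#' @export
analyze_image <- function(img, config = analysis_config(), out_dir = NULL,
                          name = "image") {
  if (is.character(img)) img <- read_grayscale_image(img)
  stopifnot(is.matrix(img))
  profile <- threshold_sweep(img, config$thresholds, keep_masses = TRUE,
                             min_cluster_px = config$min_cluster_px)
  masses_by_th <- attr(profile, "masses")

  dists <- list()
  for (m in masses_by_th)
    if (!is.null(m) && length(m) >= 5L) dists[[length(dists) + 1L]] <- ccdf(m)
  gamma_fit <- tryCatch(collapse_and_fit_exponent(dists, config$fit_range),
                        error = function(e) NULL)

  sk <- despeckle(skeletonize(binarize(img, config$reference_th),
                              threshold = config$reference_th),
                  config$min_cluster_px)
  if (!any(sk)) stop("empty skeleton at the reference threshold for ", name)
  cl <- label_clusters(sk)
  dmap <- classify_degrees(sk)

  scal <- finite_size_scaling(sk, seed = split_seed(config$seed, 11L))
  z <- complexity_zscore(crop_centre(sk, config$complexity_frame),
                         n_rand = config$n_randomizations,
                         seed = split_seed(config$seed, 12L))

  res <- structure(list(
    name = name,
    profile = profile,
    th_star_entropy = as.numeric(critical_threshold(profile, "entropy_max")),
    th_star_nc = as.numeric(critical_threshold(profile, "nc_max")),
    gamma = if (is.null(gamma_fit)) NA_real_ else gamma_fit$gamma,
    fractal_dim = as.numeric(fractal_dimension(sk)),
    scaling_slope = scal$scaling_slope,
    lz_z = z$z,
    mean_k_ref = mean_degree(dmap),
    ng_over_n_ref = cl$giant_mass / cl$n_pixels,
    masses_ref = cl$masses), class = "image_summary")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(as.data.frame(profile),
              file.path(out_dir, paste0(name, "_profile.csv")),
              row.names = FALSE)
    summ <- res[c("th_star_entropy", "th_star_nc", "gamma", "fractal_dim",
                  "scaling_slope", "lz_z", "mean_k_ref", "ng_over_n_ref")]
    summ$masses_ref <- res$masses_ref
    jsonlite::write_json(summ, file.path(out_dir, paste0(name, "_summary.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(unclass(config),
                         file.path(out_dir, paste0(name, "_config.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

# centre crop of the given side; if the frame centre happens to contain no
# skeleton at all, recentre on the occupied pixel nearest the occupancy
# centroid so the window is never empty
crop_centre <- function(skel, side) {
  nr <- nrow(skel); nc <- ncol(skel)
  if (nr <= side && nc <= side) return(skel)
  take <- function(r0, c0) {
    out <- skel[r0:(r0 + side - 1L), c0:(c0 + side - 1L), drop = FALSE]
    class(out) <- class(skel)
    out
  }
  out <- take(max(1L, (nr - side) %/% 2L + 1L), max(1L, (nc - side) %/% 2L + 1L))
  if (any(out)) return(out)
  occ <- which(skel, arr.ind = TRUE)
  if (nrow(occ) == 0L) return(out)
  ctr <- colMeans(occ)
  p <- occ[which.min((occ[, 1L] - ctr[1L])^2 + (occ[, 2L] - ctr[2L])^2), ]
  take(min(max(p[1L] - side %/% 2L, 1L), nr - side + 1L),
       min(max(p[2L] - side %/% 2L, 1L), nc - side + 1L))
}

#' Run the full synthetic study
#'
#' Generates `n_seeds` images per phenotype (fragmented / balanced /
#' hyperfused), analyzes each, builds the model's parametric curves and
#' critical line, matches every image's reference-threshold observables
#' back to `(c1, c2)` and classifies its regime. Returns one tidy row per
#' image plus study-level ordering checks (median mean degree and critical
#' threshold across phenotypes).
#'
#' @param config an `analysis_config`.
#' @param n_seeds images per phenotype.
#' @param presets phenotype list from [phenotype_presets()].
#' @param render_base `render_params` template (its seed is replaced).
#' @param curves optionally, precomputed `param_curves` to reuse.
#' @param out_dir optional output directory for the study table.
#' @return list of class `study_report`: `table` (data.frame), `orderings`
#'   (named logicals), `curves`, `critical_line`.
#' @export
full_study <- function(config = analysis_config(), n_seeds = 5L,
                       presets = phenotype_presets(config$L),
                       render_base = render_params(),
                       curves = NULL, out_dir = NULL) {
  if (is.null(curves)) {
    curves <- build_curves(config$c1_grid, config$c2_grid,
                           model_params(L = config$L, c1 = 1, c2 = 1,
                                        n_reps = config$n_reps,
                                        seed = split_seed(config$seed, 21L)))
  }
  critline <- critical_line(curves)

  rows <- list()
  for (ph_name in names(presets)) {
    ph <- presets[[ph_name]]
    for (s in seq_len(n_seeds)) {
      rp <- render_base
      # the same render seed across phenotypes at a given seed index pairs
      # the noise fields, so phenotype contrasts are purely network-driven
      rp$seed <- split_seed(config$seed, 1000L + s)
      img <- generate_model_image(ph, rp)
      ana <- analyze_image(img, config, name = paste0(ph_name, "_", s))
      # image skeletons inflate pixel degree via rasterization crossings
      # (a bias of ~+0.2, larger than the network signal on that axis),
      # while the giant fraction is unbiased: down-weight the degree axis
      mt <- match_parameters(ana$mean_k_ref, ana$ng_over_n_ref, curves,
                             weights = c(0.2, 1))
      rows[[length(rows) + 1L]] <- data.frame(
        phenotype = ph_name, seed = rp$seed,
        mean_k = ana$mean_k_ref, ng_over_n = ana$ng_over_n_ref,
        th_star = ana$th_star_entropy, gamma = ana$gamma,
        fractal_dim = ana$fractal_dim, lz_z = ana$lz_z,
        c1_hat = mt$c1_hat, c2_hat = mt$c2_hat,
        regime = classify_regime(mt, critline))
    }
  }
  tab <- do.call(rbind, rows)

  med <- function(col, ph) median(tab[[col]][tab$phenotype == ph])
  orderings <- c(
    mean_k = med("mean_k", "fragmented") <= med("mean_k", "balanced") &&
             med("mean_k", "balanced") <= med("mean_k", "hyperfused"),
    th_star = med("th_star", "fragmented") <= med("th_star", "balanced") &&
              med("th_star", "balanced") <= med("th_star", "hyperfused"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(tab, file.path(out_dir, "study_table.csv"), row.names = FALSE)
    jsonlite::write_json(as.list(orderings), file.path(out_dir, "orderings.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(table = tab, orderings = orderings, curves = curves,
                 critical_line = critline),
            class = "study_report")
}
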