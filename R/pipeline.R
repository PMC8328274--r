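# Orchestration of the four-step pipeline and batch entry points used by
# the command-line interface: count (images -> peaks/ganglia/segmentation),
# metrics (per-image summaries -> plexus metrics), fixture (synthetic data).

#' Run the four-step counting pipeline on one image
#'
#' Steps: (1) grayscale conversion, Gaussian smoothing and Otsu
#' thresholding on the center of a 3x3 partition; (2) neuron identification
#' as local maxima separated by at least \code{delta_m}; (3) DBSCAN
#' clustering into ganglia (noise = extraganglionic neurons); (4)
#' watershed-style segmentation leaving only the identified ganglia
#' labeled. If the center partition is constant (no signal there, e.g. a
#' sparse synthetic field or an empty tissue region) the threshold falls
#' back to whole-image Otsu with a warning.
#'
#' @param img an \code{\link{intensity_image}} or a file path (TIFF/PNG).
#' @param rho pixel density (pixels/um); required when \code{img} is a path.
#' @param sigma Gaussian smoothing parameter (pixels, default 7).
#' @param sigma_interpretation \code{"sd"} (default) or \code{"fwhm"}.
#' @param delta_m minimum peak separation (pixels); default \code{2.5*rho}.
#' @param eps_m DBSCAN radius (pixels); default \code{20.6*rho}.
#' @param min_neurons minimum neurons per ganglion Ng (default 3).
#' @param segment logical; compute the label image and overlay (default
#'   TRUE).
#' @return Object of class \code{plexus_result}: smoothed image, mask,
#'   peaks, labeling, ganglia summary, label image, and the effective
#'   parameters.
#' @export
count_plexus <- function(img, rho = NULL, sigma = 7,
                         sigma_interpretation = c("sd", "fwhm"),
                         delta_m = NULL, eps_m = NULL, min_neurons = 3L,
                         segment = TRUE) {
  sigma_interpretation <- match.arg(sigma_interpretation)
  if (is.character(img)) {
    if (is.null(rho)) stop("'rho' is required when loading an image from a path")
    img <- load_image(img, rho)
  }
  stopifnot(inherits(img, "intensity_image"))
  rho <- img$rho
  if (is.null(delta_m)) delta_m <- default_min_distance(rho)
  if (is.null(eps_m)) eps_m <- default_eps(rho)
  if (delta_m <= 0 || eps_m <= 0 || min_neurons < 1)
    stop("delta_m and eps_m must be positive and min_neurons >= 1")

  gray <- to_grayscale(img)
  sm <- gaussian_smooth(gray, sigma, sigma_interpretation)
  thr <- tryCatch(otsu_threshold(center_partition(sm)),
                  error = function(e) {
                    warning("center partition is constant; falling back to whole-image Otsu threshold")
                    otsu_threshold(sm)
                  })
  mask <- binarize(sm, thr)
  peaks <- detect_peaks(sm, mask, delta_m)
  labeling <- cluster_dbscan(peaks, eps_m, min_neurons)
  summ <- summarize_clusters(labeling, peaks)
  label_img <- if (segment) watershed_segment(mask, peaks, labeling) else NULL
  structure(list(image = gray, smoothed = sm, mask = mask, peaks = peaks,
                 labeling = labeling, ganglia = summ$ganglia,
                 n_neurons = summ$n_neurons, n_ganglia = summ$n_ganglia,
                 n_extraganglionic = summ$n_extraganglionic,
                 label_image = label_img,
                 params = list(rho = rho, sigma = sigma,
                               sigma_interpretation = sigma_interpretation,
                               delta_m = delta_m, eps_m = eps_m,
                               min_neurons = as.integer(min_neurons))),
            class = "plexus_result")
}

#' @export
print.plexus_result <- function(x, ...) {
  cat(sprintf("<plexus_result> %d x %d px: %d neurons, %d ganglia, %d extraganglionic\n",
              x$image$height, x$image$width, x$n_neurons, x$n_ganglia,
              x$n_extraganglionic))
  cat(sprintf("  rho = %g px/um, sigma = %g (%s), delta_m = %g px, eps_m = %g px, Ng = %d\n",
              x$params$rho, x$params$sigma, x$params$sigma_interpretation,
              x$params$delta_m, x$params$eps_m, x$params$min_neurons))
  invisible(x)
}

#' Batch-run the counting pipeline and write result files
#'
#' For each input image writes \code{<id>_peaks.csv} (image_id, peak_id,
#' row, col; 0-based, fractional allowed), \code{<id>_ganglia.csv},
#' \code{<id>_label.tif} (16-bit) and \code{<id>_overlay.png}, plus a
#' combined \code{summary.csv} (image_id, n_neurons, n_ganglia,
#' n_extraganglionic, height, width, rho) and a \code{manifest.json}
#' recording all effective parameters. Unreadable images are logged and
#' skipped; the function then signals a warning and records the failure in
#' the manifest.
#'
#' @param inputs character vector of image paths, or a directory.
#' @param rho pixel density (pixels/um), required.
#' @param out_dir output directory (created if needed).
#' @param ... passed to [count_plexus()] (sigma, delta_m, eps_m, ...).
#' @return The summary data.frame, invisibly; attribute \code{n_failed}
#'   carries the failure count.
#' @export
run_count <- function(inputs, rho, out_dir, ...) {
  if (is.null(rho) || !is.numeric(rho) || rho <= 0)
    stop("usage error: 'rho' (pixels/um) is required and must be > 0")
  if (length(inputs) == 1L && dir.exists(inputs))
    inputs <- list.files(inputs, pattern = "\\.(tif|tiff|png)$", full.names = TRUE,
                         ignore.case = TRUE)
  if (length(inputs) == 0L) stop("usage error: no input images found")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list(); failures <- character(0)
  for (path in inputs) {
    id <- tools::file_path_sans_ext(basename(path))
    res <- tryCatch(count_plexus(path, rho = rho, ...), error = function(e) e)
    if (inherits(res, "error")) {
      message("FAILED ", path, ": ", conditionMessage(res))
      failures <- c(failures, paste0(path, ": ", conditionMessage(res)))
      next
    }
    pk <- res$peaks$coordinates
    utils::write.csv(data.frame(image_id = id,
                                peak_id = seq_len(nrow(pk)) - 1L,
                                row = pk$row, col = pk$col),
                     file.path(out_dir, paste0(id, "_peaks.csv")), row.names = FALSE)
    gdf <- res$ganglia
    gdf <- cbind(data.frame(image_id = rep(id, nrow(gdf))), gdf)
    utils::write.csv(gdf, file.path(out_dir, paste0(id, "_ganglia.csv")),
                     row.names = FALSE)
    write_label_tiff(res$label_image, file.path(out_dir, paste0(id, "_label.tif")))
    write_overlay_png(render_overlay(res$image, res$label_image, res$peaks),
                      file.path(out_dir, paste0(id, "_overlay.png")))
    rows[[id]] <- data.frame(image_id = id, n_neurons = res$n_neurons,
                             n_ganglia = res$n_ganglia,
                             n_extraganglionic = res$n_extraganglionic,
                             height = res$image$height, width = res$image$width,
                             rho = rho)
    message(sprintf("%s: %d neurons, %d ganglia, %d extraganglionic",
                    id, res$n_neurons, res$n_ganglia, res$n_extraganglionic))
  }
  summary_df <- do.call(rbind, rows)
  if (!is.null(summary_df))
    utils::write.csv(summary_df, file.path(out_dir, "summary.csv"), row.names = FALSE)
  eff <- list(rho = rho, delta_m = default_min_distance(rho), eps_m = default_eps(rho))
  extra <- list(...)
  eff[names(extra)] <- extra
  manifest <- list(version = as.character(utils::packageVersion("plexuscount")),
                   parameters = eff, inputs = inputs, failures = failures)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (length(failures) > 0)
    warning(length(failures), " image(s) failed; see manifest.json")
  invisible(structure(summary_df, n_failed = length(failures)))
}

#' Aggregate per-image results into plexus metrics
#'
#' Pools the ganglia of one tissue (one or more images from [run_count()]
#' output, or a directory containing its CSVs) and writes
#' \code{metrics.json}/\code{metrics.csv}, \code{size_histogram.csv}
#' (bin_start, bin_end, frequency) and, when at least \code{min_fit}
#' ganglia are available, \code{nb_fit.json} (r, p, shift, loglik).
#'
#' @param count_dir directory written by [run_count()].
#' @param area_mm2 explicit tissue area; default computed from the imaged
#'   pixel extents and rho via [image_area_mm2()].
#' @param out_dir output directory; defaults to \code{count_dir}.
#' @param min_fit minimum ganglia for the negative-binomial fit
#'   (default 30).
#' @return The \code{plexus_metrics} object, invisibly.
#' @export
run_metrics <- function(count_dir, area_mm2 = NULL, out_dir = count_dir,
                        min_fit = 30L) {
  sfile <- file.path(count_dir, "summary.csv")
  if (!file.exists(sfile)) stop("no summary.csv in ", count_dir)
  summ <- utils::read.csv(sfile)
  if (nrow(summ) == 0L) stop("empty summary")
  if (length(unique(summ$rho)) != 1L)
    stop("inconsistent rho across images of one tissue")
  sizes <- integer(0)
  for (id in summ$image_id) {
    g <- utils::read.csv(file.path(count_dir, paste0(id, "_ganglia.csv")))
    sizes <- c(sizes, g$size)
  }
  if (is.null(area_mm2))
    area_mm2 <- sum(image_area_mm2(summ$height, summ$width, summ$rho[1]))
  met <- compute_metrics(sizes, sum(summ$n_extraganglionic), area_mm2)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(met)[c("n_neurons", "n_ganglia", "n_extraganglionic",
                                      "area_mm2", "neuronal_density",
                                      "ganglionic_density", "mean_ganglion_size")],
                       file.path(out_dir, "metrics.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.csv(data.frame(n_neurons = met$n_neurons, n_ganglia = met$n_ganglia,
                              n_extraganglionic = met$n_extraganglionic,
                              area_mm2 = met$area_mm2,
                              neuronal_density = met$neuronal_density,
                              ganglionic_density = met$ganglionic_density,
                              mean_ganglion_size = met$mean_ganglion_size),
                   file.path(out_dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(size_histogram(sizes),
                   file.path(out_dir, "size_histogram.csv"), row.names = FALSE)
  if (length(sizes) >= min_fit && stats::var(sizes) > 0) {
    fit <- fit_shifted_negative_binomial(sizes)
    jsonlite::write_json(list(r = fit$r, p = fit$p, shift = fit$shift,
                              loglik = fit$log_likelihood),
                         file.path(out_dir, "nb_fit.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(met)
}

#' Generate and write a synthetic fixture
#'
#' Writes the rendered image (\code{fixture.tif} and \code{fixture.png}),
#' the ground truth (\code{truth.csv}: neuron_id, row, col, cluster_label;
#' empty label = extraganglionic) and the parameters
#' (\code{params.json}). Deterministic per seed.
#'
#' @param params a \code{\link{fixture_params}} object.
#' @param out_dir output directory.
#' @return List with the ground truth and rendered image, invisibly.
#' @export
run_fixture <- function(params, out_dir) {
  gt <- sample_layout(params)
  img <- render_image(gt, params)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  top <- 2^params$bit_depth - 1
  tiff::writeTIFF(img$pixels / top, file.path(out_dir, "fixture.tif"),
                  bits.per.sample = params$bit_depth)
  png::writePNG(img$pixels / top, file.path(out_dir, "fixture.png"))
  utils::write.csv(data.frame(neuron_id = seq_len(nrow(gt$neurons)) - 1L,
                              row = gt$neurons$row, col = gt$neurons$col,
                              cluster_label = gt$neurons$cluster_label),
                   file.path(out_dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(params), file.path(out_dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(ground_truth = gt, image = img))
}
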