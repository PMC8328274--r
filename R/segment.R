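# Step 4: output segmentation. The binarized image is flooded from the
# ganglion peaks so that only the identified ganglia remain as labeled
# regions; everything else (background, debris, extraganglionic somata)
# is flooded to background.

#' Watershed-style segmentation of ganglia
#'
#' Connected foreground components of the mask are kept only if they
#' contain at least one ganglion member peak; kept components are then
#' partitioned among the ganglia seeded there by geodesic flooding
#' (EBImage's Voronoi propagation restricted to the mask), so that a single
#' foreground blob shared by two ganglia is split between them. All member
#' peaks of one ganglion carry the same seed label.
#'
#' @param mask a \code{foreground_mask}.
#' @param peaks the \code{\link{peak_set}} of detected neurons.
#' @param labeling the \code{cluster_labeling} for those peaks.
#' @return Integer label matrix of the mask's shape: 0 = background,
#'   k > 0 = ganglion k's region.
#' @export
watershed_segment <- function(mask, peaks, labeling) {
  stopifnot(inherits(mask, "foreground_mask"), inherits(peaks, "peak_set"),
            inherits(labeling, "cluster_labeling"))
  if (length(labeling$labels) != nrow(peaks$coordinates))
    stop("labeling and peak set refer to different numbers of neurons")
  m <- mask$mask
  out <- matrix(0L, nrow(m), ncol(m))
  lab <- labeling$labels
  keep <- !is.na(lab)
  if (!any(keep)) return(out)  # zero ganglia: all background
  # seed image: rounded member-peak pixels, labeled by ganglion id
  sr <- pmin(pmax(round(peaks$coordinates$row[keep]) + 1L, 1L), nrow(m))
  sc <- pmin(pmax(round(peaks$coordinates$col[keep]) + 1L, 1L), ncol(m))
  seeds <- matrix(0L, nrow(m), ncol(m))
  seeds[cbind(sr, sc)] <- lab[keep]
  # drop foreground components containing no ganglion peak
  comp <- EBImage::bwlabel(m * 1)
  seeded_comps <- setdiff(unique(comp[seeds > 0L]), 0L)
  m2 <- matrix(comp %in% seeded_comps, nrow(m), ncol(m))
  if (!any(m2)) return(out)
  seeds[!m2] <- 0L
  flooded <- EBImage::propagate(matrix(0, nrow(m), ncol(m)), seeds, mask = m2 * 1)
  out[] <- as.integer(round(flooded))
  out[!m2] <- 0L
  out
}

# Deterministic palette: ganglion id -> RGB via golden-ratio hue stepping
ganglion_color <- function(id) {
  hue <- (id * 0.6180339887498949) %% 1
  grDevices::col2rgb(grDevices::hsv(hue, s = 0.85, v = 1)) / 255
}

#' Render an RGB overlay of the segmentation
#'
#' The grayscale image is reproduced in RGB with each ganglion region
#' tinted a distinct, deterministic color (hue derived from the ganglion
#' id) and a marker dot drawn at every detected neuron centroid. With zero
#' ganglia the grayscale image is returned in RGB unchanged.
#'
#' @param img single-channel \code{\link{intensity_image}} (original or
#'   smoothed) used as the base layer.
#' @param label_img integer label matrix from [watershed_segment()].
#' @param peaks the \code{\link{peak_set}}; pass an empty peak set to omit
#'   markers.
#' @return Numeric array height x width x 3 with values in [0, 1].
#' @export
render_overlay <- function(img, label_img, peaks) {
  stopifnot(inherits(img, "intensity_image"))
  if (!identical(dim(label_img), dim(img$pixels)))
    stop("label image shape does not match image shape")
  g <- img$pixels
  rng <- range(g)
  g <- if (rng[2] > rng[1]) (g - rng[1]) / (rng[2] - rng[1]) else g * 0
  out <- array(g, dim = c(nrow(g), ncol(g), 3L))
  for (id in setdiff(sort(unique(as.vector(label_img))), 0L)) {
    rgbc <- ganglion_color(id)
    sel <- label_img == id
    for (ch in 1:3)
      out[, , ch][sel] <- 0.45 * g[sel] + 0.55 * rgbc[ch]
  }
  if (nrow(peaks$coordinates) > 0) {
    pr <- pmin(pmax(round(peaks$coordinates$row) + 1L, 1L), nrow(g))
    pc <- pmin(pmax(round(peaks$coordinates$col) + 1L, 1L), ncol(g))
    out[cbind(pr, pc, 1L)] <- 1; out[cbind(pr, pc, 2L)] <- 1; out[cbind(pr, pc, 3L)] <- 1
  }
  out
}

#' Write a label image as a 16-bit single-channel TIFF
#' @param label_img integer label matrix (values < 65536).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_label_tiff <- function(label_img, path) {
  if (max(label_img) > 65535L) stop("more than 65535 labels cannot be stored in 16-bit")
  tiff::writeTIFF(label_img / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write an RGB overlay as a PNG
#' @param overlay array from [render_overlay()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_overlay_png <- function(overlay, path) {
  png::writePNG(overlay, path)
  invisible(path)
}
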