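# Step 2: neuron identification. Neuron centroids are local maxima of the
# smoothed image within a circular neighborhood of radius delta_m, restricted
# to the foreground mask; co-neighborhood peaks are replaced by their mean.

#' Default minimum peak separation delta_m
#'
#' The minimum distance between detected neuron centroids, in pixels:
#' \code{delta_m = 2.5 um * rho}. Can be overridden for other imaging
#' protocols.
#'
#' @param rho pixel density (pixels/um, > 0).
#' @return delta_m in pixels.
#' @export
default_min_distance <- function(rho) {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0)
    stop("'rho' must be a single positive number (pixels/um)")
  2.5 * rho
}

#' Construct a peak set
#'
#' @param coordinates data.frame with numeric columns \code{row}, \code{col}
#'   (0-based pixel coordinates; fractional after averaging).
#' @param shape integer vector \code{c(height, width)} of the source image.
#' @param delta_m minimum separation used (pixels).
#' @return Object of class \code{peak_set}.
#' @export
peak_set <- function(coordinates, shape, delta_m) {
  coordinates <- as.data.frame(coordinates)
  stopifnot(all(c("row", "col") %in% names(coordinates)))
  if (nrow(coordinates) > 0) {
    if (any(coordinates$row < 0 | coordinates$row >= shape[1] |
            coordinates$col < 0 | coordinates$col >= shape[2]))
      stop("peak coordinates out of image bounds")
  }
  structure(list(coordinates = coordinates[, c("row", "col"), drop = FALSE],
                 shape = as.integer(shape), delta_m = as.numeric(delta_m)),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks in a %d x %d image (delta_m = %g px)\n",
              nrow(x$coordinates), x$shape[1], x$shape[2], x$delta_m))
  invisible(x)
}

# Integer offsets (dy, dx) with 0 < dy^2 + dx^2 <= r^2
disc_offsets <- function(r) {
  m <- floor(r)
  g <- expand.grid(dy = -m:m, dx = -m:m)
  g <- g[g$dy^2 + g$dx^2 <= r^2 & !(g$dy == 0 & g$dx == 0), , drop = FALSE]
  g
}

# Maximum over the circular neighborhood (excluding the pixel itself),
# out-of-image neighbors ignored (-Inf).
neighborhood_max <- function(x, r) {
  off <- disc_offsets(r)
  h <- nrow(x); w <- ncol(x)
  out <- matrix(-Inf, h, w)
  for (i in seq_len(nrow(off))) {
    dy <- off$dy[i]; dx <- off$dx[i]
    sr <- max(1L, 1L - dy):min(h, h - dy)   # dest rows with a valid source
    sc <- max(1L, 1L - dx):min(w, w - dx)
    out[sr, sc] <- pmax(out[sr, sc], x[sr + dy, sc + dx, drop = FALSE])
  }
  out
}

#' Detect neuron centroids as local intensity maxima
#'
#' Returns all pixels of the smoothed image that are maxima of their
#' circular neighborhood of radius \code{delta_m}, restricted to the
#' foreground mask, then merges co-neighborhood peaks by averaging
#' (see [merge_neighborhood_peaks()]). Plateaus of equal maximal intensity
#' yield their centroid through the same averaging rule. Deterministic for
#' a fixed input: candidate pixels are enumerated in row-major order.
#'
#' @param smoothed single-channel smoothed \code{\link{intensity_image}}.
#' @param mask \code{foreground_mask} of the same shape.
#' @param delta_m minimum peak separation in pixels (>= 1); default
#'   \code{2.5 * rho}.
#' @return A \code{\link{peak_set}}; empty if the mask has no foreground.
#' @export
detect_peaks <- function(smoothed, mask, delta_m = default_min_distance(smoothed$rho)) {
  stopifnot(inherits(smoothed, "intensity_image"), inherits(mask, "foreground_mask"))
  if (!identical(dim(mask$mask), dim(smoothed$pixels)))
    stop("mask shape does not match image shape")
  if (!is.numeric(delta_m) || length(delta_m) != 1L || !is.finite(delta_m) || delta_m < 1)
    stop("'delta_m' must be a single number >= 1 (pixels)")
  x <- smoothed$pixels
  is_peak <- (x >= neighborhood_max(x, delta_m)) & mask$mask
  idx <- which(t(is_peak))  # transpose -> row-major enumeration
  if (length(idx) == 0L)
    return(peak_set(data.frame(row = numeric(0), col = numeric(0)),
                    c(smoothed$height, smoothed$width), delta_m))
  w <- smoothed$width
  raw <- data.frame(row = (idx - 1L) %/% w, col = (idx - 1L) %% w)  # 0-based
  merge_neighborhood_peaks(raw, delta_m, shape = c(smoothed$height, smoothed$width))
}

#' Merge peaks that share a neighborhood
#'
#' Peaks closer than \code{delta_m} are grouped transitively (connected
#' components of the within-delta_m graph) and each group replaced by the
#' arithmetic mean of its coordinates. Because averaging can itself bring
#' two group means within \code{delta_m}, merging is iterated to a fixed
#' point, after which every retained pair is separated by at least
#' \code{delta_m}.
#'
#' @param raw_peaks data.frame with columns \code{row}, \code{col}
#'   (0-based pixels).
#' @param delta_m minimum separation (pixels, >= 1).
#' @param shape optional \code{c(height, width)} recorded in the result;
#'   inferred from the peaks if missing.
#' @return A \code{\link{peak_set}}.
#' @export
merge_neighborhood_peaks <- function(raw_peaks, delta_m, shape = NULL) {
  if (!is.numeric(delta_m) || length(delta_m) != 1L || !is.finite(delta_m) || delta_m < 1)
    stop("'delta_m' must be a single number >= 1 (pixels)")
  pts <- as.data.frame(raw_peaks)
  if (is.null(shape))
    shape <- c(floor(max(0, pts$row)) + 1L, floor(max(0, pts$col)) + 1L)
  repeat {
    n <- nrow(pts)
    if (n <= 1L) break
    d <- as.matrix(stats::dist(pts[, c("row", "col")]))
    adj <- d < delta_m
    comp <- graph_components(adj)
    if (max(comp) == n) break  # all singletons: fixed point
    pts <- data.frame(
      row = as.numeric(tapply(pts$row, comp, mean)),
      col = as.numeric(tapply(pts$col, comp, mean))
    )
  }
  # deterministic row-major output order
  pts <- pts[order(pts$row, pts$col), , drop = FALSE]
  rownames(pts) <- NULL
  peak_set(pts, shape, delta_m)
}

# Connected components of an adjacency matrix (logical, symmetric,
# diagonal TRUE/FALSE irrelevant); returns integer component labels.
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}
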