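#' Intensity image container
#'
#' Bundles a raster of pixel intensities with the pixel density of the
#' imaging setup. Intensities are held as numeric values on the native scale
#' of the source file (0--255 for 8-bit, 0--65535 for 16-bit); all processing
#' is done in floating point regardless of source bit depth.
#'
#' @param pixels numeric matrix (grayscale) or height x width x 3 array (RGB)
#'   of finite, non-negative intensities.
#' @param rho pixel density in pixels per micrometer (> 0); set by the
#'   imaging protocol (objective and camera pixel pitch).
#' @return An object of class \code{intensity_image} with elements
#'   \code{pixels}, \code{height}, \code{width}, \code{channels}, \code{rho}.
#' @export
intensity_image <- function(pixels, rho) {
  if (is.matrix(pixels)) {
    channels <- 1L
    h <- nrow(pixels); w <- ncol(pixels)
  } else if (is.array(pixels) && length(dim(pixels)) == 3L) {
    if (dim(pixels)[3] != 3L)
      stop("unsupported format: expected 1 or 3 channels, got ", dim(pixels)[3])
    channels <- 3L
    h <- dim(pixels)[1]; w <- dim(pixels)[2]
  } else {
    stop("unsupported format: 'pixels' must be a 2-D matrix or an RGB array (3-D image stacks are not supported)")
  }
  if (h < 1L || w < 1L) stop("image must have positive extent")
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0)
    stop("'rho' (pixel density, pixels/um) must be a single positive number")
  if (anyNA(pixels) || !all(is.finite(pixels)))
    stop("pixel intensities must all be finite")
  if (min(pixels) < 0)
    stop("pixel intensities must be non-negative")
  structure(
    list(pixels = pixels, height = h, width = w, channels = channels,
         rho = as.numeric(rho)),
    class = "intensity_image"
  )
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image> %d x %d px, %d channel(s), rho = %g px/um\n",
              x$height, x$width, x$channels, x$rho))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Load a micrograph from a TIFF or PNG file
#'
#' Reads an 8- or 16-bit, single- or 3-channel image and attaches the
#' user-supplied pixel density. Intensities are returned on the native
#' integer scale of the file (0--255 or 0--65535). Multi-page TIFFs
#' (Z-stacks) and images with more than 3 channels are rejected: the
#' pipeline operates on single 2-D fields or stitched 2-D mosaics only.
#'
#' @param path path to a \code{.tif}/\code{.tiff} or \code{.png} file.
#' @param rho pixel density (pixels/um) of the imaging protocol.
#' @return An \code{\link{intensity_image}}.
#' @export
load_image <- function(path, rho) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("cannot read image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- if (ext %in% c("tif", "tiff")) {
    infos <- tryCatch(as.data.frame(tiff::readTIFF(path, payload = FALSE, all = TRUE)),
                      error = function(e) stop("cannot read image '", path, "': ", conditionMessage(e)))
    if (nrow(infos) > 1L)
      stop("unsupported format: '", path, "' is a multi-page TIFF; 3-D image data are not supported")
    bits <- infos$bits.per.sample[1L]
    if (is.null(bits) || is.na(bits)) bits <- 8L
    raw <- tiff::readTIFF(path)  # rescaled to [0,1]; restore native scale
    if (bits <= 16L) round(raw * (2^bits - 1)) else raw * (2^bits - 1)
  } else if (ext == "png") {
    raw <- tryCatch(png::readPNG(path, info = TRUE),
                    error = function(e) stop("cannot read image '", path, "': ", conditionMessage(e)))
    info <- attr(raw, "info")
    depth <- if (!is.null(info) && !is.null(info$bit.depth)) info$bit.depth else 8L
    raw * (2^depth - 1)  # readPNG rescales to [0,1]; restore native scale
  } else {
    stop("cannot read image '", path, "': unsupported extension '", ext,
         "' (expected tif/tiff/png)")
  }
  nd <- length(dim(px))
  if (nd == 3L && dim(px)[3] > 3L)
    stop("unsupported format: '", path, "' has ", dim(px)[3],
         " channels; at most 3 (RGB) are supported")
  if (nd == 3L && dim(px)[3] == 2L)  # gray + alpha: drop alpha
    px <- px[, , 1L]
  if (nd == 3L && !is.na(dim(px)[3]) && dim(px)[3] == 1L)
    px <- px[, , 1L]
  intensity_image(px, rho)
}

#' Convert an RGB image to a single grayscale channel
#'
#' 3-channel images are combined with the Rec. 709 luma weights
#' (0.2126 R + 0.7152 G + 0.0722 B, summing to 1); single-channel images
#' pass through unchanged.
#'
#' @param img an \code{\link{intensity_image}}.
#' @return A single-channel \code{\link{intensity_image}}.
#' @export
to_grayscale <- function(img) {
  stopifnot(inherits(img, "intensity_image"))
  if (img$channels == 1L) return(img)
  w <- grayscale_weights()
  gray <- w[1] * img$pixels[, , 1] + w[2] * img$pixels[, , 2] + w[3] * img$pixels[, , 3]
  intensity_image(gray, img$rho)
}

#' Rec. 709 luma weights used by [to_grayscale()]
#' @return Named numeric vector of length 3 summing to 1.
#' @export
grayscale_weights <- function() c(r = 0.2126, g = 0.7152, b = 0.0722)
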