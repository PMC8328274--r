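# Plexus-level structural metrics: neuronal/ganglionic densities, mean
# ganglion size, ganglia-size histogram (bin width 3), shifted
# negative-binomial model of ganglion size, and manual-vs-automated
# concordance regression.

#' Imaged area in square millimeters
#'
#' Converts a pixel extent to physical area:
#' \code{(height/rho) * (width/rho) / 1e6} mm^2.
#'
#' @param height,width image extent in pixels (> 0).
#' @param rho pixel density (pixels/um, > 0).
#' @return Area in mm^2.
#' @export
image_area_mm2 <- function(height, width, rho) {
  if (any(c(height, width, rho) <= 0) || any(!is.finite(c(height, width, rho))))
    stop("height, width and rho must all be positive")
  (height / rho) * (width / rho) / 1e6
}

#' Compute plexus-level structural metrics
#'
#' Neuronal density counts every detected neuron, ganglionic or not;
#' ganglia statistics exclude extraganglionic neurons. With zero ganglia
#' both densities that involve ganglia are 0 and the mean size is \code{NA}.
#'
#' @param ganglia data.frame with a \code{size} column (one row per
#'   ganglion, sizes >= min cluster size), or a bare numeric vector of
#'   ganglion sizes.
#' @param n_extraganglionic count of extraganglionic neurons.
#' @param area_mm2 imaged tissue area in mm^2 (> 0), e.g. from
#'   [image_area_mm2()].
#' @return Object of class \code{plexus_metrics}: counts, densities
#'   (neurons/mm^2, ganglia/mm^2), ganglia sizes and mean size.
#' @export
compute_metrics <- function(ganglia, n_extraganglionic = 0L, area_mm2) {
  sizes <- if (is.data.frame(ganglia)) ganglia$size else as.numeric(ganglia)
  if (!is.numeric(area_mm2) || length(area_mm2) != 1L || !is.finite(area_mm2) || area_mm2 <= 0)
    stop("'area_mm2' must be a single positive number")
  if (n_extraganglionic < 0) stop("'n_extraganglionic' must be >= 0")
  n_g <- length(sizes)
  n_n <- sum(sizes) + n_extraganglionic
  structure(list(
    n_neurons = as.integer(n_n),
    n_ganglia = as.integer(n_g),
    n_extraganglionic = as.integer(n_extraganglionic),
    area_mm2 = area_mm2,
    neuronal_density = n_n / area_mm2,
    ganglionic_density = n_g / area_mm2,
    ganglia_sizes = as.integer(sizes),
    mean_ganglion_size = if (n_g > 0) sum(sizes) / n_g else NA_real_
  ), class = "plexus_metrics")
}

#' @export
print.plexus_metrics <- function(x, ...) {
  cat(sprintf("<plexus_metrics> %d neurons in %d ganglia (+%d extraganglionic) over %.2f mm^2\n",
              x$n_neurons, x$n_ganglia, x$n_extraganglionic, x$area_mm2))
  cat(sprintf("  neuronal density:   %.2f neurons/mm^2\n", x$neuronal_density))
  cat(sprintf("  ganglionic density: %.2f ganglia/mm^2\n", x$ganglionic_density))
  if (!is.na(x$mean_ganglion_size))
    cat(sprintf("  mean ganglion size: %.2f neurons/ganglion\n", x$mean_ganglion_size))
  invisible(x)
}

#' Ganglia-size frequency histogram
#'
#' Frequencies over contiguous bins of width \code{bin_width} neurons per
#' ganglion, starting at size 3 (bins [3-5], [6-8], ...). Interior empty
#' bins are reported with frequency 0; frequencies sum to the number of
#' ganglia.
#'
#' @param ganglia_sizes integer sizes, all >= 3.
#' @param bin_width bin width in neurons (default 3).
#' @return data.frame with \code{bin_start}, \code{bin_end},
#'   \code{frequency}; zero rows for an empty input.
#' @export
size_histogram <- function(ganglia_sizes, bin_width = 3L) {
  if (length(ganglia_sizes) == 0L)
    return(data.frame(bin_start = integer(0), bin_end = integer(0), frequency = integer(0)))
  if (any(ganglia_sizes < 3))
    stop("ganglion sizes below 3 are inconsistent with the minimum cluster size")
  bw <- as.integer(bin_width)
  idx <- (as.integer(ganglia_sizes) - 3L) %/% bw
  freq <- tabulate(idx + 1L, nbins = max(idx) + 1L)
  starts <- 3L + bw * (seq_along(freq) - 1L)
  data.frame(bin_start = starts, bin_end = starts + bw - 1L, frequency = freq)
}

#' Fit a shifted negative-binomial model of ganglion size
#'
#' Maximum-likelihood fit of the negative binomial
#' \eqn{P(K=k) = C(k+r-1, k) p^r (1-p)^k} to the shifted sizes
#' \eqn{k = size - 3} (a ganglion has at least 3 neurons, so the support
#' starts at 0 after shifting). The mean is matched analytically (for fixed
#' r the MLE of the mean is the sample mean) and the dispersion r is found
#' by a deterministic one-dimensional profile-likelihood optimization over
#' log r on [1e-6, 1e6]; \eqn{p = r / (r + \bar k)}.
#'
#' @param ganglia_sizes integer sizes, all >= 3; at least 30 recommended
#'   for a stable dispersion estimate.
#' @param shift the minimum ganglion size subtracted before fitting
#'   (default 3).
#' @return Object of class \code{nb_fit}: list with \code{r}, \code{p},
#'   \code{shift}, \code{log_likelihood}, \code{mean_size} (fitted model
#'   mean + shift).
#' @export
fit_shifted_negative_binomial <- function(ganglia_sizes, shift = 3L) {
  k <- as.numeric(ganglia_sizes) - shift
  if (length(k) < 2L) stop("need at least 2 sizes to fit")
  if (any(k < 0)) stop("all sizes must be >= the shift (", shift, ")")
  if (stats::var(k) == 0)
    stop("degenerate input: all ganglion sizes equal; the size distribution has no variance to model")
  mbar <- mean(k)
  if (mbar == 0) stop("degenerate input: all shifted sizes are zero")
  nll <- function(logr) -sum(stats::dnbinom(k, size = exp(logr), mu = mbar, log = TRUE))
  opt <- stats::optimize(nll, interval = log(c(1e-6, 1e6)), tol = 1e-10)
  r <- exp(opt$minimum)
  p <- r / (r + mbar)
  structure(list(r = r, p = p, shift = as.integer(shift),
                 log_likelihood = -opt$objective,
                 mean_size = mbar + shift),
            class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf("<nb_fit> size ~ %d + NB(r = %.3f, p = %.4f), logLik = %.2f, fitted mean size = %.2f\n",
              x$shift, x$r, x$p, x$log_likelihood, x$mean_size))
  invisible(x)
}

#' Concordance regression of automated against manual counts
#'
#' Ordinary least-squares fit \code{auto = slope * manual + intercept} with
#' the coefficient of determination, quantifying agreement between the
#' automated pipeline and a trained human rater on paired per-image (or
#' per-ganglion) neuron counts.
#'
#' @param auto_counts,manual_counts equal-length numeric vectors, n >= 3.
#' @return Object of class \code{concordance_fit}: \code{slope},
#'   \code{intercept}, \code{r_squared}.
#' @export
concordance_regression <- function(auto_counts, manual_counts) {
  if (length(auto_counts) != length(manual_counts))
    stop("paired count vectors must have equal length")
  if (length(auto_counts) < 3L) stop("need at least 3 pairs")
  if (stats::var(manual_counts) == 0)
    stop("manual counts have zero variance; regression is undefined")
  fit <- stats::lm(auto_counts ~ manual_counts)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared),
            class = "concordance_fit")
}

#' @export
print.concordance_fit <- function(x, ...) {
  cat(sprintf("<concordance_fit> auto = %.4f * manual + %.4f (r^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}
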