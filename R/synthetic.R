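# Synthetic-micrograph generator with known ground truth. Emulates bright
# soma-like blobs grouped into ganglia (>= 3 members, intra-cluster spacing
# below eps_m, inter-cluster gaps above separation_factor * eps_m) on a dim
# noisy background, so every pipeline stage can be scored without
# microscopy data.

# Intra-ganglion geometry (micrometers): somata sit on a jittered hexagonal
# lattice. Spacing and jitter are chosen so that pairwise distances stay
# above one soma diameter (no overlap) and nearest-neighbor distances stay
# below the default eps_m = 20.6 um, keeping every planted ganglion
# DBSCAN-connected.
.hex_spacing_um <- 17
.hex_jitter_um <- 1.0

#' Parameters of a synthetic fixture
#'
#' @param image_shape integer \code{c(height, width)} in pixels.
#' @param rho pixel density (pixels/um); default 1.5442, a typical 20x
#'   widefield pixel pitch (~0.65 um/pixel).
#' @param n_ganglia number of ganglia to plant.
#' @param size_law either \code{list(type = "nb", r, p)} for ganglion sizes
#'   drawn as \code{3 + NB(r, p)} (default r = 0.58, p = 0.035, the shifted
#'   negative-binomial law of ileal myenteric ganglion size), or
#'   \code{list(type = "fixed", sizes = c(...))}.
#' @param n_extraganglionic number of isolated neurons planted farther than
#'   \code{separation_factor * eps_m} from every other neuron.
#' @param soma_radius_um soma radius (um); default 7 (soma diameter ~14 um,
#'   plausible for murine myenteric neurons).
#' @param soma_peak_intensity,background_intensity intensity units on the
#'   rendered bit scale (defaults 200 and 10 on 8-bit).
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (intensity units; 0 = noise-free).
#' @param separation_factor inter-ganglion gaps exceed
#'   \code{separation_factor * eps_m} (> 1; default 2).
#' @param bit_depth 8 (default) or 16.
#' @param seed integer seed controlling both layout and noise.
#' @return A \code{fixture_params} list.
#' @export
fixture_params <- function(image_shape = c(1024L, 1024L),
                           rho = 1.5442,
                           n_ganglia = 8L,
                           size_law = list(type = "nb", r = 0.58, p = 0.035),
                           n_extraganglionic = 5L,
                           soma_radius_um = 7,
                           soma_peak_intensity = 200,
                           background_intensity = 10,
                           noise_sd = 0,
                           separation_factor = 2,
                           bit_depth = 8L,
                           seed = 1L) {
  if (soma_peak_intensity <= background_intensity)
    stop("soma_peak_intensity must exceed background_intensity")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (separation_factor <= 1) stop("separation_factor must be > 1")
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  structure(list(image_shape = as.integer(image_shape), rho = rho,
                 n_ganglia = as.integer(n_ganglia), size_law = size_law,
                 n_extraganglionic = as.integer(n_extraganglionic),
                 soma_radius_um = soma_radius_um,
                 soma_peak_intensity = soma_peak_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, separation_factor = separation_factor,
                 bit_depth = as.integer(bit_depth), seed = as.integer(seed)),
            class = "fixture_params")
}

draw_sizes <- function(law, n) {
  if (identical(law$type, "fixed")) {
    if (length(law$sizes) != n) stop("size_law$sizes must have length n_ganglia")
    as.integer(law$sizes)
  } else if (identical(law$type, "nb")) {
    3L + stats::rnbinom(n, size = law$r, prob = law$p)
  } else stop("unknown size_law type: ", law$type)
}

# n points on a jittered hex lattice (um), nearest-to-origin first
hex_cluster_offsets <- function(n, spacing = .hex_spacing_um, jitter = .hex_jitter_um) {
  m <- ceiling(sqrt(n)) + 2L
  g <- expand.grid(i = -m:m, j = -m:m)
  x <- (g$i + 0.5 * (g$j %% 2)) * spacing
  y <- g$j * spacing * sqrt(3) / 2
  ord <- order(x^2 + y^2)
  x <- x[ord][seq_len(n)]; y <- y[ord][seq_len(n)]
  cbind(row = y + stats::runif(n, -jitter, jitter),
        col = x + stats::runif(n, -jitter, jitter))
}

#' Sample a ground-truth neuron layout
#'
#' Ganglion sizes are drawn from the size law; member somata are laid out
#' on jittered hexagonal lattices (intra-ganglion nearest-neighbor spacing
#' below \code{eps_m}, no soma overlap); ganglion centers are placed by
#' rejection sampling so that inter-ganglion gaps between member somata
#' exceed \code{separation_factor * eps_m}; extraganglionic neurons are
#' placed farther than that from every other neuron. Fully determined by
#' the seed.
#'
#' @param params a \code{\link{fixture_params}} object.
#' @return Object of class \code{synthetic_ground_truth}: data.frame
#'   \code{neurons} (row, col in 0-based pixels; cluster_label, \code{NA} =
#'   extraganglionic), plus rho, image_shape, soma_radius_um, seed, params.
#' @export
sample_layout <- function(params) {
  stopifnot(inherits(params, "fixture_params"))
  set.seed(params$seed)
  rho <- params$rho
  eps_px <- default_eps(rho)
  soma_px <- params$soma_radius_um * rho
  h <- params$image_shape[1]; w <- params$image_shape[2]
  sizes <- draw_sizes(params$size_law, params$n_ganglia)
  offsets <- lapply(sizes, function(n) hex_cluster_offsets(n) * rho)  # px
  radii <- vapply(offsets, function(o) max(sqrt(o[, 1]^2 + o[, 2]^2)), numeric(1))
  gap <- params$separation_factor * eps_px
  centers <- matrix(numeric(0), 0, 2)
  max_tries <- 5000L
  for (g in seq_len(params$n_ganglia)) {
    margin <- radii[g] + soma_px + 1
    if (2 * margin >= min(h, w))
      stop("capacity: ganglion ", g, " (radius ", round(radii[g]), " px) does not fit; ",
           "use a larger image or fewer/smaller ganglia")
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      cand <- c(stats::runif(1, margin, h - 1 - margin),
                stats::runif(1, margin, w - 1 - margin))
      ok <- TRUE
      if (nrow(centers) > 0) {
        dd <- sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)
        ok <- all(dd > radii[seq_len(g - 1L)] + radii[g] + gap)
      }
      if (ok) { centers <- rbind(centers, cand); placed <- TRUE; break }
    }
    if (!placed)
      stop("capacity: could not place ganglion ", g, " after ", max_tries,
           " attempts; use a larger image or fewer ganglia")
  }
  neurons <- do.call(rbind, lapply(seq_len(params$n_ganglia), function(g) {
    data.frame(row = centers[g, 1] + offsets[[g]][, 1],
               col = centers[g, 2] + offsets[[g]][, 2],
               cluster_label = g)
  }))
  if (is.null(neurons)) neurons <- data.frame(row = numeric(0), col = numeric(0),
                                              cluster_label = integer(0))
  # extraganglionic: isolated from every neuron by more than the same gap
  for (e in seq_len(params$n_extraganglionic)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      cand <- c(stats::runif(1, soma_px + 1, h - 2 - soma_px),
                stats::runif(1, soma_px + 1, w - 2 - soma_px))
      dd <- sqrt((neurons$row - cand[1])^2 + (neurons$col - cand[2])^2)
      if (all(dd > gap)) {
        neurons <- rbind(neurons, data.frame(row = cand[1], col = cand[2],
                                             cluster_label = NA_integer_))
        placed <- TRUE; break
      }
    }
    if (!placed)
      stop("capacity: could not place extraganglionic neuron ", e,
           "; use a larger image or fewer neurons")
  }
  rownames(neurons) <- NULL
  structure(list(neurons = neurons, rho = rho,
                 image_shape = params$image_shape,
                 soma_radius_um = params$soma_radius_um,
                 seed = params$seed, params = params),
            class = "synthetic_ground_truth")
}

#' @export
print.synthetic_ground_truth <- function(x, ...) {
  cat(sprintf("<synthetic_ground_truth> %d neurons (%d ganglia, %d extraganglionic) in %d x %d px (seed %d)\n",
              nrow(x$neurons), length(unique(stats::na.omit(x$neurons$cluster_label))),
              sum(is.na(x$neurons$cluster_label)),
              x$image_shape[1], x$image_shape[2], x$seed))
  invisible(x)
}

#' Render a synthetic micrograph from a ground-truth layout
#'
#' Each soma is rendered as a radially decaying bright spot (Gaussian
#' profile with standard deviation half the soma radius, so the intensity
#' at the nominal soma edge has fallen to ~13% of the peak) on a uniform
#' background; independent Gaussian pixel noise is added and intensities
#' are clipped and rounded to the output bit range. Deterministic given the
#' ground truth's seed.
#'
#' @param gt a \code{synthetic_ground_truth} from [sample_layout()].
#' @param params the \code{\link{fixture_params}} used for the layout.
#' @return An \code{\link{intensity_image}} on the native integer scale.
#' @export
render_image <- function(gt, params = gt$params) {
  stopifnot(inherits(gt, "synthetic_ground_truth"))
  h <- gt$image_shape[1]; w <- gt$image_shape[2]
  img <- matrix(params$background_intensity, h, w)
  sd_px <- params$soma_radius_um * gt$rho / 2
  amp <- params$soma_peak_intensity - params$background_intensity
  r <- ceiling(4 * sd_px)
  for (i in seq_len(nrow(gt$neurons))) {
    cr <- gt$neurons$row[i] + 1  # 1-based continuous
    cc <- gt$neurons$col[i] + 1
    rows <- max(1L, floor(cr - r)):min(h, ceiling(cr + r))
    cols <- max(1L, floor(cc - r)):min(w, ceiling(cc + r))
    d2 <- outer((rows - cr)^2, (cols - cc)^2, "+")
    img[rows, cols] <- img[rows, cols] + amp * exp(-d2 / (2 * sd_px^2))
  }
  if (params$noise_sd > 0) {
    set.seed((gt$seed %% 2000000000L) + 1L)  # noise stream tied to the layout seed
    img <- img + stats::rnorm(length(img), 0, params$noise_sd)
  }
  top <- 2^params$bit_depth - 1
  img <- round(pmin(pmax(img, 0), top))
  intensity_image(img, gt$rho)
}

#' Score detected peaks against ground truth
#'
#' Greedy nearest-first one-to-one matching of detected peaks to true
#' neuron positions within a tolerance: candidate pairs are sorted by
#' distance and accepted while both members are unmatched. Precision =
#' matched/detected (NA when nothing was detected), recall = matched/true.
#'
#' @param gt a \code{synthetic_ground_truth}.
#' @param peaks a \code{\link{peak_set}}.
#' @param tol matching tolerance in pixels (> 0); default one soma radius.
#' @return List: \code{precision}, \code{recall}, \code{n_matched},
#'   \code{matching} (data.frame peak_idx, truth_idx, distance).
#' @export
score_detection <- function(gt, peaks, tol = gt$soma_radius_um * gt$rho) {
  stopifnot(inherits(gt, "synthetic_ground_truth"), inherits(peaks, "peak_set"))
  if (tol <= 0) stop("'tol' must be > 0")
  tp <- gt$neurons; dp <- peaks$coordinates
  n_true <- nrow(tp); n_det <- nrow(dp)
  matching <- data.frame(peak_idx = integer(0), truth_idx = integer(0),
                         distance = numeric(0))
  if (n_true > 0 && n_det > 0) {
    d <- outer(dp$row, tp$row, "-")^2 + outer(dp$col, tp$col, "-")^2
    cand <- which(d <= tol^2, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      used_p <- logical(n_det); used_t <- logical(n_true)
      for (i in seq_len(nrow(cand))) {
        p <- cand[i, 1]; tr <- cand[i, 2]
        if (!used_p[p] && !used_t[tr]) {
          used_p[p] <- TRUE; used_t[tr] <- TRUE
          matching <- rbind(matching,
                            data.frame(peak_idx = p, truth_idx = tr,
                                       distance = sqrt(d[p, tr])))
        }
      }
    }
  }
  m <- nrow(matching)
  list(precision = if (n_det > 0) m / n_det else NA_real_,
       recall = if (n_true > 0) m / n_true else NA_real_,
       n_matched = m, matching = matching)
}

#' Pairwise co-clustering agreement with ground truth
#'
#' Over all pairs of matched neurons, the fraction whose co-membership
#' (same ganglion versus not; extraganglionic neurons count as "not in the
#' same ganglion" with everything) agrees between the planted and the
#' recovered labeling. 1.0 means the recovered partition equals the planted
#' partition on the matched neurons.
#'
#' @param gt a \code{synthetic_ground_truth}.
#' @param labeling a \code{cluster_labeling} for the detected peaks.
#' @param matching the matching data.frame from [score_detection()].
#' @return Agreement fraction in [0, 1]; NA with fewer than 2 matched
#'   neurons.
#' @export
score_clustering <- function(gt, labeling, matching) {
  stopifnot(inherits(gt, "synthetic_ground_truth"), inherits(labeling, "cluster_labeling"))
  m <- nrow(matching)
  if (m < 2L) return(NA_real_)
  tl <- gt$neurons$cluster_label[matching$truth_idx]
  pl <- labeling$labels[matching$peak_idx]
  same <- function(v) {
    s <- outer(v, v, function(a, b) !is.na(a) & !is.na(b) & a == b)
    s[upper.tri(s)]
  }
  mean(same(tl) == same(pl))
}
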