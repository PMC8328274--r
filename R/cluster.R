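# Step 3: clustering detected neurons into ganglia with DBSCAN.
# A ganglion is a cluster of at least Ng (default 3) neurons; DBSCAN noise
# points are reported as extraganglionic neurons.

#' Default DBSCAN neighborhood radius eps_m
#'
#' The minimum separation defining distinct ganglia, in pixels:
#' \code{eps_m = 20.6 um * rho}. Can be overridden for other imaging
#' protocols.
#'
#' @param rho pixel density (pixels/um, > 0).
#' @return eps_m in pixels.
#' @export
default_eps <- function(rho) {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0)
    stop("'rho' must be a single positive number (pixels/um)")
  20.6 * rho
}

#' Cluster neuron centroids into ganglia with DBSCAN
#'
#' Standard DBSCAN semantics on Euclidean pixel distances: a point is a
#' core point when at least \code{min_pts} points (counting itself) lie
#' within \code{eps}; clusters are maximal density-connected sets of core
#' points plus the border points reachable from them; remaining points are
#' noise and labeled extraganglionic (\code{NA}). With \code{min_pts = 3},
#' three mutually close neurons form a minimal ganglion. Points are
#' processed in row-major sorted order so that the assignment of border
#' points reachable from two clusters is deterministic (they join the
#' cluster discovered first).
#'
#' @param peaks a \code{\link{peak_set}}.
#' @param eps neighborhood radius in pixels (> 0); default
#'   \code{20.6 * rho} via [default_eps()].
#' @param min_pts minimum neurons per ganglion Ng (>= 1, default 3).
#' @return Object of class \code{cluster_labeling}: list with integer
#'   vector \code{labels} (ganglion ids 1..k, \code{NA} = extraganglionic),
#'   \code{eps}, \code{min_pts}, \code{n_ganglia}, \code{n_extraganglionic}.
#' @export
cluster_dbscan <- function(peaks, eps, min_pts = 3L) {
  stopifnot(inherits(peaks, "peak_set"))
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) || eps <= 0)
    stop("'eps' must be a single positive number (pixels)")
  if (!is.numeric(min_pts) || length(min_pts) != 1L || min_pts < 1)
    stop("'min_pts' must be >= 1")
  min_pts <- as.integer(min_pts)
  pts <- peaks$coordinates
  n <- nrow(pts)
  labels <- rep(NA_integer_, n)
  if (n > 0L) {
    ord <- order(pts$row, pts$col)  # deterministic row-major processing
    d <- as.matrix(stats::dist(pts))
    nbhd <- d <= eps  # includes self (diagonal 0 <= eps)
    core <- rowSums(nbhd) >= min_pts
    cur <- 0L
    for (s in ord) {
      if (!is.na(labels[s]) || !core[s]) next
      cur <- cur + 1L
      labels[s] <- cur
      seeds <- which(nbhd[s, ] & is.na(labels))
      labels[seeds] <- cur
      queue <- seeds[core[seeds]]
      while (length(queue) > 0L) {
        v <- queue[[1L]]; queue <- queue[-1L]
        reach <- which(nbhd[v, ] & is.na(labels))
        labels[reach] <- cur
        queue <- c(queue, reach[core[reach]])
      }
    }
  }
  structure(list(labels = labels, eps = as.numeric(eps), min_pts = min_pts,
                 n_ganglia = if (all(is.na(labels))) 0L else max(labels, na.rm = TRUE),
                 n_extraganglionic = sum(is.na(labels))),
            class = "cluster_labeling")
}

#' @export
print.cluster_labeling <- function(x, ...) {
  cat(sprintf("<cluster_labeling> %d neurons: %d ganglia, %d extraganglionic (eps = %g px, Ng = %d)\n",
              length(x$labels), x$n_ganglia, x$n_extraganglionic, x$eps, x$min_pts))
  invisible(x)
}

#' Tabulate ganglia from a cluster labeling
#'
#' One row per ganglion with its size (neuron count) and centroid; the
#' extraganglionic count is carried alongside. Extraganglionic neurons
#' contribute to total neuron counts but to no ganglion statistic.
#'
#' @param labeling a \code{cluster_labeling} from [cluster_dbscan()].
#' @param peaks the \code{\link{peak_set}} that was clustered.
#' @return List with \code{ganglia} (data.frame: ganglion_id, size,
#'   centroid_row, centroid_col), \code{n_neurons}, \code{n_ganglia},
#'   \code{n_extraganglionic}.
#' @export
summarize_clusters <- function(labeling, peaks) {
  stopifnot(inherits(labeling, "cluster_labeling"), inherits(peaks, "peak_set"))
  if (length(labeling$labels) != nrow(peaks$coordinates))
    stop("labeling and peak set refer to different numbers of neurons")
  lab <- labeling$labels
  pts <- peaks$coordinates
  ids <- sort(unique(lab[!is.na(lab)]))
  ganglia <- data.frame(
    ganglion_id = ids,
    size = vapply(ids, function(k) sum(lab == k, na.rm = TRUE), integer(1)),
    centroid_row = vapply(ids, function(k) mean(pts$row[!is.na(lab) & lab == k]), numeric(1)),
    centroid_col = vapply(ids, function(k) mean(pts$col[!is.na(lab) & lab == k]), numeric(1))
  )
  list(ganglia = ganglia,
       n_neurons = length(lab),
       n_ganglia = length(ids),
       n_extraganglionic = sum(is.na(lab)))
}
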