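# Subtractive clustering: data-driven selection of fuzzy rule centers.
#
# Every candidate center is a data point; its "potential" is a sum of
# Gaussian kernels over all points, so dense neighbourhoods score high. The
# single radius-of-influence parameter sets the kernel width and hence the
# granularity (smaller radius -> more clusters -> more rules).

#' Subtractive-clustering parameters
#'
#' @param radius radius of influence r_a in unit-box coordinates, (0, 1].
#'   The neighbourhood size that governs cluster granularity; 0.15 is the
#'   default working value for this system.
#' @param squash ratio r_b / r_a (> 1) widening the potential-subtraction
#'   neighbourhood around an accepted center, which discourages centers
#'   crowding each other.
#' @param accept_ratio fraction of the first (largest) potential above which
#'   a candidate is accepted outright.
#' @param reject_ratio fraction of the first potential below which the
#'   candidate search stops.
#' @return object of class `subclust_params`.
#' @export
subclust_params <- function(radius = 0.15, squash = 1.25,
                            accept_ratio = 0.5, reject_ratio = 0.15) {
  if (!(radius > 0)) stopf("radius must be positive")
  if (!(squash > 1)) stopf("squash must exceed 1")
  if (!(reject_ratio > 0 && reject_ratio < accept_ratio && accept_ratio < 1)) {
    stopf("need 0 < reject_ratio < accept_ratio < 1")
  }
  structure(list(radius = radius, squash = squash,
                 accept_ratio = accept_ratio, reject_ratio = reject_ratio),
            class = "subclust_params")
}

#' Affine map of points into the unit box
#'
#' Each dimension is mapped to \[0, 1\] by its own min and max so that the
#' radius of influence has a common meaning across heterogeneous features.
#' A constant dimension maps to 0.5 everywhere.
#'
#' @param points numeric matrix, one row per point.
#' @return list with `points` (scaled matrix) and `box` (list `min`, `max`
#'   per dimension, for inversion via [unscale_from_unit_box()]).
#' @export
scale_to_unit_box <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) == 0) stopf("cannot scale an empty point set")
  lo <- apply(points, 2, min)
  hi <- apply(points, 2, max)
  span <- hi - lo
  scaled <- points
  for (d in seq_len(ncol(points))) {
    scaled[, d] <- if (span[d] > 0) (points[, d] - lo[d]) / span[d] else 0.5
  }
  list(points = scaled, box = list(min = lo, max = hi))
}

#' Invert [scale_to_unit_box()]
#'
#' @param scaled matrix of unit-box points.
#' @param box the `box` element returned by [scale_to_unit_box()].
#' @return matrix in the original coordinates (constant dimensions are
#'   restored to their constant value).
#' @export
unscale_from_unit_box <- function(scaled, box) {
  scaled <- as.matrix(scaled)
  out <- scaled
  span <- box$max - box$min
  for (d in seq_len(ncol(scaled))) {
    out[, d] <- if (span[d] > 0) scaled[, d] * span[d] + box$min[d] else box$min[d]
  }
  out
}

#' Mountain potentials of unit-scaled points
#'
#' `P_i = sum_j exp(-alpha * ||x_i - x_j||^2)` with `alpha = 4 / radius^2`:
#' a point surrounded by many near neighbours (within roughly one radius)
#' has high potential. The self term guarantees `P_i >= 1`.
#'
#' @param points unit-scaled numeric matrix.
#' @param radius radius of influence.
#' @return numeric vector of potentials.
#' @export
compute_potentials <- function(points, radius) {
  points <- as.matrix(points)
  if (!(radius > 0)) stopf("radius must be positive")
  alpha <- 4 / radius^2
  d2 <- as.matrix(stats::dist(points))^2
  unname(rowSums(exp(-alpha * d2)))
}

#' Subtractive clustering
#'
#' Iteratively picks the highest-potential point as a cluster center, then
#' subtracts from every point an amount `P* exp(-beta ||x - x*||^2)` with
#' `beta = 4 / (squash * radius)^2`, suppressing potential near the new
#' center. Candidates above `accept_ratio * P1` are accepted; below
#' `reject_ratio * P1` the search stops; in between, a candidate is accepted
#' iff `d_min / radius + P / P1 >= 1` (far enough from existing centers or
#' strong enough), otherwise its potential is zeroed and the search
#' continues. Ties on equal potentials resolve to the lowest row index.
#'
#' @param points numeric matrix of data points in their native coordinates
#'   (unit-box scaling is applied internally).
#' @param params a [subclust_params()] object.
#' @return object of class `cluster_set`: `centers` (rows of `points`),
#'   `unit_centers`, `potentials` (at the moment of selection, strictly
#'   decreasing), `indices` (row indices into `points`), `box`, `params`.
#' @export
subtractive_cluster <- function(points, params = subclust_params()) {
  points <- as.matrix(points)
  if (nrow(points) == 0) stopf("cannot cluster an empty point set")
  sc <- scale_to_unit_box(points)
  U <- sc$points
  P <- compute_potentials(U, params$radius)
  P1 <- max(P)
  beta <- 4 / (params$squash * params$radius)^2

  idx <- integer(0)
  pots <- numeric(0)
  repeat {
    k <- which.max(P) # ties -> lowest index
    pk <- P[k]
    if (length(idx) == 0) {
      accept <- TRUE
    } else if (pk >= params$accept_ratio * P1) {
      accept <- TRUE
    } else if (pk < params$reject_ratio * P1) {
      break
    } else {
      dmin <- sqrt(min(row_dist2(U[idx, , drop = FALSE], U[k, ])))
      accept <- (dmin / params$radius + pk / P1) >= 1
      if (!accept) {
        P[k] <- 0
        next
      }
    }
    idx <- c(idx, k)
    pots <- c(pots, pk)
    P <- P - pk * exp(-beta * row_dist2(U, U[k, ]))
    if (length(idx) >= nrow(U)) break
  }
  structure(list(centers = points[idx, , drop = FALSE],
                 unit_centers = U[idx, , drop = FALSE],
                 potentials = pots, indices = idx,
                 box = sc$box, params = params),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("Subtractive clustering: %d centers (radius %.3g)\n",
              length(x$indices), x$params$radius))
  invisible(x)
}
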