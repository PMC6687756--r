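#' Place-cell encoding and action decoding adapters
#'
#' Observations from an environment are translated into input-layer activity
#' by a population of place cells with Gaussian tuning curves (continuous
#' observations) or non-overlapping one-hot tuning (discrete states).  In
#' the opposite direction the activity of output units is decoded into an
#' action by taking the most active unit, thresholding, or a linear
#' read-out.  Adapters are deliberately small and composable.
#'
#' @name coding
NULL

#' Grid layout of place cells over a box of observations
#'
#' Centers form the Cartesian product of evenly spaced per-dimension grids
#' (endpoints included); the tuning width in each dimension is
#' \code{width_scale} times the grid spacing of that dimension.  A single
#' cell per dimension is centred in the middle of the interval and its
#' width is \code{width_scale} times the interval length.
#'
#' @param bounds list (or 2-column matrix) of per-dimension \code{c(low, high)}.
#' @param n_per_dim integer number of cells per dimension (recycled).
#' @param width_scale tuning width as a multiple of the grid spacing.
#' @param peak maximal response of a cell (at its centre).
#' @return An object of class \code{place_layout} with fields
#'   \code{centers} (n_cells x n_dims), \code{widths}, \code{peak}.
#' @export
make_grid_layout <- function(bounds, n_per_dim, width_scale = 1, peak = 1) {
  if (is.matrix(bounds)) bounds <- asplit(bounds, 1)
  nd <- length(bounds)
  n_per_dim <- rep_len(as.integer(n_per_dim), nd)
  stopifnot(nd >= 1, all(n_per_dim >= 1), width_scale > 0, peak > 0)
  grids <- vector("list", nd)
  widths <- numeric(nd)
  for (d in seq_len(nd)) {
    lo <- bounds[[d]][1]; hi <- bounds[[d]][2]
    if (!(lo < hi)) stop("degenerate bounds in dimension ", d)
    k <- n_per_dim[d]
    if (k == 1) {
      grids[[d]] <- (lo + hi) / 2
      widths[d] <- width_scale * (hi - lo)
    } else {
      grids[[d]] <- seq(lo, hi, length.out = k)
      widths[d] <- width_scale * (hi - lo) / (k - 1)
    }
  }
  centers <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  dimnames(centers) <- NULL
  structure(list(centers = centers, widths = widths, peak = peak),
            class = "place_layout")
}

#' Gaussian place-cell response to an observation
#'
#' Cell \eqn{k} responds with
#' \eqn{a_k = A \exp(-\sum_d (s_d - c_{kd})^2 / (2 \sigma_d^2))}
#' where \eqn{A} is the peak response, \eqn{c_k} the cell's centre and
#' \eqn{\sigma_d} the per-dimension tuning width.  Observations outside the
#' layout's bounds are encoded through the Gaussian tails, not clipped.
#'
#' @param obs numeric observation vector (length = layout dimensions).
#' @param layout a \code{place_layout}.
#' @return Activity vector of length \code{nrow(layout$centers)}, in
#'   \code{(0, peak]}.
#' @export
encode <- function(obs, layout) {
  obs <- as.numeric(obs)
  if (length(obs) != ncol(layout$centers))
    stop("observation dimension does not match layout")
  d2 <- sweep(layout$centers, 2, obs)          # c_kd - s_d
  d2 <- sweep(d2^2, 2, 2 * layout$widths^2, "/")
  layout$peak * exp(-rowSums(d2))
}

#' One-hot encoding of a discrete state
#'
#' Discrete environments use non-overlapping tuning: exactly one input cell
#' responds (at peak) per state.
#'
#' @param index state id in \code{0:(n_states - 1)}.
#' @param n_states number of discrete states.
#' @param peak response of the active cell.
#' @return Numeric vector of length \code{n_states}.
#' @export
encode_discrete <- function(index, n_states, peak = 1) {
  index <- as.integer(index)
  if (is.na(index) || index < 0 || index >= n_states)
    stop("state index out of range")
  out <- numeric(n_states)
  out[index + 1L] <- peak
  out
}

#' Decode an action as the most active unit
#'
#' @param activities numeric vector of unit activities (non-empty).
#' @param tie_rule \code{"lowest_index"} (default, deterministic) or
#'   \code{"random"} (uniform over the tied maxima, global RNG).
#' @return 0-based index of the selected unit.
#' @export
argmax_decode <- function(activities, tie_rule = c("lowest_index", "random")) {
  tie_rule <- match.arg(tie_rule)
  if (length(activities) == 0) stop("empty activity vector")
  m <- max(activities)
  idx <- which(activities == m)
  sel <- if (tie_rule == "lowest_index" || length(idx) == 1) idx[1]
         else idx[sample.int(length(idx), 1)]
  as.integer(sel - 1L)
}

#' Threshold decoder
#'
#' Elementwise strict Heaviside of (activity - thr): 1 only for activities
#' strictly above the threshold.
#'
#' @param activities numeric vector.
#' @param thr threshold.
#' @return 0/1 vector of the same length.
#' @export
threshold_decode <- function(activities, thr) {
  heaviside(activities - thr)
}

#' Linear decoder
#'
#' Continuous read-out \code{D \%*\% activities}, e.g. to drive continuous
#' actuators from a population code.
#'
#' @param D decoding matrix (outputs x units).
#' @param activities numeric vector of unit activities.
#' @return Numeric vector of length \code{nrow(D)}.
#' @export
linear_decode <- function(D, activities) {
  D <- as.matrix(D)
  if (ncol(D) != length(activities)) stop("dimension mismatch")
  drop(D %*% activities)
}
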