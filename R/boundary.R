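#' Gaussian kernel density estimate on a fixed 512-point grid
#'
#' Computes the Gaussian KDE exactly (direct summation at every grid
#' point) using the classical rule-of-thumb bandwidth
#' `0.9 * min(sd, IQR/1.34) * n^(-1/5)` scaled by `adjust`, on an
#' equally spaced 512-point grid spanning the data extended by 3
#' bandwidths on either side. These are the defaults of the standard R
#' density estimator, pinned operationally so that results are
#' reproducible to machine precision.
#'
#' @param values Numeric vector (at least 3 finite values with nonzero
#'   spread).
#' @param adjust Positive bandwidth multiplier.
#' @param n_grid Number of grid points.
#' @param cut Grid extension in bandwidths beyond the data range.
#' @return Object of class `density_curve`: list with `grid`, `density`,
#'   `bandwidth`, `adjust`, `n`.
#' @export
kde <- function(values, adjust = 1, n_grid = 512L, cut = 3) {
  values <- values[is.finite(values)]
  if (length(values) < 3) stop("need at least 3 finite values")
  if (adjust <= 0) stop("adjust must be positive")
  if (sd(values) == 0) {
    stop("zero spread: bandwidth undefined")
  }
  bw <- adjust * nrd0_bandwidth(values)
  grid <- seq(min(values) - cut * bw, max(values) + cut * bw,
              length.out = n_grid)
  # direct summation: density(x) = mean_i dnorm(x, values[i], bw)
  dens <- rowMeans(outer(grid, values,
                         function(g, v) dnorm(g, mean = v, sd = bw)))
  structure(list(grid = grid, density = dens, bandwidth = bw,
                 adjust = adjust, n = length(values)),
            class = "density_curve")
}

# Silverman/Scott rule of thumb as implemented by the standard default:
# 0.9 * min(sd, IQR/1.34) * n^(-1/5), falling back to sd if the IQR is
# zero (degenerate quartiles with positive overall spread).
nrd0_bandwidth <- function(values) {
  n <- length(values)
  spread <- min(sd(values), IQR(values) / 1.34)
  if (spread == 0) spread <- sd(values)
  0.9 * spread * n^(-1 / 5)
}

#' @export
print.density_curve <- function(x, ...) {
  cat(sprintf(
    "<density_curve> n=%d, bandwidth=%.4g (adjust=%.2g), grid [%.4g, %.4g]\n",
    x$n, x$bandwidth, x$adjust, min(x$grid), max(x$grid)))
  invisible(x)
}

restrict_curve <- function(curve, lo, hi) {
  stopifnot(lo < hi)
  idx <- which(curve$grid >= lo & curve$grid <= hi)
  list(grid = curve$grid[idx], density = curve$density[idx])
}

#' Lowest qualifying local minimum of a density curve in a range
#'
#' Restricts the curve to `[lo, hi]` and returns the abscissa of the
#' interior grid point with the lowest density among those whose density
#' is `<=` both neighbours. Ties are broken toward the lower abscissa.
#' Returns `NA` when the restricted curve is monotone (no interior
#' local minimum).
#'
#' A candidate must additionally look like a genuine between-mode
#' valley rather than a sampling wiggle:
#' * it must split off at least `min_side_mass` of the curve's total
#'   probability mass on each side (trapezoidal integral over the full
#'   grid) — a boundary between two groups has to separate a
#'   non-trivial fraction of the pairwise values, and near-empty
#'   density tails otherwise masquerade as minima at small bandwidths;
#' * its density must dip by at least `prominence` below the smaller
#'   of the two flanking density maxima (taken over the full curve,
#'   since a mode may legitimately lie outside the search window) —
#'   shallow shoulders on the flank of a single mode are sampling
#'   noise, while genuine valleys in well-separated mixtures dip far
#'   below both peaks.
#'
#' @param curve A `density_curve` from [kde()].
#' @param lo,hi Search range (percent AAI by default).
#' @param min_side_mass Minimum fraction of total mass required on
#'   each side of a qualifying minimum.
#' @param prominence Minimum relative dip: a candidate with density
#'   `d0` qualifies only if `d0 <= (1 - prominence) * min(peak_left,
#'   peak_right)`.
#' @return Abscissa of the minimum, or `NA_real_`.
#' @export
local_minimum <- function(curve, lo = 60, hi = 80,
                          min_side_mass = 0.05, prominence = 0.4) {
  stopifnot(lo < hi)
  idx <- which(curve$grid >= lo & curve$grid <= hi)
  k <- length(idx)
  if (k < 3) return(NA_real_)
  d <- curve$density[idx]
  interior <- 2:(k - 1)
  is_min <- d[interior] <= d[interior - 1] & d[interior] <= d[interior + 1]
  cand <- interior[is_min]
  if (length(cand) == 0) return(NA_real_)
  # cumulative trapezoidal mass along the full curve
  steps <- diff(curve$grid) *
    (curve$density[-length(curve$density)] + curve$density[-1]) / 2
  cum <- c(0, cumsum(steps))
  total <- cum[length(cum)]
  n_grid <- length(curve$density)
  keep <- vapply(cand, function(ci) {
    gi <- idx[ci]
    left <- cum[gi] / total
    if (left < min_side_mass || (1 - left) < min_side_mass) {
      return(FALSE)
    }
    peak_l <- max(curve$density[1:gi])
    peak_r <- max(curve$density[gi:n_grid])
    curve$density[gi] <= (1 - prominence) * min(peak_l, peak_r)
  }, logical(1))
  cand <- cand[keep]
  if (length(cand) == 0) return(NA_real_)
  best <- cand[order(d[cand], curve$grid[idx[cand]])][1]
  curve$grid[idx[best]]
}

#' Count strict local maxima of a density curve in a range
#'
#' @inheritParams local_minimum
#' @param values Numeric data; the curve is computed at `adjust = 1`.
#' @param adjust Bandwidth multiplier for the reported curve.
#' @return List with `n_modes` and `mode_positions`.
#' @export
bimodality_report <- function(values, lo = 60, hi = 80, adjust = 1) {
  curve <- kde(values, adjust = adjust)
  r <- restrict_curve(curve, lo, hi)
  k <- length(r$grid)
  if (k < 3) return(list(n_modes = 0L, mode_positions = numeric()))
  d <- r$density
  interior <- 2:(k - 1)
  is_max <- d[interior] > d[interior - 1] & d[interior] > d[interior + 1]
  pos <- r$grid[interior[is_max]]
  list(n_modes = length(pos), mode_positions = pos)
}

#' Boundary estimate with bandwidth sensitivity sweep
#'
#' Runs [kde()] + [local_minimum()] for each bandwidth adjustment in
#' `adjusts` and summarizes the sensitivity of the detected boundary.
#' The headline estimate `minimum_at` is the local minimum of the
#' `adjust = 1` curve; `sweep_interval` is the range of minima found
#' across the sweep (adjustments yielding no minimum are ignored). When
#' no adjustment yields a minimum the estimate carries a no-boundary
#' flag, mirroring distributions without a clear bimodal pattern.
#'
#' @param values Numeric vector of pooled pairwise values (each
#'   unordered pair counted once).
#' @param adjusts Bandwidth multipliers to sweep.
#' @param lo,hi Search range for the minimum.
#' @return Object of class `threshold_estimate`: list with
#'   `minimum_at`, `search_lo`, `search_hi`, `sweep_interval`,
#'   `n_modes_in_range`, `adjusts`, `minima`, `bandwidth`,
#'   `no_boundary`.
#' @export
bandwidth_sweep <- function(values, adjusts = seq(0.5, 2.0, by = 0.1),
                            lo = 60, hi = 80) {
  minima <- vapply(adjusts, function(adj) {
    local_minimum(kde(values, adjust = adj), lo, hi)
  }, numeric(1))
  found <- minima[!is.na(minima)]
  ref <- kde(values, adjust = 1)
  modes <- bimodality_report(values, lo, hi)
  at_one <- which(abs(adjusts - 1) < 1e-9)
  minimum_at <- if (length(at_one) == 1) minima[at_one]
                else local_minimum(ref, lo, hi)
  structure(list(
    minimum_at = minimum_at,
    search_lo = lo, search_hi = hi,
    sweep_interval = if (length(found) > 0) range(found)
                     else c(NA_real_, NA_real_),
    n_modes_in_range = modes$n_modes,
    adjusts = adjusts,
    minima = minima,
    bandwidth = ref$bandwidth,
    no_boundary = length(found) == 0
  ), class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  if (x$no_boundary) {
    cat("<threshold_estimate> no boundary detected in [",
        x$search_lo, ",", x$search_hi, "]\n")
  } else {
    cat(sprintf(
      "<threshold_estimate> minimum at %.2f (sweep %.2f-%.2f, %d mode(s) in [%g, %g])\n",
      x$minimum_at, x$sweep_interval[1], x$sweep_interval[2],
      x$n_modes_in_range, x$search_lo, x$search_hi))
  }
  invisible(x)
}
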