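# Laminar quantification of labeled neurons along the cortical depth axis.
# Depth is normalized per section: 0 = ventricular surface, 1 = pial
# surface (normalization is the caller's responsibility). The Ctip2-positive
# interval anchors the deep-layer subregion.

#' Depth-intensity profile along the cortical wall
#'
#' A 1-D profile of signal (e.g. GFP intensity, or unit mass per labeled
#' cell) versus normalized cortical depth, together with the Ctip2-positive
#' depth interval that defines the deep layers. Per-cell depth lists are
#' supported directly by passing the depths as `positions` with unit
#' `intensity`.
#'
#' @param positions Numeric vector of depths in \[0, 1\] (0 = ventricle,
#'   1 = pia).
#' @param intensity Nonnegative signal per position (recycled; default 1,
#'   i.e. one cell per position).
#' @param ctip2_interval Length-2 increasing numeric within \[0, 1\].
#' @return Object of class `depth_profile`.
#' @export
depth_profile <- function(positions, intensity = 1, ctip2_interval = c(0.25, 0.55)) {
  if (!is.numeric(positions) || any(positions < 0 | positions > 1)) {
    stop_circscape("positions must lie in [0, 1]", "circscape_data_error")
  }
  intensity <- rep_len(intensity, length(positions))
  if (any(intensity < 0)) {
    stop_circscape("intensity must be nonnegative", "circscape_data_error")
  }
  if (!is.numeric(ctip2_interval) || length(ctip2_interval) != 2L ||
      ctip2_interval[1] >= ctip2_interval[2] ||
      ctip2_interval[1] < 0 || ctip2_interval[2] > 1) {
    stop_circscape("ctip2_interval must be an increasing interval within [0, 1]",
                   "circscape_parameter_error")
  }
  structure(list(positions = positions, intensity = intensity,
                 ctip2_interval = as.numeric(ctip2_interval)),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("depth_profile: %d points, total mass %.4g, Ctip2 interval [%.3g, %.3g]\n",
              length(x$positions), sum(x$intensity),
              x$ctip2_interval[1], x$ctip2_interval[2]))
  invisible(x)
}

#' Percentage of signal per depth bin
#'
#' Splits the depth axis into `n_bins` equal intervals and reports the
#' percentage of total signal per bin, with bin 1 the pia-most bin and bin
#' `n_bins` the ventricle-most (so retention near the ventricle shows up in
#' the high-numbered bins). Mass exactly on a bin boundary is assigned to
#' the pia-ward bin.
#'
#' @param profile A [depth_profile()].
#' @param n_bins Number of bins (default 10).
#' @return Numeric vector of length `n_bins` summing to 100, named
#'   `bin1`..`bin<n>`.
#' @export
bin_percentages <- function(profile, n_bins = 10) {
  stopifnot(inherits(profile, "depth_profile"))
  if (!is_count(n_bins) || n_bins < 1) {
    stop_circscape("n_bins must be a positive integer", "circscape_parameter_error")
  }
  total <- sum(profile$intensity)
  if (total <= 0) {
    stop_circscape("total signal is zero; bin percentages undefined",
                   "circscape_quantification_error")
  }
  # depth d falls in bin n_bins - floor(d * n_bins), clamped; boundary depths
  # (d * n_bins integer) land pia-ward by this formula.
  bin <- n_bins - floor(profile$positions * n_bins)
  bin[bin < 1L] <- 1L          # d = 1 exactly
  bin[bin > n_bins] <- n_bins  # d = 0 exactly
  mass <- vapply(seq_len(n_bins), function(k) sum(profile$intensity[bin == k]),
                 numeric(1))
  stats::setNames(100 * mass / total, paste0("bin", seq_len(n_bins)))
}

#' Percentage of signal per cortical subregion
#'
#' Reports the percentage of total signal in the upper layers
#' (UL, depths above the Ctip2-positive interval), the deep layers
#' (DL, the Ctip2-positive interval, inclusive) and the ventricular zone
#' (VZ, depths below it).
#'
#' @param profile A [depth_profile()].
#' @return Named numeric vector `c(UL, DL, VZ)` summing to 100.
#' @export
subregion_percentages <- function(profile) {
  stopifnot(inherits(profile, "depth_profile"))
  total <- sum(profile$intensity)
  if (total <= 0) {
    stop_circscape("total signal is zero; subregion percentages undefined",
                   "circscape_quantification_error")
  }
  lo <- profile$ctip2_interval[1]
  hi <- profile$ctip2_interval[2]
  d <- profile$positions
  ul <- sum(profile$intensity[d > hi])
  dl <- sum(profile$intensity[d >= lo & d <= hi])
  vz <- sum(profile$intensity[d < lo])
  100 * c(UL = ul, DL = dl, VZ = vz) / total
}
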