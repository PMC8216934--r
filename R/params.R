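#' Smoothing and detection parameters
#'
#' Bundles the tunable constants of the measurement pipeline. The two
#' parameters that matter most are `alpha` (contour smoothing) and `beta`
#' (curvature smoothing); both are *fractions of the raw contour point count*,
#' so the rectangular contour filter averages `2*floor(alpha*n) + 1` points and
#' the triangular curvature filter spans `2*floor(beta*n) + 1` points for a
#' contour of `n` points. They are normally calibrated with
#' [tune_smoothing()]; the defaults are the values selected by that
#' calibration on the original training set (alpha = 0.025, beta = 0.055).
#'
#' @param alpha Contour-smoothing fraction, in (0, 0.2]. The rectangular
#'   filter trims `floor(alpha*n)` points from each end of the contour.
#' @param beta Curvature-smoothing fraction, in (0, 0.2]. The triangular
#'   filter trims `floor(beta*n)` further points from each end of the
#'   curvature profile.
#' @param refine_threshold Curvature magnitude (1/um) below which the
#'   refinement stage widens its window to `round(1/|k|)` points; at or above
#'   it the window is `refine_cap` points.
#' @param refine_cap Refinement window (points) used where `|k| >=
#'   refine_threshold`.
#' @param exclusion_fraction Fraction of the smoothed-curvature profile
#'   excluded from landmark detection at each end (arc-length normalized);
#'   digitization start/end noise lives there.
#' @param midline_position Normalized abscissa treated as the contour's axis
#'   of symmetry when picking the central landmark. Empirically 0.475 rather
#'   than 0.5 because freehand digitization is slightly asymmetric.
#' @param min_prominence Optional minimum prominence (1/um) an extremum must
#'   have to be considered a landmark candidate; 0 disables the filter.
#'
#' @return An object of class `smoothing_params` (a named list).
#' @examples
#' smoothing_params()
#' smoothing_params(alpha = 0.01, beta = 0.02)
#' @export
smoothing_params <- function(alpha = 0.025,
                             beta = 0.055,
                             refine_threshold = 0.1,
                             refine_cap = 10,
                             exclusion_fraction = 0.20,
                             midline_position = 0.475,
                             min_prominence = 0) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 0.2) {
    abort("`alpha` must be a single number in (0, 0.2].")
  }
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 0 || beta > 0.2) {
    abort("`beta` must be a single number in (0, 0.2].")
  }
  if (!is.numeric(refine_threshold) || refine_threshold <= 0) {
    abort("`refine_threshold` must be a positive curvature (1/um).")
  }
  if (!is.numeric(refine_cap) || refine_cap < 1) {
    abort("`refine_cap` must be a window of at least 1 point.")
  }
  if (exclusion_fraction < 0 || exclusion_fraction >= 0.5) {
    abort("`exclusion_fraction` must be in [0, 0.5).")
  }
  if (midline_position < exclusion_fraction ||
      midline_position > 1 - exclusion_fraction) {
    abort(paste0(
      "`midline_position` must lie inside the admissible window [",
      exclusion_fraction, ", ", 1 - exclusion_fraction, "]."
    ))
  }
  if (min_prominence < 0) abort("`min_prominence` must be >= 0.")
  structure(
    list(
      alpha = alpha, beta = beta,
      refine_threshold = refine_threshold,
      refine_cap = as.integer(round(refine_cap)),
      exclusion_fraction = exclusion_fraction,
      midline_position = midline_position,
      min_prominence = min_prominence
    ),
    class = "smoothing_params"
  )
}

#' @export
print.smoothing_params <- function(x, ...) {
  cat("<smoothing_params>\n")
  cat(sprintf("  alpha (contour smoothing):   %.4g\n", x$alpha))
  cat(sprintf("  beta  (curvature smoothing): %.4g\n", x$beta))
  cat(sprintf("  refinement: 1/|k| window below %.3g 1/um, else %d points\n",
              x$refine_threshold, x$refine_cap))
  cat(sprintf("  landmark window: [%.3g, %.3g], midline %.3g\n",
              x$exclusion_fraction, 1 - x$exclusion_fraction,
              x$midline_position))
  invisible(x)
}

# margin trimmed from each side by a smoothing stage: floor(frac * n), >= 1
smoothing_margin <- function(frac, n) {
  max(1L, as.integer(floor(frac * n)))
}

# round half away from zero (used for the adaptive refinement window)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

as_smoothing_params <- function(params) {
  if (inherits(params, "smoothing_params")) return(params)
  if (is.list(params)) return(do.call(smoothing_params, params))
  abort("`params` must be created with `smoothing_params()`.")
}
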