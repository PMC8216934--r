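#' Local extrema of the smoothed curvature inside the admissible window
#'
#' Extrema are strict sign changes of the first difference of `k_smoothed`;
#' a plateau contributes its first index. The first and last
#' `exclusion_fraction` of the profile (normalized arc length over the
#' smoothed-curvature support) are excluded: curvature there is noisy and the
#' landmarks are never expected in it.
#'
#' @param profile Output of [curvature_profile()] (or [smooth_curvature()]).
#' @param params [smoothing_params()].
#' @return Tibble of candidate extrema sorted by index: columns `index`
#'   (smoothed-contour index), `s_norm` (abscissa normalized to \[0, 1\] over
#'   the smoothed-curvature support), `value` (`k_smoothed`), `kind`
#'   (`"maximum"` or `"minimum"`), `x`, `y` (micrometers).
#' @export
find_extrema <- function(profile, params = smoothing_params()) {
  params <- as_smoothing_params(params)
  if (!"k_smoothed" %in% names(profile)) {
    abort("`profile` lacks `k_smoothed`; run `smooth_curvature()` first.")
  }
  ok <- which(!is.na(profile$k_smoothed))
  if (length(ok) < 3) return(empty_extrema())
  v <- profile$k_smoothed[ok]
  s <- profile$s[ok]
  span <- s[length(s)] - s[1]
  s_norm <- if (span > 0) (s - s[1]) / span else rep(0, length(s))

  ext <- local_extrema(v)
  if (nrow(ext) == 0) return(empty_extrema())

  out <- tibble::tibble(
    index = profile$index[ok[ext$pos]],
    s_norm = s_norm[ext$pos],
    value = v[ext$pos],
    kind = ext$kind,
    x = profile$x[ok[ext$pos]],
    y = profile$y[ok[ext$pos]]
  )
  if (params$min_prominence > 0 && nrow(out) > 1) {
    prom <- vapply(seq_len(nrow(out)), function(i) {
      lo <- if (i > 1) abs(out$value[i] - out$value[i - 1]) else Inf
      hi <- if (i < nrow(out)) abs(out$value[i] - out$value[i + 1]) else Inf
      min(lo, hi)
    }, numeric(1))
    out <- out[prom >= params$min_prominence, ]
  }
  lo <- params$exclusion_fraction
  out <- out[out$s_norm >= lo & out$s_norm <= 1 - lo, ]
  out[order(out$index), ]
}

empty_extrema <- function() {
  tibble::tibble(
    index = integer(0), s_norm = numeric(0), value = numeric(0),
    kind = character(0), x = numeric(0), y = numeric(0)
  )
}

# strict local extrema of a numeric sequence; plateaus yield their first index
local_extrema <- function(v) {
  d <- sign(diff(v))
  idx <- which(d != 0)
  if (length(idx) < 2) {
    return(tibble::tibble(pos = integer(0), kind = character(0)))
  }
  sg <- d[idx]
  brk <- which(diff(sg) != 0)           # run boundaries among nonzero diffs
  if (length(brk) == 0) {
    return(tibble::tibble(pos = integer(0), kind = character(0)))
  }
  run_end <- idx[brk]                   # last diff index of each run but the final
  run_sign <- sg[brk]
  tibble::tibble(
    pos = run_end + 1L,                 # first index of the extremum plateau
    kind = ifelse(run_sign > 0, "maximum", "minimum")
  )
}

#' Assign the five ventral-branch landmarks from candidate extrema
#'
#' Applies the detection rules: landmark 3 is the curvature maximum closest
#' (in normalized abscissa) to the midline position; landmark 2 is the lowest
#' minimum left of landmark 3 and landmark 1 the maximum (left of landmark 2)
#' closest to landmark 2; symmetrically, landmark 4 is the lowest minimum
#' right of landmark 3 and landmark 5 the maximum (right of landmark 4)
#' closest to landmark 4. If more than one maximum then lies strictly between
#' landmarks 2 and 4, landmark 3 is reassigned to the highest of them. A
#' specimen whose profile lacks any of the five roles is excluded with a
#' reason, never silently imputed. Ties are broken toward the smaller index.
#'
#' @param extrema Tibble from [find_extrema()], sorted by index.
#' @param params [smoothing_params()].
#' @return A `branch_detection` object: list with `status` (`"valid"` or
#'   `"excluded"`), `landmarks` (tibble with columns `landmark`, `index`,
#'   `s_norm`, `value`, `kind`, `x`, `y` when valid, otherwise `NULL`) and
#'   `reason` (`NA` or the missing role).
#' @export
assign_landmarks <- function(extrema, params = smoothing_params()) {
  params <- as_smoothing_params(params)
  excluded <- function(reason) {
    structure(list(status = "excluded", landmarks = NULL, reason = reason),
              class = "branch_detection")
  }
  if (nrow(extrema) == 0) return(excluded("no-extrema"))
  maxima <- extrema[extrema$kind == "maximum", ]
  minima <- extrema[extrema$kind == "minimum", ]
  if (nrow(maxima) == 0) return(excluded("missing-L3"))

  pick_first <- function(tbl, ord) tbl[order(ord, tbl$index), ][1, ]

  l3 <- pick_first(maxima, abs(maxima$s_norm - params$midline_position))

  left_min <- minima[minima$index < l3$index, ]
  if (nrow(left_min) == 0) return(excluded("missing-L2"))
  l2 <- pick_first(left_min, left_min$value)

  left_max <- maxima[maxima$index < l2$index, ]
  if (nrow(left_max) == 0) return(excluded("missing-L1"))
  l1 <- pick_first(left_max, abs(left_max$s_norm - l2$s_norm))

  right_min <- minima[minima$index > l3$index, ]
  if (nrow(right_min) == 0) return(excluded("missing-L4"))
  l4 <- pick_first(right_min, right_min$value)

  right_max <- maxima[maxima$index > l4$index, ]
  if (nrow(right_max) == 0) return(excluded("missing-L5"))
  l5 <- pick_first(right_max, abs(right_max$s_norm - l4$s_norm))

  # resampling: with several maxima strictly between L2 and L4, take the highest
  between <- maxima[maxima$index > l2$index & maxima$index < l4$index, ]
  if (nrow(between) > 1) {
    l3 <- pick_first(between, -between$value)
  }

  lmk <- dplyr::bind_rows(l1, l2, l3, l4, l5)
  lmk <- dplyr::mutate(lmk, landmark = 1:5, .before = 1)
  if (any(diff(lmk$index) <= 0)) return(excluded("aberrant-ordering"))
  structure(list(status = "valid", landmarks = lmk, reason = NA_character_),
            class = "branch_detection")
}

#' Detect the five landmarks on a curvature profile
#'
#' Wrapper chaining [find_extrema()] and [assign_landmarks()].
#'
#' @param profile Output of [curvature_profile()].
#' @param params [smoothing_params()].
#' @return A `branch_detection` object (see [assign_landmarks()]).
#' @export
detect_landmarks <- function(profile, params = smoothing_params()) {
  params <- as_smoothing_params(params)
  assign_landmarks(find_extrema(profile, params), params)
}

#' @export
print.branch_detection <- function(x, ...) {
  cat("<branch_detection> status:", x$status)
  if (x$status == "excluded") cat("  reason:", x$reason)
  cat("\n")
  if (!is.null(x$landmarks)) print(x$landmarks)
  invisible(x)
}

#' @method tidy branch_detection
#' @export
tidy.branch_detection <- function(x, ...) {
  if (is.null(x$landmarks)) {
    return(tibble::tibble(
      landmark = integer(0), index = integer(0), s_norm = numeric(0),
      value = numeric(0), kind = character(0), x = numeric(0), y = numeric(0)
    ))
  }
  x$landmarks
}

#' Re-estimate the midline position from a set of curvature profiles
#'
#' An optional helper, not part of the original detection procedure: for a
#' new dataset the midline can be re-estimated as the mean normalized
#' abscissa of the global smoothed-curvature maximum across profiles. Use the
#' result as `midline_position` in [smoothing_params()].
#'
#' @param profiles List of curvature profiles.
#' @return A single normalized abscissa.
#' @export
estimate_midline <- function(profiles) {
  pos <- vapply(profiles, function(p) {
    ok <- which(!is.na(p$k_smoothed))
    if (length(ok) < 3) return(NA_real_)
    s <- p$s[ok]
    sn <- (s - s[1]) / (s[length(s)] - s[1])
    sn[which.max(p$k_smoothed[ok])]
  }, numeric(1))
  mean(pos, na.rm = TRUE)
}
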