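#' Signed curvature from the circumscribed circle of three points
#'
#' The curvature at `N` is the inverse of the circumradius of the triangle
#' `M N P`, signed by turn direction. The sign convention matches the rest of
#' the pipeline: with the contour in mathematical orientation (y up) and
#' traversed left to right, curvature is positive where the contour bulges
#' toward +Y (a clockwise turn), so spine peaks are curvature maxima and
#' cavities are minima. Collinear points have zero curvature; coincident
#' points are a degenerate-geometry error.
#'
#' @param M,N,P Numeric length-2 vectors `(x, y)`.
#' @return Signed curvature (1/um when coordinates are in um).
#' @examples
#' circumcircle_curvature(c(0, 0), c(1, 0), c(2, 0))   # collinear: 0
#' circumcircle_curvature(c(-1, 0), c(0, 1), c(1, 0))  # unit-circle arch: +1
#' @export
circumcircle_curvature <- function(M, N, P) {
  stopifnot(length(M) == 2, length(N) == 2, length(P) == 2)
  k <- circumcircle_curvature_vec(M[1], M[2], N[1], N[2], P[1], P[2])
  k
}

# vectorized core; clockwise-positive sign
circumcircle_curvature_vec <- function(xm, ym, xn, yn, xp, yp, where = NULL) {
  ax <- xn - xm
  ay <- yn - ym
  bx <- xp - xn
  by <- yp - yn
  mn <- sqrt(ax^2 + ay^2)
  np <- sqrt(bx^2 + by^2)
  pm <- sqrt((xm - xp)^2 + (ym - yp)^2)
  deg <- mn == 0 | np == 0 | pm == 0
  if (any(deg)) {
    i <- which(deg)[1]
    lab <- if (is.null(where)) i else where[i]
    abort(paste0("degenerate geometry: coincident points at index ", lab, "."))
  }
  cross <- ax * by - ay * bx
  -2 * cross / (mn * np * pm)
}

#' Rectangular smoothing of a contour
#'
#' First smoothing layer: each point of the smoothed contour is the arithmetic
#' mean of the `2*floor(alpha*n) + 1` raw points centered on it, where `n` is
#' the raw point count. The result is `floor(alpha*n)` points shorter on each
#' side.
#'
#' @param contour Normalized contour (tibble `x`, `y`, micrometers).
#' @param params [smoothing_params()].
#' @return A tibble `x`, `y` with attributes `n_raw` (raw point count) and
#'   `margin` (points trimmed per side).
#' @export
smooth_contour <- function(contour, params = smoothing_params()) {
  params <- as_smoothing_params(params)
  check_contour(contour)
  n <- nrow(contour)
  m <- smoothing_margin(params$alpha, n)
  if (n - 2 * m < 3) {
    abort(paste0("`alpha` too large: smoothing window (", 2 * m + 1,
                 " points) leaves fewer than 3 of the ", n,
                 " contour points."))
  }
  w <- rep(1 / (2 * m + 1), 2 * m + 1)
  xs <- stats::filter(contour$x, w, sides = 2)
  ys <- stats::filter(contour$y, w, sides = 2)
  idx <- (m + 1):(n - m)
  out <- tibble::tibble(x = as.numeric(xs[idx]), y = as.numeric(ys[idx]))
  attr(out, "n_raw") <- n
  attr(out, "margin") <- m
  out
}

#' Raw curvature profile of a smoothed contour
#'
#' Computes, at every interior point, the circumcircle curvature over the
#' immediate neighbors (a three-point sliding window), and the curvilinear
#' abscissa `s` (cumulative Euclidean arc length from the first smoothed
#' point).
#'
#' @param smoothed Output of [smooth_contour()].
#' @return A curvature profile: a tibble with one row per smoothed-contour
#'   point and columns `index`, `x`, `y`, `s`, `k_raw` (NA at the two
#'   endpoints), carrying forward the `n_raw` attribute. Columns `k_refined`
#'   and `k_smoothed` are added by the later stages.
#' @export
raw_curvature <- function(smoothed) {
  check_contour(smoothed)
  L <- nrow(smoothed)
  x <- smoothed$x
  y <- smoothed$y
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  zero <- which(seg == 0)
  if (length(zero) > 0) {
    abort(paste0("degenerate geometry: repeated point at smoothed index ",
                 zero[1] + 1, "."))
  }
  j <- 2:(L - 1)
  k <- circumcircle_curvature_vec(x[j - 1], y[j - 1], x[j], y[j],
                                  x[j + 1], y[j + 1], where = j)
  out <- tibble::tibble(
    index = seq_len(L),
    x = x, y = y,
    s = c(0, cumsum(seg)),
    k_raw = c(NA_real_, k, NA_real_)
  )
  attr(out, "n_raw") <- attr(smoothed, "n_raw") %||% L
  attr(out, "margin") <- attr(smoothed, "margin") %||% 0L
  out
}

#' Adaptive refinement of the raw curvature
#'
#' Second curvature pass: at each point the circumcircle is recomputed over a
#' symmetric window of `a` points, where `a = round(1/|k_raw|)` when
#' `|k_raw|` is below `refine_threshold` and `a = refine_cap` otherwise.
#' Flat regions are therefore measured over a longer baseline (more
#' smoothing) while sharp peaks keep their short window. Near the profile
#' ends `a` is clamped to the available points.
#'
#' @param profile Output of [raw_curvature()].
#' @param params [smoothing_params()].
#' @return The profile with a `k_refined` column filled wherever `k_raw` is
#'   defined.
#' @export
refine_curvature <- function(profile, params = smoothing_params()) {
  params <- as_smoothing_params(params)
  if (!"k_raw" %in% names(profile)) abort("`profile` lacks `k_raw`; run `raw_curvature()` first.")
  L <- nrow(profile)
  j <- which(!is.na(profile$k_raw))
  kr <- abs(profile$k_raw[j])
  a <- ifelse(kr < params$refine_threshold,
              round_half_away(1 / kr),    # Inf where kr == 0; clamped below
              params$refine_cap)
  a <- pmax(1, pmin(a, j - 1L, L - j))
  a <- as.integer(a)
  k <- circumcircle_curvature_vec(
    profile$x[j - a], profile$y[j - a],
    profile$x[j], profile$y[j],
    profile$x[j + a], profile$y[j + a],
    where = j
  )
  profile$k_refined <- NA_real_
  profile$k_refined[j] <- k
  profile
}

#' Triangular smoothing of the refined curvature
#'
#' Third layer: a weighted moving average of the refined curvature with
#' triangular weights `w_i = b - |i - j|` (center weight `b`, zero at the
#' window edge), where `b = floor(beta * n)` and `n` is the raw contour point
#' count. The smoothed curvature is defined `b` points inside each end of the
#' refined profile.
#'
#' @param profile Output of [refine_curvature()].
#' @param params [smoothing_params()].
#' @return The profile with a `k_smoothed` column.
#' @export
smooth_curvature <- function(profile, params = smoothing_params()) {
  params <- as_smoothing_params(params)
  if (!"k_refined" %in% names(profile)) {
    abort("`profile` lacks `k_refined`; run `refine_curvature()` first.")
  }
  L <- nrow(profile)
  n_raw <- attr(profile, "n_raw") %||% L
  b <- smoothing_margin(params$beta, n_raw)
  lo <- 2 + b          # first contour index with the full window inside k_refined
  hi <- (L - 1) - b
  if (lo > hi) {
    abort(paste0("`beta` too large: triangular window (b = ", b,
                 ") leaves no smoothed-curvature points."))
  }
  w <- b - abs(seq(-b, b))
  w <- w / sum(w)
  inner <- profile$k_refined[2:(L - 1)]
  ks <- as.numeric(stats::filter(inner, w, sides = 2))
  profile$k_smoothed <- NA_real_
  profile$k_smoothed[lo:hi] <- ks[(lo:hi) - 1]
  attr(profile, "margin_curv") <- b
  profile
}

#' Full curvature profile of a normalized contour
#'
#' Convenience wrapper chaining [smooth_contour()], [raw_curvature()],
#' [refine_curvature()] and [smooth_curvature()].
#'
#' @param contour Normalized contour (micrometers, math orientation).
#' @param params [smoothing_params()].
#' @return A curvature-profile tibble with columns `index`, `x`, `y`, `s`,
#'   `k_raw`, `k_refined`, `k_smoothed` (the smoothing margins are `NA`).
#' @examples
#' arc <- generate_circle(radius = 20, arc_fraction = 0.4, n_points = 600)
#' prof <- curvature_profile(arc, smoothing_params(alpha = 0.01, beta = 0.01))
#' median(prof$k_smoothed, na.rm = TRUE)  # ~ 1/20
#' @export
curvature_profile <- function(contour, params = smoothing_params()) {
  params <- as_smoothing_params(params)
  contour |>
    smooth_contour(params) |>
    raw_curvature() |>
    refine_curvature(params) |>
    smooth_curvature(params)
}

#' Plot a curvature profile
#'
#' Line plot of the smoothed signed curvature against the curvilinear
#' abscissa, optionally overlaying detected landmarks (maxima red, minima
#' blue, the convention of curvature-profile figures in this literature).
#'
#' @param profile Output of [curvature_profile()].
#' @param landmarks Optional detection outcome from [detect_landmarks()].
#' @return A ggplot object.
#' @export
plot_curvature_profile <- function(profile, landmarks = NULL) {
  dat <- profile[!is.na(profile$k_smoothed), ]
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$s, y = .data$k_smoothed)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "curvilinear abscissa (um)",
                  y = "smoothed curvature (1/um)")
  if (!is.null(landmarks) && inherits(landmarks, "branch_detection") &&
      landmarks$status == "valid") {
    lmk <- landmarks$landmarks
    lmk$s <- profile$s[match(lmk$index, profile$index)]
    p <- p + ggplot2::geom_point(
      data = lmk,
      ggplot2::aes(x = .data$s, y = .data$value, color = .data$kind),
      size = 2
    ) +
      ggplot2::scale_color_manual(
        values = c(maximum = "red", minimum = "blue"), name = NULL
      )
  }
  p
}
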