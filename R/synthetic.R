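#' Sampled circular arc with known analytic curvature
#'
#' Calibration shape: an open arc of a circle, evenly sampled, bulging toward
#' +Y so that its signed curvature under the pipeline's convention is
#' +1/radius everywhere.
#'
#' @param radius Circle radius (micrometers).
#' @param arc_fraction Fraction of the full circle subtended, in (0, 1).
#' @param n_points Number of sampled points.
#' @return A normalized contour tibble (`x`, `y`, micrometers, left-to-right).
#' @examples
#' arc <- generate_circle(10, arc_fraction = 0.5, n_points = 800)
#' @export
generate_circle <- function(radius, arc_fraction = 0.5, n_points = 800) {
  if (!is.numeric(radius) || radius <= 0) abort("`radius` must be positive.")
  if (arc_fraction <= 0 || arc_fraction >= 1) {
    abort("`arc_fraction` must be in (0, 1) for an open arc.")
  }
  if (n_points < 3) abort("`n_points` must be at least 3.")
  half <- pi * arc_fraction
  phi <- seq(-half, half, length.out = n_points)
  tibble::tibble(x = radius * sin(phi), y = radius * cos(phi))
}

#' Synthetic ventral-branch contour with known ground truth
#'
#' Builds a smooth open curve emulating a digitized ventral-branch outline:
#' two lateral spine bumps flanking a central ridge bump, all Gaussian, on a
#' raised plateau baseline with smooth shoulders, optionally perturbed by correlated
#' digitization jitter (low-pass-filtered Gaussian displacement along the
#' local normal, mimicking freehand pen noise). The five ground-truth
#' landmarks are the construction's height extrema (spine tops, cavities,
#' ridge top), located by numeric optimization of the analytic generating
#' function, and the ground-truth spine thrust is [spine_thrust()] applied to
#' them exactly.
#'
#' With narrow bumps the cavities sit near the baseline, so the ground-truth
#' spine thrust is approximately `spine_height - ridge_height`.
#'
#' @param span Total contour width (micrometers).
#' @param baseline_height Height of the underlying plateau (micrometers).
#' @param spine_height Amplitude of the two lateral spine bumps above the
#'   baseline (micrometers); approximately their height above the cavities.
#' @param ridge_height Amplitude of the central ridge bump (micrometers);
#'   must be positive so the ridge is a real maximum.
#' @param spine_positions Normalized x positions of the two spines, one in
#'   (0, 0.5), one in (0.5, 1).
#' @param bump_width Gaussian standard deviation of each bump (micrometers).
#' @param n_points Number of digitized points (typically 500-1000).
#' @param jitter_sd Standard deviation of the correlated digitization jitter
#'   (micrometers); 0 for a noise-free shape.
#' @param seed Integer seed driving the jitter; required only for
#'   reproducible noise.
#' @return A `synthetic_branch` object: list with `contour` (normalized
#'   tibble, micrometers), `true_landmarks` (tibble `landmark`, `x`, `y`),
#'   `true_st` (micrometers) and `params`.
#' @examples
#' shp <- generate_branch_contour(spine_height = 4, ridge_height = 1)
#' shp$true_st  # ~ 3
#' @export
generate_branch_contour <- function(span = 50,
                                    baseline_height = 5,
                                    spine_height = 4,
                                    ridge_height = 1,
                                    spine_positions = c(0.30, 0.70),
                                    bump_width = 2.5,
                                    n_points = 700,
                                    jitter_sd = 0,
                                    seed = NULL) {
  if (n_points < 3) abort("`n_points` must be at least 3.")
  if (jitter_sd < 0) abort("`jitter_sd` must be >= 0.")
  if (length(spine_positions) != 2 ||
      spine_positions[1] <= 0 || spine_positions[1] >= 0.5 ||
      spine_positions[2] <= 0.5 || spine_positions[2] >= 1) {
    abort("`spine_positions` must be two fractions flanking 0.5.")
  }
  if (ridge_height <= 0) abort("`ridge_height` must be positive (the ridge is a maximum).")
  if (spine_height <= 0) abort("`spine_height` must be positive (spines are maxima).")
  sig <- bump_width
  x1 <- spine_positions[1] * span
  x3 <- 0.5 * span
  x5 <- spine_positions[2] * span

  g <- function(x, c) exp(-(x - c)^2 / (2 * sig^2))
  # C2 smootherstep shoulders rising to a plateau that covers all five
  # extrema, so the baseline contributes nothing to their relative heights
  ramp <- function(t) {
    t <- pmin(pmax(t, 0), 1)
    t^3 * (10 - 15 * t + 6 * t^2)
  }
  m1 <- x1 - 3 * sig
  m2 <- x5 + 3 * sig
  base <- function(x) {
    up <- if (m1 > 0) ramp(x / m1) else rep(1, length(x))
    down <- if (m2 < span) ramp((span - x) / (span - m2)) else rep(1, length(x))
    baseline_height * pmin(up, down)
  }
  f <- function(x) {
    base(x) +
      spine_height * (g(x, x1) + g(x, x5)) +
      ridge_height * g(x, x3)
  }

  opt <- function(lower, upper, maximum) {
    o <- optimize(f, c(lower, upper), maximum = maximum, tol = 1e-10)
    c(if (maximum) o$maximum else o$minimum,
      if (maximum) o$objective else o$objective)
  }
  p1 <- opt(x1 - 3 * sig, (x1 + x3) / 2, TRUE)
  p3 <- opt((x1 + x3) / 2, (x3 + x5) / 2, TRUE)
  p5 <- opt((x3 + x5) / 2, x5 + 3 * sig, TRUE)
  p2 <- opt(p1[1], p3[1], FALSE)
  p4 <- opt(p3[1], p5[1], FALSE)

  lx <- c(p1[1], p2[1], p3[1], p4[1], p5[1])
  ly <- c(p1[2], p2[2], p3[2], p4[2], p5[2])
  tol <- 1e-3
  merged <- any(diff(lx) <= sig / 10) ||
    ly[1] <= ly[2] + tol || ly[3] <= max(ly[2], ly[4]) + tol ||
    ly[5] <= ly[4] + tol
  if (merged) {
    abort("generator error: contour extrema merged; widen `spine_positions` or narrow `bump_width`.")
  }
  true_landmarks <- tibble::tibble(landmark = 1:5, x = lx, y = ly)
  true_st <- spine_thrust(true_landmarks)$st_um

  xs <- seq(0, span, length.out = n_points)
  ys <- f(xs)
  if (jitter_sd > 0) {
    noise <- if (is.null(seed)) {
      correlated_noise(n_points, jitter_sd)
    } else {
      withr::with_seed(seed, correlated_noise(n_points, jitter_sd))
    }
    # displace along the local normal of the noise-free curve
    tx <- c(diff(xs), diff(xs)[n_points - 1])
    ty <- c(diff(ys), diff(ys)[n_points - 1])
    tl <- sqrt(tx^2 + ty^2)
    xs <- xs - noise * ty / tl
    ys <- ys + noise * tx / tl
  }
  structure(
    list(
      contour = tibble::tibble(x = xs, y = ys),
      true_landmarks = true_landmarks,
      true_st = true_st,
      params = list(
        span = span, baseline_height = baseline_height,
        spine_height = spine_height, ridge_height = ridge_height,
        spine_positions = spine_positions, bump_width = bump_width,
        n_points = n_points, jitter_sd = jitter_sd, seed = seed
      )
    ),
    class = "synthetic_branch"
  )
}

# low-pass-filtered Gaussian noise rescaled to the requested sd
correlated_noise <- function(n, sd_target, window_frac = 0.03) {
  w <- max(3L, as.integer(round(window_frac * n)))
  e <- rnorm(n + 2 * w)
  sm <- as.numeric(stats::filter(e, rep(1 / (2 * w + 1), 2 * w + 1), sides = 2))
  sm <- sm[(w + 1):(w + n)]
  sm / sd(sm) * sd_target
}

#' @export
print.synthetic_branch <- function(x, ...) {
  cat(sprintf(
    "<synthetic_branch> %d points, span %.3g um, true ST = %.3f um, jitter sd %.3g um\n",
    nrow(x$contour), x$params$span, x$true_st, x$params$jitter_sd
  ))
  invisible(x)
}

#' Simulate a structured population of synthetic specimens
#'
#' Generates a full dataset (manifest + pixel-space contours + ground truth)
#' emulating a rearing-temperature study design: groups defined by species,
#' strain and temperature, each with its own mean spine thrust. Individual
#' target ST values are drawn around the group mean, and each target is
#' realized *geometrically*, by setting the spine bump amplitude to
#' `ridge_height + target`, so the group effect is carried by the contour
#' geometry rather than by bookkeeping. Contours are emitted in pixel image
#' coordinates (y axis down), exactly as a digitizer would produce them, so
#' they exercise the whole normalization path.
#'
#' The default groups mirror a two-species, two-temperature design with
#' 30 individuals per group: a plastic, rounded species whose ST rises by
#' 3.4 um at 18 degrees C relative to 25 degrees C, and a spiny species with
#' no temperature effect.
#'
#' @param groups Tibble with columns `species`, `strain`, `temperature_C`,
#'   `n`, `mean_st` (and optionally `collection_year`).
#' @param between_individual_sd Standard deviation of individual target ST
#'   around the group mean (micrometers).
#' @param base Named list of overrides passed to
#'   [generate_branch_contour()] (e.g. `n_points`, `bump_width`).
#' @param ridge_height Central ridge amplitude (micrometers); individual
#'   spine amplitude is `ridge_height + target ST`.
#' @param jitter_sd Digitization jitter for every individual (micrometers).
#' @param scale_um_per_px Pixel size used to express the emitted contours in
#'   pixels.
#' @param seed Integer seed; all randomness (targets and jitter) derives from
#'   it.
#' @param dir Optional directory; when given, contour CSVs, `manifest.csv`
#'   and `truth.csv` are written there.
#' @return A `synthetic_population` object: list with `manifest` (tibble),
#'   `contours` (named list of pixel tibbles), `truth` (tibble
#'   `specimen_id`, `species`, `strain`, `temperature_C`, `target_st`,
#'   `true_st`) and `dir`.
#' @export
generate_population <- function(groups = default_population_groups(),
                                between_individual_sd = 1.5,
                                base = list(),
                                ridge_height = 3,
                                jitter_sd = 0.5,
                                scale_um_per_px = 0.5,
                                seed = 1,
                                dir = NULL) {
  need <- c("species", "strain", "temperature_C", "n", "mean_st")
  if (!is.data.frame(groups) || !all(need %in% names(groups))) {
    abort(paste0("`groups` must have columns: ", paste(need, collapse = ", "), "."))
  }
  if (any(groups$n < 1)) abort("every group must have n >= 1.")
  if (!"collection_year" %in% names(groups)) groups$collection_year <- 2015L

  total <- sum(groups$n)
  draws <- withr::with_seed(seed, {
    list(
      target = rnorm(total,
                     mean = rep(groups$mean_st, groups$n),
                     sd = between_individual_sd),
      jseed = sample.int(.Machine$integer.max - 1L, total)
    )
  })
  # geometric guard rails: spine amplitude must stay a detectable maximum
  target <- pmin(pmax(draws$target, -ridge_height + 0.5), 12)

  grp <- groups[rep(seq_len(nrow(groups)), groups$n), ]
  within_idx <- unlist(lapply(groups$n, seq_len))
  ids <- sprintf("%s_%s_%gC_%03d", grp$species, grp$strain,
                 grp$temperature_C, within_idx)

  contours <- vector("list", total)
  true_st <- numeric(total)
  for (i in seq_len(total)) {
    args <- utils::modifyList(
      list(
        spine_height = ridge_height + target[i],
        ridge_height = ridge_height,
        jitter_sd = jitter_sd,
        seed = draws$jseed[i]
      ),
      base
    )
    shp <- do.call(generate_branch_contour, args)
    true_st[i] <- shp$true_st
    # emit in image pixel coordinates (y down), as a digitizer would
    contours[[i]] <- tibble::tibble(
      x = shp$contour$x / scale_um_per_px,
      y = -shp$contour$y / scale_um_per_px
    )
  }
  names(contours) <- ids

  manifest <- tibble::tibble(
    specimen_id = ids,
    species = grp$species,
    strain = grp$strain,
    temperature_C = grp$temperature_C,
    collection_year = grp$collection_year,
    scale_um_per_px = scale_um_per_px,
    source_file = paste0(ids, ".csv")
  )
  truth <- tibble::tibble(
    specimen_id = ids,
    species = grp$species,
    strain = grp$strain,
    temperature_C = grp$temperature_C,
    target_st = target,
    true_st = true_st
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (id in ids) write_contour(contours[[id]], file.path(dir, paste0(id, ".csv")))
    readr::write_csv(manifest, file.path(dir, "manifest.csv"))
    readr::write_csv(truth, file.path(dir, "truth.csv"))
  }
  structure(
    list(manifest = manifest, contours = contours, truth = truth, dir = dir),
    class = "synthetic_population"
  )
}

#' Default simulated study design
#'
#' Two species by two rearing temperatures, 30 individuals per group. The
#' rounded species carries a +3.4 um spine-thrust shift at 18 vs 25 degrees
#' C (the plastic response); the spiny species has equal means at both
#' temperatures and sits about 9 um above the rounded species at 25 degrees
#' C, the magnitude of the interspecific difference.
#'
#' @return A groups tibble for [generate_population()].
#' @export
default_population_groups <- function() {
  tibble::tibble(
    species = c("santomea_like", "santomea_like", "yakuba_like", "yakuba_like"),
    strain = c("synth1", "synth1", "synth2", "synth2"),
    temperature_C = c(18, 25, 18, 25),
    collection_year = 2015L,
    n = 30L,
    mean_st = c(3.9, 0.5, 9.0, 9.0)
  )
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat(sprintf("<synthetic_population> %d specimens in %d group(s)\n",
              nrow(x$manifest),
              nrow(unique(x$truth[, c("species", "strain", "temperature_C")]))))
  invisible(x)
}
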