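test_that("circumcircle curvature matches closed-form geometry", {
  # collinear points: flat contour, zero curvature
  expect_identical(circumcircle_curvature(c(0, 0), c(1, 0), c(2, 0)), 0)

  # arch inscribed in the unit circle, traversed left to right: +1
  expect_equal(circumcircle_curvature(c(-1, 0), c(0, 1), c(1, 0)), 1)

  # orientation antisymmetry: reversed traversal negates the sign
  expect_equal(circumcircle_curvature(c(1, 0), c(0, 1), c(-1, 0)), -1)

  # equilateral triangle, side s: circumradius R = s / sqrt(3), |k| = sqrt(3)/s
  s <- 2
  tri <- rbind(c(0, 0), c(s, 0), c(s / 2, s * sqrt(3) / 2))
  k <- circumcircle_curvature(tri[1, ], tri[2, ], tri[3, ])
  expect_equal(abs(k), sqrt(3) / s, tolerance = 1e-12)

  expect_error(circumcircle_curvature(c(0, 0), c(0, 0), c(1, 1)),
               "coincident")
  expect_error(circumcircle_curvature(c(0, 0), c(1, 1), c(0, 0)),
               "coincident")
})

test_that("rectangular contour smoothing averages the centered window", {
  ct <- tibble::tibble(x = c(0, 1, 2, 3, 4), y = c(0, 3, 0, 3, 0))
  # alpha * n = 1: mean of 3 neighbors, one point trimmed per side
  sm <- smooth_contour(ct, smoothing_params(alpha = 0.2, beta = 0.1))
  expect_equal(sm$x, c(1, 2, 3))
  expect_equal(sm$y, c(1, 2, 1))

  # constants are preserved (mean-preserving divisor)
  ctc <- tibble::tibble(x = seq(0, 10, length.out = 50), y = rep(2.5, 50))
  smc <- smooth_contour(ctc, smoothing_params(alpha = 0.1, beta = 0.1))
  expect_true(all(abs(smc$y - 2.5) < 1e-12))

  # n = 1000, alpha = 0.025: output 950 points (25 trimmed per side)
  big <- wiggly_contour(n = 1000)
  expect_equal(nrow(smooth_contour(big, smoothing_params(alpha = 0.025))), 950)
})

test_that("raw curvature profile recovers analytic circle curvature and abscissa", {
  arc <- generate_circle(radius = 10, arc_fraction = 0.4, n_points = 800)
  prof <- arc |>
    smooth_contour(smoothing_params(alpha = 0.002, beta = 0.002)) |>
    raw_curvature()
  inner <- prof$k_raw[!is.na(prof$k_raw)]
  expect_equal(median(inner), 0.1, tolerance = 1e-3)

  # unit-spaced collinear points: s = 0, 1, 2, ... and k exactly 0
  line <- tibble::tibble(x = 0:9, y = rep(1, 10))
  lp <- raw_curvature(line)
  expect_equal(lp$s, as.numeric(0:9))
  expect_true(all(abs(lp$k_raw[2:9]) == 0))

  dup <- tibble::tibble(x = c(0, 1, 1, 2), y = c(0, 1, 1, 0))
  expect_error(raw_curvature(dup), "repeated point")
})

test_that("adaptive refinement widens the window where curvature is small", {
  # R = 100 um arc: |k_raw| = 0.01 < 0.1, so the window is ~1/k = 100 points,
  # which beats the 3-point estimate under digitization noise
  arc <- generate_circle(radius = 100, arc_fraction = 0.6, n_points = 900)
  noisy <- arc
  noisy$y <- noisy$y + withr::with_seed(11, rnorm(900, sd = 0.02))
  params <- smoothing_params(alpha = 0.002, beta = 0.002)
  prof <- noisy |> smooth_contour(params) |> raw_curvature() |>
    refine_curvature(params)
  ok <- !is.na(prof$k_refined)
  err_raw <- median(abs(prof$k_raw[ok] - 0.01))
  err_ref <- median(abs(prof$k_refined[ok] - 0.01))
  expect_lt(err_ref, err_raw)
  expect_equal(median(prof$k_refined[ok]), 0.01, tolerance = 0.1)

  # above the threshold the window is capped: a sharp small circle keeps its
  # sharp estimate (R = 2 um: |k| = 0.5 >= 0.1)
  arc2 <- generate_circle(radius = 2, arc_fraction = 0.5, n_points = 500)
  prof2 <- arc2 |> smooth_contour(params) |> raw_curvature() |>
    refine_curvature(params)
  ok2 <- !is.na(prof2$k_refined)
  expect_equal(median(prof2$k_refined[ok2]), 0.5, tolerance = 1e-2)
})

test_that("triangular curvature smoothing preserves constants and trims beta*n", {
  arc <- generate_circle(radius = 20, arc_fraction = 0.5, n_points = 600)
  params <- smoothing_params(alpha = 0.01, beta = 0.02)
  prof <- curvature_profile(arc, params)
  ok <- !is.na(prof$k_smoothed)
  # a constant-curvature profile stays constant through the weighted mean
  expect_equal(median(prof$k_smoothed[ok]), 0.05, tolerance = 5e-4)
  expect_lt(diff(range(prof$k_smoothed[ok])), 1e-3)

  # stage lengths: |smoothed| = n - 2*floor(alpha*n),
  # |k_smoothed| = |smoothed| - 2 - 2*floor(beta*n)
  n <- 600
  expect_equal(sum(!is.na(prof$k_smoothed)),
               (n - 2 * floor(0.01 * n)) - 2 - 2 * floor(0.02 * n))

  # windows that leave no points are a parameter error, not silent truncation
  tiny <- tibble::tibble(x = as.numeric(0:4), y = c(0, 1, 0, 1, 0))
  expect_error(curvature_profile(tiny, smoothing_params(alpha = 0.2, beta = 0.2)),
               "too large")
})

test_that("signed curvature is similarity-equivariant and reversal-antisymmetric", {
  ct <- wiggly_contour(n = 500)
  params <- smoothing_params(alpha = 0.01, beta = 0.01)
  base <- curvature_profile(ct, params)
  ok <- which(!is.na(base$k_smoothed))

  # uniform scaling by c scales curvature by 1/c: exact for the raw stage;
  # the refined/smoothed stages follow it closely but not exactly, because
  # the adaptive refinement window keys on absolute curvature in 1/um (the
  # procedure is calibrated for micrometer units, which is why the pixel
  # scale must be supplied)
  c_ <- 2.5
  scaled <- curvature_profile(tibble::tibble(x = ct$x * c_, y = ct$y * c_), params)
  expect_equal(scaled$k_raw[ok], base$k_raw[ok] / c_, tolerance = 1e-9)
  d <- abs(scaled$k_smoothed[ok] - base$k_smoothed[ok] / c_)
  expect_lt(median(d), 0.02 * max(abs(base$k_smoothed[ok])) / c_)

  # rigid motion leaves curvature unchanged
  rt <- rigid_xy(ct$x, ct$y, angle = 0.3, dx = 7, dy = -3)
  moved <- curvature_profile(tibble::tibble(x = rt$x, y = rt$y), params)
  expect_equal(moved$k_smoothed[ok], base$k_smoothed[ok], tolerance = 1e-9)

  # reversing the traversal negates every signed curvature
  revd <- curvature_profile(ct[nrow(ct):1, ], params)
  expect_equal(rev(revd$k_smoothed[!is.na(revd$k_smoothed)]),
               -base$k_smoothed[ok], tolerance = 1e-9)
})

test_that("spine peaks are curvature maxima and cavities minima", {
  # the whole-pipeline sign contract: on a normalized branch contour the
  # three bumps (toward +Y) are maxima of k_smoothed, the two cavities minima
  shp <- generate_branch_contour(spine_height = 4, ridge_height = 1.5)
  prof <- curvature_profile(shp$contour)
  det <- detect_landmarks(prof)
  expect_equal(det$status, "valid")
  expect_equal(det$landmarks$kind,
               c("maximum", "minimum", "maximum", "minimum", "maximum"))
  expect_true(all(det$landmarks$value[c(1, 3, 5)] > 0))
  expect_true(all(det$landmarks$value[c(2, 4)] < 0))
})
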