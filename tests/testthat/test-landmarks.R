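sin_profile <- function(n = 800, periods = 2, excl = 0) {
  # a synthetic curvature profile carrier: k_smoothed = sin over `periods`
  s <- seq(0, periods * 2 * pi, length.out = n)
  tibble::tibble(
    index = seq_len(n), x = s, y = 0, s = s,
    k_raw = sin(s), k_refined = sin(s), k_smoothed = sin(s)
  )
}

test_that("extrema are strict sign changes of the first difference", {
  p <- smoothing_params(exclusion_fraction = 0)
  ext <- find_extrema(sin_profile(), p)
  expect_equal(sum(ext$kind == "maximum"), 2)
  expect_equal(sum(ext$kind == "minimum"), 2)
  # positions of sin extrema: pi/2, 3pi/2, 5pi/2, 7pi/2
  expect_equal(sort(ext$s_norm), c(1, 3, 5, 7) / 8, tolerance = 1e-2)

  # monotone profile: no extrema
  mono <- sin_profile()
  mono$k_smoothed <- seq_along(mono$index) * 0.01
  expect_equal(nrow(find_extrema(mono, p)), 0)
})

test_that("plateaus yield their first index", {
  v <- c(0, 1, 2, 2, 2, 1, 0, -1, -1, 0)
  prof <- tibble::tibble(
    index = seq_along(v), x = seq_along(v), y = 0,
    s = as.numeric(seq_along(v)), k_raw = v, k_refined = v, k_smoothed = v
  )
  ext <- find_extrema(prof, smoothing_params(exclusion_fraction = 0))
  expect_equal(ext$index, c(3L, 8L))
  expect_equal(ext$kind, c("maximum", "minimum"))
})

test_that("the exclusion window drops extrema near the contour ends", {
  ext_all <- find_extrema(sin_profile(), smoothing_params(exclusion_fraction = 0))
  ext_win <- find_extrema(sin_profile(), smoothing_params(exclusion_fraction = 0.20))
  # the maximum at normalized abscissa 1/8 = 0.125 < 0.20 must be gone
  expect_equal(nrow(ext_all), 4)
  expect_true(all(ext_win$s_norm >= 0.2 & ext_win$s_norm <= 0.8))
  expect_lt(nrow(ext_win), nrow(ext_all))
})

test_that("the worked landmark assignment example resolves as specified", {
  ext <- bank(
    s_norm = c(0.30, 0.38, 0.48, 0.56, 0.65),
    value = c(2, -1, 1, -1, 2),
    kind = c("maximum", "minimum", "maximum", "minimum", "maximum")
  )
  det <- assign_landmarks(ext, smoothing_params())
  expect_equal(det$status, "valid")
  expect_equal(det$landmarks$s_norm, c(0.30, 0.38, 0.48, 0.56, 0.65))
  expect_equal(det$landmarks$kind[c(1, 3, 5)], rep("maximum", 3))
  expect_equal(det$landmarks$kind[c(2, 4)], rep("minimum", 2))
})

test_that("each missing landmark role leads to exclusion with its reason", {
  full <- bank(
    s_norm = c(0.30, 0.38, 0.48, 0.56, 0.65),
    value = c(2, -1, 1, -1, 2),
    kind = c("maximum", "minimum", "maximum", "minimum", "maximum")
  )
  p <- smoothing_params()
  drop_rows <- function(b, i) b[-i, ]

  expect_equal(assign_landmarks(full[0, ], p)$reason, "no-extrema")
  # no minimum left of the central maximum
  expect_equal(assign_landmarks(drop_rows(full, 2), p)$reason, "missing-L2")
  # no maximum left of landmark 2
  expect_equal(assign_landmarks(drop_rows(full, 1), p)$reason, "missing-L1")
  # no minimum right of landmark 3
  expect_equal(assign_landmarks(drop_rows(full, 4), p)$reason, "missing-L4")
  # no maximum right of landmark 4
  expect_equal(assign_landmarks(drop_rows(full, 5), p)$reason, "missing-L5")
  # minima only
  expect_equal(assign_landmarks(full[full$kind == "minimum", ], p)$reason,
               "missing-L3")
})

test_that("landmark 3 is resampled to the highest maximum between 2 and 4", {
  ext <- bank(
    s_norm = c(0.30, 0.38, 0.45, 0.50, 0.56, 0.65),
    value = c(2, -1, 1.0, 1.8, -1, 2),
    kind = c("maximum", "minimum", "maximum", "maximum", "minimum", "maximum")
  )
  det <- assign_landmarks(ext, smoothing_params())
  expect_equal(det$status, "valid")
  # the initial pick (0.45, closest to midline 0.475) yields to the higher 0.50
  expect_equal(det$landmarks$s_norm[3], 0.50)
  expect_equal(det$landmarks$value[3], 1.8)
})

test_that("landmark 2 is the lowest minimum left of landmark 3", {
  ext <- bank(
    s_norm = c(0.25, 0.32, 0.40, 0.48, 0.56, 0.65),
    value = c(2, -0.5, -1.2, 1, -1, 2),
    kind = c("maximum", "minimum", "minimum", "maximum", "minimum", "maximum")
  )
  det <- assign_landmarks(ext, smoothing_params())
  expect_equal(det$status, "valid")
  expect_equal(det$landmarks$value[2], -1.2)
  expect_equal(det$landmarks$s_norm[2], 0.40)
})

test_that("assignment agrees with a brute-force oracle on a scripted bank", {
  p <- smoothing_params()
  cases <- list(
    bank(c(0.30, 0.38, 0.48, 0.56, 0.65), c(2, -1, 1, -1, 2),
         c("maximum", "minimum", "maximum", "minimum", "maximum")),
    bank(c(0.30, 0.38, 0.45, 0.50, 0.56, 0.65), c(2, -1, 1, 1.8, -1, 2),
         c("maximum", "minimum", "maximum", "maximum", "minimum", "maximum")),
    bank(c(0.25, 0.32, 0.40, 0.48, 0.56, 0.65), c(2, -0.5, -1.2, 1, -1, 2),
         c("maximum", "minimum", "minimum", "maximum", "minimum", "maximum")),
    bank(c(0.48, 0.56, 0.65), c(1, -1, 2), c("maximum", "minimum", "maximum")),
    bank(c(0.30, 0.38, 0.48), c(2, -1, 1), c("maximum", "minimum", "maximum"))
  )
  # plus randomized alternating banks, the shape real profiles produce
  withr::with_seed(101, {
    for (i in 1:40) {
      cases[[length(cases) + 1]] <- random_bank(
        sample(0:9, 1), sample(c("maximum", "minimum"), 1)
      )
    }
  })
  for (ext in cases) {
    got <- assign_landmarks(ext, p)
    want <- oracle_assign(ext, midline = p$midline_position)
    expect_equal(got$status, want$status)
    if (want$status == "valid") {
      expect_equal(got$landmarks$index, want$index)
    } else {
      expect_equal(got$reason, want$reason)
    }
  }
})

test_that("detection is deterministic and landmarks ordered inside the window", {
  shp <- generate_branch_contour(jitter_sd = 0.5, seed = 3)
  prof <- curvature_profile(shp$contour)
  d1 <- detect_landmarks(prof)
  d2 <- detect_landmarks(curvature_profile(shp$contour))
  expect_equal(d1$landmarks, d2$landmarks)
  expect_true(all(diff(d1$landmarks$s_norm) > 0))
  expect_true(all(d1$landmarks$s_norm >= 0.2 & d1$landmarks$s_norm <= 0.8))
})

test_that("noise-free synthetic landmarks match construction ground truth", {
  shp <- generate_branch_contour(spine_height = 4, ridge_height = 1)
  det <- detect_landmarks(curvature_profile(shp$contour))
  expect_equal(det$status, "valid")
  # positions of detected landmarks within the smoothing margin of truth:
  # the contour filter spans ~1.3 um of arc at the default alpha, so
  # curvature extrema may sit up to about that far from the height extrema
  expect_lt(max(abs(det$landmarks$x - shp$true_landmarks$x)), 1.5)
  expect_lt(max(abs(det$landmarks$y - shp$true_landmarks$y)), 0.5)
})
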