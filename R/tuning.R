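#' Squared Pearson correlation
#'
#' @param x,y Numeric vectors of equal length (>= 3) with nonzero variance.
#' @return The square of the sample Pearson correlation coefficient.
#' @examples
#' pearson_r2(1:10, 2 * (1:10) + 1)  # 1
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("at least 3 paired values are required.")
  if (anyNA(x) || anyNA(y)) abort("missing values are not allowed.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("undefined correlation: zero variance in `x` or `y`.")
  }
  stats::cor(x, y)^2
}

#' Calibrate the smoothing parameters by grid search
#'
#' For every (alpha, beta) cell of the grid, the full pipeline is run on
#' every specimen; specimens with an excluded or errored outcome are dropped
#' from that cell, and the squared Pearson correlation between automatic and
#' manual (reference) spine thrust is computed over the survivors. The
#' selected cell maximizes r2; exact ties are resolved toward the lowest
#' degree of smoothing, formalized as smallest `alpha + beta`, then smallest
#' `beta`. Cells where fewer than 3 specimens survive (or variance
#' degenerates) are undefined and never selected.
#'
#' @param specimens Tibble with a list-column `contour` of normalized
#'   contours (micrometers, math orientation) and a numeric column
#'   `manual_st` of reference spine-thrust values; an optional `specimen_id`
#'   column is carried through. See [tuning_specimens()].
#' @param alpha_grid,beta_grid Increasing vectors of candidate fractions.
#' @param params Base [smoothing_params()] supplying the non-tuned constants.
#' @return An `st_tuning` object: list with `surface` (tibble `alpha`,
#'   `beta`, `r2`, `n_used`), `best_alpha`, `best_beta`, `best_r2`,
#'   `n_specimens`. `tidy()` returns the surface, `glance()` the selected
#'   optimum, `autoplot()` the r2 heatmap.
#' @export
tune_smoothing <- function(specimens,
                           alpha_grid = seq(0.005, 0.050, by = 0.005),
                           beta_grid = seq(0.005, 0.100, by = 0.005),
                           params = smoothing_params()) {
  if (!is.data.frame(specimens) ||
      !all(c("contour", "manual_st") %in% names(specimens))) {
    abort("`specimens` must have a `contour` list-column and a `manual_st` column.")
  }
  if (nrow(specimens) < 3) abort("at least 3 specimens are required for tuning.")
  if (length(alpha_grid) == 0 || length(beta_grid) == 0) {
    abort("`alpha_grid` and `beta_grid` must be non-empty.")
  }
  params <- as_smoothing_params(params)

  grid <- tidyr::expand_grid(alpha = sort(alpha_grid), beta = sort(beta_grid))
  cells <- purrr::pmap(grid, function(alpha, beta) {
    p <- params
    p$alpha <- alpha
    p$beta <- beta
    auto <- purrr::map_dbl(specimens$contour, function(ct) {
      tryCatch({
        m <- measure_contour(ct, p)
        if (m$status == "valid") m$st_um else NA_real_
      }, error = function(e) NA_real_)
    })
    ok <- !is.na(auto)
    n_used <- sum(ok)
    r2 <- if (n_used >= 3 &&
              sd(auto[ok]) > 0 && sd(specimens$manual_st[ok]) > 0) {
      pearson_r2(specimens$manual_st[ok], auto[ok])
    } else {
      NA_real_
    }
    tibble::tibble(r2 = r2, n_used = n_used)
  })
  surface <- dplyr::bind_cols(grid, dplyr::bind_rows(cells))
  best <- select_best_cell(surface)

  structure(
    list(
      surface = surface,
      best_alpha = best$alpha,
      best_beta = best$beta,
      best_r2 = best$r2,
      n_specimens = nrow(specimens)
    ),
    class = "st_tuning"
  )
}

# deterministic, total selection rule: maximal r2, ties toward the lowest
# degree of smoothing (smallest alpha + beta, then smallest beta, then alpha);
# undefined (NA) cells are never selectable
select_best_cell <- function(surface) {
  defined <- surface[!is.na(surface$r2), ]
  if (nrow(defined) == 0) {
    abort("tuning failed: no grid cell had >= 3 surviving specimens with variance.")
  }
  defined[order(-defined$r2, defined$alpha + defined$beta,
                defined$beta, defined$alpha), ][1, ]
}

#' Bundle contours and reference values for tuning
#'
#' @param contours List of normalized contours.
#' @param manual_st Numeric vector of reference spine-thrust values
#'   (micrometers), same length and order.
#' @param specimen_id Optional ids.
#' @return A tibble suitable for [tune_smoothing()].
#' @export
tuning_specimens <- function(contours, manual_st, specimen_id = NULL) {
  if (length(contours) != length(manual_st)) {
    abort("`contours` and `manual_st` must have the same length.")
  }
  tibble::tibble(
    specimen_id = specimen_id %||% paste0("spec", seq_along(contours)),
    contour = unname(contours),
    manual_st = manual_st
  )
}

#' @export
print.st_tuning <- function(x, ...) {
  cat("<st_tuning> ", nrow(x$surface), " cells, ", x$n_specimens,
      " specimens\n", sep = "")
  cat(sprintf("  best: alpha = %.4g, beta = %.4g, r2 = %.4f\n",
              x$best_alpha, x$best_beta, x$best_r2))
  invisible(x)
}

#' @method tidy st_tuning
#' @export
tidy.st_tuning <- function(x, ...) x$surface

#' @method glance st_tuning
#' @export
glance.st_tuning <- function(x, ...) {
  tibble::tibble(
    best_alpha = x$best_alpha, best_beta = x$best_beta,
    best_r2 = x$best_r2, n_cells = nrow(x$surface),
    n_specimens = x$n_specimens
  )
}

#' @method autoplot st_tuning
#' @export
autoplot.st_tuning <- function(object, ...) {
  surf <- object$surface
  best <- surf[surf$alpha == object$best_alpha & surf$beta == object$best_beta, ]
  ggplot2::ggplot(surf, ggplot2::aes(x = .data$alpha, y = .data$beta)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$r2)) +
    ggplot2::geom_tile(data = best, fill = NA, color = "white",
                       linewidth = 1) +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::labs(x = "contour smoothing (alpha)",
                  y = "curvature smoothing (beta)", fill = "r²")
}

#' Repeatability of two measurement passes
#'
#' Ordinary least-squares regression of a second measurement pass on a first
#' (same specimens digitized twice), the standard repeatability check for
#' this pipeline: slope near 1, intercept near 0 and high r2 indicate
#' statistically reproducible measurements.
#'
#' @param first,second Data frames with columns `specimen_id` and `st_um`
#'   (one row per specimen), or plain numeric vectors of equal length taken
#'   as already paired.
#' @return One-row tibble: `slope`, `intercept`, `r2`, `n`.
#' @export
repeatability <- function(first, second) {
  if (is.data.frame(first) || is.data.frame(second)) {
    for (nm in c("first", "second")) {
      v <- get(nm)
      if (!is.data.frame(v) || !all(c("specimen_id", "st_um") %in% names(v))) {
        abort(paste0("`", nm, "` must have columns specimen_id and st_um."))
      }
    }
    only1 <- setdiff(first$specimen_id, second$specimen_id)
    only2 <- setdiff(second$specimen_id, first$specimen_id)
    if (length(only1) > 0 || length(only2) > 0) {
      abort(paste0(
        "unpaired specimen ids: ",
        paste(c(only1, only2), collapse = ", "), "."
      ))
    }
    merged <- dplyr::inner_join(
      dplyr::select(first, "specimen_id", st1 = "st_um"),
      dplyr::select(second, "specimen_id", st2 = "st_um"),
      by = "specimen_id"
    )
    x <- merged$st1
    y <- merged$st2
  } else {
    if (length(first) != length(second)) {
      abort("`first` and `second` must have equal length.")
    }
    x <- as.numeric(first)
    y <- as.numeric(second)
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) abort("at least 3 paired measurements are required.")
  fit <- lm(y ~ x)
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = summary(fit)$r.squared,
    n = length(x)
  )
}
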