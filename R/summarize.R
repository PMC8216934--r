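#' Group-level descriptive statistics of spine thrust
#'
#' For each group: count, mean, standard error, median, quartiles (linear
#' interpolation between order statistics), interquartile range, and the
#' notched-boxplot half-width of the 95% confidence interval of the median,
#' `1.58 * IQR / sqrt(n)`. SE and notch are reported missing for n < 2.
#' Rows with a missing value (excluded specimens) are dropped first.
#'
#' @param measurements Tibble of per-specimen measurements (e.g. from
#'   [measure_branches()]).
#' @param ... Grouping columns, tidy-select style (e.g. `species, strain,
#'   temperature_C`).
#' @param value Column holding the measured values (default `st_um`).
#' @return A tibble with one row per group: the grouping columns plus `n`,
#'   `mean`, `se`, `median`, `q1`, `q3`, `iqr`, `notch`.
#' @examples
#' df <- tibble::tibble(sp = c("a", "a", "a", "a", "a"), st_um = 1:5)
#' summarize_st(df, sp)  # notch = 1.58 * 2 / sqrt(5)
#' @export
summarize_st <- function(measurements, ..., value = st_um) {
  v <- enquo(value)
  if (!is.data.frame(measurements)) abort("`measurements` must be a data frame.")
  if (nrow(measurements) == 0) {
    warn("no measurements to summarize; returning an empty summary.")
    groups <- dplyr::select(measurements, ...)
    return(dplyr::bind_cols(
      groups,
      tibble::tibble(
        n = integer(0), mean = numeric(0), se = numeric(0),
        median = numeric(0), q1 = numeric(0), q3 = numeric(0),
        iqr = numeric(0), notch = numeric(0)
      )
    ))
  }
  dat <- dplyr::filter(measurements, !is.na(!!v))
  if (nrow(dat) == 0) {
    warn("all values are missing; returning an empty summary.")
    return(summarize_st(dat[0, ], ..., value = !!v))
  }
  dat |>
    dplyr::group_by(dplyr::across(c(...))) |>
    dplyr::summarise(st_group_stats(!!v), .groups = "drop")
}

# one-row descriptive statistics for a group of values
st_group_stats <- function(values) {
  if (length(values) == 0) abort("empty group.")
  n <- length(values)
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  tibble::tibble(
    n = n,
    mean = mean(values),
    se = if (n >= 2) sd(values) / sqrt(n) else NA_real_,
    median = q[2],
    q1 = q[1],
    q3 = q[3],
    iqr = iqr,
    notch = if (n >= 2) 1.58 * iqr / sqrt(n) else NA_real_
  )
}

#' Plot spine thrust by group
#'
#' Notched boxplots (the notch is the 95% confidence interval of the median,
#' `+/- 1.58 IQR / sqrt(n)`) with individual values and group mean +/- SE
#' overlaid, the standard way these group comparisons are displayed.
#'
#' @param measurements Per-specimen measurements.
#' @param x Grouping column for the x axis (e.g. `strain`).
#' @param color Optional column mapped to color (e.g. `temperature_C`).
#' @param value Value column (default `st_um`).
#' @return A ggplot object.
#' @export
plot_st_groups <- function(measurements, x, color = NULL, value = st_um) {
  xq <- enquo(x)
  cq <- enquo(color)
  vq <- enquo(value)
  dat <- dplyr::filter(measurements, !is.na(!!vq))
  has_color <- !quo_is_null(cq)
  if (has_color) {
    dat <- dplyr::mutate(dat, .color = factor(!!cq))
  }
  mapping <- if (has_color) {
    ggplot2::aes(x = factor(!!xq), y = !!vq, color = .data$.color)
  } else {
    ggplot2::aes(x = factor(!!xq), y = !!vq)
  }
  point_layer <- if (has_color) {
    ggplot2::geom_point(
      position = ggplot2::position_jitterdodge(jitter.width = 0.15,
                                               dodge.width = 0.8),
      alpha = 0.4, size = 0.8
    )
  } else {
    ggplot2::geom_point(
      position = ggplot2::position_jitter(width = 0.15),
      alpha = 0.4, color = "grey40", size = 0.8
    )
  }
  p <- ggplot2::ggplot(dat, mapping) +
    ggplot2::geom_boxplot(notch = TRUE, outlier.shape = NA,
                          position = ggplot2::position_dodge(width = 0.8)) +
    point_layer +
    ggplot2::stat_summary(
      fun.data = ggplot2::mean_se,
      position = ggplot2::position_dodge(width = 0.8),
      shape = 18, size = 0.6
    ) +
    ggplot2::labs(x = NULL, y = "spine thrust (um)",
                  color = if (has_color) rlang::as_label(cq) else NULL)
  p
}
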