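#' Measure one normalized contour
#'
#' Runs the full pipeline on a single contour already in micrometers and
#' mathematical orientation: curvature profile, landmark detection, spine
#' thrust. Detection failure is an *excluded* row, not an error.
#'
#' @param contour Normalized contour (tibble `x`, `y`, micrometers; see
#'   [normalize_contour()]).
#' @param params [smoothing_params()].
#' @return A one-row tibble: `status` (`"valid"` or `"excluded"`),
#'   `exclusion_reason`, `st_um`, `y_l1`, `y_l3`, `y_l5`, and landmark
#'   coordinates `lm1_x` ... `lm5_y` (micrometers; `NA` when excluded).
#' @examples
#' shp <- generate_branch_contour(seed = 1)
#' measure_contour(shp$contour)
#' @export
measure_contour <- function(contour, params = smoothing_params()) {
  params <- as_smoothing_params(params)
  profile <- curvature_profile(contour, params)
  det <- detect_landmarks(profile, params)
  if (det$status != "valid") {
    return(tibble::tibble(
      status = "excluded", exclusion_reason = det$reason,
      st_um = NA_real_, y_l1 = NA_real_, y_l3 = NA_real_, y_l5 = NA_real_,
      !!!empty_landmark_cols()
    ))
  }
  st <- spine_thrust(det)
  lmw <- landmark_wide(det$landmarks)
  dplyr::bind_cols(
    tibble::tibble(status = "valid", exclusion_reason = NA_character_),
    st, lmw
  )
}

landmark_wide <- function(lmk) {
  o <- order(lmk$landmark)
  vals <- c(rbind(lmk$x[o], lmk$y[o]))
  names(vals) <- paste0("lm", rep(1:5, each = 2), c("_x", "_y"))
  tibble::as_tibble(as.list(vals))
}

empty_landmark_cols <- function() {
  setNames(
    rep(list(NA_real_), 10),
    paste0("lm", rep(1:5, each = 2), c("_x", "_y"))
  )
}

#' Measure every specimen in a manifest
#'
#' Batch orchestration: for each manifest row the contour is read (or taken
#' from `contours`), normalized with the specimen's pixel scale, and
#' measured. Every specimen yields exactly one output row: measured, excluded
#' with a reason, or errored with the error message. Reruns on identical
#' inputs are bit-identical (the pipeline is deterministic).
#'
#' @param manifest Manifest tibble (see [read_manifest()]) or a manifest CSV
#'   path.
#' @param contours Optional named list of raw pixel contours keyed by
#'   `specimen_id` (e.g. from [generate_population()]); when absent, each
#'   specimen's `source_file` is read from `contour_dir`.
#' @param contour_dir Directory that `source_file` paths are relative to.
#' @param params [smoothing_params()].
#' @param verbose Emit a summary message (counts, exclusion fraction).
#' @return A tibble with the manifest columns plus the [measure_contour()]
#'   columns, one row per specimen, in manifest order.
#' @export
measure_branches <- function(manifest, contours = NULL, contour_dir = ".",
                             params = smoothing_params(), verbose = FALSE) {
  if (is.character(manifest) && length(manifest) == 1) {
    contour_dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  manifest <- check_manifest(manifest)
  params <- as_smoothing_params(params)

  rows <- purrr::map(seq_len(nrow(manifest)), function(i) {
    id <- manifest$specimen_id[i]
    tryCatch({
      raw <- if (!is.null(contours)) {
        if (is.null(contours[[id]])) abort(paste0("no contour supplied for ", id))
        contours[[id]]
      } else {
        read_contour(file.path(contour_dir, manifest$source_file[i]))
      }
      nc <- normalize_contour(raw, manifest$scale_um_per_px[i])
      measure_contour(nc, params)
    }, error = function(e) {
      tibble::tibble(
        status = "error", exclusion_reason = conditionMessage(e),
        st_um = NA_real_, y_l1 = NA_real_, y_l3 = NA_real_, y_l5 = NA_real_,
        !!!empty_landmark_cols()
      )
    })
  })
  out <- dplyr::bind_cols(manifest, dplyr::bind_rows(rows))
  if (verbose) {
    n <- nrow(out)
    nv <- sum(out$status == "valid")
    message(sprintf(
      "measured %d/%d specimens (%d excluded or errored, %.1f%%)",
      nv, n, n - nv, 100 * (n - nv) / max(1, n)
    ))
  }
  out
}

#' Landmarks of a measurements table in long format
#'
#' Reshapes the wide `lm*_x`/`lm*_y` columns of a measurements table into one
#' row per landmark, ready for [write_tps()].
#'
#' @param measurements Output of [measure_branches()].
#' @return Tibble with columns `specimen_id`, `landmark`, `x`, `y` (valid
#'   specimens only).
#' @export
measurement_landmarks <- function(measurements) {
  ok <- measurements[measurements$status == "valid", ]
  if (nrow(ok) == 0) {
    return(tibble::tibble(specimen_id = character(0), landmark = integer(0),
                          x = numeric(0), y = numeric(0)))
  }
  long <- tidyr::pivot_longer(
    ok[, c("specimen_id", paste0("lm", rep(1:5, each = 2), c("_x", "_y")))],
    cols = -"specimen_id",
    names_to = c("landmark", "axis"),
    names_pattern = "lm(\\d)_(x|y)",
    values_to = "value"
  )
  wide <- tidyr::pivot_wider(long, names_from = "axis", values_from = "value")
  wide$landmark <- as.integer(wide$landmark)
  dplyr::arrange(wide, .data$specimen_id, .data$landmark)
}
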