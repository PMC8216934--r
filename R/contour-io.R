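#' Read a digitized contour file
#'
#' A contour file holds one hand-digitized open polyline: two numeric columns
#' (x, y, pixel units, one point per row, digitization order), comma or
#' whitespace separated, with an optional `x,y` header line.
#'
#' @param path Path to the contour file.
#' @return A tibble with numeric columns `x` and `y`, one row per digitized
#'   point, in file order.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("x,y", "0,0", "1,2", "2,0"), f)
#' read_contour(f)
#' @export
read_contour <- function(path) {
  if (!file.exists(path)) abort(paste0("contour file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) abort(paste0("malformed contour (empty file): ", path))

  parse_row <- function(line) {
    fields <- strsplit(trimws(line), "[,;[:space:]]+")[[1]]
    suppressWarnings(as.numeric(fields))
  }

  first <- parse_row(lines[keep[1]])
  has_header <- anyNA(first) || length(first) < 2
  data_rows <- if (has_header) keep[-1] else keep
  if (length(data_rows) < 3) {
    abort(paste0("malformed contour (fewer than 3 points): ", path))
  }

  xy <- matrix(NA_real_, nrow = length(data_rows), ncol = 2)
  for (i in seq_along(data_rows)) {
    row <- data_rows[i]
    vals <- parse_row(lines[row])
    if (length(vals) < 2 || anyNA(vals[1:2])) {
      abort(paste0("non-numeric contour row ", row, " in ", path))
    }
    xy[i, ] <- vals[1:2]
  }
  tibble::tibble(x = xy[, 1], y = xy[, 2])
}

#' Write a contour to a CSV file
#'
#' @param contour A tibble/data frame with columns `x` and `y`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contour <- function(contour, path) {
  check_contour(contour)
  readr::write_csv(tibble::as_tibble(contour[, c("x", "y")]), path)
  invisible(path)
}

check_contour <- function(contour, min_points = 3) {
  if (!is.data.frame(contour) || !all(c("x", "y") %in% names(contour))) {
    abort("a contour must be a data frame with columns `x` and `y`.")
  }
  if (nrow(contour) < min_points) {
    abort(paste0("malformed contour: fewer than ", min_points, " points."))
  }
  if (anyNA(contour$x) || anyNA(contour$y)) {
    abort("malformed contour: missing coordinates.")
  }
  invisible(contour)
}

#' Convert a raw pixel contour to micrometers in mathematical orientation
#'
#' Applies the units/orientation contract the rest of the pipeline relies on:
#' coordinates are scaled from pixels to micrometers, the image y axis is
#' flipped (`y_um = -y_px * scale`) so that the spines point toward +Y, and
#' the traversal is reversed if needed so that the contour runs left to right
#' (first x <= last x). Under this contract spine peaks are signed-curvature
#' maxima and spiny forms get a positive spine thrust.
#'
#' @param contour Tibble with pixel columns `x`, `y` (e.g. from
#'   [read_contour()]).
#' @param scale_um_per_px Pixel size in micrometers. If `NULL`, 1 is assumed
#'   with a warning, because the curvature refinement threshold is expressed
#'   in 1/um and therefore scale-dependent.
#' @return A tibble with columns `x`, `y` in micrometers, with attributes
#'   `scale_um_per_px`, `y_flipped` and `reversed` recording the applied
#'   transform (see [denormalize_contour()]).
#' @examples
#' normalize_contour(tibble::tibble(x = c(0, 1, 2), y = c(0, 2, 0)),
#'                   scale_um_per_px = 0.5)
#' @export
normalize_contour <- function(contour, scale_um_per_px = NULL) {
  check_contour(contour)
  if (is.null(scale_um_per_px)) {
    warn("`scale_um_per_px` not supplied; assuming 1 (pixels taken as micrometers).")
    scale_um_per_px <- 1
  }
  if (!is.numeric(scale_um_per_px) || length(scale_um_per_px) != 1 ||
      !is.finite(scale_um_per_px) || scale_um_per_px <= 0) {
    abort("`scale_um_per_px` must be a single positive number.")
  }
  dup <- which(diff(contour$x) == 0 & diff(contour$y) == 0)
  if (length(dup) > 0) {
    abort(paste0("degenerate contour: repeated consecutive point at row ",
                 dup[1] + 1, "."))
  }
  x <- contour$x * scale_um_per_px
  y <- -contour$y * scale_um_per_px
  n <- length(x)
  reversed <- x[1] > x[n]
  if (reversed) {
    x <- rev(x)
    y <- rev(y)
  }
  out <- tibble::tibble(x = x, y = y)
  attr(out, "scale_um_per_px") <- scale_um_per_px
  attr(out, "y_flipped") <- TRUE
  attr(out, "reversed") <- reversed
  out
}

#' Invert the normalization transform
#'
#' Maps a contour produced by [normalize_contour()] back to the original
#' pixel coordinates using the transform recorded in its attributes.
#'
#' @param contour A normalized contour carrying normalization attributes.
#' @return A tibble with pixel columns `x`, `y` in the original digitization
#'   order.
#' @export
denormalize_contour <- function(contour) {
  scale <- attr(contour, "scale_um_per_px")
  if (is.null(scale)) {
    abort("`contour` carries no normalization provenance; was it produced by `normalize_contour()`?")
  }
  x <- contour$x
  y <- contour$y
  if (isTRUE(attr(contour, "reversed"))) {
    x <- rev(x)
    y <- rev(y)
  }
  tibble::tibble(x = x / scale, y = -y / scale)
}

manifest_columns <- c(
  "specimen_id", "species", "strain", "temperature_C",
  "collection_year", "scale_um_per_px", "source_file"
)

#' Read and validate a specimen manifest
#'
#' The manifest is one CSV row per specimen with columns `specimen_id`,
#' `species`, `strain`, `temperature_C`, `collection_year`,
#' `scale_um_per_px` and `source_file` (the per-specimen contour CSV,
#' relative to the manifest's directory unless absolute).
#'
#' @param path Manifest CSV path.
#' @return A validated tibble, one row per specimen.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(paste0("manifest not found: ", path))
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_manifest(m)
}

check_manifest <- function(manifest) {
  if (!is.data.frame(manifest)) abort("the manifest must be a data frame.")
  missing <- setdiff(manifest_columns, names(manifest))
  if (length(missing) > 0) {
    abort(paste0("manifest is missing required column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  dup <- unique(manifest$specimen_id[duplicated(manifest$specimen_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate specimen_id in manifest: ",
                 paste(dup, collapse = ", "), "."))
  }
  bad <- !is.finite(manifest$scale_um_per_px) | manifest$scale_um_per_px <= 0
  if (any(bad)) {
    abort(paste0("non-positive scale_um_per_px for specimen(s): ",
                 paste(manifest$specimen_id[bad], collapse = ", "), "."))
  }
  tibble::as_tibble(manifest)
}

#' Write / read a measurements table
#'
#' One row per specimen: metadata, status (`valid`, `excluded` or `error`),
#' spine thrust in micrometers, the five landmark coordinates in micrometers
#' and the exclusion reason for non-valid rows. Values round-trip through the
#' file at full double precision.
#'
#' @param measurements Tibble as produced by [measure_branches()].
#' @param path Output CSV path.
#' @return `path` invisibly (for `write_measurements`); a tibble (for
#'   `read_measurements`).
#' @export
write_measurements <- function(measurements, path) {
  if (!is.data.frame(measurements)) {
    abort("`measurements` must be a data frame.")
  }
  readr::write_csv(tibble::as_tibble(measurements), path, na = "")
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) abort(paste0("measurements file not found: ", path))
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  na = c("", "NA"))
}

#' Write landmarks in TPS format
#'
#' Emits one `LM=5` block per specimen with landmark coordinates in
#' micrometers, followed by an `ID=` line, the landmark interchange format of
#' standard geometric-morphometrics tools.
#'
#' @param landmarks Tibble with columns `specimen_id`, `landmark` (1..5),
#'   `x`, `y` (micrometers).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(landmarks, path) {
  need <- c("specimen_id", "landmark", "x", "y")
  if (!is.data.frame(landmarks) || !all(need %in% names(landmarks))) {
    abort("`landmarks` must have columns specimen_id, landmark, x, y.")
  }
  ids <- unique(landmarks$specimen_id)
  out <- character(0)
  for (id in ids) {
    block <- landmarks[landmarks$specimen_id == id, ]
    block <- block[order(block$landmark), ]
    out <- c(
      out,
      sprintf("LM=%d", nrow(block)),
      sprintf("%.6f %.6f", block$x, block$y),
      paste0("ID=", id)
    )
  }
  writeLines(out, path)
  invisible(path)
}

#' Read landmarks from a TPS file
#'
#' @param path TPS file path.
#' @return Tibble with columns `specimen_id`, `landmark`, `x`, `y`.
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) abort(paste0("TPS file not found: ", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  res <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!grepl("^LM\\s*=", lines[i], ignore.case = TRUE)) {
      abort(paste0("expected LM= at line ", i, " of ", path))
    }
    nlm <- as.integer(sub("^LM\\s*=\\s*", "", lines[i], ignore.case = TRUE))
    coords <- lines[i + seq_len(nlm)]
    xy <- do.call(rbind, lapply(coords, function(l) {
      as.numeric(strsplit(l, "[[:space:],]+")[[1]][1:2])
    }))
    i <- i + nlm + 1
    id <- NA_character_
    while (i <= length(lines) && !grepl("^LM\\s*=", lines[i], ignore.case = TRUE)) {
      if (grepl("^ID\\s*=", lines[i], ignore.case = TRUE)) {
        id <- sub("^ID\\s*=\\s*", "", lines[i], ignore.case = TRUE)
      }
      i <- i + 1
    }
    res[[length(res) + 1]] <- tibble::tibble(
      specimen_id = id, landmark = seq_len(nlm), x = xy[, 1], y = xy[, 2]
    )
  }
  dplyr::bind_rows(res)
}
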