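#' Spine thrust from a set of five landmarks
#'
#' Spine thrust (ST) measures how much the two lateral spines rise above the
#' central ridge. It is computed in the branch frame: the X axis passes
#' through landmarks 2 and 4 (the two cavities), oriented from 2 to 4, and
#' the Y axis completes a right-handed (counterclockwise) orthonormal basis.
#' With `Y1`, `Y3`, `Y5` the frame Y coordinates of landmarks 1, 3 and 5,
#'
#' `ST = (Y1 + Y5) / 2 - Y3`  (micrometers).
#'
#' ST is invariant under rigid motion of the landmark set, scales linearly
#' under uniform scaling (form, not pure shape), is positive for spiny
#' (*D. yakuba*-like) branches and null or negative for rounded
#' (*D. santomea*-like) branches.
#'
#' @param landmarks One of: a valid `branch_detection` from
#'   [detect_landmarks()]; a tibble with columns `landmark` (1..5), `x`, `y`;
#'   or a 5x2 matrix of coordinates ordered landmark 1 to 5. Micrometers.
#' @return A one-row tibble: `st_um`, `y_l1`, `y_l3`, `y_l5` (frame Y
#'   coordinates, micrometers).
#' @examples
#' lm <- tibble::tibble(
#'   landmark = 1:5,
#'   x = c(1, 0, 5, 10, 9),
#'   y = c(4, 0, 1, 0, 4)
#' )
#' spine_thrust(lm)  # st_um = 3
#' @export
spine_thrust <- function(landmarks) {
  P <- landmark_coords(landmarks)
  d <- P[4, ] - P[2, ]
  len <- sqrt(sum(d^2))
  if (!is.finite(len) || len < .Machine$double.eps * 100) {
    abort("degenerate frame: landmarks 2 and 4 coincide.")
  }
  u <- d / len
  v <- c(-u[2], u[1])   # +90 degrees counterclockwise
  rel <- sweep(P, 2, P[2, ])
  Y <- as.numeric(rel %*% v)
  tibble::tibble(
    st_um = (Y[1] + Y[5]) / 2 - Y[3],
    y_l1 = Y[1], y_l3 = Y[3], y_l5 = Y[5]
  )
}

landmark_coords <- function(landmarks) {
  if (inherits(landmarks, "branch_detection")) {
    if (landmarks$status != "valid") {
      abort("cannot compute spine thrust: detection outcome is excluded.")
    }
    landmarks <- landmarks$landmarks
  }
  if (is.matrix(landmarks)) {
    if (!all(dim(landmarks) == c(5, 2))) {
      abort("a landmark matrix must be 5 x 2 (landmarks 1..5, columns x, y).")
    }
    return(unname(landmarks))
  }
  if (is.data.frame(landmarks)) {
    need <- c("landmark", "x", "y")
    if (!all(need %in% names(landmarks)) || nrow(landmarks) != 5 ||
        !setequal(landmarks$landmark, 1:5)) {
      abort("a landmark table must have 5 rows with columns landmark (1..5), x, y.")
    }
    o <- order(landmarks$landmark)
    return(cbind(landmarks$x[o], landmarks$y[o]))
  }
  abort("`landmarks` must be a branch_detection, a 5-row table, or a 5x2 matrix.")
}
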