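# shared fixtures and independent oracles, all built in code

# rigid motion of an n x 2 coordinate matrix / data frame columns x, y
rigid_xy <- function(x, y, angle, dx = 0, dy = 0) {
  list(
    x = cos(angle) * x - sin(angle) * y + dx,
    y = sin(angle) * x + cos(angle) * y + dy
  )
}

# a gently wiggly open test contour (micrometers, left-to-right)
wiggly_contour <- function(n = 600, span = 40) {
  x <- seq(0, span, length.out = n)
  tibble::tibble(x = x, y = 3 * sin(x / 4) + 0.5 * cos(x / 1.5))
}

# extremum-bank constructor for landmark-rule tests
bank <- function(s_norm, value, kind) {
  tibble::tibble(
    index = as.integer(round(s_norm * 1000)),
    s_norm = s_norm,
    value = value,
    kind = kind,
    x = s_norm * 50,
    y = value
  )
}

# Brute-force, loop-based re-implementation of the landmark assignment rules,
# written independently of the package's vectorized path: landmark 3 is the
# maximum closest to the midline, 2 the lowest minimum to its left, 1 the
# maximum closest to 2 (left of 2), 4 the lowest minimum right of 3, 5 the
# maximum closest to 4 (right of 4); then if more than one maximum lies
# strictly between 2 and 4, landmark 3 moves to the highest of them. Ties go
# to the smaller index. Returns either list(status="excluded", reason=...) or
# list(status="valid", index=c(i1..i5)).
oracle_assign <- function(ext, midline = 0.475) {
  nr <- nrow(ext)
  is_max <- ext$kind == "maximum"
  excl <- function(reason) list(status = "excluded", reason = reason)

  closest <- function(rows, target) {
    best <- NA_integer_
    bestd <- Inf
    for (i in rows) {
      d <- abs(ext$s_norm[i] - target)
      if (d < bestd) {
        bestd <- d
        best <- i
      }
    }
    best
  }
  lowest <- function(rows) {
    best <- NA_integer_
    bestv <- Inf
    for (i in rows) {
      if (ext$value[i] < bestv) {
        bestv <- ext$value[i]
        best <- i
      }
    }
    best
  }
  highest <- function(rows) {
    best <- NA_integer_
    bestv <- -Inf
    for (i in rows) {
      if (ext$value[i] > bestv) {
        bestv <- ext$value[i]
        best <- i
      }
    }
    best
  }

  if (nr == 0) return(excl("no-extrema"))
  maxima <- which(is_max)
  if (length(maxima) == 0) return(excl("missing-L3"))
  i3 <- closest(maxima, midline)

  left_min <- which(!is_max & seq_len(nr) < i3)
  if (length(left_min) == 0) return(excl("missing-L2"))
  i2 <- lowest(left_min)

  left_max <- which(is_max & seq_len(nr) < i2)
  if (length(left_max) == 0) return(excl("missing-L1"))
  i1 <- closest(left_max, ext$s_norm[i2])

  right_min <- which(!is_max & seq_len(nr) > i3)
  if (length(right_min) == 0) return(excl("missing-L4"))
  i4 <- lowest(right_min)

  right_max <- which(is_max & seq_len(nr) > i4)
  if (length(right_max) == 0) return(excl("missing-L5"))
  i5 <- closest(right_max, ext$s_norm[i4])

  between <- which(is_max & seq_len(nr) > i2 & seq_len(nr) < i4)
  if (length(between) > 1) i3 <- highest(between)

  idx <- c(i1, i2, i3, i4, i5)
  if (any(diff(idx) <= 0)) return(excl("aberrant-ordering"))
  list(status = "valid", index = ext$index[idx])
}

# random alternating extremum bank (what real curvature profiles produce);
# abscissae are drawn without replacement so indices are distinct
random_bank <- function(n_ext, start_kind = "maximum") {
  s <- sort(sample(seq(0.21, 0.79, by = 0.002), n_ext))
  kinds <- rep(c(start_kind, setdiff(c("maximum", "minimum"), start_kind)),
               length.out = n_ext)
  bank(s, round(rnorm(n_ext), 2), kinds)
}
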