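#' Signed area of a polygon
#'
#' Shoelace formula on an open vertex matrix (first vertex not repeated).
#' The sign reflects vertex orientation; use [polygon_area()] for the
#' unsigned area.
#'
#' @param poly Two-column numeric matrix of vertices (x, y), in µm.
#' @return Signed area in µm².
#' @keywords internal
polygon_area_signed <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' Polygon area
#' @inheritParams polygon_area_signed
#' @return Area in µm² (non-negative).
#' @export
polygon_area <- function(poly) abs(polygon_area_signed(poly))

#' Polygon perimeter
#' @inheritParams polygon_area_signed
#' @return Perimeter in µm.
#' @export
polygon_perimeter <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

#' Polygon centroid
#' @inheritParams polygon_area_signed
#' @return Length-2 numeric vector (x, y) in µm.
#' @keywords internal
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}

#' Test whether points fall inside a polygon
#'
#' Even-odd rule with the half-open edge convention, so points exactly on a
#' shared edge are claimed by exactly one of two abutting polygons.
#'
#' @param px,py Numeric vectors of point coordinates.
#' @inheritParams polygon_area_signed
#' @return Logical vector.
#' @export
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi <= py & py < yj) | (yj <= py & py < yi))
    if (any(crosses)) {
      t <- (py[crosses] - yi) / (yj - yi)
      xhit <- xi + t * (xj - xi)
      inside[crosses] <- xor(inside[crosses], px[crosses] < xhit)
    }
    j <- i
  }
  inside
}

# Evaluate `code` under a fixed RNG seed without touching the caller's
# global RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
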