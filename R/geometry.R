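# Internal polygon and raster geometry.
#
# Conventions (documented in the package vignette and ?read_section):
# pixel coordinates are 0-based (x = column, y = row); a raster is a numeric
# matrix indexed [y + 1, x + 1]; polygons are n x 2 matrices of (x, y) vertices
# with the closing edge implicit (last vertex joins the first).

poly_matrix <- function(x, y = NULL) {
  if (is.null(y)) {
    p <- as.matrix(x)
  } else {
    p <- cbind(x, y)
  }
  storage.mode(p) <- "double"
  colnames(p) <- c("x", "y")
  p
}

# Drop consecutive duplicate vertices (and a repeated closing vertex).
poly_dedupe <- function(poly) {
  n <- nrow(poly)
  if (n < 2) return(poly)
  keep <- c(TRUE, rowSums(abs(poly[-1, , drop = FALSE] -
                                poly[-n, , drop = FALSE])) > 0)
  poly <- poly[keep, , drop = FALSE]
  n <- nrow(poly)
  if (n > 1 && all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  poly
}

poly_edge_lengths <- function(poly) {
  nxt <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  sqrt(rowSums((nxt - poly)^2))
}

poly_perimeter <- function(poly) sum(poly_edge_lengths(poly))

poly_signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Proper-crossing test for two closed segments; shared endpoints of adjacent
# polygon edges are handled by the caller (adjacent edges are skipped).
segments_cross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

poly_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent edges (share a vertex), including the wrap pair (1, n)
      if (j == i + 1 || (i == 1 && j == n)) next
      a <- poly[i, ]; b <- poly[if (i == n) 1 else i + 1, ]
      c <- poly[j, ]; d <- poly[if (j == n) 1 else j + 1, ]
      if (segments_cross(a, b, c, d)) return(FALSE)
    }
  }
  TRUE
}

# Even-odd ray casting, vectorised over query points.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xj <- c(x[n], x[-n]); yj <- c(y[n], y[-n])
  inside <- logical(length(px))
  for (k in seq_len(n)) {
    cond <- ((y[k] > py) != (yj[k] > py))
    if (any(cond)) {
      xi <- (xj[k] - x[k]) * (py[cond] - y[k]) / (yj[k] - y[k]) + x[k]
      inside[cond] <- xor(inside[cond], px[cond] < xi)
    }
  }
  inside
}

# Resample the closed boundary at equal arc-length steps. Returns the sample
# points, their arc positions (px) and fractions of total perimeter, and the
# unit inward normal at each sample.
poly_resample <- function(poly, step) {
  stopifnot(step > 0)
  per <- poly_perimeter(poly)
  n_s <- max(4L, floor(per / step))
  s <- (seq_len(n_s) - 1) * (per / n_s)
  el <- poly_edge_lengths(poly)
  cum <- c(0, cumsum(el))
  edge <- findInterval(s, cum, rightmost.closed = TRUE)
  edge[edge > nrow(poly)] <- nrow(poly)
  t_in <- (s - cum[edge]) / el[edge]
  nxt <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  pts <- poly[edge, , drop = FALSE] + t_in * (nxt[edge, , drop = FALSE] -
                                                poly[edge, , drop = FALSE])
  # tangent by central difference on the resampled loop -> smooth normals
  ip <- c(2:n_s, 1); im <- c(n_s, 1:(n_s - 1))
  tx <- pts[ip, 1] - pts[im, 1]
  ty <- pts[ip, 2] - pts[im, 2]
  tl <- sqrt(tx^2 + ty^2)
  tl[tl == 0] <- 1
  tx <- tx / tl; ty <- ty / tl
  if (poly_signed_area(poly) > 0) {
    nx <- -ty; ny <- tx           # CCW: interior to the left of the tangent
  } else {
    nx <- ty; ny <- -tx
  }
  list(points = poly_matrix(pts[, 1], pts[, 2]),
       arc = s, frac = s / per, perimeter = per,
       normal = poly_matrix(nx, ny))
}

# Bilinear interpolation at continuous 0-based (x, y); coordinates are clamped
# to the raster so band samples near the edge degrade gracefully.
bilinear <- function(raster, x, y) {
  nr <- nrow(raster); nc <- ncol(raster)
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  x0 <- pmin(floor(x), nc - 2); x0[nc == 1] <- 0
  y0 <- pmin(floor(y), nr - 2); y0[nr == 1] <- 0
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1)
  i01 <- cbind(y0 + 1, pmin(x0 + 2, nc))
  i10 <- cbind(pmin(y0 + 2, nr), x0 + 1)
  i11 <- cbind(pmin(y0 + 2, nr), pmin(x0 + 2, nc))
  raster[i00] * (1 - fx) * (1 - fy) + raster[i01] * fx * (1 - fy) +
    raster[i10] * (1 - fx) * fy + raster[i11] * fx * fy
}
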