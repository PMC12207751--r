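## Planar geometry primitives for strip-transect effort computation.
## All coordinates are projected kilometres; polygons are matrices with
## columns (x, y), vertices in order, not closed.

## Corners of the rectangle obtained by buffering segment (p0, p1) by `hw`
## each side with flat end caps (a physical survey strip of width 2*hw).
seg_buffer <- function(x0, y0, x1, y1, hw) {
  dx <- x1 - x0; dy <- y1 - y0
  len <- sqrt(dx^2 + dy^2)
  if (len <= 0) return(NULL)
  nx <- -dy / len; ny <- dx / len   # unit normal
  cbind(x = c(x0 + hw * nx, x1 + hw * nx, x1 - hw * nx, x0 - hw * nx),
        y = c(y0 + hw * ny, y1 + hw * ny, y1 - hw * ny, y0 - hw * ny))
}

## Sutherland-Hodgman clip of a convex polygon against the axis-aligned
## rectangle (xlo, xhi, ylo, yhi). Convex in, convex out.
clip_poly_rect <- function(poly, xlo, xhi, ylo, yhi) {
  clip_half <- function(p, keep, cross_t) {
    n <- nrow(p)
    if (n == 0) return(p)
    inside <- keep(p)
    out_x <- numeric(0); out_y <- numeric(0)
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1L else k + 1L
      if (inside[k]) { out_x <- c(out_x, p[k, 1]); out_y <- c(out_y, p[k, 2]) }
      if (inside[k] != inside[k2]) {
        t <- cross_t(p[k, ], p[k2, ])
        out_x <- c(out_x, p[k, 1] + t * (p[k2, 1] - p[k, 1]))
        out_y <- c(out_y, p[k, 2] + t * (p[k2, 2] - p[k, 2]))
      }
    }
    cbind(x = out_x, y = out_y)
  }
  p <- poly
  p <- clip_half(p, function(q) q[, 1] >= xlo,
                 function(a, b) (xlo - a[1]) / (b[1] - a[1]))
  p <- clip_half(p, function(q) q[, 1] <= xhi,
                 function(a, b) (xhi - a[1]) / (b[1] - a[1]))
  p <- clip_half(p, function(q) q[, 2] >= ylo,
                 function(a, b) (ylo - a[2]) / (b[2] - a[2]))
  p <- clip_half(p, function(q) q[, 2] <= yhi,
                 function(a, b) (yhi - a[2]) / (b[2] - a[2]))
  p
}

## Shoelace area of a polygon (absolute value).
poly_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

## Liang-Barsky: parameter interval [t0, t1] of segment (p0, p1) inside the
## rectangle, or NULL if disjoint. Used for in-cell trackline lengths.
clip_seg_rect <- function(x0, y0, x1, y1, xlo, xhi, ylo, yhi) {
  dx <- x1 - x0; dy <- y1 - y0
  t0 <- 0; t1 <- 1
  for (s in list(c(-dx, x0 - xlo), c(dx, xhi - x0),
                 c(-dy, y0 - ylo), c(dy, yhi - y0))) {
    p <- s[1]; q <- s[2]
    if (p == 0) { if (q < 0) return(NULL) }
    else {
      r <- q / p
      if (p < 0) { if (r > t1) return(NULL); if (r > t0) t0 <- r }
      else       { if (r < t0) return(NULL); if (r < t1) t1 <- r }
    }
  }
  c(t0, t1)
}

## Uniform sample of n points inside a convex polygon (fan triangulation).
sample_in_poly <- function(n, poly) {
  m <- nrow(poly)
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  if (m < 3) stop("degenerate polygon")
  areas <- vapply(2:(m - 1), function(k)
    poly_area(poly[c(1, k, k + 1), , drop = FALSE]), 0)
  tri <- sample.int(m - 2, n, replace = TRUE, prob = pmax(areas, 1e-300))
  a <- poly[1, ]; b <- poly[tri + 1, , drop = FALSE]; c_ <- poly[tri + 2, , drop = FALSE]
  u <- stats::runif(n); v <- stats::runif(n)
  flip <- u + v > 1
  u[flip] <- 1 - u[flip]; v[flip] <- 1 - v[flip]
  cbind(x = a[1] + u * (b[, 1] - a[1]) + v * (c_[, 1] - a[1]),
        y = a[2] + u * (b[, 2] - a[2]) + v * (c_[, 2] - a[2]))
}

polyline_length <- function(x, y) sum(sqrt(diff(x)^2 + diff(y)^2))
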