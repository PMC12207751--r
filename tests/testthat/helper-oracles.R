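# Independent oracles used across tests. They deliberately use different
# algorithms from the package internals they check.

# Area of the intersection of two convex polygons by vertex enumeration:
# corners of A inside B, corners of B inside A, and all edge-edge crossing
# points, hulled and measured by the shoelace formula. Independent of the
# Sutherland-Hodgman clipper used by the package.
convex_intersection_area <- function(A, B) {
  inside <- function(P, Q) {
    # point P inside convex polygon Q (counter-clockwise or clockwise)
    n <- nrow(Q)
    s <- 0
    for (i in seq_len(n)) {
      j <- if (i == n) 1 else i + 1
      cr <- (Q[j, 1] - Q[i, 1]) * (P[2] - Q[i, 2]) -
        (Q[j, 2] - Q[i, 2]) * (P[1] - Q[i, 1])
      if (abs(cr) < 1e-12) next
      if (s == 0) s <- sign(cr) else if (sign(cr) != s) return(FALSE)
    }
    TRUE
  }
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- p2 - p1; d2 <- p4 - p3
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-14) return(NULL)
    t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / den
    u <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / den
    if (t < -1e-12 || t > 1 + 1e-12 || u < -1e-12 || u > 1 + 1e-12) return(NULL)
    p1 + t * d1
  }
  pts <- NULL
  for (i in seq_len(nrow(A))) if (inside(A[i, ], B)) pts <- rbind(pts, A[i, ])
  for (i in seq_len(nrow(B))) if (inside(B[i, ], A)) pts <- rbind(pts, B[i, ])
  for (i in seq_len(nrow(A))) {
    i2 <- if (i == nrow(A)) 1 else i + 1
    for (j in seq_len(nrow(B))) {
      j2 <- if (j == nrow(B)) 1 else j + 1
      p <- seg_int(A[i, ], A[i2, ], B[j, ], B[j2, ])
      if (!is.null(p)) pts <- rbind(pts, p)
    }
  }
  if (is.null(pts) || nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts)
  P <- pts[h, , drop = FALSE]
  x <- P[, 1]; y <- P[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Corners of the flat-capped buffer rectangle of a segment (re-derived
# independently via rotation matrices).
oracle_strip_rect <- function(p0, p1, hw) {
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  u <- d / len
  nrm <- c(-u[2], u[1])
  rbind(p0 + hw * nrm, p1 + hw * nrm, p1 - hw * nrm, p0 - hw * nrm)
}

# Brute-force Dijkstra over an explicit adjacency list (O(V^2) scan),
# independent of igraph.
oracle_dijkstra <- function(n_vertices, edges, source) {
  dist <- rep(Inf, n_vertices)
  dist[source] <- 0
  done <- rep(FALSE, n_vertices)
  adj <- vector("list", n_vertices)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]; w <- edges[k, 3]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  repeat {
    cand <- which(!done & is.finite(dist))
    if (length(cand) == 0) break
    v <- cand[which.min(dist[cand])]
    done[v] <- TRUE
    for (k in seq_len(NROW(adj[[v]]))) {
      b <- adj[[v]][k, 1]; w <- adj[[v]][k, 2]
      if (dist[v] + w < dist[b]) dist[b] <- dist[v] + w
    }
  }
  dist
}

# Interpolated quantile computed from first principles (sorting plus linear
# interpolation at h = (n - 1) p + 1), independent of stats::quantile.
oracle_quantile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# A small default world shared by several tests.
small_world <- function(seed = 1, extent = c(0, 96, 0, 96)) {
  gen_environment(world_config(
    extent = extent,
    land_spec = list(list(x = extent[2] - 4, y = mean(extent[3:4]),
                          rx = 16, ry = 40))), seed = seed)
}

# Model-ready records for a quick survey over a depth-driven truth.
quick_survey <- function(seed = 1, intercept = -1.2, theta = 2,
                         detect = list(delta_alt = 0,
                                       beta_ss = c(high = 0, low = 0)),
                         group_probs = c(0.805, 0.107, 0.088),
                         broad_spacing_km = 6, fine_region = NULL,
                         extent = c(0, 96, 0, 96)) {
  w <- small_world(seed, extent)
  tr <- gen_truth(w, effects = list(depth = function(d)
    0.9 * exp(pmax(d, -1200) / 300)),
    intercept = intercept, theta = theta, detect = detect,
    group_probs = group_probs)
  de <- gen_transects(w, broad_spacing_km = broad_spacing_km,
                      fine_region = fine_region, seed = seed + 1)
  si <- gen_sightings(tr, de, seed = seed + 2)
  rec <- append_covariates(
    aggregate_counts(w$grid, si, effort_per_cell(w$grid, de)),
    build_covariates(w))
  list(world = w, truth = tr, design = de, sightings = si, records = rec)
}
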