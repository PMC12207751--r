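## Covariate engineering: distances, gradients, IDW appending, temporal
## matching, the land-avoiding colony proximity score and Box-Cox
## transforms.

#' Euclidean distance from cell centres to a target point set
#'
#' @param grid a [build_grid()] grid (cell centres are the query points).
#' @param targets two-column matrix or data.frame of target coordinates (km),
#'   e.g. coastline vertices or shelf-contour vertices.
#' @return numeric vector: per-cell distance (km) to the nearest target.
#' @export
distance_to_set <- function(grid, targets) {
  targets <- as.matrix(targets)
  if (nrow(targets) == 0) stop_param("target set is empty")
  cc <- cell_centres(grid)
  out <- numeric(nrow(cc))
  block <- 512L
  for (s in seq(1, nrow(cc), by = block)) {
    e <- min(s + block - 1L, nrow(cc))
    d2 <- outer(cc$x[s:e], targets[, 1], "-")^2 +
      outer(cc$y[s:e], targets[, 2], "-")^2
    out[s:e] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' Coastline and shelf-edge vertex sets of a synthetic world
#'
#' The coastline is the set of cell-corner vertices of edges separating land
#' from sea cells; the shelf contour is the analogous boundary between cells
#' shallower and deeper than `iso_depth_m`.
#'
#' @param world a `dsm_world`.
#' @param iso_depth_m isobath defining the shelf edge (default -500 m).
#' @return two-column matrix of vertex coordinates (km).
#' @export
coastline_points <- function(world) boundary_points(world$grid, world$land)

#' @rdname coastline_points
#' @export
shelf_contour_points <- function(world, iso_depth_m = -500) {
  deep <- world$fields$depth <= iso_depth_m
  deep[is.na(deep)] <- FALSE
  if (!any(deep) || all(deep[!world$land]))
    stop_param("no ", iso_depth_m, " m contour inside the study area")
  boundary_points(world$grid, deep)
}

boundary_points <- function(grid, mask) {
  nx <- grid$nx; ny <- grid$ny
  pts <- NULL
  ## vertical edges between horizontally adjacent cells of opposite status
  dif <- mask[-nx, , drop = FALSE] != mask[-1, , drop = FALSE]
  idx <- which(dif, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    x <- grid$x0 + idx[, 1] * grid$cell_km
    y0 <- grid$y0 + (idx[, 2] - 1) * grid$cell_km
    pts <- rbind(pts, cbind(x, y0), cbind(x, y0 + grid$cell_km))
  }
  dif <- mask[, -ny, drop = FALSE] != mask[, -1, drop = FALSE]
  idx <- which(dif, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    y <- grid$y0 + idx[, 2] * grid$cell_km
    x0 <- grid$x0 + (idx[, 1] - 1) * grid$cell_km
    pts <- rbind(pts, cbind(x0, y), cbind(x0 + grid$cell_km, y))
  }
  if (is.null(pts)) stop_param("mask has no boundary inside the grid")
  unique(pts)
}

#' Gradient magnitude of a gridded field (Horn's method)
#'
#' Central 3 x 3 finite differences with Sobel-style weighting in the
#' interior; one-sided differences at grid edges. Missing neighbours
#' propagate to missing output.
#'
#' @param field nx x ny matrix.
#' @param cell_km grid spacing (km).
#' @param degrees if `TRUE`, return slope in degrees (`atan` of the
#'   magnitude with the field in the same length unit as the grid is not
#'   assumed: the magnitude is first interpreted as rise-per-km).
#' @return matrix of gradient magnitudes (field units per km), or degrees.
#' @export
terrain_gradient <- function(field, cell_km, degrees = FALSE) {
  nx <- nrow(field); ny <- ncol(field)
  pad <- matrix(NA_real_, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- field
  ## replicate edges so border cells get one-sided differences
  pad[1, ] <- pad[2, ]; pad[nx + 2, ] <- pad[nx + 1, ]
  pad[, 1] <- pad[, 2]; pad[, ny + 2] <- pad[, ny + 1]
  i <- 2:(nx + 1); j <- 2:(ny + 1)
  z <- function(di, dj) pad[i + di, j + dj, drop = FALSE]
  ## effective x-spacing doubles in the interior (i-1 .. i+1) but the edge
  ## replication halves it at borders; account per-cell
  hx <- matrix(2, nx, ny); hx[c(1, nx), ] <- 1
  hy <- matrix(2, nx, ny); hy[, c(1, ny)] <- 1
  gx <- (z(1, -1) + 2 * z(1, 0) + z(1, 1) -
           z(-1, -1) - 2 * z(-1, 0) - z(-1, 1)) / (4 * hx * cell_km)
  gy <- (z(-1, 1) + 2 * z(0, 1) + z(1, 1) -
           z(-1, -1) - 2 * z(0, -1) - z(1, -1)) / (4 * hy * cell_km)
  mag <- sqrt(gx^2 + gy^2)
  if (degrees) atan(mag / 1000) * 180 / pi else mag  # field in m -> degrees
}

#' Inverse-distance-weighted interpolation
#'
#' Appends point values to query locations with weights `d^-power`; an exact
#' hit (distance below 1e-9) returns the source value itself. Queries with
#' no source inside `max_radius` return `NA`.
#'
#' @param src data.frame with `x`, `y`, `value`.
#' @param query data.frame with `x`, `y`.
#' @param power IDW exponent (default 2).
#' @param max_radius search radius in km (default `Inf`).
#' @return numeric vector of interpolated values, one per query row.
#' @export
idw_append <- function(src, query, power = 2, max_radius = Inf) {
  if (nrow(src) == 0) stop_param("at least one source point is required")
  out <- numeric(nrow(query))
  for (k in seq_len(nrow(query))) {
    d <- sqrt((src$x - query$x[k])^2 + (src$y - query$y[k])^2)
    hit <- which(d < 1e-9)
    if (length(hit) > 0) { out[k] <- src$value[hit[1]]; next }
    use <- d <= max_radius
    if (!any(use)) { out[k] <- NA_real_; next }
    w <- d[use]^(-power)
    out[k] <- sum(w * src$value[use]) / sum(w)
  }
  out
}

#' Match a Julian day to its 8-day composite window
#'
#' Remote-sensing composites cover fixed windows `[8k + 1, 8k + 8]` of the
#' Julian calendar. `temporal_match` returns the layer whose window contains
#' `julian_day`; for daily layers (e.g. salinity) it returns the mean of the
#' 8 daily layers of that window.
#'
#' @param layers named list of matrices. For composites, names are the
#'   window start days ("1", "9", "17", ...); for daily layers, names are
#'   the Julian days.
#' @param julian_day integer day of year.
#' @param daily whether `layers` are daily (averaged over the window).
#' @return the matched (or averaged) layer.
#' @export
temporal_match <- function(layers, julian_day, daily = FALSE) {
  w <- composite_window(julian_day)
  if (!daily) {
    key <- as.character(w[1])
    if (!key %in% names(layers))
      stop_param("no composite layer covering day ", julian_day)
    return(layers[[key]])
  }
  keys <- as.character(seq(w[1], w[2]))
  if (!all(keys %in% names(layers)))
    stop_param("daily layers do not cover window ", w[1], "-", w[2])
  Reduce(`+`, layers[keys]) / length(keys)
}

#' @rdname temporal_match
#' @export
composite_window <- function(julian_day) {
  if (julian_day < 1) stop_param("julian_day must be >= 1")
  k <- (julian_day - 1) %/% 8
  c(8 * k + 1, 8 * k + 8)
}

#' Land-avoiding colony proximity score
#'
#' For every colony, the shortest over-sea path length from each sea cell
#' centre to the colony is computed on the 8-connected cell graph
#' (orthogonal step = cell size, diagonal = cell size * sqrt(2)); land cells
#' are impassable and each colony is snapped to its nearest sea cell. The
#' score of a cell is the sum over colonies of breeding pairs divided by the
#' squared distance, with distance clamped below at half a cell so the
#' colony's own cell is finite. Colonies unreachable from a cell (enclosed
#' basins) contribute zero there.
#'
#' @param world a `dsm_world`.
#' @param colonies data.frame with `x`, `y`, `pairs`.
#' @return numeric vector over all cells (NA on land): score in
#'   pairs km^-2.
#' @export
colony_proximity_score <- function(world, colonies) {
  if (is.null(colonies) || nrow(colonies) == 0)
    stop_param("colony table is empty")
  grid <- world$grid
  d <- sea_distance_km(world, cbind(colonies$x, colonies$y))
  d <- pmax(d, grid$cell_km / 2)      # clamp at the colony's own cell
  unreachable <- is.infinite(d)
  if (any(unreachable)) {
    message(sum(unreachable), " (cell, colony) pair(s) unreachable over sea; ",
            "those colonies contribute 0 there")
    d[unreachable] <- Inf
  }
  score <- as.vector((1 / d^2) %*% colonies$pairs)
  score[as.vector(world$land)] <- NA_real_
  score
}

## Least-cost over-sea distances (km) from every cell to each origin point
## (snapped to its nearest sea cell). Returns an n_cells x n_origins matrix
## with NA on land rows and Inf where unreachable.
sea_distance_km <- function(world, origins) {
  grid <- world$grid
  sea <- which(!as.vector(world$land))
  cc <- cell_centres(grid)
  idx_of <- integer(n_cells(grid)); idx_of[sea] <- seq_along(sea)
  ## 8-neighbour edges among sea cells
  nx <- grid$nx; ny <- grid$ny
  i <- (sea - 1L) %% nx + 1L; j <- (sea - 1L) %/% nx + 1L
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (s in list(c(1L, 0L, 1), c(0L, 1L, 1), c(1L, 1L, sqrt(2)),
                 c(1L, -1L, sqrt(2)))) {
    i2 <- i + s[1]; j2 <- j + s[2]
    ok <- i2 >= 1L & i2 <= nx & j2 >= 1L & j2 <= ny
    nb <- (j2[ok] - 1L) * nx + i2[ok]
    sea_nb <- idx_of[nb] > 0L
    from <- c(from, idx_of[sea[ok]][sea_nb])
    to <- c(to, idx_of[nb][sea_nb])
    w <- c(w, rep(s[3] * grid$cell_km, sum(sea_nb)))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w),
    directed = FALSE,
    vertices = data.frame(name = seq_along(sea)))
  snap <- vapply(seq_len(nrow(origins)), function(k)
    which.min((cc$x[sea] - origins[k, 1])^2 + (cc$y[sea] - origins[k, 2])^2), 0L)
  dmat <- matrix(NA_real_, n_cells(grid), nrow(origins))
  ## vertex order in g is seq_along(sea) by construction
  dmat[sea, ] <- t(igraph::distances(g, v = as.character(snap),
                                     algorithm = "dijkstra"))
  dmat
}

sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x); s2 <- mean((x - m)^2)
  mean((x - m)^3) / s2^1.5
}

#' Box-Cox transformation with persisted lambda
#'
#' Estimates the Box-Cox parameter by maximising the profile log-likelihood
#' of the normal model over lambda in [-2, 2] (coarse 0.01 grid, then local
#' refinement), after shifting the variable by `1 - min(x)` when any value
#' is non-positive. The fitted `lambda` and `shift` are stored so the same
#' transform can be re-applied at prediction time, and an exact inverse is
#' provided.
#'
#' @param x numeric vector.
#' @param lambda optional fixed lambda (skips estimation).
#' @return a `dsm_boxcox` object: `lambda`, `shift`, the transformed values
#'   in `$y`.
#' @export
boxcox_fit <- function(x, lambda = NULL) {
  x <- as.numeric(x)
  shift <- if (min(x, na.rm = TRUE) <= 0) 1 - min(x, na.rm = TRUE) else 0
  xs <- x + shift
  if (any(xs <= 0, na.rm = TRUE)) stop_param("non-positive values after shift")
  if (is.null(lambda)) {
    ok <- is.finite(xs)
    ll <- function(l) {
      y <- bc_forward(xs[ok], l)
      n <- sum(ok)
      -n / 2 * log(mean((y - mean(y))^2)) + (l - 1) * sum(log(xs[ok]))
    }
    grid_l <- seq(-2, 2, by = 0.01)
    vals <- vapply(grid_l, ll, 0)
    k <- which.max(vals)
    lo <- grid_l[max(1, k - 1)]; hi <- grid_l[min(length(grid_l), k + 1)]
    lambda <- stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-8)$maximum
  }
  structure(list(lambda = lambda, shift = shift, y = bc_forward(xs, lambda)),
            class = "dsm_boxcox")
}

bc_forward <- function(x, lambda)
  if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda

#' @rdname boxcox_fit
#' @param object a fitted `dsm_boxcox`.
#' @param newx raw values to transform with the stored lambda and shift.
#' @export
boxcox_apply <- function(object, newx) {
  xs <- newx + object$shift
  if (any(xs <= 0, na.rm = TRUE))
    stop_param("non-positive values after stored shift")
  bc_forward(xs, object$lambda)
}

#' @rdname boxcox_fit
#' @param y transformed values to map back to the raw scale.
#' @export
boxcox_inverse <- function(object, y) {
  l <- object$lambda
  x <- if (abs(l) < 1e-12) exp(y) else (y * l + 1)^(1 / l)
  x - object$shift
}

#' Assemble the per-cell covariate table of a synthetic world
#'
#' Computes every model covariate for all sea cells: distance to coast,
#' distance to the 500 m isobath, depth (non-positive), seabed slope,
#' chl-a, SST, SSS, their gradient magnitudes and the colony proximity
#' score. Dynamic fields can be taken from a specific survey year or
#' averaged over years (the prediction-grid convention).
#'
#' @param world a `dsm_world`.
#' @param colonies optional colony table for the proximity score.
#' @param year a survey year present in the world, `"mean"` for the
#'   across-year average, or `NULL` for the climatology.
#' @return data.frame keyed by `cell` with centre coordinates and all
#'   covariates; sea cells only.
#' @export
build_covariates <- function(world, colonies = NULL, year = NULL) {
  grid <- world$grid
  cc <- cell_centres(grid)
  dyn <- dynamic_fields(world, year)
  depth <- world$fields$depth
  tab <- data.frame(
    cell = cc$cell, x = cc$x, y = cc$y,
    dist_coast = distance_to_set(grid, coastline_points(world)),
    dist_shelf = distance_to_set(grid, shelf_contour_points(world)),
    depth = as.vector(depth),
    slope = as.vector(terrain_gradient(depth, grid$cell_km, degrees = TRUE)),
    chl_a = as.vector(dyn$chl_a),
    sst = as.vector(dyn$sst),
    sss = as.vector(dyn$sss),
    grad_chl = as.vector(terrain_gradient(dyn$chl_a, grid$cell_km)),
    grad_sst = as.vector(terrain_gradient(dyn$sst, grid$cell_km)),
    grad_sss = as.vector(terrain_gradient(dyn$sss, grid$cell_km)))
  if (!is.null(colonies))
    tab$colony_score <- colony_proximity_score(world, colonies)
  tab[!as.vector(world$land), , drop = FALSE]
}

dynamic_fields <- function(world, year) {
  if (is.null(year)) return(world$fields[c("chl_a", "sst", "sss")])
  if (identical(year, "mean")) {
    yf <- world$year_fields
    if (length(yf) == 0) return(world$fields[c("chl_a", "sst", "sss")])
    out <- lapply(c("chl_a", "sst", "sss"), function(v)
      Reduce(`+`, lapply(yf, `[[`, v)) / length(yf))
    names(out) <- c("chl_a", "sst", "sss")
    return(out)
  }
  key <- as.character(year)
  if (!key %in% names(world$year_fields))
    stop_param("no fields for year ", year)
  world$year_fields[[key]]
}

#' Join per-cell covariates onto the (cell x pass) survey records
#'
#' @param records output of [aggregate_counts()].
#' @param covariates output of [build_covariates()] (or its
#'   [auto_boxcox()]-transformed version; the transform attribute is
#'   carried over).
#' @return `records` with the covariate columns appended by cell id.
#' @export
append_covariates <- function(records, covariates) {
  keep <- setdiff(names(covariates), c("x", "y"))
  out <- merge(records, covariates[keep], by = "cell", sort = FALSE)
  attr(out, "boxcox") <- attr(covariates, "boxcox")
  out
}

#' Apply Box-Cox transforms across a covariate table
#'
#' Transforms every requested column (default: those with absolute sample
#' skewness above 1) and stores the fitted `dsm_boxcox` objects as the
#' `"boxcox"` attribute, so [reapply_boxcox()] can use the same lambdas on a
#' prediction table.
#'
#' @param tab covariate data.frame.
#' @param vars columns to consider; default all numeric covariates except
#'   coordinates and `cell`.
#' @param skew_threshold transform when `|skewness|` exceeds this.
#' @return the transformed table with the `"boxcox"` attribute.
#' @export
auto_boxcox <- function(tab, vars = NULL, skew_threshold = 1) {
  if (is.null(vars))
    vars <- setdiff(names(tab)[vapply(tab, is.numeric, TRUE)],
                    c("cell", "x", "y", "count", "effort_km2", "line_km",
                      "julian_day", "year", "mean_ss"))
  tf <- list()
  for (v in vars) {
    if (abs(sample_skewness(tab[[v]])) > skew_threshold) {
      bc <- boxcox_fit(tab[[v]])
      tab[[v]] <- bc$y
      bc$y <- NULL
      tf[[v]] <- bc
    }
  }
  attr(tab, "boxcox") <- tf
  tab
}

#' @rdname auto_boxcox
#' @param newtab a raw-scale table to transform with the lambdas stored on
#'   `tab` (never re-estimated).
#' @export
reapply_boxcox <- function(tab, newtab) {
  tf <- attr(tab, "boxcox")
  for (v in names(tf)) newtab[[v]] <- boxcox_apply(tf[[v]], newtab[[v]])
  attr(newtab, "boxcox") <- tf
  newtab
}
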