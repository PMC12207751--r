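## Gridding: intersect survey strips with analysis cells, accumulate
## on-effort area per (cell x survey pass), and aggregate sighting counts.
## A survey pass is one transect flown on one day; repeated passes over a
## cell stay separate rows so the effort offset keeps its meaning.

## Candidate cell ids whose rectangles can intersect the axis-aligned
## bounding box (xlo..xhi, ylo..yhi).
candidate_cells <- function(grid, xlo, xhi, ylo, yhi) {
  i0 <- max(1L, floor((xlo - grid$x0) / grid$cell_km) + 1L)
  i1 <- min(grid$nx, floor((xhi - grid$x0) / grid$cell_km - 1e-12) + 1L)
  j0 <- max(1L, floor((ylo - grid$y0) / grid$cell_km) + 1L)
  j1 <- min(grid$ny, floor((yhi - grid$y0) / grid$cell_km - 1e-12) + 1L)
  if (i1 < i0 || j1 < j0) return(integer(0))
  as.vector(outer(i0:i1, (j0:j1 - 1L) * grid$nx, "+"))
}

## Clipped strip polygons of one straight segment: list of (cell, poly, area)
## plus the in-cell trackline length per cell.
strip_cell_polys <- function(grid, x0, y0, x1, y1, hw) {
  rect <- seg_buffer(x0, y0, x1, y1, hw)
  if (is.null(rect)) return(NULL)
  cells <- candidate_cells(grid, min(rect[, 1]), max(rect[, 1]),
                           min(rect[, 2]), max(rect[, 2]))
  out <- vector("list", length(cells)); n <- 0L
  cr <- cell_rect(grid, cells)
  seg_len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  for (k in seq_along(cells)) {
    p <- clip_poly_rect(rect, cr[k, 1], cr[k, 2], cr[k, 3], cr[k, 4])
    a <- poly_area(p)
    if (a > 1e-12) {
      tt <- clip_seg_rect(x0, y0, x1, y1, cr[k, 1], cr[k, 2], cr[k, 3], cr[k, 4])
      lin <- if (is.null(tt)) 0 else (tt[2] - tt[1]) * seg_len
      n <- n + 1L
      out[[n]] <- list(cell = cells[k], poly = p, area = a, line_km = lin)
    }
  }
  out[seq_len(n)]
}

## Merge on-effort segments of one pass that share a carrier line into
## maximal non-overlapping sub-segments (1-D interval union along the line),
## so overlapping strips within a pass are never double-counted.
merge_collinear <- function(seg) {
  if (nrow(seg) <= 1) return(seg[, c("x0", "y0", "x1", "y1")])
  ux <- seg$x1[1] - seg$x0[1]; uy <- seg$y1[1] - seg$y0[1]
  l <- sqrt(ux^2 + uy^2); ux <- ux / l; uy <- uy / l
  perp <- abs((seg$x0 - seg$x0[1]) * uy - (seg$y0 - seg$y0[1]) * ux) +
    abs((seg$x1 - seg$x0[1]) * uy - (seg$y1 - seg$y0[1]) * ux)
  if (any(perp > 1e-9)) return(seg[, c("x0", "y0", "x1", "y1")])  # not collinear
  t0 <- (seg$x0 - seg$x0[1]) * ux + (seg$y0 - seg$y0[1]) * uy
  t1 <- (seg$x1 - seg$x0[1]) * ux + (seg$y1 - seg$y0[1]) * uy
  lo <- pmin(t0, t1); hi <- pmax(t0, t1)
  o <- order(lo); lo <- lo[o]; hi <- hi[o]
  mlo <- lo[1]; mhi <- hi[1]; res <- NULL
  for (k in seq_along(lo)[-1]) {
    if (lo[k] <= mhi + 1e-12) mhi <- max(mhi, hi[k])
    else { res <- rbind(res, c(mlo, mhi)); mlo <- lo[k]; mhi <- hi[k] }
  }
  res <- rbind(res, c(mlo, mhi))
  data.frame(x0 = seg$x0[1] + res[, 1] * ux, y0 = seg$y0[1] + res[, 1] * uy,
             x1 = seg$x0[1] + res[, 2] * ux, y1 = seg$y0[1] + res[, 2] * uy)
}

#' Per-cell survey effort area
#'
#' Buffers every on-effort transect segment by the strip half-width (flat end
#' caps), clips the strip to each grid cell, and returns the surveyed area
#' per (cell, survey pass). Off-effort segments contribute nothing.
#' Overlapping on-effort intervals along the same straight trackline within
#' one pass are unioned before buffering, so effort is never double-counted.
#' Mean Beaufort sea state per cell is length-weighted along the in-cell
#' trackline.
#'
#' @param grid a [build_grid()] grid.
#' @param transects a `dsm_transects` survey design (or its segment
#'   data.frame) from [gen_transects()].
#' @param strip_half_width_km half strip width, default 0.2 km (200 m each
#'   side of the trackline).
#' @return data.frame with one row per (cell, pass) having positive effort:
#'   `cell`, `transect_id`, `effort_km2`, `line_km`, `mean_ss`, `altitude`,
#'   `julian_day`, `year`.
#' @export
effort_per_cell <- function(grid, transects, strip_half_width_km = 0.2) {
  seg <- if (inherits(transects, "dsm_transects")) transects$segments else transects
  check_positive(strip_half_width_km, "strip_half_width_km")
  zero_len <- with(seg, sqrt((x1 - x0)^2 + (y1 - y0)^2)) <= 0
  if (any(zero_len)) {
    message(sum(zero_len), " zero-length segment(s) contribute no effort")
    seg <- seg[!zero_len, , drop = FALSE]
  }
  acc <- new.env(parent = emptyenv())
  add <- function(key, cell, pass, area, wss, lin, area_w, wss_a,
                  alt, jd, yr) {
    cur <- acc[[key]]
    if (is.null(cur))
      acc[[key]] <- list(cell = cell, pass = pass, area = area, wss = wss,
                         lin = lin, area_w = area_w, wss_a = wss_a,
                         alt = alt, jd = jd, yr = yr)
    else {
      cur$area <- cur$area + area; cur$wss <- cur$wss + wss
      cur$lin <- cur$lin + lin
      cur$area_w <- cur$area_w + area_w; cur$wss_a <- cur$wss_a + wss_a
      acc[[key]] <- cur
    }
  }
  for (id in unique(seg$transect_id)) {
    s <- seg[seg$transect_id == id & seg$effort, , drop = FALSE]
    if (nrow(s) == 0) next
    merged <- merge_collinear(s)
    ## effort area from the merged (non-overlapping) carrier sub-segments
    for (k in seq_len(nrow(merged))) {
      polys <- strip_cell_polys(grid, merged$x0[k], merged$y0[k],
                                merged$x1[k], merged$y1[k], strip_half_width_km)
      for (p in polys)
        add(paste0(id, ":", p$cell), p$cell, id, p$area, 0, 0, 0, 0,
            s$altitude[1], s$julian_day[1], s$year[1])
    }
    ## sea-state weights from the original legs (in-cell trackline lengths)
    for (k in seq_len(nrow(s))) {
      polys <- strip_cell_polys(grid, s$x0[k], s$y0[k], s$x1[k], s$y1[k],
                                strip_half_width_km)
      for (p in polys)
        add(paste0(id, ":", p$cell), p$cell, id, 0,
            p$line_km * s$sea_state[k], p$line_km,
            p$area, p$area * s$sea_state[k],
            s$altitude[1], s$julian_day[1], s$year[1])
    }
  }
  keys <- ls(acc)
  if (length(keys) == 0)
    return(data.frame(cell = integer(0), transect_id = character(0),
                      effort_km2 = numeric(0), line_km = numeric(0),
                      mean_ss = numeric(0), altitude = character(0),
                      julian_day = integer(0), year = integer(0)))
  rows <- lapply(keys, function(k) acc[[k]])
  out <- data.frame(
    cell = vapply(rows, `[[`, 0L, "cell"),
    transect_id = vapply(rows, function(r) as.character(r$pass), ""),
    effort_km2 = vapply(rows, `[[`, 0, "area"),
    line_km = vapply(rows, `[[`, 0, "lin"),
    mean_ss = vapply(rows, function(r) {
      ## length-weighted along the in-cell trackline; cells receiving only
      ## lateral strip spillover fall back to area weighting
      if (r$lin > 0) r$wss / r$lin
      else if (r$area_w > 0) r$wss_a / r$area_w else NA_real_
    }, 0),
    altitude = vapply(rows, function(r) as.character(r$alt), ""),
    julian_day = vapply(rows, function(r) as.integer(r$jd), 0L),
    year = vapply(rows, function(r) as.integer(r$yr), 0L))
  out <- out[out$effort_km2 > 1e-12, , drop = FALSE]
  out[order(out$transect_id, out$cell), , drop = FALSE]
}

#' Aggregate sighting counts onto the effort table
#'
#' Sums recorded group sizes per (cell, pass): the response is the number of
#' individuals. Cells with effort but no sightings get count zero; a sighting
#' in a (cell, pass) with no recorded effort raises a consistency warning and
#' is kept with zero effort so no individual is ever lost.
#'
#' @param grid a [build_grid()] grid.
#' @param sightings data.frame with `transect_id`, `x`, `y`, `group_size`.
#' @param effort output of [effort_per_cell()].
#' @return the effort table with `count` added and cell-centre coordinates
#'   `x`, `y` — one row per (cell, survey pass).
#' @export
aggregate_counts <- function(grid, sightings, effort) {
  out <- effort
  out$count <- 0L
  if (nrow(sightings) > 0) {
    cells <- cell_of(grid, sightings$x, sightings$y)
    key_e <- paste0(out$transect_id, ":", out$cell)
    key_s <- paste0(sightings$transect_id, ":", cells)
    tot <- tapply(sightings$group_size, key_s, sum)
    m <- match(names(tot), key_e)
    orphan <- is.na(m)
    out$count[m[!orphan]] <- as.integer(tot[!orphan])
    if (any(orphan)) {
      warning(sum(orphan), " sighting group(s) fall outside all surveyed strips")
      ok <- which(orphan)
      first <- match(names(tot)[ok], key_s)
      extra <- data.frame(cell = cells[first],
                          transect_id = sightings$transect_id[first],
                          effort_km2 = 0, line_km = 0, mean_ss = NA_real_,
                          altitude = NA_character_, julian_day = NA_integer_,
                          year = NA_integer_,
                          count = as.integer(tot[ok]))
      out <- rbind(out, extra)
    }
  }
  cc <- cell_centres(grid)
  out$x <- cc$x[out$cell]; out$y <- cc$y[out$cell]
  rownames(out) <- NULL
  out
}

#' Restrict to cells surveyed at both altitudes
#'
#' Keeps only the grid cells that were surveyed by at least one high-altitude
#' (broad-scale) and one low-altitude (fine-scale) pass, retaining every pass
#' of those cells as its own row. This is the dataset on which the
#' survey-altitude detectability model is fitted, so that the altitude effect
#' is not confounded with the coastal/offshore gradient.
#'
#' @param records output of [aggregate_counts()].
#' @return the subset of `records`, same columns.
#' @export
dual_altitude_subset <- function(records) {
  alt <- split(records$altitude, records$cell)
  keep <- names(alt)[vapply(alt, function(a)
    any(a == "high") && any(a == "low"), TRUE)]
  records[records$cell %in% as.integer(keep), , drop = FALSE]
}
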