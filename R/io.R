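## Plain-text interchange: ESRI ASCII grids for fields, CSV for transect
## vertices / sightings / colonies, JSON sidecar for the synthetic truth.

#' Write and read gridded fields as ESRI ASCII grids
#'
#' @param field nx x ny matrix in cell-id orientation.
#' @param grid the matching `dsm_grid`.
#' @param file path of the `.asc` file.
#' @export
write_ascii_grid <- function(field, grid, file) {
  con <- file(file, "w"); on.exit(close(con))
  writeLines(c(paste("ncols", grid$nx), paste("nrows", grid$ny),
               paste("xllcorner", grid$x0), paste("yllcorner", grid$y0),
               paste("cellsize", grid$cell_km),
               "NODATA_value -9999"), con)
  m <- field; m[is.na(m)] <- -9999
  ## ASCII grids run north to south: top row first
  for (j in rev(seq_len(grid$ny)))
    writeLines(paste(format(m[, j], trim = TRUE), collapse = " "), con)
  invisible(file)
}

#' @rdname write_ascii_grid
#' @return `read_ascii_grid`: list with `field` matrix and `grid`.
#' @export
read_ascii_grid <- function(file) {
  hdr <- utils::read.table(file, nrows = 6,
                           col.names = c("key", "value"),
                           colClasses = c("character", "numeric"))
  v <- stats::setNames(hdr$value, tolower(hdr$key))
  nx <- as.integer(v["ncols"]); ny <- as.integer(v["nrows"])
  dat <- scan(file, skip = 6, quiet = TRUE)
  m <- matrix(dat, nrow = nx)[, rev(seq_len(ny)), drop = FALSE]
  m[m == v["nodata_value"]] <- NA_real_
  grid <- build_grid(unname(c(v["xllcorner"], v["xllcorner"] + nx * v["cellsize"],
                              v["yllcorner"], v["yllcorner"] + ny * v["cellsize"])),
                     unname(v["cellsize"]))
  list(field = m, grid = grid)
}

#' Write a survey design, sightings and truth sidecar to a directory
#'
#' Transects are written as ordered strip vertices (one row per segment
#' endpoint), sightings as a flat CSV, environmental fields as ASCII grids
#' and the generating truth (intercept, dispersion, detection parameters,
#' total abundance) as a JSON sidecar.
#'
#' @param sim a [simulate_survey()] result.
#' @param dir output directory (created if needed).
#' @export
write_survey <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seg <- sim$design$segments
  verts <- rbind(
    data.frame(transect_id = seg$transect_id, vertex = 1L,
               x_km = seg$x0, y_km = seg$y0, altitude = seg$altitude,
               sea_state = seg$sea_state, julian_day = seg$julian_day,
               year = seg$year, effort_flag = as.integer(seg$effort)),
    data.frame(transect_id = seg$transect_id, vertex = 2L,
               x_km = seg$x1, y_km = seg$y1, altitude = seg$altitude,
               sea_state = seg$sea_state, julian_day = seg$julian_day,
               year = seg$year, effort_flag = as.integer(seg$effort)))
  verts <- verts[order(verts$transect_id, verts$y_km, verts$vertex), ]
  utils::write.csv(verts, file.path(dir, "transects.csv"), row.names = FALSE)
  utils::write.csv(sim$sightings, file.path(dir, "sightings.csv"),
                   row.names = FALSE)
  for (nm in names(sim$world$fields))
    write_ascii_grid(sim$world$fields[[nm]], sim$world$grid,
                     file.path(dir, paste0(nm, ".asc")))
  tr <- sim$truth
  jsonlite::write_json(
    list(intercept = tr$intercept, theta = tr$theta,
         detect = tr$detect, total_N_true = tr$total_N_true,
         group_probs = tr$group_probs, group_geom = tr$group_geom),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a colony table
#'
#' @param file CSV with columns `name`, `x_km`, `y_km`, `pairs`.
#' @return data.frame with `name`, `x`, `y`, `pairs`.
#' @export
read_colonies <- function(file) {
  d <- utils::read.csv(file)
  need <- c("name", "x_km", "y_km", "pairs")
  if (!all(need %in% names(d)))
    stop_param("colony file needs columns: ", paste(need, collapse = ", "))
  if (any(d$pairs < 1)) stop_param("colony pairs must be >= 1")
  data.frame(name = d$name, x = d$x_km, y = d$y_km, pairs = d$pairs)
}

#' Quick image of a gridded field
#'
#' @param field nx x ny matrix.
#' @param grid the matching `dsm_grid`.
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @export
plot_field <- function(field, grid, main = "", ...) {
  graphics::image(x = grid$x0 + (seq_len(grid$nx) - 0.5) * grid$cell_km,
                  y = grid$y0 + (seq_len(grid$ny) - 0.5) * grid$cell_km,
                  z = field, xlab = "x (km)", ylab = "y (km)", main = main,
                  asp = 1, useRaster = TRUE, ...)
  invisible(NULL)
}
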