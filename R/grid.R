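#' Build a planar analysis grid
#'
#' Constructs the regular analysis grid (default 4 x 4 km) covering a
#' rectangular study extent in projected planar kilometres. Cells are indexed
#' half-open: a point on an interior cell boundary belongs to the cell on its
#' +x / +y side, so every point of the extent maps to exactly one cell.
#'
#' @param extent numeric vector `c(x_min, x_max, y_min, y_max)` in km.
#' @param cell_km cell side length in km (default 4). The extent must be an
#'   exact multiple of `cell_km` in both directions (it is expanded outward to
#'   the next multiple otherwise, with a message).
#' @return An object of class `dsm_grid`: a list with `x0`, `y0`, `cell_km`,
#'   `nx`, `ny`. Cell ids run 1..`nx*ny` column-major in x-then-y order; the
#'   centre of cell (i, j) is `(x0 + (i - 0.5) cell_km, y0 + (j - 0.5) cell_km)`.
#' @examples
#' g <- build_grid(c(0, 40, 0, 40), 4)
#' n_cells(g)  # 100
#' @export
build_grid <- function(extent, cell_km = 4) {
  if (length(extent) != 4 || extent[2] <= extent[1] || extent[4] <= extent[3])
    stop_param("extent must be c(x_min, x_max, y_min, y_max) with positive area")
  check_positive(cell_km, "cell_km")
  w <- extent[2] - extent[1]; h <- extent[4] - extent[3]
  nx <- ceiling(w / cell_km - 1e-9); ny <- ceiling(h / cell_km - 1e-9)
  if (abs(nx * cell_km - w) > 1e-9 || abs(ny * cell_km - h) > 1e-9)
    message("extent is not a multiple of cell_km; expanded to ",
            nx, " x ", ny, " cells")
  structure(list(x0 = extent[1], y0 = extent[3], cell_km = cell_km,
                 nx = as.integer(nx), ny = as.integer(ny)),
            class = "dsm_grid")
}

#' @rdname build_grid
#' @param grid a `dsm_grid`.
#' @export
n_cells <- function(grid) grid$nx * grid$ny

#' @export
print.dsm_grid <- function(x, ...) {
  cat(sprintf("dsm_grid: %d x %d cells of %g km (extent [%g, %g] x [%g, %g] km)\n",
              x$nx, x$ny, x$cell_km, x$x0, x$x0 + x$nx * x$cell_km,
              x$y0, x$y0 + x$ny * x$cell_km))
  invisible(x)
}

#' Cell centres of an analysis grid
#'
#' @param grid a `dsm_grid`.
#' @return data.frame with columns `cell`, `x`, `y` (centre coordinates, km).
#' @export
cell_centres <- function(grid) {
  i <- rep(seq_len(grid$nx), times = grid$ny)
  j <- rep(seq_len(grid$ny), each = grid$nx)
  data.frame(cell = seq_len(n_cells(grid)),
             x = grid$x0 + (i - 0.5) * grid$cell_km,
             y = grid$y0 + (j - 0.5) * grid$cell_km)
}

#' Map points to grid cells (half-open convention)
#'
#' @param grid a `dsm_grid`.
#' @param x,y point coordinates in km.
#' @return integer cell ids; points outside the grid extent are an error.
#' @export
cell_of <- function(grid, x, y) {
  i <- floor((x - grid$x0) / grid$cell_km) + 1L
  j <- floor((y - grid$y0) / grid$cell_km) + 1L
  bad <- i < 1L | i > grid$nx | j < 1L | j > grid$ny
  if (any(bad))
    stop_param(sum(bad), " point(s) fall outside the grid extent")
  (j - 1L) * grid$nx + i
}

cell_rect <- function(grid, cell) {
  cell <- as.integer(cell)
  i <- (cell - 1L) %% grid$nx + 1L
  j <- (cell - 1L) %/% grid$nx + 1L
  cbind(xlo = grid$x0 + (i - 1L) * grid$cell_km,
        xhi = grid$x0 + i * grid$cell_km,
        ylo = grid$y0 + (j - 1L) * grid$cell_km,
        yhi = grid$y0 + j * grid$cell_km)
}

grid_extent <- function(grid)
  c(grid$x0, grid$x0 + grid$nx * grid$cell_km,
    grid$y0, grid$y0 + grid$ny * grid$cell_km)
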