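#' Configure a synthetic survey world
#'
#' Defines the rectangular planar study area, grid resolution, synthetic
#' coastline and the Gaussian-random-field parameters of each environmental
#' variable. The generated world stands in for a real study region (gridded
#' bathymetry, chlorophyll-a, SST and salinity over coastal and offshore
#' waters) so that the whole analysis pipeline can be exercised against a
#' known ground truth.
#'
#' @param extent `c(x_min, x_max, y_min, y_max)` in planar km.
#' @param cell_km grid resolution in km (default 4).
#' @param land_spec list of ellipses, each `list(x, y, rx, ry)` (km); cell
#'   centres falling inside any ellipse are land. The first entry is the main
#'   island, further entries are islets.
#' @param field_specs per-variable random-field parameters: named list with
#'   entries `mean`, `sd` and correlation length `L` (km, > 0). Variables
#'   `chl_a`, `sst`, `sss` are required; `depth_rough` perturbs the
#'   bathymetry. Chlorophyll is exponentiated after simulation so it is
#'   positive and right-skewed like real ocean-colour data.
#' @param depth_slope_m_per_km mean seabed slope away from the coast; with
#'   the default 8 m/km a 500 m isobath (shelf-edge proxy) lies about 60 km
#'   offshore.
#' @param years survey years with their own realisations of the dynamic
#'   fields (chl-a, SST, SSS); the base field is the climatology.
#' @param year_sd standard deviation of the smooth year-specific anomalies
#'   added to each dynamic field.
#' @return A `world_config` list, to be passed to [gen_environment()].
#' @export
world_config <- function(extent = c(0, 160, 0, 160), cell_km = 4,
                         land_spec = list(list(x = 150, y = 80, rx = 28, ry = 70)),
                         field_specs = list(
                           depth_rough = list(mean = 0,  sd = 40,  L = 25),
                           chl_a       = list(mean = -0.7, sd = 0.5, L = 30),
                           sst         = list(mean = 14, sd = 1.2, L = 40),
                           sss         = list(mean = 35, sd = 0.4, L = 45)),
                         depth_slope_m_per_km = 8,
                         years = c(2015, 2016, 2021, 2022),
                         year_sd = 0.15) {
  if (length(extent) != 4 || extent[2] <= extent[1] || extent[4] <= extent[3])
    stop_param("extent must enclose a strictly positive area")
  check_positive(cell_km, "cell_km")
  for (nm in names(field_specs)) {
    fs <- field_specs[[nm]]
    if (is.null(fs$L) || !is.finite(fs$L) || fs$L <= 0)
      stop_param("correlation length for '", nm, "' must be > 0")
    if (fs$sd < 0) stop_param("sd for '", nm, "' must be >= 0")
  }
  structure(list(extent = extent, cell_km = cell_km, land_spec = land_spec,
                 field_specs = field_specs,
                 depth_slope_m_per_km = depth_slope_m_per_km,
                 years = years, year_sd = year_sd),
            class = "world_config")
}

## Stationary Gaussian random field on the grid by circulant embedding:
## the target squared-exponential covariance sd^2 exp(-(h/L)^2) is laid out
## on an enlarged torus, its FFT gives the eigenvalues of the embedding, and
## one complex white-noise synthesis yields the field. Correlation drops to
## exp(-1) at lag L, which is what the variogram-range checks estimate.
grf_sim <- function(nx, ny, cell_km, sd, L) {
  if (sd == 0) return(matrix(0, nx, ny))
  mx <- stats::nextn(2 * nx, 2); my <- stats::nextn(2 * ny, 2)
  dx <- pmin(0:(mx - 1), mx - 0:(mx - 1)) * cell_km
  dy <- pmin(0:(my - 1), my - 0:(my - 1)) * cell_km
  d2 <- outer(dx^2, dy^2, "+")
  cov <- sd^2 * exp(-d2 / L^2)
  lam <- Re(stats::fft(cov))
  lam[lam < 0] <- 0   # embedding may be slightly indefinite; clamp
  xi <- matrix(stats::rnorm(mx * my), mx, my) +
    1i * matrix(stats::rnorm(mx * my), mx, my)
  z <- stats::fft(sqrt(lam) * xi) / sqrt(mx * my)
  Re(z)[seq_len(nx), seq_len(ny), drop = FALSE]
}

land_mask_from_spec <- function(grid, land_spec) {
  cc <- cell_centres(grid)
  land <- rep(FALSE, nrow(cc))
  for (e in land_spec)
    land <- land | ((cc$x - e$x)^2 / e$rx^2 + (cc$y - e$y)^2 / e$ry^2 <= 1)
  matrix(land, grid$nx, grid$ny)
}

## Euclidean distance (km) from each cell centre to the nearest land cell
## centre; used to shape the synthetic bathymetry.
dist_to_land_cells <- function(grid, land) {
  cc <- cell_centres(grid)
  if (!any(land)) return(matrix(Inf, grid$nx, grid$ny))
  lx <- cc$x[as.vector(land)]; ly <- cc$y[as.vector(land)]
  d <- vapply(seq_len(nrow(cc)), function(k)
    sqrt(min((cc$x[k] - lx)^2 + (cc$y[k] - ly)^2)), 0)
  matrix(d, grid$nx, grid$ny)
}

#' Generate the synthetic environment
#'
#' Simulates spatially autocorrelated environmental fields (bathymetry,
#' chlorophyll-a, SST, SSS) on the analysis grid, together with a rasterised
#' land mask. Depth is built from a smooth offshore-deepening profile plus a
#' random-field perturbation, clamped to be non-positive at sea and `NA` on
#' land; chlorophyll is exponentiated so it is positive. Each survey year
#' receives its own smooth anomaly of the dynamic fields. Fields are
#' bitwise-reproducible for a fixed seed.
#'
#' @param config a [world_config()].
#' @param seed integer seed; all randomness flows through it.
#' @return A `dsm_world`: list with `grid` (a [build_grid()] object), `land`
#'   (logical nx x ny matrix), `fields` (named list of nx x ny matrices:
#'   `depth` in m, `chl_a` mg m^-3, `sst` degC, `sss` permil), `year_fields`
#'   (per-year dynamic fields) and `config`.
#' @export
gen_environment <- function(config, seed = 1) {
  stopifnot(inherits(config, "world_config"))
  grid <- build_grid(config$extent, config$cell_km)
  with_seed(seed, {
    land <- land_mask_from_spec(grid, config$land_spec)
    fs <- config$field_specs
    sim <- function(spec) spec$mean +
      grf_sim(grid$nx, grid$ny, grid$cell_km, spec$sd, spec$L)
    dl <- if (any(land)) dist_to_land_cells(grid, land)
          else matrix(0, grid$nx, grid$ny)   # open ocean: no coastal profile
    depth <- -(config$depth_slope_m_per_km * dl) + sim(fs$depth_rough)
    depth[depth > 0] <- 0           # land artefacts at sea centres clamped
    depth[land] <- NA_real_
    fields <- list(depth = depth,
                   chl_a = exp(sim(fs$chl_a)),
                   sst = sim(fs$sst),
                   sss = sim(fs$sss))
    year_fields <- list()
    for (yr in config$years) {
      anom <- function(spec) grf_sim(grid$nx, grid$ny, grid$cell_km,
                                     config$year_sd * max(spec$sd, 1e-12), spec$L)
      year_fields[[as.character(yr)]] <- list(
        chl_a = fields$chl_a * exp(anom(fs$chl_a)),
        sst = fields$sst + anom(fs$sst),
        sss = fields$sss + anom(fs$sss))
    }
    structure(list(grid = grid, land = land, fields = fields,
                   year_fields = year_fields, config = config),
              class = "dsm_world")
  })
}

#' @export
print.dsm_world <- function(x, ...) {
  cat(sprintf("dsm_world: %d x %d cells (%g km), %d land / %d sea\n",
              x$grid$nx, x$grid$ny, x$grid$cell_km,
              sum(x$land), sum(!x$land)))
  invisible(x)
}

sea_cells <- function(world) which(!as.vector(world$land))

## Value of a (possibly derived) covariate at every cell, as a vector in
## cell-id order. Derived names: x, y, dist_coast.
field_values <- function(world, name) {
  if (name %in% names(world$fields)) return(as.vector(world$fields[[name]]))
  cc <- cell_centres(world$grid)
  switch(name,
         x = cc$x,
         y = cc$y,
         dist_coast = {
           d <- dist_to_land_cells(world$grid, world$land)
           as.vector(d)
         },
         stop_param("effect references unknown covariate '", name, "'"))
}

#' Build the true density surface
#'
#' Constructs the known expected-density surface `lambda_true` (individuals
#' per km^2 per cell) from closed-form partial effects of generated
#' covariates on the log scale, together with the detection and dispersion
#' parameters that drive the sighting generator. Density is zero on land.
#'
#' @param world a `dsm_world` from [gen_environment()].
#' @param effects named list of vectorised functions; each name must be a
#'   generated field (`depth`, `chl_a`, `sst`, `sss`) or one of `x`, `y`,
#'   `dist_coast`. log lambda = intercept + sum of effects.
#' @param intercept intercept of log lambda (log birds per km^2).
#' @param theta negative-binomial size (dispersion) parameter of the latent
#'   group counts; `Inf` gives Poisson.
#' @param detect detection parameters on the log scale:
#'   `list(delta_alt =, beta_ss = c(high =, low =))`. Detection probability
#'   for a group is `min(1, exp(delta_alt * [altitude == high] +
#'   beta_ss[altitude] * sea_state))`; at sea state 0 and low altitude it
#'   equals 1.
#' @param colonies optional colony table (`data.frame` with `name`, `x`, `y`,
#'   `pairs`); locations must fall on land and pairs must be >= 1.
#' @param group_probs probabilities of group sizes 1, 2 and 3+ (3+ is split
#'   geometrically with success probability `group_geom`).
#' @param group_geom geometric parameter of the 3+ tail.
#' @return A `dsm_truth`: `lambda` matrix, `total_N_true`, the inputs above,
#'   and `mean_group_size`.
#' @export
gen_truth <- function(world, effects = list(), intercept = -2,
                      theta = 2,
                      detect = list(delta_alt = 0, beta_ss = c(high = 0, low = 0)),
                      colonies = NULL,
                      group_probs = c(0.805, 0.107, 0.088),
                      group_geom = 0.5) {
  stopifnot(inherits(world, "dsm_world"))
  if (theta <= 0) stop_param("theta must be > 0 (Inf for Poisson)")
  eta <- rep(intercept, n_cells(world$grid))
  for (nm in names(effects))
    eta <- eta + effects[[nm]](field_values(world, nm))
  lambda <- matrix(exp(eta), world$grid$nx, world$grid$ny)
  lambda[world$land] <- 0
  if (!is.null(colonies)) {
    if (any(colonies$pairs < 1)) stop_param("colony pairs must be >= 1")
    on_land <- world$land[cbind(
      pmin(pmax(floor((colonies$x - world$grid$x0) / world$grid$cell_km) + 1, 1), world$grid$nx),
      pmin(pmax(floor((colonies$y - world$grid$y0) / world$grid$cell_km) + 1, 1), world$grid$ny))]
    if (!all(on_land)) stop_param("colony locations must fall on land cells")
  }
  p_detect_min <- exp(min(0, detect$delta_alt) +
                        min(0, min(detect$beta_ss)) * 9)
  if (p_detect_min <= 0) stop_param("detection parameters give p = 0")
  mean_group <- sum(group_probs * c(1, 2, 3 + (1 - group_geom) / group_geom))
  structure(list(grid = world$grid, land = world$land, lambda = lambda,
                 partial_effects = effects, intercept = intercept,
                 theta = theta, detect = detect, colonies = colonies,
                 group_probs = group_probs, group_geom = group_geom,
                 mean_group_size = mean_group,
                 total_N_true = sum(lambda) * world$grid$cell_km^2),
            class = "dsm_truth")
}

#' @export
print.dsm_truth <- function(x, ...) {
  cat(sprintf("dsm_truth: total N = %.0f (theta = %g, delta_alt = %g)\n",
              x$total_N_true, x$theta, x$detect$delta_alt))
  invisible(x)
}
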