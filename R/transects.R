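#' Generate a synthetic strip-transect survey design
#'
#' Lays out parallel straight transects over the study area: a broad-scale
#' set flown at high altitude across the whole extent, and an optional
#' fine-scale set flown at low altitude inside `fine_region` (spaced about
#' two nautical miles apart by default, mirroring typical coastal designs).
#' Lines run north-south (constant x) and are placed fence-post fashion from
#' the region's western edge. Each transect is one survey pass: it carries a
#' year, a Julian day, and a piecewise-constant Beaufort sea-state sequence
#' drawn per leg from `sea_state_probs` (>= 95% of mass on states <= 3 by
#' default).
#'
#' @param world a `dsm_world` (or a `dsm_grid`).
#' @param broad_spacing_km spacing of broad-scale transects (km).
#' @param fine_spacing_km spacing of fine-scale transects (km), default
#'   3.704 km = 2 nautical miles.
#' @param fine_region `c(x_min, x_max, y_min, y_max)` of the fine-scale
#'   block, or `NULL` for none; must lie within the extent. A zero-area
#'   region yields no fine transects.
#' @param years candidate survey years, sampled per transect.
#' @param day_range inclusive Julian-day range sampled per transect.
#' @param sea_state_probs probabilities of Beaufort states `0:(length-1)`
#'   per leg.
#' @param n_legs number of equal-length legs per transect (each leg gets its
#'   own sea state and effort flag).
#' @param off_effort_prob probability that a leg is off effort.
#' @param seed integer seed.
#' @return A `dsm_transects`: list with `segments` (one row per leg:
#'   `transect_id`, `x0`, `y0`, `x1`, `y1`, `altitude`, `sea_state`,
#'   `julian_day`, `year`, `effort`) and `total_length_km` (on- plus
#'   off-effort trackline).
#' @export
gen_transects <- function(world, broad_spacing_km = 20,
                          fine_spacing_km = 3.704, fine_region = NULL,
                          years = NULL, day_range = c(135, 260),
                          sea_state_probs = c(0.35, 0.30, 0.20, 0.12, 0.03),
                          n_legs = 2, off_effort_prob = 0.02, seed = 1) {
  grid <- if (inherits(world, "dsm_world")) world$grid else world
  ext <- grid_extent(grid)
  check_positive(broad_spacing_km, "broad_spacing_km")
  check_positive(fine_spacing_km, "fine_spacing_km")
  if (is.null(years))
    years <- if (inherits(world, "dsm_world")) world$config$years else 2021
  if (!is.null(fine_region)) {
    if (fine_region[1] < ext[1] - 1e-9 || fine_region[2] > ext[2] + 1e-9 ||
        fine_region[3] < ext[3] - 1e-9 || fine_region[4] > ext[4] + 1e-9)
      stop_param("fine_region must lie within the study extent")
  }
  line_positions <- function(x_min, x_max, spacing) {
    if (x_max - x_min <= 0) return(numeric(0))
    x_min + spacing * (0:floor((x_max - x_min) / spacing + 1e-9))
  }
  with_seed(seed, {
    mk <- function(xs, y_lo, y_hi, altitude, prefix) {
      segs <- NULL
      for (k in seq_along(xs)) {
        id <- sprintf("%s%03d", prefix, k)
        yr <- if (length(years) == 1) years else sample(years, 1)
        jd <- sample(seq(day_range[1], day_range[2]), 1)
        yb <- seq(y_lo, y_hi, length.out = n_legs + 1)
        segs <- rbind(segs, data.frame(
          transect_id = id,
          x0 = xs[k], y0 = yb[-(n_legs + 1)], x1 = xs[k], y1 = yb[-1],
          altitude = altitude,
          sea_state = sample(seq_along(sea_state_probs) - 1L, n_legs,
                             replace = TRUE, prob = sea_state_probs),
          julian_day = jd, year = yr,
          effort = stats::runif(n_legs) >= off_effort_prob))
      }
      segs
    }
    segs <- mk(line_positions(ext[1], ext[2], broad_spacing_km),
               ext[3], ext[4], "high", "B")
    if (!is.null(fine_region)) {
      fx <- line_positions(fine_region[1], fine_region[2], fine_spacing_km)
      if (fine_region[4] > fine_region[3] && length(fx) > 0)
        segs <- rbind(segs, mk(fx, fine_region[3], fine_region[4], "low", "F"))
    }
    structure(list(segments = segs,
                   total_length_km = sum(sqrt((segs$x1 - segs$x0)^2 +
                                                (segs$y1 - segs$y0)^2))),
              class = "dsm_transects")
  })
}

#' @export
print.dsm_transects <- function(x, ...) {
  s <- x$segments
  cat(sprintf("dsm_transects: %d transects (%d high, %d low), %.0f km trackline\n",
              length(unique(s$transect_id)),
              length(unique(s$transect_id[s$altitude == "high"])),
              length(unique(s$transect_id[s$altitude == "low"])),
              x$total_length_km))
  invisible(x)
}

draw_group_sizes <- function(n, probs, geom_p) {
  cls <- sample.int(3L, n, replace = TRUE, prob = probs)
  sz <- cls
  k3 <- cls == 3L
  sz[k3] <- 3L + stats::rgeom(sum(k3), geom_p)
  sz
}

#' Generate detection-thinned sightings along a survey design
#'
#' Places latent storm-petrel groups in each (cell x pass) strip
#' intersection with a negative-binomial count whose mean is
#' `lambda_true * on-effort strip area / mean group size`, assigns group
#' sizes from the configured distribution (about 80% singletons), and
#' retains each group with the altitude- and sea-state-dependent detection
#' probability `min(1, exp(delta_alt * [high] + beta_ss[altitude] *
#' sea_state))`; at sea state 0 and low altitude detection is complete.
#' Detected groups get a uniform position inside the strip polygon they
#' arose from.
#'
#' @param truth a `dsm_truth` from [gen_truth()].
#' @param design a `dsm_transects` from [gen_transects()].
#' @param seed integer seed.
#' @param strip_half_width_km strip half width (default 0.2 km).
#' @return data.frame of sightings: `transect_id`, `x`, `y`, `group_size`.
#' @export
gen_sightings <- function(truth, design, seed = 1, strip_half_width_km = 0.2) {
  stopifnot(inherits(truth, "dsm_truth"), inherits(design, "dsm_transects"))
  grid <- truth$grid
  ext <- grid_extent(grid)
  seg <- design$segments
  if (any(seg$x0 < ext[1] | seg$x1 > ext[2] | seg$y0 < ext[3] - 1e-9 |
            seg$y1 > ext[4] + 1e-9))
    stop_param("design strips must lie within the study extent")
  det <- truth$detect
  p_of <- function(alt, ss) {
    p <- exp(det$delta_alt * (alt == "high") + det$beta_ss[[alt]] * ss)
    if (any(p > 1)) {
      warning("detection probability > 1 clamped to 1")
      p <- pmin(p, 1)
    }
    p
  }
  lam <- as.vector(truth$lambda)
  with_seed(seed, {
    res_x <- numeric(0); res_y <- numeric(0)
    res_sz <- integer(0); res_id <- character(0)
    for (id in unique(seg$transect_id)) {
      s <- seg[seg$transect_id == id & seg$effort, , drop = FALSE]
      if (nrow(s) == 0) next
      ## clipped strip polygons per (cell, leg)
      polys <- list(); cells <- integer(0); areas <- numeric(0); legs <- integer(0)
      for (k in seq_len(nrow(s))) {
        pk <- strip_cell_polys(grid, s$x0[k], s$y0[k], s$x1[k], s$y1[k],
                               strip_half_width_km)
        for (p in pk) {
          polys[[length(polys) + 1L]] <- p$poly
          cells <- c(cells, p$cell); areas <- c(areas, p$area)
          legs <- c(legs, k)
        }
      }
      if (length(cells) == 0) next
      for (cl in unique(cells)) {
        idx <- which(cells == cl)
        a_tot <- sum(areas[idx])
        mu <- lam[cl] * a_tot / truth$mean_group_size
        if (mu <= 0) next
        ng <- if (is.infinite(truth$theta)) stats::rpois(1, mu)
        else stats::rnbinom(1, size = truth$theta, mu = mu)
        if (ng == 0) next
        which_poly <- idx[sample.int(length(idx), ng, replace = TRUE,
                                     prob = areas[idx])]
        sz <- draw_group_sizes(ng, truth$group_probs, truth$group_geom)
        keep <- stats::runif(ng) <
          p_of(s$altitude[1], s$sea_state[legs[which_poly]])
        if (!any(keep)) next
        for (w in which(keep)) {
          pt <- sample_in_poly(1, polys[[which_poly[w]]])
          res_x <- c(res_x, pt[1]); res_y <- c(res_y, pt[2])
          res_sz <- c(res_sz, sz[w]); res_id <- c(res_id, id)
        }
      }
    }
    data.frame(transect_id = res_id, x = res_x, y = res_y,
               group_size = res_sz)
  })
}

#' Simulate a complete synthetic survey
#'
#' Convenience wrapper running environment generation, truth construction,
#' transect layout, sighting generation, effort gridding and count
#' aggregation, returning everything downstream stages need.
#'
#' @param config a [world_config()].
#' @param effects,intercept,theta,detect passed to [gen_truth()].
#' @param seed master seed; sub-stages derive their own streams from it.
#' @param ... passed to [gen_transects()].
#' @return list with `world`, `truth`, `design`, `sightings`, `records`
#'   (the model-ready (cell x pass) table from [aggregate_counts()]).
#' @export
simulate_survey <- function(config = world_config(), effects = list(),
                            intercept = -2, theta = 2,
                            detect = list(delta_alt = 0,
                                          beta_ss = c(high = 0, low = 0)),
                            seed = 1, ...) {
  world <- gen_environment(config, seed = seed)
  truth <- gen_truth(world, effects = effects, intercept = intercept,
                     theta = theta, detect = detect)
  design <- gen_transects(world, seed = seed + 1L, ...)
  sightings <- gen_sightings(truth, design, seed = seed + 2L)
  effort <- effort_per_cell(world$grid, design)
  records <- aggregate_counts(world$grid, sightings, effort)
  list(world = world, truth = truth, design = design,
       sightings = sightings, records = records)
}
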