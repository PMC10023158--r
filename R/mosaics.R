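#' Retinal mosaic simulation and density recovery profiles
#'
#' Simulates one or more homotypic ganglion-cell mosaics inside a circular
#' model retina and estimates Rodieck-style density recovery profiles
#' (DRPs). A single mosaic shows an exclusion-zone dip near zero distance;
#' the union of several independent mosaics progressively fills the dip —
#' the signature used to decide how many cell types a labeled population
#' contains.
#'
#' @name mosaics
NULL

#' Generate hard-core mosaics in a circular model retina
#'
#' Places `total_cells` soma centers by sequential rejection sampling,
#' split evenly across `n_mosaics` independent mosaics, subject to: (1) no
#' two somata overlap (all pairwise distances at least `2 * soma_radius`,
#' the monolayer constraint), and (2) cells of the same mosaic respect a
#' noisy exclusion zone set by the mosaic's coverage factor (cells per unit
#' area). The exclusion radius is the mean nearest-neighbor distance of a
#' random field at the mosaic's density, `0.5 / sqrt(lambda)`, with
#' Gaussian jitter drawn per candidate placement; this keeps the packing
#' fraction of the exclusion discs constant (about pi/16) at any density,
#' so placement remains feasible at every mosaic count.
#'
#' @param n_mosaics number of independent mosaics (>= 1).
#' @param total_cells total cells across all mosaics (default 669, the
#'   average labeled-cell count per retina).
#' @param retina_radius_um model retina radius, micrometers (default 2000).
#' @param soma_radius_um soma radius, micrometers (default 15).
#' @param exclusion_noise_sd_um SD of the Gaussian jitter on the exclusion
#'   distance (default 15; draws are floored at the hard-core distance).
#' @param max_tries placement retry budget per cell (default 10000);
#'   exhausting it is an error reporting the achieved count.
#' @param seed integer seed.
#' @return an object of class `mosaic_field`: data.frame `positions`
#'   (`cell_id`, `mosaic_id`, `x_um`, `y_um`) plus `retina_radius_um`,
#'   `soma_radius_um`, `center` (c(0, 0)), and `exclusion_um` per mosaic.
#' @export
generate_mosaics <- function(n_mosaics = 1, total_cells = 669,
                             retina_radius_um = 2000, soma_radius_um = 15,
                             exclusion_noise_sd_um = 15,
                             max_tries = 10000, seed = 1) {
  stopifnot(n_mosaics >= 1, total_cells >= 1, retina_radius_um > 0,
            soma_radius_um >= 0, exclusion_noise_sd_um >= 0)
  set.seed(derive_seed(seed, 5L))
  per <- rep(floor(total_cells / n_mosaics), n_mosaics)
  per[seq_len(total_cells - sum(per))] <- per[seq_len(max(0, total_cells - sum(per)))] + 1L
  area <- pi * retina_radius_um^2
  lambda <- per / area # coverage factor per mosaic, cells/um^2
  exclusion <- 0.5 / sqrt(lambda) # mean CSR nearest-neighbor distance
  hard <- 2 * soma_radius_um

  # randomized placement order across mosaics
  order_vec <- sample(rep(seq_len(n_mosaics), per))
  x <- numeric(total_cells)
  y <- numeric(total_cells)
  mid <- integer(total_cells)
  placed <- 0L
  for (m in order_vec) {
    ok <- FALSE
    for (tries in seq_len(max_tries)) {
      # uniform point in the disc
      rr <- retina_radius_um * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      px <- rr * cos(th)
      py <- rr * sin(th)
      if (placed > 0L) {
        d2 <- (x[seq_len(placed)] - px)^2 + (y[seq_len(placed)] - py)^2
        if (any(d2 < hard^2)) next
        same <- mid[seq_len(placed)] == m
        if (any(same)) {
          dmin <- pmax(hard, exclusion[m] +
                         stats::rnorm(sum(same), 0, exclusion_noise_sd_um))
          if (any(d2[same] < dmin^2)) next
        }
      }
      placed <- placed + 1L
      x[placed] <- px
      y[placed] <- py
      mid[placed] <- m
      ok <- TRUE
      break
    }
    if (!ok) {
      stop(sprintf("mosaic placement failed after %d tries (%d of %d cells placed)",
                   max_tries, placed, total_cells))
    }
  }
  positions <- data.frame(cell_id = sprintf("c%04d", seq_len(total_cells)),
                          mosaic_id = mid, x_um = x, y_um = y,
                          stringsAsFactors = FALSE)
  structure(list(positions = positions, retina_radius_um = retina_radius_um,
                 soma_radius_um = soma_radius_um, center = c(0, 0),
                 exclusion_um = exclusion, seed = seed),
            class = "mosaic_field")
}

#' @export
print.mosaic_field <- function(x, ...) {
  cat(sprintf("<mosaic_field> %d cells in %d mosaic(s), retina radius %g um\n",
              nrow(x$positions), length(unique(x$positions$mosaic_id)),
              x$retina_radius_um))
  invisible(x)
}

# area of the intersection of a disc (center distance d from origin,
# radius r) with the retina disc (radius R centered at the origin)
lens_area <- function(d, r, R) {
  if (r <= 0) return(0)
  if (d >= r + R) return(0)
  if (d <= abs(R - r)) return(pi * min(r, R)^2)
  # standard circle-circle intersection (lens) area
  a1 <- r^2 * acos((d^2 + r^2 - R^2) / (2 * d * r))
  a2 <- R^2 * acos((d^2 + R^2 - r^2) / (2 * d * R))
  a3 <- 0.5 * sqrt(pmax(0, (-d + r + R) * (d + r - R) * (d - r + R) * (d + r + R)))
  a1 + a2 - a3
}

#' Density recovery profile
#'
#' For every reference cell, neighbors are counted in concentric annuli;
#' the density in each annulus is the total neighbor count divided by the
#' total annulus area summed over reference cells. With
#' `edge_correction = "clip"` (default) each annulus area is clipped to the
#' retina disc by exact circular-segment geometry, which keeps the
#' estimator unbiased near the boundary; `"none"` uses full annulus areas.
#'
#' @param field a `mosaic_field`, or a two-column matrix/data.frame of
#'   positions (micrometers; then `retina_radius_um` is required for the
#'   clip correction).
#' @param bin_um annulus width, micrometers (default 10, resolving the
#'   30 um hard core).
#' @param max_um maximum distance (default 150).
#' @param edge_correction `"clip"` or `"none"`.
#' @param retina_radius_um retina radius when `field` is a bare matrix.
#' @return an object of class `density_recovery_profile`: data.frame
#'   `profile` (`r_lo_um`, `r_hi_um`, `r_mid_um`, `count`, `density_mm2`)
#'   plus `mean_density_mm2`.
#' @export
density_recovery_profile <- function(field, bin_um = 10, max_um = 150,
                                     edge_correction = c("clip", "none"),
                                     retina_radius_um = NULL) {
  edge_correction <- match.arg(edge_correction)
  if (bin_um <= 0) stop("`bin_um` must be positive")
  if (inherits(field, "mosaic_field")) {
    xy <- cbind(field$positions$x_um, field$positions$y_um)
    R <- field$retina_radius_um
  } else {
    xy <- as.matrix(field)
    R <- retina_radius_um
    if (is.null(R) && edge_correction == "clip") {
      stop("`retina_radius_um` required for clip edge correction")
    }
  }
  n <- nrow(xy)
  if (n < 2) stop("need at least 2 points")
  edges <- seq(0, max_um, by = bin_um)
  if (edges[length(edges)] < max_um) edges <- c(edges, max_um)
  nb <- length(edges) - 1L

  d <- as.matrix(stats::dist(xy))
  diag(d) <- Inf
  counts <- vapply(seq_len(nb), function(k) {
    sum(d >= edges[k] & d < edges[k + 1L])
  }, numeric(1))

  if (edge_correction == "clip") {
    d0 <- sqrt(rowSums(xy^2))
    areas <- vapply(seq_len(nb), function(k) {
      sum(vapply(d0, function(dd) {
        lens_area(dd, edges[k + 1L], R) - lens_area(dd, edges[k], R)
      }, numeric(1)))
    }, numeric(1))
  } else {
    areas <- n * pi * (edges[-1]^2 - edges[-length(edges)]^2)
  }
  density <- counts / areas * 1e6 # cells/um^2 -> cells/mm^2
  mean_density <- if (!is.null(R)) n / (pi * R^2) * 1e6 else NA_real_
  structure(list(
    profile = data.frame(r_lo_um = edges[-length(edges)], r_hi_um = edges[-1],
                         r_mid_um = (edges[-1] + edges[-length(edges)]) / 2,
                         count = counts, density_mm2 = density),
    mean_density_mm2 = mean_density),
    class = "density_recovery_profile")
}

#' @export
print.density_recovery_profile <- function(x, ...) {
  cat(sprintf("<density_recovery_profile> %d bins, mean density %.1f cells/mm^2\n",
              nrow(x$profile), x$mean_density_mm2))
  invisible(x)
}

#' Estimate retina center and radius from perimeter points
#'
#' Enumerates all unique triples of the marked perimeter points; the retina
#' center is the componentwise median of the triples' circumcenters and the
#' radius is the median of their circumradii. Degenerate (near-collinear)
#' triples are skipped.
#'
#' @param points matrix or data.frame of at least 3 (typically 8) perimeter
#'   coordinates (x, y).
#' @return list with `center` (length-2) and `radius`.
#' @export
estimate_center_radius <- function(points) {
  xy <- as.matrix(points)
  n <- nrow(xy)
  if (n < 3) stop("need at least 3 perimeter points")
  trip <- utils::combn(n, 3)
  centers <- matrix(NA_real_, ncol(trip), 2)
  radii <- rep(NA_real_, ncol(trip))
  scale <- max(stats::dist(xy))
  for (k in seq_len(ncol(trip))) {
    p <- xy[trip[, k], , drop = FALSE]
    ax <- p[1, 1]; ay <- p[1, 2]
    bx <- p[2, 1]; by <- p[2, 2]
    cx <- p[3, 1]; cy <- p[3, 2]
    dd <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(dd) < 1e-9 * scale^2) next # collinear
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / dd
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / dd
    centers[k, ] <- c(ux, uy)
    radii[k] <- sqrt((ux - ax)^2 + (uy - ay)^2)
  }
  if (all(is.na(radii))) stop("all perimeter-point triples are degenerate")
  list(center = c(stats::median(centers[, 1], na.rm = TRUE),
                  stats::median(centers[, 2], na.rm = TRUE)),
       radius = stats::median(radii, na.rm = TRUE))
}

#' Normalized polar retinal coordinates
#'
#' Expresses cell positions in a frame shared across retinas: radial
#' distance from the retina center normalized by the retina radius, and
#' angle measured from the dorsal-ventral axis.
#'
#' @param positions matrix or data.frame of (x, y) positions.
#' @param center retina center, length-2.
#' @param radius retina radius (> 0).
#' @param dorsal_angle_deg angle of the dorsal axis in the measurement
#'   frame, degrees (default 90).
#' @return data.frame with `r` (in \[0, 1\] inside the retina) and
#'   `angle_deg` (degrees from the dorsal axis, on \[0, 360)).
#' @export
normalize_coordinates <- function(positions, center, radius,
                                  dorsal_angle_deg = 90) {
  if (radius <= 0) stop("`radius` must be positive")
  xy <- as.matrix(positions)
  dx <- xy[, 1] - center[1]
  dy <- xy[, 2] - center[2]
  data.frame(r = sqrt(dx^2 + dy^2) / radius,
             angle_deg = wrap360(rad2deg(atan2(dy, dx)) - dorsal_angle_deg))
}

#' Invert normalized polar coordinates back to the measurement frame
#' @param coords data.frame from [normalize_coordinates()].
#' @inheritParams normalize_coordinates
#' @return matrix of (x, y) positions.
#' @export
denormalize_coordinates <- function(coords, center, radius,
                                    dorsal_angle_deg = 90) {
  a <- deg2rad(coords$angle_deg + dorsal_angle_deg)
  cbind(x = center[1] + radius * coords$r * cos(a),
        y = center[2] + radius * coords$r * sin(a))
}
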