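#' Direction-tuning statistics for directional responses
#'
#' These functions implement the standard circular statistics used to
#' characterize direction-selective retinal ganglion cells: the preferred
#' direction (vector sum), the direction selectivity index (DSI), the linear
#' tuning-curve area, preferred-direction normalization, the normalized
#' tuning-curve area, and the tuning width at a response fraction.
#'
#' Conventions for all-zero spike tuning curves (cells that fail to spike for
#' every direction, as happens at low contrast): the linear tuning-curve area
#' is 0, the normalized area is 0, and the DSI is 1. These conventions are
#' stated for spike responses; all-zero responses in other units (`"mV"`,
#' `"pA"`, `"ratio"`) raise an error instead, because the limiting behavior
#' that motivates the spike conventions does not apply to subthreshold
#' measurements.
#'
#' @name tuning
NULL

is_spike_unit <- function(unit) unit %in% c("spikes", "spikes_per_s")

#' Preferred direction of a tuning curve
#'
#' Direction of the vector sum of the responses to all eight stimulus
#' directions. This is not necessarily the single probed direction that
#' evoked the largest response. The null direction is defined as 180 degrees
#' away.
#'
#' @param resp a [directional_response()] (or a length-8 numeric vector of
#'   responses at the default directions).
#' @return preferred direction in degrees on \[0, 360).
#' @export
preferred_direction <- function(resp) {
  resp <- as_directional_response(resp)
  m <- resp$response
  if (all(m == 0)) stop("preferred direction undefined: all responses are zero")
  th <- deg2rad(resp$directions)
  vx <- sum(m * cos(th))
  vy <- sum(m * sin(th))
  if (sqrt(vx^2 + vy^2) < 1e-12 * sum(m)) {
    stop("preferred direction undefined: vector sum has zero magnitude")
  }
  wrap360(rad2deg(atan2(vy, vx)))
}

#' Direction selectivity index
#'
#' Magnitude of the vector sum of the responses divided by their scalar sum.
#' Ranges from 0 (untuned) to 1 (responds in a single direction). All-zero
#' spike responses return 1 by convention.
#'
#' @inheritParams preferred_direction
#' @return DSI, dimensionless in \[0, 1\].
#' @export
direction_selectivity_index <- function(resp) {
  resp <- as_directional_response(resp)
  m <- resp$response
  if (any(m < 0)) stop("responses must be non-negative")
  if (all(m == 0)) {
    if (is_spike_unit(resp$unit)) return(1)
    stop("DSI undefined for all-zero non-spike responses")
  }
  th <- deg2rad(resp$directions)
  sqrt(sum(m * cos(th))^2 + sum(m * sin(th))^2) / sum(m)
}

#' Linear tuning-curve area
#'
#' Area under the linear tuning curve divided by 360 degrees. The integral is
#' taken with the trapezoid rule on the circular domain, including the
#' wraparound segment from the last probed direction back to the first
#' (315 -> 360 == 0). All-zero spike curves return 0 by convention. Setting
#' `method = "rectangle"` instead averages the probed responses (each
#' direction weighted by its 45 degree sector), which shifts delta-like
#' curves by a constant factor; the trapezoid rule is the default.
#'
#' @inheritParams preferred_direction
#' @param method `"trapezoid"` (default) or `"rectangle"`.
#' @return area in response units.
#' @export
linear_tuning_area <- function(resp, method = c("trapezoid", "rectangle")) {
  method <- match.arg(method)
  resp <- as_directional_response(resp)
  m <- resp$response
  if (all(m == 0) && is_spike_unit(resp$unit)) return(0)
  if (method == "rectangle") return(mean(m))
  m_ext <- c(m, m[1])
  d_ext <- c(resp$directions, resp$directions[1] + 360)
  sum((m_ext[-1] + m_ext[-9]) / 2 * diff(d_ext)) / 360
}

#' Preferred-direction response by circular interpolation
#' @keywords internal
pd_response <- function(resp, pd = NULL) {
  resp <- as_directional_response(resp)
  if (is.null(pd)) pd <- preferred_direction(resp)
  circ_interp(resp$directions, resp$response, pd)
}

#' Normalize a tuning curve to its preferred-direction response
#'
#' Divides the response in all eight directions by the response in the
#' preferred direction. When the preferred direction (vector sum) falls
#' between probed directions, the preferred-direction response is estimated
#' by linear interpolation of the two neighboring probed directions.
#'
#' @inheritParams preferred_direction
#' @return a unitless [directional_response()] whose interpolated
#'   preferred-direction response equals 1.
#' @export
normalize_curve <- function(resp) {
  resp <- as_directional_response(resp)
  m <- resp$response
  # a perfectly uniform curve has no unique preferred direction, but every
  # direction carries the preferred response: normalization is all ones
  if (max(m) > 0 && diff(range(m)) <= 1e-12 * max(m)) {
    return(directional_response(response = m / max(m),
                                directions = resp$directions, unit = "ratio"))
  }
  pd <- preferred_direction(resp)
  r_pd <- pd_response(resp, pd)
  if (r_pd <= 0) {
    stop("normalization undefined: interpolated preferred-direction response is 0")
  }
  directional_response(response = resp$response / r_pd,
                       directions = resp$directions, unit = "ratio")
}

#' Normalized tuning-curve area
#'
#' Area under the preferred-direction-normalized tuning curve divided by
#' 360 degrees. Perfectly circular (uniform) tuning curves take the value 1;
#' larger values indicate wider curves. All-zero spike curves return 0 by
#' convention.
#'
#' @inheritParams linear_tuning_area
#' @return dimensionless area, >= 0.
#' @export
normalized_area <- function(resp, method = c("trapezoid", "rectangle")) {
  method <- match.arg(method)
  resp <- as_directional_response(resp)
  if (all(resp$response == 0) && is_spike_unit(resp$unit)) return(0)
  linear_tuning_area(normalize_curve(resp), method = method)
}

#' Tuning width at a response fraction
#'
#' Angular extent of the contiguous region around the preferred direction
#' where the piecewise-linearly interpolated normalized response is at least
#' `fraction`. Crossings are located by linear interpolation between probed
#' directions; when several crossings exist on one side, the one nearest the
#' preferred direction is used.
#'
#' @inheritParams preferred_direction
#' @param fraction response fraction in \[0, 1); default 0.5 (width at 50
#'   percent response magnitude).
#' @return a list with `width_deg` and logical `saturated` (`TRUE` when the
#'   normalized curve never drops below `fraction`, in which case the width
#'   is 360).
#' @export
width_at_fraction <- function(resp, fraction = 0.5) {
  stopifnot(fraction >= 0, fraction < 1)
  nc <- normalize_curve(resp)
  if (fraction == 0 || all(nc$response >= fraction)) {
    return(list(width_deg = 360, saturated = TRUE))
  }
  pd <- preferred_direction(resp)
  # walk from the preferred direction in each rotational sense until the
  # interpolated curve crosses `fraction`
  half_width <- function(sense) {
    step <- 45 * sense
    a_prev <- pd
    v_prev <- circ_interp(nc$directions, nc$response, pd) # >= 1 > fraction
    # nearest probed direction strictly ahead of pd in this sense
    for (k in 1:9) {
      a_next <- if (sense > 0) {
        45 * ceiling((pd + 1e-9) / 45) + 45 * (k - 1)
      } else {
        45 * floor((pd - 1e-9) / 45) - 45 * (k - 1)
      }
      v_next <- circ_interp(nc$directions, nc$response, a_next)
      if (v_next < fraction) {
        w <- (v_prev - fraction) / (v_prev - v_next) * abs(a_next - a_prev)
        return(abs(a_prev - pd) + w)
      }
      a_prev <- a_next
      v_prev <- v_next
    }
    180 # never drops on this side within a half turn
  }
  w <- half_width(+1) + half_width(-1)
  list(width_deg = min(w, 360), saturated = FALSE)
}

#' Classify a cell as a Superior or Inferior oDSGC
#'
#' Applies the classification rule used for retrogradely labeled
#' MTN-projecting cells: a cell is an oDSGC when its spike DSI exceeds
#' `dsi_min` and its preferred direction lies more than `axis_margin_deg`
#' away from the temporal-nasal axis; otherwise it is excluded. An included
#' cell is `"Superior"` when its preferred direction has a dorsal-to-ventral
#' retinal component (superior motion in visual space; directions are
#' inverted by the lens), `"Inferior"` when ventral-to-dorsal.
#'
#' @inheritParams preferred_direction
#' @param axes orientation of the retinal frame: a list giving the angles
#'   (degrees) of the nasal and dorsal directions. Default nasal = 0,
#'   dorsal = 90, so a preferred direction pointing ventral (negative y)
#'   marks a Superior oDSGC.
#' @param dsi_min minimum DSI for inclusion (default 0.05).
#' @param axis_margin_deg minimum angular distance of the preferred
#'   direction from the temporal-nasal axis (default 30).
#' @return `"Superior"`, `"Inferior"`, or `"excluded"`.
#' @export
classify_odsgc <- function(resp, axes = list(nasal = 0, dorsal = 90),
                           dsi_min = 0.05, axis_margin_deg = 30) {
  resp <- as_directional_response(resp)
  if (all(resp$response == 0)) return("excluded")
  pd <- tryCatch(preferred_direction(resp), error = function(e) NA_real_)
  if (is.na(pd)) return("excluded")
  dsi <- direction_selectivity_index(resp)
  if (dsi <= dsi_min) return("excluded")
  # distance from the temporal-nasal axis (a line, not a direction)
  d_axis <- min(ang_diff(pd, axes$nasal), ang_diff(pd, axes$nasal + 180))
  if (d_axis <= axis_margin_deg) return("excluded")
  ventral <- axes$dorsal + 180
  if (ang_diff(pd, ventral) < 90) "Superior" else "Inferior"
}

#' Per-cell tuning metrics table
#'
#' Convenience wrapper computing all tuning metrics for a list of cells, as
#' written to `tuning_metrics.csv`.
#'
#' @param cells a list of [directional_response()] objects, optionally named.
#' @param fit_vm logical; also fit a Von Mises curve per cell (slower).
#' @return a data.frame with one row per cell: `cell_id`, `pd_deg`, `dsi`,
#'   `area`, `norm_area`, `width50_deg`, and, when `fit_vm` is `TRUE`,
#'   `vm_mu`, `vm_kappa`.
#' @export
tuning_metrics <- function(cells, fit_vm = FALSE) {
  ids <- names(cells)
  if (is.null(ids)) ids <- sprintf("cell%03d", seq_along(cells))
  rows <- lapply(seq_along(cells), function(i) {
    r <- as_directional_response(cells[[i]])
    zero <- all(r$response == 0)
    pd <- if (zero) NA_real_ else preferred_direction(r)
    w <- if (zero) NA_real_ else width_at_fraction(r)$width_deg
    out <- data.frame(
      cell_id = ids[i],
      pd_deg = pd,
      dsi = direction_selectivity_index(r),
      area = linear_tuning_area(r),
      norm_area = normalized_area(r),
      width50_deg = w,
      stringsAsFactors = FALSE
    )
    if (fit_vm) {
      fit <- if (zero) NULL else tryCatch(fit_von_mises(r), error = function(e) NULL)
      out$vm_mu <- if (is.null(fit)) NA_real_ else fit$mu
      out$vm_kappa <- if (is.null(fit)) NA_real_ else fit$kappa
    }
    out
  })
  do.call(rbind, rows)
}
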