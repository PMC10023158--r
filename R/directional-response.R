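#' Directional response of a single cell
#'
#' Container for the responses of one cell to motion in eight directions:
#' the substrate for every tuning metric in the package. Responses may be
#' spike counts, firing rates, peak subthreshold depolarizations (mV), peak
#' currents (pA) or E/I ratios; the unit is carried as a tag and never
#' interpreted numerically.
#'
#' @param directions probed motion directions in degrees, retinal
#'   coordinates. Must be eight distinct sorted angles on \[0, 360) with 45
#'   degree spacing (the standard drifting-bar protocol).
#' @param response mean response per direction, non-negative, same length as
#'   `directions`.
#' @param trials optional matrix of per-trial responses (trials in rows,
#'   directions in columns). When given, its column means must match
#'   `response` within tolerance.
#' @param unit unit tag, one of `"spikes"`, `"spikes_per_s"`, `"mV"`,
#'   `"pA"`, `"ratio"`.
#' @return an object of class `directional_response`.
#' @examples
#' r <- directional_response(response = c(4, 2, 1, 0, 0, 0, 1, 2))
#' preferred_direction(r)
#' direction_selectivity_index(r)
#' @export
directional_response <- function(response,
                                 directions = seq(0, 315, by = 45),
                                 trials = NULL,
                                 unit = c("spikes", "spikes_per_s", "mV",
                                          "pA", "ratio")) {
  unit <- match.arg(unit)
  directions <- as.double(directions)
  response <- as.double(response)
  if (length(directions) != 8L || anyDuplicated(directions) ||
      is.unsorted(directions) || any(directions < 0 | directions >= 360) ||
      any(abs(diff(directions) - 45) > 1e-9)) {
    stop("`directions` must be 8 distinct sorted angles on [0, 360) with 45 degree spacing")
  }
  if (length(response) != 8L) stop("`response` must have length 8")
  if (anyNA(response)) stop("`response` must not contain NA")
  if (any(response < 0)) stop("responses must be non-negative")
  if (!is.null(trials)) {
    trials <- as.matrix(trials)
    if (ncol(trials) != 8L) stop("`trials` must have 8 columns (directions)")
    if (max(abs(colMeans(trials) - response)) > 1e-6) {
      stop("per-direction mean of `trials` does not match `response`")
    }
  }
  structure(list(directions = directions, response = response,
                 trials = trials, unit = unit),
            class = "directional_response")
}

#' @export
print.directional_response <- function(x, ...) {
  cat("<directional_response> unit:", x$unit, "\n")
  m <- rbind(direction_deg = x$directions, response = round(x$response, 3))
  print(m)
  invisible(x)
}

as_directional_response <- function(x, unit = "spikes") {
  if (inherits(x, "directional_response")) return(x)
  directional_response(response = x, unit = unit)
}
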