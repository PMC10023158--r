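#' Table dialects and validated CSV IO
#'
#' All tables exchanged by the pipeline are RFC-4180 CSV files with header
#' rows, angles in degrees, times in seconds, and conductances in nS (units
#' are embedded in the column names). Each dialect has a fixed column set
#' and per-column validity rules; [read_table()] rejects malformed files
#' with an error naming the offending row and column.
#'
#' Dialects:
#' \describe{
#'   \item{tuning_curves}{`cell_id`, `cell_type`, `contrast`,
#'     `direction_deg`, `trial`, `response` (response >= 0).}
#'   \item{conductances}{`time_s`, `channel` (`ex`/`in`), `direction_deg`,
#'     `conductance_ns` (>= 0).}
#'   \item{rates}{`time_s`, `population`, `rate_hz` (>= 0).}
#'   \item{eye_trace}{`time_s`, `theta_deg`, `is_saccade` (0/1).}
#'   \item{positions}{`cell_id`, `mosaic_id`, `x_um`, `y_um`.}
#' }
#'
#' @name table_io
NULL

dialect_schemas <- list(
  tuning_curves = list(
    cols = c("cell_id", "cell_type", "contrast", "direction_deg", "trial",
             "response"),
    numeric = c("direction_deg", "trial", "response"),
    nonneg = c("response", "trial")),
  conductances = list(
    cols = c("time_s", "channel", "direction_deg", "conductance_ns"),
    numeric = c("time_s", "direction_deg", "conductance_ns"),
    nonneg = c("conductance_ns", "time_s")),
  rates = list(
    cols = c("time_s", "population", "rate_hz"),
    numeric = c("time_s", "rate_hz"),
    nonneg = c("rate_hz", "time_s")),
  eye_trace = list(
    cols = c("time_s", "theta_deg", "is_saccade"),
    numeric = c("time_s", "theta_deg", "is_saccade"),
    nonneg = c("time_s")),
  positions = list(
    cols = c("cell_id", "mosaic_id", "x_um", "y_um"),
    numeric = c("x_um", "y_um"),
    nonneg = character(0))
)

#' Read a validated pipeline table
#'
#' @param path CSV file path.
#' @param dialect one of `"tuning_curves"`, `"conductances"`, `"rates"`,
#'   `"eye_trace"`, `"positions"`.
#' @return a validated data.frame.
#' @export
read_table <- function(path, dialect) {
  schema <- dialect_schemas[[dialect]]
  if (is.null(schema)) stop("unknown dialect: ", dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(schema$cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  df <- df[schema$cols]
  for (col in schema$numeric) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (anyNA(df[[col]]) || length(bad)) {
      row <- if (length(bad)) bad[1] else which(is.na(df[[col]]))[1]
      stop(sprintf("%s: non-numeric or missing value in column '%s', row %d",
                   path, col, row))
    }
    df[[col]] <- v
  }
  for (col in schema$nonneg) {
    bad <- which(df[[col]] < 0)
    if (length(bad)) {
      stop(sprintf("%s: negative value in column '%s', row %d",
                   path, col, bad[1]))
    }
  }
  df
}

#' Write a pipeline table
#'
#' @param df a data.frame conforming to the dialect.
#' @param path output CSV path.
#' @inheritParams read_table
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, dialect) {
  schema <- dialect_schemas[[dialect]]
  if (is.null(schema)) stop("unknown dialect: ", dialect)
  missing <- setdiff(schema$cols, names(df))
  if (length(missing)) {
    stop("data.frame missing column(s): ", paste(missing, collapse = ", "))
  }
  utils::write.csv(df[schema$cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

conductance_set_to_table <- function(set) {
  n <- length(set$time)
  rbind(
    data.frame(time_s = set$time, channel = "ex", direction_deg = NA_real_,
               conductance_ns = set$g_ex, stringsAsFactors = FALSE),
    do.call(rbind, lapply(seq_along(set$directions), function(j) {
      data.frame(time_s = set$time, channel = "in",
                 direction_deg = set$directions[j],
                 conductance_ns = set$g_in[, j], stringsAsFactors = FALSE)
    })))
}

eye_trace_to_table <- function(trace) {
  is_sac <- rep(0L, length(trace$time))
  if (nrow(trace$saccades) > 0) {
    for (k in seq_len(nrow(trace$saccades))) {
      is_sac[trace$time >= trace$saccades$start[k] &
               trace$time <= trace$saccades$end[k]] <- 1L
    }
  }
  data.frame(time_s = trace$time, theta_deg = trace$theta,
             is_saccade = is_sac)
}

rates_to_table <- function(rates) {
  rbind(data.frame(time_s = rates$time, population = "Superior",
                   rate_hz = rates$superior, stringsAsFactors = FALSE),
        data.frame(time_s = rates$time, population = "Inferior",
                   rate_hz = rates$inferior, stringsAsFactors = FALSE))
}
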