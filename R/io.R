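#' Write a temperature field as long-format CSV
#'
#' Plain-text persistence: one row per pixel-day with columns
#' `scenario,date,row,col,tmax,tmin`.
#'
#' @param field A `temperature_field`.
#' @param path Output file.
#' @export
write_field_csv <- function(field, path) {
  d <- dim(field$tmax)
  grid <- expand.grid(row = seq_len(d[2]), col = seq_len(d[3]),
                      day = seq_len(d[1]))
  idx <- cbind(grid$day, grid$row, grid$col)
  out <- data.frame(scenario = field$scenario_name,
                    date = field$dates[grid$day],
                    row = grid$row, col = grid$col,
                    tmax = field$tmax[idx], tmin = field$tmin[idx])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a temperature field written by [write_field_csv()]
#'
#' @param path CSV file.
#' @return A `temperature_field`.
#' @export
read_field_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  dates <- sort(unique(as.Date(df$date)))
  nr <- max(df$row); nc <- max(df$col)
  tmax <- array(NA_real_, c(length(dates), nr, nc))
  tmin <- tmax
  day <- match(as.Date(df$date), dates)
  tmax[cbind(day, df$row, df$col)] <- df$tmax
  tmin[cbind(day, df$row, df$col)] <- df$tmin
  temperature_field(df$scenario[1], dates, tmax, tmin)
}

#' Write a numeric grid (LCZ codes, population, statistics) as CSV
#'
#' @param grid A matrix.
#' @param path Output file.
#' @param value Name of the value column.
#' @export
write_grid_csv <- function(grid, path, value = "value") {
  df <- data.frame(row = as.vector(row(grid)), col = as.vector(col(grid)))
  df[[value]] <- as.vector(unclass(grid))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write stations or mortality series as CSV
#'
#' Stations use columns `station_id,date,tmax_obs` (plus pixel indices and
#' the paired model value); mortality uses `date,deaths,tmax`.
#'
#' @param x A `station_set` or `mortality_series`.
#' @param path Output file.
#' @export
write_series_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read a mortality series CSV (`date,deaths,tmax`)
#'
#' @param path CSV file.
#' @return A `mortality_series`.
#' @export
read_mortality_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  if (any(df$deaths < 0)) stop("negative death counts")
  class(df) <- c("mortality_series", "data.frame")
  df
}

#' Load a run configuration from YAML
#'
#' @param path YAML file with sections per pipeline stage; see
#'   [default_run_config()] for the recognised keys.
#' @return A run-config list merged over the defaults.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_run_config(), user)
}
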