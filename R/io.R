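#' Write a trial set of traces to CSV
#'
#' Long format: `trial`, `time` (s), `value`. Suitable for small fixtures
#' and cross-language regression files.
#'
#' @param traces list of numeric vectors / [current_trace()] /
#'   `simulation_result`, or a samples x trials matrix
#' @param dt sample interval (s)
#' @param file output path
#' @export
write_traces_csv <- function(traces, dt, file) {
  m <- as_trial_matrix(traces)
  df <- tibble::tibble(
    trial = rep(seq_len(ncol(m)), each = nrow(m)),
    time = rep((seq_len(nrow(m)) - 1) * dt, ncol(m)),
    value = as.vector(m)
  )
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Read a trial set of traces from CSV
#'
#' @param file path written by [write_traces_csv()]
#' @return list: `traces` (samples x trials matrix), `dt` (s)
#' @export
read_traces_csv <- function(file) {
  df <- utils::read.csv(file)
  stopifnot(all(c("trial", "time", "value") %in% names(df)))
  m <- do.call(cbind, split(df$value, df$trial))
  dt <- diff(sort(unique(df$time)))[1]
  list(traces = m, dt = dt)
}

#' Write biophysical parameters to a YAML file
#'
#' @param params a [biophys_params()]
#' @param file output path
#' @export
write_params_yaml <- function(params, file) {
  yaml::write_yaml(unclass(params), file)
  invisible(file)
}

#' Read biophysical parameters from a YAML file
#'
#' @param file path written by [write_params_yaml()]
#' @return a [biophys_params()]
#' @export
read_params_yaml <- function(file) {
  vals <- yaml::read_yaml(file)
  do.call(biophys_params, vals)
}

#' Export footprint window positions to CSV
#'
#' @param positions per-trial start-time lists from [insert_footprints()]
#' @param width window width (ms)
#' @param file output path
#' @export
write_positions_csv <- function(positions, width, file) {
  df <- purrr::imap_dfr(positions, function(st, i) {
    tibble::tibble(trial = i, start_ms = st, width_ms = width)
  })
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
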