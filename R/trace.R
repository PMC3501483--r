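#' Voltage-clamp photocurrent sweep
#'
#' One TEVC sweep: a uniformly sampled membrane-current time series with
#' the light window and holding potential, plus construct / cell / day /
#' solution labels used for grouping and same-day WT normalization.
#'
#' @param times sample times, s; strictly increasing uniform grid.
#' @param currents membrane current, uA (inward negative).
#' @param holding_mV holding potential, mV.
#' @param light_on,light_off light window, s; must lie inside the time
#'   range.
#' @param construct,cell_id,day,solution metadata labels.
#' @param sample_rate_Hz sampling rate; inferred from \code{times} when
#'   omitted.
#' @return A list of class \code{"tevc_trace"}.
#' @export
tevc_trace <- function(times, currents, holding_mV, light_on, light_off,
                       construct = "WT", cell_id = "cell1", day = "day1",
                       solution = "Na", sample_rate_Hz = NULL) {
  stopifnot(is.numeric(times), is.numeric(currents),
            length(times) == length(currents), length(times) >= 2L)
  dt <- diff(times)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  if (diff(range(dt)) > 1e-6 * mean(dt))
    stop("times must form a uniform grid")
  if (!(light_on >= times[1] && light_off <= times[length(times)] &&
        light_on < light_off))
    stop("light window [", light_on, ", ", light_off,
         "] must lie inside the recorded time range")
  if (is.null(sample_rate_Hz)) sample_rate_Hz <- 1 / mean(dt)
  structure(list(times = times, currents = currents,
                 holding_mV = holding_mV, light_on = light_on,
                 light_off = light_off, construct = construct,
                 cell_id = cell_id, day = day, solution = solution,
                 sample_rate_Hz = sample_rate_Hz),
            class = "tevc_trace")
}

#' @export
print.tevc_trace <- function(x, ...) {
  cat(sprintf(
    "TEVC sweep: %s / %s / %s / %s, %g mV, %d samples @ %g Hz, light [%g, %g] s\n",
    x$construct, x$cell_id, x$day, x$solution, x$holding_mV,
    length(x$times), x$sample_rate_Hz, x$light_on, x$light_off))
  invisible(x)
}

# fields serialized into the "# key=value" CSV header
.trace_header_fields <- c("construct", "cell_id", "day", "solution",
                          "holding_mV", "light_on_s", "light_off_s",
                          "sample_rate_Hz")

#' Write a sweep to the trace CSV dialect
#'
#' Plain-text format: comment lines \code{# key=value} carrying the sweep
#' metadata, then a \code{time_s,current_uA} two-column CSV body.
#'
#' @param trace a [tevc_trace()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "tevc_trace"))
  meta <- c(construct = trace$construct, cell_id = trace$cell_id,
            day = trace$day, solution = trace$solution,
            holding_mV = format(trace$holding_mV),
            light_on_s = format(trace$light_on),
            light_off_s = format(trace$light_off),
            sample_rate_Hz = format(trace$sample_rate_Hz))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", names(meta), "=", meta), con)
  writeLines("time_s,current_uA", con)
  writeLines(paste(format(trace$times, digits = 10, trim = TRUE),
                   format(trace$currents, digits = 8, trim = TRUE),
                   sep = ","), con)
  invisible(path)
}

#' Read a sweep from the trace CSV dialect
#'
#' @param path file written by [write_trace_csv()].
#' @return A [tevc_trace()].
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  kv <- sub("^# ", "", hdr)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  meta <- stats::setNames(as.list(vals), keys)
  missing <- setdiff(.trace_header_fields, keys)
  if (length(missing))
    stop("trace header of ", path, " is missing: ",
         paste(missing, collapse = ", "))
  body <- utils::read.csv(text = lines[!grepl("^# ", lines)])
  if (!all(c("time_s", "current_uA") %in% names(body)))
    stop("trace body of ", path, " must have columns time_s,current_uA")
  tevc_trace(times = body$time_s, currents = body$current_uA,
             holding_mV = as.numeric(meta$holding_mV),
             light_on = as.numeric(meta$light_on_s),
             light_off = as.numeric(meta$light_off_s),
             construct = meta$construct, cell_id = meta$cell_id,
             day = meta$day, solution = meta$solution,
             sample_rate_Hz = as.numeric(meta$sample_rate_Hz))
}
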