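#' Construct an electrophysiology trace
#'
#' A uniformly sampled time series: current in pA for voltage-clamp
#' recordings, membrane voltage in mV for current-clamp recordings.
#'
#' @param samples numeric vector of measurements.
#' @param sampling_rate sampling rate in Hz.
#' @param t0 time of the first sample, seconds.
#' @param mode `"vc"` (voltage clamp, samples in pA) or `"cc"`
#'   (current clamp, samples in mV).
#' @return object of class `ephys_trace`.
#' @export
ephys_trace <- function(samples, sampling_rate, t0 = 0, mode = c("vc", "cc")) {
  mode <- match.arg(mode)
  samples <- as.numeric(samples)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be > 0")
  if (length(samples) < 2L) stop("a trace needs at least 2 samples")
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 t0 = t0, mode = mode),
            class = "ephys_trace")
}

#' @export
print.ephys_trace <- function(x, ...) {
  cat(sprintf("<ephys_trace> %s, %d samples @ %g kHz (%.3f s)\n", x$mode,
              length(x$samples), x$sampling_rate / 1000,
              length(x$samples) / x$sampling_rate))
  invisible(x)
}

trace_duration <- function(trace) length(trace$samples) / trace$sampling_rate

trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1L) / trace$sampling_rate
}

#' Voltage-step protocol description
#'
#' @param holding holding potential, mV.
#' @param step_targets vector of step target potentials, mV.
#' @param step_onset step onset after sweep start, ms.
#' @param step_duration step duration, ms.
#' @param sweep_duration total sweep duration, ms.
#' @return object of class `step_protocol`.
#' @export
step_protocol <- function(holding = -80,
                          step_targets = c(-95, -85, -75, -65),
                          step_onset = 10, step_duration = 40,
                          sweep_duration = step_onset + step_duration + 10) {
  if (step_onset + step_duration > sweep_duration)
    stop("step must fit within the sweep")
  structure(list(holding = holding, step_targets = step_targets,
                 step_onset = step_onset, step_duration = step_duration,
                 sweep_duration = sweep_duration),
            class = "step_protocol")
}

#' Voltage-ramp protocol description
#'
#' @param start holding/start potential, mV.
#' @param pre_duration time at `start` before the ramp, ms.
#' @param end ramp end potential, mV.
#' @param ramp_duration ramp duration, ms.
#' @param post_duration time after ramp end (back at `start`), ms.
#' @return object of class `ramp_protocol`.
#' @export
ramp_protocol <- function(start = -90, pre_duration = 200, end = 60,
                          ramp_duration = 800, post_duration = 0) {
  if (ramp_duration <= 0) stop("ramp_duration must be > 0")
  structure(list(start = start, pre_duration = pre_duration, end = end,
                 ramp_duration = ramp_duration, post_duration = post_duration),
            class = "ramp_protocol")
}

# command voltage per sample for a protocol (shared by simulator and analysis)
command_voltage <- function(protocol, sampling_rate, step_target = NULL) {
  dt_ms <- 1000 / sampling_rate
  if (inherits(protocol, "step_protocol")) {
    stopifnot(!is.null(step_target))
    n <- round(protocol$sweep_duration / dt_ms)
    t_ms <- (seq_len(n) - 1L) * dt_ms
    v <- rep(protocol$holding, n)
    on <- t_ms >= protocol$step_onset &
      t_ms < protocol$step_onset + protocol$step_duration
    v[on] <- step_target
    v
  } else if (inherits(protocol, "ramp_protocol")) {
    n <- round((protocol$pre_duration + protocol$ramp_duration +
                  protocol$post_duration) / dt_ms)
    t_ms <- (seq_len(n) - 1L) * dt_ms
    v <- rep(protocol$start, n)
    ramping <- t_ms >= protocol$pre_duration &
      t_ms < protocol$pre_duration + protocol$ramp_duration
    v[ramping] <- protocol$start + (protocol$end - protocol$start) *
      (t_ms[ramping] - protocol$pre_duration) / protocol$ramp_duration
    v
  } else stop("unknown protocol")
}

#' Read a trace from columnar CSV/TSV plus a JSON metadata sidecar
#'
#' The trace file has columns `time_s` and `value`; the sidecar is a JSON
#' object with at least `sampling_rate_hz` and `mode` ("vc" or "cc"), and
#' optionally `Rs_mohm`, `cell_id`, `species`, `line`, `day` and a `protocol`
#' block.
#'
#' @param path trace file (CSV or TSV, detected from the header line).
#' @param meta_path JSON sidecar; defaults to `path` with a `.json` extension.
#' @return list with `trace` ([ephys_trace()]) and `meta` (named list).
#' @export
read_trace_csv <- function(path, meta_path = sub("\\.[ct]sv$", ".json", path)) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep)
  if (!all(c("time_s", "value") %in% names(d)))
    stop("trace file must have columns time_s, value")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$sampling_rate_hz))
    stop("metadata must name sampling_rate_hz")
  tr <- ephys_trace(d$value, meta$sampling_rate_hz, t0 = d$time_s[1],
                    mode = meta$mode %||% "vc")
  list(trace = tr, meta = meta)
}

#' Write a trace and its metadata sidecar
#'
#' @param trace an [ephys_trace()].
#' @param path output CSV path.
#' @param meta named list written as the JSON sidecar.
#' @param meta_path sidecar path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, meta = list(),
                            meta_path = sub("\\.[ct]sv$", ".json", path)) {
  d <- data.frame(time_s = trace_times(trace), value = trace$samples)
  utils::write.csv(d, path, row.names = FALSE)
  meta$sampling_rate_hz <- trace$sampling_rate
  meta$mode <- trace$mode
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
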