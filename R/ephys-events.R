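#' Count action potentials in a current-clamp step family
#'
#' An action potential is an upward crossing of `threshold` (default -20 mV);
#' crossings closer together than the refractory period are counted once.
#'
#' @param traces list of current-clamp [ephys_trace()]s, one per current step.
#' @param threshold crossing threshold, mV.
#' @param refractory minimum separation between counted crossings, ms.
#' @return list of class `ap_result`: `per_step_counts`, `max_count`.
#' @export
count_aps <- function(traces, threshold = -20, refractory = 1) {
  if (inherits(traces, "ephys_trace")) traces <- list(traces)
  if (length(traces) < 1L) stop("need at least one step trace")
  counts <- vapply(traces, function(tr) {
    v <- tr$samples
    up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
    if (length(up) <= 1L) return(length(up))
    min_gap <- refractory / 1000 * tr$sampling_rate
    kept <- up[1]; last <- up[1]
    for (i in up[-1]) {
      if (i - last >= min_gap) { kept <- c(kept, i); last <- i }
    }
    length(kept)
  }, 0L)
  structure(list(per_step_counts = counts, max_count = max(counts)),
            class = "ap_result")
}

#' Triangular-template EPSC detection parameters
#'
#' The template has a linear rise over `max_rise` ms and a linear decay over
#' `max_fall` ms (unit peak). `noise_sd` is the amplitude floor for accepted
#' events and `max_amplitude` the cap above which detections are rejected.
#' `detection_criterion` thresholds the template statistic (fitted scale
#' divided by its standard error); the default of 5 holds the false-event
#' rate on pure noise at the stated noise level well below 0.1 Hz while
#' retaining sensitivity across the 30-100 pA amplitude range.
#'
#' @param noise_sd estimated baseline noise SD, pA (default 14).
#' @param max_rise template rise time, ms (default 1.5).
#' @param max_fall template fall time, ms (default 6).
#' @param max_amplitude amplitude cap, pA (default 500).
#' @param detection_criterion detection statistic threshold (default 5).
#' @return list of class `triangular_template_params`.
#' @export
triangular_template_params <- function(noise_sd = 14, max_rise = 1.5,
                                       max_fall = 6, max_amplitude = 500,
                                       detection_criterion = 5) {
  stopifnot(noise_sd > 0, max_rise > 0, max_fall > 0, max_amplitude > 0,
            detection_criterion >= 0)
  structure(list(noise_sd = noise_sd, max_rise = max_rise,
                 max_fall = max_fall, max_amplitude = max_amplitude,
                 detection_criterion = detection_criterion),
            class = "triangular_template_params")
}

triangular_template <- function(params, sampling_rate) {
  nr <- max(1L, round(params$max_rise * sampling_rate / 1000))
  nf <- max(1L, round(params$max_fall * sampling_rate / 1000))
  c(seq_len(nr) / nr, 1 - seq_len(nf) / nf)
}

#' Detect spontaneous EPSCs by scaled-template matching
#'
#' Slides a triangular template (linear rise, linear decay) along the
#' inward-rectified trace; at each position the template is fitted by least
#' squares with a free scale and offset. Positions where the detection
#' statistic (scale over its standard error) reaches
#' `params$detection_criterion`, the fitted amplitude exceeds
#' `params$noise_sd` and does not exceed `params$max_amplitude` are event
#' candidates; contiguous candidate runs are merged to the local statistic
#' maximum. Events are returned inward-positive.
#'
#' @param trace voltage-clamp [ephys_trace()] (pA; inward currents negative).
#' @param params [triangular_template_params()].
#' @return list of class `epsc_result`: `events` (data.frame: time s,
#'   amplitude pA, rise ms, fall ms, criterion), `duration` s, `frequency`
#'   Hz, `log10_frequency` (NA with `zero_events = TRUE` when no events).
#' @export
detect_epscs <- function(trace, params = triangular_template_params()) {
  stopifnot(inherits(trace, "ephys_trace"))
  fs <- trace$sampling_rate
  if (fs < 1000) stop("sampling rate below 1 kHz: insufficient resolution")
  dur <- trace_duration(trace)
  if (dur < 1) stop("trace shorter than 1 s")

  x <- -trace$samples                      # inward-positive
  tm <- triangular_template(params, fs)
  N <- length(tm)
  ST <- sum(tm); STT <- sum(tm^2)
  Stt_c <- STT - ST^2 / N
  SxT <- as.numeric(stats::filter(x, rev(tm), sides = 1))
  Sx <- as.numeric(stats::filter(x, rep(1, N), sides = 1))
  Sxx <- as.numeric(stats::filter(x^2, rep(1, N), sides = 1))
  scale <- (SxT - Sx * ST / N) / Stt_c
  syy_c <- Sxx - Sx^2 / N
  sse <- pmax(syy_c - scale^2 * Stt_c, 0)
  se_scale <- sqrt(sse / (N - 2)) / sqrt(Stt_c)
  stat <- scale / se_scale

  ok <- !is.na(stat) & stat >= params$detection_criterion &
    scale > params$noise_sd & scale <= params$max_amplitude
  ok[is.na(ok)] <- FALSE
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  ev_end <- integer(0)
  for (i in which(r$values)) {
    seg <- starts[i]:ends[i]
    ev_end <- c(ev_end, seg[which.max(stat[seg])])
  }
  # merge detections closer than one template length (ripples and the decay
  # tail of an event re-trigger the statistic): keep the local criterion
  # maximum of each cluster
  if (length(ev_end) > 1L) {
    min_sep <- N
    kept <- integer(0)
    cluster <- ev_end[1]
    for (e in ev_end[-1]) {
      if (e - cluster[length(cluster)] < min_sep) cluster <- c(cluster, e)
      else { kept <- c(kept, cluster[which.max(stat[cluster])]); cluster <- e }
    }
    kept <- c(kept, cluster[which.max(stat[cluster])])
    ev_end <- kept
  }

  if (length(ev_end)) {
    onset <- ev_end - N + 1L
    amp <- scale[ev_end]
    offset <- (Sx[ev_end] - amp * ST) / N
    # the cap is an artifact-rejection rule: discard detections within three
    # template lengths of any sample above the cap, so partial-template fits
    # riding on, or trailing in the decay of, an oversized deflection cannot
    # re-enter below the cap
    over <- x > params$max_amplitude
    under_cap <- vapply(seq_along(ev_end), function(j) {
      w <- max(1L, onset[j] - 3L * N):min(length(x), onset[j] + 3L * N)
      !any(over[w])
    }, TRUE)
    ev_end <- ev_end[under_cap]
    onset <- onset[under_cap]; amp <- amp[under_cap]
    offset <- offset[under_cap]
  }
  if (length(ev_end)) {
    kin <- t(vapply(seq_along(ev_end), function(j) {
      o <- max(1L, onset[j])
      w <- o:min(length(x), o + 2L * N)
      xs <- x[w] - offset[j]
      pk <- which.max(xs[seq_len(min(length(xs), N))])
      below10 <- which(xs[seq_len(pk)] < 0.1 * amp[j])
      i10 <- if (length(below10)) max(below10) else 1L
      above90 <- which(xs[i10:pk] >= 0.9 * amp[j])
      i90 <- if (length(above90)) i10 + min(above90) - 1L else pk
      rise <- (i90 - i10) / fs * 1000
      post <- which(xs[pk:length(xs)] < amp[j] * exp(-1))
      fall <- if (length(post)) (min(post) - 1) / fs * 1000 else NA_real_
      c(rise, fall)
    }, c(0, 0)))
    events <- data.frame(
      time = trace$t0 + (onset - 1L) / fs,
      amplitude = amp,
      rise = kin[, 1],
      fall = kin[, 2],
      criterion = stat[ev_end])
  } else {
    events <- data.frame(time = numeric(0), amplitude = numeric(0),
                         rise = numeric(0), fall = numeric(0),
                         criterion = numeric(0))
  }
  freq <- nrow(events) / dur
  structure(list(events = events, duration = dur, frequency = freq,
                 log10_frequency = if (nrow(events) > 0) log10(freq) else NA_real_,
                 zero_events = nrow(events) == 0L),
            class = "epsc_result")
}

#' Log-frequency transform of an EPSC detection result
#'
#' Returns `log10(frequency)` for cells with at least one event; zero-event
#' cells are flagged (value NA) and are meant to be excluded from the
#' transformed series.
#'
#' @param result an `epsc_result`.
#' @return list: `log10_frequency` (NA when zero events), `zero_flag`.
#' @export
epsc_frequency_transform <- function(result) {
  stopifnot(inherits(result, "epsc_result"))
  if (result$duration <= 0) stop("duration must be positive")
  n <- nrow(result$events)
  list(log10_frequency = if (n > 0) log10(n / result$duration) else NA_real_,
       zero_flag = n == 0L)
}
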