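#' Fit the fast capacitive transient of a voltage step
#'
#' Least-squares single-exponential fit `I(t) = A*exp(-t/tau) + Iss` over the
#' first `fit_window` microseconds after step onset, skipping the first
#' `skip_samples` samples (anti-alias filter artifacts). For the whole-cell
#' circuit (pipette resistance Rs in series with Rcell parallel Ccell) the
#' fitted constant is `tau_fast = Ccell * (Rs*Rcell/(Rs+Rcell))`, so
#' `Ccell = tau_fast * (Rs+Rcell)/(Rs*Rcell)` when an input-resistance
#' estimate is supplied, and `Ccell = tau_fast / Rs` (the large-Rcell limit)
#' otherwise.
#'
#' @param trace voltage-clamp [ephys_trace()] of one step sweep (current, pA).
#' @param protocol a [step_protocol()].
#' @param step_target the step target of this sweep, mV.
#' @param rs series resistance, MOhm.
#' @param fit_window fit window after onset, microseconds (default 500).
#' @param rcell optional input-resistance estimate, MOhm, enabling the
#'   series-parallel correction.
#' @param iss optional fixed steady-state current, pA (e.g. the measured
#'   plateau); fixing it conditions the short-window fit much better than
#'   estimating all three parameters from 500 us of data.
#' @param skip_samples samples skipped at onset (default 2).
#' @return list with `tau_fast` (ms), `ccell` (pF), `a`, `iss`, and `ok`
#'   (FALSE with NA estimates when the fit fails or tau falls outside
#'   (0.01, 10) ms).
#' @export
fit_capacitive_transient <- function(trace, protocol, step_target, rs,
                                     fit_window = 500, rcell = NULL,
                                     iss = NULL, skip_samples = 2) {
  stopifnot(inherits(trace, "ephys_trace"), inherits(protocol, "step_protocol"))
  if (step_target == protocol$holding)
    stop("zero-amplitude step: nothing to fit")
  if (rs <= 0) stop("rs must be > 0")
  fs <- trace$sampling_rate
  onset <- round(protocol$step_onset / 1000 * fs) + 1L
  nwin <- max(0L, round(fit_window * 1e-6 * fs))
  idx <- seq(onset + skip_samples, onset + nwin - 1L)
  idx <- idx[idx <= length(trace$samples)]
  if (length(idx) < 5L)
    stop("fewer than 5 samples in the fit window")
  t_ms <- (idx - onset) / fs * 1000
  y <- trace$samples[idx]

  sse_for <- function(log_tau) {
    tau <- exp(log_tau)
    e <- exp(-t_ms / tau)
    if (is.null(iss)) sum(stats::lm.fit(cbind(e, 1), y)$residuals^2)
    else sum(stats::lm.fit(cbind(e), y - iss)$residuals^2)
  }
  opt <- stats::optimize(sse_for, interval = log(c(0.005, 20)))
  tau <- exp(opt$minimum)
  fail <- !is.finite(tau) || tau <= 0.01 || tau >= 10
  e <- exp(-t_ms / tau)
  cf <- if (is.null(iss)) stats::lm.fit(cbind(e, 1), y)$coefficients
  else c(stats::lm.fit(cbind(e), y - iss)$coefficients, iss)
  ccell <- if (is.null(rcell)) tau / rs * 1000 else
    tau * (rs + rcell) / (rs * rcell) * 1000
  if (fail)
    return(list(tau_fast = NA_real_, ccell = NA_real_,
                a = NA_real_, iss = NA_real_, ok = FALSE))
  list(tau_fast = tau, ccell = ccell, a = unname(cf[1]), iss = unname(cf[2]),
       ok = TRUE)
}

#' Input resistance from step plateau currents
#'
#' The plateau current of each sweep is the mean over 10 ms starting 20 ms
#' after step onset; the total resistance is the least-squares slope of
#' command voltage on plateau current across sweeps, and the input
#' resistance is that slope minus the series resistance.
#'
#' @param traces list of voltage-clamp [ephys_trace()]s, one per step target.
#' @param protocol a [step_protocol()]; `protocol$step_targets` must match
#'   `traces` in order.
#' @param rs series resistance subtracted from the measured slope, MOhm
#'   (default 0).
#' @param plateau_start,plateau_length plateau averaging window relative to
#'   step onset, ms.
#' @return Input resistance in MOhm.
#' @export
rcell_from_plateau <- function(traces, protocol, rs = 0,
                               plateau_start = 20, plateau_length = 10) {
  stopifnot(inherits(protocol, "step_protocol"))
  targets <- protocol$step_targets
  if (length(traces) != length(targets))
    stop("one trace per step target required")
  if (length(unique(targets)) < 2L)
    stop("degenerate step set: need >= 2 distinct step targets")
  plat <- vapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    fs <- tr$sampling_rate
    a <- round((protocol$step_onset + plateau_start) / 1000 * fs) + 1L
    b <- round((protocol$step_onset + plateau_start + plateau_length) / 1000 * fs)
    if (b > length(tr$samples)) stop("plateau window exceeds trace")
    mean(tr$samples[a:b])
  }, 0)
  i_na <- plat / 1000  # pA -> nA so the slope is in MOhm
  slope <- stats::coef(stats::lm(targets ~ i_na))[2]
  unname(slope) - rs
}

running_mean <- function(x, k) {
  k <- max(1L, as.integer(k))
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
}

#' Analyze a voltage-ramp sweep
#'
#' Estimates the input resistance from the current slope over the command
#' window `slope_window` (default -75 to -65 mV) and the resting membrane
#' potential from the zero-current crossing of the ramp. A capacitive
#' pedestal (the constant `C*dV/dt` offset the ramp adds to the current) is
#' estimated as the difference between the quasi-steady ramp current
#' extrapolated back to ramp onset and the pre-ramp holding current, and is
#' subtracted before the crossing is located. When the corrected current is
#' non-monotonic just above the slope window (subthreshold inward current
#' distorting the crossing), the crossing of the slope-window linear fit is
#' used instead.
#'
#' @param trace voltage-clamp [ephys_trace()] of the ramp sweep (pA).
#' @param protocol a [ramp_protocol()].
#' @param rs series resistance subtracted from the measured total resistance,
#'   MOhm (default 0).
#' @param slope_window command-voltage window for the resistance fit, mV.
#' @return list with `rcell` (MOhm), `vrmp` (mV; NA when undefined),
#'   `vrmp_method` ("crossing", "fit", or "undefined"), `pedestal` (pA).
#' @export
analyze_ramp <- function(trace, protocol, rs = 0, slope_window = c(-75, -65)) {
  stopifnot(inherits(trace, "ephys_trace"), inherits(protocol, "ramp_protocol"))
  fs <- trace$sampling_rate
  vcmd <- command_voltage(protocol, fs)
  n <- min(length(vcmd), length(trace$samples))
  vcmd <- vcmd[seq_len(n)]
  i_pa <- trace$samples[seq_len(n)]
  lo <- min(slope_window); hi <- max(slope_window)
  if (min(vcmd) > lo || max(vcmd) < hi)
    stop("command voltage does not span the slope window")

  n_pre <- round(protocol$pre_duration / 1000 * fs)
  n_ramp <- round(protocol$ramp_duration / 1000 * fs)
  hold_idx <- seq(max(1L, floor(n_pre / 2)), n_pre)
  i_hold <- mean(i_pa[hold_idx])

  ramp_idx <- seq(n_pre + 1L, min(n, n_pre + n_ramp))
  t_ms <- (ramp_idx - (n_pre + 1L)) / fs * 1000
  early <- t_ms >= 20 & t_ms <= min(120, protocol$ramp_duration / 4)
  fit0 <- stats::lm(i_pa[ramp_idx][early] ~ t_ms[early])
  i0 <- unname(stats::coef(fit0)[1])
  pedestal <- i0 - i_hold
  icorr <- i_pa[ramp_idx] - pedestal
  v <- vcmd[ramp_idx]

  in_win <- v >= lo & v <= hi
  fitw <- stats::lm(icorr[in_win] ~ v[in_win])
  b <- stats::coef(fitw)
  slope_pa_per_mv <- unname(b[2])
  rcell <- 1000 / slope_pa_per_mv - rs   # pA/mV -> MOhm after pA->nA
  v_fit_cross <- -unname(b[1]) / slope_pa_per_mv
  resid_sd <- stats::sd(stats::residuals(fitw))

  # non-monotonicity screen just above the window (2 mV bins, hi .. hi+20)
  nb <- v > hi & v <= hi + 20
  nonmono <- FALSE
  if (sum(nb) > 20) {
    bins <- cut(v[nb], breaks = seq(hi, hi + 20, by = 2))
    bm <- tapply(icorr[nb], bins, mean)
    bn <- tapply(icorr[nb], bins, length)
    keep <- !is.na(bm)
    bm <- bm[keep]; bn <- bn[keep]
    if (length(bm) >= 2) {
      guard <- 4 * resid_sd / sqrt(max(1, min(bn)))
      nonmono <- any(diff(bm) < -guard)
    }
  }

  if (nonmono) {
    vrmp <- v_fit_cross
    method <- "fit"
  } else {
    sm <- running_mean(icorr, round(15 / 1000 * fs))
    cross <- which(sm[-length(sm)] <= 0 & sm[-1] > 0)
    cross <- cross[!is.na(cross)]
    if (length(cross)) {
      v0 <- v[cross[1]]
      loc <- abs(v - v0) <= 3
      fit_loc <- stats::lm(icorr[loc] ~ v[loc])
      bl <- stats::coef(fit_loc)
      vrmp <- -unname(bl[1]) / unname(bl[2])
      method <- "crossing"
    } else if (v_fit_cross >= min(v) && v_fit_cross <= max(v)) {
      vrmp <- v_fit_cross
      method <- "fit"
    } else {
      vrmp <- NA_real_
      method <- "undefined"
    }
  }
  list(rcell = rcell, vrmp = vrmp, vrmp_method = method, pedestal = pedestal)
}

max_pairwise_reldev <- function(x) (max(x) - min(x)) / max(x)

#' Consolidate passive-property estimates
#'
#' When the independent estimates of a quantity agree (maximal pairwise
#' relative deviation, relative to the larger value, below `tol`) they are
#' averaged; otherwise the median is taken and a disagreement flag raised.
#' The membrane time constant is reported as `Rcell*Ccell` in ms.
#'
#' @param rcell_estimates,ccell_estimates numeric vectors (MOhm, pF); at
#'   least 2 finite values each.
#' @param vrmp_estimates optional numeric vector (mV); averaged (single
#'   values pass through).
#' @param rs series resistance carried into the QC record, MOhm.
#' @param tol agreement tolerance (default 0.1).
#' @return object of class `passive_properties`: `vrmp`, `rcell`, `ccell`,
#'   `tau` (ms), `rs`, `estimates_per_method`, `qc` (with
#'   `estimator_disagreement`).
#' @export
consolidate_passive <- function(rcell_estimates, ccell_estimates,
                                vrmp_estimates = NULL, rs = NA_real_,
                                tol = 0.1) {
  combine <- function(x, what) {
    x <- x[is.finite(x)]
    if (length(x) < 2L)
      stop(sprintf("need >= 2 finite %s estimates to consolidate", what))
    if (max_pairwise_reldev(x) < tol)
      list(value = mean(x), disagree = FALSE)
    else
      list(value = stats::median(x), disagree = TRUE)
  }
  r <- combine(rcell_estimates, "Rcell")
  c_ <- combine(ccell_estimates, "Ccell")
  vrmp <- if (is.null(vrmp_estimates)) NA_real_ else
    mean(vrmp_estimates[is.finite(vrmp_estimates)])
  structure(list(
    vrmp = vrmp, rcell = r$value, ccell = c_$value,
    tau = r$value * c_$value / 1000, rs = rs,
    estimates_per_method = list(rcell = rcell_estimates,
                                ccell = ccell_estimates,
                                vrmp = vrmp_estimates),
    qc = list(estimator_disagreement = r$disagree || c_$disagree)),
    class = "passive_properties")
}

#' Recording-stability quality control
#'
#' Flags recordings whose series resistance exceeds 25 MOhm, drifted up by
#' more than 5 MOhm, or whose initial passive values (Rcell, Ccell, Vrmp)
#' changed by more than 20%.
#'
#' @param initial,current `passive_properties` (or lists with fields `rs`,
#'   `rcell`, `ccell`, `vrmp`).
#' @param rs_limit absolute Rs cap, MOhm.
#' @param rs_drift_limit allowed Rs increase, MOhm.
#' @param drift_frac allowed relative change of initial values.
#' @return list of logical flags: `rs_exceeded`, `rs_drift_exceeded`,
#'   `initial_values_drifted`, `exclude`.
#' @export
qc_recording <- function(initial, current, rs_limit = 25,
                         rs_drift_limit = 5, drift_frac = 0.2) {
  relchange <- function(a, b) abs(b - a) / abs(a)
  rs_exceeded <- isTRUE(current$rs > rs_limit)
  rs_drift_exceeded <- isTRUE(current$rs - initial$rs > rs_drift_limit)
  drift <- c(relchange(initial$rcell, current$rcell),
             relchange(initial$ccell, current$ccell),
             relchange(initial$vrmp, current$vrmp))
  initial_values_drifted <- isTRUE(any(drift > drift_frac, na.rm = TRUE))
  list(rs_exceeded = rs_exceeded,
       rs_drift_exceeded = rs_drift_exceeded,
       initial_values_drifted = initial_values_drifted,
       exclude = rs_exceeded || rs_drift_exceeded || initial_values_drifted)
}

#' Passive properties from a step family plus a ramp sweep
#'
#' Convenience wrapper running [rcell_from_plateau()], per-sweep
#' [fit_capacitive_transient()] (with the series-parallel correction using
#' the plateau resistance) and [analyze_ramp()], then consolidating with
#' [consolidate_passive()]. An optional amplifier-style estimate pair can be
#' supplied as an extra method.
#'
#' @param step_traces list of step sweeps (one per protocol target).
#' @param ramp_trace ramp sweep.
#' @param step_proto,ramp_proto the protocols.
#' @param rs series resistance, MOhm.
#' @param software_estimate optional list(rcell=, ccell=) from the amplifier.
#' @return `passive_properties`.
#' @export
estimate_passive_properties <- function(step_traces, ramp_trace,
                                        step_proto = step_protocol(),
                                        ramp_proto = ramp_protocol(),
                                        rs = 15, software_estimate = NULL) {
  rcell_step <- rcell_from_plateau(step_traces, step_proto, rs = rs)
  cc <- vapply(seq_along(step_traces), function(i) {
    tr <- step_traces[[i]]
    fs <- tr$sampling_rate
    a <- round((step_proto$step_onset + 20) / 1000 * fs) + 1L
    b <- round((step_proto$step_onset + 30) / 1000 * fs)
    fit_capacitive_transient(tr, step_proto,
                             step_proto$step_targets[i], rs = rs,
                             rcell = rcell_step,
                             iss = mean(tr$samples[a:b]))$ccell
  }, 0)
  ramp <- analyze_ramp(ramp_trace, ramp_proto, rs = rs)
  rcell_est <- c(step = rcell_step, ramp = ramp$rcell)
  # per-sweep capacitance fits act as replicate methods
  ccell_est <- stats::setNames(cc, paste0("step", seq_along(cc)))
  if (!is.null(software_estimate)) {
    rcell_est <- c(rcell_est, software = software_estimate$rcell)
    ccell_est <- c(ccell_est, software = software_estimate$ccell)
  }
  consolidate_passive(rcell_est, ccell_est, vrmp_estimates = ramp$vrmp,
                      rs = rs)
}
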