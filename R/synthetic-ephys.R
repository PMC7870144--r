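#' Parameters for the single-compartment membrane simulator
#'
#' The forward model is the standard whole-cell circuit: pipette series
#' resistance `rs` in series with the membrane (input resistance `rcell` in
#' parallel with capacitance `ccell`), resting at `vrmp`. An optional
#' subthreshold voltage-gated inward conductance (Boltzmann activation,
#' instantaneous) can be added to emulate incipient sodium currents.
#'
#' @param rcell input resistance, MOhm.
#' @param ccell whole-cell capacitance, pF.
#' @param rs series resistance, MOhm.
#' @param vrmp resting membrane potential, mV.
#' @param noise_sd Gaussian current noise SD, pA (voltage clamp).
#' @param na_current `NULL`, or list(gmax_ns, erev, vhalf, slope) for the
#'   subthreshold conductance (nS, mV, mV, mV).
#' @return list of class `membrane_sim_params`.
#' @export
membrane_sim_params <- function(rcell = 500, ccell = 30, rs = 15,
                                vrmp = -75, noise_sd = 5,
                                na_current = NULL) {
  stopifnot(rcell > 0, ccell > 0, rs > 0, noise_sd >= 0)
  structure(list(rcell = rcell, ccell = ccell, rs = rs, vrmp = vrmp,
                 noise_sd = noise_sd, na_current = na_current),
            class = "membrane_sim_params")
}

# inward conductance current in pA at membrane voltage v (mV)
na_current_pa <- function(na, v) {
  if (is.null(na)) return(0)
  act <- 1 / (1 + exp(-(v - na$vhalf) / na$slope))
  na$gmax_ns * act * (v - na$erev)   # nS * mV = pA
}

#' Simulate a voltage-clamp sweep
#'
#' Integrates the single-compartment circuit under the protocol's command
#' voltage. The linear circuit is advanced with the exact exponential update
#' per sample (zero-order-hold command); with a nonlinear conductance the
#' membrane equation is sub-stepped with RK4. Gaussian current noise is added
#' to the sampled pipette current.
#'
#' @param p a [membrane_sim_params()].
#' @param protocol a [step_protocol()] (give `step_target`) or
#'   [ramp_protocol()].
#' @param step_target step target, mV (step protocols only).
#' @param sampling_rate Hz (default 20 kHz, the step-protocol rate).
#' @param seed optional RNG seed.
#' @return list: `trace` (current, pA), `truth` (the parameters plus the
#'   analytic fast time constant `tau_fast_ms` and, for steps, the analytic
#'   plateau current).
#' @export
simulate_voltage_clamp <- function(p, protocol, step_target = NULL,
                                   sampling_rate = 2e4, seed = NULL) {
  stopifnot(inherits(p, "membrane_sim_params"))
  if (!is.null(seed)) set.seed(seed)
  vcmd <- command_voltage(protocol, sampling_rate, step_target = step_target)
  n <- length(vcmd)
  dt_ms <- 1000 / sampling_rate
  g <- 1 / p$rs + 1 / p$rcell                 # uS
  tau_ms <- p$ccell / (1000 * g)              # pF / uS = us -> ms
  decay <- exp(-dt_ms / tau_ms)
  vm <- numeric(n)
  # start at steady state for the initial command
  vm[1] <- (vcmd[1] / p$rs + p$vrmp / p$rcell) / g
  if (is.null(p$na_current)) {
    vinf <- (vcmd / p$rs + p$vrmp / p$rcell) / g
    for (k in seq_len(n - 1L))
      vm[k + 1L] <- vinf[k] + (vm[k] - vinf[k]) * decay
  } else {
    nsub <- 4L
    h <- dt_ms / nsub
    dvm <- function(v, vc) {
      i_pa <- 1000 * (vc - v) / p$rs - 1000 * (v - p$vrmp) / p$rcell -
        na_current_pa(p$na_current, v)
      i_pa / p$ccell          # pA / pF = mV/ms
    }
    for (k in seq_len(n - 1L)) {
      v <- vm[k]
      for (s in seq_len(nsub)) {
        k1 <- dvm(v, vcmd[k])
        k2 <- dvm(v + h / 2 * k1, vcmd[k])
        k3 <- dvm(v + h / 2 * k2, vcmd[k])
        k4 <- dvm(v + h * k3, vcmd[k])
        v <- v + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      vm[k + 1L] <- v
    }
  }
  i_pa <- 1000 * (vcmd - vm) / p$rs
  if (p$noise_sd > 0) i_pa <- i_pa + stats::rnorm(n, 0, p$noise_sd)
  truth <- list(rcell = p$rcell, ccell = p$ccell, rs = p$rs, vrmp = p$vrmp,
                tau_fast_ms = tau_ms)
  if (inherits(protocol, "step_protocol") && !is.null(step_target))
    truth$plateau_pa <- 1000 * (step_target - p$vrmp) / (p$rs + p$rcell)
  list(trace = ephys_trace(i_pa, sampling_rate, mode = "vc"), truth = truth)
}

#' Simulate the four-step voltage family of the passive protocol
#'
#' @inheritParams simulate_voltage_clamp
#' @param protocol a [step_protocol()].
#' @return list: `traces` (one per step target), `truth`.
#' @export
simulate_step_family <- function(p, protocol = step_protocol(),
                                 sampling_rate = 2e4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  traces <- lapply(protocol$step_targets, function(tg)
    simulate_voltage_clamp(p, protocol, step_target = tg,
                           sampling_rate = sampling_rate)$trace)
  list(traces = traces,
       truth = list(rcell = p$rcell, ccell = p$ccell, rs = p$rs,
                    vrmp = p$vrmp,
                    tau_fast_ms = p$ccell / (1000 * (1 / p$rs + 1 / p$rcell))))
}

#' Simulate a current-clamp step family with stylized action potentials
#'
#' The passive voltage response to each current step is integrated exactly;
#' the passive depolarization is soft-capped at -35 mV (the analysis only
#' counts threshold crossings, so conductance-based spike dynamics are not
#' modelled). For each depolarizing step the requested number of stylized
#' spikes (2 ms, peak +20 mV) is inserted at evenly spaced known times;
#' hyperpolarizing steps never receive spikes.
#'
#' @param p a [membrane_sim_params()].
#' @param step_currents injected current per step, pA.
#' @param n_spikes integer vector: planted spike count per step.
#' @param step_onset,step_duration step timing, ms.
#' @param sampling_rate Hz (default 10 kHz).
#' @param noise_sd_mv voltage noise SD, mV.
#' @param seed optional RNG seed.
#' @return list: `traces` (one [ephys_trace()] per step), `truth`
#'   (`per_step_counts` actually inserted, `max_count`).
#' @export
simulate_current_clamp <- function(p, step_currents, n_spikes,
                                   step_onset = 50, step_duration = 500,
                                   sampling_rate = 1e4, noise_sd_mv = 0.3,
                                   seed = NULL) {
  stopifnot(inherits(p, "membrane_sim_params"),
            length(step_currents) == length(n_spikes))
  if (!is.null(seed)) set.seed(seed)
  fs <- sampling_rate
  dt_ms <- 1000 / fs
  sweep_ms <- step_onset + step_duration + 50
  n <- round(sweep_ms / dt_ms)
  t_ms <- (seq_len(n) - 1L) * dt_ms
  tau_m <- p$rcell * p$ccell / 1000           # ms
  on <- t_ms >= step_onset & t_ms < step_onset + step_duration
  i_on <- round(step_onset / dt_ms) + 1L
  traces <- vector("list", length(step_currents))
  planted <- integer(length(step_currents))
  for (s in seq_along(step_currents)) {
    iinj <- ifelse(on, step_currents[s], 0)
    vinf <- p$vrmp + iinj * p$rcell / 1000    # pA * MOhm = uV*... -> mV
    vinf <- pmin(vinf, -35)                   # stylized sodium-free ceiling
    v <- numeric(n); v[1] <- p$vrmp
    dec <- exp(-dt_ms / tau_m)
    for (k in seq_len(n - 1L))
      v[k + 1L] <- vinf[k] + (v[k] - vinf[k]) * dec
    ns <- if (step_currents[s] > 0) as.integer(n_spikes[s]) else 0L
    if (ns > 0) {
      # evenly spaced spike onsets within the step, >= 2.5 ms apart
      gap <- step_duration - 20
      times <- step_onset + 10 + (seq_len(ns) - 1L) * gap / max(ns, 1L)
      half <- max(1L, round(1 / dt_ms))       # 1 ms rise, 1 ms fall
      for (tt in times) {
        j <- round(tt / dt_ms) + 1L
        base <- v[j]
        up <- seq(j, min(n, j + half - 1L))
        v[up] <- base + (20 - base) * seq_along(up) / half
        dn <- seq(min(n, j + half), min(n, j + 2L * half - 1L))
        v[dn] <- 20 + (base - 5 - 20) * seq_along(dn) / half
      }
    }
    planted[s] <- ns
    if (noise_sd_mv > 0) v <- v + stats::rnorm(n, 0, noise_sd_mv)
    traces[[s]] <- ephys_trace(v, fs, mode = "cc")
  }
  list(traces = traces,
       truth = list(per_step_counts = planted, max_count = max(planted)))
}

#' Parameters for the synthetic EPSC train
#'
#' Poisson event times, lognormal amplitudes and a biexponential kernel
#' (`exp(-t/decay) - exp(-t/rise)`, unit peak) in Gaussian noise. The default
#' amplitude distribution places 95% of its mass in 30-100 pA.
#'
#' @param rate event rate, Hz.
#' @param amp_meanlog,amp_sdlog lognormal amplitude parameters (pA scale).
#' @param rise,decay kernel time constants, ms (`rise < decay`).
#' @param noise_sd Gaussian noise SD, pA.
#' @param duration trace duration, s.
#' @param sampling_rate Hz.
#' @return list of class `epsc_train_params`.
#' @export
epsc_train_params <- function(rate = 0.5,
                              amp_meanlog = log(sqrt(30 * 100)),
                              amp_sdlog = log(100 / 30) / (2 * 1.96),
                              rise = 0.5, decay = 4, noise_sd = 14,
                              duration = 60, sampling_rate = 1e4) {
  stopifnot(rate >= 0, rise > 0, decay > rise, noise_sd >= 0, duration > 0)
  structure(as.list(environment()), class = "epsc_train_params")
}

#' Simulate a spontaneous-EPSC voltage-clamp trace
#'
#' @param p an [epsc_train_params()].
#' @param seed optional RNG seed.
#' @return list: `trace` ([ephys_trace()], pA, inward events negative),
#'   `truth` (data.frame of onset `time` s and `amplitude` pA).
#' @export
simulate_epsc_trace <- function(p = epsc_train_params(), seed = NULL) {
  stopifnot(inherits(p, "epsc_train_params"))
  if (!is.null(seed)) set.seed(seed)
  fs <- p$sampling_rate
  n <- round(p$duration * fs)
  x <- if (p$noise_sd > 0) stats::rnorm(n, 0, p$noise_sd) else numeric(n)
  n_ev <- stats::rpois(1, p$rate * p$duration)
  kernel_ms <- 8 * p$decay
  times <- sort(stats::runif(n_ev, 0, p$duration - kernel_ms / 1000))
  amps <- stats::rlnorm(n_ev, p$amp_meanlog, p$amp_sdlog)
  if (n_ev > 0) {
    L <- round(kernel_ms / 1000 * fs)
    tt <- (seq_len(L) - 1L) / fs * 1000
    tpk <- log(p$decay / p$rise) * p$rise * p$decay / (p$decay - p$rise)
    norm <- exp(-tpk / p$decay) - exp(-tpk / p$rise)
    k <- (exp(-tt / p$decay) - exp(-tt / p$rise)) / norm
    for (i in seq_len(n_ev)) {
      j <- round(times[i] * fs) + 1L
      idx <- j:min(j + L - 1L, n)
      x[idx] <- x[idx] - amps[i] * k[seq_along(idx)]  # inward negative
    }
  }
  list(trace = ephys_trace(x, fs, mode = "vc"),
       truth = data.frame(time = times, amplitude = amps))
}
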