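# an ideal resistor "recording": I = (V - reversal)/R, constant per sweep
resistor_step_traces <- function(proto, r_mohm, reversal = -80, fs = 2e4) {
  lapply(proto$step_targets, function(tg) {
    v <- command_voltage(proto, fs, step_target = tg)
    ephys_trace(1000 * (v - reversal) / r_mohm, fs, mode = "vc")
  })
}

test_that("plateau resistance is exact on an ideal resistor", {
  proto <- step_protocol()
  traces <- resistor_step_traces(proto, 500)
  expect_equal(rcell_from_plateau(traces, proto), 500, tolerance = 1e-9)

  # two-step minimal input gives the same value
  proto2 <- step_protocol(step_targets = c(-95, -65))
  traces2 <- resistor_step_traces(proto2, 500)
  expect_equal(rcell_from_plateau(traces2, proto2), 500, tolerance = 1e-9)

  proto_bad <- step_protocol(step_targets = c(-90, -90))
  expect_error(rcell_from_plateau(resistor_step_traces(proto_bad, 500),
                                  proto_bad), "degenerate")
})

test_that("plateau resistance on a simulated cell is series-corrected", {
  p <- membrane_sim_params(rcell = 800, ccell = 30, rs = 15, vrmp = -75,
                           noise_sd = 5)
  fam <- simulate_step_family(p, step_protocol(), seed = 21)
  est <- rcell_from_plateau(fam$traces, step_protocol(), rs = 15)
  expect_lt(abs(est - 800) / 800, 0.03)
})

test_that("capacitive transient fit recovers tau and Ccell", {
  proto <- step_protocol()
  p <- membrane_sim_params(rcell = 500, ccell = 30, rs = 15, vrmp = -75,
                           noise_sd = 0)
  fam <- simulate_step_family(p, proto)
  ft <- fit_capacitive_transient(fam$traces[[1]], proto, -95, rs = 15,
                                 rcell = 500)
  # noiseless: tau equals the analytic Rs||Rcell * C constant within 1%
  expect_lt(abs(ft$tau_fast - fam$truth$tau_fast_ms) / fam$truth$tau_fast_ms,
            0.01)
  expect_lt(abs(ft$ccell - 30) / 30, 0.02)

  # without the input-resistance correction the large-Rcell limit holds
  p_inf <- membrane_sim_params(rcell = 5e5, ccell = 30, rs = 15, vrmp = -75,
                               noise_sd = 0)
  fam_inf <- simulate_step_family(p_inf, proto)
  ft_inf <- fit_capacitive_transient(fam_inf$traces[[1]], proto, -95, rs = 15)
  expect_lt(abs(ft_inf$tau_fast - 15 * 30 / 1000) / (15 * 30 / 1000), 0.01)
  expect_lt(abs(ft_inf$ccell - 30) / 30, 0.01)

  expect_error(fit_capacitive_transient(fam$traces[[1]], proto, -80, rs = 15),
               "zero-amplitude")
})

test_that("noisy capacitance estimates stay accurate in the median", {
  errs <- vapply(1:30, function(s) {
    set.seed(s)
    p <- membrane_sim_params(rcell = 500, ccell = 30, rs = 15, vrmp = -75,
                             noise_sd = 5)
    fam <- simulate_step_family(p, step_protocol())
    rc <- rcell_from_plateau(fam$traces, step_protocol(), rs = 15)
    tr <- fam$traces[[1]]
    a <- round((step_protocol()$step_onset + 20) / 1000 * tr$sampling_rate) + 1
    b <- round((step_protocol()$step_onset + 30) / 1000 * tr$sampling_rate)
    ft <- fit_capacitive_transient(tr, step_protocol(), -95, rs = 15,
                                   rcell = rc, iss = mean(tr$samples[a:b]))
    abs(ft$ccell - 30) / 30
  }, 0)
  expect_lt(stats::median(errs), 0.05)
})

test_that("ramp analysis is exact on an ideal resistor", {
  proto <- ramp_protocol()
  fs <- 2e4
  v <- command_voltage(proto, fs)
  tr <- ephys_trace(1000 * (v - (-80)) / 500, fs, mode = "vc")
  res <- analyze_ramp(tr, proto)
  expect_equal(res$rcell, 500, tolerance = 1e-6)
  expect_equal(res$vrmp, -80, tolerance = 1e-6)
})

test_that("ramp Vrmp survives the capacitive pedestal within 1 mV", {
  errs <- vapply(1:10, function(s) {
    p <- membrane_sim_params(rcell = 500, ccell = 30, rs = 15, vrmp = -75,
                             noise_sd = 5)
    sim <- simulate_voltage_clamp(p, ramp_protocol(), seed = 500 + s)
    abs(analyze_ramp(sim$trace, ramp_protocol(), rs = 15)$vrmp + 75)
  }, 0)
  expect_lt(stats::median(errs), 1)
  expect_lt(max(errs), 1.5)
})

test_that("subthreshold sodium current triggers the linear-fit fallback", {
  p <- membrane_sim_params(rcell = 500, ccell = 30, rs = 15, vrmp = -75,
                           noise_sd = 5,
                           na_current = list(gmax_ns = 1.5, erev = 60,
                                             vhalf = -48, slope = 5))
  sim <- simulate_voltage_clamp(p, ramp_protocol(), seed = 77)
  res <- analyze_ramp(sim$trace, ramp_protocol(), rs = 15)
  expect_identical(res$vrmp_method, "fit")
  expect_lt(abs(res$vrmp + 75), 2)
})

test_that("consolidation averages agreeing estimates and medians outliers", {
  ok <- consolidate_passive(c(100, 105, 95), c(29, 30, 31))
  expect_equal(ok$rcell, 100)
  expect_false(ok$qc$estimator_disagreement)

  bad <- consolidate_passive(c(100, 150, 100), c(30, 30))
  expect_equal(bad$rcell, 100)
  expect_true(bad$qc$estimator_disagreement)

  tau <- consolidate_passive(c(500, 500), c(30, 30))
  expect_equal(tau$tau, 15)   # MOhm * pF / 1000 = ms

  expect_error(consolidate_passive(c(100), c(30, 30)), ">= 2 finite")
})

test_that("QC flags are pure threshold functions", {
  base <- list(rs = 18, rcell = 500, ccell = 30, vrmp = -75)
  mod <- function(...) utils::modifyList(base, list(...))
  expect_true(qc_recording(base, mod(rs = 26))$rs_exceeded)
  expect_false(qc_recording(base, mod(rs = 25))$rs_exceeded)
  expect_false(qc_recording(base, mod(rs = 22))$rs_drift_exceeded)   # +4
  expect_true(qc_recording(base, mod(rs = 23.5))$rs_drift_exceeded)  # +5.5
  expect_true(qc_recording(base, mod(rcell = 650))$initial_values_drifted)
  expect_false(qc_recording(base, mod(rcell = 590))$initial_values_drifted)
  expect_true(qc_recording(base, mod(ccell = 30 * 1.25))$initial_values_drifted)
  expect_false(qc_recording(base, base)$exclude)
})

test_that("consolidated recovery is accurate on randomized cells", {
  errs <- t(vapply(1:25, function(s) {
    set.seed(1000 + s)
    p <- membrane_sim_params(rcell = stats::runif(1, 100, 1500),
                             ccell = stats::runif(1, 10, 60),
                             rs = stats::runif(1, 10, 25),
                             vrmp = stats::runif(1, -80, -65), noise_sd = 5)
    fam <- simulate_step_family(p, step_protocol())
    ramp <- simulate_voltage_clamp(p, ramp_protocol())
    pp <- estimate_passive_properties(fam$traces, ramp$trace, rs = p$rs)
    c(r = abs(pp$rcell - p$rcell) / p$rcell,
      c = abs(pp$ccell - p$ccell) / p$ccell,
      v = abs(pp$vrmp - p$vrmp))
  }, c(r = 0, c = 0, v = 0)))
  expect_lt(stats::median(errs[, "r"]), 0.05)
  expect_lt(stats::median(errs[, "c"]), 0.05)
  expect_lt(stats::median(errs[, "v"]), 1)
})
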