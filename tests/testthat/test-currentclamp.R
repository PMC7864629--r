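test_that("RMP is the mean of the initial zero-current window", {
  tr <- voltage_trace(rep(-60, 2000), rep(0, 2000), 10000)
  expect_equal(measure_rmp(tr), -60)
  set.seed(11)
  v <- -60 + rnorm(1000)
  tr2 <- voltage_trace(v, rep(0, 1000), 10000)
  expect_lt(abs(measure_rmp(tr2) - -60), 0.1)  # SE of mean ~ 1/sqrt(1000)
  tr3 <- voltage_trace(rep(-60, 1000), rep(10, 1000), 10000)
  expect_error(measure_rmp(tr3), "zero-current")
})

ohmic_sweep <- function(i_pa, r_gohm = 1, v0 = -65, sr = 10000) {
  n_base <- round(0.1 * sr); n_step <- round(0.5 * sr)
  v <- c(rep(v0, n_base), rep(v0 + i_pa * r_gohm, n_step), rep(v0, n_base))
  stim <- c(rep(0, n_base), rep(i_pa, n_step), rep(0, n_base))
  voltage_trace(v, stim, sr, holding_potential = v0)
}

test_that("input resistance recovers an ideal ohmic cell exactly", {
  sweeps <- lapply(seq(-50, 30, 10), ohmic_sweep)
  expect_equal(input_resistance(sweeps), 1000, tolerance = 1e-9)
  # two points define the same line
  two <- lapply(c(-50, 30), ohmic_sweep)
  expect_warning(r2 <- input_resistance(two), "2 distinct")
  expect_equal(r2, 1000, tolerance = 1e-9)
  expect_error(input_resistance(list(ohmic_sweep(-50))), "usable steps")
})

test_that("input resistance of the simulated passive neuron is 1/g_leak", {
  p <- neuron_params(g_na_ns = 0, g_kdr_ns = 0, g_m_ns = 0, g_bk_ns = 0,
                     g_sk_ns = 0, g_leak_ns = 1, e_leak_mv = -65)
  sweeps <- simulate_neuron(p, stimulus_protocol("step_family"))
  expect_lt(abs(input_resistance(sweeps) - 1000), 10)
})

test_that("AP detection finds synthetic peaks and ignores flat traces", {
  flat <- voltage_trace(rep(-65, 5000), rep(0, 5000), 25000)
  expect_identical(detect_aps(flat), integer(0))
  sp <- make_gaussian_spike(sd_ms = 1)
  pk <- detect_aps(sp)
  expect_length(pk, 1)
  expect_lt(abs(pk - which.max(sp$voltage)), 2)  # argmax oracle
})

test_that("train-evoked spikes are found with 20 ms ISIs", {
  tr <- simulate_neuron(neuron_params(), stimulus_protocol("pulse_train"))
  pk <- detect_aps(tr)
  expect_length(pk, 25)
  isis <- diff(pk) / tr$sampling_rate * 1000
  expect_true(all(abs(isis - 20) < 1))
})

test_that("threshold is read where dV/dt crosses the criterion", {
  # piecewise trace: 2 mV/ms to -40 mV, then 50 mV/ms to a peak
  sr <- 25000
  dt_ms <- 1000 / sr
  seg1 <- seq(-60, -40, by = 2 * dt_ms)
  seg2 <- seq(-40 + 50 * dt_ms, 20, by = 50 * dt_ms)
  v <- c(seg1, seg2, rev(seg2))
  tr <- voltage_trace(v, rep(0, length(v)), sr)
  pk <- which.max(v)
  thr <- ap_threshold(tr, pk, criterion_dvdt = 5)
  expect_lt(abs(thr - -40), 0.5)  # brute-force sample-scan value
  # unreachable criterion
  ramp <- voltage_trace(seq(-80, -60, length.out = 500), rep(0, 500), 25000)
  expect_error(ap_threshold(ramp, 400, criterion_dvdt = 5), "never reaches")
})

test_that("triangular spike has closed-form amplitude and half-width", {
  tr <- make_triangle_spike(v_h = -65, peak = 35, rise_ms = 1, fall_ms = 2)
  pk <- which.max(tr$voltage)
  res <- ap_amplitude_halfwidth(tr, pk, v_h = -65)
  expect_equal(res$amplitude_mv, 100)
  # half level -15 mV crossed at half the rise and half the fall: 1.5 ms
  expect_lt(abs(res$half_width_ms - 1.5), 1000 / tr$sampling_rate)
})

test_that("Gaussian spike half-width equals its FWHM", {
  for (sd_ms in c(0.4, 0.8, 1.6)) {
    tr <- make_gaussian_spike(sd_ms = sd_ms)
    pk <- which.max(tr$voltage)
    res <- ap_amplitude_halfwidth(tr, pk, v_h = -65)
    fwhm <- 2 * sd_ms * sqrt(2 * log(2))
    expect_lt(abs(res$half_width_ms - fwhm), 1000 / tr$sampling_rate)
  }
})

test_that("fAHP is read where the smoothed derivative settles", {
  # repolarisation to a flat plateau: derivative exactly 0 there
  sr <- 25000
  v <- c(seq(-65, 30, length.out = 26), seq(30, -58, length.out = 45),
         rep(-58, 500))
  tr <- voltage_trace(v, rep(0, length(v)), sr)
  pk <- which.max(v)
  expect_lt(abs(fahp(tr, pk) - -58), 0.5)
  # exponential repolarisation toward -60 with tau = 1 ms enters the band
  # when |dV/dt| = (V - -60)/tau <= 0.5, i.e. within 0.5 mV of -60
  t_ms <- seq(0, 15, by = 1000 / sr)
  v2 <- c(seq(-65, 30, length.out = 26), -60 + 90 * exp(-t_ms / 1))
  tr2 <- voltage_trace(v2, rep(0, length(v2)), sr)
  expect_lt(abs(fahp(tr2, which.max(v2)) - -60), 0.75)
  # simulated AP: fAHP close to the post-peak local minimum (brute force)
  ramp <- simulate_neuron(neuron_params(), stimulus_protocol("ramp"))
  pk3 <- detect_aps(ramp)[1]
  f <- fahp(ramp, pk3)
  local_min <- min(ramp$voltage[pk3:(pk3 + round(0.01 * ramp$sampling_rate))])
  expect_lt(abs(f - local_min), 1)
})

test_that("post-train AHPs follow the closed form of a decaying trace", {
  sr <- 10000
  v_h <- -65
  n_pre <- 100
  t_s <- seq(1 / sr, 1.5, by = 1 / sr)
  v <- c(rep(v_h, n_pre), v_h - 5 * exp(-t_s / 0.5))
  stim <- c(rep(1200, n_pre), rep(0, length(t_s)))
  tr <- voltage_trace(v, stim, sr, holding_potential = v_h)
  res <- post_burst_ahp(tr)
  expect_lt(abs(res$mahp_mv - -5), 0.01)
  expect_lt(abs(res$sahp_mv - -5 * exp(-2)), 0.01)
  # flat trace: both zero
  v2 <- c(rep(v_h, n_pre), rep(v_h, length(t_s)))
  tr2 <- voltage_trace(v2, stim, sr, holding_potential = v_h)
  res2 <- post_burst_ahp(tr2)
  expect_equal(res2$mahp_mv, 0)
  expect_equal(res2$sahp_mv, 0)
  # too-short recording errors
  short <- voltage_trace(v[1:(n_pre + sr)], stim[1:(n_pre + sr)], sr)
  expect_error(post_burst_ahp(short), "1.2 s")
})

test_that("QC gates pass study-typical cells and are strict at boundaries", {
  good <- data.frame(rs_mohm = 14.5, rn_mohm = 900.6, v_rest_mv = -53.5,
                     ap_amplitude_mv = 88)
  expect_true(apply_qc(good)$pass)
  expect_false(apply_qc(transform(good, rs_mohm = 30))$pass)
  expect_false(apply_qc(transform(good, v_rest_mv = -45))$pass)
  expect_false(apply_qc(transform(good, rn_mohm = 200))$pass)
  expect_false(apply_qc(transform(good, ap_amplitude_mv = 80))$pass)
  miss <- transform(good, rn_mohm = NA)
  expect_true(is.na(apply_qc(miss)$pass))
})

test_that("QC pass-rate on a cohort equals direct row-wise filtering", {
  set.seed(21)
  n <- 200
  cohort <- data.frame(
    rs_mohm = runif(n, 5, 40), rn_mohm = runif(n, 100, 1500),
    v_rest_mv = runif(n, -70, -30), ap_amplitude_mv = runif(n, 60, 120))
  res <- apply_qc(cohort)
  oracle <- with(cohort, rs_mohm < 30 & rn_mohm > 200 & v_rest_mv < -45 &
                   ap_amplitude_mv > 80)
  expect_identical(res$pass, oracle)
})

test_that("feature extraction is stable under resampling 10 to 50 kHz", {
  feats <- lapply(c(10000, 50000), function(sr) {
    tr <- simulate_neuron(neuron_params(),
                          stimulus_protocol("ramp", sampling_rate_hz = sr),
                          dt_ms = 0.02)
    pk <- detect_aps(tr)[1]
    c(thr = ap_threshold(tr, pk),
      hw = ap_amplitude_halfwidth(tr, pk)$half_width_ms,
      amp = ap_amplitude_halfwidth(tr, pk)$amplitude_mv)
  })
  expect_lt(abs(feats[[1]]["thr"] - feats[[2]]["thr"]), 0.5)
  expect_lt(abs(feats[[1]]["hw"] - feats[[2]]["hw"]), 0.1)
  expect_lt(abs(feats[[1]]["amp"] - feats[[2]]["amp"]), 0.5)
})
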