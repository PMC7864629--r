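test_that("full block leaves pure leak after the drug", {
  vc <- simulate_voltage_clamp(
    channel_params(drug_block_fraction = 1, noise_sd_pa = 0))
  post <- vc$post
  g <- 0.5; e <- -80
  n_step <- post$n_step_samples
  for (j in seq_along(post$steps_mv)) {
    expected <- c(rep(g * (post$steps_mv[j] - e), n_step),
                  rep(g * (0 - e), nrow(post$current_pa) - n_step))
    expect_equal(post$current_pa[, j], expected, tolerance = 1e-9)
  }
})

test_that("zero channel conductance subtracts to zero", {
  vc <- simulate_voltage_clamp(channel_params(g_max_ns = 0, noise_sd_pa = 0))
  sub <- subtract_drug(vc$pre, vc$post)
  expect_true(all(sub$current_pa == 0))
})

test_that("subtraction isolates the channel current and is linear", {
  pars <- channel_params(noise_sd_pa = 0)
  vc <- simulate_voltage_clamp(pars)
  sub <- subtract_drug(vc$pre, vc$post)
  # closed-form channel current at +30 mV, 999 ms
  j30 <- which(sub$steps_mv == 30)
  p_inf <- function(v) 1 / (1 + exp(-(v - -20) / 10))
  p0 <- p_inf(-80)
  p999 <- p_inf(30) + (p0 - p_inf(30)) * exp(-999 / 100)
  i_expect <- 5 * p999 * (30 - -85)
  mc <- measure_currents(sub)
  expect_equal(mc$peak_pa[j30], i_expect, tolerance = 1e-6)
  # 80% block: subtracted = 0.8 x channel current
  vc8 <- simulate_voltage_clamp(
    channel_params(drug_block_fraction = 0.8, noise_sd_pa = 0))
  sub8 <- subtract_drug(vc8$pre, vc8$post)
  expect_equal(sub8$current_pa, 0.8 * sub$current_pa, tolerance = 1e-9)
  # relative activation at 950 ms reaches 1 - exp(-9.5) of steady state
  sr <- sub$sampling_rate_hz
  i950 <- sub$current_pa[round(0.950 * sr), j30]
  i_inf <- 5 * p_inf(30) * (30 - -85)
  i_0 <- 5 * p0 * (30 - -85)
  expect_equal((i950 - i_0) / (i_inf - i_0), 1 - exp(-9.5),
               tolerance = 1e-6)
  # mismatched sweep sets are rejected
  other <- simulate_voltage_clamp(pars, vc_protocol(steps_mv = c(-80, 0)))
  expect_error(subtract_drug(vc$pre, other$post), "step potentials")
})

test_that("peak current at 999 ms matches the saturating closed form", {
  sr <- 10000
  t <- seq_len(1.3 * sr) / sr * 1000
  i_t <- 100 * (1 - exp(-t / 100))
  sweeps <- structure(list(
    cell_id = "x", condition = "subtracted", capacitance_pf = 10,
    sampling_rate_hz = sr, steps_mv = 0, n_step_samples = sr,
    current_pa = matrix(i_t, ncol = 1), seal_gohm = 1, rs_mohm = 10),
    class = "vc_sweep_set")
  mc <- measure_currents(sweeps)
  expect_equal(mc$peak_pa, 100 * (1 - exp(-9.99)), tolerance = 1e-9)
  # zero trace gives zero measurements
  sweeps$current_pa <- matrix(0, nrow = 1.3 * sr, ncol = 1)
  mc0 <- measure_currents(sweeps)
  expect_equal(mc0$peak_pa, 0)
  expect_equal(mc0$tail_pa, 0)
})

test_that("current density and percent-of-WT follow their definitions", {
  expect_equal(current_density(500, 10), 50)
  set.seed(41)
  wt <- rnorm(20, 100, 10)
  variant <- rnorm(20, 18.4, 5)
  res <- percent_of_wt(variant, wt)
  expect_equal(res$percent_of_wt, 100 * mean(variant) / mean(wt))
  expect_equal(res$reduction_percent, 100 - res$percent_of_wt)
  # identical groups: exactly 100%, zero reduction
  same <- percent_of_wt(wt, wt)
  expect_equal(same$percent_of_wt, 100)
  expect_equal(same$reduction_percent, 0)
  # scale invariance
  res2 <- percent_of_wt(3.7 * variant, 3.7 * wt)
  expect_equal(res2$percent_of_wt, res$percent_of_wt)
  expect_error(percent_of_wt(variant, rep(0, 5)), "zero")
})

test_that("activation tau is recovered without bias on noiseless traces", {
  sr <- 10000
  for (tau in c(25, 50, 100, 200, 400)) {
    vc <- simulate_voltage_clamp(channel_params(tau_ms = tau,
                                                noise_sd_pa = 0))
    sub <- subtract_drug(vc$pre, vc$post)
    j <- which(sub$steps_mv == 30)
    f <- fit_activation_tau(sub$current_pa[seq_len(sub$n_step_samples), j],
                            sr, 30)
    expect_true(f$converged)
    expect_lt(abs(f$tau_ms - tau) / tau, 0.005)
  }
})

test_that("tau is recovered within 10% median error at 5% noise", {
  sr <- 10000
  tau <- 100
  errs <- vapply(1:40, function(s) {
    vc <- simulate_voltage_clamp(
      channel_params(tau_ms = tau, noise_sd_pa = 0.05 * 570), seed = s)
    sub <- subtract_drug(vc$pre, vc$post)
    j <- which(sub$steps_mv == 30)
    f <- fit_activation_tau(sub$current_pa[seq_len(sub$n_step_samples), j],
                            sr, 30)
    abs(f$tau_ms - tau) / tau
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("degenerate flat traces are flagged unconverged", {
  f <- fit_activation_tau(rep(5, 10000), 10000, 0)
  expect_false(f$converged)
  expect_true(is.na(f$tau_ms))
  expect_error(fit_activation_tau(rep(5, 10000), 10000, -50), "restricted")
})

test_that("voltage-clamp QC boundaries are inclusive", {
  ok <- list(seal_gohm = 0.5, rs_mohm = 20)
  expect_true(qc_voltage_clamp(ok)$pass)
  expect_false(qc_voltage_clamp(list(seal_gohm = 0.4, rs_mohm = 10))$pass)
  expect_false(qc_voltage_clamp(list(seal_gohm = 1, rs_mohm = 25))$pass)
  expect_true(is.na(qc_voltage_clamp(list(seal_gohm = NA,
                                          rs_mohm = 10))$pass))
})

test_that("G-V from tails recovers the simulated Boltzmann", {
  vc <- simulate_voltage_clamp(
    channel_params(v_half_mv = -20, slope_mv = 10, noise_sd_pa = 0))
  sub <- subtract_drug(vc$pre, vc$post)
  gv <- gv_from_tails(measure_currents(sub))
  expect_true(gv$converged)
  expect_lt(abs(gv$v_half_mv - -20), 1)
  expect_lt(abs(gv$slope_mv - 10), 0.5)
  # saturated curve normalises to ~1 everywhere
  vcs <- simulate_voltage_clamp(
    channel_params(v_half_mv = -150, slope_mv = 5, noise_sd_pa = 0))
  subs <- subtract_drug(vcs$pre, vcs$post)
  gvs <- gv_from_tails(measure_currents(subs), fit = FALSE,
                       subtract_baseline = FALSE)
  expect_true(all(gvs$gv$g_norm > 0.97))
})
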