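#' Parameters of the single-compartment conductance-based neuron
#'
#' The synthetic neuron is a single-compartment Hodgkin-Huxley-style model
#' with a fast Na-like spiking conductance, a delayed-rectifier K
#' conductance, and three AHP-relevant K conductances: a slow
#' non-inactivating M-type conductance (gM), a fast voltage- and
#' Ca-dependent BK-type conductance (gBK), and a voltage-independent
#' Ca-activated SK-type conductance (gSK). Spikes increment a single
#' intracellular Ca pool (arbitrary units) that decays exponentially, which
#' gives SK/BK their afterhyperpolarization role. Units: capacitance pF,
#' conductance nS, potential mV, time ms; g*V is then in pA and (g*V)/C in
#' mV/ms.
#'
#' @param capacitance_pf Membrane capacitance (pF, > 0).
#' @param g_leak_ns,e_leak_mv Leak conductance (nS, >= 0) and reversal (mV).
#' @param g_na_ns,e_na_mv Fast Na-like conductance and reversal.
#' @param g_kdr_ns Delayed-rectifier K conductance.
#' @param g_m_ns M-type K conductance.
#' @param g_bk_ns BK-type K conductance.
#' @param g_sk_ns SK-type K conductance.
#' @param e_k_mv K reversal potential.
#' @param na_half_mv,na_slope_mv Activation midpoint/slope of the Na
#'   conductance (instantaneous cubed activation).
#' @param na_inact_half_mv,na_inact_slope_mv,na_inact_tau_ms Na inactivation
#'   gate parameters.
#' @param kdr_half_mv,kdr_slope_mv,kdr_tau_ms Delayed-rectifier gate.
#' @param m_half_mv,m_slope_mv,m_tau_ms M-conductance gate (slow).
#' @param bk_half_mv,bk_slope_mv,bk_tau_ms,bk_ca_kd BK gate; its steady state
#'   is the product of a Boltzmann in voltage and Ca/(Ca + bk_ca_kd).
#' @param sk_ca_kd SK half-activating Ca (arbitrary units); SK activation is
#'   Ca^2 / (Ca^2 + sk_ca_kd^2), voltage independent and instantaneous.
#' @param ca_influx_per_spike Ca increment (a.u.) added when the voltage
#'   crosses 0 mV upward.
#' @param ca_decay_tau_ms Ca pool decay time constant (ms, > 0).
#' @param noise_sd_mv Additive Gaussian voltage noise, SD in mV per sqrt(ms).
#' @return A list of class `neuron_params`.
#' @export
neuron_params <- function(capacitance_pf = 30,
                          g_leak_ns = 1, e_leak_mv = -55,
                          g_na_ns = 600, e_na_mv = 60,
                          g_kdr_ns = 120,
                          g_m_ns = 0.5, g_bk_ns = 1, g_sk_ns = 1,
                          e_k_mv = -90,
                          na_half_mv = -28, na_slope_mv = 7,
                          na_inact_half_mv = -40, na_inact_slope_mv = 8,
                          na_inact_tau_ms = 3,
                          kdr_half_mv = 0, kdr_slope_mv = 8, kdr_tau_ms = 3,
                          m_half_mv = -35, m_slope_mv = 10, m_tau_ms = 150,
                          bk_half_mv = -10, bk_slope_mv = 12, bk_tau_ms = 1,
                          bk_ca_kd = 15,
                          sk_ca_kd = 10,
                          ca_influx_per_spike = 1,
                          ca_decay_tau_ms = 500,
                          noise_sd_mv = 0) {
  p <- as.list(environment())
  gs <- c(p$g_leak_ns, p$g_na_ns, p$g_kdr_ns, p$g_m_ns, p$g_bk_ns, p$g_sk_ns)
  if (any(gs < 0)) stop("all conductances must be >= 0")
  if (p$capacitance_pf <= 0) stop("capacitance must be > 0")
  if (p$ca_decay_tau_ms <= 0) stop("ca_decay_tau_ms must be > 0")
  structure(p, class = "neuron_params")
}

#' Current-clamp stimulus protocols
#'
#' Builds one of the three current-injection protocols used for the
#' current-clamp phenotyping:
#' \describe{
#'   \item{ramp}{a linear current ramp from 0 to `ramp_amplitude_pa` over
#'     `ramp_duration_ms` (defaults 80 pA / 500 ms), used for single-AP
#'     features;}
#'   \item{step_family}{a family of 500 ms square steps from -50 to +30 pA in
#'     10 pA increments, used for input resistance;}
#'   \item{pulse_train}{25 brief (2 ms) suprathreshold pulses at 50 Hz
#'     (default 1.2 nA; some protocols use 1.4 nA, hence configurable),
#'     followed by >= 1.2 s of silence for the post-train medium/slow AHP.}
#' }
#'
#' @param kind One of `"ramp"`, `"step_family"`, `"pulse_train"`.
#' @param sampling_rate_hz Output sampling rate (>= 10 kHz).
#' @param holding_potential_mv Holding potential V_h (mV).
#' @param baseline_ms Silent baseline before the stimulus.
#' @param ramp_amplitude_pa,ramp_duration_ms Ramp endpoint and duration.
#' @param step_amplitudes_pa Step family amplitudes (pA, uniform increments).
#' @param step_duration_ms Step duration.
#' @param train_n_pulses,train_pulse_ms,train_amplitude_pa,train_rate_hz
#'   Pulse-train shape (25 pulses, 2 ms, 1200 pA, 50 Hz).
#' @param post_train_window_s Silence after the last pulse (>= 1.2 s).
#' @param tail_ms Silence appended after ramp/step stimuli.
#' @return A list of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(kind = c("ramp", "step_family", "pulse_train"),
                              sampling_rate_hz = 25000,
                              holding_potential_mv = -65,
                              baseline_ms = 100,
                              ramp_amplitude_pa = 80, ramp_duration_ms = 500,
                              step_amplitudes_pa = seq(-50, 30, by = 10),
                              step_duration_ms = 500,
                              train_n_pulses = 25, train_pulse_ms = 2,
                              train_amplitude_pa = 1200, train_rate_hz = 50,
                              post_train_window_s = 1.2,
                              tail_ms = 200) {
  kind <- match.arg(kind)
  if (sampling_rate_hz < 10000) stop("sampling_rate_hz must be >= 10 kHz")
  if (kind == "pulse_train" && post_train_window_s < 1.2) {
    stop("post_train_window_s must be >= 1.2 s to measure the slow AHP")
  }
  if (kind == "step_family") {
    inc <- diff(step_amplitudes_pa)
    if (length(inc) > 0 && any(abs(inc - inc[1]) > 1e-9)) {
      stop("step_amplitudes_pa must have uniform increments")
    }
  }
  structure(as.list(environment()), class = "stimulus_protocol")
}

#' Stimulus waveforms of a protocol
#'
#' @param protocol A [stimulus_protocol()].
#' @return A list of numeric stimulus vectors (pA), one per sweep, each with
#'   attribute `amplitude_pa` where meaningful.
#' @export
build_stimulus <- function(protocol) {
  sr <- protocol$sampling_rate_hz
  ms <- function(x) round(x * sr / 1000)
  nb <- ms(protocol$baseline_ms)
  if (protocol$kind == "ramp") {
    nr <- ms(protocol$ramp_duration_ms)
    stim <- c(rep(0, nb),
              seq(0, protocol$ramp_amplitude_pa, length.out = nr),
              rep(0, ms(protocol$tail_ms)))
    return(list(structure(stim, amplitude_pa = protocol$ramp_amplitude_pa)))
  }
  if (protocol$kind == "step_family") {
    nstep <- ms(protocol$step_duration_ms)
    ntail <- ms(protocol$tail_ms)
    return(lapply(protocol$step_amplitudes_pa, function(a) {
      structure(c(rep(0, nb), rep(a, nstep), rep(0, ntail)),
                amplitude_pa = a)
    }))
  }
  # pulse_train
  period <- ms(1000 / protocol$train_rate_hz)
  width <- ms(protocol$train_pulse_ms)
  one <- c(rep(protocol$train_amplitude_pa, width), rep(0, period - width))
  stim <- c(rep(0, nb), rep(one, protocol$train_n_pulses - 1),
            rep(protocol$train_amplitude_pa, width),
            rep(0, ms(protocol$post_train_window_s * 1000)))
  list(structure(stim, amplitude_pa = protocol$train_amplitude_pa))
}

boltz <- function(v, half, slope) 1 / (1 + exp(-(v - half) / slope))

# zero-current fixed point of the subthreshold (leak + steady M/Kdr/Na) model,
# found by bisection on the steady-state current balance
passive_rest <- function(p) {
  f <- function(v) {
    h <- 1 / (1 + exp((v - p$na_inact_half_mv) / p$na_inact_slope_mv))
    p$g_leak_ns * (v - p$e_leak_mv) +
      p$g_na_ns * boltz(v, p$na_half_mv, p$na_slope_mv)^3 * h *
        (v - p$e_na_mv) +
      p$g_kdr_ns * boltz(v, p$kdr_half_mv, p$kdr_slope_mv) * (v - p$e_k_mv) +
      p$g_m_ns * boltz(v, p$m_half_mv, p$m_slope_mv) * (v - p$e_k_mv)
  }
  stats::uniroot(f, c(-120, -20), tol = 1e-10)$root
}

#' Simulate a current-clamp sweep from the conductance-based neuron
#'
#' Integrates the model with a fixed-step explicit scheme (forward Euler for
#' voltage and Ca, exponential Euler for the gating variables) at
#' `dt_ms` <= 0.05 ms, then samples the solution at the protocol sampling
#' rate. Before the stimulus begins the model is initialised at steady state
#' for the holding current that clamps the resting model at the protocol
#' holding potential. Output is bit-reproducible for a fixed seed.
#'
#' @param params A [neuron_params()].
#' @param protocol A [stimulus_protocol()].
#' @param seed Integer seed for the voltage noise (ignored when
#'   `noise_sd_mv = 0` apart from reproducibility of the call).
#' @param dt_ms Integration step (ms, <= 0.05).
#' @param clamp_holding When `TRUE` (default, matching the recording
#'   configuration) a constant bias current holds the model at the protocol
#'   holding potential before the stimulus; with `FALSE` no bias is injected
#'   and the model rests at its own resting potential (used e.g. for
#'   zero-current RMP sweeps).
#' @return A [voltage_trace()] for `ramp`/`pulse_train`, or a list of
#'   `voltage_trace` sweeps for `step_family`.
#' @export
simulate_neuron <- function(params, protocol, seed = 1, dt_ms = 0.02,
                            clamp_holding = TRUE) {
  stopifnot(inherits(params, "neuron_params"),
            inherits(protocol, "stimulus_protocol"))
  if (dt_ms > 0.05) stop("dt_ms must be <= 0.05 ms")
  set.seed(seed)
  stims <- build_stimulus(protocol)
  sweeps <- lapply(stims, function(s) {
    simulate_sweep(params, s, protocol$sampling_rate_hz,
                   protocol$holding_potential_mv, dt_ms, clamp_holding)
  })
  for (i in seq_along(sweeps)) {
    attr(sweeps[[i]], "amplitude_pa") <- attr(stims[[i]], "amplitude_pa")
  }
  if (length(sweeps) == 1) sweeps[[1]] else sweeps
}

# One sweep of the fixed-step integration. The stimulus vector is given at
# the output sampling rate; it is held constant over the sub-steps within
# each output sample.
simulate_sweep <- function(p, stim, sampling_rate, v_hold, dt_ms,
                           clamp_holding = TRUE) {
  nsub <- max(1L, round(1000 / sampling_rate / dt_ms))
  dt <- 1000 / sampling_rate / nsub
  n_out <- length(stim)

  # gates at steady state for the starting potential; with clamp_holding a
  # constant bias current balances the model exactly at v_hold
  v <- if (clamp_holding) v_hold else passive_rest(p)
  h <- 1 / (1 + exp((v - p$na_inact_half_mv) / p$na_inact_slope_mv))
  n_g <- boltz(v, p$kdr_half_mv, p$kdr_slope_mv)
  w <- boltz(v, p$m_half_mv, p$m_slope_mv)
  b <- 0
  ca <- 0
  i_hold <- if (clamp_holding) {
    p$g_leak_ns * (v - p$e_leak_mv) +
      p$g_na_ns * boltz(v, p$na_half_mv, p$na_slope_mv)^3 * h *
        (v - p$e_na_mv) +
      p$g_kdr_ns * n_g * (v - p$e_k_mv) +
      p$g_m_ns * w * (v - p$e_k_mv)
  } else 0

  out <- numeric(n_out)
  noise_scale <- p$noise_sd_mv * sqrt(dt)
  noise <- if (p$noise_sd_mv > 0) stats::rnorm(n_out * nsub) else NULL
  last_spike <- -Inf
  t <- 0
  k <- 0L
  for (i in seq_len(n_out)) {
    i_inj <- stim[i] + i_hold
    for (j in seq_len(nsub)) {
      k <- k + 1L
      m_inf <- boltz(v, p$na_half_mv, p$na_slope_mv)
      i_na <- p$g_na_ns * m_inf^3 * h * (v - p$e_na_mv)
      i_k <- p$g_kdr_ns * n_g * (v - p$e_k_mv)
      i_m <- p$g_m_ns * w * (v - p$e_k_mv)
      i_bk <- p$g_bk_ns * b * (v - p$e_k_mv)
      s_inf <- ca^2 / (ca^2 + p$sk_ca_kd^2)
      i_sk <- p$g_sk_ns * s_inf * (v - p$e_k_mv)
      i_leak <- p$g_leak_ns * (v - p$e_leak_mv)
      dv <- (i_inj - i_leak - i_na - i_k - i_m - i_bk - i_sk) /
        p$capacitance_pf * dt
      v_new <- v + dv
      if (!is.null(noise)) v_new <- v_new + noise_scale * noise[k]
      # exponential Euler on the gates
      h_inf <- 1 / (1 + exp((v - p$na_inact_half_mv) / p$na_inact_slope_mv))
      h <- h_inf + (h - h_inf) * exp(-dt / p$na_inact_tau_ms)
      n_inf <- boltz(v, p$kdr_half_mv, p$kdr_slope_mv)
      n_g <- n_inf + (n_g - n_inf) * exp(-dt / p$kdr_tau_ms)
      w_inf <- boltz(v, p$m_half_mv, p$m_slope_mv)
      w <- w_inf + (w - w_inf) * exp(-dt / p$m_tau_ms)
      b_inf <- boltz(v, p$bk_half_mv, p$bk_slope_mv) * ca / (ca + p$bk_ca_kd)
      b <- b_inf + (b - b_inf) * exp(-dt / p$bk_tau_ms)
      ca <- ca * exp(-dt / p$ca_decay_tau_ms)
      t <- t + dt
      if (v < 0 && v_new >= 0 && (t - last_spike) > 2) {
        ca <- ca + p$ca_influx_per_spike
        last_spike <- t
      }
      v <- v_new
      if (!is.finite(v)) {
        stop(sprintf(paste0("integration diverged at t = %.2f ms; ",
                            "check conductances (g_na = %g nS, g_kdr = %g nS)",
                            " against dt_ms = %g"),
                     t, p$g_na_ns, p$g_kdr_ns, dt))
      }
    }
    out[i] <- v
  }
  voltage_trace(out, as.numeric(stim), sampling_rate,
                holding_potential = v_hold)
}
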