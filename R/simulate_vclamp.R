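#' Voltage-clamp step protocol
#'
#' The whole-cell protocol for slowly activating K currents: from a holding
#' potential of -80 mV, 1000 ms depolarising steps from -80 to +40 mV in
#' +10 mV increments (one sweep every 20 s), each followed by a 300 ms step
#' to 0 mV for tail-current analysis.
#'
#' @param holding_mv Holding potential (default -80).
#' @param steps_mv Step potentials (default -80 to +40 by 10; uniform).
#' @param step_duration_ms Step duration (default 1000).
#' @param tail_potential_mv Tail potential (default 0).
#' @param tail_duration_ms Tail duration (default 300).
#' @param inter_sweep_s Sweep interval (default 20 s; metadata only).
#' @param sampling_rate_hz Sampling rate (default 10 kHz).
#' @return A list of class `vc_protocol`.
#' @export
vc_protocol <- function(holding_mv = -80, steps_mv = seq(-80, 40, by = 10),
                        step_duration_ms = 1000, tail_potential_mv = 0,
                        tail_duration_ms = 300, inter_sweep_s = 20,
                        sampling_rate_hz = 10000) {
  if (length(steps_mv) > 1) {
    inc <- diff(steps_mv)
    if (any(abs(inc - inc[1]) > 1e-9)) stop("steps_mv must be uniform")
  }
  if (step_duration_ms <= 0 || tail_duration_ms <= 0) {
    stop("durations must be > 0")
  }
  structure(as.list(environment()), class = "vc_protocol")
}

#' Parameters of the simulated Boltzmann-gated K channel
#'
#' A non-inactivating channel whose open probability relaxes with a single
#' exponential toward a Boltzmann steady state, plus an ohmic leak. A
#' fraction `drug_block_fraction` of the channel conductance is removed in
#' the post-drug condition, so the pre-minus-post subtraction isolates the
#' drug-sensitive current.
#'
#' @param g_max_ns Maximal channel conductance (nS).
#' @param v_half_mv,slope_mv Boltzmann midpoint and slope (slope != 0).
#' @param tau_ms Activation time constant in ms: a single number or a
#'   function of voltage (mV).
#' @param reversal_mv Channel reversal potential (default -85, a K channel).
#' @param g_leak_ns,e_leak_mv Leak conductance and reversal.
#' @param capacitance_pf Membrane capacitance (metadata for densities).
#' @param drug_block_fraction Blocked fraction in [0, 1] (default 1, a
#'   saturating blocker dose).
#' @param noise_sd_pa Additive Gaussian current noise SD (pA).
#' @param seal_gohm,rs_mohm Seal and series resistance metadata for QC.
#' @return A list of class `channel_params`.
#' @export
channel_params <- function(g_max_ns = 5, v_half_mv = -20, slope_mv = 10,
                           tau_ms = 100, reversal_mv = -85,
                           g_leak_ns = 0.5, e_leak_mv = -80,
                           capacitance_pf = 10, drug_block_fraction = 1,
                           noise_sd_pa = 0, seal_gohm = 1, rs_mohm = 10) {
  p <- as.list(environment())
  if (p$slope_mv == 0) stop("slope_mv must be non-zero")
  if (p$drug_block_fraction < 0 || p$drug_block_fraction > 1) {
    stop("drug_block_fraction must be in [0, 1]")
  }
  structure(p, class = "channel_params")
}

tau_at <- function(params, v) {
  if (is.function(params$tau_ms)) params$tau_ms(v) else params$tau_ms
}

#' Simulate a pre/post-drug voltage-clamp sweep pair
#'
#' For each protocol step the channel open probability starts at its
#' holding-potential steady state and relaxes exponentially toward the step
#' steady state; the tail segment relaxes from the end-of-step value toward
#' the tail-potential steady state with the tail-potential time constant.
#' The pre-drug sweep carries the full channel conductance, the post-drug
#' sweep the unblocked fraction; leak and noise are present in both.
#'
#' @param params A [channel_params()].
#' @param protocol A [vc_protocol()].
#' @param seed Integer seed for the current noise.
#' @param cell_id Cell identifier.
#' @return A list with elements `pre` and `post`, each a `vc_sweep_set`:
#'   current matrix (samples x steps, pA), step potentials, capacitance,
#'   sampling rate, condition, and QC metadata.
#' @export
simulate_voltage_clamp <- function(params = channel_params(),
                                   protocol = vc_protocol(), seed = 1,
                                   cell_id = "cell") {
  stopifnot(inherits(params, "channel_params"),
            inherits(protocol, "vc_protocol"))
  set.seed(seed)
  sr <- protocol$sampling_rate_hz
  n_step <- round(protocol$step_duration_ms * sr / 1000)
  n_tail <- round(protocol$tail_duration_ms * sr / 1000)
  t_step <- seq_len(n_step) / sr * 1000   # ms; sample i sits at t = i/sr
  t_tail <- seq_len(n_tail) / sr * 1000
  p_inf <- function(v) boltz(v, params$v_half_mv, params$slope_mv)
  p0 <- p_inf(protocol$holding_mv)
  one_condition <- function(g_channel) {
    cur <- vapply(protocol$steps_mv, function(v) {
      pinf_v <- p_inf(v)
      p_t <- pinf_v + (p0 - pinf_v) * exp(-t_step / tau_at(params, v))
      i_step <- g_channel * p_t * (v - params$reversal_mv) +
        params$g_leak_ns * (v - params$e_leak_mv)
      p_end <- p_t[n_step]
      vt <- protocol$tail_potential_mv
      pinf_t <- p_inf(vt)
      p_tl <- pinf_t + (p_end - pinf_t) * exp(-t_tail / tau_at(params, vt))
      i_tail <- g_channel * p_tl * (vt - params$reversal_mv) +
        params$g_leak_ns * (vt - params$e_leak_mv)
      c(i_step, i_tail)
    }, numeric(n_step + n_tail))
    if (params$noise_sd_pa > 0) {
      cur <- cur + stats::rnorm(length(cur), sd = params$noise_sd_pa)
    }
    cur
  }
  mk <- function(cur, condition) {
    structure(list(cell_id = cell_id, condition = condition,
                   capacitance_pf = params$capacitance_pf,
                   sampling_rate_hz = sr,
                   steps_mv = protocol$steps_mv,
                   n_step_samples = n_step,
                   current_pa = cur,
                   seal_gohm = params$seal_gohm, rs_mohm = params$rs_mohm,
                   protocol = protocol),
              class = "vc_sweep_set")
  }
  list(pre = mk(one_condition(params$g_max_ns), "pre_drug"),
       post = mk(one_condition(params$g_max_ns *
                                 (1 - params$drug_block_fraction)),
                 "post_drug"))
}

#' @export
print.vc_sweep_set <- function(x, ...) {
  cat(sprintf(
    "<vc_sweep_set> cell '%s' (%s): %d steps (%g..%g mV), C_m = %g pF\n",
    x$cell_id, x$condition, length(x$steps_mv), min(x$steps_mv),
    max(x$steps_mv), x$capacitance_pf))
  invisible(x)
}
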