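#' Construct a current-clamp voltage trace
#'
#' A `voltage_trace` holds one sweep of sampled membrane potential together
#' with the injected-current waveform and the acquisition metadata the
#' downstream extractors need (holding potential, junction-potential state,
#' series resistance).
#'
#' @param voltage Numeric vector of membrane potential samples (mV).
#' @param stimulus Numeric vector of injected current (pA), same length as
#'   `voltage`.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param holding_potential Holding potential V_h in mV (default -65).
#' @param series_resistance Series resistance R_S in megaohm, from the
#'   acquisition metadata (optional).
#' @param ljp_corrected Logical; have the potentials already been shifted by
#'   the liquid junction potential?
#' @param ljp_mv The junction potential (mV) applied when `ljp_corrected` is
#'   `TRUE`. Required in that case.
#' @return An object of class `voltage_trace`.
#' @seealso [ljp_correct()], [measure_rmp()], [detect_aps()]
#' @export
voltage_trace <- function(voltage, stimulus, sampling_rate,
                          holding_potential = -65,
                          series_resistance = NA_real_,
                          ljp_corrected = FALSE, ljp_mv = NA_real_) {
  voltage <- as.numeric(voltage)
  stimulus <- as.numeric(stimulus)
  if (length(voltage) != length(stimulus)) {
    stop("`voltage` and `stimulus` must have the same length (got ",
         length(voltage), " and ", length(stimulus), ")")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number (Hz)")
  }
  if (isTRUE(ljp_corrected) && is.na(ljp_mv)) {
    stop("an LJP-corrected trace must record the applied `ljp_mv`")
  }
  structure(
    list(voltage = voltage, stimulus = stimulus,
         sampling_rate = as.numeric(sampling_rate),
         holding_potential = as.numeric(holding_potential),
         series_resistance = as.numeric(series_resistance),
         ljp_corrected = isTRUE(ljp_corrected),
         ljp_mv = as.numeric(ljp_mv)),
    class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %d samples @ %g kHz (%.1f ms), V_h = %g mV%s\n",
              length(x$voltage), x$sampling_rate / 1000,
              1000 * length(x$voltage) / x$sampling_rate,
              x$holding_potential,
              if (x$ljp_corrected) sprintf(", LJP-corrected (%g mV)", x$ljp_mv)
              else ""))
  invisible(x)
}

#' Sample times of a trace
#'
#' @param trace A [voltage_trace()].
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
trace_times <- function(trace) {
  (seq_along(trace$voltage) - 1) / trace$sampling_rate
}

#' First time derivative of the membrane potential
#'
#' Central finite differences in the interior, forward/backward differences at
#' the edges, scaled to mV/ms.
#'
#' @param trace A [voltage_trace()].
#' @return Numeric vector of dV/dt in mV/ms, same length as the trace.
#' @export
trace_dvdt <- function(trace) {
  v <- trace$voltage
  n <- length(v)
  if (n < 2) stop("trace too short to differentiate")
  dt_ms <- 1000 / trace$sampling_rate
  d <- numeric(n)
  d[1] <- (v[2] - v[1]) / dt_ms
  d[n] <- (v[n] - v[n - 1]) / dt_ms
  if (n > 2) d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt_ms)
  d
}
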