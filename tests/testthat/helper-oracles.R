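# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Junction potential by direct numerical integration of the stationary
# Nernst-Planck potential gradient along the linear mixing path.
oracle_ljp_numeric <- function(pipette, bath, temperature_k = 306.65) {
  merged <- merge(as.data.frame(pipette), as.data.frame(bath),
                  by = c("species", "charge", "mobility"), all = TRUE,
                  suffixes = c("_p", "_b"))
  merged$conc_mm_p[is.na(merged$conc_mm_p)] <- 0
  merged$conc_mm_b[is.na(merged$conc_mm_b)] <- 0
  z <- merged$charge; u <- merged$mobility
  cp <- merged$conc_mm_p; cb <- merged$conc_mm_b
  rt_f <- 8.314462618 * temperature_k / 96485.33212 * 1000
  top <- sum(z * u * (cb - cp))
  f <- function(x) {
    vapply(x, function(xx) {
      -rt_f * top / sum(z^2 * u * ((1 - xx) * cp + xx * cb))
    }, numeric(1))
  }
  # bath-minus-pipette potential; negate to the package's pipette-referenced
  # correction convention
  -stats::integrate(f, 0, 1, rel.tol = 1e-12)$value
}

# Brute-force Poisson tail sum P(N >= n | lambda), accumulated in log space
# so extreme tails keep full relative precision; returns log P.
oracle_log_poisson_tail <- function(n, lambda, terms = 2000) {
  k <- seq(n, n + terms)
  logs <- -lambda + k * log(lambda) - lgamma(k + 1)
  m <- max(logs)
  m + log(sum(exp(logs - m)))
}
oracle_surprise <- function(n, rate, span) {
  -oracle_log_poisson_tail(n, rate * span)
}

# Synthetic spikes with known geometry, returned as voltage_trace objects.
make_gaussian_spike <- function(v_h = -65, peak = 35, sd_ms = 0.5,
                                sampling_rate = 25000, dur_ms = 40,
                                center_ms = dur_ms / 2) {
  t <- seq(0, dur_ms, by = 1000 / sampling_rate)
  v <- v_h + (peak - v_h) * exp(-((t - center_ms)^2) / (2 * sd_ms^2))
  voltage_trace(v, rep(0, length(v)), sampling_rate,
                holding_potential = v_h)
}

make_triangle_spike <- function(v_h = -65, peak = 35, rise_ms = 1,
                                fall_ms = 2, sampling_rate = 25000,
                                pad_ms = 10) {
  sr <- sampling_rate
  up <- seq(v_h, peak, length.out = round(rise_ms * sr / 1000) + 1)
  down <- seq(peak, v_h, length.out = round(fall_ms * sr / 1000) + 1)[-1]
  v <- c(rep(v_h, round(pad_ms * sr / 1000)), up, down,
         rep(v_h, round(pad_ms * sr / 1000)))
  voltage_trace(v, rep(0, length(v)), sr, holding_potential = v_h)
}
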