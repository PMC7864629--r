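#' Biphasic extracellular spike template
#'
#' A ~1 ms biphasic waveform (negative-then-positive, derivative-of-Gaussian
#' shape) normalised to a unit negative peak.
#'
#' @param sampling_rate_hz Sampling rate.
#' @param width_ms Total template width (default 1 ms).
#' @return Numeric template vector.
#' @export
spike_template <- function(sampling_rate_hz = 12500, width_ms = 1) {
  n <- max(5L, round(width_ms * sampling_rate_hz / 1000))
  t <- seq(-1, 1, length.out = n)
  w <- -t * exp(-(t / 0.45)^2)   # biphasic, negative lobe first
  w / abs(min(w))
}

#' Simulate raw extracellular MEA signals from a raster
#'
#' Per electrode, the raw signal is Gaussian white noise plus the spike
#' template inserted at every raster spike time, with the template peak
#' expressed as a multiple of the noise RMS. Overlapping spikes superpose
#' linearly (a warning reports how many).
#'
#' @param raster A [spike_raster()].
#' @param amplitude_rms Template negative-peak amplitude as a multiple of
#'   the noise RMS (default 12).
#' @param noise_sd Noise standard deviation in signal units (default 1; 0
#'   gives a noiseless signal whose threshold crossings equal the planted
#'   spikes).
#' @param sampling_rate_hz Sampling rate (default 12.5 kHz).
#' @param seed Integer seed.
#' @return A list of class `raw_mea_signal`: per-electrode numeric signals,
#'   with attributes `sampling_rate_hz`, `ground_truth` (the raster) and
#'   `noise_sd`.
#' @export
simulate_extracellular <- function(raster, amplitude_rms = 12, noise_sd = 1,
                                   sampling_rate_hz = 12500, seed = 1) {
  stopifnot(inherits(raster, "spike_raster"))
  set.seed(seed)
  dur <- attr(raster, "duration_s")
  n <- round(dur * sampling_rate_hz)
  tmpl <- spike_template(sampling_rate_hz)
  amp <- amplitude_rms * max(noise_sd, 1e-12)
  half <- length(tmpl) %/% 2
  n_overlap <- 0L
  sig <- lapply(unclass(raster), function(times) {
    x <- if (noise_sd > 0) stats::rnorm(n, sd = noise_sd) else numeric(n)
    idx <- round(times * sampling_rate_hz) + 1L
    if (length(idx) > 1 && any(diff(idx) < length(tmpl))) {
      n_overlap <<- n_overlap + sum(diff(idx) < length(tmpl))
    }
    for (i in idx) {
      lo <- i - half
      span <- seq_along(tmpl) + lo - 1L
      ok <- span >= 1L & span <= n
      x[span[ok]] <- x[span[ok]] + amp * tmpl[ok]
    }
    x
  })
  if (n_overlap > 0) {
    warning(n_overlap, " spike pairs closer than the template width; ",
            "superposed linearly")
  }
  structure(sig, sampling_rate_hz = sampling_rate_hz,
            ground_truth = raster, noise_sd = noise_sd,
            class = "raw_mea_signal")
}

#' Threshold spike detection on a raw extracellular signal
#'
#' Band-pass filters the signal (Butterworth, default 300-5000 Hz), sets a
#' per-channel threshold at `k` times a robust noise RMS estimate
#' (median(|x|)/0.6745, computed over rolling windows so the threshold
#' adapts to slow noise changes), and emits one event per threshold
#' crossing of either polarity with a dead time, timed at the extremum of
#' the crossing.
#'
#' @param x Numeric signal vector (one electrode) or a `raw_mea_signal`.
#' @param sampling_rate_hz Sampling rate (>= 12.5 kHz nominal; required for
#'   plain vectors).
#' @param band Band-pass corner frequencies in Hz (default c(300, 5000)).
#' @param k Threshold multiple of the noise RMS (default 6).
#' @param dead_time_ms Dead time after each event (default 1 ms).
#' @param rms_window_s Window for the rolling robust RMS (default 10 s).
#' @return Numeric vector of spike times (s); for a `raw_mea_signal`, a
#'   [spike_raster()].
#' @export
detect_spikes_raw <- function(x, sampling_rate_hz = NULL,
                              band = c(300, 5000), k = 6,
                              dead_time_ms = 1, rms_window_s = 10) {
  if (inherits(x, "raw_mea_signal")) {
    sr <- attr(x, "sampling_rate_hz")
    dur <- length(x[[1]]) / sr
    trains <- lapply(unclass(x), detect_spikes_raw, sampling_rate_hz = sr,
                     band = band, k = k, dead_time_ms = dead_time_ms,
                     rms_window_s = rms_window_s)
    return(spike_raster(trains, duration_s = dur, well_id = "detected"))
  }
  sr <- sampling_rate_hz
  if (is.null(sr)) stop("sampling_rate_hz is required")
  n <- length(x)
  if (n < 3 * sr / band[1]) {
    stop("signal shorter than the band-pass filter warm-up")
  }
  bf <- signal::butter(2, band / (sr / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)
  # rolling robust RMS -> per-sample threshold
  win <- max(1L, round(rms_window_s * sr))
  n_win <- ceiling(n / win)
  thr <- numeric(n)
  # floor against degenerate (near-noiseless) channels, where the robust RMS
  # collapses to numerical filter residue
  thr_floor <- 1e-3 * max(abs(xf))
  for (b in seq_len(n_win)) {
    idx <- ((b - 1L) * win + 1L):min(b * win, n)
    rms <- stats::median(abs(xf[idx])) / 0.6745
    thr[idx] <- max(k * rms, thr_floor)
  }
  over <- which(abs(xf) > thr)
  if (length(over) == 0) return(numeric(0))
  dead <- max(1L, round(dead_time_ms * sr / 1000))
  # group crossings separated by less than the dead time into one event,
  # timed at the extremum of the group
  grp <- cumsum(c(1L, as.integer(diff(over) >= dead)))
  vapply(split(over, grp), function(seg) {
    ext <- seg[which.max(abs(xf[seg]))]
    (ext - 1L) / sr
  }, numeric(1), USE.NAMES = FALSE)
}
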