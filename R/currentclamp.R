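#' Resting membrane potential from a zero-current sweep
#'
#' Mean voltage over the first `window_ms` of a sweep recorded without
#' current injection (the resting potential is taken right after break-in,
#' before any stimulus).
#'
#' @param trace A [voltage_trace()].
#' @param window_ms Averaging window from the start of the sweep (default
#'   100 ms).
#' @return RMP in mV.
#' @export
measure_rmp <- function(trace, window_ms = 100) {
  n <- min(length(trace$voltage),
           max(1L, round(window_ms * trace$sampling_rate / 1000)))
  if (any(trace$stimulus[seq_len(n)] != 0)) {
    stop("stimulus is non-zero inside the RMP window; ",
         "RMP requires a zero-current sweep")
  }
  mean(trace$voltage[seq_len(n)])
}

# index range of the (constant, non-zero) current step in a sweep
find_step <- function(trace) {
  on <- which(trace$stimulus != 0)
  if (length(on) == 0) return(NULL)
  list(start = on[1], end = on[length(on)],
       amplitude = stats::median(trace$stimulus[on]))
}

#' Input resistance from a subthreshold step family
#'
#' Ordinary least-squares slope of the steady-state voltage deflection
#' against injected current over a family of 500 ms current steps
#' (-50 to +30 pA). Steady state is the mean over the last `ss_window_ms` of
#' each step; the baseline is the pre-step mean. Sweeps that contain action
#' potentials are excluded with a warning.
#'
#' @param sweeps List of [voltage_trace()] sweeps, one per step amplitude.
#' @param ss_window_ms Steady-state window at the end of each step
#'   (default 100 ms).
#' @param ap_peak_mv Peak criterion used to flag spiking sweeps (mV).
#' @return Input resistance R_N in megaohm.
#' @export
input_resistance <- function(sweeps, ss_window_ms = 100, ap_peak_mv = 0) {
  if (inherits(sweeps, "voltage_trace")) sweeps <- list(sweeps)
  pts <- lapply(sweeps, function(tr) {
    step <- find_step(tr)
    if (is.null(step)) return(NULL)  # 0 pA sweep carries no information
    nss <- max(1L, round(ss_window_ms * tr$sampling_rate / 1000))
    ss_idx <- max(step$start, step$end - nss + 1L):step$end
    if (max(tr$voltage[ss_idx]) > ap_peak_mv ||
        length(detect_aps(tr, min_peak = ap_peak_mv)) > 0) {
      warning(sprintf("sweep at %+g pA contains APs; excluded", step$amplitude))
      return(NULL)
    }
    base_idx <- seq_len(step$start - 1L)
    base <- if (length(base_idx) > 0) mean(tr$voltage[base_idx]) else
      tr$holding_potential
    c(i = step$amplitude, dv = mean(tr$voltage[ss_idx]) - base)
  })
  pts <- do.call(rbind, pts[!vapply(pts, is.null, logical(1))])
  if (is.null(pts) || nrow(pts) < 2 || length(unique(pts[, "i"])) < 2) {
    stop("need >= 2 usable steps at distinct amplitudes ",
         "(>= 3 recommended) to estimate input resistance")
  }
  if (length(unique(pts[, "i"])) < 3) {
    warning("input resistance estimated from only 2 distinct step amplitudes")
  }
  slope <- stats::coef(stats::lm(dv ~ i, data = as.data.frame(pts)))[["i"]]
  slope * 1000  # mV/pA -> megaohm
}

#' Detect action-potential peaks
#'
#' Finds local maxima above `min_peak` whose approach (the preceding 2 ms)
#' reaches a rate of rise of at least `min_dvdt`, with a minimum peak
#' separation.
#'
#' @param trace A [voltage_trace()] sampled at >= 10 kHz.
#' @param min_peak Minimum peak voltage (mV, default 0).
#' @param min_dvdt Minimum pre-peak dV/dt (mV/ms, default 10).
#' @param min_separation_ms Minimum separation between accepted peaks
#'   (default 2 ms).
#' @return Integer vector of peak sample indices (possibly empty), strictly
#'   increasing.
#' @export
detect_aps <- function(trace, min_peak = 0, min_dvdt = 10,
                       min_separation_ms = 2) {
  v <- trace$voltage
  n <- length(v)
  if (n < 3) return(integer(0))
  cand <- which(v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] > v[3:n] &
                  v[2:(n - 1)] > min_peak) + 1L
  if (length(cand) == 0) return(integer(0))
  d <- trace_dvdt(trace)
  pre <- max(1L, round(min_separation_ms * trace$sampling_rate / 1000))
  ok <- vapply(cand, function(i) {
    max(d[max(1L, i - pre):i]) >= min_dvdt
  }, logical(1))
  cand <- cand[ok]
  if (length(cand) == 0) return(integer(0))
  # enforce separation, keeping the taller peak of any conflicting pair
  keep <- integer(0)
  for (i in cand[order(-v[cand])]) {
    if (all(abs(i - keep) >= pre)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Action-potential threshold by the dV/dt criterion
#'
#' The threshold is the voltage on the rising phase where the first
#' derivative of the trace first sustains the criterion rate of rise
#' (default 5 mV/ms): searching backward from the peak, the last upward
#' crossing of dV/dt through the criterion, linearly interpolated between
#' the bracketing samples.
#'
#' @param trace A [voltage_trace()].
#' @param peak_index AP peak sample index (from [detect_aps()]).
#' @param criterion_dvdt Criterion rate of rise in mV/ms (default 5).
#' @return Threshold voltage in mV.
#' @export
ap_threshold <- function(trace, peak_index, criterion_dvdt = 5) {
  d <- trace_dvdt(trace)
  v <- trace$voltage
  if (peak_index < 2) stop("peak index too early to hold a rising phase")
  above <- which(d[seq_len(peak_index - 1L)] >= criterion_dvdt)
  if (length(above) == 0) {
    stop(sprintf("dV/dt never reaches %g mV/ms before the peak at %d",
                 criterion_dvdt, peak_index))
  }
  # start of the last super-criterion run = last upward crossing
  i <- above[length(above)]
  while (i > 1 && d[i - 1] >= criterion_dvdt) i <- i - 1L
  if (i == 1) return(v[1])
  lo <- i - 1L  # d[lo] < criterion <= d[lo + 1]
  frac <- (criterion_dvdt - d[lo]) / (d[lo + 1] - d[lo])
  v[lo] + frac * (v[lo + 1] - v[lo])
}

# linearly interpolated crossing time (in samples, 1-based fractional)
cross_time <- function(v, i, level) i + (level - v[i]) / (v[i + 1] - v[i])

#' AP amplitude and half-width relative to the holding potential
#'
#' Amplitude is the difference between V_h and the AP peak; the half-width
#' is the time spent above the half-amplitude level V_h + amplitude/2, with
#' linear interpolation at the two crossings.
#'
#' @param trace A [voltage_trace()].
#' @param peak_index AP peak sample index.
#' @param v_h Holding potential (mV); defaults to the trace's.
#' @param max_fall_ms Give up if the falling crossing is not found within
#'   this window after the peak (default 20 ms).
#' @return List with `amplitude_mv` and `half_width_ms`.
#' @export
ap_amplitude_halfwidth <- function(trace, peak_index,
                                   v_h = trace$holding_potential,
                                   max_fall_ms = 20) {
  v <- trace$voltage
  sr <- trace$sampling_rate
  amp <- v[peak_index] - v_h
  if (amp <= 0) stop("AP peak is not above the holding potential")
  half <- v_h + amp / 2
  # rising crossing: last upward crossing of `half` before the peak
  i <- peak_index
  while (i > 1 && v[i - 1] > half) i <- i - 1
  if (i == 1) stop("rising half-amplitude crossing not found")
  t_rise <- cross_time(v, i - 1L, half)
  # falling crossing: first downward crossing after the peak
  j_max <- min(length(v) - 1L, peak_index + round(max_fall_ms * sr / 1000))
  j <- peak_index
  while (j <= j_max && v[j + 1] > half) j <- j + 1
  if (j > j_max || v[j + 1] > half) {
    stop(sprintf("falling half-amplitude crossing not found within %g ms",
                 max_fall_ms))
  }
  t_fall <- cross_time(v, j, half)
  list(amplitude_mv = amp, half_width_ms = (t_fall - t_rise) * 1000 / sr)
}

#' Fast afterhyperpolarization after a single AP
#'
#' After the peak, the 1 ms sliding average of the first derivative is
#' followed through the repolarisation; the fAHP is the voltage at the first
#' sample where that mean derivative returns into the band 0 +/- `band`
#' (mV/ms) after having been below -`band`, i.e. where the fast
#' repolarisation flattens out.
#'
#' @param trace A [voltage_trace()].
#' @param peak_index AP peak sample index.
#' @param band Half-width of the derivative band (mV/ms, default 0.5).
#' @param window_ms Search window after the peak (default 10 ms).
#' @param slide_ms Width of the sliding average (default 1 ms).
#' @return fAHP voltage in mV, or `NA` (with a message) if the derivative
#'   never settles inside the band within the window.
#' @export
fahp <- function(trace, peak_index, band = 0.5, window_ms = 10,
                 slide_ms = 1) {
  sr <- trace$sampling_rate
  d <- trace_dvdt(trace)
  k <- max(1L, round(slide_ms * sr / 1000))
  sm <- stats::filter(d, rep(1 / k, k), sides = 2)
  hi <- min(length(d), peak_index + round(window_ms * sr / 1000))
  idx <- (peak_index + 1L):hi
  sm_w <- as.numeric(sm[idx])
  below <- which(sm_w < -band)
  if (length(below) == 0) {
    message("fAHP: repolarisation never exceeded the derivative band; ",
            "no fAHP reported")
    return(NA_real_)
  }
  settle <- which(abs(sm_w) <= band & seq_along(sm_w) > below[1])
  if (length(settle) == 0) {
    message("fAHP: derivative did not settle within ", window_ms,
            " ms of the peak; no fAHP reported")
    return(NA_real_)
  }
  trace$voltage[idx[settle[1]]]
}

#' Medium and slow afterhyperpolarization after a pulse train
#'
#' From the sweep containing the 50 Hz train of 25 suprathreshold pulses:
#' the mAHP is the most negative voltage within 1 s after the offset of the
#' last current pulse, and the sAHP the voltage exactly 1 s after that
#' offset (nearest sample), both expressed relative to V_h (negative values
#' = hyperpolarised).
#'
#' @param trace A [voltage_trace()] containing the train; the pulse offset
#'   is read from the stimulus channel.
#' @param v_h Holding potential (mV); defaults to the trace's.
#' @return List with `mahp_mv` and `sahp_mv`.
#' @export
post_burst_ahp <- function(trace, v_h = trace$holding_potential) {
  sr <- trace$sampling_rate
  on <- which(trace$stimulus != 0)
  if (length(on) == 0) stop("no stimulus found in the train sweep")
  offset <- on[length(on)]
  need <- offset + round(1.2 * sr)
  if (length(trace$voltage) < need) {
    stop("recording must extend >= 1.2 s beyond the last pulse offset")
  }
  one_s <- offset + round(1.0 * sr)
  seg <- trace$voltage[(offset + 1L):one_s]
  list(mahp_mv = min(seg) - v_h,
       sahp_mv = trace$voltage[one_s] - v_h)
}

#' Quality-control limits for current-clamp cells
#'
#' The four inclusion gates: series resistance < 30 megaohm, input
#' resistance > 200 megaohm, resting potential < -45 mV, and AP amplitude
#' > 80 mV from V_h. All comparisons are strict.
#'
#' @param max_rs_mohm,min_rn_mohm,max_v_rest_mv,min_ap_amplitude_mv The four
#'   limits.
#' @return A list of class `qc_limits`.
#' @export
qc_limits <- function(max_rs_mohm = 30, min_rn_mohm = 200,
                      max_v_rest_mv = -45, min_ap_amplitude_mv = 80) {
  lim <- list(max_rs_mohm = max_rs_mohm, min_rn_mohm = min_rn_mohm,
              max_v_rest_mv = max_v_rest_mv,
              min_ap_amplitude_mv = min_ap_amplitude_mv)
  if (!all(vapply(lim, is.finite, logical(1)))) stop("all limits must be finite")
  structure(lim, class = "qc_limits")
}

#' Apply the current-clamp quality-control gates
#'
#' @param cells A data.frame with columns `rs_mohm`, `rn_mohm`, `v_rest_mv`,
#'   `ap_amplitude_mv` (one row per cell), or a list with those fields for a
#'   single cell.
#' @param limits A [qc_limits()].
#' @return A data.frame with logical `pass` and a `reasons` string listing
#'   every violated gate (empty when passing); a missing field makes the
#'   cell indeterminate (`pass = NA`, reason flags the field).
#' @export
apply_qc <- function(cells, limits = qc_limits()) {
  if (!is.data.frame(cells)) cells <- as.data.frame(cells)
  need <- c("rs_mohm", "rn_mohm", "v_rest_mv", "ap_amplitude_mv")
  missing_cols <- setdiff(need, names(cells))
  if (length(missing_cols) > 0) {
    stop("missing QC fields: ", paste(missing_cols, collapse = ", "))
  }
  res <- lapply(seq_len(nrow(cells)), function(i) {
    row <- cells[i, ]
    if (anyNA(row[need])) {
      return(list(pass = NA,
                  reasons = paste0("missing: ",
                                   paste(need[is.na(row[need])],
                                         collapse = ", "))))
    }
    fails <- character(0)
    if (!(row$rs_mohm < limits$max_rs_mohm))
      fails <- c(fails, sprintf("R_S %g >= %g MOhm", row$rs_mohm,
                                limits$max_rs_mohm))
    if (!(row$rn_mohm > limits$min_rn_mohm))
      fails <- c(fails, sprintf("R_N %g <= %g MOhm", row$rn_mohm,
                                limits$min_rn_mohm))
    if (!(row$v_rest_mv < limits$max_v_rest_mv))
      fails <- c(fails, sprintf("V_rest %g >= %g mV", row$v_rest_mv,
                                limits$max_v_rest_mv))
    if (!(row$ap_amplitude_mv > limits$min_ap_amplitude_mv))
      fails <- c(fails, sprintf("AP amplitude %g <= %g mV",
                                row$ap_amplitude_mv,
                                limits$min_ap_amplitude_mv))
    list(pass = length(fails) == 0, reasons = paste(fails, collapse = "; "))
  })
  data.frame(pass = vapply(res, `[[`, logical(1), "pass"),
             reasons = vapply(res, `[[`, character(1), "reasons"),
             stringsAsFactors = FALSE)
}

#' Extract the per-cell current-clamp feature set
#'
#' Convenience wrapper running the individual extractors over one cell's
#' sweeps: RMP sweep (zero current), subthreshold step family, ramp sweep
#' (first-AP features) and pulse-train sweep (post-train AHPs).
#'
#' @param rmp_sweep,step_sweeps,ramp_sweep,train_sweep Sweeps as produced by
#'   [simulate_neuron()] or the readers; any may be `NULL` to skip.
#' @param rs_mohm Series resistance from acquisition metadata.
#' @return One-row data.frame with unit-suffixed feature columns.
#' @export
extract_cc_features <- function(rmp_sweep = NULL, step_sweeps = NULL,
                                ramp_sweep = NULL, train_sweep = NULL,
                                rs_mohm = NA_real_) {
  out <- data.frame(rs_mohm = rs_mohm, rn_mohm = NA_real_,
                    v_rest_mv = NA_real_, ap_threshold_mv = NA_real_,
                    ap_amplitude_mv = NA_real_, ap_half_width_ms = NA_real_,
                    fahp_mv = NA_real_, mahp_mv = NA_real_,
                    sahp_mv = NA_real_)
  if (!is.null(rmp_sweep)) out$v_rest_mv <- measure_rmp(rmp_sweep)
  if (!is.null(step_sweeps)) out$rn_mohm <- input_resistance(step_sweeps)
  if (!is.null(ramp_sweep)) {
    peaks <- detect_aps(ramp_sweep)
    if (length(peaks) > 0) {
      first <- peaks[1]
      out$ap_threshold_mv <- ap_threshold(ramp_sweep, first)
      ahw <- ap_amplitude_halfwidth(ramp_sweep, first)
      out$ap_amplitude_mv <- ahw$amplitude_mv
      out$ap_half_width_ms <- ahw$half_width_ms
      out$fahp_mv <- fahp(ramp_sweep, first)
    }
  }
  if (!is.null(train_sweep)) {
    ahp <- post_burst_ahp(train_sweep)
    out$mahp_mv <- ahp$mahp_mv
    out$sahp_mv <- ahp$sahp_mv
  }
  out
}
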