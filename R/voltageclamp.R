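#' Drug-sensitive current by pre/post subtraction
#'
#' Sample-wise pre-drug minus post-drug currents for matched sweeps; only
#' the drug-sensitive component survives the subtraction, which is the
#' background-removal step for selective channel blockers.
#'
#' @param pre,post `vc_sweep_set` objects for the same cell with identical
#'   step sets and trace lengths.
#' @return A `vc_sweep_set` with `condition = "subtracted"`.
#' @export
subtract_drug <- function(pre, post) {
  stopifnot(inherits(pre, "vc_sweep_set"), inherits(post, "vc_sweep_set"))
  if (!identical(pre$steps_mv, post$steps_mv)) {
    stop("pre and post sweep sets have different step potentials")
  }
  if (!identical(dim(pre$current_pa), dim(post$current_pa))) {
    stop("pre and post current traces differ in length")
  }
  if (!identical(pre$cell_id, post$cell_id)) {
    stop("pre and post sweeps are from different cells")
  }
  out <- pre
  out$current_pa <- pre$current_pa - post$current_pa
  out$condition <- "subtracted"
  out
}

#' Peak and tail currents per voltage step
#'
#' The peak current is read at the sample nearest `peak_at_ms` (default
#' 999 ms) after the start of the depolarising step, the tail current at the
#' sample nearest `tail_at_ms` (default 5 ms) after the switch to the tail
#' potential. Optionally a short averaging window centred on the sample.
#'
#' @param sweeps A `vc_sweep_set`.
#' @param peak_at_ms,tail_at_ms Measurement latencies (ms).
#' @param window_ms Averaging window (0 = single sample, the default).
#' @return Data.frame with `step_mv`, `peak_pa`, `tail_pa`.
#' @export
measure_currents <- function(sweeps, peak_at_ms = 999, tail_at_ms = 5,
                             window_ms = 0) {
  stopifnot(inherits(sweeps, "vc_sweep_set"))
  sr <- sweeps$sampling_rate_hz
  n_step <- sweeps$n_step_samples
  n_tot <- nrow(sweeps$current_pa)
  i_peak <- round(peak_at_ms * sr / 1000)
  i_tail <- n_step + round(tail_at_ms * sr / 1000)
  if (i_peak > n_step || i_tail > n_tot) {
    stop("trace shorter than the requested measurement latency")
  }
  grab <- function(col, i) {
    if (window_ms <= 0) return(col[i])
    hw <- round(window_ms / 2 * sr / 1000)
    mean(col[max(1, i - hw):min(length(col), i + hw)])
  }
  data.frame(
    step_mv = sweeps$steps_mv,
    peak_pa = apply(sweeps$current_pa, 2, grab, i = i_peak),
    tail_pa = apply(sweeps$current_pa, 2, grab, i = i_tail))
}

#' Current density
#'
#' @param peak_pa Peak current (pA).
#' @param capacitance_pf Membrane capacitance (pF, > 0).
#' @return Current density in pA/pF.
#' @export
current_density <- function(peak_pa, capacitance_pf) {
  if (any(capacitance_pf <= 0)) stop("capacitance must be > 0")
  peak_pa / capacitance_pf
}

#' Group current density as percent of wild type
#'
#' Expresses a variant group's mean current density as a percentage of the
#' wild-type group mean, with a first-order (delta-method) standard error
#' propagated from the two group SEMs, and the complementary percentage
#' reduction.
#'
#' @param variant,wt Numeric vectors of per-cell current densities
#'   (>= 2 cells each).
#' @return List with `percent_of_wt`, `sem`, `reduction_percent`,
#'   `reduction_sem`.
#' @export
percent_of_wt <- function(variant, wt) {
  if (length(variant) < 2 || length(wt) < 2) {
    stop("need >= 2 cells per group for a SEM")
  }
  mv <- mean(variant); mw <- mean(wt)
  if (mw == 0) stop("wild-type mean density is zero")
  sv <- stats::sd(variant) / sqrt(length(variant))
  sw <- stats::sd(wt) / sqrt(length(wt))
  pct <- 100 * mv / mw
  sem <- abs(pct) * sqrt((sv / mv)^2 + (sw / mw)^2)
  list(percent_of_wt = pct, sem = sem,
       reduction_percent = 100 - pct, reduction_sem = sem)
}

#' Fit a single-exponential activation time constant
#'
#' Nonlinear least-squares fit of I(t) = A (1 - exp(-t/tau)) + C over a
#' window of the depolarising step (default 50-1000 ms after step onset),
#' the standard description of a slowly activating, non-inactivating
#' current. Initial guesses come from the data (C = mean of the first 5 ms
#' of the window, A = end-minus-start, tau = time to 63% of the rise);
#' tau is bounded to [1, 5000] ms.
#'
#' @param current_pa Current samples of one step (pA).
#' @param sampling_rate_hz Sampling rate.
#' @param voltage_mv Step potential (fits are meaningful between -30 and
#'   +40 mV; outside that range the fit is refused).
#' @param window_ms Fit window relative to step onset (default c(50, 1000)).
#' @return A list of class `activation_fit`: `voltage_mv`, `tau_ms`,
#'   `amplitude_pa`, `offset_pa`, `rss`, `converged`.
#' @export
fit_activation_tau <- function(current_pa, sampling_rate_hz, voltage_mv,
                               window_ms = c(50, 1000)) {
  if (voltage_mv < -30 || voltage_mv > 40) {
    stop("activation-tau fits are restricted to steps in [-30, +40] mV")
  }
  sr <- sampling_rate_hz
  i0 <- max(1L, round(window_ms[1] * sr / 1000))
  i1 <- min(length(current_pa), round(window_ms[2] * sr / 1000))
  if (i1 <= i0) stop("fit window outside the trace")
  t <- (i0:i1) / sr * 1000
  y <- current_pa[i0:i1]
  fail <- function() {
    structure(list(voltage_mv = voltage_mv, tau_ms = NA_real_,
                   amplitude_pa = NA_real_, offset_pa = NA_real_,
                   rss = NA_real_, converged = FALSE),
              class = "activation_fit")
  }
  if (stats::sd(y) < 1e-12) return(fail())  # flat trace: no kinetics
  n5 <- max(2L, round(5 * sr / 1000))
  c0 <- mean(y[seq_len(min(n5, length(y)))])
  a0 <- y[length(y)] - c0
  if (abs(a0) < 1e-12) return(fail())
  i63 <- which(abs(y - c0) >= 0.63 * abs(a0))[1]
  tau0 <- if (is.na(i63)) diff(range(t)) / 3 else max(1, t[i63] - t[1])
  df <- data.frame(t = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * (1 - exp(-t / tau)) + C, data = df,
                      start = list(A = a0, C = c0, tau = tau0),
                      lower = c(A = -Inf, C = -Inf, tau = 1),
                      upper = c(A = Inf, C = Inf, tau = 5000),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail())
  cf <- stats::coef(fit)
  conv <- cf[["tau"]] > 1 + 1e-9 && cf[["tau"]] < 5000 - 1e-9
  structure(list(voltage_mv = voltage_mv, tau_ms = cf[["tau"]],
                 amplitude_pa = cf[["A"]], offset_pa = cf[["C"]],
                 rss = sum(stats::resid(fit)^2), converged = conv),
            class = "activation_fit")
}

#' Activation time constants across a sweep set
#'
#' Runs [fit_activation_tau()] on every step of a (typically
#' drug-subtracted) sweep set within the fit-valid voltage range.
#'
#' @param sweeps A `vc_sweep_set`.
#' @param window_ms Fit window, see [fit_activation_tau()].
#' @return Data.frame with one row per fitted step.
#' @export
fit_activation <- function(sweeps, window_ms = c(50, 1000)) {
  stopifnot(inherits(sweeps, "vc_sweep_set"))
  use <- which(sweeps$steps_mv >= -30 & sweeps$steps_mv <= 40)
  rows <- lapply(use, function(j) {
    f <- fit_activation_tau(sweeps$current_pa[seq_len(sweeps$n_step_samples),
                                              j],
                            sweeps$sampling_rate_hz, sweeps$steps_mv[j],
                            window_ms)
    data.frame(step_mv = f$voltage_mv, tau_ms = f$tau_ms,
               amplitude_pa = f$amplitude_pa, offset_pa = f$offset_pa,
               rss = f$rss, converged = f$converged)
  })
  do.call(rbind, rows)
}

#' Voltage-clamp quality control
#'
#' Inclusion requires seal resistance >= 0.5 gigaohm and series resistance
#' <= 20 megaohm (both boundaries inclusive).
#'
#' @param sweeps A `vc_sweep_set` (or any list with `seal_gohm` and
#'   `rs_mohm`).
#' @param min_seal_gohm,max_rs_mohm The two limits.
#' @return List with logical `pass` and `reasons`; missing metadata gives
#'   `pass = NA`.
#' @export
qc_voltage_clamp <- function(sweeps, min_seal_gohm = 0.5, max_rs_mohm = 20) {
  seal <- sweeps$seal_gohm
  rs <- sweeps$rs_mohm
  if (is.null(seal) || is.null(rs) || is.na(seal) || is.na(rs)) {
    return(list(pass = NA, reasons = "missing seal/series resistance"))
  }
  fails <- character(0)
  if (seal < min_seal_gohm) {
    fails <- c(fails, sprintf("seal %g < %g GOhm", seal, min_seal_gohm))
  }
  if (rs > max_rs_mohm) {
    fails <- c(fails, sprintf("R_S %g > %g MOhm", rs, max_rs_mohm))
  }
  list(pass = length(fails) == 0, reasons = paste(fails, collapse = "; "))
}

#' Normalised conductance-voltage relation from tail currents
#'
#' Because tails are measured at a fixed potential, the tail amplitude is
#' proportional to the open probability reached at the preceding step; the
#' normalised G-V curve is |tail(V)| / max |tail|, optionally fitted with a
#' Boltzmann 1 / (1 + exp(-(V - V_half)/k)).
#'
#' @param currents Data.frame from [measure_currents()] (`step_mv`,
#'   `tail_pa`).
#' @param fit Fit a Boltzmann to the normalised curve (default TRUE).
#' @param subtract_baseline Subtract the smallest tail magnitude before
#'   normalising (default TRUE): the brief tail relaxation toward the
#'   tail-potential open probability adds the same offset to every step, and
#'   the most hyperpolarised step (channel closed) isolates it.
#' @return List with `gv` (data.frame `step_mv`, `g_norm`, `tail_sign`) and,
#'   when fitted, `v_half_mv`, `slope_mv`, `converged`.
#' @export
gv_from_tails <- function(currents, fit = TRUE, subtract_baseline = TRUE) {
  tail <- currents$tail_pa
  m <- max(abs(tail))
  if (m <= 0) stop("all tail currents are zero; cannot normalise")
  base <- if (subtract_baseline) min(abs(tail)) else 0
  gv <- data.frame(step_mv = currents$step_mv,
                   g_norm = (abs(tail) - base) / (m - base),
                   tail_sign = sign(tail))
  out <- list(gv = gv)
  if (fit) {
    bfit <- tryCatch(
      minpack.lm::nlsLM(g_norm ~ 1 / (1 + exp(-(step_mv - vh) / k)),
                        data = gv,
                        start = list(vh = stats::median(gv$step_mv), k = 10)),
      error = function(e) NULL)
    if (is.null(bfit)) {
      out$v_half_mv <- NA_real_
      out$slope_mv <- NA_real_
      out$converged <- FALSE
    } else {
      cf <- stats::coef(bfit)
      out$v_half_mv <- cf[["vh"]]
      out$slope_mv <- cf[["k"]]
      out$converged <- TRUE
    }
  }
  out
}
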