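#' Construct a spike raster for one MEA well
#'
#' @param spikes A data.frame with columns `electrode` and `time_s`, or a
#'   named list of per-electrode spike-time vectors (seconds).
#' @param duration_s Recording duration (default 300 s).
#' @param well_id Well identifier.
#' @param sort Sort unordered spike times with a warning instead of failing.
#' @return An object of class `spike_raster`: a named list of strictly
#'   increasing per-electrode spike-time vectors with attributes
#'   `duration_s` and `well_id`.
#' @export
spike_raster <- function(spikes, duration_s = 300, well_id = "well",
                         sort = TRUE) {
  if (is.data.frame(spikes)) {
    stopifnot(all(c("electrode", "time_s") %in% names(spikes)))
    spikes <- split(spikes$time_s, as.character(spikes$electrode))
  }
  spikes <- lapply(spikes, as.numeric)
  for (e in names(spikes)) {
    t <- spikes[[e]]
    if (any(t < 0 | t > duration_s)) {
      stop("electrode ", e, ": spike times outside [0, ", duration_s, "] s")
    }
    if (is.unsorted(t, strictly = TRUE)) {
      if (!sort) stop("electrode ", e, ": spike times not strictly increasing")
      warning("electrode ", e, ": spike times sorted (duplicates dropped)")
      t <- sort(unique(t))
    }
    spikes[[e]] <- t
  }
  structure(spikes, duration_s = duration_s, well_id = well_id,
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  n <- vapply(unclass(x), length, integer(1))
  cat(sprintf("<spike_raster> well '%s': %d electrodes, %d spikes, %g s\n",
              attr(x, "well_id"), length(x), sum(n), attr(x, "duration_s")))
  invisible(x)
}

#' Parameters for the synthetic MEA spike-train generator
#'
#' The generator is a two-state renewal process per electrode: a homogeneous
#' Poisson background (`tonic_rate_hz`) superimposed with compound bursts
#' whose onsets are Poisson at `burst_rate_per_min`. Burst spike counts are
#' negative-binomially distributed around `spikes_per_burst_mean` (Poisson
#' when `spikes_per_burst_dispersion = 1`) and intra-burst intervals are
#' gamma-distributed around `intra_burst_isi_ms`. The defaults describe the
#' bursty phenotype well used for detector benchmarking: 64 electrodes,
#' 300 s, 0.5 Hz tonic firing, 6 bursts/min of ~10 spikes at 10 ms
#' intervals.
#'
#' @param n_electrodes Number of electrodes (default 64).
#' @param duration_s Recording duration (default 300 s).
#' @param active_fraction Fraction of electrodes that are active (0-1).
#' @param tonic_rate_hz Background Poisson rate (>= 0).
#' @param burst_rate_per_min Burst-onset rate (>= 0).
#' @param spikes_per_burst_mean,spikes_per_burst_dispersion Mean and
#'   variance/mean ratio of the burst spike count (minimum 2 spikes).
#' @param intra_burst_isi_ms,intra_burst_jitter Mean intra-burst interval
#'   (ms) and its coefficient of variation.
#' @param refractory_ms Absolute refractory period enforced on the merged
#'   train (violating spikes are thinned with a warning).
#' @param seed Integer seed.
#' @return A list of class `spike_train_params`.
#' @export
spike_train_params <- function(n_electrodes = 64, duration_s = 300,
                               active_fraction = 1,
                               tonic_rate_hz = 0.5,
                               burst_rate_per_min = 6,
                               spikes_per_burst_mean = 10,
                               spikes_per_burst_dispersion = 2,
                               intra_burst_isi_ms = 10,
                               intra_burst_jitter = 0.3,
                               refractory_ms = 2,
                               seed = 1) {
  p <- as.list(environment())
  if (p$tonic_rate_hz < 0 || p$burst_rate_per_min < 0) {
    stop("rates must be >= 0")
  }
  if (p$active_fraction < 0 || p$active_fraction > 1) {
    stop("active_fraction must be in [0, 1]")
  }
  if (p$tonic_rate_hz > 0 && p$intra_burst_isi_ms >= 1000 / p$tonic_rate_hz) {
    stop("intra-burst ISI must be shorter than the mean tonic ISI")
  }
  structure(p, class = "spike_train_params")
}

#' Simulate an MEA well with planted bursts
#'
#' Generates a [spike_raster()] plus the ground-truth list of planted burst
#' intervals, for benchmarking the burst detector. Inactive electrodes emit
#' fewer than 1 spike/min. After merging tonic and burst spikes the
#' refractory period is enforced by thinning (with a warning when spikes are
#' dropped); ground-truth bursts are rebuilt from the surviving spikes and
#' bursts reduced below 2 spikes are discarded.
#'
#' @param params A [spike_train_params()].
#' @return A list with `raster` (a [spike_raster()]) and `ground_truth`
#'   (data.frame: electrode, start_s, end_s, n_spikes).
#' @export
simulate_mea_well <- function(params = spike_train_params()) {
  stopifnot(inherits(params, "spike_train_params"))
  set.seed(params$seed)
  p <- params
  dur <- p$duration_s
  n_active <- round(p$n_electrodes * p$active_fraction)
  electrodes <- sprintf("e%02d", seq_len(p$n_electrodes))
  trains <- vector("list", p$n_electrodes)
  names(trains) <- electrodes
  gt <- list()
  n_thinned <- 0L
  for (ei in seq_len(p$n_electrodes)) {
    if (ei > n_active) {
      # inactive: sparse firing, guaranteed below 1 spike/min
      cap <- max(0L, ceiling(dur / 60) - 1L)
      n <- min(stats::rpois(1, 0.3 * dur / 60), cap)
      trains[[ei]] <- sort(stats::runif(n, 0, dur))
      next
    }
    tonic <- if (p$tonic_rate_hz > 0) {
      n <- stats::rpois(1, p$tonic_rate_hz * dur)
      sort(stats::runif(n, 0, dur))
    } else numeric(0)
    burst_times <- list()
    if (p$burst_rate_per_min > 0) {
      n_b <- stats::rpois(1, p$burst_rate_per_min / 60 * dur)
      onsets <- sort(stats::runif(n_b, 0, dur))
      for (on in onsets) {
        m <- p$spikes_per_burst_mean
        disp <- p$spikes_per_burst_dispersion
        k <- if (disp > 1) {
          stats::rnbinom(1, size = m / (disp - 1), mu = m)
        } else stats::rpois(1, m)
        k <- max(2L, k)
        shp <- 1 / p$intra_burst_jitter^2
        isis <- stats::rgamma(k - 1, shape = shp,
                              rate = shp / (p$intra_burst_isi_ms / 1000))
        tt <- on + c(0, cumsum(isis))
        tt <- tt[tt <= dur]
        if (length(tt) >= 2) burst_times[[length(burst_times) + 1]] <- tt
      }
    }
    merged <- sort(c(tonic, unlist(burst_times)))
    # refractory thinning on the merged train
    if (length(merged) > 1) {
      keep <- thin_refractory(merged, p$refractory_ms / 1000)
      n_thinned <- n_thinned + sum(!keep)
      kept <- merged[keep]
    } else kept <- merged
    trains[[ei]] <- kept
    for (tt in burst_times) {
      surv <- tt[tt %in% kept]
      if (length(surv) >= 2) {
        gt[[length(gt) + 1]] <- data.frame(
          electrode = electrodes[ei], start_s = surv[1],
          end_s = surv[length(surv)], n_spikes = length(surv),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (n_thinned > 0) {
    warning(n_thinned, " spikes thinned by the ", p$refractory_ms,
            " ms refractory period")
  }
  gt <- if (length(gt) > 0) do.call(rbind, gt) else
    data.frame(electrode = character(0), start_s = numeric(0),
               end_s = numeric(0), n_spikes = integer(0))
  list(raster = spike_raster(trains, duration_s = dur, well_id = "sim"),
       ground_truth = gt)
}

# logical keep-vector enforcing a minimum gap on a sorted time vector
thin_refractory <- function(times, min_gap_s) {
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= min_gap_s) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  keep
}
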