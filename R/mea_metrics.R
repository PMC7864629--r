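#' Active electrodes of a well
#'
#' An electrode is active when it fires at least 1 spike/min, i.e. its
#' spike count is at least `duration_s / 60` (inclusive threshold; 5 spikes
#' in a 300 s recording).
#'
#' @param raster A [spike_raster()].
#' @return Character vector of active electrode ids.
#' @export
active_electrodes <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  dur <- attr(raster, "duration_s")
  counts <- vapply(unclass(raster), length, integer(1))
  names(raster)[counts >= dur / 60]
}

#' Well mean firing frequency
#'
#' Total number of spikes on active electrodes divided by the number of
#' active electrodes and the recording duration.
#'
#' @param raster A [spike_raster()].
#' @param active_only Count only spikes on active electrodes (default,
#'   consistent with the per-active-electrode denominator); `FALSE` counts
#'   all spikes.
#' @return Mean firing frequency in Hz, or `NA` if no electrode is active.
#' @export
mean_firing_frequency <- function(raster, active_only = TRUE) {
  act <- active_electrodes(raster)
  if (length(act) == 0) return(NA_real_)
  dur <- attr(raster, "duration_s")
  use <- if (active_only) act else names(raster)
  total <- sum(vapply(unclass(raster)[use], length, integer(1)))
  total / (length(act) * dur)
}

#' Inter-spike-interval coefficient of variation
#'
#' Per active electrode with at least `min_spikes` spikes, the CoV is
#' SD(ISI)/mean(ISI); the well value is the unweighted mean of the
#' per-electrode CoVs (the `pooled` variant pools all ISIs before computing
#' a single CoV).
#'
#' @param raster A [spike_raster()].
#' @param min_spikes Minimum spikes per electrode (default 3, giving >= 2
#'   intervals).
#' @param pooled Pool ISIs across electrodes instead of averaging
#'   per-electrode CoVs.
#' @return Dimensionless CoV, or `NA` when no electrode qualifies.
#' @export
isi_cov <- function(raster, min_spikes = 3, pooled = FALSE) {
  act <- active_electrodes(raster)
  isis <- lapply(unclass(raster)[act], diff)
  isis <- isis[vapply(isis, length, integer(1)) >= min_spikes - 1]
  if (length(isis) == 0) return(NA_real_)
  if (pooled) {
    all_isi <- unlist(isis)
    return(stats::sd(all_isi) / mean(all_isi))
  }
  mean(vapply(isis, function(x) stats::sd(x) / mean(x), numeric(1)))
}

#' Well-level burst summary metrics
#'
#' Aggregates per-electrode burst detections into the well metrics: burst
#' frequency (total bursts / bursting electrodes / duration), inter-burst
#' interval CoV (per electrode with >= 3 bursts, averaged), mean spikes per
#' burst, and burst percentage (spikes inside bursts as a percentage of all
#' spikes on active electrodes).
#'
#' @param raster A [spike_raster()].
#' @param bursts Per-electrode burst table from [detect_bursts_raster()].
#' @return A list with `n_bursting_electrodes`, `n_bursts`,
#'   `burst_frequency_hz`, `ibi_cov`, `spikes_per_burst`, `burst_percent`.
#'   Burst metrics are `NA` when no electrode bursts (burst_percent is then
#'   0).
#' @export
burst_summary <- function(raster, bursts) {
  stopifnot(inherits(raster, "spike_raster"))
  dur <- attr(raster, "duration_s")
  act <- active_electrodes(raster)
  total_spikes <- sum(vapply(unclass(raster)[act], length, integer(1)))
  if (nrow(bursts) == 0) {
    return(list(n_bursting_electrodes = 0L, n_bursts = 0L,
                burst_frequency_hz = NA_real_, ibi_cov = NA_real_,
                spikes_per_burst = NA_real_, burst_percent = 0))
  }
  bursting <- unique(bursts$electrode)
  n_bursts <- nrow(bursts)
  ibi_covs <- vapply(split(bursts$start_s, bursts$electrode), function(s) {
    if (length(s) < 3) return(NA_real_)
    ibi <- diff(sort(s))
    stats::sd(ibi) / mean(ibi)
  }, numeric(1))
  in_burst <- sum(bursts$n_spikes)
  list(n_bursting_electrodes = length(bursting),
       n_bursts = n_bursts,
       burst_frequency_hz = n_bursts / (length(bursting) * dur),
       ibi_cov = if (all(is.na(ibi_covs))) NA_real_ else
         mean(ibi_covs, na.rm = TRUE),
       spikes_per_burst = mean(bursts$n_spikes),
       burst_percent = 100 * in_burst / total_spikes)
}

#' All well-level MEA metrics
#'
#' Runs the activity and burst metrics over one well: active electrodes,
#' mean firing frequency, ISI CoV, and the burst summary from
#' Poisson-surprise detection.
#'
#' @param raster A [spike_raster()].
#' @param min_surprise,seed_factor,min_spikes Burst-detector knobs, see
#'   [detect_bursts()].
#' @return One-row data.frame with the nine well metrics.
#' @export
well_metrics <- function(raster, min_surprise = 10, seed_factor = 0.5,
                         min_spikes = 3) {
  act <- active_electrodes(raster)
  bursts <- detect_bursts_raster(raster, min_surprise = min_surprise,
                                 seed_factor = seed_factor,
                                 min_spikes = min_spikes)
  bursts <- bursts[bursts$electrode %in% act, , drop = FALSE]
  bs <- burst_summary(raster, bursts)
  data.frame(well_id = attr(raster, "well_id"),
             n_active_electrodes = length(act),
             mean_firing_frequency_hz = mean_firing_frequency(raster),
             isi_cov = isi_cov(raster),
             n_bursting_electrodes = bs$n_bursting_electrodes,
             n_bursts = bs$n_bursts,
             burst_frequency_hz = bs$burst_frequency_hz,
             ibi_cov = bs$ibi_cov,
             spikes_per_burst = bs$spikes_per_burst,
             burst_percent = bs$burst_percent,
             stringsAsFactors = FALSE)
}

#' Per-well metric changes after drug application
#'
#' Pairs pre- and post-drug well metric tables by `well_id` and returns the
#' per-well differences (post minus pre) for every numeric metric,
#' preserving the paired structure for downstream statistics.
#'
#' @param pre,post Data.frames from [well_metrics()] (one row per well).
#' @return Data.frame of per-well metric differences.
#' @export
drug_delta <- function(pre, post) {
  if (!setequal(pre$well_id, post$well_id) ||
      nrow(pre) != nrow(post)) {
    stop("pre and post tables must describe the same wells")
  }
  post <- post[match(pre$well_id, post$well_id), , drop = FALSE]
  num <- vapply(pre, is.numeric, logical(1))
  delta <- post[, num, drop = FALSE] - pre[, num, drop = FALSE]
  names(delta) <- paste0("delta_", names(delta))
  cbind(well_id = pre$well_id, delta, stringsAsFactors = FALSE)
}
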