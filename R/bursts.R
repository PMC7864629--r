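#' Poisson surprise of a spike run
#'
#' The surprise statistic of a run of `n` spikes spanning `span_s` seconds
#' on an electrode firing at `rate_hz`: S = -ln P(N >= n) for N ~
#' Poisson(rate * span). Computed on the log scale, so very improbable runs
#' do not underflow.
#'
#' @param n Number of spikes in the run (>= 1).
#' @param rate_hz Electrode mean firing rate (spikes/s).
#' @param span_s Time span of the run (s).
#' @return The surprise S (natural log), dimensionless.
#' @export
poisson_surprise <- function(n, rate_hz, span_s) {
  lambda <- rate_hz * span_s
  -stats::ppois(n - 1, lambda, lower.tail = FALSE, log.p = TRUE)
}

#' Poisson-surprise burst detection on a single spike train
#'
#' Surprise-maximisation burst detection adaptive to the electrode's mean
#' firing rate. Candidate bursts are seeded by runs of consecutive
#' inter-spike intervals shorter than `seed_factor` times the mean ISI; each
#' candidate is extended forward spike-by-spike while the Poisson surprise
#' increases, then trimmed from its start while the surprise increases
#' further. Candidates with surprise >= `min_surprise` and at least
#' `min_spikes` spikes are accepted; accepted bursts are non-overlapping,
#' resolved greedily in time order.
#'
#' @param spike_times Strictly increasing spike times (s).
#' @param duration_s Recording duration (s, > 0); sets the mean rate
#'   `length(spike_times) / duration_s`.
#' @param min_surprise Acceptance threshold on S (natural log; default 10).
#' @param seed_factor ISI seeding criterion relative to the mean ISI
#'   (default 0.5).
#' @param min_spikes Minimum spikes per burst (default 3).
#' @return A data.frame of class `burst_table` with columns `start_s`,
#'   `end_s`, `first_spike`, `last_spike`, `n_spikes`, `surprise` (possibly
#'   zero rows).
#' @export
detect_bursts <- function(spike_times, duration_s, min_surprise = 10,
                          seed_factor = 0.5, min_spikes = 3) {
  if (missing(duration_s) || duration_s <= 0) {
    stop("duration_s must be > 0")
  }
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      first_spike = integer(0), last_spike = integer(0),
                      n_spikes = integer(0), surprise = numeric(0))
  class(empty) <- c("burst_table", "data.frame")
  n <- length(spike_times)
  if (n < min_spikes) return(empty)
  if (is.unsorted(spike_times, strictly = TRUE)) {
    stop("spike times must be strictly increasing")
  }
  rate <- n / duration_s
  isi <- diff(spike_times)
  crit <- seed_factor * mean(isi)
  fast <- isi < crit
  s_of <- function(i, j) {
    poisson_surprise(j - i + 1, rate, spike_times[j] - spike_times[i])
  }
  bursts <- list()
  i <- 1L
  while (i <= n - 1L) {
    if (!fast[i]) { i <- i + 1L; next }
    # seed: maximal run of fast ISIs starting at i
    j <- i + 1L
    while (j <= n - 1L && fast[j]) j <- j + 1L
    # extend forward while surprise increases
    s <- s_of(i, j)
    while (j < n && s_of(i, j + 1L) > s) {
      j <- j + 1L
      s <- s_of(i, j)
    }
    # trim from the start while surprise increases
    while (j - i + 1L > min_spikes && s_of(i + 1L, j) > s) {
      i <- i + 1L
      s <- s_of(i, j)
    }
    if (s >= min_surprise && (j - i + 1L) >= min_spikes) {
      bursts[[length(bursts) + 1]] <- data.frame(
        start_s = spike_times[i], end_s = spike_times[j],
        first_spike = i, last_spike = j,
        n_spikes = j - i + 1L, surprise = s)
    }
    i <- j + 1L
  }
  out <- if (length(bursts) > 0) do.call(rbind, bursts) else empty
  class(out) <- c("burst_table", "data.frame")
  out
}

#' Burst detection across a raster
#'
#' Runs [detect_bursts()] on every electrode of a [spike_raster()].
#'
#' @param raster A [spike_raster()].
#' @param ... Passed to [detect_bursts()].
#' @return A data.frame of per-electrode bursts with an `electrode` column.
#' @export
detect_bursts_raster <- function(raster, ...) {
  stopifnot(inherits(raster, "spike_raster"))
  dur <- attr(raster, "duration_s")
  out <- lapply(names(raster), function(e) {
    b <- detect_bursts(raster[[e]], dur, ...)
    if (nrow(b) > 0) cbind(electrode = e, b, stringsAsFactors = FALSE)
    else NULL
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(electrode = character(0), start_s = numeric(0),
                      end_s = numeric(0), first_spike = integer(0),
                      last_spike = integer(0), n_spikes = integer(0),
                      surprise = numeric(0)))
  }
  do.call(rbind, out)
}

#' Match detected bursts against planted ground truth
#'
#' A detected burst matches a planted burst on the same electrode when
#' their interval overlap is at least `min_overlap` of the shorter
#' interval. Used for recall/precision benchmarking of the detector.
#'
#' @param detected Data.frame from [detect_bursts_raster()].
#' @param truth Ground-truth data.frame (`electrode`, `start_s`, `end_s`).
#' @param min_overlap Minimum fractional overlap (default 0.5).
#' @return List with `recall`, `precision`, `n_matched`.
#' @export
match_bursts <- function(detected, truth, min_overlap = 0.5) {
  if (nrow(truth) == 0) {
    return(list(recall = NA_real_,
                precision = if (nrow(detected) == 0) NA_real_ else 0,
                n_matched = 0L))
  }
  overlap_ok <- function(s1, e1, s2, e2) {
    ov <- min(e1, e2) - max(s1, s2)
    shorter <- min(e1 - s1, e2 - s2)
    if (shorter <= 0) return(ov >= 0)  # point bursts: require contact
    ov >= min_overlap * shorter
  }
  truth_hit <- logical(nrow(truth))
  det_hit <- logical(nrow(detected))
  for (k in seq_len(nrow(detected))) {
    same <- which(truth$electrode == detected$electrode[k])
    for (m in same) {
      if (overlap_ok(detected$start_s[k], detected$end_s[k],
                     truth$start_s[m], truth$end_s[m])) {
        truth_hit[m] <- TRUE
        det_hit[k] <- TRUE
      }
    }
  }
  list(recall = mean(truth_hit),
       precision = if (nrow(detected) > 0) mean(det_hit) else NA_real_,
       n_matched = sum(truth_hit))
}
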