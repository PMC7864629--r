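test_that("degenerate generator settings give an empty well", {
  p <- spike_train_params(tonic_rate_hz = 0, burst_rate_per_min = 0,
                          n_electrodes = 8, seed = 1)
  sim <- simulate_mea_well(p)
  expect_equal(sum(vapply(unclass(sim$raster), length, integer(1))), 0)
  expect_equal(nrow(sim$ground_truth), 0)
})

test_that("tonic Poisson spike counts match the Poisson oracle", {
  p <- spike_train_params(tonic_rate_hz = 5, burst_rate_per_min = 0,
                          duration_s = 300, n_electrodes = 64,
                          active_fraction = 1, seed = 5)
  sim <- suppressWarnings(simulate_mea_well(p))
  counts <- vapply(unclass(sim$raster), length, integer(1))
  # mean 1500, SE across 64 electrodes = sqrt(1500/64)
  expect_lt(abs(mean(counts) - 1500), 3 * sqrt(1500 / 64) + 1.5)
})

test_that("planted burst count matches the Poisson-onset oracle", {
  p <- spike_train_params(seed = 9)  # 6 bursts/min, 300 s, 64 electrodes
  sim <- suppressWarnings(simulate_mea_well(p))
  per_electrode <- table(factor(sim$ground_truth$electrode,
                                levels = names(sim$raster)))
  expect_lt(abs(mean(per_electrode) - 30), 3 * sqrt(30 / 64) + 0.5)
})

test_that("generator output is deterministic and internally consistent", {
  p <- spike_train_params(n_electrodes = 8, seed = 33)
  a <- suppressWarnings(simulate_mea_well(p))
  b <- suppressWarnings(simulate_mea_well(p))
  expect_identical(a$raster, b$raster)
  expect_identical(a$ground_truth, b$ground_truth)
  # every ground-truth burst holds >= 2 raster spikes, and all spike
  # times are strictly increasing
  for (e in names(a$raster)) {
    expect_false(is.unsorted(a$raster[[e]], strictly = TRUE))
  }
  gt <- a$ground_truth
  for (i in seq_len(nrow(gt))) {
    s <- a$raster[[gt$electrode[i]]]
    inside <- sum(s >= gt$start_s[i] & s <= gt$end_s[i])
    expect_gte(inside, 2)
  }
})

test_that("inactive electrodes stay below one spike per minute", {
  p <- spike_train_params(active_fraction = 0.5, tonic_rate_hz = 5,
                          burst_rate_per_min = 0, seed = 3)
  sim <- suppressWarnings(simulate_mea_well(p))
  counts <- vapply(unclass(sim$raster), length, integer(1))
  act <- active_electrodes(sim$raster)
  expect_equal(length(act), 32)
  inactive <- setdiff(names(sim$raster), act)
  expect_true(all(counts[inactive] < 300 / 60))
})

test_that("active-electrode rule is an inclusive count threshold", {
  mk <- function(n) sort(runif(n, 0, 300))
  set.seed(8)
  r <- spike_raster(list(five = mk(5), four = mk(4)), duration_s = 300)
  expect_identical(active_electrodes(r), "five")
})

test_that("mean firing frequency follows its definition", {
  r1 <- spike_raster(list(a = seq(0.5, 299.5, length.out = 300)),
                     duration_s = 300)
  expect_equal(mean_firing_frequency(r1), 1.0)
  r2 <- spike_raster(list(a = seq(0.5, 299.5, length.out = 300),
                          b = seq(0.25, 299.75, length.out = 600)),
                     duration_s = 300)
  expect_equal(mean_firing_frequency(r2), 1.5)
  # Poisson well: 5 Hz within 3 SE
  p <- spike_train_params(tonic_rate_hz = 5, burst_rate_per_min = 0,
                          seed = 12)
  sim <- suppressWarnings(simulate_mea_well(p))
  se <- sqrt(5 / (64 * 300))
  expect_lt(abs(mean_firing_frequency(sim$raster) - 5), 3 * se + 0.01)
})

test_that("ISI CoV is 0 for regular, 1 for Poisson, > 1 for bursty firing", {
  reg <- spike_raster(list(a = seq(0.1, 299.9, by = 0.1)), duration_s = 300)
  expect_equal(isi_cov(reg), 0)
  set.seed(4)
  pois <- spike_raster(list(a = sort(runif(1500, 0, 300))), duration_s = 300)
  expect_lt(abs(isi_cov(pois) - 1), 0.08)
  # two-state bursty train: 10 ms intra-burst, 10 s between bursts
  bursty <- unlist(lapply(seq(5, 295, by = 10), function(on) {
    on + (0:9) * 0.01
  }))
  rb <- spike_raster(list(a = bursty), duration_s = 300)
  expect_gt(isi_cov(rb), 1)
})

test_that("burst summary conserves spikes and handles edge cases", {
  p <- spike_train_params(n_electrodes = 16, seed = 77)
  sim <- suppressWarnings(simulate_mea_well(p))
  det <- detect_bursts_raster(sim$raster)
  bs <- burst_summary(sim$raster, det)
  total <- sum(vapply(unclass(sim$raster)[active_electrodes(sim$raster)],
                      length, integer(1)))
  in_bursts <- sum(det$n_spikes)
  expect_equal(bs$burst_percent, 100 * in_bursts / total)
  expect_lte(in_bursts, total)
  expect_lte(bs$n_bursting_electrodes, length(active_electrodes(sim$raster)))
  # all spikes inside bursts -> 100% (bursts separated by long silences)
  trains <- unlist(lapply(seq(10, 290, by = 10), function(on) {
    on + (0:9) * 0.01
  }))
  one <- spike_raster(list(a = trains), duration_s = 300)
  db <- detect_bursts_raster(one)
  expect_equal(burst_summary(one, db)$burst_percent, 100)
  # no bursts -> 0% and missing burst metrics
  reg <- spike_raster(list(a = seq(1, 299, by = 1)), duration_s = 300)
  bs0 <- burst_summary(reg, detect_bursts_raster(reg))
  expect_equal(bs0$burst_percent, 0)
  expect_true(is.na(bs0$burst_frequency_hz))
})

test_that("drug deltas are paired by well and zero for identical tables", {
  p <- spike_train_params(n_electrodes = 8, seed = 2)
  sim <- suppressWarnings(simulate_mea_well(p))
  wm <- well_metrics(sim$raster)
  d <- drug_delta(wm, wm)
  num <- vapply(d, is.numeric, logical(1))
  expect_true(all(unlist(d[, num]) == 0 | is.na(unlist(d[, num]))))
  wm2 <- wm
  wm2$well_id <- "other"
  expect_error(drug_delta(wm, wm2), "same wells")
})
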