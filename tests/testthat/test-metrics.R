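# Metrics layer: spike detection, waveform metrics, synchronization,
# potentiation index, group statistics.

test_that("spike trains validate their contract", {
  expect_error(spike_train(c(3, 2, 5), c(0, 10)), "strictly increasing")
  expect_error(spike_train(c(2, 12), c(0, 10)), "outside")
  st <- spike_train(c(2, 5), c(0, 10))
  expect_s3_class(st, "spike_train")
})

test_that("detect_spikes: flat trace, constructed crossings, interpolation", {
  t <- seq(0, 200, by = 0.1)
  expect_length(detect_spikes(t, rep(-65, length(t)))$times, 0L)

  # triangular pulses crossing 10 mV upward at exactly 100 and 150 ms
  v <- rep(-65, length(t))
  bump <- function(v, t0) {
    idx <- t >= t0 - 2 & t <= t0 + 2
    v[idx] <- -65 + (85 + 10) * (1 - abs(t[idx] - t0) / 2)  # peaks at +30
    v
  }
  # construct so the upward 10 mV crossing is at t0 - 2 + 2*(75/95)
  v <- bump(bump(v, 102), 152)
  st <- detect_spikes(t, v, 10)
  expect_length(st$times, 2L)
  cross <- 100 + 2 * 75 / 95
  expect_lt(abs(st$times[1] - cross), 0.05 / 2 + 1e-9)
  expect_lt(abs(st$times[2] - (cross + 50)), 0.05 / 2 + 1e-9)

  expect_error(detect_spikes(c(0, 1, 3), c(0, 0, 0)), "uniformly sampled")
})

test_that("spike count matches an independent crossing counter on a real run", {
  cell <- fixture_cell(1)
  r <- run_orthodromic(cell, gamma_drive_spec(seed = 2, duration_ms = 600))
  v <- r$traces$traces$v[, 1]
  # independent counter: count sign changes of (v - thr) from - to +
  s <- sign(v - 10)
  independent <- sum(s[-1] > 0 & s[-length(s)] <= 0)
  expect_equal(length(r$spikes$times), independent)
})

test_that("half-width is the above-threshold duration with interpolation", {
  # triangle crossing 10 mV up at 5.0 ms and down at 6.2 ms
  t <- seq(0, 12, by = 0.001)
  v <- rep(0, length(t))
  ramp <- t >= 5.0 & t <= 5.6
  v[ramp] <- 10 + (t[ramp] - 5.0) / 0.6 * 20
  fall <- t > 5.6 & t <= 6.2
  v[fall] <- 30 - (t[fall] - 5.6) / 0.6 * 20
  expect_lt(abs(half_width(t, v, 10) - 1.2), 0.005)
  expect_error(half_width(t, rep(0, length(t)), 10), "undefined-metric")

  # scaling amplitude up widens the crossings: width non-decreasing
  w1 <- half_width(t, v, 10)
  w2 <- half_width(t, v * 1.5, 10)
  expect_gte(w2, w1)

  # spreadsheet-style manual check on a simulated somatic spike
  cell <- fixture_cell(1)
  soma <- soma_compartment(cell)
  r <- simulate_cell(cell, tstop = 40,
                     iclamps = data.frame(comp = soma, amp = 2, start = 10, dur = 2),
                     record_comps = soma)
  tt <- r$t; vv <- r$traces$v[, 1]
  above <- which(vv >= 10)
  i0 <- above[1]; i1 <- above[length(above)]
  t1 <- tt[i0 - 1] + (10 - vv[i0 - 1]) / (vv[i0] - vv[i0 - 1]) * (tt[i0] - tt[i0 - 1])
  t2 <- tt[i1] + (vv[i1] - 10) / (vv[i1] - vv[i1 + 1]) * (tt[i1 + 1] - tt[i1])
  expect_equal(half_width(tt, vv, 10), t2 - t1, tolerance = 1e-12)
})

test_that("peak amplitude and depolarization time behave on constructed traces", {
  t <- seq(0, 50, by = 0.1)
  # monotone decay from an initial depolarization: peak at onset
  v <- -65 + 60 * exp(-t / 20)
  expect_equal(depolarization_time(t, v, stimulus_onset = 0), 0)
  # single bump peaking 12.5 ms after onset at 63 mV
  v2 <- -65 + 128 * exp(-(t - 22.5)^2 / 8)
  expect_equal(peak_amplitude(v2), max(v2))
  expect_lt(abs(peak_amplitude(v2) - 63), 0.01)
  expect_lt(abs(depolarization_time(t, v2, stimulus_onset = 10) - 12.5), 0.051)
  expect_error(peak_amplitude(numeric(0)), "empty")
})

test_that("depolarization time grows with distance along the apical trunk", {
  b <- run_bap(fixture_cell(1))
  trunk <- b$map[b$map$region == "apical_primary", ]
  fit <- cor(trunk$dist_um, trunk$depol_time_ms)
  expect_gt(fit, 0.9)
})

test_that("mean firing rate: count over window, empty train, window additivity", {
  st <- spike_train(seq(50, 950, length.out = 15), c(0, 1000))
  expect_equal(mean_firing_rate(st), 15)
  expect_equal(mean_firing_rate(spike_train(numeric(0), c(0, 1000))), 0)
  a <- spike_train(c(100, 300), c(0, 500))
  b <- spike_train(c(600, 700, 900), c(500, 1000))
  whole <- spike_train(c(100, 300, 600, 700, 900), c(0, 1000))
  expect_equal(mean_firing_rate(whole),
               (mean_firing_rate(a) + mean_firing_rate(b)) / 2)
})

test_that("synchronization: definitional cases", {
  x <- spike_train(c(100, 200, 300), c(0, 400))
  expect_equal(spike_sync(x, x), 1.0)
  y <- spike_train(c(150, 250, 350), c(0, 400))  # all gaps >> windows
  expect_equal(spike_sync(x, y), 0.0)
  m <- spike_sync_matrix(list(x, y, x))
  expect_equal(diag(m), rep(1, 3))
  expect_equal(m, t(m))
  expect_equal(m[1, 3], 1.0)
  expect_error(spike_sync_matrix(list(x)), "at least two")
})

test_that("synchronization matches the independent reference on random sets", {
  for (seed in 1:20) {
    trains <- random_train_set(n_trains = 4, seed = seed)
    got <- spike_sync_matrix(trains)
    ref <- oracle_sync_matrix(trains)
    expect_lt(max(abs(got - ref)), 1e-9)
  }
  # sparse-train convention: a single-spike train uses the partner's window
  one <- spike_train(500, c(0, 1000))
  many <- spike_train(c(100, 499, 900), c(0, 1000))
  expect_equal(spike_sync(one, many), oracle_spike_sync(500, c(100, 499, 900)))
})

test_that("synchronization values stay in [0,1] with unit diagonal on random sets", {
  for (seed in 21:26) {
    trains <- random_train_set(n_trains = 5, seed = seed, rate_hz = 15)
    m <- spike_sync_matrix(trains)
    expect_true(all(m >= 0 & m <= 1))
    expect_equal(diag(m), rep(1, 5))
  }
})

test_that("every detected spike has positive width", {
  cell <- fixture_cell(1)
  r <- run_orthodromic(cell, gamma_drive_spec(seed = 1, duration_ms = 500))
  wm <- spike_waveform_metrics(r$traces$t, r$traces$traces$v[, 1])
  expect_equal(nrow(wm), length(r$spikes$times))
  expect_true(all(wm$half_width_ms > 0))
})

test_that("potentiation index: no-potentiation identity and input checks", {
  fake <- structure(list(
    epsp_alone = list(peak_v_mV = -68, peak_ca_mM = 6e-5),
    bap_alone = list(peak_v_mV = 20, peak_ca_mM = 4e-4),
    paired = list(peak_v_mV = 20, peak_ca_mM = 6e-5)), class = "ca1_pairing")
  expect_equal(as.numeric(potentiation_index(fake, "ca")), 1.0)
  expect_equal(attr(potentiation_index(fake, "voltage"), "method"), "voltage")
  broken <- fake; broken$paired <- NULL
  expect_error(potentiation_index(broken), "missing condition")
})

test_that("group comparisons match the frozen cross-check and handle edge cases", {
  x <- c(1.1, 2.3, 3.2, 4.8, 5.0, 6.1)
  y <- c(2.0, 3.5, 4.1, 5.9, 7.2, 8.3)
  z <- c(10, 11, 12, 13, 14, 15)
  tab <- compare_groups(c(x, y, z), rep(c("x", "y", "z"), each = 6))
  # values frozen from an independent statistics package (scipy.stats
  # mannwhitneyu, asymptotic, two-sided)
  row_xy <- tab[tab$group1 == "x" & tab$group2 == "y", ]
  expect_equal(row_xy$statistic, 12)
  expect_lt(abs(row_xy$p_mannwhitney - 0.3784775932446789), 1e-6)
  row_xz <- tab[tab$group1 == "x" & tab$group2 == "z", ]
  expect_equal(row_xz$statistic, 0)   # complete separation
  expect_lt(abs(row_xz$p_mannwhitney - 0.005074868097940253), 1e-6)
  expect_true(row_xz$significant)
  expect_true(all(c("tukey_diff", "tukey_lwr", "tukey_upr", "p_tukey") %in% names(tab)))

  # a group compared with itself is not significant
  tab2 <- compare_groups(c(x, x), rep(c("a", "b"), each = 6))
  expect_false(tab2$significant)
  expect_gte(tab2$p_mannwhitney, 0.95)

  # degenerate all-identical samples are reported, not crashed
  tab3 <- compare_groups(rep(1, 12), rep(c("a", "b"), each = 6))
  expect_equal(tab3$p_mannwhitney, 1)
  expect_false(tab3$significant)

  expect_error(compare_groups(1:4, c("a", "a", "b", "b")), "n >= 3")
})

test_that("metric layer is pure: identical traces give identical tables", {
  cell <- fixture_cell(1)
  r <- run_orthodromic(cell, gamma_drive_spec(seed = 6, duration_ms = 300))
  w1 <- spike_waveform_metrics(r$traces$t, r$traces$traces$v[, 1])
  w2 <- spike_waveform_metrics(r$traces$t, r$traces$traces$v[, 1])
  expect_identical(w1, w2)
})
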