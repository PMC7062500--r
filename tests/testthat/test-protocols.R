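# Stimulation protocols: placement, event statistics, orthodromic drive,
# bAP readouts, STDP pairing.

test_that("synapse placement respects region, distance, and the seed", {
  cell <- fixture_cell(1)
  sp <- gamma_drive_spec(seed = 3)
  pl <- place_random_synapses(cell, sp)
  expect_equal(nrow(pl), sp$n_synapses)
  expect_true(all(pl$dist_um >= sp$min_distance_um - 1e-9))
  reg <- cell$grid$compartments$region[pl$comp]
  expect_true(all(reg == "apical_primary"))

  pl2 <- place_random_synapses(cell, sp)
  expect_identical(pl, pl2)
  pl3 <- place_random_synapses(cell, gamma_drive_spec(seed = 4))
  expect_false(identical(pl$comp, pl3$comp))

  # infeasible placement
  expect_error(place_random_synapses(cell, gamma_drive_spec(min_distance_um = 1e5)),
               "placement error")
})

test_that("placement density is uniform per unit length over eligible cable", {
  cell <- fixture_cell(1)
  sp <- gamma_drive_spec(n_synapses = 10000L, seed = 9)
  pl <- place_random_synapses(cell, sp)
  co <- cell$grid$compartments
  elig <- which(co$region == "apical_primary" & co$dist_um >= 100)
  counts <- table(factor(pl$comp, levels = elig))
  expected <- sp$n_synapses * co$length_um[elig] / sum(co$length_um[elig])
  # 3 sigma of the binomial expectation per compartment
  sigma <- sqrt(expected * (1 - co$length_um[elig] / sum(co$length_um[elig])))
  expect_true(all(abs(as.numeric(counts) - expected) <= 3.5 * sigma))
})

test_that("gamma events: periodic limit, Poisson mean, window containment", {
  per <- gamma_drive_spec(noise = 0, rate_hz = 40, duration_ms = 500, seed = 1)
  evs <- gamma_drive_events(per)
  for (e in evs) {
    expect_lt(max(abs(diff(e) - 25)), 1e-9)
    expect_true(all(e >= 0 & e < 500))
  }

  poi <- gamma_drive_spec(noise = 1, rate_hz = 40, duration_ms = 10000,
                          n_synapses = 4L, seed = 2)
  evp <- gamma_drive_events(poi)
  isis <- unlist(lapply(evp, diff))
  se <- sd(isis) / sqrt(length(isis))
  expect_lt(abs(mean(isis) - 25), 3 * se)

  # determinism
  expect_identical(gamma_drive_events(poi), gamma_drive_events(poi))
})

test_that("zero synaptic weight produces no spikes and a quiet soma", {
  cell <- fixture_cell(1)
  r <- run_orthodromic(cell, gamma_drive_spec(weight_uS = 0, seed = 1,
                                              duration_ms = 400))
  expect_length(r$spikes$times, 0L)
  # after the initial settling transient, V stays within 2 mV of rest
  v_late <- r$traces$traces$v[r$traces$t >= 200, 1]
  expect_lt(max(v_late) - min(v_late), 2)
})

test_that("calibrated drive fires in the physiological band; seeds differ", {
  cell <- fixture_cell(1)
  trains <- lapply(1:3, function(s) {
    run_orthodromic(cell, gamma_drive_spec(seed = s))$spikes
  })
  mfr <- vapply(trains, mean_firing_rate, numeric(1))
  expect_true(all(mfr >= 5 & mfr <= 30))
  # distinct spike patterns: pairwise synchronization below 1
  sm <- spike_sync_matrix(trains)
  off <- sm[upper.tri(sm)]
  expect_true(all(off < 1))
})

test_that("bAP: antidromic ordering and passive attenuation", {
  cell <- fixture_cell(1)
  b <- run_bap(cell)
  expect_equal(length(b$soma_spikes$times), 1L)
  # somatic peak precedes every dendritic peak
  soma_t <- b$traces$t[which.max(b$traces$traces$v[, 1])]
  api_pk_t <- b$map$depol_time_ms + cell$config$protocols$bap$delay_ms
  expect_true(all(api_pk_t >= soma_t - b$traces$dt))

  # passive-only cell: peak strictly decreasing with distance along the trunk
  pas <- strip_active(fixture_cell(1))
  soma <- soma_compartment(pas)
  co <- pas$grid$compartments
  api <- which(co$region == "apical_primary")
  r <- simulate_cell(pas, tstop = 40,
                     iclamps = data.frame(comp = soma, amp = 2, start = 10, dur = 2),
                     record_comps = api)
  pk <- apply(r$traces$v, 2, max)
  ord <- order(co$dist_um[api])
  expect_true(all(diff(pk[ord]) < 0))
})

test_that("bAP protocol rejects pulses that trigger zero or multiple spikes", {
  cell <- fixture_cell(1)
  expect_error(run_bap(cell, amp_nA = 0.01), "protocol error")
  # sustained drive on a K[Ca]-free cell fires repetitively: also rejected
  ko <- apply_condition(cell, "cagk_ko")
  expect_error(run_bap(ko, amp_nA = 0.5, dur_ms = 150, tstop_ms = 200),
               "protocol error")
})

test_that("bAP map is a frozen deterministic fixture", {
  cell <- fixture_cell(1)
  m1 <- run_bap(cell)$map
  m2 <- run_bap(cell)$map
  expect_identical(m1, m2)
})

test_that("STDP pairing: separation limit and supra-additive calcium", {
  cell <- fixture_cell(1)
  far <- run_stdp_pairing(cell, stdp_spec(delta_t_ms = 500))
  # no interaction: paired peak equals the larger alone peak
  expect_lt(abs(far$paired$peak_v_mV -
                max(far$epsp_alone$peak_v_mV, far$bap_alone$peak_v_mV)) /
            abs(max(far$epsp_alone$peak_v_mV, far$bap_alone$peak_v_mV)), 0.01)
  expect_lt(abs(potentiation_index(far, "ca") - 1), 0.05)

  near <- run_stdp_pairing(cell, stdp_spec(delta_t_ms = 10))
  expect_true(near$paired_within_window)
  expect_gt(near$paired$peak_ca_mM, near$epsp_alone$peak_ca_mM)
  expect_gt(potentiation_index(near, "ca"), 1)

  # swapping the pairing order changes the readout (asymmetry recorded)
  rev <- run_stdp_pairing(cell, stdp_spec(delta_t_ms = -10))
  expect_false(isTRUE(all.equal(rev$paired$peak_ca_mM, near$paired$peak_ca_mM)))
})

test_that("protocols are deterministic: identical tables across repeat runs", {
  cell <- fixture_cell(1)
  r1 <- run_orthodromic(cell, gamma_drive_spec(seed = 5, duration_ms = 300))
  r2 <- run_orthodromic(cell, gamma_drive_spec(seed = 5, duration_ms = 300))
  expect_identical(r1$spikes$times, r2$spikes$times)
  expect_identical(r1$traces$traces$v, r2$traces$traces$v)
})

test_that("trace CSV export lays out one column per site and variable", {
  cell <- fixture_cell(1)
  soma <- soma_compartment(cell)
  r <- simulate_cell(cell, tstop = 5, record_comps = c(soma, soma + 1L),
                     record_vars = c("v", "ca"))
  f <- tempfile(fileext = ".csv")
  write_traces_csv(r, f)
  d <- utils::read.csv(f)
  expect_equal(ncol(d), 1 + 2 * 2)
  expect_equal(nrow(d), length(r$t))
})
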