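# Stimulation protocols: gamma-frequency synaptic drive (orthodromic),
# somatic current clamp (backpropagating spikes), and bAP/EPSP pairing
# (STDP). All protocols are deterministic given (config, seed).

#' Gamma-drive specification
#'
#' Ten glutamatergic synapses placed randomly along the apical primary
#' dendrite at least 100 um from the soma, firing at 40 Hz with fractional
#' randomness 1 (Poisson limit): inter-event intervals are
#' `(1 - noise) * mean + noise * Exp(mean)`.
#'
#' @param n_synapses synapse count
#' @param rate_hz event rate per synapse
#' @param noise fractional randomness in `[0, 1]`
#' @param min_distance_um placement threshold from the soma
#' @param region placement region
#' @param duration_ms drive duration
#' @param weight_uS synaptic peak conductance
#' @param tau_ms decay time constant of the single-exponential synapse
#' @param e_rev synaptic reversal, mV
#' @param seed integer seed
#' @return list spec
#' @export
gamma_drive_spec <- function(n_synapses = NULL, rate_hz = NULL, noise = NULL,
                             min_distance_um = NULL, region = NULL,
                             duration_ms = NULL, weight_uS = NULL,
                             tau_ms = NULL, e_rev = NULL, seed = 1L) {
  d <- default_config()$protocols$gamma_drive
  sp <- list(n_synapses = n_synapses %||% d$n_synapses,
             rate_hz = rate_hz %||% d$rate_hz, noise = noise %||% d$noise,
             min_distance_um = min_distance_um %||% d$min_distance_um,
             region = region %||% d$region,
             duration_ms = duration_ms %||% d$duration_ms,
             weight_uS = weight_uS %||% d$weight_uS,
             tau_ms = tau_ms %||% d$tau_ms, e_rev = e_rev %||% d$e_rev,
             seed = as.integer(seed))
  stopifnot(sp$rate_hz > 0, sp$noise >= 0, sp$noise <= 1, sp$n_synapses >= 1)
  sp
}

#' Place synapses uniformly by arc length over eligible cable
#'
#' Eligible compartments lie in the target region at or beyond the minimum
#' path distance; locations are sampled with probability proportional to
#' compartment length and uniformly within a compartment.
#'
#' @param cell a `ca1_cell`
#' @param spec a [gamma_drive_spec()] (fields `region`, `min_distance_um`,
#'   `n_synapses`, `seed` are used)
#' @return data frame: comp, section, pos, dist_um
#' @export
place_random_synapses <- function(cell, spec = gamma_drive_spec()) {
  comp <- cell$grid$compartments
  elig <- which(comp$region == spec$region &
                comp$dist_um >= spec$min_distance_um)
  if (length(elig) < 1L)
    stop("placement error: no eligible cable in region '", spec$region,
         "' beyond ", spec$min_distance_um, " um")
  with_local_seed(spec$seed, {
    idx <- sample(elig, spec$n_synapses, replace = TRUE,
                  prob = comp$length_um[elig])
    u <- stats::runif(spec$n_synapses)
    sec <- comp$section[idx]
    # position within the section: compartment midpoint +- half its span
    ns <- cell$grid$nseg[sec]
    pos <- comp$pos[idx] + (u - 0.5) / ns
    data.frame(comp = idx, section = sec, pos = pos,
               dist_um = path_distance(cell$morphology, sec, pos))
  })
}

#' Generate seeded gamma-drive event times
#'
#' @param spec a [gamma_drive_spec()]
#' @return list of per-synapse event-time vectors (ms), each within
#'   `[0, duration_ms)`
#' @export
gamma_drive_events <- function(spec = gamma_drive_spec()) {
  stopifnot(spec$duration_ms > 0)
  mean_isi <- 1000 / spec$rate_hz
  with_local_seed(spec$seed + 104729L, {
    lapply(seq_len(spec$n_synapses), function(s) {
      tt <- numeric(0)
      t <- 0
      repeat {
        isi <- (1 - spec$noise) * mean_isi +
               if (spec$noise > 0) spec$noise * stats::rexp(1, 1 / mean_isi) else 0
        t <- t + isi
        if (t >= spec$duration_ms) break
        tt <- c(tt, t)
      }
      tt
    })
  })
}

#' Run the orthodromic gamma-drive protocol
#'
#' Places the synapses, draws the event trains, runs the cell, and detects
#' somatic spikes at the configured 10 mV threshold.
#'
#' @param cell a `ca1_cell`
#' @param spec a [gamma_drive_spec()]
#' @param record_comps extra compartments to record (soma always included)
#' @param record_vars variables to record
#' @return list: `traces` (a `ca1_traces`), `spikes` (a `spike_train`),
#'   `synapses` (placement table), `spec`
#' @export
run_orthodromic <- function(cell, spec = gamma_drive_spec(),
                            record_comps = NULL, record_vars = "v") {
  placement <- place_random_synapses(cell, spec)
  evs <- gamma_drive_events(spec)
  synapses <- data.frame(comp = placement$comp, kind = 1L,
                         tau1 = spec$tau_ms, tau2 = spec$tau_ms,
                         e = spec$e_rev, weight = spec$weight_uS)
  events <- data.frame(
    syn = rep(seq_along(evs), vapply(evs, length, integer(1))),
    time = unlist(evs))
  soma <- soma_compartment(cell)
  rc <- unique(c(soma, record_comps))
  tr <- simulate_cell(cell, tstop = spec$duration_ms, synapses = synapses,
                      events = events, record_comps = rc,
                      record_vars = record_vars)
  thr <- cell$config$simulation$spike_threshold
  spikes <- detect_spikes(tr$t, tr$traces$v[, 1], threshold = thr)
  list(traces = tr, spikes = spikes, synapses = placement, spec = spec)
}

#' Run the backpropagating action potential protocol
#'
#' A somatic current pulse triggers exactly one somatic spike that invades
#' the apical tree; per-compartment absolute peak voltage and
#' depolarization time (stimulus onset to peak) are returned for every
#' apical compartment.
#'
#' @param cell a `ca1_cell`
#' @param amp_nA,dur_ms pulse amplitude and duration
#' @param delay_ms pulse onset
#' @param tstop_ms simulation end
#' @param record_vars extra variables recorded at the apical compartments
#' @return list: `map` (data frame comp, region, dist_um, peak_mV,
#'   depol_time_ms), `traces`, `soma_spikes`
#' @export
run_bap <- function(cell, amp_nA = NULL, dur_ms = NULL, delay_ms = NULL,
                    tstop_ms = NULL, record_vars = "v") {
  d <- cell$config$protocols$bap
  amp_nA <- amp_nA %||% d$amp_nA; dur_ms <- dur_ms %||% d$dur_ms
  delay_ms <- delay_ms %||% d$delay_ms; tstop_ms <- tstop_ms %||% d$tstop_ms
  comp <- cell$grid$compartments
  soma <- soma_compartment(cell)
  api <- which(comp$region %in% .APICAL_REGIONS)
  tr <- simulate_cell(cell, tstop = tstop_ms,
                      iclamps = data.frame(comp = soma, amp = amp_nA,
                                           start = delay_ms, dur = dur_ms),
                      record_comps = c(soma, api), record_vars = record_vars)
  thr <- cell$config$simulation$spike_threshold
  st <- detect_spikes(tr$t, tr$traces$v[, 1], threshold = thr)
  if (length(st$times) != 1L)
    stop("protocol error: pulse produced ", length(st$times),
         " somatic spikes; calibrate amp_nA/dur_ms for exactly one")
  vm <- tr$traces$v[, -1, drop = FALSE]
  keep <- tr$t >= delay_ms
  pk <- apply(vm[keep, , drop = FALSE], 2, max)
  tpk <- tr$t[keep][apply(vm[keep, , drop = FALSE], 2, which.max)]
  map <- data.frame(comp = api, region = comp$region[api],
                    dist_um = comp$dist_um[api], peak_mV = unname(pk),
                    depol_time_ms = unname(tpk) - delay_ms)
  list(map = map, traces = tr, soma_spikes = st)
}

#' STDP pairing specification
#'
#' One EPSP (double-exponential synapse at the distal end of the primary
#' trunk) paired with one somatically evoked bAP, `delta_t` ms after EPSP
#' onset. Potentiation is read out at the synapse compartment.
#'
#' @param delta_t_ms EPSP-onset-to-bAP interval (paired when <= 35 ms)
#' @param epsp_weight_uS synaptic conductance
#' @param settle_ms pre-stimulus settling time
#' @param tail_ms recording tail after the bAP
#' @param readout_ms calcium readout window after EPSP onset
#' @param n_pairings pairings per trial
#' @param inter_pairing_ms interval between pairings
#' @return list spec
#' @export
stdp_spec <- function(delta_t_ms = NULL, epsp_weight_uS = NULL,
                      settle_ms = NULL, tail_ms = NULL, readout_ms = NULL,
                      n_pairings = 1L, inter_pairing_ms = 200) {
  d <- default_config()$protocols$stdp
  list(delta_t_ms = delta_t_ms %||% d$delta_t_ms,
       window_ms = d$window_ms,
       epsp_tau_rise = d$epsp_tau_rise, epsp_tau_decay = d$epsp_tau_decay,
       epsp_weight_uS = epsp_weight_uS %||% d$epsp_weight_uS,
       epsp_e_rev = d$epsp_e_rev,
       settle_ms = settle_ms %||% d$settle_ms, tail_ms = tail_ms %||% d$tail_ms,
       readout_ms = readout_ms %||% d$readout_ms,
       n_pairings = as.integer(n_pairings), inter_pairing_ms = inter_pairing_ms)
}

# distal-most compartment of the primary trunk
.stdp_synapse_comp <- function(cell) {
  comp <- cell$grid$compartments
  prim <- which(comp$region == "apical_primary")
  prim[which.max(comp$dist_um[prim])]
}

#' Run the STDP pairing protocol
#'
#' Runs EPSP-alone, bAP-alone, and paired conditions, each from an
#' identical initial state (fresh solver state, identical settling
#' period), and returns voltage and calcium readouts at the synapse.
#'
#' @param cell a `ca1_cell`
#' @param spec an [stdp_spec()]
#' @return a `ca1_pairing` list: per-condition readouts (`peak_v_mV`,
#'   `peak_ca_mM`, `auc_ca`) plus traces at the synapse compartment
#' @export
run_stdp_pairing <- function(cell, spec = stdp_spec()) {
  bp <- cell$config$protocols$bap
  soma <- soma_compartment(cell)
  syn_comp <- .stdp_synapse_comp(cell)
  epsp_on <- spec$settle_ms
  span <- (spec$n_pairings - 1L) * spec$inter_pairing_ms
  tstop <- spec$settle_ms + span + max(spec$delta_t_ms, 0) + bp$dur_ms + spec$tail_ms

  synapses <- data.frame(comp = syn_comp, kind = 2L,
                         tau1 = spec$epsp_tau_rise, tau2 = spec$epsp_tau_decay,
                         e = spec$epsp_e_rev, weight = spec$epsp_weight_uS)
  onsets <- epsp_on + (seq_len(spec$n_pairings) - 1L) * spec$inter_pairing_ms
  epsp_events <- data.frame(syn = 1L, time = onsets)
  bap_clamps <- data.frame(comp = soma, amp = bp$amp_nA,
                           start = onsets + spec$delta_t_ms, dur = bp$dur_ms)

  run_one <- function(with_epsp, with_bap) {
    tr <- simulate_cell(
      cell, tstop = tstop,
      synapses = if (with_epsp) synapses else NULL,
      events = if (with_epsp) epsp_events else NULL,
      iclamps = if (with_bap) bap_clamps else NULL,
      record_comps = c(syn_comp, soma),
      record_vars = c("v", "ca", "i_ncx", "i_kca", "i_k_total", "i_na_total"))
    keep <- tr$t >= epsp_on
    # calcium readouts are taken in a window around the synaptic event, so
    # a bAP far outside the pairing window does not enter the index
    win <- tr$t >= epsp_on & tr$t <= epsp_on + span + spec$readout_ms
    vs <- tr$traces$v[keep, 1]
    cas <- tr$traces$ca[win, 1]
    ca_rest <- cell$config$capool$ca_rest
    list(traces = tr,
         peak_v_mV = max(vs),
         peak_ca_mM = max(cas),
         auc_ca = sum(pmax(cas - ca_rest, 0)) * tr$dt)
  }

  out <- list(epsp_alone = run_one(TRUE, FALSE),
              bap_alone = run_one(FALSE, TRUE),
              paired = run_one(TRUE, TRUE),
              spec = spec, synapse_comp = syn_comp,
              paired_within_window = spec$delta_t_ms <= spec$window_ms)
  class(out) <- "ca1_pairing"
  out
}

#' @export
print.ca1_pairing <- function(x, ...) {
  cat("ca1_pairing (delta_t =", x$spec$delta_t_ms, "ms):\n")
  for (cond in c("epsp_alone", "bap_alone", "paired")) {
    cat(sprintf("  %-10s peak V %8.2f mV   peak Ca %.3e mM\n", cond,
                x[[cond]]$peak_v_mV, x[[cond]]$peak_ca_mM))
  }
  invisible(x)
}
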