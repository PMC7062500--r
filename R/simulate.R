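# Thin R wrapper around the compiled Crank-Nicolson integrator.

.empty_synapses <- function() {
  data.frame(comp = integer(0), kind = integer(0), tau1 = numeric(0),
             tau2 = numeric(0), e = numeric(0), weight = numeric(0))
}

.empty_events <- function() data.frame(syn = integer(0), time = numeric(0))

.empty_iclamps <- function() {
  data.frame(comp = integer(0), amp = numeric(0), start = numeric(0),
             dur = numeric(0))
}

.engine_pars <- function(cell) {
  cfg <- cell$config
  n <- nrow(cell$grid$compartments)
  list(
    cm = rep(cfg$passive$cm, n),
    ena = cfg$reversal$ena, ek = cfg$reversal$ek, eca = cfg$reversal$eca,
    ncx = list(gamma = cfg$ncx$gamma, ksat = cfg$ncx$ksat,
               km_na = cfg$ncx$km_na, km_ca = cfg$ncx$km_ca,
               km_ca_act = cfg$ncx$km_ca_act, n_hill = cfg$ncx$n_hill,
               na_i = cfg$ions$na_i, na_o = cfg$ions$na_o,
               ca_o = cfg$ions$ca_o, temperature_K = cfg$ions$temperature_K),
    kca = list(alpha = cfg$kca$alpha, beta = cfg$kca$beta, n = cfg$kca$hill_n,
               tau_min = cfg$kca$tau_min),
    capool = list(shell_depth_um = cfg$capool$shell_depth_um,
                  tau_decay_ms = cfg$capool$tau_decay_ms,
                  ca_rest = cfg$capool$ca_rest, ca_min = cfg$capool$ca_min)
  )
}

#' Run a simulation of a cell model
#'
#' Integrates the cable equation with all configured mechanisms under the
#' given stimuli. Synaptic events snap to the time step containing them
#' (error at most dt/2).
#'
#' @param cell a `ca1_cell`
#' @param tstop end time, ms
#' @param synapses data frame: comp, kind (1 single-exp, 2 double-exp),
#'   tau1, tau2, e, weight (uS)
#' @param events data frame: syn (1-based synapse index), time (ms),
#'   sorted by time
#' @param iclamps data frame: comp, amp (nA), start, dur (ms)
#' @param record_comps compartment indices to record (default: soma)
#' @param record_vars variables among v, ca, i_ncx, i_ncx_ca, i_ncx_na,
#'   i_kca, i_k_total, i_na_total, i_cal, i_ca_total
#' @param dt time step, ms
#' @param v_init initial voltage, mV (ignored when `init_state` is given)
#' @param t0 start time, ms
#' @param init_state optional solver state from a previous run's
#'   `final_state`
#' @param sample_every record every k-th step
#' @return a `ca1_traces` object: `t`, `traces` (named list of matrices,
#'   one column per recorded compartment), `final_state`, `stats`
#' @export
simulate_cell <- function(cell, tstop, synapses = NULL, events = NULL,
                          iclamps = NULL, record_comps = NULL,
                          record_vars = "v", dt = NULL, v_init = NULL,
                          t0 = 0, init_state = NULL, sample_every = 1L) {
  cfg <- cell$config
  dt <- dt %||% cfg$simulation$dt
  v_init <- v_init %||% cfg$simulation$v_init
  if (dt <= 0) stop("parameter error: dt must be positive")
  comp <- cell$grid$compartments
  record_comps <- record_comps %||% soma_compartment(cell)
  synapses <- synapses %||% .empty_synapses()
  events <- events %||% .empty_events()
  iclamps <- iclamps %||% .empty_iclamps()
  if (nrow(events) > 1L && is.unsorted(events$time))
    events <- events[order(events$time), , drop = FALSE]

  res <- .run_engine_cpp(
    grid = list(parent = as.integer(comp$parent) - 1L,
                area_cm2 = comp$area_cm2, g_axial_uS = comp$g_axial_uS),
    dens = cell$densities,
    pars = .engine_pars(cell),
    syns = list(comp = as.integer(synapses$comp) - 1L,
                kind = as.integer(synapses$kind),
                tau1 = as.numeric(synapses$tau1),
                tau2 = as.numeric(synapses$tau2),
                e = as.numeric(synapses$e),
                weight = as.numeric(synapses$weight)),
    events = list(syn = as.integer(events$syn) - 1L,
                  time = as.numeric(events$time)),
    iclamps = list(comp = as.integer(iclamps$comp) - 1L,
                   amp = as.numeric(iclamps$amp),
                   start = as.numeric(iclamps$start),
                   dur = as.numeric(iclamps$dur)),
    rec = list(comps = as.integer(record_comps) - 1L,
               vars = as.character(record_vars)),
    dt = dt, tstop = tstop, t0 = t0, v_init = v_init,
    init_state = init_state, sample_every = as.integer(sample_every))

  for (k in seq_along(res$traces)) {
    colnames(res$traces[[k]]) <- paste0("comp", record_comps)
  }
  structure(list(t = res$t, traces = res$traces, final_state = res$final_state,
                 stats = res$stats, dt = dt * sample_every,
                 record_comps = record_comps),
            class = "ca1_traces")
}

#' @export
print.ca1_traces <- function(x, ...) {
  cat("ca1_traces:", length(x$t), "samples x", length(x$record_comps),
      "compartments; vars:", paste(names(x$traces), collapse = ", "), "\n")
  invisible(x)
}

#' Index of the somatic compartment
#' @param cell a `ca1_cell`
#' @return compartment index
#' @export
soma_compartment <- function(cell) {
  comp <- cell$grid$compartments
  idx <- which(comp$region == "soma")
  if (!length(idx)) stop("lookup error: cell has no soma compartment")
  idx[(length(idx) + 1L) %/% 2L]
}

#' Advance the solver state by one time step
#'
#' Single Crank-Nicolson step with staggered gating and pool updates;
#' useful for state-level tests and custom integration loops.
#'
#' @param cell a `ca1_cell`
#' @param state solver state (a `final_state` list) or NULL to start from
#'   the configured initial voltage
#' @param dt step, ms
#' @param t0 current time, ms
#' @param iclamps,synapses,events stimuli as in [simulate_cell()]
#' @return list with the advanced `state` and the voltage vector `v`
#' @export
advance_step <- function(cell, state = NULL, dt = NULL, t0 = 0,
                         iclamps = NULL, synapses = NULL, events = NULL) {
  dt <- dt %||% cell$config$simulation$dt
  res <- simulate_cell(cell, tstop = t0 + dt, dt = dt, t0 = t0,
                       init_state = state, iclamps = iclamps,
                       synapses = synapses, events = events,
                       record_comps = soma_compartment(cell))
  list(state = res$final_state, v = res$final_state$v, t = t0 + dt)
}

#' Export recorded traces as a tidy CSV
#'
#' One time column plus one column per recorded site and variable.
#'
#' @param traces a `ca1_traces`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_traces_csv <- function(traces, path) {
  out <- data.frame(t_ms = traces$t)
  for (v in names(traces$traces)) {
    m <- traces$traces[[v]]
    colnames(m) <- paste0(v, "_", colnames(m))
    out <- cbind(out, as.data.frame(m))
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
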