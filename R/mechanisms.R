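# Membrane mechanisms at the equation level.
#
# The Na+/Ca2+ exchanger current is the product of an allosteric factor
# (Hill activation by intracellular Ca2+) and an electrochemical driving
# factor (Weber-type formulation); the exchanger is electrogenic with a
# 3 Na+ : 1 Ca2+ cycle, so the sodium and calcium component currents are
# +3 and -2 times the net current. The Ca2+-activated K+ conductance is a
# Destexhe-type m^2 conductance with Hill-type calcium activation. These R
# functions are the reference formulas; the compiled engine implements the
# same expressions, and parity is enforced by tests.

#' Default ionic conditions
#'
#' Intracellular Ca 50 nM and Na 10 mM; extracellular Ca 2 mM and
#' Na 140 mM; temperature 307.15 K.
#'
#' @param Ca_i,Na_i,Ca_o,Na_o concentrations, mM
#' @param temperature_K temperature, Kelvin
#' @return list of ion conditions
#' @export
ion_conditions <- function(Ca_i = 5e-5, Na_i = 10, Ca_o = 2, Na_o = 140,
                           temperature_K = 307.15) {
  if (any(c(Ca_i, Na_i, Ca_o, Na_o, temperature_K) <= 0))
    stop("domain error: concentrations and temperature must be positive")
  list(Ca_i = Ca_i, Na_i = Na_i, Ca_o = Ca_o, Na_o = Na_o,
       temperature_K = temperature_K)
}

#' Load mechanism parameter defaults
#'
#' All mechanism constants live in one structured config file
#' (`inst/extdata/config/mechanisms.yaml`), the single source of truth for
#' exchanger, K[Ca], channel, calcium-pool, and protocol defaults.
#'
#' @param path optional path to an alternative YAML config
#' @return nested list of parameters
#' @export
default_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "config", "mechanisms.yaml", package = "ca1sim")
  }
  if (!nzchar(path) || !file.exists(path)) stop("config error: config file not found")
  yaml::read_yaml(path)
}

#' NCX parameter record
#'
#' @param vmax maximal current density scale, mA/cm2
#' @param gamma voltage-dependence partition in `[0, 1]`
#' @param ksat saturation factor
#' @param km_na,km_ca half-saturation constants for extracellular Na and Ca, mM
#' @param km_ca_act half-activation Ca of the allosteric site, mM
#' @param n_hill Hill exponent of allosteric activation
#' @return list of NCX parameters
#' @export
ncx_params <- function(vmax = NULL, gamma = NULL, ksat = NULL, km_na = NULL,
                       km_ca = NULL, km_ca_act = NULL, n_hill = NULL) {
  d <- default_config()$ncx
  p <- list(vmax = vmax %||% d$vmax, gamma = gamma %||% d$gamma,
            ksat = ksat %||% d$ksat, km_na = km_na %||% d$km_na,
            km_ca = km_ca %||% d$km_ca, km_ca_act = km_ca_act %||% d$km_ca_act,
            n_hill = n_hill %||% d$n_hill)
  stopifnot(p$vmax >= 0, p$gamma >= 0, p$gamma <= 1, p$ksat >= 0,
            p$km_na > 0, p$km_ca > 0, p$km_ca_act > 0, p$n_hill > 0)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Allosteric activation factor of the exchanger
#'
#' `Allo = 1 / (1 + (Km_Ca_act / Ca_i)^n_Hill)`: Hill activation by
#' intracellular calcium, strictly increasing, in (0, 1).
#'
#' @param Ca_i intracellular calcium, mM
#' @param p NCX parameters from [ncx_params()]
#' @return dimensionless factor in (0, 1)
#' @export
ncx_allosteric_factor <- function(Ca_i, p = ncx_params()) {
  if (any(Ca_i <= 0)) stop("domain error: Ca_i must be positive")
  1 / (1 + (p$km_ca_act / Ca_i)^p$n_hill)
}

#' Electrochemical driving factor of the exchanger
#'
#' Evaluates the Weber-type driving term: translocation numerator
#' `[Na]i^3 [Ca]o e^(g VF/RT) - [Na]o^3 [Ca]i e^((g-1) VF/RT)` over the
#' saturation denominator, scaled by `vmax`. Positive values are net
#' outward current (reverse mode, calcium entry).
#'
#' @param V membrane potential, mV
#' @param ions ion conditions from [ion_conditions()]; `ions$Ca_i` is the
#'   intracellular calcium sensed by the exchanger
#' @param p NCX parameters
#' @return current density, mA/cm2 (outward positive)
#' @export
ncx_delta_e <- function(V, ions = ion_conditions(), p = ncx_params()) {
  if (any(abs(V) > 1000)) stop("domain error: |V| > 1000 mV overflows the exponentials")
  vfrt <- V * 1e-3 * .FARADAY / (.GAS_CONSTANT * ions$temperature_K)
  num <- ions$Na_i^3 * ions$Ca_o * exp(p$gamma * vfrt) -
         ions$Na_o^3 * ions$Ca_i * exp((p$gamma - 1) * vfrt)
  den <- (p$km_na^3 + ions$Na_o^3) * (p$km_ca + ions$Ca_o) *
         (1 + p$ksat * exp((p$gamma - 1) * vfrt))
  p$vmax * num / den
}

#' Analytic exchanger reversal potential
#'
#' The 3:1 electrogenic cycle reverses at
#' `V_rev = (RT/F) ln([Na]o^3 [Ca]i / ([Na]i^3 [Ca]o))`.
#'
#' @param ions ion conditions
#' @return mV
#' @export
ncx_reversal_potential <- function(ions = ion_conditions()) {
  rtf <- .GAS_CONSTANT * ions$temperature_K / .FARADAY * 1e3   # mV
  rtf * log(ions$Na_o^3 * ions$Ca_i / (ions$Na_i^3 * ions$Ca_o))
}

#' Exchanger current and its ionic components
#'
#' Net current `phi = Allo * DeltaE`; per the 3 Na+ : 1 Ca2+ electrogenic
#' cycle the component currents are `i_Na = 3 phi` and `i_Ca = -2 phi`
#' (so `i_Na + i_Ca = phi`). The molar calcium flux fed to the pool is the
#' calcium component divided by `2F` per unit shell volume: calcium leaves
#' the cell in forward mode (`phi < 0`) and enters in reverse mode.
#'
#' @param V membrane potential, mV
#' @param Ca_i intracellular calcium sensed by the exchanger, mM
#' @param ions ion conditions (extracellular side and Na_i)
#' @param p NCX parameters
#' @param allo_scale multiplicative scale on the allosteric factor
#'   (product clamped at 1)
#' @return list: `i_total`, `i_ca`, `i_na` (mA/cm2, outward positive) and
#'   `j_ca` (mM um / ms equivalent molar flux density, positive into the cell)
#' @export
ncx_current_and_fluxes <- function(V, Ca_i, ions = ion_conditions(),
                                   p = ncx_params(), allo_scale = 1) {
  ions$Ca_i <- Ca_i
  allo <- pmin(1, ncx_allosteric_factor(Ca_i, p) * allo_scale)
  phi <- allo * ncx_delta_e(V, ions, p)
  i_ca <- -2 * phi
  list(i_total = phi, i_ca = i_ca, i_na = 3 * phi,
       j_ca = -i_ca / (2 * .FARADAY) * 1e4)   # mol/(cm2 s) -> mM um/ms scale
}

#' K[Ca] parameter record
#'
#' @param gbar maximal permeability, S/cm2
#' @param e_k potassium reversal, mV
#' @param alpha Ca-binding rate coefficient, ms^-1 mM^-n
#' @param beta unbinding rate, ms^-1
#' @param n Hill exponent (2)
#' @param tau_min time-constant floor, ms
#' @return list of K[Ca] parameters
#' @export
kca_params <- function(gbar = NULL, e_k = NULL, alpha = NULL, beta = NULL,
                       n = NULL, tau_min = NULL) {
  d <- default_config()
  k <- d$kca
  p <- list(gbar = gbar %||% k$gbar, e_k = e_k %||% d$reversal$ek,
            alpha = alpha %||% k$alpha, beta = beta %||% k$beta,
            n = n %||% k$hill_n, tau_min = tau_min %||% k$tau_min)
  stopifnot(p$gbar >= 0, p$alpha > 0, p$beta > 0, p$n > 0, p$tau_min >= 0)
  p
}

#' Steady-state K[Ca] activation
#'
#' `m_inf = alpha Ca^n / (alpha Ca^n + beta)`, monotone increasing in Ca.
#'
#' @param Ca_i intracellular calcium, mM
#' @param p K[Ca] parameters
#' @return value in `[0, 1)`
#' @export
kca_m_inf <- function(Ca_i, p = kca_params()) {
  if (any(Ca_i < 0)) stop("domain error: Ca_i must be non-negative")
  ac <- p$alpha * Ca_i^p$n
  ac / (ac + p$beta)
}

#' K[Ca] activation time constant
#'
#' `tau = max(1 / (alpha Ca^n + beta), tau_min)`, decreasing in Ca above
#' the floor.
#'
#' @inheritParams kca_m_inf
#' @return ms
#' @export
kca_tau <- function(Ca_i, p = kca_params()) {
  if (any(Ca_i < 0)) stop("domain error: Ca_i must be non-negative")
  pmax(1 / (p$alpha * Ca_i^p$n + p$beta), p$tau_min)
}

#' K[Ca] current
#'
#' `i = gbar m^2 (V - E_K)`.
#'
#' @param V membrane potential, mV
#' @param m activation state in `[0, 1]`
#' @param p K[Ca] parameters
#' @return current density, mA/cm2
#' @export
kca_current <- function(V, m, p = kca_params()) {
  stopifnot(all(m >= 0), all(m <= 1))
  p$gbar * m^2 * (V - p$e_k)
}

#' Advance the K[Ca] activation state one step
#'
#' First-order relaxation of `m` toward `m_inf(Ca)` with time constant
#' `tau(Ca)`, integrated exactly for the step.
#'
#' @param m current activation
#' @param Ca_i calcium, mM
#' @param dt step, ms
#' @param p K[Ca] parameters
#' @return updated activation
#' @export
kca_step <- function(m, Ca_i, dt, p = kca_params()) {
  minf <- kca_m_inf(Ca_i, p)
  tau <- kca_tau(Ca_i, p)
  m + (1 - exp(-dt / tau)) * (minf - m)
}

#' Calcium pool parameters
#'
#' @param shell_depth submembrane shell depth, um
#' @param tau_decay clearance (pump) time constant, ms
#' @param ca_rest resting calcium, mM
#' @param ca_min floor, mM
#' @return list
#' @export
ca_pool_params <- function(shell_depth = NULL, tau_decay = NULL,
                           ca_rest = NULL, ca_min = NULL) {
  d <- default_config()$capool
  p <- list(shell_depth = shell_depth %||% d$shell_depth_um,
            tau_decay = tau_decay %||% d$tau_decay_ms,
            ca_rest = ca_rest %||% d$ca_rest, ca_min = ca_min %||% d$ca_min)
  stopifnot(p$shell_depth > 0, p$tau_decay > 0, p$ca_rest > 0, p$ca_min > 0)
  p
}

#' Advance the submembrane calcium pool one step
#'
#' `d[Ca]/dt = -i_Ca / (2 F depth) - (Ca - Ca_rest) / tau_decay`, clipped
#' at the floor; an inward calcium current (negative `i_ca_total`) raises
#' calcium. Integrated with the same implicit-decay update as the engine.
#'
#' @param Ca_i calcium, mM
#' @param i_ca_total total calcium current density, mA/cm2 (outward positive)
#' @param dt step, ms
#' @param p pool parameters
#' @return updated calcium, mM
#' @export
ca_pool_step <- function(Ca_i, i_ca_total, dt, p = ca_pool_params()) {
  if (any(Ca_i < p$ca_min)) stop("domain error: Ca_i below the pool floor")
  fac <- 1 / (2 * .FARADAY * p$shell_depth * 1e-4)   # mA/cm2 -> mM/ms
  ca <- (Ca_i + dt * (-i_ca_total * fac + p$ca_rest / p$tau_decay)) /
        (1 + dt / p$tau_decay)
  pmax(ca, p$ca_min)
}

#' Hodgkin-Huxley channel specification
#'
#' Ohmic channel with independent gating variables; each gate is given in
#' inf/tau form as a function of voltage. The reduced complement used by
#' the cell model (Na, KDR, KA, L-type Ca) is available through
#' [hh_rate_functions()]; other channel types can be described with the
#' same structure but are off by default.
#'
#' @param name channel name
#' @param gbar maximal conductance density, S/cm2
#' @param e_rev reversal potential, mV
#' @param gates named list; each entry is `list(inf = function(V),
#'   tau = function(V), exponent = k)`
#' @return an `hh_channel_spec`
#' @export
hh_channel_spec <- function(name, gbar, e_rev, gates) {
  stopifnot(gbar >= 0, is.list(gates))
  structure(list(name = name, gbar = gbar, e_rev = e_rev, gates = gates),
            class = "hh_channel_spec")
}

#' Rate functions of the reduced channel complement
#'
#' Classic HH-style kinetics (rest near -65 mV): transient Na (m^3 h),
#' delayed rectifier K (n^4), inactivating A-type K (a b), and an L-type
#' Ca gate (m^2, fixed +120 mV reversal). These are the exact expressions
#' compiled into the engine.
#'
#' @param V membrane potential, mV (vectorized)
#' @return named list of `inf` and `tau` values per gate
#' @export
hh_rate_functions <- function(V) {
  vt <- function(x, y) ifelse(abs(x / y) < 1e-6, y + x / 2, x / (1 - exp(-x / y)))
  am <- 0.1 * vt(V + 40, 10); bm <- 4 * exp(-(V + 65) / 18)
  ah <- 0.07 * exp(-(V + 65) / 20); bh <- 1 / (1 + exp(-(V + 35) / 10))
  an <- 0.01 * vt(V + 55, 10); bn <- 0.125 * exp(-(V + 65) / 80)
  list(
    na_m = list(inf = am / (am + bm), tau = 1 / (am + bm)),
    na_h = list(inf = ah / (ah + bh), tau = 1 / (ah + bh)),
    kdr_n = list(inf = an / (an + bn), tau = 1 / (an + bn)),
    ka_a = list(inf = 1 / (1 + exp(-(V + 30) / 15)), tau = rep(1, length(V))),
    ka_b = list(inf = 1 / (1 + exp((V + 70) / 6)), tau = rep(15, length(V))),
    cal_m = list(inf = 1 / (1 + exp(-(V + 15) / 6)), tau = rep(1.5, length(V)))
  )
}

#' Evaluate an HH channel: current and one gating step
#'
#' @param V membrane potential, mV
#' @param gates named numeric vector of gate states in `[0, 1]`
#' @param spec an [hh_channel_spec()]
#' @param dt time step, ms (gates advanced by exact exponential relaxation)
#' @return list with `i` (mA/cm2) and `gates` (updated)
#' @export
hh_channel_current <- function(V, gates, spec, dt) {
  stopifnot(all(gates >= 0), all(gates <= 1))
  open <- 1
  newg <- gates
  for (nm in names(spec$gates)) {
    gd <- spec$gates[[nm]]
    open <- open * gates[[nm]]^gd$exponent
    inf <- gd$inf(V); tau <- gd$tau(V)
    newg[[nm]] <- gates[[nm]] + (1 - exp(-dt / tau)) * (inf - gates[[nm]])
  }
  list(i = spec$gbar * open * (V - spec$e_rev), gates = newg)
}
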