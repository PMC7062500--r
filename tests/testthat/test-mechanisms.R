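# Equation-level mechanism fidelity: exchanger, K[Ca], calcium pool, HH
# channels, and parity between the R formula layer and the compiled engine.

test_that("allosteric factor: half-saturation, saturation limit, monotonicity", {
  p <- ncx_params()
  expect_equal(ncx_allosteric_factor(p$km_ca_act, p), 0.5)
  p2 <- ncx_params(n_hill = 2)
  expect_lt(abs(ncx_allosteric_factor(1e6 * p2$km_ca_act, p2) - 1), 1e-10)
  ca <- 10^seq(-6, -1, length.out = 50)
  a <- ncx_allosteric_factor(ca, p)
  expect_true(all(diff(a) > 0))
  expect_true(all(a > 0 & a < 1))
  expect_error(ncx_allosteric_factor(0, p), "domain error")

  # direct one-line evaluation at the resting calcium
  expect_equal(ncx_allosteric_factor(5e-5, p),
               1 / (1 + (p$km_ca_act / 5e-5)^p$n_hill))
})

test_that("electrochemical factor: zero at the thermodynamic reversal", {
  ions <- ion_conditions()
  p <- ncx_params()
  vrev <- ncx_reversal_potential(ions)
  expect_lt(abs(ncx_delta_e(vrev, ions, p)), 1e-14)
  expect_gt(ncx_delta_e(vrev + 50, ions, p), 0)
  expect_lt(ncx_delta_e(vrev - 50, ions, p), 0)
  expect_error(ncx_delta_e(1500, ions, p), "domain error")
})

test_that("reversal root sits near -71 mV for the printed concentrations", {
  ions <- ion_conditions()   # Ca_i 50 nM, Na_i 10, Ca_o 2, Na_o 140, 307.15 K
  p <- ncx_params()
  root <- uniroot(function(v) ncx_delta_e(v, ions, p),
                  c(-150, 50), tol = 1e-8)$root
  expect_lt(abs(root - ncx_reversal_potential(ions)), 0.01)
  expect_lt(abs(root - (-71)), 1.0)
})

test_that("reversal by bisection matches the closed form on random ion sets", {
  set.seed(42)
  p <- ncx_params()
  for (k in 1:25) {
    ions <- ion_conditions(Ca_i = 10^runif(1, -5, -3), Na_i = runif(1, 5, 20),
                           Ca_o = runif(1, 1, 3), Na_o = runif(1, 100, 160))
    vrev <- ncx_reversal_potential(ions)
    f <- function(v) ncx_delta_e(v, ions, p)
    root <- uniroot(f, c(vrev - 60, vrev + 60), tol = 1e-9)$root
    expect_lt(abs(root - vrev), 0.01)
  }
})

test_that("exchanger stoichiometry: i_na / i_ca = -3/2, components sum to total", {
  set.seed(7)
  for (k in 1:20) {
    out <- ncx_current_and_fluxes(V = runif(1, -90, 40), Ca_i = 10^runif(1, -5, -3))
    expect_equal(out$i_na / out$i_ca, -1.5)
    expect_equal(out$i_na + out$i_ca, out$i_total)
  }
  # reversal: everything zero
  out <- ncx_current_and_fluxes(ncx_reversal_potential(), 5e-5)
  expect_lt(abs(out$i_total), 1e-16)
  # strong depolarization at resting calcium: reverse mode, calcium entering
  out <- ncx_current_and_fluxes(30, 5e-5)
  expect_gt(out$i_total, 0)
  expect_lt(out$i_ca, 0)   # inward calcium component
  expect_gt(out$j_ca, 0)   # flux into the pool
})

test_that("engine NCX evaluator agrees with the R formulas", {
  cfg <- default_config()
  pars <- list(gamma = cfg$ncx$gamma, ksat = cfg$ncx$ksat,
               km_na = cfg$ncx$km_na, km_ca = cfg$ncx$km_ca,
               km_ca_act = cfg$ncx$km_ca_act, n_hill = cfg$ncx$n_hill,
               na_i = cfg$ions$na_i, na_o = cfg$ions$na_o, ca_o = cfg$ions$ca_o,
               temperature_K = cfg$ions$temperature_K)
  p <- ncx_params()
  for (v in c(-90, -71, -40, 0, 30)) {
    for (ca in c(5e-5, 5e-4, 5e-3)) {
      eng <- .engine_ncx_eval(v, ca, p$vmax, 1.0, pars)
      ref <- ncx_current_and_fluxes(v, ca, ion_conditions(Ca_i = ca), p)
      expect_equal(eng$i_total, ref$i_total, tolerance = 1e-12)
      expect_equal(eng$i_ca, ref$i_ca, tolerance = 1e-12)
    }
  }
})

test_that("K[Ca]: limits, half-activation, tau identity, current", {
  p <- kca_params()
  expect_equal(kca_m_inf(0, p), 0)
  ca_half <- sqrt(p$beta / p$alpha)
  expect_equal(kca_m_inf(ca_half, p), 0.5)
  expect_equal(kca_tau(0, p), min(1 / p$beta, Inf))

  ca <- 10^seq(-6, -2, length.out = 40)
  expect_true(all(diff(kca_m_inf(ca, p)) > 0))
  expect_true(all(diff(kca_tau(ca, p)) <= 0))

  # algebraic identity m_inf / tau = alpha Ca^n wherever tau is off the floor
  off_floor <- kca_tau(ca, p) > p$tau_min
  expect_lt(max(abs(kca_m_inf(ca[off_floor], p) / kca_tau(ca[off_floor], p) -
                    p$alpha * ca[off_floor]^p$n)), 1e-12)

  expect_equal(kca_current(V = -20, m = 0, p), 0)
  expect_equal(kca_current(V = p$e_k, m = 0.7, p), 0)
  # dissipative: current sign equals sign of V - E_K
  expect_gt(kca_current(p$e_k + 30, 0.5, p), 0)
  expect_lt(kca_current(p$e_k - 30, 0.5, p), 0)

  # direct evaluation of the activation curve at 1 uM
  expect_equal(kca_m_inf(1e-3, p),
               p$alpha * 1e-6 / (p$alpha * 1e-6 + p$beta))
})

test_that("K[Ca] relaxation at clamped Ca matches the closed form", {
  p <- kca_params()
  ca <- 4e-4
  minf <- kca_m_inf(ca, p); tau <- kca_tau(ca, p)
  dt <- 0.025
  m <- 0.05
  ts <- seq(dt, 20, by = dt)
  trace <- numeric(length(ts))
  for (i in seq_along(ts)) {
    m <- kca_step(m, ca, dt, p)
    trace[i] <- m
  }
  closed <- minf + (0.05 - minf) * exp(-ts / tau)
  expect_lt(max(abs(trace - closed)) / minf, 0.001)
})

test_that("calcium pool: equilibrium, exponential clearance, constant-current ODE", {
  p <- ca_pool_params()
  expect_equal(ca_pool_step(p$ca_rest, 0, 0.025, p), p$ca_rest)

  # decay toward rest with tau_decay
  dt <- 0.025
  ca <- 1e-3
  ts <- seq(dt, 100, by = dt)
  tr <- numeric(length(ts))
  for (i in seq_along(ts)) { ca <- ca_pool_step(ca, 0, dt, p); tr[i] <- ca }
  closed <- p$ca_rest + (1e-3 - p$ca_rest) * exp(-ts / p$tau_decay)
  expect_lt(max(abs(tr - closed)) / 1e-3, 0.001)

  # constant inward current for 10 ms: analytic solution of the linear ODE
  i_ca <- -0.01   # inward
  src <- -i_ca / (2 * 96485.33212 * p$shell_depth * 1e-4)
  ca <- p$ca_rest
  for (k in seq_len(400)) ca <- ca_pool_step(ca, i_ca, dt, p)
  ca_inf <- p$ca_rest + src * p$tau_decay
  closed <- ca_inf + (p$ca_rest - ca_inf) * exp(-10 / p$tau_decay)
  expect_lt(abs(ca - closed) / closed, 0.001)

  # floor respected
  expect_gte(ca_pool_step(p$ca_min, 1, dt, p), p$ca_min)
})

test_that("forward-mode exchanger alone clears calcium monotonically", {
  p <- ncx_params()
  pool <- ca_pool_params(tau_decay = 1e9)   # disable the pump: NCX only
  ions <- ion_conditions()
  vrev <- ncx_reversal_potential(ions)
  ca <- 2e-3
  trace <- numeric(200)
  for (k in 1:200) {
    out <- ncx_current_and_fluxes(vrev - 30, ca, ions, p)  # forward mode
    ca <- ca_pool_step(ca, out$i_ca, 0.1, pool)
    trace[k] <- ca
  }
  expect_true(all(diff(trace) < 0))
  expect_gte(min(trace), pool$ca_min)
})

test_that("HH layer: closed gates, reversal, rate parity with the engine", {
  rates <- hh_rate_functions(-40)
  spec <- hh_channel_spec("na", gbar = 0.12, e_rev = 50, gates = list(
    m = list(inf = function(v) hh_rate_functions(v)$na_m$inf,
             tau = function(v) hh_rate_functions(v)$na_m$tau, exponent = 3),
    h = list(inf = function(v) hh_rate_functions(v)$na_h$inf,
             tau = function(v) hh_rate_functions(v)$na_h$tau, exponent = 1)))
  out <- hh_channel_current(-40, c(m = 0, h = 1), spec, dt = 0.025)
  expect_equal(out$i, 0)
  out <- hh_channel_current(50, c(m = 0.9, h = 0.5), spec, dt = 0.025)
  expect_equal(out$i, 0)   # V at reversal
  out <- hh_channel_current(0, c(m = 0.5, h = 0.5), spec, dt = 0.025)
  expect_equal(out$i, 0.12 * 0.5^3 * 0.5 * (0 - 50))
  expect_true(all(out$gates >= 0 & out$gates <= 1))

  for (v in c(-80, -65, -40, 0, 30)) {
    eng <- .engine_gate_rates(v)
    ref <- hh_rate_functions(v)
    expect_equal(eng$na_m_inf, ref$na_m$inf, tolerance = 1e-12)
    expect_equal(eng$na_h_tau, ref$na_h$tau, tolerance = 1e-12)
    expect_equal(eng$kdr_n_inf, ref$kdr_n$inf, tolerance = 1e-12)
    expect_equal(eng$ka_a_inf, ref$ka_a$inf, tolerance = 1e-12)
    expect_equal(eng$cal_m_inf, ref$cal_m$inf, tolerance = 1e-12)
  }
})

test_that("reduced soma complement fires to a current step", {
  # qualitative excitability: >= 1 spike with peak above +20 mV
  cell <- fixture_cell(1)
  soma <- soma_compartment(cell)
  r <- simulate_cell(cell, tstop = 60,
                     iclamps = data.frame(comp = soma, amp = 1, start = 10, dur = 5),
                     record_comps = soma)
  st <- detect_spikes(r$t, r$traces$v[, 1], 10)
  expect_gte(length(st$times), 1L)
  expect_gt(max(r$traces$v[, 1]), 20)
})
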