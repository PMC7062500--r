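# Synthetic morphologies, analytic cable solutions, and canned spike
# trains. These generate every input the pipeline needs without downloads:
# CA1-like trees with a known trunk/oblique/tuft partition, closed-form
# passive references for the solver, and spike-train fixtures for the
# synchronization metric.

#' Default geometry for the reduced CA1-like morphology
#'
#' Proportions follow a typical rat CA1 pyramidal cell at desk scale
#' (~100 compartments): 20x20 um soma, 400 um tapering apical trunk, three
#' 150 um oblique branches, a terminal bifurcation into four 150 um tuft
#' branches, two 200 um basal dendrites, and a 300 um axon.
#'
#' @return named list of geometry parameters (um)
#' @export
reduced_ca1_spec <- function() {
  list(
    soma_length = 20, soma_diam = 20,
    trunk_length = 400, trunk_diam_prox = 2.5, trunk_diam_dist = 1.0,
    n_obliques = 3, oblique_length = 150, oblique_diam = 1.0,
    oblique_base_dist = c(120, 200, 280), oblique_jitter = 15,
    tuft_branches = 4, tuft_length = 150, tuft_diam = 1.0,
    n_basal = 2, basal_length = 200, basal_diam = 1.5,
    axon_length = 300, axon_diam = 1.0,
    point_spacing = 20
  )
}

# straight run of SWC points from `from_xyz` in direction `dir`; when the
# parent is a soma point the run must include its own start point
# (include_start = TRUE) so the section length is fully accounted for
.swc_run <- function(rows, from_xyz, dir, length, r0, r1, type, parent_id,
                     spacing, role, roles, include_start = FALSE) {
  npts <- max(2L, ceiling(length / spacing) + 1L)
  tt <- seq(0, 1, length.out = npts)
  if (!include_start) tt <- tt[-1]   # first point coincides with parent
  dir <- dir / sqrt(sum(dir^2))
  id0 <- if (nrow(rows)) max(rows$id) else 0L
  pid <- parent_id
  for (k in seq_along(tt)) {
    id <- id0 + k
    rows[nrow(rows) + 1L, ] <- list(id, type,
                                    from_xyz[1] + dir[1] * tt[k] * length,
                                    from_xyz[2] + dir[2] * tt[k] * length,
                                    from_xyz[3] + dir[3] * tt[k] * length,
                                    (r0 + (r1 - r0) * tt[k]), pid)
    roles[[length(roles) + 1L]] <- role
    pid <- id
  }
  list(rows = rows, roles = roles, tip_id = pid)
}

.empty_swc <- function() {
  data.frame(id = integer(0), type = integer(0), x = numeric(0), y = numeric(0),
             z = numeric(0), r = numeric(0), parent = integer(0))
}

#' Generate a ball-and-stick morphology
#'
#' Soma plus a single unbranched apical cable; exact geometry for analytic
#' cable comparisons.
#'
#' @param length apical cable length, um
#' @param diam apical cable diameter, um
#' @param soma_diam soma diameter (spherical soma), um
#' @param point_spacing spacing of SWC sample points, um
#' @return a `ca1_morphology` with ground-truth region labels in
#'   `attr(, "ground_truth")`
#' @export
generate_ball_and_stick <- function(length = 400, diam = 1, soma_diam = 20,
                                    point_spacing = 20) {
  stopifnot(length > 0, diam > 0, soma_diam > 0)
  rows <- .empty_swc()
  rows[1, ] <- list(1L, 1L, 0, 0, 0, soma_diam / 2, -1L)
  roles <- list("soma")
  run <- .swc_run(rows, c(0, 0, 0), c(0, 1, 0), length, diam / 2, diam / 2,
                  4L, 1L, point_spacing, "apical_primary", roles,
                  include_start = TRUE)
  m <- build_morphology(run$rows)
  attr(m, "ground_truth") <- .roles_to_regions(m, unlist(run$roles))
  m
}

.roles_to_regions <- function(m, point_roles) {
  ps <- attr(m, "point_section")
  sec_role <- character(nrow(m$sections))
  for (i in seq_len(nrow(m$sections))) {
    r <- point_roles[ps == i]
    sec_role[i] <- r[length(r)]   # role of the distal-most point
  }
  sec_role
}

#' Generate a reduced CA1-like morphology
#'
#' Deterministic given `seed`: oblique attachment distances are jittered
#' and branch azimuths randomized, but region counts are fixed by the spec.
#' The apical tree is a tapering trunk with oblique side branches and a
#' terminal bifurcation into a tuft (built as a two-level binary tree with
#' `tuft_branches` terminal branches).
#'
#' @param spec geometry list from [reduced_ca1_spec()] (entries may be
#'   overridden)
#' @param seed integer seed
#' @return a `ca1_morphology`; ground-truth region labels in
#'   `attr(, "ground_truth")`
#' @export
generate_reduced_ca1 <- function(spec = reduced_ca1_spec(), seed = 1L) {
  spec <- utils::modifyList(reduced_ca1_spec(), spec)
  with_local_seed(seed, {
    sp <- spec
    stopifnot(sp$trunk_length > 0, sp$n_obliques >= 0, sp$tuft_branches >= 2)
    rows <- .empty_swc()
    # 3-point soma along x: equivalent cylinder soma_length x soma_diam
    hl <- sp$soma_length / 2; r <- sp$soma_diam / 2
    rows[1, ] <- list(1L, 1L, 0, 0, 0, r, -1L)
    rows[2, ] <- list(2L, 1L, -hl, 0, 0, r, 1L)
    rows[3, ] <- list(3L, 1L, hl, 0, 0, r, 1L)
    roles <- list("soma", "soma", "soma")

    jit <- stats::runif(sp$n_obliques, -sp$oblique_jitter, sp$oblique_jitter)
    att <- sort(sp$oblique_base_dist[seq_len(sp$n_obliques)] + jit)
    if (any(att <= 0) || any(att >= sp$trunk_length))
      stop("generation error: oblique attachment outside the trunk")
    # trunk in runs between attachment points, branch azimuths random
    brk <- c(0, att, sp$trunk_length)
    dprox <- sp$trunk_diam_prox; ddist <- sp$trunk_diam_dist
    trunk_r <- function(d) (dprox + (ddist - dprox) * d / sp$trunk_length) / 2
    pid <- 1L; from <- c(0, 0, 0)
    branch_ids <- integer(0); branch_xyz <- list()
    for (k in seq_len(length(brk) - 1L)) {
      seg <- brk[k + 1L] - brk[k]
      run <- .swc_run(rows, from, c(0, 1, 0), seg,
                      trunk_r(brk[k]), trunk_r(brk[k + 1L]),
                      4L, pid, sp$point_spacing, "apical_primary", roles,
                      include_start = (k == 1L))
      rows <- run$rows; roles <- run$roles; pid <- run$tip_id
      from <- c(0, brk[k + 1L], 0)
      if (k <= length(att)) { branch_ids <- c(branch_ids, pid); branch_xyz[[k]] <- from }
    }
    trunk_tip <- pid; trunk_tip_xyz <- from

    for (k in seq_len(sp$n_obliques)) {
      phi <- stats::runif(1, 0, 2 * pi)
      dir <- c(cos(phi), 0.2, sin(phi))
      run <- .swc_run(rows, branch_xyz[[k]], dir, sp$oblique_length,
                      sp$oblique_diam / 2, sp$oblique_diam / 2,
                      4L, branch_ids[k], sp$point_spacing, "apical_oblique", roles)
      rows <- run$rows; roles <- run$roles
    }

    # tuft: two stems off the trunk tip, each carrying tuft_branches/2 terminals
    n_term <- as.integer(sp$tuft_branches)
    per_stem <- c(ceiling(n_term / 2), floor(n_term / 2))
    for (sstem in 1:2) {
      phi <- stats::runif(1, 0, 2 * pi)
      dir <- c(0.5 * cos(phi), 1, 0.5 * sin(phi))
      run <- .swc_run(rows, trunk_tip_xyz, dir, sp$tuft_length,
                      sp$tuft_diam / 2, sp$tuft_diam / 2,
                      4L, trunk_tip, sp$point_spacing, "apical_tuft", roles)
      rows <- run$rows; roles <- run$roles
      stem_tip <- run$tip_id
      stem_xyz <- trunk_tip_xyz + dir / sqrt(sum(dir^2)) * sp$tuft_length
      for (tb in seq_len(per_stem[sstem])) {
        phi2 <- stats::runif(1, 0, 2 * pi)
        dir2 <- c(0.8 * cos(phi2), 1, 0.8 * sin(phi2))
        run <- .swc_run(rows, stem_xyz, dir2, sp$tuft_length,
                        sp$tuft_diam / 2, sp$tuft_diam / 2,
                        4L, stem_tip, sp$point_spacing, "apical_tuft", roles)
        rows <- run$rows; roles <- run$roles
      }
    }

    for (b in seq_len(sp$n_basal)) {
      phi <- stats::runif(1, 0, 2 * pi)
      dir <- c(0.6 * cos(phi), -1, 0.6 * sin(phi))
      run <- .swc_run(rows, c(0, 0, 0), dir, sp$basal_length,
                      sp$basal_diam / 2, sp$basal_diam / 2,
                      3L, 1L, sp$point_spacing, "basal", roles,
                      include_start = TRUE)
      rows <- run$rows; roles <- run$roles
    }

    run <- .swc_run(rows, c(0, 0, 0), c(0, -1, 0), sp$axon_length,
                    sp$axon_diam / 2, sp$axon_diam / 2,
                    2L, 1L, sp$point_spacing, "axon", roles,
                    include_start = TRUE)
    rows <- run$rows; roles <- run$roles

    m <- build_morphology(rows)
    attr(m, "ground_truth") <- .roles_to_regions(m, unlist(roles))
    attr(m, "spec") <- sp
    attr(m, "seed") <- as.integer(seed)
    m
  })
}

#' Write a morphology fixture: SWC plus a JSON sidecar of region labels
#'
#' @param m morphology with a `ground_truth` attribute
#' @param path SWC output path; the sidecar is written at `<path>.regions.json`
#' @return `path`, invisibly
#' @export
write_morphology_fixture <- function(m, path) {
  write_swc(m, path)
  gt <- attr(m, "ground_truth")
  if (!is.null(gt)) {
    jsonlite::write_json(
      list(section = m$sections$name, region = gt),
      paste0(path, ".regions.json"))
  }
  invisible(path)
}

#' Analytic solutions for the passive finite sealed-end cable
#'
#' Steady-state voltage profile and separation-of-variables step response
#' for a uniform cylinder with constant current injected at `x = 0` and
#' sealed ends, used as solver oracles.
#'
#' @param length cable length, um
#' @param diam diameter, um
#' @param Ra axial resistivity, ohm cm
#' @param g_pas leak conductance density, S/cm2
#' @param Cm specific capacitance, uF/cm2
#' @param i_inj injected current, nA
#' @return list with `lambda_um`, `r_input_Mohm`, and functions
#'   `v_steady(x_um)` (deviation from rest, mV) and `v_step(x_um, t_ms)`
#' @export
reference_passive_solution <- function(length, diam, Ra = 150, g_pas = 2.5e-5,
                                       Cm = 1, i_inj = 0.1) {
  stopifnot(length > 0, diam > 0, Ra > 0, g_pas > 0, Cm > 0)
  a_cm <- diam / 2 * 1e-4
  L_cm <- length * 1e-4
  r_a <- Ra / (pi * a_cm^2)                  # ohm/cm
  r_m <- 1 / (g_pas * pi * 2 * a_cm)         # ohm cm
  lambda_cm <- sqrt(r_m / r_a)
  tau_ms <- Cm / g_pas * 1e-3                # uF/cm2 / (S/cm2) = us -> ms
  Lc <- L_cm / lambda_cm
  r_input <- r_a * lambda_cm / tanh(Lc)      # ohm, sealed far end
  I_A <- i_inj * 1e-9
  v0 <- I_A * r_input * 1e3                  # mV

  v_steady <- function(x_um) {
    xc <- x_um * 1e-4 / lambda_cm
    v0 * cosh(Lc - xc) / cosh(Lc)
  }
  # step response by cosine eigenfunction expansion of the steady profile
  nmodes <- 200L
  xg <- seq(0, length, length.out = 2001L)
  vs <- v_steady(xg)
  cn <- numeric(nmodes + 1L)
  w <- c(0.5, rep(1, length(xg) - 2L), 0.5) * (xg[2] - xg[1])  # trapezoid
  cn[1] <- sum(w * vs) / length
  for (n in seq_len(nmodes)) {
    cn[n + 1L] <- 2 / length * sum(w * vs * cos(n * pi * xg / length))
  }
  v_step <- function(x_um, t_ms) {
    n <- 0:nmodes
    taus <- tau_ms / (1 + (n * pi * lambda_cm / L_cm)^2)
    vapply(x_um, function(x) {
      v_steady(x) - sum(cn * cos(n * pi * x / length) * exp(-t_ms / taus))
    }, numeric(1))
  }
  list(lambda_um = lambda_cm * 1e4, tau_ms = tau_ms,
       r_input_Mohm = r_input * 1e-6, v_steady = v_steady, v_step = v_step)
}

#' Canned spike-train sets for metric tests
#'
#' @param case one of `identical_pair`, `disjoint_pair`, `jittered_pair`,
#'   `poisson_set`
#' @param seed integer seed (used by the stochastic cases)
#' @param n_trains number of trains for `poisson_set`
#' @param rate_hz Poisson rate
#' @param duration_ms window length
#' @param jitter_ms jitter for `jittered_pair`
#' @return list of `spike_train` objects (see [spike_train()])
#' @export
canned_spike_trains <- function(case = c("identical_pair", "disjoint_pair",
                                         "jittered_pair", "poisson_set"),
                                seed = 1L, n_trains = 5L, rate_hz = 10,
                                duration_ms = 1000, jitter_ms = 1) {
  case <- match.arg(case)
  base <- seq(50, duration_ms - 50, by = 100)
  switch(case,
    identical_pair = list(spike_train(base, c(0, duration_ms)),
                          spike_train(base, c(0, duration_ms))),
    disjoint_pair = list(spike_train(base, c(0, duration_ms)),
                         spike_train(base + 50, c(0, duration_ms))),
    jittered_pair = with_local_seed(seed, {
      j <- stats::runif(length(base), -jitter_ms, jitter_ms)
      list(spike_train(base, c(0, duration_ms)),
           spike_train(sort(base + j), c(0, duration_ms)))
    }),
    poisson_set = with_local_seed(seed, {
      lapply(seq_len(n_trains), function(i) {
        t <- cumsum(stats::rexp(ceiling(rate_hz * duration_ms / 1000 * 3) + 10,
                                rate_hz / 1000))
        spike_train(t[t < duration_ms], c(0, duration_ms))
      })
    })
  )
}
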