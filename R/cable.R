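# Spatial discretization and the tree solver.
#
# The d_lambda rule sets each section's compartment count from the AC
# length constant at 100 Hz; compartment membrane areas come from frustum
# sums over the 3D geometry and axial conductances from the integral of
# Ra / (pi r(l)^2) over half-compartments (closed form for linear taper).

#' Passive membrane parameters
#'
#' Typical CA1 values; all configurable.
#'
#' @param Cm specific capacitance, uF/cm2
#' @param Ra axial resistivity, ohm cm
#' @param g_leak leak conductance density, S/cm2
#' @param E_leak leak reversal, mV
#' @return list of passive parameters
#' @export
passive_params <- function(Cm = 1, Ra = 150, g_leak = 2.5e-5, E_leak = -65) {
  stopifnot(Cm > 0, Ra > 0, g_leak > 0)
  list(Cm = Cm, Ra = Ra, g_leak = g_leak, E_leak = E_leak)
}

#' Compartment count from the d_lambda rule
#'
#' The AC length constant at frequency `f` is
#' `lambda_f = 1e5 * sqrt(diam / (4 pi f Ra Cm))` (um), and the compartment
#' count is the smallest odd integer consistent with the published rounding
#' `floor((L / (d_lambda * lambda_f) + 0.9) / 2) * 2 + 1`.
#'
#' @param length section length, um
#' @param diam section diameter, um
#' @param Ra axial resistivity, ohm cm
#' @param Cm specific capacitance, uF/cm2
#' @param d_lambda fraction of lambda_f per compartment (default 0.1)
#' @param f frequency, Hz (default 100)
#' @return odd positive integer
#' @export
d_lambda_nseg <- function(length, diam, Ra = 150, Cm = 1, d_lambda = 0.1, f = 100) {
  if (any(c(length, diam, Ra, Cm, d_lambda, f) <= 0))
    stop("parameter error: d_lambda_nseg requires positive inputs")
  lambda_f <- 1e5 * sqrt(diam / (4 * pi * f * Ra * Cm))
  as.integer(floor((length / (d_lambda * lambda_f) + 0.9) / 2) * 2 + 1)
}

# interpolated radius at arc position s within a section's geometry
.interp_r <- function(g, s) {
  stats::approx(g$arc, g$r, xout = s, rule = 2)$y
}

# integral of dl / r(l)^2 over [s1, s2] for piecewise-linear r(l);
# closed form per piece: dl / (r_a * r_b)
.axial_integral <- function(g, s1, s2) {
  if (s2 <= s1) return(0)
  brk <- sort(unique(c(s1, s2, g$arc[g$arc > s1 & g$arc < s2])))
  tot <- 0
  for (k in seq_len(length(brk) - 1L)) {
    a <- brk[k]; b <- brk[k + 1L]
    ra <- .interp_r(g, a); rb <- .interp_r(g, b)
    tot <- tot + (b - a) / (ra * rb)
  }
  tot
}

# frustum lateral area over [s1, s2], um^2
.area_integral <- function(g, s1, s2) {
  if (s2 <= s1) return(0)
  brk <- sort(unique(c(s1, s2, g$arc[g$arc > s1 & g$arc < s2])))
  tot <- 0
  for (k in seq_len(length(brk) - 1L)) {
    a <- brk[k]; b <- brk[k + 1L]
    tot <- tot + pi * (.interp_r(g, a) + .interp_r(g, b)) * (b - a)
  }
  tot
}

#' Discretize a morphology into a Hines-ordered compartment grid
#'
#' @param m a `ca1_morphology`
#' @param p passive parameters from [passive_params()]
#' @param d_lambda discretization fraction (default 0.1)
#' @param nseg_override optional named integer vector (by section index) or a
#'   single integer forcing the compartment count of every section
#' @return a `ca1_grid`: data frame with one row per compartment
#'   (comp, section, pos, length_um, diam_um, area_cm2, parent,
#'   g_axial_uS, dist_um) plus `morphology`, `passive` attributes
#' @export
build_grid <- function(m, p = passive_params(), d_lambda = 0.1,
                       nseg_override = NULL) {
  s <- m$sections
  nsec <- nrow(s)
  if (any(s$length <= 0)) stop("discretization error: zero-length section")

  nseg <- integer(nsec)
  for (i in seq_len(nsec)) {
    nseg[i] <- d_lambda_nseg(s$length[i], s$diam[i], p$Ra, p$Cm, d_lambda)
  }
  if (!is.null(nseg_override)) {
    if (length(nseg_override) == 1L && is.null(names(nseg_override))) {
      nseg[] <- as.integer(nseg_override)
    } else {
      idx <- as.integer(names(nseg_override))
      nseg[idx] <- as.integer(nseg_override)
    }
  }
  if (any(nseg %% 2L == 0L)) stop("discretization error: even compartment count")

  comp_section <- integer(0); comp_pos <- numeric(0)
  comp_len <- numeric(0); comp_diam <- numeric(0); comp_area <- numeric(0)
  comp_parent <- integer(0); comp_gax <- numeric(0)
  first_comp <- integer(nsec); last_comp <- integer(nsec)
  half_res_dist <- numeric(0)   # MOhm from compartment centre to distal end

  # axial resistance helper: Ra * integral(dl / (pi r^2)), um -> Mohm
  # Ra [ohm cm] * (um / um^2) = ohm * 1e4 * 1e-6... work it out once:
  # l in um = 1e-4 cm, r in um: integral dl/r^2 [1/um] -> cm^-1 requires
  # *1e4; R = Ra/pi * I[1/um] * 1e4 ohm = Ra/pi * I * 1e-2 Mohm
  res_Mohm <- function(g, s1, s2) p$Ra / pi * .axial_integral(g, s1, s2) * 1e-2

  ci <- 0L
  for (i in seq_len(nsec)) {
    g <- m$geom[[i]]
    L <- s$length[i]
    ns <- nseg[i]
    bounds <- seq(0, L, length.out = ns + 1L)
    for (k in seq_len(ns)) {
      ci <- ci + 1L
      a <- bounds[k]; b <- bounds[k + 1L]
      mid <- (a + b) / 2
      ar_um2 <- .area_integral(g, a, b)
      len <- b - a
      comp_section[ci] <- i
      comp_pos[ci] <- mid / L
      comp_len[ci] <- len
      comp_diam[ci] <- ar_um2 / (pi * len)
      comp_area[ci] <- ar_um2 * 1e-8          # um^2 -> cm^2
      r_up <- res_Mohm(g, a, mid)             # centre to proximal boundary
      r_dn <- res_Mohm(g, mid, b)             # centre to distal boundary
      half_res_dist[ci] <- r_dn
      if (k == 1L) {
        first_comp[i] <- ci
        comp_parent[ci] <- NA_integer_        # resolved below
        comp_gax[ci] <- r_up                  # stash half-resistance
      } else {
        comp_parent[ci] <- ci - 1L
        comp_gax[ci] <- 1 / (r_up + half_res_dist[ci - 1L])
      }
    }
    last_comp[i] <- ci
  }
  n <- ci

  # connect first compartments across sections
  for (i in seq_len(nsec)) {
    ci <- first_comp[i]
    pseq <- s$parent[i]
    if (pseq == 0L) {
      comp_parent[ci] <- 0L
      comp_gax[ci] <- 0
    } else if (s$structure[pseq] == "soma") {
      # attach at the soma centre: only the child's half-resistance
      comp_parent[ci] <- first_comp[pseq] + (nseg[pseq] %/% 2L)
      comp_gax[ci] <- 1 / comp_gax[ci]
    } else {
      # attach at parent position 1.0: parent's distal half-resistance
      pc <- last_comp[pseq]
      comp_parent[ci] <- pc
      comp_gax[ci] <- 1 / (comp_gax[ci] + half_res_dist[pc])
    }
  }

  grid <- data.frame(
    comp = seq_len(n), section = comp_section, pos = comp_pos,
    length_um = comp_len, diam_um = comp_diam, area_cm2 = comp_area,
    parent = comp_parent, g_axial_uS = comp_gax,
    dist_um = path_distance(m, comp_section, comp_pos))
  grid$region <- NA_character_
  stopifnot(all(grid$parent < grid$comp))   # Hines ordering
  structure(list(compartments = grid, nseg = nseg, morphology = m,
                 passive = p, d_lambda = d_lambda),
            class = "ca1_grid")
}

#' @export
print.ca1_grid <- function(x, ...) {
  cat("ca1_grid:", nrow(x$compartments), "compartments over",
      length(x$nseg), "sections (d_lambda =", x$d_lambda, ")\n")
  invisible(x)
}

#' Locate the compartment containing a (section, position) location
#'
#' @param grid a `ca1_grid`
#' @param section section index
#' @param pos position in `[0, 1]`
#' @return compartment index
#' @export
compartment_at <- function(grid, section, pos) {
  ns <- grid$nseg[section]
  k <- pmin(pmax(floor(pos * ns), 0), ns - 1L)
  idx <- which(grid$compartments$section == section)[1]
  as.integer(idx + k)
}

#' Exact O(n) solve of a tree-structured symmetric linear system
#'
#' The system matrix has diagonal `diag`, and `off[i]` couples compartment
#' `i` to `parent[i]` (symmetric). One down-sweep eliminates children into
#' parents; one up-sweep back-substitutes.
#'
#' @param parent integer vector, 0 for the root, `parent[i] < i` otherwise
#' @param diag diagonal entries
#' @param off off-diagonal entries (entry for the root is ignored)
#' @param rhs right-hand side
#' @return solution vector
#' @export
hines_solve <- function(parent, diag, off, rhs) {
  stopifnot(length(diag) == length(parent), length(rhs) == length(parent))
  .hines_solve_cpp(as.integer(parent) - 1L, as.numeric(diag),
                   as.numeric(off), as.numeric(rhs))
}
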