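# Cell assembly: compose morphology + grid + mechanism distributions into a
# runnable cell, and apply the knockout / localization / gradient
# manipulations studied in the experiments.

.REGION_LEVELS <- c("soma", "axon", "basal", "apical_primary",
                    "apical_oblique", "apical_tuft", "other")
.APICAL_REGIONS <- c("apical_primary", "apical_oblique", "apical_tuft")

#' Build a runnable cell model
#'
#' Discretizes the morphology, classifies apical regions, and resolves the
#' configured mechanism distributions into per-compartment density vectors.
#' Wildtype means every configured mechanism present in all of its listed
#' regions.
#'
#' @param m a `ca1_morphology`
#' @param config parameter list from [default_config()]
#' @param d_lambda discretization fraction
#' @return a `ca1_cell`
#' @export
build_cell <- function(m, config = default_config(), d_lambda = 0.1) {
  p <- passive_params(Cm = config$passive$cm, Ra = config$passive$ra,
                      g_leak = config$passive$g_pas, E_leak = config$passive$e_pas)
  grid <- build_grid(m, p, d_lambda)
  regions <- classify_apical_regions(m)
  comp <- grid$compartments
  comp$region <- regions[comp$section]
  grid$compartments <- comp

  cell <- structure(list(morphology = m, grid = grid, regions = regions,
                         config = config, densities = NULL,
                         manipulations = list()),
                    class = "ca1_cell")
  cell$densities <- .resolve_densities(cell)
  cell$wildtype_densities <- cell$densities
  cell
}

# wildtype per-compartment density vectors from the config distributions
.resolve_densities <- function(cell) {
  comp <- cell$grid$compartments
  cfg <- cell$config
  n <- nrow(comp)
  reg <- comp$region
  dend <- reg %in% c("basal", .APICAL_REGIONS)

  gna <- numeric(n)
  gna[reg == "soma"] <- cfg$na$gbar_soma
  gna[reg == "axon"] <- cfg$na$gbar_axon
  gna[dend] <- cfg$na$gbar_dend

  gkdr <- numeric(n)
  gkdr[reg == "soma"] <- cfg$kdr$gbar_soma
  gkdr[reg == "axon"] <- cfg$kdr$gbar_axon
  gkdr[dend] <- cfg$kdr$gbar_dend

  gka <- numeric(n)
  gka[dend | reg == "soma"] <-
    cfg$ka$gbar * (1 + cfg$ka$dist_factor_per_100um *
                     comp$dist_um[dend | reg == "soma"] / 100)

  gcal <- numeric(n)
  gcal[reg == "soma" | reg %in% .APICAL_REGIONS] <- cfg$cal$gbar

  gkca <- numeric(n)
  gkca[reg %in% c("soma", "basal", .APICAL_REGIONS)] <- cfg$kca$gbar

  ncx_vmax <- numeric(n)
  ncx_vmax[reg %in% c("soma", "basal", .APICAL_REGIONS)] <- cfg$ncx$vmax

  list(
    g_pas = rep(cfg$passive$g_pas, n),
    e_pas = rep(cfg$passive$e_pas, n),
    gna = gna, gkdr = gkdr, gka = gka, gcal = gcal, gkca = gkca,
    ncx_vmax = ncx_vmax,
    ncx_alloscale = rep(1, n)
  )
}

#' @export
print.ca1_cell <- function(x, ...) {
  cat("ca1_cell:", nrow(x$grid$compartments), "compartments;",
      if (length(x$manipulations)) paste(length(x$manipulations), "manipulation(s)")
      else "wildtype", "\n")
  invisible(x)
}

.MECH_DENSITY <- c(ncx = "ncx_vmax", kca = "gkca", na = "gna", kdr = "gkdr",
                   ka = "gka", cal = "gcal")

#' Localize a mechanism to a set of regions (or knock it out)
#'
#' Density is kept at its wildtype value inside the listed regions and set
#' to zero everywhere else. An empty region set is a full knockout.
#' Manipulations compose (e.g. a double knockout of `ncx` and `kca`).
#'
#' @param cell a `ca1_cell`
#' @param mechanism one of `ncx`, `kca`, `na`, `kdr`, `ka`, `cal`
#' @param regions character vector of region labels (possibly empty)
#' @return the modified cell
#' @export
apply_localization <- function(cell, mechanism, regions = character(0)) {
  if (!mechanism %in% names(.MECH_DENSITY))
    stop("configuration error: unknown mechanism '", mechanism, "'")
  bad <- setdiff(regions, .REGION_LEVELS)
  if (length(bad)) stop("configuration error: unknown region(s) ",
                        paste(bad, collapse = ", "))
  field <- .MECH_DENSITY[[mechanism]]
  base <- cell$wildtype_densities[[field]]
  mask <- cell$grid$compartments$region %in% regions
  cell$densities[[field]] <- ifelse(mask, base, 0)
  cell$manipulations <- c(cell$manipulations,
                          list(list(type = "localize", mechanism = mechanism,
                                    regions = regions)))
  cell
}

#' Apply a linear spatial gradient to exchanger density or allostery
#'
#' The per-compartment factor grows linearly with path distance from the
#' proximal to the distal anchor of the targeted apical region:
#' `f(d) = v_prox + (v_dist - v_prox) (d - d_min)/(d_max - d_min)`.
#' `property = "density"` scales the exchanger `Vmax`;
#' `property = "allostery"` scales the allosteric factor (the engine clamps
#' the product at 1). The default endpoints (0.5, 1.5) keep the mean factor
#' at 1, so gradient and constant models hold total capacity comparable.
#'
#' @param cell a `ca1_cell`
#' @param mechanism mechanism name (gradients target the exchanger)
#' @param property `"density"` or `"allostery"`
#' @param v_prox,v_dist factor at the proximal / distal anchor
#' @param regions apical region labels carrying the gradient
#' @return the modified cell
#' @export
apply_linear_gradient <- function(cell, mechanism = "ncx",
                                  property = c("density", "allostery"),
                                  v_prox = 0.5, v_dist = 1.5,
                                  regions = .APICAL_REGIONS) {
  property <- match.arg(property)
  if (!mechanism %in% names(.MECH_DENSITY))
    stop("configuration error: unknown mechanism '", mechanism, "'")
  comp <- cell$grid$compartments
  mask <- comp$region %in% regions
  if (!any(mask)) stop("configuration error: no compartments in the target regions")
  d <- comp$dist_um[mask]
  if (max(d) - min(d) < 1e-9)
    stop("configuration error: degenerate gradient (d_max == d_min)")
  fac <- v_prox + (v_dist - v_prox) * (d - min(d)) / (max(d) - min(d))
  if (property == "density") {
    field <- .MECH_DENSITY[[mechanism]]
    cell$densities[[field]][mask] <- cell$densities[[field]][mask] * fac
  } else {
    cell$densities$ncx_alloscale[mask] <- cell$densities$ncx_alloscale[mask] * fac
  }
  cell$manipulations <- c(cell$manipulations,
                          list(list(type = "gradient", mechanism = mechanism,
                                    property = property, v_prox = v_prox,
                                    v_dist = v_dist, regions = regions)))
  cell
}

#' Revert all manipulations
#'
#' @param cell a `ca1_cell`
#' @return the wildtype cell
#' @export
revert_manipulations <- function(cell) {
  cell$densities <- cell$wildtype_densities
  cell$manipulations <- list()
  cell
}

#' Apply a named experimental condition
#'
#' Condition labels follow the experiment taxonomy: `wt`, `ncx_ko`,
#' `ncx_prim`, `ncx_obq`, `ncx_tuft`, `ncx_density_li`, `ncx_allostery_li`,
#' `ncx_density_allostery_li`, `cagk_ko`, `cagk_prim`, `cagk_obq`,
#' `cagk_tuft`, `cagk_ncx_ko`.
#'
#' @param cell a wildtype `ca1_cell`
#' @param condition label
#' @return the manipulated cell
#' @export
apply_condition <- function(cell, condition) {
  cell <- revert_manipulations(cell)
  loc <- function(mech, regs) apply_localization(cell, mech, regs)
  all_regions <- c("soma", "basal", .APICAL_REGIONS)
  switch(condition,
    wt = cell,
    ncx_ko = loc("ncx", character(0)),
    ncx_prim = loc("ncx", "apical_primary"),
    ncx_obq = loc("ncx", "apical_oblique"),
    ncx_tuft = loc("ncx", "apical_tuft"),
    ncx_density_li = {
      cell <- apply_localization(cell, "ncx", "apical_primary")
      apply_linear_gradient(cell, "ncx", "density", regions = "apical_primary")
    },
    ncx_allostery_li = {
      cell <- apply_localization(cell, "ncx", "apical_primary")
      apply_linear_gradient(cell, "ncx", "allostery", regions = "apical_primary")
    },
    ncx_density_allostery_li = {
      cell <- apply_localization(cell, "ncx", "apical_primary")
      cell <- apply_linear_gradient(cell, "ncx", "density", regions = "apical_primary")
      apply_linear_gradient(cell, "ncx", "allostery", regions = "apical_primary")
    },
    cagk_ko = loc("kca", character(0)),
    cagk_prim = loc("kca", "apical_primary"),
    cagk_obq = loc("kca", "apical_oblique"),
    cagk_tuft = loc("kca", "apical_tuft"),
    cagk_ncx_ko = {
      cell <- apply_localization(cell, "ncx", character(0))
      apply_localization(cell, "kca", character(0))
    },
    stop("configuration error: unknown condition '", condition, "'")
  )
}
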