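#' Oxygen and glucose descriptions for static culture
#'
#' Literature-style defaults for the nutrient viability model; the source
#' design's exact uptake constants are not published, so these are declared
#' package defaults, overridable per call and echoed into every result.
#'
#' Oxygen: D 3.0e-9 (medium) / 2.0e-9 (tissue) m^2/s, air-saturated medium
#' 0.2 mol/m^3 at the top (Dirichlet, the medium-air interface resupplies
#' it), Vmax 2.0e-3 mol/(m^3 s), Km 5e-3 mol/m^3.  Glucose: D 9.0e-10 /
#' 6.0e-10 m^2/s, initial reservoir 25 mol/m^3, no top resupply (no-flux),
#' Vmax 1.5e-3 mol/(m^3 s), Km 0.5 mol/m^3.
#'
#' @param C_sat dissolved-oxygen saturation, mol/m^3.
#' @param Vmax,Km Michaelis-Menten constants, mol/(m^3 s) and mol/m^3.
#' @return A list with \code{$species} ([species_params()]), the top
#'   boundary type/value and the initial concentration.
#' @export
oxygen_species <- function(C_sat = 0.2, Vmax = 2.0e-3, Km = 5e-3) {
  list(species = species_params("oxygen", D_medium = 3.0e-9,
                                D_tissue = 2.0e-9,
                                uptake = mm_kinetics(Vmax, Km)),
       top = "dirichlet", C_top = C_sat, C_init = C_sat)
}

#' @rdname oxygen_species
#' @param C_glc0 initial glucose concentration of fresh medium, mol/m^3.
#' @export
glucose_species <- function(C_glc0 = 25, Vmax = 1.5e-3, Km = 0.5) {
  list(species = species_params("glucose", D_medium = 9.0e-10,
                                D_tissue = 6.0e-10,
                                uptake = mm_kinetics(Vmax, Km)),
       top = "noflux", C_top = NA_real_, C_init = C_glc0)
}

#' Unit-cell static-culture domain
#'
#' One microwell plus its share of the overlying medium, standing in for
#' the periodic array: an axisymmetric column whose outer radius gives the
#' same area as the square unit cell (side = well pitch), with symmetry
#' (no-flux) side boundaries.  The default 1000 um medium depth corresponds
#' to 400 uL spread over the ~2 x 2 cm slab.
#'
#' @param tissue a [tissue_model()] seated at the well bottom.
#' @param medium_depth_um medium column above the array surface, um.
#' @param well_diameter_um,well_depth_um well size, um.
#' @param unit_cell_pitch_um well pitch of the array, um.
#' @param dr_um,dz_um grid resolution, um.
#' @return An [axi_domain()] with attribute \code{culture} recording the
#'   construction parameters.
#' @export
static_culture_domain <- function(tissue = tissue_model("sphere", 500),
                                  medium_depth_um = 1000,
                                  well_diameter_um = 700,
                                  well_depth_um = 900,
                                  unit_cell_pitch_um = 1500,
                                  dr_um = 25, dz_um = 25) {
  stopifnot(medium_depth_um > 0)
  R_cell <- unit_cell_pitch_um / sqrt(pi)  # equal-area circle
  nr <- round(R_cell / dr_um)
  nz <- round((well_depth_um + medium_depth_um) / dz_um)
  r <- (seq_len(nr) - 0.5) * dr_um
  z <- (seq_len(nz) - 0.5) * dz_um
  mat <- matrix(1L, nr, nz)
  mat[outer(r, z, function(r, z) r > well_diameter_um / 2 & z < well_depth_um)] <- 0L
  if (!is.null(tissue)) {
    if (tissue$diameter_um > well_diameter_um)
      stop("tissue diameter exceeds the well diameter")
    tr <- tissue$diameter_um / 2
    tis <- if (tissue$shape == "sphere")
      outer(r, z, function(r, z) r^2 + (z - tr)^2 < tr^2)
    else outer(r, z, function(r, z) r < tr & z < tissue$height_um)
    mat[tis] <- 2L
  }
  d <- axi_domain(mat, dr_um, dz_um, top_bc = "noflux")
  attr(d, "culture") <- list(medium_depth_um = medium_depth_um,
                             well_depth_um = well_depth_um,
                             well_diameter_um = well_diameter_um,
                             unit_cell_pitch_um = unit_cell_pitch_um,
                             tissue = tissue)
  d
}

#' Simulate static-culture nutrient viability
#'
#' Independent reaction--diffusion solves (one per species) for a tissue in
#' a microwell between medium changes: oxygen is resupplied at the
#' medium--air interface, glucose only by the finite medium reservoir; both
#' are consumed by Michaelis--Menten uptake in the tissue.  Viability is
#' read as the minimum tissue concentration staying at or above Km.
#'
#' @param domain a [static_culture_domain()].
#' @param species list of species descriptions as returned by
#'   [oxygen_species()] / [glucose_species()].
#' @param t_end simulated span, s (default 24 h).
#' @param dt time step, s.
#' @return A \code{viability_result}: per species the minimum-in-tissue
#'   time series, \code{time_below_Km} (s, or \code{Inf} for "never"),
#'   the mass ledger, and the parameters used.
#' @export
simulate_static_culture <- function(domain,
                                    species = list(oxygen_species(),
                                                   glucose_species()),
                                    t_end = 86400, dt = 60) {
  stopifnot(inherits(domain, "axi_domain"))
  res <- list()
  for (sp in species) {
    if (is.null(sp$species$uptake))
      stop("viability species need Michaelis-Menten parameters")
    dom <- domain
    dom$top_bc <- rep(sp$top, domain$nr)
    dom$top_bc[domain$material[, domain$nz] == 0L] <- "noflux"
    C0 <- matrix(sp$C_init, domain$nr, domain$nz)
    run <- axi_march(dom, sp$species, C0, t_end, dt,
                     bnd = if (identical(sp$top, "dirichlet")) sp$C_top else 0,
                     uptake = sp$species$uptake)
    below <- which(run$min_tissue < sp$species$uptake$Km)
    res[[sp$species$name]] <- list(
      times = run$times_fine, min_tissue = run$min_tissue,
      Km = sp$species$uptake$Km, C_init = sp$C_init, C_top = sp$C_top,
      time_below_Km = if (length(below)) run$times_fine[below[1]] else Inf,
      mass = run$mass, params = sp$species)
  }
  structure(list(species = res, t_end = t_end, dt = dt, domain = domain),
            class = "viability_result")
}

#' @export
print.viability_result <- function(x, ...) {
  cat(sprintf("Static-culture viability over %.1f h:\n", x$t_end / 3600))
  for (nm in names(x$species)) {
    s <- x$species[[nm]]
    cat(sprintf("  %s: min tissue concentration %.4g mol/m^3 (Km %.3g) -> %s\n",
                nm, min(s$min_tissue), s$Km,
                if (is.infinite(s$time_below_Km)) "stays above Km"
                else sprintf("falls below Km at %.2f h", s$time_below_Km / 3600)))
  }
  invisible(x)
}

#' Minimum tissue concentration at a time
#'
#' @param result a [simulate_static_culture()] result.
#' @param species species name ("oxygen" or "glucose").
#' @param t time, s (0 returns the initial concentration).
#' @return mol/m^3, linearly interpolated in time.
#' @export
min_core_concentration <- function(result, species, t) {
  s <- result$species[[species]]
  if (is.null(s)) stop("unknown species: ", species)
  if (t > result$t_end) stop("t exceeds the simulated span")
  stats::approx(c(0, s$times), c(s$C_init, s$min_tissue), xout = t)$y
}

#' Does the tissue survive until t?
#'
#' @inheritParams min_core_concentration
#' @return \code{TRUE} iff the minimum tissue concentration stayed at or
#'   above Km up to \code{t}.
#' @export
survives <- function(result, species, t = result$t_end) {
  s <- result$species[[species]]
  if (is.null(s)) stop("unknown species: ", species)
  s$time_below_Km > t
}

#' Medium-refresh sufficiency check
#'
#' With the reservoir reset at t = 0, can the tissue go \code{interval_s}
#' seconds (default 24 h, the typical medium refreshment interval) without
#' any species dropping below its Km?
#'
#' @param domain a [static_culture_domain()].
#' @param species as in [simulate_static_culture()].
#' @param interval_s refresh interval, s.
#' @param dt time step, s.
#' @return Named logical vector, one entry per species.
#' @export
medium_refresh_check <- function(domain,
                                 species = list(oxygen_species(),
                                                glucose_species()),
                                 interval_s = 86400, dt = 60) {
  if (interval_s < 0) stop("interval must be non-negative")
  if (interval_s == 0)
    return(stats::setNames(rep(TRUE, length(species)),
                           vapply(species, function(s) s$species$name, "")))
  res <- simulate_static_culture(domain, species, t_end = interval_s, dt = dt)
  vapply(res$species, function(s) s$time_below_Km > interval_s, logical(1))
}
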