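#' Species transport parameters
#'
#' @param name species name.
#' @param D_medium,D_tissue diffusivities in culture medium and in tissue,
#'   m^2/s.
#' @param uptake optional [mm_kinetics()]; absent means a conservative
#'   (non-consumed) species.
#' @return A \code{species_params} object.
#' @export
species_params <- function(name, D_medium, D_tissue = D_medium,
                           uptake = NULL) {
  stopifnot(D_medium > 0, D_tissue > 0)
  if (!is.null(uptake)) stopifnot(inherits(uptake, "mm_kinetics"))
  structure(list(name = name, D_medium = D_medium, D_tissue = D_tissue,
                 uptake = uptake),
            class = "species_params")
}

#' Michaelis-Menten uptake kinetics
#'
#' Saturating consumption rate \eqn{R(C) = V_{max} C / (K_m + C)}: maximal
#' at nutrient abundance, first-order below the half-saturation
#' concentration \code{Km}, which doubles as the viability threshold.
#'
#' @param Vmax maximal volumetric uptake, mol/(m^3 s).
#' @param Km half-saturation concentration, mol/m^3.
#' @export
mm_kinetics <- function(Vmax, Km) {
  stopifnot(Vmax >= 0, Km > 0)
  structure(list(Vmax = Vmax, Km = Km), class = "mm_kinetics")
}

#' Default reagent species
#'
#' Reagent transport uses the diffusion coefficient of glucose in water
#' (9.0e-10 m^2/s at 37 C; 6.7e-10 at 25 C is selectable), in medium and
#' tissue alike, and no uptake.
#'
#' @param temperature_C 37 (default) or 25.
#' @export
reagent_species <- function(temperature_C = 37) {
  D <- if (temperature_C == 25) 6.7e-10 else 9.0e-10
  species_params("reagent", D_medium = D, D_tissue = D)
}

#' Axisymmetric well + tissue domain
#'
#' One microwell (default 700 um diameter x 900 um deep) with a tissue
#' model seated at the bottom, discretised in (r, z).  The well mouth (top)
#' is a Dirichlet boundary at the streamed concentration; walls and bottom
#' are no-flux.  A mixed layer of depth \code{mixed_depth_um} below the
#' mouth can be declared well-stirred (diffusivity inflated) to emulate
#' convective stirring by the gap flow; the default 0 is the conservative
#' pure-diffusion choice.
#'
#' @param tissue a [tissue_model()] or NULL for an empty well.
#' @param well_diameter_um,well_depth_um well size, um.
#' @param mixed_depth_um well-mixed layer depth below the mouth, um.
#' @param dr_um,dz_um grid resolution, um.
#' @return An [axi_domain()] with attribute \code{well} recording the
#'   construction parameters.
#' @export
well_domain <- function(tissue = tissue_model("sphere", 500),
                        well_diameter_um = 700, well_depth_um = 900,
                        mixed_depth_um = 0, dr_um = 12.5, dz_um = 12.5) {
  R <- well_diameter_um / 2
  nr <- round(R / dr_um); nz <- round(well_depth_um / dz_um)
  mat <- matrix(1L, nr, nz)
  r <- (seq_len(nr) - 0.5) * dr_um
  z <- (seq_len(nz) - 0.5) * dz_um
  if (!is.null(tissue)) {
    if (tissue$diameter_um > well_diameter_um)
      stop("tissue diameter exceeds the well diameter")
    if (mixed_depth_um > well_depth_um - tissue$height_um)
      stop("mixed layer would overlap the tissue")
    tr <- tissue$diameter_um / 2
    tis <- if (tissue$shape == "sphere") {
      outer(r, z, function(r, z) r^2 + (z - tr)^2 < tr^2)
    } else {
      outer(r, z, function(r, z) r < tr & z < tissue$height_um)
    }
    mat[tis] <- 2L
  }
  mixed <- NULL
  if (mixed_depth_um > 0)
    mixed <- outer(r, z, function(r, z) z > well_depth_um - mixed_depth_um)
  d <- axi_domain(mat, dr_um, dz_um, top_bc = "dirichlet",
                  mixed_cells = mixed)
  attr(d, "well") <- list(well_diameter_um = well_diameter_um,
                          well_depth_um = well_depth_um,
                          mixed_depth_um = mixed_depth_um, tissue = tissue)
  d
}

#' Sphere-in-bath validation domain
#'
#' A tissue sphere centred in a well-stirred bath box, used to cross-check
#' the solver against the textbook transient series solution for a sphere
#' with fixed surface concentration.  Pass a species whose \code{D_medium}
#' is much larger than \code{D_tissue} so the bath is effectively uniform.
#'
#' @param radius_um sphere radius, um.
#' @param bath_margin_um bath thickness around the sphere, um.
#' @param dr_um,dz_um grid resolution, um.
#' @export
sphere_in_bath_domain <- function(radius_um = 250, bath_margin_um = 100,
                                  dr_um = 10, dz_um = 10) {
  ext <- radius_um + bath_margin_um
  nr <- round(ext / dr_um); nz <- round(2 * ext / dz_um)
  r <- (seq_len(nr) - 0.5) * dr_um
  z <- (seq_len(nz) - 0.5) * dz_um
  mat <- matrix(1L, nr, nz)
  mat[outer(r, z, function(r, z) r^2 + (z - ext)^2 < radius_um^2)] <- 2L
  axi_domain(mat, dr_um, dz_um, top_bc = "dirichlet")
}

#' Simulate reagent transport into a well
#'
#' Diffusive transport (plus optional Michaelis-Menten uptake and
#' mixed-layer stirring) of a species streamed over the well mouth at
#' concentration \code{C_mouth}.
#'
#' @param domain a [well_domain()] (or any [axi_domain()] with a Dirichlet
#'   top).
#' @param species a [species_params()].
#' @param C_mouth mouth concentration: a constant or a function of time (s).
#' @param t_end,dt simulated span and step, s.  The implicit scheme is
#'   unconditionally stable; \code{scheme = "explicit"} enforces
#'   \code{dt <= 0.25 min(dr, dz)^2 / max(D)} and refuses otherwise.
#' @param save_times times (s) at which full fields are stored (default 51
#'   evenly spaced frames).
#' @param C0 initial concentration (default 0).
#' @return A \code{concentration_history}: saved \code{frames} (r, z, time),
#'   per-step tissue minima, region masks, a mass ledger
#'   (\code{$mass$closure} is the relative balance error), and provenance.
#' @export
simulate_well_transport <- function(domain, species = reagent_species(),
                                    C_mouth = 1, t_end = 1500, dt = 2,
                                    save_times = NULL, C0 = 0,
                                    scheme = c("implicit", "explicit")) {
  scheme <- match.arg(scheme)
  C0m <- if (is.matrix(C0)) C0 else matrix(C0, domain$nr, domain$nz)
  uptake <- species$uptake
  run <- axi_march(domain, species, C0m, t_end, dt, bnd = C_mouth,
                   uptake = uptake, save_times = save_times,
                   scheme = scheme)
  cm_end <- if (is.function(C_mouth)) C_mouth(t_end) else C_mouth
  structure(c(run, list(domain = domain, species = species,
                        C_mouth = C_mouth, C_mouth_final = cm_end)),
            class = "concentration_history")
}

#' @export
print.concentration_history <- function(x, ...) {
  cat(sprintf("Concentration history: %s, %d frames over %.0f s (dt = %.2g s, %s)\n",
              x$species$name, length(x$save_times),
              max(x$times_fine), x$dt, x$scheme))
  if (any(x$tissue))
    cat(sprintf("  final tissue minimum: %.4g (mouth %.4g)\n",
                x$min_tissue[length(x$min_tissue)], x$C_mouth_final))
  cat(sprintf("  mass-balance closure error: %.2g\n", x$mass$closure))
  invisible(x)
}

#' Time for the tissue to reach steady state
#'
#' First time at which the minimum concentration over the tissue region
#' reaches \code{threshold} of the mouth concentration, linearly
#' interpolated between steps.  Returns \code{NA} (with a message attribute)
#' if the threshold is not crossed within the simulated span.
#'
#' @param history a [simulate_well_transport()] result.
#' @param threshold fraction of the mouth concentration (default 0.95).
#' @return Time in seconds (0 if \code{threshold <= 0}).
#' @export
time_to_steady_state <- function(history, threshold = 0.95) {
  if (threshold <= 0) return(0)
  target <- threshold * history$C_mouth_final
  frac <- history$min_tissue
  t <- history$times_fine
  above <- which(frac >= target)
  if (!length(above))
    return(structure(NA_real_, message = "not reached by t_end"))
  k <- above[1]
  if (k == 1) return(t[1])
  t[k - 1] + (target - frac[k - 1]) / (frac[k] - frac[k - 1]) *
    (t[k] - t[k - 1])
}

#' Bound-dye accumulation and fluorescence-intensity proxy
#'
#' Linear (non-saturating) dye binding: the bound dye at each point is
#' \eqn{B(x, t) = \int_0^t k_{bind} C(x, s) ds} (trapezoidal rule over the
#' stored frames); mean bound dye over the tissue is reported as the
#' fluorescence-intensity proxy.  A saturating option
#' \eqn{dB/dt = k_{bind} C (1 - B / B_{max})} is available but off by
#' default.
#'
#' @param history a [simulate_well_transport()] result.
#' @param k_bind binding rate constant, 1/s.
#' @param duration incubation time, s; must not exceed the simulated span.
#' @param B_max saturation level (Inf = linear accumulation).
#' @return A list: \code{B} (bound-dye map), \code{mean_fi} (tissue mean),
#'   \code{duration}.
#' @export
dye_accumulation <- function(history, k_bind, duration,
                             B_max = Inf) {
  if (k_bind < 0) stop("k_bind must be non-negative")
  st <- history$save_times
  if (duration > max(st) + 1e-9) stop("duration exceeds the simulated span")
  keep <- which(st <= duration + 1e-9)
  tt <- st[keep]
  if (length(tt) < 2) stop("need at least two stored frames before `duration`")
  nrz <- dim(history$frames)[1:2]
  B <- matrix(0, nrz[1], nrz[2])
  for (k in seq_len(length(tt) - 1)) {
    dtk <- tt[k + 1] - tt[k]
    Cmid <- (history$frames[, , keep[k]] + history$frames[, , keep[k + 1]]) / 2
    dB <- k_bind * Cmid * dtk
    if (is.finite(B_max)) dB <- dB * pmax(1 - B / B_max, 0)
    B <- B + dB
  }
  tis <- if (any(history$tissue)) history$tissue else history$liquid
  list(B = B, mean_fi = mean(B[tis]), duration = duration)
}
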