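# Axisymmetric (r, z) finite-volume diffusion engine.
#
# Cells are annular rings of size dr x dz; cell (i, j) has centre radius
# r_i = (i - 1/2) dr and volume 2 pi r_i dr dz.  Conductances between
# liquid cells use harmonic-mean diffusivities; solid cells carry no flux.
# The top boundary is, per column, either a Dirichlet concentration
# (half-cell conductance) or no-flux; all other outer boundaries are
# no-flux and the axis is a symmetry boundary.  Time stepping is backward
# Euler on the diffusion operator (one sparse Cholesky factorisation per
# (domain, D, dt)), with Michaelis-Menten uptake handled in a split
# sub-step solved exactly per cell (positive root of a quadratic), so the
# mass ledger closes to solver precision.

#' Axisymmetric simulation domain
#'
#' Low-level constructor; use [well_domain()], [static_culture_domain()] or
#' [sphere_in_bath_domain()] for the standard cases.
#'
#' @param material integer matrix (nr x nz): 0 solid, 1 medium, 2 tissue.
#'   Row i is the ring at radius (i - 1/2) * dr_um, column j the slab at
#'   height (j - 1/2) * dz_um above the domain floor.
#' @param dr_um,dz_um cell sizes, um.
#' @param top_bc character vector of length nr: "dirichlet" or "noflux"
#'   per top-face column (solid columns are forced to "noflux").
#' @param mixed_cells optional logical matrix marking a well-mixed region
#'   whose diffusivity is inflated (factor 1e3) to emulate convective
#'   stirring.
#' @return An object of class \code{axi_domain}.
#' @export
axi_domain <- function(material, dr_um, dz_um, top_bc = "noflux",
                       mixed_cells = NULL) {
  stopifnot(is.matrix(material), dr_um > 0, dz_um > 0)
  nr <- nrow(material); nz <- ncol(material)
  top_bc <- rep_len(top_bc, nr)
  top_bc[material[, nz] == 0L] <- "noflux"
  if (!is.null(mixed_cells)) stopifnot(dim(mixed_cells) == dim(material))
  structure(list(material = material, nr = nr, nz = nz,
                 dr_um = dr_um, dz_um = dz_um,
                 r_um = (seq_len(nr) - 0.5) * dr_um,
                 z_um = (seq_len(nz) - 0.5) * dz_um,
                 top_bc = top_bc, mixed_cells = mixed_cells),
            class = "axi_domain")
}

#' @export
print.axi_domain <- function(x, ...) {
  cat(sprintf("Axisymmetric domain: %d x %d cells (%.1f x %.1f um), r <= %.0f um, z <= %.0f um\n",
              x$nr, x$nz, x$dr_um, x$dz_um, x$nr * x$dr_um, x$nz * x$dz_um))
  cat(sprintf("  medium %d, tissue %d, solid %d cells; %d Dirichlet top columns\n",
              sum(x$material == 1L), sum(x$material == 2L),
              sum(x$material == 0L), sum(x$top_bc == "dirichlet")))
  invisible(x)
}

# Per-cell diffusivity (m^2/s) from a species description.
axi_cell_D <- function(domain, species, mix_factor = 1e3) {
  D <- matrix(0, domain$nr, domain$nz)
  D[domain$material == 1L] <- species$D_medium
  D[domain$material == 2L] <- species$D_tissue
  if (!is.null(domain$mixed_cells)) D[domain$mixed_cells] <- D[domain$mixed_cells] * mix_factor
  D
}

# Assemble volumes, conductances and the backward-Euler factorisation.
# Units: m, s; concentrations are whatever the caller uses.
axi_operator <- function(domain, D, dt) {
  nr <- domain$nr; nz <- domain$nz
  dr <- domain$dr_um * 1e-6; dz <- domain$dz_um * 1e-6
  liquid <- domain$material > 0L
  idx <- matrix(0L, nr, nz)
  idx[liquid] <- seq_len(sum(liquid))
  n <- sum(liquid)
  r_c <- (seq_len(nr) - 0.5) * dr
  V <- matrix(2 * pi * r_c * dr * dz, nr, nz)[liquid]

  ii <- integer(0); jj <- integer(0); gg <- numeric(0)
  hmean <- function(a, b) ifelse(a > 0 & b > 0, 2 * a * b / (a + b), 0)
  # radial faces between (i, j) and (i + 1, j)
  if (nr > 1) {
    for (i in seq_len(nr - 1)) {
      ok <- liquid[i, ] & liquid[i + 1, ]
      if (!any(ok)) next
      A <- 2 * pi * (i * dr) * dz
      G <- hmean(D[i, ok], D[i + 1, ok]) * A / dr
      ii <- c(ii, idx[i, ok]); jj <- c(jj, idx[i + 1, ok]); gg <- c(gg, G)
    }
  }
  # axial faces between (i, j) and (i, j + 1)
  if (nz > 1) {
    for (j in seq_len(nz - 1)) {
      ok <- liquid[, j] & liquid[, j + 1]
      if (!any(ok)) next
      A <- 2 * pi * r_c[ok] * dr
      G <- hmean(D[ok, j], D[ok, j + 1]) * A / dz
      ii <- c(ii, idx[ok, j]); jj <- c(jj, idx[ok, j + 1]); gg <- c(gg, G)
    }
  }
  # top Dirichlet half-cell conductances
  g_top <- numeric(n)
  dir_col <- which(domain$top_bc == "dirichlet" & liquid[, nz])
  if (length(dir_col)) {
    A <- 2 * pi * r_c[dir_col] * dr
    g_top[idx[dir_col, nz]] <- D[dir_col, nz] * A / (dz / 2)
  }
  G <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(gg, gg),
                            dims = c(n, n))
  deg <- Matrix::rowSums(G) + g_top
  L <- Matrix::Diagonal(n, deg) - G
  A_sys <- Matrix::forceSymmetric(Matrix::Diagonal(n, V) + dt * L)
  ch <- Matrix::Cholesky(A_sys, LDL = FALSE)
  list(idx = idx, liquid = liquid, n = n, V = V, g_top = g_top,
       L = L, A_sys = A_sys, ch = ch, dt = dt)
}

# March the diffusion(-uptake) problem.  C0: nr x nz initial field (solid
# entries ignored).  bnd: function(t) -> Dirichlet value at the top (scalar),
# or a constant.  uptake: NULL or list(Vmax, Km) applied to tissue cells.
# Returns fields sampled at save_times plus per-step tissue minima and a
# mass ledger.
axi_march <- function(domain, species, C0, t_end, dt, bnd = 0,
                      uptake = NULL, save_times = NULL,
                      scheme = c("implicit", "explicit")) {
  scheme <- match.arg(scheme)
  D <- axi_cell_D(domain, species)
  if (scheme == "explicit") {
    dmax <- max(D)
    dt_req <- 0.25 * min(domain$dr_um, domain$dz_um)^2 * 1e-12 / dmax
    if (dt > dt_req)
      stop(sprintf("explicit step unstable: need dt <= %.4g s", dt_req))
  }
  op <- axi_operator(domain, D, dt)
  bnd_fun <- if (is.function(bnd)) bnd else function(t) bnd
  tissue <- domain$material == 2L
  tis_id <- op$idx[tissue]
  Vmax <- Km <- NULL
  if (!is.null(uptake)) { Vmax <- uptake$Vmax; Km <- uptake$Km }

  nstep <- ceiling(t_end / dt)
  times_fine <- seq_len(nstep) * dt
  if (is.null(save_times)) save_times <- seq(0, t_end, length.out = 51)
  save_times <- sort(unique(pmin(save_times, t_end)))
  C <- C0[op$liquid]
  frames <- array(NA_real_, c(domain$nr, domain$nz, length(save_times)))
  fill_frame <- function(k, C) {
    f <- matrix(NA_real_, domain$nr, domain$nz)
    f[op$liquid] <- C
    frames[, , k] <<- f
  }
  saved <- rep(FALSE, length(save_times))
  hit0 <- which(save_times <= 0)
  for (k in hit0) { fill_frame(k, C); saved[k] <- TRUE }
  min_tis <- numeric(nstep)
  influx <- 0; consumed <- 0
  mass0 <- sum(op$V * C)
  for (s in seq_len(nstep)) {
    t_new <- s * dt
    cb <- bnd_fun(t_new)
    consumed_step <- 0
    if (scheme == "implicit") {
      rhs <- op$V * C + dt * op$g_top * cb
      if (is.null(uptake) || !length(tis_id)) {
        C_new <- as.numeric(Matrix::solve(op$ch, rhs))
      } else {
        # semi-implicit Michaelis-Menten: rate Vmax C_new / (Km + C_it),
        # Picard-iterated so the discrete steady state is exact
        C_it <- C
        for (it in seq_len(8L)) {
          k <- numeric(op$n)
          k[tis_id] <- Vmax / (Km + pmax(C_it[tis_id], 0))
          A <- op$A_sys + Matrix::Diagonal(op$n, dt * op$V * k)
          C_new <- as.numeric(Matrix::solve(Matrix::Cholesky(A, LDL = FALSE),
                                            rhs))
          if (max(abs(C_new - C_it)) < 1e-10 * max(abs(C_new), 1)) break
          C_it <- C_new
        }
        consumed_step <- dt * sum(op$V[tis_id] * k[tis_id] * C_new[tis_id])
      }
      influx <- influx + dt * sum(op$g_top * (cb - C_new))
    } else {
      cb_old <- bnd_fun(t_new - dt)
      r_up <- numeric(op$n)
      if (!is.null(uptake) && length(tis_id))
        r_up[tis_id] <- Vmax * pmax(C[tis_id], 0) / (Km + pmax(C[tis_id], 0))
      C_new <- C + dt / op$V *
        (as.numeric(-op$L %*% C) + op$g_top * cb_old) - dt * r_up
      influx <- influx + dt * sum(op$g_top * (cb_old - C))
      consumed_step <- dt * sum(op$V * r_up)
    }
    consumed <- consumed + consumed_step
    if (any(C_new < -1e-9)) warning("numerical undershoot clamped")
    C <- pmax(C_new, 0)
    min_tis[s] <- if (length(tis_id)) min(C[tis_id]) else NA_real_
    hit <- which(!saved & save_times <= t_new + 1e-9)
    for (k in hit) { fill_frame(k, C); saved[k] <- TRUE }
  }
  mass_end <- sum(op$V * C)
  list(save_times = save_times, frames = frames,
       times_fine = times_fine, min_tissue = min_tis,
       mass = list(initial = mass0, final = mass_end, influx = influx,
                   consumed = consumed,
                   final_uptake_rate = consumed_step / dt,
                   closure = abs(mass_end - mass0 - influx + consumed) /
                     max(abs(mass_end), abs(mass0), 1e-300)),
       liquid = op$liquid, tissue = tissue, dt = dt, scheme = scheme)
}
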