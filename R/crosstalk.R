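#' Inter-pixel crosstalk from a depth-averaged advection--diffusion solve
#'
#' Solves the steady depth-averaged advection--diffusion equation for the
#' reagent injected at each pixel (its source disk held at concentration 1,
#' all other sources at 0, aspiration apertures absorbing, bath inflow at 0)
#' and reports the mean concentration of each reagent within the region of
#' every pixel.  Entry \code{(i, j)} of the returned matrix is the mean
#' concentration of reagent \code{j} in the region of pixel \code{i}; the
#' off-diagonal entries are the foreign-fluid fractions (crosstalk).
#'
#' Two region definitions are supported.  \code{"wells"} (default) averages
#' over the microwell openings of each pixel group -- the locations where
#' tissue sits and the biologically meaningful crosstalk readout.
#' \code{"footprint"} averages over the full streamline-classified pixel
#' footprint; because each 6 mm footprint boundary carries an unavoidable
#' diffusive smear, footprint means include a boundary-layer contribution
#' that the well positions (>= 0.75 mm inside the boundary) do not see.
#'
#' With \code{by = "label"} one solve is performed per distinct reagent
#' label of \code{pattern} instead of one per pixel (columns are then
#' labels); this is what [crosstalk_free()] uses.
#'
#' @param geometry a [pcd_geometry()].
#' @param flow an [per_aperture_rates()] result.
#' @param cfg a [flow_config()] (viscosity is unused here).
#' @param pattern a [pixel_pattern()]; used for labels and grouping.
#' @param D_reagent reagent diffusivity, m^2/s (default 9e-10, glucose-like).
#' @param region "wells" or "footprint".
#' @param by "pixel" (9 solves, 9 x 9 matrix) or "label" (one solve per
#'   label).
#' @param grid_um solver cell size, um.  The upwind scheme adds numerical
#'   diffusion of order \code{u * dx / 2}; 25 um keeps it at the scale of
#'   the physical diffusivity at the operating speeds.
#' @param margin_mm domain margin beyond the tip edge (default 3).
#' @param array the [microwell_array()] (for \code{region = "wells"});
#'   defaults to the standard array on \code{geometry}.
#' @param tol,max_sweeps Gauss-Seidel stopping controls.
#' @return A \code{crosstalk} object: \code{matrix} (regions x sources),
#'   \code{mass_balance} (injected vs absorbed tracer, relative closure
#'   error), \code{peclet} and a \code{diffusion_dominated} flag (Peclet
#'   below 1 invalidates the confinement assumption), and solver
#'   diagnostics.
#' @export
crosstalk_matrix <- function(geometry, flow, cfg = flow_config(), pattern,
                             D_reagent = 9e-10,
                             region = c("wells", "footprint"),
                             by = c("pixel", "label"),
                             grid_um = 25, margin_mm = 3, array = NULL,
                             tol = 1e-7, max_sweeps = 4000L) {
  region <- match.arg(region)
  by <- match.arg(by)
  ap <- aperture_table(geometry, flow)
  src <- ap[ap$sign > 0, ]
  pitch_m <- geometry$pixel_pitch_um * 1e-6
  hx <- geometry$n_pixels_x / 2 * pitch_m + margin_mm * 1e-3
  hy <- geometry$n_pixels_y / 2 * pitch_m + margin_mm * 1e-3
  dx <- grid_um * 1e-6
  nx <- ceiling(2 * hx / dx); ny <- ceiling(2 * hy / dx)
  xc <- (seq_len(nx) - (nx + 1) / 2) * dx
  yc <- (seq_len(ny) - (ny + 1) / 2) * dx
  xf <- (0:nx - nx / 2) * dx
  yf <- (0:ny - ny / 2) * dx
  # face-normal velocities from the analytic superposition
  gu <- expand.grid(px = xf, py = yc)
  uf <- matrix(hs_velocity(gu$px, gu$py, ap)$u, nx + 1, ny)
  gv <- expand.grid(px = xc, py = yf)
  vf <- matrix(hs_velocity(gv$px, gv$py, ap)$v, nx, ny + 1)

  r_src <- geometry$aperture_radius_um * 1e-6
  cx <- matrix(xc, nx, ny); cy <- matrix(yc, nx, ny, byrow = TRUE)
  ctype <- matrix(0L, nx, ny)
  src_cell <- vector("list", nrow(src))
  for (k in seq_len(nrow(src))) {
    inside <- (cx - src$x[k])^2 + (cy - src$y[k])^2 < r_src^2
    ctype[inside] <- 1L
    src_cell[[k]] <- inside
  }
  # geometric pixel index of every cell (fast initial guess)
  px_tab <- geometry$pixels
  half <- pitch_m / 2
  cell_pixel <- matrix(0L, nx, ny)
  for (p in seq_len(nrow(px_tab))) {
    inside <- abs(cx - px_tab$x[p] * 1e-6) <= half &
      abs(cy - px_tab$y[p] * 1e-6) <= half
    cell_pixel[inside] <- px_tab$pixel[p]
  }
  # characteristic Peclet at half a pitch from a source
  u_char <- abs(src$strength[1]) / (pitch_m / 2)
  peclet <- u_char * pitch_m / D_reagent
  if (peclet < 1)
    warning("Peclet below 1: diffusion-dominated regime, flow confinement assumption invalid")

  labs <- pattern$assignment[as.character(seq_len(nrow(src)))]
  sources <- if (by == "pixel") as.list(seq_len(nrow(src))) else
    lapply(pattern$labels, function(l) which(labs == l))
  src_names <- if (by == "pixel") as.character(seq_len(nrow(src))) else
    pattern$labels

  region_cells <- crosstalk_regions(region, geometry, flow, cfg, array,
                                    cx, cy, cell_pixel)
  M <- matrix(NA_real_, length(region_cells), length(sources),
              dimnames = list(names(region_cells), src_names))
  diags <- list(); mass <- list()
  for (s in seq_along(sources)) {
    C <- matrix(0, nx, ny)
    C[cell_pixel %in% sources[[s]]] <- 1
    for (k in seq_len(nrow(src)))
      C[src_cell[[k]]] <- as.numeric(k %in% sources[[s]])
    sol <- ad_steady_gs(C, ctype, uf, vf, dx, D_reagent, tol,
                        as.integer(max_sweeps))
    diags[[s]] <- sol[c("sweeps", "converged", "max_change")]
    mass[[s]] <- ad_mass_audit(sol$C, ctype, uf, vf, dx, D_reagent)
    for (i in seq_along(region_cells))
      M[i, s] <- mean(sol$C[region_cells[[i]]])
  }
  structure(list(matrix = M, by = by, region = region,
                 peclet = peclet, diffusion_dominated = peclet < 1,
                 mass_balance = mass, solver = diags,
                 grid_um = grid_um, D_reagent = D_reagent,
                 pattern = pattern),
            class = "crosstalk")
}

# Cell index sets over which pixel-wise means are taken.
crosstalk_regions <- function(region, geometry, flow, cfg, array,
                              cx, cy, cell_pixel) {
  n_px <- nrow(geometry$pixels)
  if (region == "wells") {
    if (is.null(array)) array <- microwell_array(geometry)
    w <- array$wells
    r_w <- array$well_diameter_um / 2 * 1e-6
    out <- lapply(seq_len(n_px), function(p) {
      ww <- w[w$pixel == p, ]
      hit <- matrix(FALSE, nrow(cx), ncol(cx))
      for (i in seq_len(nrow(ww)))
        hit <- hit | ((cx - ww$x[i] * 1e-6)^2 + (cy - ww$y[i] * 1e-6)^2 < r_w^2)
      which(hit)
    })
  } else {
    fp <- pixel_footprints(geometry, flow, cfg, resolution_per_mm = 10)
    # nearest-neighbour lookup of the coarse footprint label at each cell
    dgx <- fp$x_mm[2] - fp$x_mm[1]
    ix <- round((cx[, 1] * 1e3 - fp$x_mm[1]) / dgx) + 1L
    iy <- round((cy[1, ] * 1e3 - fp$y_mm[1]) / dgx) + 1L
    ok_x <- ix >= 1 & ix <= length(fp$x_mm)
    ok_y <- iy >= 1 & iy <= length(fp$y_mm)
    lab_cell <- matrix(0L, nrow(cx), ncol(cx))
    lab_cell[ok_x, ok_y] <- fp$label[ix[ok_x], iy[ok_y]]
    out <- lapply(seq_len(n_px), function(p) which(lab_cell == p))
  }
  names(out) <- as.character(seq_len(n_px))
  out
}

# Tracer mass audit of a converged steady solution: injected flux out of the
# Dirichlet source cells vs tracer absorbed at sinks plus boundary outflux.
ad_mass_audit <- function(C, ctype, uf, vf, dx, D) {
  nx <- nrow(C); ny <- ncol(C)
  # interior vertical faces: flux (+x) between cell (i-1) and i, i = 2..nx
  u_in <- uf[2:nx, , drop = FALSE] * dx
  Fx <- pmax(u_in, 0) * C[1:(nx - 1), ] + pmin(u_in, 0) * C[2:nx, ] -
    D * (C[2:nx, ] - C[1:(nx - 1), ])
  v_in <- vf[, 2:ny, drop = FALSE] * dx
  Fy <- pmax(v_in, 0) * C[, 1:(ny - 1)] + pmin(v_in, 0) * C[, 2:ny] -
    D * (C[, 2:ny] - C[, 1:(ny - 1)])
  net <- matrix(0, nx, ny)
  net[2:nx, ] <- net[2:nx, ] + Fx
  net[1:(nx - 1), ] <- net[1:(nx - 1), ] - Fx
  net[, 2:ny] <- net[, 2:ny] + Fy
  net[, 1:(ny - 1)] <- net[, 1:(ny - 1)] - Fy
  # boundary faces: inflow carries C = 0, outflow leaves at the cell value
  bw <- uf[1, ] * dx;  net[1, ] <- net[1, ] + pmin(bw, 0) * C[1, ]
  be <- uf[nx + 1, ] * dx; net[nx, ] <- net[nx, ] - pmax(be, 0) * C[nx, ]
  bs <- vf[, 1] * dx;  net[, 1] <- net[, 1] + pmin(bs, 0) * C[, 1]
  bn <- vf[, ny + 1] * dx; net[, ny] <- net[, ny] - pmax(bn, 0) * C[, ny]
  boundary_out <- sum(pmax(be, 0) * C[nx, ]) - sum(pmin(bw, 0) * C[1, ]) +
    sum(pmax(vf[, ny + 1] * dx, 0) * C[, ny]) - sum(pmin(bs, 0) * C[, 1])
  dir <- ctype == 1L
  injected <- -sum(net[dir])       # net flux out of the source cells
  absorbed <- sum(net[!dir])       # sink absorption q * C at convergence
  list(injected = injected, absorbed = absorbed,
       boundary_out = boundary_out,
       closure = abs(injected - absorbed) / max(abs(injected), 1e-300))
}

#' @export
print.crosstalk <- function(x, ...) {
  off <- crosstalk_max_foreign(x)
  cat(sprintf("Crosstalk (%s means, %s solves, %.0f um grid): max foreign fraction %.3g\n",
              x$region, x$by, x$grid_um, off))
  invisible(x)
}

# Largest foreign-reagent fraction over all pixel regions.
crosstalk_max_foreign <- function(x) {
  labs <- x$pattern$assignment[rownames(x$matrix)]
  mx <- 0
  for (i in seq_len(nrow(x$matrix))) {
    foreign <- if (x$by == "label") colnames(x$matrix) != labs[i] else
      x$pattern$assignment[colnames(x$matrix)] != labs[i]
    if (any(foreign)) mx <- max(mx, x$matrix[i, foreign])
  }
  mx
}

#' Crosstalk-free verdict
#'
#' A display pattern is declared crosstalk-free when the mean foreign
#' reagent concentration in every pixel's well region stays below the given
#' threshold (default 1\%; the source text reports crosstalk-free operation
#' qualitatively, the number is a package decision).
#'
#' @inheritParams crosstalk_matrix
#' @param threshold foreign-concentration threshold (default 0.01).
#' @param ... passed to [crosstalk_matrix()].
#' @return Logical, with the crosstalk object as attribute
#'   \code{"crosstalk"}.
#' @export
crosstalk_free <- function(geometry, flow, cfg = flow_config(), pattern,
                           threshold = 0.01, ...) {
  ct <- crosstalk_matrix(geometry, flow, cfg, pattern, by = "label", ...)
  ok <- crosstalk_max_foreign(ct) < threshold
  attr(ok, "crosstalk") <- ct
  ok
}
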