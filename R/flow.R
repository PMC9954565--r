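#' Per-aperture flow rates
#'
#' Splits the operating flow rates over the apertures of the display.  Each
#' injection aperture injects \code{Q_inj_uLs}; the total aspiration is
#' \code{ratio} times the total injection (a ratio above 1 draws immersion
#' liquid from the bath and prevents spillage), shared equally by the
#' aspiration apertures.
#'
#' @param geometry a [pcd_geometry()].
#' @param Q_inj_uLs injection rate per aperture, uL/s (default 0.5).
#' @param ratio aspiration-to-injection flow rate ratio (default 1.4).
#' @return An \code{aperture_flow} object with per-aperture rates (uL/s) and
#'   totals.
#' @examples
#' af <- per_aperture_rates(pcd_geometry(), 0.5, 1.4)
#' af$Q_asp_uLs  # 1.4 * 9 * 0.5 / 16 = 0.39375
#' @export
per_aperture_rates <- function(geometry, Q_inj_uLs = 0.5, ratio = 1.4) {
  if (Q_inj_uLs <= 0 || ratio <= 0) stop("flow rates and ratio must be positive")
  n_inj <- nrow(geometry$injection_xy)
  n_asp <- nrow(geometry$aspiration_xy)
  Q_asp <- ratio * n_inj * Q_inj_uLs / n_asp
  structure(list(Q_inj_uLs = Q_inj_uLs, Q_asp_uLs = Q_asp, ratio = ratio,
                 total_inj_uLs = n_inj * Q_inj_uLs,
                 total_asp_uLs = n_asp * Q_asp),
            class = "aperture_flow")
}

#' @export
print.aperture_flow <- function(x, ...) {
  cat(sprintf("Aperture flow: %.3g uL/s per injection, %.5g uL/s per aspiration (ratio %.2f)\n",
              x$Q_inj_uLs, x$Q_asp_uLs, x$ratio))
  cat(sprintf("  totals: inject %.3g uL/s, aspirate %.3g uL/s\n",
              x$total_inj_uLs, x$total_asp_uLs))
  invisible(x)
}

#' Flow model configuration
#'
#' @param viscosity_Pa_s dynamic viscosity, Pa s (default water at 37 C,
#'   6.9e-4).
#' @param domain_half_width_mm half-width of the open bath domain; default
#'   extends 1.5 pixel pitches beyond the tip edge (set when the geometry is
#'   known).
#' @param resolution_per_mm grid points per mm for field evaluation
#'   (default 4; at least 10 points per pixel pitch are required).
#' @return A \code{flow_config} object.
#' @export
flow_config <- function(viscosity_Pa_s = 6.9e-4, domain_half_width_mm = NULL,
                        resolution_per_mm = 4) {
  stopifnot(viscosity_Pa_s > 0, resolution_per_mm > 0)
  structure(list(viscosity_Pa_s = viscosity_Pa_s,
                 domain_half_width_mm = domain_half_width_mm,
                 resolution_per_mm = resolution_per_mm),
            class = "flow_config")
}

# Signed aperture table in SI units.  strength = s * Q / (2 pi h), m^2/s:
# the depth-averaged radial velocity at distance r from an isolated aperture
# is strength / r.
aperture_table <- function(geometry, flow) {
  h_m <- geometry$gap_height_um * 1e-6
  inj <- geometry$injection_xy * 1e-6
  asp <- geometry$aspiration_xy * 1e-6
  Qi <- flow$Q_inj_uLs * 1e-9   # m^3/s
  Qa <- flow$Q_asp_uLs * 1e-9
  data.frame(
    x = c(inj[, 1], asp[, 1]), y = c(inj[, 2], asp[, 2]),
    sign = c(rep(1, nrow(inj)), rep(-1, nrow(asp))),
    Q = c(rep(Qi, nrow(inj)), rep(Qa, nrow(asp))),
    strength = c(rep(Qi, nrow(inj)), rep(-Qa, nrow(asp))) / (2 * pi * h_m))
}

# Superposed depth-averaged velocity (m/s) at points (px, py) in m.
hs_velocity <- function(px, py, apertures) {
  u <- numeric(length(px)); v <- numeric(length(px))
  for (k in seq_len(nrow(apertures))) {
    dx <- px - apertures$x[k]; dy <- py - apertures$y[k]
    r2 <- dx * dx + dy * dy
    s <- apertures$strength[k] / r2
    u <- u + s * dx
    v <- v + s * dy
  }
  list(u = u, v = v)
}

# Default bath truncation: 1.5 pixel pitches beyond the tip edge.
default_half_width_mm <- function(geometry) {
  pitch_mm <- geometry$pixel_pitch_um / 1e3
  (max(geometry$n_pixels_x, geometry$n_pixels_y) / 2 + 1.5) * pitch_mm
}

#' Depth-averaged velocity field under the display
#'
#' Superposes the Hele-Shaw point source/sink solutions of all apertures:
#' \deqn{\bar u(x) = \sum_k s_k \frac{Q_k}{2\pi h}\frac{x - x_k}{|x - x_k|^2}}
#' with \eqn{s_k = +1} for injection and \eqn{-1} for aspiration apertures.
#' Values within one aperture radius of an aperture centre are masked
#' (the point solution is singular there).
#'
#' @param geometry a [pcd_geometry()].
#' @param flow an [per_aperture_rates()] result.
#' @param cfg a [flow_config()].
#' @return A \code{flow_field} object: grid vectors \code{x_mm}, \code{y_mm},
#'   matrices \code{u}, \code{v}, \code{speed} (m/s, \code{NA} inside
#'   aperture exclusion disks) and the provenance (\code{geometry},
#'   \code{flow}, \code{cfg} including the gap height used).
#' @export
velocity_field <- function(geometry, flow, cfg = flow_config()) {
  hw <- cfg$domain_half_width_mm
  if (is.null(hw)) hw <- default_half_width_mm(geometry)
  cfg$domain_half_width_mm <- hw
  if (cfg$resolution_per_mm * geometry$pixel_pitch_um / 1e3 < 10)
    stop("resolution too coarse: need at least 10 points per pixel pitch")
  n <- round(2 * hw * cfg$resolution_per_mm) + 1
  x <- seq(-hw, hw, length.out = n) * 1e-3
  g <- expand.grid(px = x, py = x)
  ap <- aperture_table(geometry, flow)
  vel <- hs_velocity(g$px, g$py, ap)
  excl <- rep(FALSE, nrow(g))
  r_ex <- geometry$aperture_radius_um * 1e-6
  for (k in seq_len(nrow(ap)))
    excl <- excl | ((g$px - ap$x[k])^2 + (g$py - ap$y[k])^2 < r_ex^2)
  u <- matrix(vel$u, n, n); v <- matrix(vel$v, n, n)
  u[matrix(excl, n, n)] <- NA_real_
  v[matrix(excl, n, n)] <- NA_real_
  structure(list(x_mm = x * 1e3, y_mm = x * 1e3, u = u, v = v,
                 speed = sqrt(u^2 + v^2),
                 geometry = geometry, flow = flow, cfg = cfg,
                 apertures = ap),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("Hele-Shaw flow field: %d x %d grid over +/- %.1f mm, h = %.0f um\n",
              length(x$x_mm), length(x$y_mm), x$cfg$domain_half_width_mm,
              x$geometry$gap_height_um))
  cat(sprintf("  max depth-averaged speed (outside apertures): %.3g m/s\n",
              max(x$speed, na.rm = TRUE)))
  invisible(x)
}

#' Wall shear stress under the display
#'
#' Plane-Poiseuille wall shear from the depth-averaged speed,
#' \eqn{\tau = 6 \mu |\bar u| / h}, evaluated on the field grid outside the
#' aperture exclusion disks.  The supremum sits on the exclusion-disk rim,
#' so the maximum additionally samples a ring of points at one aperture
#' radius around every aperture.
#'
#' @param field a [velocity_field()] result.
#' @param cfg the same [flow_config()] the field was computed with.
#' @return A \code{wall_shear} object: the shear map \code{tau} (Pa), the
#'   overall \code{max_tau_Pa}, and \code{safety_factor} relative to the
#'   ~1 Pa physiologically safe bound for sensitive cells.
#' @export
wall_shear_stress <- function(field, cfg = field$cfg) {
  if (!identical(cfg[c("viscosity_Pa_s", "resolution_per_mm")],
                 field$cfg[c("viscosity_Pa_s", "resolution_per_mm")]))
    stop("cfg does not match the configuration the field was computed with")
  mu <- cfg$viscosity_Pa_s
  h_m <- field$geometry$gap_height_um * 1e-6
  tau <- 6 * mu * field$speed / h_m
  # rim samples: the analytic speed is maximal at the exclusion radius
  ap <- field$apertures
  r_ex <- field$geometry$aperture_radius_um * 1e-6
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  rim_max <- 0
  for (k in seq_len(nrow(ap))) {
    vel <- hs_velocity(ap$x[k] + r_ex * cos(th), ap$y[k] + r_ex * sin(th),
                       ap)
    rim_max <- max(rim_max, sqrt(vel$u^2 + vel$v^2))
  }
  max_tau <- max(6 * mu * rim_max / h_m, max(tau, na.rm = TRUE))
  structure(list(tau = tau, x_mm = field$x_mm, y_mm = field$y_mm,
                 max_tau_Pa = max_tau, safety_factor = 1 / max_tau,
                 gap_height_um = field$geometry$gap_height_um),
            class = "wall_shear")
}

#' @export
print.wall_shear <- function(x, ...) {
  cat(sprintf("Wall shear (h = %.0f um): max tau = %.3g Pa, safety factor vs 1 Pa = %.3g\n",
              x$gap_height_um, x$max_tau_Pa, x$safety_factor))
  invisible(x)
}

#' Pixel footprints by reverse streamline tracing
#'
#' Labels every substrate point by the injection aperture whose fluid
#' occupies it: the streamline through the point is integrated backwards
#' (against the depth-averaged flow, advection-dominated limit) until it
#' enters an aperture disk of a source, leaves the truncated bath domain
#' ("bath"), or exceeds the step budget ("unresolved").
#'
#' @param geometry a [pcd_geometry()].
#' @param flow an [per_aperture_rates()] result.
#' @param cfg a [flow_config()].
#' @param resolution_per_mm classification grid density (default 10).
#' @param margin_mm how far beyond the tip edge to classify (default 0: the
#'   tip region itself, where the microwell array sits).
#' @param max_steps step budget per point.
#' @param include_aspiration set \code{FALSE} to trace in the field of the
#'   injection apertures alone (e.g. a single free source).
#' @return A \code{pixel_footprints} object: \code{label} matrix (pixel
#'   index, 0 = bath, -1 = unresolved), grid vectors, per-pixel
#'   \code{areas_mm2}, and the counts of bath/unresolved points.
#' @export
pixel_footprints <- function(geometry, flow, cfg = flow_config(),
                             resolution_per_mm = 10, margin_mm = 0,
                             max_steps = 2000L, include_aspiration = TRUE) {
  ap <- aperture_table(geometry, flow)
  if (!include_aspiration) ap <- ap[ap$sign > 0, ]
  src <- ap[ap$sign > 0, ]
  hw_dom <- cfg$domain_half_width_mm
  if (is.null(hw_dom)) hw_dom <- default_half_width_mm(geometry)
  pitch_mm <- geometry$pixel_pitch_um / 1e3
  hx <- geometry$n_pixels_x / 2 * pitch_mm + margin_mm
  hy <- geometry$n_pixels_y / 2 * pitch_mm + margin_mm
  dg <- 1 / resolution_per_mm
  x <- seq(-hx + dg / 2, hx - dg / 2, by = dg) * 1e-3
  y <- seq(-hy + dg / 2, hy - dg / 2, by = dg) * 1e-3
  pts <- expand.grid(px = x, py = y)
  nx <- length(x); ny <- length(y)
  r_src <- geometry$aperture_radius_um * 1e-6
  dom_m <- hw_dom * 1e-3
  step <- dg * 1e-3 / 2          # half a grid spacing, in m
  lab <- rep.int(-1L, nrow(pts))
  px <- pts$px; py <- pts$py
  active <- seq_along(px)
  nearest_source <- function(qx, qy) {
    best_d2 <- rep(Inf, length(qx)); best <- integer(length(qx))
    for (k in seq_len(nrow(src))) {
      d2 <- (qx - src$x[k])^2 + (qy - src$y[k])^2
      hit <- d2 < best_d2
      best_d2[hit] <- d2[hit]; best[hit] <- k
    }
    list(k = best, d2 = best_d2)
  }
  for (s in seq_len(max_steps)) {
    if (!length(active)) break
    qx <- px[active]; qy <- py[active]
    ns <- nearest_source(qx, qy)
    done <- ns$d2 < r_src^2
    lab[active[done]] <- ns$k[done]
    out <- abs(qx) > dom_m | abs(qy) > dom_m
    lab[active[out]] <- 0L
    keep <- !(done | out)
    active <- active[keep]
    if (!length(active)) break
    qx <- px[active]; qy <- py[active]
    # midpoint rule on the unit direction field, against the flow
    v1 <- hs_velocity(qx, qy, ap)
    sp1 <- sqrt(v1$u^2 + v1$v^2)
    sp1[sp1 == 0] <- NA_real_
    mx <- qx - 0.5 * step * v1$u / sp1
    my <- qy - 0.5 * step * v1$v / sp1
    v2 <- hs_velocity(mx, my, ap)
    sp2 <- sqrt(v2$u^2 + v2$v^2)
    sp2[sp2 == 0] <- NA_real_
    px[active] <- qx - step * v2$u / sp2
    py[active] <- qy - step * v2$v / sp2
  }
  lab_m <- matrix(lab, nx, ny)
  cell_mm2 <- dg^2
  areas <- vapply(seq_len(nrow(src)),
                  function(k) sum(lab == k) * cell_mm2, numeric(1))
  structure(list(label = lab_m, x_mm = x * 1e3, y_mm = y * 1e3,
                 areas_mm2 = areas,
                 n_bath = sum(lab == 0L), n_unresolved = sum(lab == -1L),
                 geometry = geometry, flow = flow,
                 resolution_per_mm = resolution_per_mm),
            class = "pixel_footprints")
}

#' @export
print.pixel_footprints <- function(x, ...) {
  cat(sprintf("Pixel footprints (%d x %d points at %.0f/mm):\n",
              length(x$x_mm), length(x$y_mm), x$resolution_per_mm))
  cat("  areas (mm^2):", paste(sprintf("%.1f", x$areas_mm2), collapse = ", "),
      "\n")
  cat(sprintf("  bath points: %d, unresolved: %d\n", x$n_bath, x$n_unresolved))
  invisible(x)
}
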