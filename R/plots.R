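# Base-graphics views of the main result objects.

#' @export
plot.flow_field <- function(x, ...) {
  sp <- x$speed
  graphics::image(x$x_mm, x$y_mm, sp, asp = 1,
                  xlab = "x (mm)", ylab = "y (mm)",
                  main = sprintf("Depth-averaged speed (m/s), h = %.0f um",
                                 x$geometry$gap_height_um), ...)
  graphics::points(x$geometry$injection_xy / 1e3, pch = 3)
  graphics::points(x$geometry$aspiration_xy / 1e3, pch = 1)
  invisible(x)
}

#' @export
plot.wall_shear <- function(x, ...) {
  graphics::image(x$x_mm, x$y_mm, x$tau, asp = 1,
                  xlab = "x (mm)", ylab = "y (mm)",
                  main = sprintf("Wall shear (Pa), max %.3g", x$max_tau_Pa),
                  ...)
  invisible(x)
}

#' @export
plot.pixel_footprints <- function(x, ...) {
  graphics::image(x$x_mm, x$y_mm, x$label, asp = 1,
                  col = grDevices::hcl.colors(12, "Spectral"),
                  xlab = "x (mm)", ylab = "y (mm)",
                  main = "Pixel footprints (streamline classification)", ...)
  invisible(x)
}

#' @export
plot.concentration_history <- function(x, frame = dim(x$frames)[3], ...) {
  f <- x$frames[, , frame]
  graphics::image(x$domain$r_um, x$domain$z_um, f,
                  xlab = "r (um)", ylab = "z (um)",
                  main = sprintf("%s concentration, t = %.0f s",
                                 x$species$name, x$save_times[frame]), ...)
  invisible(x)
}

#' @export
plot.viability_result <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, length(x$species)))
  on.exit(graphics::par(old))
  for (nm in names(x$species)) {
    s <- x$species[[nm]]
    graphics::plot(s$times / 3600, s$min_tissue, type = "l",
                   xlab = "time (h)", ylab = "min tissue conc. (mol/m^3)",
                   main = nm, ...)
    graphics::abline(h = s$Km, lty = 2)
  }
  invisible(x)
}
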