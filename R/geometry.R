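#' Pixelated chemical display geometry
#'
#' Constructs the geometry of a pixelated chemical display (PCD): a square
#' grid of fluidic pixels, each served by one injection aperture at the pixel
#' centre and four aspiration apertures on its corners.  Corner apertures are
#' shared between adjacent pixels, so an \code{nx} by \code{ny} display has
#' \code{nx * ny} injection and \code{(nx + 1) * (ny + 1)} aspiration
#' apertures.
#'
#' Coordinates are in micrometres, origin at the display centre, x rightward
#' and y upward; the "top right" pixel is the one with maximal x and y.
#'
#' @param n_pixels_x,n_pixels_y number of pixels along x and y (default 3).
#' @param pixel_pitch_mm pixel pitch in mm (default 6, a 36 mm^2 pixel).
#' @param gap_height_um gap between the display face and the substrate, um.
#'   Not printed in the source design; 200 um is a declared assumption and
#'   every flow result echoes the value used.
#' @param aperture_radius_um aperture radius, um (declared assumption).
#' @return An object of class \code{pcd_geometry} with fields
#'   \code{injection_xy} and \code{aspiration_xy} (matrices of um
#'   coordinates), the pixel index table \code{pixels}, and the scalar
#'   parameters above.
#' @examples
#' g <- pcd_geometry()
#' nrow(g$injection_xy)   # 9
#' nrow(g$aspiration_xy)  # 16
#' @export
pcd_geometry <- function(n_pixels_x = 3L, n_pixels_y = 3L,
                         pixel_pitch_mm = 6, gap_height_um = 200,
                         aperture_radius_um = 250) {
  stopifnot(n_pixels_x >= 1, n_pixels_y >= 1, pixel_pitch_mm > 0,
            gap_height_um > 0, aperture_radius_um > 0)
  pitch <- pixel_pitch_mm * 1e3  # um
  cx <- (seq_len(n_pixels_x) - (n_pixels_x + 1) / 2) * pitch
  cy <- (seq_len(n_pixels_y) - (n_pixels_y + 1) / 2) * pitch
  pixels <- expand.grid(col = seq_len(n_pixels_x), row = seq_len(n_pixels_y))
  pixels$x <- cx[pixels$col]
  pixels$y <- cy[pixels$row]
  pixels$pixel <- seq_len(nrow(pixels))
  corner_x <- (seq_len(n_pixels_x + 1) - 1 - n_pixels_x / 2) * pitch
  corner_y <- (seq_len(n_pixels_y + 1) - 1 - n_pixels_y / 2) * pitch
  corners <- expand.grid(x = corner_x, y = corner_y)
  structure(list(
    n_pixels_x = as.integer(n_pixels_x),
    n_pixels_y = as.integer(n_pixels_y),
    pixel_pitch_um = pitch,
    gap_height_um = gap_height_um,
    aperture_radius_um = aperture_radius_um,
    injection_xy = cbind(x = pixels$x, y = pixels$y),
    aspiration_xy = cbind(x = corners$x, y = corners$y),
    pixels = pixels[, c("pixel", "row", "col", "x", "y")]
  ), class = "pcd_geometry")
}

#' @export
print.pcd_geometry <- function(x, ...) {
  cat(sprintf("PCD geometry: %d x %d pixels, pitch %.1f mm\n",
              x$n_pixels_x, x$n_pixels_y, x$pixel_pitch_um / 1e3))
  cat(sprintf("  %d injection apertures (pixel centres), %d aspiration apertures (corners)\n",
              nrow(x$injection_xy), nrow(x$aspiration_xy)))
  cat(sprintf("  gap height %.0f um, aperture radius %.0f um\n",
              x$gap_height_um, x$aperture_radius_um))
  invisible(x)
}

#' Microwell array layout
#'
#' The tumour-model holder: groups of cylindrical microwells, one 4 x 4
#' group centred under each fluidic pixel at a pitch of one quarter of the
#' pixel pitch.
#'
#' @param geometry a [pcd_geometry()] describing the display above the array.
#' @param wells_per_group wells per pixel group; must be a perfect square
#'   (default 16).
#' @param well_diameter_um,well_depth_um well dimensions, um (defaults
#'   700 and 900).
#' @return An object of class \code{microwell_array}; \code{$wells} is a
#'   data frame with one row per well (well, group, pixel, x, y in um).
#' @examples
#' plat <- build_default_platform()
#' nrow(plat$array$wells)  # 144
#' @export
microwell_array <- function(geometry = pcd_geometry(), wells_per_group = 16L,
                            well_diameter_um = 700, well_depth_um = 900) {
  side <- sqrt(wells_per_group)
  stopifnot(side == round(side), well_diameter_um > 0, well_depth_um > 0)
  side <- as.integer(side)
  well_pitch <- geometry$pixel_pitch_um / side
  stopifnot(well_pitch > well_diameter_um)  # wells must not overlap
  off <- (seq_len(side) - (side + 1) / 2) * well_pitch
  grid <- expand.grid(ox = off, oy = off)
  px <- geometry$pixels
  wells <- do.call(rbind, lapply(seq_len(nrow(px)), function(i) {
    data.frame(group = i, pixel = px$pixel[i],
               x = px$x[i] + grid$ox, y = px$y[i] + grid$oy)
  }))
  wells <- cbind(well = seq_len(nrow(wells)), wells)
  structure(list(
    n_groups = nrow(px),
    wells_per_group = as.integer(wells_per_group),
    well_diameter_um = well_diameter_um,
    well_depth_um = well_depth_um,
    well_pitch_um = well_pitch,
    wells = wells
  ), class = "microwell_array")
}

#' @export
print.microwell_array <- function(x, ...) {
  cat(sprintf("Microwell array: %d groups of %d wells (%d total)\n",
              x$n_groups, x$wells_per_group, nrow(x$wells)))
  cat(sprintf("  wells %.0f um diameter x %.0f um deep, pitch %.2f mm\n",
              x$well_diameter_um, x$well_depth_um, x$well_pitch_um / 1e3))
  invisible(x)
}

#' 3D tumour model dimensions
#'
#' Describes one tumour model inside a microwell: a spheroid (sphere) or a
#' microdissected tissue (MDT, cylinder punched from a tissue slice).
#'
#' @param shape "sphere" or "cylinder".
#' @param diameter_um tissue diameter, um.
#' @param height_um cylinder height, um; forced equal to the diameter for
#'   spheres.  Default 350 (slice thickness of an MDT punch).
#' @param position "seated" (resting at the well bottom) or "protruding".
#' @param protrusion_um length sticking out above the array surface, um.
#' @param well the host [microwell_array()] (used to check containment).
#' @return An object of class \code{tissue_model}.
#' @export
tissue_model <- function(shape = c("sphere", "cylinder"), diameter_um = 500,
                         height_um = 350,
                         position = c("seated", "protruding"),
                         protrusion_um = 0, well = NULL) {
  shape <- match.arg(shape)
  position <- match.arg(position)
  if (shape == "sphere") height_um <- diameter_um
  stopifnot(diameter_um > 0, height_um > 0, protrusion_um >= 0,
            protrusion_um <= diameter_um)
  if (position == "seated" && protrusion_um != 0)
    stop("a seated tissue has zero protrusion")
  if (!is.null(well) && diameter_um > well$well_diameter_um)
    stop("tissue diameter exceeds the host well diameter")
  structure(list(shape = shape, diameter_um = diameter_um,
                 height_um = height_um, position = position,
                 protrusion_um = protrusion_um),
            class = "tissue_model")
}

#' Default drug-screening platform geometry
#'
#' The as-built platform: a 3 x 3 display with 6 mm pixel pitch over an
#' array of 9 groups of 16 microwells (144 wells of 700 um diameter and
#' 900 um depth).
#'
#' @param ... passed to [pcd_geometry()] to override defaults.
#' @return A list with elements \code{geometry} and \code{array}.
#' @export
build_default_platform <- function(...) {
  g <- pcd_geometry(...)
  list(geometry = g, array = microwell_array(g))
}

#' Checkerboard reagent pattern
#'
#' Alternating reagent/carrier assignment used to visualise pixel crosstalk:
#' starting from the top-right pixel, every other pixel streams the
#' reagent-containing fluid (concentration 1), the rest the carrier fluid
#' (concentration 0).  On the 3 x 3 display this gives 5 reagent and 4
#' carrier pixels.
#'
#' @param geometry a [pcd_geometry()]; the layout must be square 3 x 3
#'   (or the degenerate 1 x 1).
#' @return A \code{pixel_pattern} object: \code{$assignment} maps pixel index
#'   to label ("reagent" or "carrier").
#' @export
checkerboard_pattern <- function(geometry) {
  if (!((geometry$n_pixels_x == 3 && geometry$n_pixels_y == 3) ||
        (geometry$n_pixels_x == 1 && geometry$n_pixels_y == 1)))
    stop("checkerboard pattern is only defined for the 3 x 3 (or 1 x 1) display")
  px <- geometry$pixels
  # parity relative to the top-right pixel (max row, max col)
  ref <- (geometry$n_pixels_x + geometry$n_pixels_y) %% 2L
  lab <- ifelse((px$row + px$col) %% 2L == ref, "reagent", "carrier")
  pixel_pattern(assignment = stats::setNames(lab, px$pixel))
}

#' Triplicate pixel grouping
#'
#' Partition of the 9 pixels into 3 disjoint groups of 3, each connected to
#' one reagent flask so that every condition runs in experimental triplicate.
#' The default grouping is by row; groups are labelled A (bottom row) to C.
#'
#' @param geometry a 3 x 3 [pcd_geometry()].
#' @return A \code{pixel_pattern} whose \code{$groups} maps group label to
#'   the three pixel indices, and whose assignment labels each pixel with
#'   its group.
#' @export
triplicate_groups <- function(geometry) {
  if (geometry$n_pixels_x != 3 || geometry$n_pixels_y != 3)
    stop("triplicate grouping is only defined for the 3 x 3 display")
  px <- geometry$pixels
  lab <- LETTERS[px$row]
  pixel_pattern(assignment = stats::setNames(lab, px$pixel),
                groups = split(px$pixel, lab))
}

#' Pixel-to-reagent assignment
#'
#' @param assignment named character vector: names are pixel indices, values
#'   reagent (or group) labels; every pixel must appear exactly once.
#' @param groups optional named list mapping group labels to pixel indices;
#'   must partition the pixels.
#' @return A \code{pixel_pattern} object.
#' @export
pixel_pattern <- function(assignment, groups = NULL) {
  stopifnot(is.character(assignment), !is.null(names(assignment)))
  if (anyDuplicated(names(assignment)))
    stop("each pixel must have exactly one label")
  if (!is.null(groups)) {
    all_px <- sort(as.integer(unlist(groups)))
    if (!identical(all_px, sort(as.integer(names(assignment)))))
      stop("groups must partition the pixels")
  }
  structure(list(assignment = assignment,
                 labels = sort(unique(unname(assignment))),
                 groups = groups),
            class = "pixel_pattern")
}

#' @export
print.pixel_pattern <- function(x, ...) {
  tab <- table(x$assignment)
  cat("Pixel pattern:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize platform geometry
#'
#' `platform_to_yaml()`/`platform_from_yaml()` round-trip the construction
#' parameters through a YAML config file; `platform_coords_json()` exports
#' the aperture and well coordinate tables as JSON; `wells_csv()` writes the
#' well table (well, group, pixel, x, y) as CSV.
#'
#' @param platform a list as returned by [build_default_platform()].
#' @param path file to write (or read, for `platform_from_yaml`).
#' @return `platform_from_yaml()` returns the reconstructed platform;
#'   the writers return `path` invisibly.
#' @export
platform_to_yaml <- function(platform, path) {
  g <- platform$geometry; a <- platform$array
  cfg <- list(
    geometry = list(n_pixels_x = g$n_pixels_x, n_pixels_y = g$n_pixels_y,
                    pixel_pitch_mm = g$pixel_pitch_um / 1e3,
                    gap_height_um = g$gap_height_um,
                    aperture_radius_um = g$aperture_radius_um),
    array = list(wells_per_group = a$wells_per_group,
                 well_diameter_um = a$well_diameter_um,
                 well_depth_um = a$well_depth_um))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname platform_to_yaml
#' @export
platform_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  g <- do.call(pcd_geometry, cfg$geometry)
  a <- do.call(microwell_array, c(list(geometry = g), cfg$array))
  list(geometry = g, array = a)
}

#' @rdname platform_to_yaml
#' @export
platform_coords_json <- function(platform, path) {
  g <- platform$geometry
  jsonlite::write_json(list(
    injection_xy_um = as.data.frame(g$injection_xy),
    aspiration_xy_um = as.data.frame(g$aspiration_xy),
    wells_um = platform$array$wells), path, digits = NA)
  invisible(path)
}

#' @rdname platform_to_yaml
#' @export
wells_csv <- function(platform, path) {
  utils::write.csv(platform$array$wells, path, row.names = FALSE)
  invisible(path)
}
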