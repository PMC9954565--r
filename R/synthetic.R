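# Seeded generators of synthetic experiments: pixel-patterned spheroid
# micrographs with known fluorescence, nuclei/positive mask pairs with a
# known translocation fraction, and per-sample translocation datasets.
# Every generator consumes one pseudo-random stream derived from
# (seed, call tag), so adding generators never perturbs existing fixtures,
# and ships a machine-readable truth table.

# Run code under a derived, restorable RNG stream.
with_stream <- function(seed, tag, code) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  s <- (as.numeric(seed) * 1000003 + h * 7919) %% 2147483629
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(s))
  force(code)
}

#' Synthetic spheroid micrographs with known fluorescence
#'
#' Emulates the staining experiment's imaging data: one 16-bit-range
#' grayscale image per fluidic pixel, containing one disk-shaped spheroid
#' per microwell of the 4 x 4 group, with foreground mean = true FI +
#' background level and additive Gaussian noise.  The default truth model
#' is linear in incubation time (non-saturating dye accumulation), so two
#' durations have an FI ratio equal to their time ratio.
#'
#' @param channel_by_pixel named character vector: pixel index -> channel
#'   (dye) label.
#' @param duration_h_by_pixel named numeric vector: pixel index ->
#'   incubation duration in hours.
#' @param fi_truth function(duration_h) -> true corrected FI (counts);
#'   default 40 counts per hour.
#' @param noise_sd additive Gaussian noise, counts.
#' @param seed integer seed; the same seed reproduces identical output.
#' @param n_spheroids number of spheroids per pixel (<= 16).
#' @param um_per_px image scale (default 10 um per pixel side).
#' @param spheroid_diameter_um spheroid diameter (must fit the well pitch).
#' @param well_pitch_um microwell pitch within a group.
#' @param background background level, counts (default 100).
#' @return A \code{synthetic_images} object: \code{images} (named list of
#'   matrices, values in counts), \code{disks} (per-spheroid image
#'   coordinates), \code{truth} (per-spheroid channel, duration and true
#'   FI) and the generation parameters.
#' @export
gen_spheroid_images <- function(channel_by_pixel, duration_h_by_pixel,
                                fi_truth = function(d) 40 * d,
                                noise_sd = 5, seed = 1,
                                n_spheroids = 16, um_per_px = 10,
                                spheroid_diameter_um = 450,
                                well_pitch_um = 1500, background = 100) {
  pixels <- names(channel_by_pixel)
  stopifnot(!is.null(pixels), setequal(pixels, names(duration_h_by_pixel)),
            n_spheroids <= 16)
  pitch_px <- well_pitch_um / um_per_px
  r_px <- spheroid_diameter_um / 2 / um_per_px
  if (2 * r_px >= pitch_px)
    stop("spheroids overlap: diameter exceeds the well pitch")
  side <- round(4 * pitch_px)
  centres <- (seq_len(4) - 0.5) * pitch_px
  grid <- expand.grid(cx = centres, cy = centres)
  xs <- matrix(seq_len(side), side, side)
  ys <- matrix(seq_len(side), side, side, byrow = TRUE)
  images <- list(); disks <- list(); truth <- list()
  with_stream(seed, "spheroid_images", {
    sph_id <- 0L
    for (p in pixels) {
      img <- matrix(background, side, side)
      true_fi <- fi_truth(duration_h_by_pixel[[p]])
      use <- seq_len(n_spheroids)
      for (k in use) {
        inside <- (xs - grid$cx[k])^2 + (ys - grid$cy[k])^2 < r_px^2
        img[inside] <- background + true_fi
        sph_id <- sph_id + 1L
        disks[[sph_id]] <- data.frame(spheroid = sph_id, pixel = p,
                                      cx = grid$cx[k], cy = grid$cy[k],
                                      r = r_px)
        truth[[sph_id]] <- data.frame(spheroid = sph_id, pixel = p,
                                      channel = channel_by_pixel[[p]],
                                      duration_h = duration_h_by_pixel[[p]],
                                      true_fi = true_fi)
      }
      if (noise_sd > 0)
        img <- img + matrix(stats::rnorm(side * side, 0, noise_sd), side, side)
      images[[p]] <- pmin(pmax(img, 0), 65535)
    }
  })
  structure(list(images = images, disks = do.call(rbind, disks),
                 truth = do.call(rbind, truth),
                 background = background, noise_sd = noise_sd,
                 um_per_px = um_per_px, seed = seed),
            class = "synthetic_images")
}

#' Measure FI records from synthetic images
#'
#' Quantifies a [gen_spheroid_images()] result the way the staining
#' analysis is done: per spheroid, the mean intensity inside its disk
#' (tissue FI per area) minus the mean intensity of the image background
#' (everything outside all disks).  Regions come from the generator's
#' ground truth, mirroring manually drawn ROIs.
#'
#' @param sim a \code{synthetic_images} object.
#' @param n_per_pixel how many spheroids to measure per pixel (default 3,
#'   chosen at random as in the source protocol).
#' @param seed seed for the random spheroid selection.
#' @return Records data frame suitable for [summarize_fi()], with the truth
#'   columns joined for convenience.
#' @export
measure_fi_records <- function(sim, n_per_pixel = 3, seed = 1) {
  stopifnot(inherits(sim, "synthetic_images"))
  side <- nrow(sim$images[[1]])
  xs <- matrix(seq_len(side), side, side)
  ys <- matrix(seq_len(side), side, side, byrow = TRUE)
  recs <- list()
  with_stream(seed, "measure_fi", {
    for (p in names(sim$images)) {
      img <- sim$images[[p]]
      dk <- sim$disks[sim$disks$pixel == p, ]
      fg_any <- matrix(FALSE, side, side)
      for (i in seq_len(nrow(dk)))
        fg_any <- fg_any | ((xs - dk$cx[i])^2 + (ys - dk$cy[i])^2 < dk$r[i]^2)
      bg <- mean(img[!fg_any])
      pick <- sample(seq_len(nrow(dk)), min(n_per_pixel, nrow(dk)))
      for (i in pick) {
        inside <- (xs - dk$cx[i])^2 + (ys - dk$cy[i])^2 < dk$r[i]^2
        recs[[length(recs) + 1L]] <-
          data.frame(spheroid = dk$spheroid[i], pixel = p,
                     tissue_fi = mean(img[inside]), background_fi = bg)
      }
    }
  })
  out <- do.call(rbind, recs)
  out <- merge(out, sim$truth[, c("spheroid", "channel", "duration_h")],
               by = "spheroid")
  out$duration <- out$duration_h
  out$corrected_fi <- corrected_fi(out$tissue_fi, out$background_fi)
  out
}

#' Synthetic nuclei / positive-nuclei mask pair
#'
#' Places non-overlapping elliptical nuclei at random and marks a subset
#' positive so that the positive-to-total area ratio matches
#' \code{target_fraction} as closely as whole nuclei allow (within one
#' nucleus's area).  The achieved fraction is pixel-exact by construction.
#'
#' @param n_nuclei number of nuclei.
#' @param target_fraction target positive area fraction in [0, 1].
#' @param seed integer seed.
#' @param img_size mask side, pixels.
#' @param axes_px range of ellipse semi-axes, pixels.
#' @param max_tries placement attempts before giving up.
#' @return List: \code{nuclei_mask}, \code{positive_mask} (logical
#'   matrices) and \code{truth} (achieved fraction, per-nucleus table).
#' @export
gen_translocation_masks <- function(n_nuclei, target_fraction, seed = 1,
                                    img_size = 512, axes_px = c(6, 12),
                                    max_tries = 20000) {
  stopifnot(target_fraction >= 0, target_fraction <= 1, n_nuclei >= 1)
  xs <- matrix(seq_len(img_size), img_size, img_size)
  ys <- matrix(seq_len(img_size), img_size, img_size, byrow = TRUE)
  with_stream(seed, "translocation_masks", {
    placed <- list(); tries <- 0
    occupied <- matrix(FALSE, img_size, img_size)
    while (length(placed) < n_nuclei) {
      tries <- tries + 1
      if (tries > max_tries)
        stop("cannot place ", n_nuclei, " non-overlapping nuclei")
      a <- stats::runif(1, axes_px[1], axes_px[2])
      b <- stats::runif(1, axes_px[1], axes_px[2])
      th <- stats::runif(1, 0, pi)
      cx <- stats::runif(1, a + 1, img_size - a - 1)
      cy <- stats::runif(1, a + 1, img_size - a - 1)
      dx <- xs - cx; dy <- ys - cy
      u <- dx * cos(th) + dy * sin(th); v <- -dx * sin(th) + dy * cos(th)
      ell <- (u / a)^2 + (v / b)^2 <= 1
      if (any(ell & occupied)) next
      occupied <- occupied | ell
      placed[[length(placed) + 1L]] <- ell
    }
    areas <- vapply(placed, sum, numeric(1))
    total <- sum(areas)
    ord <- sample(seq_along(placed))
    cum <- cumsum(areas[ord])
    n_pos <- sum(cum <= target_fraction * total + 1e-9)
    # include one more nucleus if that lands closer to the target
    if (n_pos < length(ord)) {
      under <- abs(ifelse(n_pos > 0, cum[n_pos], 0) - target_fraction * total)
      over <- abs(cum[n_pos + 1] - target_fraction * total)
      if (over < under) n_pos <- n_pos + 1
    }
    pos_idx <- ord[seq_len(n_pos)]
    positive <- matrix(FALSE, img_size, img_size)
    for (i in pos_idx) positive <- positive | placed[[i]]
    achieved <- sum(areas[pos_idx]) / total
    list(nuclei_mask = occupied, positive_mask = positive,
         truth = list(achieved_fraction = achieved,
                      target_fraction = target_fraction,
                      n_nuclei = n_nuclei, n_positive = length(pos_idx),
                      areas_px = areas, seed = seed))
  })
}

#' Synthetic TNF translocation dataset
#'
#' Per-sample nuclear translocation fractions for a set of treatment
#' conditions, drawn from normal distributions clamped to [0, 1].  The
#' default effect sizes emulate a transient NF-kB response: low in the
#' control, maximal after a 30 min exposure, partially declined after
#' 240 min (control < 240 min < 30 min).
#'
#' @param means named numeric vector of condition means.
#' @param sd common standard deviation.
#' @param n samples per condition (>= 3).
#' @param seed integer seed.
#' @return List: \code{values} (condition -> fractions, ready for
#'   [compare_groups()]) and \code{truth} (the generating parameters).
#' @export
gen_tnf_dataset <- function(means = c(control = 0.20, tnf_30min = 0.60,
                                      tnf_240min = 0.35),
                            sd = 0.05, n = 9, seed = 1) {
  if (n < 3) stop("need at least 3 samples per condition")
  vals <- with_stream(seed, "tnf_dataset", {
    lapply(means, function(m) pmin(pmax(stats::rnorm(n, m, sd), 0), 1))
  })
  list(values = vals, truth = list(means = means, sd = sd, n = n, seed = seed))
}

#' Write synthetic images and truth tables to disk
#'
#' Images go out as 16-bit grayscale TIFF (requires the \pkg{tiff}
#' package), truth and disk tables as CSV.
#'
#' @param sim a [gen_spheroid_images()] result.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_synthetic_images <- function(sim, dir) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("writing TIFF images requires the 'tiff' package")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in names(sim$images))
    tiff::writeTIFF(sim$images[[p]] / 65535, file.path(dir, paste0("pixel_", p, ".tif")),
                    bits.per.sample = 16)
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  utils::write.csv(sim$disks, file.path(dir, "disks.csv"), row.names = FALSE)
  invisible(dir)
}
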