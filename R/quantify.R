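#' Background-corrected fluorescence intensity per area
#'
#' The staining readout: tissue fluorescence intensity per unit area minus
#' the background intensity per unit area.  Negative results are allowed
#' (they can arise from noise around zero signal) but flagged with a
#' warning.
#'
#' @param tissue_fi,background_fi intensities per area; vectors are
#'   corrected elementwise.
#' @return \code{tissue_fi - background_fi}.
#' @export
corrected_fi <- function(tissue_fi, background_fi) {
  if (!all(is.finite(tissue_fi)) || !all(is.finite(background_fi)))
    stop("intensities must be finite")
  out <- tissue_fi - background_fi
  if (any(out < 0)) warning("negative corrected FI (background above tissue)")
  out
}

#' Summarize corrected FI by channel and incubation duration
#'
#' Per (channel, duration) cell: the number of spheroids, mean corrected FI
#' and standard error of the mean (sd / sqrt(n)), as in the platform's
#' staining analysis (3 spheroids per fluidic pixel, 9 per channel and
#' duration).
#'
#' @param records data frame with columns \code{channel}, \code{duration}
#'   and \code{corrected_fi} (or \code{tissue_fi} + \code{background_fi},
#'   corrected on the fly).
#' @return Data frame: channel, duration, n, mean_fi, sem.
#' @export
summarize_fi <- function(records) {
  if (!"corrected_fi" %in% names(records))
    records$corrected_fi <- corrected_fi(records$tissue_fi,
                                         records$background_fi)
  stopifnot(all(c("channel", "duration") %in% names(records)))
  if (!nrow(records)) {
    warning("no records to summarize")
    return(data.frame(channel = character(0), duration = numeric(0),
                      n = integer(0), mean_fi = numeric(0), sem = numeric(0)))
  }
  key <- interaction(records$channel, records$duration, drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(r) {
    n <- nrow(r)
    data.frame(channel = r$channel[1], duration = r$duration[1], n = n,
               mean_fi = mean(r$corrected_fi),
               sem = if (n > 1) stats::sd(r$corrected_fi) / sqrt(n) else NA_real_)
  }))
  rownames(out) <- NULL
  out[order(out$channel, out$duration), ]
}

#' Nuclear translocation fraction
#'
#' Area of marker-positive nuclei divided by the total nuclear area, the
#' NF-kB (p65) activation readout: surface area of p65-positive nuclei over
#' the surface area of all nuclei.  The positive mask is intersected with
#' the nuclei mask, so stray positive pixels outside nuclei never inflate
#' the fraction.
#'
#' @param nuclei_mask,positive_mask binary (logical or 0/1) matrices of the
#'   same shape.
#' @return Fraction in [0, 1].
#' @export
translocation_fraction <- function(nuclei_mask, positive_mask) {
  if (!all(dim(nuclei_mask) == dim(positive_mask)))
    stop("masks must have the same shape")
  nuc <- nuclei_mask > 0
  pos <- positive_mask > 0 & nuc
  total <- sum(nuc)
  if (total == 0) stop("empty nuclei mask: fraction undefined")
  sum(pos) / total
}

#' Nonparametric group comparison
#'
#' The platform's statistical contract: a Kruskal-Wallis rank-sum omnibus
#' test across conditions followed by pairwise Dunn tests (rank-based
#' z statistics on the pooled mean ranks, with a tie correction), adjusted
#' for multiple comparisons.  The adjustment method is configuration, not
#' inference, and is recorded in the output.
#'
#' @param values named list: condition -> numeric vector (>= 2 conditions,
#'   >= 3 values each).
#' @param p_adjust adjustment passed to [stats::p.adjust()] (default
#'   "holm"; use "none" for raw Dunn p-values).
#' @return A \code{group_comparison} object: \code{omnibus_p},
#'   \code{omnibus_statistic}, and \code{pairwise} (data frame with z and
#'   adjusted p per condition pair).
#' @export
compare_groups <- function(values, p_adjust = "holm") {
  if (length(values) < 2) stop("need at least 2 groups")
  if (any(lengths(values) < 3)) stop("need at least 3 values per group")
  if (is.null(names(values)) || any(names(values) == ""))
    names(values) <- paste0("group", seq_along(values))
  x <- unlist(values, use.names = FALSE)
  g <- factor(rep(names(values), lengths(values)), levels = names(values))
  N <- length(x)
  if (length(unique(x)) == 1) {
    warning("all values tied: no discriminating information, p = 1")
    pw <- t(utils::combn(names(values), 2))
    pairwise <- data.frame(group1 = pw[, 1], group2 = pw[, 2],
                           z = 0, p = 1, p_adjusted = 1)
    return(structure(list(omnibus_statistic = 0, omnibus_p = 1,
                          pairwise = pairwise, p_adjust = p_adjust),
                     class = "group_comparison"))
  }
  kw <- stats::kruskal.test(x, g)
  r <- rank(x)
  Rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  pw <- t(utils::combn(names(values), 2))
  z <- (Rbar[pw[, 1]] - Rbar[pw[, 2]]) /
    sqrt(s2 * (1 / n[pw[, 1]] + 1 / n[pw[, 2]]))
  p <- 2 * stats::pnorm(-abs(z))
  pairwise <- data.frame(group1 = pw[, 1], group2 = pw[, 2],
                         z = as.numeric(z), p = as.numeric(p),
                         p_adjusted = stats::p.adjust(as.numeric(p),
                                                      method = p_adjust))
  structure(list(omnibus_statistic = unname(kw$statistic),
                 omnibus_p = kw$p.value,
                 pairwise = pairwise, p_adjust = p_adjust),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: chi-squared = %.3f, p = %.4g\n",
              x$omnibus_statistic, x$omnibus_p))
  cat(sprintf("Dunn pairwise (adjustment: %s):\n", x$p_adjust))
  print.data.frame(x$pairwise, digits = 4)
  invisible(x)
}
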