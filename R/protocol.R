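#' Timed reagent schedule
#'
#' An ordered list of events assigning a reagent to a pixel group (or to
#' "all" groups) at integer minutes.  At every instant each group streams
#' exactly one reagent; the first event must be at t = 0.  The
#' \code{transition_time} (default 20 min) is the time a freshly switched
#' reagent needs to reach a constant concentration inside the tissue; it is
#' deducted once per contiguous reagent block when effective exposures are
#' computed.
#'
#' @param events data frame with columns \code{time} (min, integer),
#'   \code{group} (character, or "all") and \code{reagent}.
#' @param t_end schedule end, min.
#' @param groups character vector of the pixel-group labels.
#' @param transition_time_min minutes deducted per contiguous reagent block.
#' @return A \code{pcd_schedule} object.
#' @export
pcd_schedule <- function(events, t_end, groups = c("1", "2", "3"),
                         transition_time_min = 20) {
  stopifnot(is.data.frame(events),
            all(c("time", "group", "reagent") %in% names(events)))
  if (any(events$time != round(events$time)))
    stop("event times must be integer minutes")
  events$time <- as.integer(events$time)
  events$group <- as.character(events$group)
  events$reagent <- as.character(events$reagent)
  events <- events[order(events$time), , drop = FALSE]
  rownames(events) <- NULL
  sch <- structure(list(events = events, t_end = as.integer(t_end),
                        groups = as.character(groups),
                        transition_time_min = transition_time_min),
                   class = "pcd_schedule")
  v <- validate_schedule(sch)
  if (length(v)) stop("invalid schedule: ", paste(v, collapse = "; "))
  sch
}

# Expand events into per-group timelines: for each group a data frame of
# contiguous (start, stop, reagent) blocks covering [0, t_end].
schedule_blocks <- function(schedule) {
  ev <- schedule$events
  lapply(stats::setNames(nm = schedule$groups), function(g) {
    sel <- ev[ev$group %in% c(g, "all"), , drop = FALSE]
    sel <- sel[order(sel$time), , drop = FALSE]
    # a later event replaces the active reagent
    keep <- !duplicated(sel$time, fromLast = TRUE)
    sel <- sel[keep, , drop = FALSE]
    b <- data.frame(start = sel$time,
                    stop = c(sel$time[-1], schedule$t_end),
                    reagent = sel$reagent)
    # re-asserting the active reagent does not start a new block
    new_block <- c(TRUE, b$reagent[-1] != b$reagent[-nrow(b)])
    run <- cumsum(new_block)
    data.frame(start = tapply(b$start, run, min),
               stop = tapply(b$stop, run, max),
               reagent = b$reagent[new_block],
               row.names = NULL)
  })
}

#' Validate a schedule
#'
#' Checks the structural invariants: first event at t = 0, events within
#' [0, t_end], non-decreasing times, and full single-reagent coverage of
#' every group at all times.  Violations are returned as data, not raised.
#'
#' @param schedule a \code{pcd_schedule} (or a bare list shaped like one).
#' @return Character vector of violations; empty if the schedule is valid.
#' @export
validate_schedule <- function(schedule) {
  ev <- schedule$events
  out <- character(0)
  if (!nrow(ev)) return("schedule has no events")
  if (any(ev$time > schedule$t_end))
    out <- c(out, "event after t_end")
  if (any(ev$time < 0)) out <- c(out, "event before t = 0")
  for (g in schedule$groups) {
    sel <- ev[ev$group %in% c(g, "all"), , drop = FALSE]
    if (!nrow(sel) || min(sel$time) != 0)
      out <- c(out, sprintf("group %s has no reagent at t = 0", g))
    if (anyDuplicated(sel[, c("time", "group")]) &&
        any(table(sel$time[sel$group == g]) > 1))
      out <- c(out, sprintf("group %s has overlapping assignments", g))
  }
  out
}

#' The TNF stimulation schedule
#'
#' The 300 min cytokine protocol: neutral culture medium at every pixel for
#' the first 20 min; TNF started in group 1 at 20 min and in group 2 at
#' 230 min (from then on TNF streams at 6 pixels); group 3 stays on medium
#' throughout as the control; all flasks swapped for PBS at 280 min for a
#' 20 min rinse.
#'
#' @param transition_time_min see [pcd_schedule()].
#' @return A \code{pcd_schedule}.
#' @export
build_tnf_schedule <- function(transition_time_min = 20) {
  ev <- data.frame(
    time = c(0, 20, 230, 280),
    group = c("all", "1", "2", "all"),
    reagent = c("medium", "TNF", "TNF", "PBS"))
  pcd_schedule(ev, t_end = 300, groups = c("1", "2", "3"),
               transition_time_min = transition_time_min)
}

#' The two-phase staining schedule
#'
#' Culture medium for 20 min, a first dye per group for 2 h, then -- with
#' no pause or wash -- a rotated dye per group for 3 h, and a PBS rinse of
#' at least 10 min.
#'
#' @param dye_rotation named character vector mapping each of three dye
#'   labels to the dye streamed in the second phase on the same group
#'   (must be a bijection on the three labels).
#' @param rinse_min PBS rinse length, min (>= 10).
#' @param transition_time_min see [pcd_schedule()].
#' @return A \code{pcd_schedule} with groups named after the phase-1 dyes.
#' @export
build_staining_schedule <- function(dye_rotation = c(green = "red",
                                                     red = "blue",
                                                     blue = "green"),
                                    rinse_min = 10,
                                    transition_time_min = 20) {
  dyes <- names(dye_rotation)
  if (length(dyes) != 3 || !setequal(dyes, unname(dye_rotation)))
    stop("dye_rotation must be a bijection on the three dye labels")
  if (rinse_min < 10) stop("the rinse lasts at least 10 min")
  ev <- rbind(
    data.frame(time = 0, group = "all", reagent = "medium"),
    data.frame(time = 20, group = dyes, reagent = dyes),
    data.frame(time = 140, group = dyes, reagent = unname(dye_rotation)),
    data.frame(time = 320, group = "all", reagent = "PBS"))
  pcd_schedule(ev, t_end = 320 + rinse_min, groups = dyes,
               transition_time_min = transition_time_min)
}

#' Effective exposures of a schedule
#'
#' For every contiguous (group, reagent) block, the effective exposure is
#' the wall-clock duration minus one transition time (floored at zero):
#' after a reagent switch the tissue concentration needs the transition
#' time to plateau, so that span does not count as exposure.  This
#' arithmetic reconciles the TNF timeline (TNF streamed 20-280 and 230-280
#' min) with its nominal 240 and 30 min exposures.
#'
#' @param schedule a [pcd_schedule()].
#' @return An \code{exposure_report} data frame: group, reagent, start,
#'   stop, nominal and effective minutes (one row per contiguous block),
#'   with the transition time recorded as an attribute.
#' @export
effective_exposures <- function(schedule) {
  blocks <- schedule_blocks(schedule)
  out <- do.call(rbind, lapply(names(blocks), function(g) {
    b <- blocks[[g]]
    cbind(group = g, b)
  }))
  out$nominal_min <- out$stop - out$start
  out$effective_min <- pmax(out$nominal_min - schedule$transition_time_min, 0)
  rownames(out) <- NULL
  structure(out, transition_time_min = schedule$transition_time_min,
            class = c("exposure_report", "data.frame"))
}

# Total effective exposure of one group to one reagent, min.
exposure_of <- function(report, group, reagent) {
  sel <- report$group == group & report$reagent == reagent
  sum(report$effective_min[sel])
}

#' Serialize a schedule to / from JSON
#'
#' @param schedule a [pcd_schedule()].
#' @param path file path.
#' @return `schedule_from_json()` returns the reconstructed schedule.
#' @export
schedule_to_json <- function(schedule, path) {
  jsonlite::write_json(list(events = schedule$events,
                            t_end = schedule$t_end,
                            groups = schedule$groups,
                            transition_time_min = schedule$transition_time_min),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname schedule_to_json
#' @export
schedule_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pcd_schedule(as.data.frame(x$events), t_end = x$t_end, groups = x$groups,
               transition_time_min = x$transition_time_min)
}

#' @export
print.pcd_schedule <- function(x, ...) {
  cat(sprintf("Schedule: %d events over %d min, groups {%s}, transition time %d min\n",
              nrow(x$events), x$t_end, paste(x$groups, collapse = ", "),
              x$transition_time_min))
  print.data.frame(x$events)
  invisible(x)
}
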