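#' Assign each trajectory frame to an arena zone
#'
#' Labels every frame by a point-in-region test.  Open-field precedence is
#' center > peripheral > middle with boundaries closed toward the more
#' extreme zone (a point exactly on the center-square edge is center; a
#' point exactly `peripheral_band_cm` from a wall is peripheral).  EPM
#' points on the center/arm boundary belong to the arm.  Samples outside
#' the arena beyond a 1-cm tolerance are flagged (`NA` zone), excluded from
#' durations and reported in `n_flagged`.
#'
#' @param traj a [trajectory()].
#' @param arena an [open_field_arena()], [epm_arena()] or
#'   [two_chamber_arena()].
#' @param tolerance_cm out-of-bounds tolerance (points within it are snapped
#'   to the nearest in-bounds zone).
#' @return An object of class `zone_series`: data frame `time_s`, `zone`
#'   (character, `NA` for flagged frames) with attributes `durations`
#'   (named numeric, s), `n_flagged`, `frame_rate_hz`, `arena`.
#' @examples
#' tr <- trajectory(seq(0, 1, by = 0.04), rep(20, 26), rep(20, 26), 25)
#' z <- assign_zones(tr, open_field_arena())
#' zone_durations(z)
#' @export
assign_zones <- function(traj, arena, tolerance_cm = 1) {
  stopifnot(inherits(traj, "trajectory"), inherits(arena, "arena_spec"))
  x <- traj$x_cm; y <- traj$y_cm
  zone <- switch(arena$kind,
    open_field = zones_open_field(x, y, arena, tolerance_cm),
    epm = zones_epm(x, y, arena, tolerance_cm),
    two_chamber = zones_two_chamber(x, y, arena, tolerance_cm))
  n_flagged <- sum(is.na(zone))
  if (n_flagged > 0)
    message(sprintf("assign_zones: %d frame(s) out of bounds, flagged and excluded", n_flagged))
  dt <- 1 / frame_rate(traj)
  labs <- arena_zones(arena)
  durations <- stats::setNames(vapply(labs, function(z)
    sum(zone == z, na.rm = TRUE) * dt, numeric(1)), labs)
  out <- data.frame(time_s = traj$time_s, zone = zone,
                    stringsAsFactors = FALSE)
  attr(out, "durations") <- durations
  attr(out, "n_flagged") <- n_flagged
  attr(out, "frame_rate_hz") <- frame_rate(traj)
  attr(out, "arena") <- arena
  class(out) <- c("zone_series", "data.frame")
  out
}

zones_open_field <- function(x, y, arena, tol) {
  s <- arena$side_cm; c2 <- arena$center_side_cm / 2; b <- arena$peripheral_band_cm
  oob <- x < -tol | x > s + tol | y < -tol | y > s + tol
  # snap tolerated out-of-bounds samples onto the wall
  xc <- pmin(pmax(x, 0), s); yc <- pmin(pmax(y, 0), s)
  lo <- s / 2 - c2; hi <- s / 2 + c2
  wall_dist <- pmin(xc, s - xc, yc, s - yc)
  zone <- ifelse(xc >= lo & xc <= hi & yc >= lo & yc <= hi, "center",
          ifelse(wall_dist <= b, "peripheral", "middle"))
  zone[oob] <- NA_character_
  zone
}

zones_epm <- function(x, y, arena, tol) {
  L <- arena$arm_length_cm; w2 <- arena$arm_width_cm / 2
  cs <- arena$center_side_cm; side <- 2 * L + cs
  mid <- side / 2
  in_x_band <- abs(y - mid) <= w2   # open arms run along x
  in_y_band <- abs(x - mid) <= w2   # closed arms run along y
  zone <- rep(NA_character_, length(x))
  cen_lo <- L; cen_hi <- L + cs
  # arms take precedence over the center square (boundary closed toward arm)
  zone[in_x_band & x <= cen_lo] <- "open_arm_1"
  zone[in_x_band & x >= cen_hi] <- "open_arm_2"
  zone[in_y_band & y <= cen_lo & is.na(zone)] <- "closed_arm_1"
  zone[in_y_band & y >= cen_hi & is.na(zone)] <- "closed_arm_2"
  in_center <- x > cen_lo & x < cen_hi & y > cen_lo & y < cen_hi
  zone[is.na(zone) & in_center] <- "epm_center"
  # tolerated off-maze samples snap to the nearest band
  off <- is.na(zone)
  near_x <- abs(y - mid) <= w2 + tol
  near_y <- abs(x - mid) <= w2 + tol
  zone[off & near_x & x <= cen_lo] <- "open_arm_1"
  zone[off & near_x & x >= cen_hi] <- "open_arm_2"
  off <- is.na(zone)
  zone[off & near_y & y <= cen_lo] <- "closed_arm_1"
  zone[off & near_y & y >= cen_hi] <- "closed_arm_2"
  zone
}

zones_two_chamber <- function(x, y, arena, tol) {
  cs <- arena$chamber_side_cm; g <- arena$gap_cm
  oob <- x < -tol | x > 2 * cs + g + tol | y < -tol | y > cs + tol
  zone <- ifelse(x <= cs, "chamber_1",
          ifelse(x >= cs + g, "chamber_2", "gap"))
  zone[oob] <- NA_character_
  zone
}

#' @export
print.zone_series <- function(x, ...) {
  cat("<zone_series>", nrow(x), "frames;",
      attr(x, "n_flagged"), "flagged\n")
  print(round(attr(x, "durations"), 2))
  invisible(x)
}

#' Per-zone total durations of a zone series
#' @param zones a `zone_series`.
#' @return named numeric vector of durations in seconds.
#' @export
zone_durations <- function(zones) attr(zones, "durations")

#' Per-epoch, per-zone occupancy durations
#'
#' Tallies the time spent in each zone within each epoch.  A frame belongs
#' to an epoch when `start_s <= time_s < end_s`.  Per-epoch durations sum to
#' the epoch length covered by frames (within one frame interval).
#'
#' @param zones a `zone_series` from [assign_zones()].
#' @param epochs data frame with columns `label`, `start_s`, `end_s`;
#'   epochs must not overlap.
#' @return long data frame `epoch`, `zone`, `duration_s`.
#' @export
occupancy_summary <- function(zones, epochs) {
  stopifnot(inherits(zones, "zone_series"),
            all(c("label", "start_s", "end_s") %in% names(epochs)))
  ep <- epochs[order(epochs$start_s), , drop = FALSE]
  if (nrow(ep) > 1 && any(ep$start_s[-1] < ep$end_s[-nrow(ep)]))
    stop("epochs must not overlap")
  tr_lo <- zones$time_s[1]; tr_hi <- zones$time_s[nrow(zones)]
  if (any(ep$end_s < tr_lo) || any(ep$start_s > tr_hi))
    stop("epochs must lie within the recording")
  dt <- 1 / attr(zones, "frame_rate_hz")
  labs <- arena_zones(attr(zones, "arena"))
  out <- do.call(rbind, lapply(seq_len(nrow(ep)), function(i) {
    sel <- zones$time_s >= ep$start_s[i] & zones$time_s < ep$end_s[i]
    if (!any(sel)) warning(sprintf("epoch '%s' contains no frames", ep$label[i]))
    z <- zones$zone[sel]
    data.frame(epoch = ep$label[i], zone = labs,
               duration_s = vapply(labs, function(l)
                 sum(z == l, na.rm = TRUE) * dt, numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out
}

#' Closed-loop zone trigger mask
#'
#' Emulates position-triggered light delivery: the mask is true exactly on
#' frames inside `active_epoch` whose zone is in `trigger_zones`.  Rising
#' and falling edges (light on/off times) are returned alongside.
#'
#' @param zones a `zone_series`.
#' @param trigger_zones character vector of zone labels that trigger.
#' @param active_epoch numeric length 2, `(start_s, end_s)` of the phase in
#'   which triggering is armed.
#' @return list with `mask` (logical per frame) and `edges` (data frame
#'   `on_s`, `off_s`).
#' @export
trigger_mask <- function(zones, trigger_zones, active_epoch) {
  stopifnot(inherits(zones, "zone_series"), length(active_epoch) == 2)
  labs <- arena_zones(attr(zones, "arena"))
  if (!all(trigger_zones %in% labs))
    stop("trigger_zones must be valid zone labels for this arena")
  t <- zones$time_s
  if (active_epoch[1] > t[length(t)] || active_epoch[2] < t[1] ||
      active_epoch[1] >= active_epoch[2])
    stop("active_epoch outside recording")
  mask <- t >= active_epoch[1] & t < active_epoch[2] &
    !is.na(zones$zone) & zones$zone %in% trigger_zones
  d <- diff(c(FALSE, mask, FALSE))
  on_i <- which(d == 1); off_i <- which(d == -1) - 1L
  dt <- 1 / attr(zones, "frame_rate_hz")
  edges <- data.frame(on_s = t[on_i], off_s = t[off_i] + dt)
  list(mask = mask, edges = edges)
}
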