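BOUT_LABELS <- c("approach", "retreat", "freeze", "SAP", "jump", "head_dip",
                 "body_elongation", "investigation", "sniff", "mount")

#' Behavioral bout table
#'
#' A bout table holds labeled behavioral intervals.  Rows are sorted by
#' start time; bouts sharing a label must not overlap.
#'
#' @param label character vector of bout labels (see `BOUT_LABELS`).
#' @param start_s,end_s bout boundaries in seconds, `start_s < end_s`.
#' @return data frame of class `bout_table`.
#' @export
bout_table <- function(label = character(), start_s = numeric(),
                       end_s = numeric()) {
  label <- as.character(label)
  stopifnot(length(label) == length(start_s), length(start_s) == length(end_s))
  if (!all(label %in% BOUT_LABELS))
    stop("unknown bout label(s): ",
         paste(setdiff(label, BOUT_LABELS), collapse = ", "))
  if (any(start_s >= end_s)) stop("bouts must have start_s < end_s")
  o <- order(start_s)
  d <- data.frame(label = label[o], start_s = start_s[o], end_s = end_s[o],
                  stringsAsFactors = FALSE)
  for (l in unique(d$label)) {
    b <- d[d$label == l, ]
    if (nrow(b) > 1 && any(b$start_s[-1] < b$end_s[-nrow(b)]))
      stop("overlapping bouts with label '", l, "'")
  }
  class(d) <- c("bout_table", "data.frame")
  d
}

#' Read / write bout CSV (columns label,start_s,end_s)
#' @param path file path.
#' @return a `bout_table`.
#' @export
read_bouts <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  bout_table(d$label, d$start_s, d$end_s)
}

#' @rdname read_bouts
#' @param bouts a `bout_table`.
#' @export
write_bouts <- function(bouts, path) {
  utils::write.csv(format_num_df(as.data.frame(bouts)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Detect approach-retreat bouts toward the open-field object
#'
#' Automatic surrogate for manual annotation of object-directed excursions.
#' The distance to the object is smoothed with a centered moving median,
#' candidate excursions are found as alternating extrema of the smoothed
#' distance (small oscillations below `hysteresis_cm` are pruned), and an
#' approach is accepted when the descent covers at least `min_disp_cm`,
#' lasts at least `min_dur_s` and has a mean radial speed of at least
#' `v_min_cm_s`.  The approach ends (and the retreat starts) at the local
#' distance minimum, the "turning point".  Bout onsets/offsets are refined
#' to the span where the radial speed exceeds `v_min_cm_s / 2`, so that slow
#' drift preceding a dash toward the object is not counted as approach.
#'
#' @param traj a [trajectory()].
#' @param arena an [open_field_arena()] with `object_xy` set.
#' @param smooth_s moving-median window (s).
#' @param v_min_cm_s minimum mean radial speed.
#' @param min_disp_cm minimum net displacement toward/away from the object.
#' @param min_dur_s minimum bout duration.
#' @param hysteresis_cm extrema-pruning threshold.
#' @return a `bout_table` with `approach` and `retreat` rows; each approach
#'   is followed by at most one retreat.
#' @export
detect_approach_retreat <- function(traj, arena, smooth_s = 0.5,
                                    v_min_cm_s = 2, min_disp_cm = 5,
                                    min_dur_s = 0.5, hysteresis_cm = 1) {
  stopifnot(inherits(traj, "trajectory"), inherits(arena, "arena_spec"))
  if (arena$kind != "open_field" || is.null(arena$object_xy))
    stop("detect_approach_retreat needs an open-field arena with object_xy")
  t <- traj$time_s
  if (t[length(t)] - t[1] < smooth_s)
    stop("trajectory shorter than the smoothing window")
  d <- sqrt((traj$x_cm - arena$object_xy[1])^2 +
            (traj$y_cm - arena$object_xy[2])^2)
  fr <- frame_rate(traj)
  k <- max(3L, as.integer(round(smooth_s * fr)))
  if (k %% 2 == 0) k <- k + 1L
  ds <- as.numeric(stats::runmed(d, k))
  ext <- zigzag_extrema(ds, hysteresis_cm)
  dt <- 1 / fr
  v <- c(0, diff(ds)) / dt   # radial velocity of smoothed distance
  n <- length(ds)
  # the moving median flattens the distance minimum into a short plateau;
  # recover the exact turning point from the raw distance around it
  turn_at <- function(i) {
    w <- max(1, i - k):min(n, i + k)
    w[which.min(d[w])]
  }
  res <- list()
  if (nrow(ext) >= 2) {
    for (i in seq_len(nrow(ext) - 1)) {
      i0 <- ext$index[i]; i1 <- ext$index[i + 1]
      going_in <- ext$type[i] == "max"   # max -> min segment
      if (going_in) {
        # skip the smoothing plateau at the valley floor (at most one
        # smoothing window), then walk back through the final descent
        j1 <- i1
        while (j1 - 1 >= max(i0, i1 - k) && v[j1] >= -v_min_cm_s / 2)
          j1 <- j1 - 1
        j <- j1
        while (j - 1 >= i0 && v[j] < -v_min_cm_s / 2) j <- j - 1
        seg <- c(j, turn_at(i1))
        disp <- ds[j] - ds[i1]
      } else {
        # skip the valley-floor plateau, then follow the rise
        j0 <- i0
        while (j0 + 1 <= min(i1, i0 + k) && v[j0 + 1] <= v_min_cm_s / 2)
          j0 <- j0 + 1
        j <- j0
        while (j + 1 <= i1 && v[j + 1] > v_min_cm_s / 2) j <- j + 1
        seg <- c(turn_at(i0), j)
        disp <- ds[j] - ds[i0]
      }
      dur <- t[seg[2]] - t[seg[1]]
      if (seg[2] > seg[1] && disp >= min_disp_cm && dur >= min_dur_s &&
          disp / dur >= v_min_cm_s) {
        res[[length(res) + 1]] <- data.frame(
          label = if (going_in) "approach" else "retreat",
          start_s = t[seg[1]], end_s = t[seg[2]])
      }
    }
  }
  if (!length(res)) return(bout_table())
  b <- do.call(rbind, res)
  # keep at most one retreat per approach: a retreat must start within half
  # the minimum bout duration of the preceding approach's turning point
  keep <- rep(TRUE, nrow(b))
  b <- b[order(b$start_s), ]
  pair_tol <- max(min_dur_s, 2 * dt)
  for (i in which(b$label == "retreat")) {
    prev <- which(b$label == "approach" & b$end_s <= b$start_s[i] + 1e-9)
    if (!length(prev) || b$start_s[i] - max(b$end_s[prev]) > pair_tol + 1e-9)
      keep[i] <- FALSE
  }
  b <- b[keep, , drop = FALSE]
  bout_table(b$label, b$start_s, b$end_s)
}

# alternating extrema of a series with hysteresis pruning; for a maximum the
# last index attaining the extreme value is kept (so a dwell before a descent
# maps to the dwell's end), for a minimum the first index (the turning point)
zigzag_extrema <- function(x, hyst) {
  n <- length(x)
  idx <- integer(0); typ <- character(0)
  cur_i <- 1L; cur_v <- x[1]
  dir <- 0L  # 0 unknown, +1 rising (tracking max), -1 falling (tracking min)
  for (i in 2:n) {
    v <- x[i]
    if (dir >= 0) {               # tracking a maximum
      if (v >= cur_v) { cur_v <- v; cur_i <- i }
      else if (cur_v - v >= hyst) {
        idx <- c(idx, cur_i); typ <- c(typ, "max")
        dir <- -1L; cur_v <- v; cur_i <- i
      }
      if (dir == 0L && v - x[1] >= hyst) dir <- 1L
    } else {                      # tracking a minimum
      if (v < cur_v) { cur_v <- v; cur_i <- i }
      else if (v - cur_v >= hyst) {
        idx <- c(idx, cur_i); typ <- c(typ, "min")
        dir <- 1L; cur_v <- v; cur_i <- i
      }
    }
  }
  idx <- c(idx, cur_i); typ <- c(typ, if (dir < 0) "min" else "max")
  data.frame(index = idx, type = typ, stringsAsFactors = FALSE)
}

#' Exclude bouts separated by less than a minimum interval
#'
#' Consecutive same-label bouts whose gap (next start minus current end) is
#' strictly less than `min_gap_s` are both excluded; a gap of exactly
#' `min_gap_s` is retained.  Exclusion (not merging) mirrors how rapid
#' re-engagements are dropped from correlation analyses.  The operation is
#' idempotent.
#'
#' @param bouts a `bout_table`, sorted.
#' @param min_gap_s minimum allowed gap in seconds (default 1).
#' @return filtered `bout_table`.
#' @export
enforce_min_interval <- function(bouts, min_gap_s = 1.0) {
  stopifnot(inherits(bouts, "bout_table"))
  if (min_gap_s < 0) stop("min_gap_s must be nonnegative")
  if (nrow(bouts) < 2) return(bouts)
  drop <- rep(FALSE, nrow(bouts))
  for (l in unique(bouts$label)) {
    i <- which(bouts$label == l)
    if (length(i) < 2) next
    gaps <- bouts$start_s[i[-1]] - bouts$end_s[i[-length(i)]]
    close <- which(gaps < min_gap_s)
    drop[i[close]] <- TRUE
    drop[i[close + 1]] <- TRUE
  }
  out <- bouts[!drop, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bout_table", "data.frame")
  out
}

#' Frame-wise behavior mask from a bout table
#'
#' @param bouts a `bout_table`.
#' @param time_s frame times.
#' @param labels bout labels included in the mask (default approach+retreat).
#' @return logical vector, TRUE on frames inside a bout.
#' @export
bouts_to_mask <- function(bouts, time_s,
                          labels = c("approach", "retreat")) {
  mask <- rep(FALSE, length(time_s))
  b <- bouts[bouts$label %in% labels, , drop = FALSE]
  for (i in seq_len(nrow(b)))
    mask <- mask | (time_s >= b$start_s[i] & time_s <= b$end_s[i])
  mask
}

#' Mean locomotion velocity
#'
#' Total path length divided by either the moving time (frames whose
#' 0.5-s-smoothed instantaneous speed exceeds `moving_threshold_cm_s`) or a
#' fixed window length (`window_s`), matching the two velocity conventions
#' used for open-field/EPM scoring and for staged stimulation epochs.
#'
#' @param traj a [trajectory()].
#' @param mode `"moving_time"` or `"fixed_window"`.
#' @param window_s divisor for `fixed_window` mode (default 30 s).
#' @param moving_threshold_cm_s speed above which a frame counts as moving.
#' @param smooth_s speed smoothing window for the moving classification.
#' @return velocity in cm/s; `NA` (with a warning) if moving time is zero.
#' @export
compute_velocity <- function(traj, mode = c("moving_time", "fixed_window"),
                             window_s = 30, moving_threshold_cm_s = 1,
                             smooth_s = 0.5) {
  mode <- match.arg(mode)
  step <- sqrt(diff(traj$x_cm)^2 + diff(traj$y_cm)^2)
  path <- sum(step)
  if (mode == "fixed_window") return(path / window_s)
  dt <- diff(traj$time_s)
  speed <- step / dt
  k <- max(1L, as.integer(round(smooth_s * frame_rate(traj))))
  if (k > 1) speed <- stats::filter(speed, rep(1 / k, k), sides = 2)
  moving <- !is.na(speed) & speed > moving_threshold_cm_s
  moving_time <- sum(dt[moving])
  if (moving_time == 0) {
    warning("zero moving time; velocity undefined")
    return(NA_real_)
  }
  path / moving_time
}
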