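#' Animal trajectory
#'
#' A trajectory is a data frame with columns `time_s`, `x_cm`, `y_cm` and a
#' nominal frame rate.  Time must be strictly increasing and the median
#' frame interval must agree with the nominal rate within 10%.
#'
#' @param time_s strictly increasing times in seconds.
#' @param x_cm,y_cm positions in cm.
#' @param frame_rate_hz nominal video frame rate (20-30 Hz typical).
#' @return data frame of class `trajectory` with attribute `frame_rate_hz`.
#' @export
trajectory <- function(time_s, x_cm, y_cm, frame_rate_hz = 25) {
  time_s <- as.numeric(time_s); x_cm <- as.numeric(x_cm); y_cm <- as.numeric(y_cm)
  n <- length(time_s)
  if (n < 2) stop("trajectory needs at least 2 samples")
  if (length(x_cm) != n || length(y_cm) != n)
    stop("time_s, x_cm, y_cm must have equal length")
  if (anyNA(time_s) || anyNA(x_cm) || anyNA(y_cm))
    stop("trajectory must have no missing samples")
  dt <- diff(time_s)
  if (any(dt <= 0)) stop("time_s must be strictly increasing")
  if (abs(stats::median(dt) - 1 / frame_rate_hz) > 0.1 / frame_rate_hz)
    stop("median frame interval inconsistent with frame_rate_hz (>10% off)")
  out <- data.frame(time_s = time_s, x_cm = x_cm, y_cm = y_cm)
  attr(out, "frame_rate_hz") <- frame_rate_hz
  class(out) <- c("trajectory", "data.frame")
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames, %.1f s at %g Hz\n",
              nrow(x), x$time_s[nrow(x)] - x$time_s[1],
              attr(x, "frame_rate_hz")))
  invisible(x)
}

#' Frame rate of a trajectory
#' @param traj a `trajectory`.
#' @return nominal frame rate in Hz.
#' @export
frame_rate <- function(traj) attr(traj, "frame_rate_hz")

#' Read / write trajectory CSV (columns time_s,x_cm,y_cm)
#'
#' @param path file path.
#' @param frame_rate_hz nominal frame rate; if `NULL`, inferred from the
#'   median frame interval.
#' @return `read_trajectory` returns a `trajectory`.
#' @export
read_trajectory <- function(path, frame_rate_hz = NULL) {
  d <- utils::read.csv(path)
  need <- c("time_s", "x_cm", "y_cm")
  if (!all(need %in% names(d)))
    stop("trajectory CSV must have columns time_s,x_cm,y_cm")
  if (is.null(frame_rate_hz))
    frame_rate_hz <- 1 / stats::median(diff(d$time_s))
  trajectory(d$time_s, d$x_cm, d$y_cm, frame_rate_hz)
}

#' @rdname read_trajectory
#' @param traj a `trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(format_num_df(as.data.frame(traj)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
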