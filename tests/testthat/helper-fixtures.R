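# small deterministic fixtures shared across tests

# straight-line trajectory at constant frame rate
line_traj <- function(from, to, duration_s = 10, fr = 25) {
  t <- seq(0, duration_s, by = 1 / fr)
  trajectory(t,
             seq(from[1], to[1], length.out = length(t)),
             seq(from[2], to[2], length.out = length(t)), fr)
}

# stationary animal
still_traj <- function(xy = c(5, 5), duration_s = 10, fr = 25) {
  t <- seq(0, duration_s, by = 1 / fr)
  trajectory(t, rep(xy[1], length(t)), rep(xy[2], length(t)), fr)
}

# piecewise-linear track visiting given waypoints at given times,
# sampled at the frame rate
waypoint_traj <- function(times, xs, ys, fr = 25) {
  t <- seq(times[1], times[length(times)], by = 1 / fr)
  trajectory(t, stats::approx(times, xs, t)$y, stats::approx(times, ys, t)$y,
             fr)
}

# uniform fluor trace from a function of time
make_trace <- function(f, duration_s = 120, fs = 100) {
  t <- seq(0, duration_s, by = 1 / fs)
  fluor_trace(t, f(t))
}

# dff trace directly from values (bypassing detrending) for unit tests
make_dff <- function(values, fs = 100, t0 = 0) {
  t <- t0 + seq_along(values) / fs - 1 / fs
  d <- data.frame(time_s = t, dff = values)
  attr(d, "F0") <- 1
  attr(d, "baseline") <- structure(list(context = "synthetic",
                                        window = range(t)),
                                   class = "baseline_spec")
  attr(d, "fs_hz") <- fs
  class(d) <- c("dff_trace", "data.frame")
  d
}
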