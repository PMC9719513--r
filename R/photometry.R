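#' Fluorescence trace
#'
#' Uniformly sampled raw fluorescence (nominal 500 Hz acquisition, possibly
#' downsampled).  `F_adj` (trend-adjusted fluorescence) is added by
#' [detrend_trace()].
#'
#' @param time_s uniformly spaced times in seconds.
#' @param F_raw raw fluorescence, arbitrary units.
#' @param F_adj optional trend-adjusted fluorescence.
#' @return data frame of class `fluor_trace`.
#' @export
fluor_trace <- function(time_s, F_raw, F_adj = NULL) {
  time_s <- as.numeric(time_s); F_raw <- as.numeric(F_raw)
  stopifnot(length(time_s) == length(F_raw), length(time_s) >= 2)
  dt <- diff(time_s)
  if (any(abs(dt - stats::median(dt)) > 0.01 * stats::median(dt)))
    stop("fluorescence sampling must be uniform within 1%")
  d <- data.frame(time_s = time_s, F_raw = F_raw)
  if (!is.null(F_adj)) {
    stopifnot(length(F_adj) == length(time_s))
    d$F_adj <- as.numeric(F_adj)
  }
  attr(d, "fs_hz") <- 1 / stats::median(dt)
  class(d) <- c("fluor_trace", "data.frame")
  d
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("<fluor_trace> %d samples at %.1f Hz%s\n", nrow(x),
              attr(x, "fs_hz"), if ("F_adj" %in% names(x)) " (detrended)" else ""))
  invisible(x)
}

#' Read fluorescence CSV (columns time_s,F_raw)
#' @param path file path.
#' @return a `fluor_trace`.
#' @export
read_fluor <- function(path) {
  d <- utils::read.csv(path)
  fluor_trace(d$time_s, d$F_raw)
}

#' Remove the slow photobleaching trend from a fluorescence trace
#'
#' Default method fits a mono-exponential `a*exp(-t/tau) + c` to the raw
#' trace by least squares and subtracts the fitted trend minus its final
#' value, an additive correction that preserves units and scale.  The
#' alternative subtracts a running 8th-percentile baseline (60-s window)
#' the same way.  A non-convergent exponential fit falls back to the
#' running percentile with a warning.
#'
#' @param trace a [fluor_trace()] of at least 60 s.
#' @param method `"exp_fit"` (default) or `"running_percentile"`.
#' @param window_s running-percentile window.
#' @param percentile running-percentile level.
#' @return the trace with an `F_adj` column and attribute `detrend` listing
#'   the method and fitted parameters.
#' @export
detrend_trace <- function(trace, method = c("exp_fit", "running_percentile"),
                          window_s = 60, percentile = 0.08) {
  stopifnot(inherits(trace, "fluor_trace"))
  method <- match.arg(method)
  t <- trace$time_s; f <- trace$F_raw
  if (t[length(t)] - t[1] < 60) stop("trace must be at least 60 s")
  info <- list(method = method)
  trend <- NULL
  if (method == "exp_fit") {
    # the trend is slow, so fit on a decimated grid and evaluate everywhere
    idx <- unique(round(seq(1, length(t), length.out = min(length(t), 2000))))
    td <- t[idx] - t[1]; fd <- f[idx]
    fit <- try(suppressWarnings({
      b0 <- as.numeric(stats::quantile(fd, 0.05))
      a0 <- max(mean(fd[seq_len(max(2, length(fd) %/% 100))]) - b0, 1e-6)
      tau0 <- (t[length(t)] - t[1]) / 2
      minpack.lm::nlsLM(fd ~ a * exp(-td / tau) + b,
                        start = list(a = a0, tau = tau0, b = b0),
                        lower = c(a = 0, tau = 1e-3, b = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }), silent = TRUE)
    if (inherits(fit, "try-error")) {
      warning("exponential fit did not converge; falling back to running percentile")
      method <- "running_percentile"
      info$method <- "running_percentile"
      info$fallback <- TRUE
    } else {
      p <- stats::coef(fit)
      trend <- p[["a"]] * exp(-(t - t[1]) / p[["tau"]]) + p[["b"]]
      info$pars <- as.list(p)
    }
  }
  if (method == "running_percentile") {
    trend <- running_percentile(f, t, window_s, percentile)
    info$window_s <- window_s; info$percentile <- percentile
  }
  out <- trace
  out$F_adj <- f - (trend - trend[length(trend)])
  attr(out, "detrend") <- info
  attr(out, "fs_hz") <- attr(trace, "fs_hz")
  class(out) <- class(trace)
  out
}

# running quantile evaluated on a coarse grid of window centers and linearly
# interpolated; exact sliding quantiles at 500 Hz would be needlessly slow
running_percentile <- function(f, t, window_s, p) {
  dur <- t[length(t)] - t[1]
  centers <- seq(t[1], t[length(t)], by = max(window_s / 4, dur / 400))
  q <- vapply(centers, function(tc) {
    sel <- t >= tc - window_s / 2 & t <= tc + window_s / 2
    as.numeric(stats::quantile(f[sel], p))
  }, numeric(1))
  stats::approx(centers, q, xout = t, rule = 2)$y
}

#' Baseline specification for dF/F
#'
#' Encodes the four context-specific baseline rules: open field, new cage
#' and home cage use the mean fluorescence over the pre-stimulus window
#' (the 10 min before object/stimulus introduction); the EPM uses the mean
#' over the whole trial.
#'
#' @param context one of `"open_field_pre_object"`, `"new_cage_pre_stimulus"`,
#'   `"home_cage_pre_stimulus"`, `"epm_whole_trial"`.
#' @param stimulus_in_s stimulus/object introduction time (required for the
#'   pre-stimulus contexts).
#' @param trial_end_s end of the trial (required for `epm_whole_trial`).
#' @param start_s start of the baseline window (default 0).
#' @return list of class `baseline_spec` with the window.
#' @export
baseline_spec <- function(context = c("open_field_pre_object",
                                      "new_cage_pre_stimulus",
                                      "home_cage_pre_stimulus",
                                      "epm_whole_trial"),
                          stimulus_in_s = NULL, trial_end_s = NULL,
                          start_s = 0) {
  context <- match.arg(context)
  window <- if (context == "epm_whole_trial") {
    if (is.null(trial_end_s)) stop("epm_whole_trial needs trial_end_s")
    c(start_s, trial_end_s)
  } else {
    if (is.null(stimulus_in_s)) stop(context, " needs stimulus_in_s")
    c(start_s, stimulus_in_s)
  }
  if (diff(window) <= 0) stop("baseline window must have positive length")
  structure(list(context = context, window = window), class = "baseline_spec")
}

#' Compute dF/F from a detrended trace
#'
#' `dff(t) = (F_adj(t) - F0) / F0` with `F0` the mean of `F_adj` over the
#' baseline window.  dF/F is a unitless fraction internally; multiply by
#' 100 for percent at presentation.
#'
#' @param trace a detrended [fluor_trace()] (with `F_adj`).
#' @param baseline a [baseline_spec()].
#' @return data frame of class `dff_trace` (`time_s`, `dff`) with
#'   attributes `F0`, `baseline` and `fs_hz`.
#' @export
compute_dff <- function(trace, baseline) {
  stopifnot(inherits(trace, "fluor_trace"), inherits(baseline, "baseline_spec"))
  if (!"F_adj" %in% names(trace)) stop("trace must be detrended first")
  w <- baseline$window
  if (w[1] < trace$time_s[1] - 1e-9 || w[2] > trace$time_s[nrow(trace)] + 1e-9)
    stop("baseline window outside recording")
  # pre-stimulus baselines end strictly before the stimulus moment; the
  # whole-trial baseline includes its final sample
  sel <- if (baseline$context == "epm_whole_trial")
    trace$time_s >= w[1] & trace$time_s <= w[2]
  else trace$time_s >= w[1] & trace$time_s < w[2]
  F0 <- mean(trace$F_adj[sel])
  if (F0 <= 0) stop("baseline F0 <= 0: detrending produced nonphysical values")
  out <- data.frame(time_s = trace$time_s, dff = (trace$F_adj - F0) / F0)
  attr(out, "F0") <- F0
  attr(out, "baseline") <- baseline
  attr(out, "fs_hz") <- attr(trace, "fs_hz")
  class(out) <- c("dff_trace", "data.frame")
  out
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf("<dff_trace> %d samples, F0 = %.3f (%s)\n", nrow(x),
              attr(x, "F0"), attr(x, "baseline")$context))
  invisible(x)
}

#' Per-zone mean dF/F
#'
#' Matches each trajectory frame to the nearest dF/F sample (no
#' interpolation of the raw signal) and averages the matched values per
#' zone over the frames of `epoch`.
#'
#' @param dff a `dff_trace`.
#' @param zones a `zone_series`.
#' @param epoch numeric length 2 `(start_s, end_s)`, or `NULL` for the
#'   whole series.
#' @return named numeric: mean dF/F per zone (`NA` for unvisited zones).
#' @export
zone_mean_dff <- function(dff, zones, epoch = NULL) {
  stopifnot(inherits(dff, "dff_trace"), inherits(zones, "zone_series"))
  sel <- rep(TRUE, nrow(zones))
  if (!is.null(epoch))
    sel <- zones$time_s >= epoch[1] & zones$time_s < epoch[2]
  if (!any(sel)) stop("epoch contains no frames")
  ft <- zones$time_s[sel]; fz <- zones$zone[sel]
  vals <- dff$dff[nearest_index(ft, dff$time_s)]
  labs <- arena_zones(attr(zones, "arena"))
  stats::setNames(vapply(labs, function(l) {
    v <- vals[!is.na(fz) & fz == l]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1)), labs)
}

#' Event-aligned dF/F average with nested (event-then-animal) averaging
#'
#' Segments each animal's dF/F trace around event onsets, averages first
#' across events within the animal and then across animals; SEM is computed
#' across animals.  Partial windows at the recording edges are dropped with
#' a warning.  With unbalanced event counts this differs from pooling all
#' events, and deliberately so: every animal contributes equally.
#'
#' @param traces a single `dff_trace` or a named list of them (one per
#'   animal).
#' @param events numeric vector of onsets, or a named list parallel to
#'   `traces`.
#' @param pre_s,post_s window around each onset in seconds.
#' @return list of class `event_aligned`: `time_s` (relative grid),
#'   `per_animal` (matrix animals x time), `mean`, `sem`, `n_events`
#'   (per animal), `n_animals`.
#' @export
align_to_events <- function(traces, events, pre_s = 5, post_s = 5) {
  if (inherits(traces, "dff_trace")) {
    traces <- list(animal_1 = traces)
    events <- list(animal_1 = events)
  }
  stopifnot(is.list(traces), is.list(events),
            length(traces) == length(events))
  fs <- attr(traces[[1]], "fs_hz")
  rel <- seq(-round(pre_s * fs), round(post_s * fs)) / fs
  per_animal <- list(); n_events <- integer(0)
  for (a in seq_along(traces)) {
    tr <- traces[[a]]
    segs <- extract_segments(tr, events[[a]], pre_s, post_s)
    if (is.null(segs)) {
      message("align_to_events: animal ", a, " has no usable events; dropped")
      next
    }
    per_animal[[length(per_animal) + 1]] <- colMeans(segs)
    names(per_animal)[length(per_animal)] <-
      if (!is.null(names(traces))) names(traces)[a] else paste0("animal_", a)
    n_events <- c(n_events, nrow(segs))
  }
  if (!length(per_animal)) stop("no animal had usable events")
  m <- do.call(rbind, per_animal)
  structure(list(time_s = rel, per_animal = m,
                 mean = colMeans(m),
                 sem = apply(m, 2, sem),
                 n_events = n_events, n_animals = nrow(m)),
            class = "event_aligned")
}

extract_segments <- function(trace, onsets, pre_s, post_s) {
  fs <- attr(trace, "fs_hz")
  npre <- round(pre_s * fs); npost <- round(post_s * fs)
  n <- nrow(trace)
  idx <- nearest_index(onsets, trace$time_s)
  ok <- idx - npre >= 1 & idx + npost <= n
  if (any(!ok))
    warning(sprintf("%d partial event window(s) dropped", sum(!ok)))
  idx <- idx[ok]
  if (!length(idx)) return(NULL)
  t(vapply(idx, function(i) trace$dff[(i - npre):(i + npost)],
           numeric(npre + npost + 1)))
}

#' Consecutive 30-s window means around a stimulus
#'
#' Tiles non-overlapping windows of `window_s` backward and forward from
#' the stimulus time over the whole recording and returns each window's
#' mean dF/F.  Window index -1 is the window immediately before the
#' stimulus, +1 immediately after.
#'
#' @param dff a `dff_trace`.
#' @param stimulus_in_s stimulus time in seconds.
#' @param window_s window length (default 30).
#' @return data frame `window`, `start_s`, `end_s`, `mean_dff`.
#' @export
stimulus_window_means <- function(dff, stimulus_in_s, window_s = 30) {
  t0 <- dff$time_s[1]; t1 <- dff$time_s[nrow(dff)]
  if (stimulus_in_s < t0 || stimulus_in_s > t1)
    stop("stimulus time outside recording")
  n_pre <- floor((stimulus_in_s - t0) / window_s)
  n_post <- floor((t1 - stimulus_in_s) / window_s)
  if (n_pre < 1 || n_post < 1)
    stop("need at least one full window before and after the stimulus")
  idx <- c(-(n_pre:1), 1:n_post)
  out <- do.call(rbind, lapply(idx, function(k) {
    s <- stimulus_in_s + if (k < 0) k * window_s else (k - 1) * window_s
    e <- s + window_s
    sel <- dff$time_s >= s & dff$time_s < e
    data.frame(window = k, start_s = s, end_s = e, mean_dff = mean(dff$dff[sel]))
  }))
  out
}

#' dF/F at approach ends and latency to the next approach
#'
#' Extracts the dF/F value at each approach's end (the turning point before
#' the retreat) and the latency from that end to the next approach's start.
#' The first approach is excluded by default to rule out initial-exposure
#' effects; the last approach has no defined latency.
#'
#' @param dff a `dff_trace`.
#' @param bouts a `bout_table` containing approach rows.
#' @param exclude_first drop the first approach (default TRUE).
#' @return data frame `bout_index`, `end_s`, `dff_end`, `latency_s`
#'   (`NA` for the last approach).
#' @export
approach_end_series <- function(dff, bouts, exclude_first = TRUE) {
  app <- bouts[bouts$label == "approach", , drop = FALSE]
  if (!nrow(app)) {
    warning("no approaches in bout table")
    return(data.frame(bout_index = integer(), end_s = numeric(),
                      dff_end = numeric(), latency_s = numeric()))
  }
  app <- app[order(app$start_s), ]
  latency <- c(app$start_s[-1] - app$end_s[-nrow(app)], NA_real_)
  vals <- dff$dff[nearest_index(app$end_s, dff$time_s)]
  out <- data.frame(bout_index = seq_len(nrow(app)), end_s = app$end_s,
                    dff_end = vals, latency_s = latency)
  if (exclude_first && nrow(out) >= 1) out <- out[-1, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binarize a fluorescence signal at k standard deviations
#'
#' Marks samples where the trend-adjusted fluorescence exceeds
#' `mean + k_sd * SD` (upper-tail default, since calcium transients are
#' positive deflections) or deviates from the mean by more than
#' `k_sd * SD` in either direction (`sided = "two"`).  Mean and SD are
#' taken over the full analyzed epoch of the supplied series.
#'
#' @param trace a `fluor_trace` with `F_adj`, a `dff_trace`, or a bare
#'   numeric vector.
#' @param k_sd threshold in SD units (default 2).
#' @param sided `"upper"` or `"two"`.
#' @return logical vector.
#' @export
binarize_signal <- function(trace, k_sd = 2, sided = c("upper", "two")) {
  sided <- match.arg(sided)
  x <- if (is.numeric(trace)) trace
       else if (inherits(trace, "dff_trace")) trace$dff
       else if ("F_adj" %in% names(trace)) trace$F_adj
       else stop("trace must carry F_adj (detrend first) or be a dff_trace")
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) stop("degenerate trace: SD = 0")
  if (sided == "upper") x > m + k_sd * s else abs(x - m) > k_sd * s
}

#' Spearman correlation between binarized signal and behavior masks
#'
#' Computes the Spearman rank correlation (midranks) between two 0/1 series
#' on a common time base, e.g. the 2-SD-binarized fluorescence and the
#' frame-wise approach-retreat mask after [enforce_min_interval()].  On
#' binary data this equals the phi coefficient.  p is two-sided
#' (t approximation, appropriate for the long series involved).
#'
#' @param signal_mask,behavior_mask logical/0-1 vectors of equal length.
#' @return a `correlation_result` (r, p, n, method); r is `NA` with a
#'   `degenerate` flag when either mask is constant.
#' @export
binarized_activity_correlation <- function(signal_mask, behavior_mask) {
  stopifnot(length(signal_mask) == length(behavior_mask))
  x <- as.numeric(signal_mask); y <- as.numeric(behavior_mask)
  n <- length(x)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(structure(list(r = NA_real_, p = NA_real_, n = n,
                          method = "spearman", degenerate = TRUE),
                     class = "correlation_result"))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = n,
                 method = "spearman", degenerate = FALSE),
            class = "correlation_result")
}

#' Summary correlation between paired per-bout or per-trial values
#'
#' Wraps the Spearman (rank) and Pearson (linear) correlation tests used
#' for approach-end dF/F vs latency, mean approach-end dF/F vs
#' peripheral-zone time, and open-arm dF/F vs closed-arm time.  `r_squared`
#' is reported for Pearson.
#'
#' @param x,y paired finite numeric vectors, n >= 3.
#' @param method `"spearman"` or `"pearson"`.
#' @return a `correlation_result` (r, r_squared for Pearson, p, n, method).
#' @export
summary_correlation <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired finite values")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  res <- list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
              method = method)
  if (method == "pearson") res$r_squared <- res$r^2
  structure(res, class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation> %s r = %.3f%s, p = %.3g, n = %d\n", x$method,
              x$r, if (!is.null(x$r_squared))
                sprintf(" (r^2 = %.3f)", x$r_squared) else "",
              x$p, x$n))
  invisible(x)
}

#' Spatial dF/F heatmap
#'
#' Bins the arena into `bin_cm` squares and averages the frame-matched
#' dF/F per visited bin; unvisited bins are `NA`.  The occupancy grid
#' (frame counts) is returned alongside.
#'
#' @param dff a `dff_trace`.
#' @param traj a [trajectory()].
#' @param bin_cm spatial bin size (default 1 cm).
#' @param arena optional `arena_spec` fixing the grid extent (defaults to
#'   the trajectory's bounding box).
#' @return list `mean` (matrix), `count` (matrix), `x_breaks`, `y_breaks`.
#' @export
spatial_heatmap <- function(dff, traj, bin_cm = 1, arena = NULL) {
  if (bin_cm <= 0) stop("bin_cm must be positive")
  xr <- if (!is.null(arena)) c(0, arena$bbox[1]) else range(traj$x_cm)
  yr <- if (!is.null(arena)) c(0, arena$bbox[2]) else range(traj$y_cm)
  xb <- seq(xr[1], xr[2] + bin_cm, by = bin_cm)
  yb <- seq(yr[1], yr[2] + bin_cm, by = bin_cm)
  xi <- findInterval(traj$x_cm, xb, all.inside = TRUE)
  yi <- findInterval(traj$y_cm, yb, all.inside = TRUE)
  vals <- dff$dff[nearest_index(traj$time_s, dff$time_s)]
  nx <- length(xb) - 1L; ny <- length(yb) - 1L
  cell <- (yi - 1L) * nx + xi
  cnt <- tabulate(cell, nbins = nx * ny)
  sums <- rep(0, nx * ny)
  agg <- tapply(vals, cell, sum)
  sums[as.integer(names(agg))] <- agg
  mean_grid <- matrix(ifelse(cnt > 0, sums / cnt, NA_real_), nrow = nx)
  list(mean = mean_grid, count = matrix(cnt, nrow = nx),
       x_breaks = xb, y_breaks = yb)
}
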