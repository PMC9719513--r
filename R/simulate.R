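#' Simulation configuration
#'
#' Bundles all parameters of the synthetic-data generator, grouped per
#' sub-generator.  Every random draw is fixed by `seed`; each sub-generator
#' consumes its own pseudo-random stream derived from the master seed, so
#' adding one generator does not perturb the others.
#'
#' Defaults emulate the study conditions: a 20-min open-field session
#' (object introduced at half time) filmed at 25 Hz, photometry sampled at
#' 500 Hz, a 10-min plus-maze trial, ~20% first-epoch catFISH activation
#' with ~75% conditional co-activation, and 5-Hz baseline single units
#' with a 3x event gain.
#'
#' @param seed master integer seed.
#' @param session list: `duration_s`, `object_in_s`, `frame_rate_hz`,
#'   `photometry_rate_hz`, `epm_duration_s`.
#' @param behavior list: `wall_preference_weight` (probability that a
#'   relocation stays on the wall), `bout_rate_per_min` (planted
#'   approach-retreat rate after object introduction), `approach_depth_cm`
#'   (closest distance to the object reached), `bout_speed_cm_s`,
#'   `epm_open_avoidance` (1 - probability an arm visit is to an open arm),
#'   `epm_progressive_slope` (within-session decline of open-arm entry
#'   probability).
#' @param calcium list: `F_baseline`, `distance_gain` (fractional
#'   fluorescence per unit of object proximity; 0 gives an EYFP-like
#'   control), `kernel_rise_s`, `kernel_decay_s` (slow-indicator kernel),
#'   `bleach_tau_s`, `noise_sd`.
#' @param spikes list: `n_units`, `baseline_rate_hz`, `event_gain`,
#'   `gain_duration_s`, `tuned_fraction_A`, `tuned_fraction_B`,
#'   `overlap_rho` (probability that a B-ensemble unit also belongs to A;
#'   1 nests B inside A, 0 makes the ensembles disjoint), `refractory_s`
#'   (absolute refractory period imposed after thinning).
#' @param catfish list: `n_cells`, `p_first`, `conditional_overlap_q`
#'   (P(first-epoch active | second-epoch active)), `p_second_marginal`,
#'   `n_animals`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, session = list(), behavior = list(),
                       calcium = list(), spikes = list(), catfish = list()) {
  cfg <- list(
    seed = as.integer(seed),
    session = utils::modifyList(list(
      duration_s = 1200, object_in_s = 600, frame_rate_hz = 25,
      photometry_rate_hz = 500, epm_duration_s = 600), session),
    behavior = utils::modifyList(list(
      wall_preference_weight = 0.8, bout_rate_per_min = 2,
      approach_depth_cm = 3, bout_speed_cm_s = 15,
      epm_open_avoidance = 0.75, epm_progressive_slope = 0.5), behavior),
    calcium = utils::modifyList(list(
      F_baseline = 100, distance_gain = 0.3, kernel_rise_s = 0.2,
      kernel_decay_s = 1.5, bleach_tau_s = 2000, noise_sd = 1), calcium),
    spikes = utils::modifyList(list(
      n_units = 100, baseline_rate_hz = 5, event_gain = 3,
      gain_duration_s = 2, tuned_fraction_A = 0.3, tuned_fraction_B = 0.3,
      overlap_rho = 0.5, refractory_s = 0.003), spikes),
    catfish = utils::modifyList(list(
      n_cells = 500, p_first = 0.2, conditional_overlap_q = 0.75,
      p_second_marginal = 0.15, n_animals = 4), catfish))
  probs <- c(cfg$behavior$wall_preference_weight,
             cfg$behavior$epm_open_avoidance,
             cfg$spikes$tuned_fraction_A, cfg$spikes$tuned_fraction_B,
             cfg$spikes$overlap_rho, cfg$catfish$p_first,
             cfg$catfish$conditional_overlap_q,
             cfg$catfish$p_second_marginal)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  nonneg <- c(cfg$session$duration_s, cfg$behavior$bout_rate_per_min,
              cfg$calcium$distance_gain, cfg$calcium$noise_sd,
              cfg$spikes$baseline_rate_hz, cfg$spikes$event_gain)
  if (any(nonneg < 0)) stop("rates, durations and gains must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

# perimeter parameterization of the wall path at `margin` cm from the wall
perimeter_point <- function(s, side, margin = 2) {
  L <- side - 2 * margin
  s <- s %% (4 * L)
  if (s < L) c(margin + s, margin)
  else if (s < 2 * L) c(side - margin, margin + (s - L))
  else if (s < 3 * L) c(side - margin - (s - 2 * L), side - margin)
  else c(margin, side - margin - (s - 3 * L))
}

#' Simulate an open-field session with planted approach-retreat bouts
#'
#' Generates a dwell-and-relocate biased walk along the arena wall (the
#' thigmotaxis the analyses assume), with occasional interior visits at
#' probability `1 - wall_preference_weight`, and, after object
#' introduction, straight approach excursions toward the object at rate
#' `bout_rate_per_min` with immediate retreats.  Every planted bout's
#' onset, turning point and retreat end are recorded as ground truth.
#' Peripheral-zone time increases with `wall_preference_weight` by
#' construction.
#'
#' @param cfg a [sim_config()].
#' @param arena an [open_field_arena()] (defaults to the 40-cm box with a
#'   central object).
#' @return list: `traj` ([trajectory()]), `bouts` (ground-truth
#'   `bout_table`), `object_epoch` (`c(object_in_s, duration_s)`), `arena`.
#' @export
simulate_open_field_session <- function(cfg, arena = open_field_arena()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seeds(cfg$seed, "of_traj"))
  ses <- cfg$session; beh <- cfg$behavior
  side <- arena$side_cm; obj <- arena$object_xy
  dur <- ses$duration_s; t_obj <- ses$object_in_s
  hop_speed <- 8
  # planted bout schedule (post-object only)
  bout_times <- numeric(0)
  if (beh$bout_rate_per_min > 0) {
    tt <- t_obj + 10
    while (tt < dur - 20) {
      bout_times <- c(bout_times, tt)
      tt <- tt + 8 + stats::rexp(1, beh$bout_rate_per_min / 60)
    }
  }
  s_arc <- stats::runif(1, 0, 2)           # start near a corner
  pos <- perimeter_point(s_arc, side)
  wt <- 0; wx <- pos[1]; wy <- pos[2]      # waypoint vectors
  gt <- list()
  t <- 0; bi <- 1
  add_way <- function(tm, p) { wt <<- c(wt, tm); wx <<- c(wx, p[1]); wy <<- c(wy, p[2]) }
  while (t < dur) {
    post <- t >= t_obj
    wall_p <- if (post) min(1, beh$wall_preference_weight + 0.15)
              else beh$wall_preference_weight
    dwell <- 1.5 + stats::rexp(1, 1 / 1.5)
    t_dwell_end <- min(t + dwell, dur)
    nb <- if (bi <= length(bout_times)) bout_times[bi] else Inf
    if (post && nb <= t_dwell_end) {
      t0 <- max(nb, t + 0.5)
      if (t0 >= dur) { add_way(dur, pos); break }
      add_way(t0, pos)
      u <- (pos - obj) / sqrt(sum((pos - obj)^2))
      target <- obj + beh$approach_depth_cm * u
      d1 <- sqrt(sum((pos - target)^2))
      t_arr <- t0 + d1 / beh$bout_speed_cm_s
      t_back <- t_arr + d1 / beh$bout_speed_cm_s
      add_way(t_arr, target); add_way(t_back, pos)
      gt[[length(gt) + 1]] <- data.frame(start_s = t0, turn_s = t_arr,
                                         end_s = t_back)
      t <- t_back; bi <- bi + 1
      next
    }
    add_way(t_dwell_end, pos); t <- t_dwell_end
    if (t >= dur) break
    safe <- !post || nb - t > 20
    if (stats::runif(1) < wall_p || !safe) {
      s_arc <- s_arc + sample(c(-1, 1), 1) * stats::runif(1, 2, 5)
      np <- perimeter_point(s_arc, side)
      t <- t + sqrt(sum((np - pos)^2)) / hop_speed
      pos <- np; add_way(min(t, dur), pos)
    } else {
      ang <- stats::runif(1, 0, 2 * pi)
      r <- stats::runif(1, 10, 16)
      ip <- pmin(pmax(obj + r * c(cos(ang), sin(ang)), 3), side - 3)
      t <- t + sqrt(sum((ip - pos)^2)) / hop_speed
      add_way(min(t, dur), ip)
      t <- min(t + stats::runif(1, 1, 3), dur)
      add_way(t, ip)
      np <- perimeter_point(s_arc <- stats::runif(1, 0, 4 * (side - 4)), side)
      t <- t + sqrt(sum((np - ip)^2)) / hop_speed
      pos <- np; add_way(min(t, dur), pos)
    }
  }
  if (wt[length(wt)] < dur) add_way(dur, pos)
  keep <- !duplicated(wt, fromLast = TRUE)   # clamped segments can tie at dur
  wt <- wt[keep]; wx <- wx[keep]; wy <- wy[keep]
  ft <- seq(0, dur, by = 1 / ses$frame_rate_hz)
  traj <- trajectory(ft, stats::approx(wt, wx, ft, rule = 2)$y,
                     stats::approx(wt, wy, ft, rule = 2)$y,
                     ses$frame_rate_hz)
  bouts <- if (length(gt)) {
    g <- do.call(rbind, gt)
    bout_table(c(rep("approach", nrow(g)), rep("retreat", nrow(g))),
               c(g$start_s, g$turn_s), c(g$turn_s, g$end_s))
  } else bout_table()
  list(traj = traj, bouts = bouts, object_epoch = c(t_obj, dur),
       arena = arena)
}

#' Simulate an elevated plus-maze session
#'
#' Semi-Markov arm-visit sequence: from the maze center the animal enters
#' an open arm with probability
#' `(1 - epm_open_avoidance) * (1 - epm_progressive_slope * t / duration)`
#' (clipped at 0) and a closed arm otherwise, runs to a random depth along
#' the arm centerline, dwells, and returns.  Open-arm entry times (zone
#' boundary crossings) and per-visit intervals are recorded as ground
#' truth.
#'
#' @param cfg a [sim_config()].
#' @param arena an [epm_arena()].
#' @return list: `traj`, `arena`, `entries` (data frame `arm`, `enter_s`,
#'   `exit_s`), `open_entry_times`.
#' @export
simulate_epm_session <- function(cfg, arena = epm_arena()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seeds(cfg$seed, "epm_traj"))
  ses <- cfg$session; beh <- cfg$behavior
  dur <- ses$epm_duration_s
  L <- arena$arm_length_cm; cs <- arena$center_side_cm
  mid <- (2 * L + cs) / 2
  speed <- 8
  center <- c(mid, mid)
  # arm unit vectors from the center; open arms along x
  dirs <- list(open_arm_1 = c(-1, 0), open_arm_2 = c(1, 0),
               closed_arm_1 = c(0, -1), closed_arm_2 = c(0, 1))
  wt <- 0; wx <- mid; wy <- mid
  add_way <- function(tm, p) { wt <<- c(wt, tm); wx <<- c(wx, p[1]); wy <<- c(wy, p[2]) }
  t <- 0; entries <- list()
  while (t < dur) {
    t <- min(t + stats::runif(1, 1, 3), dur)   # dwell in center
    add_way(t, center)
    if (t >= dur) break
    p_open <- (1 - beh$epm_open_avoidance) *
      max(0, 1 - beh$epm_progressive_slope * t / dur)
    open <- stats::runif(1) < p_open
    arm <- if (open) sample(c("open_arm_1", "open_arm_2"), 1)
           else sample(c("closed_arm_1", "closed_arm_2"), 1)
    u <- dirs[[arm]]
    depth <- stats::runif(1, 8, L - 3)         # distance past the arm boundary
    tip <- center + u * (cs / 2 + depth)
    t_enter <- t + (cs / 2) / speed            # boundary crossing
    t_tip <- t + (cs / 2 + depth) / speed
    dwell <- stats::rlnorm(1, log(4), 0.5)
    t_leave <- t_tip + dwell
    t_exit <- t_leave + depth / speed          # boundary crossing on return
    t_back <- t_leave + (cs / 2 + depth) / speed
    if (t_back > dur) {                        # truncate final visit
      t_back <- dur
      add_way(t_tip, tip); add_way(min(t_leave, dur), tip)
      if (t_leave < dur) add_way(dur, tip + u * (-speed * (dur - t_leave)))
      entries[[length(entries) + 1]] <- data.frame(
        arm = arm, enter_s = t_enter, exit_s = dur)
      break
    }
    add_way(t_tip, tip); add_way(t_leave, tip); add_way(t_back, center)
    entries[[length(entries) + 1]] <- data.frame(
      arm = arm, enter_s = t_enter, exit_s = t_exit)
    t <- t_back
  }
  if (wt[length(wt)] < dur) add_way(dur, c(wx[length(wx)], wy[length(wy)]))
  keep <- !duplicated(wt, fromLast = TRUE)
  wt <- wt[keep]; wx <- wx[keep]; wy <- wy[keep]
  ft <- seq(0, dur, by = 1 / ses$frame_rate_hz)
  traj <- trajectory(ft, stats::approx(wt, wx, ft, rule = 2)$y,
                     stats::approx(wt, wy, ft, rule = 2)$y,
                     ses$frame_rate_hz)
  ent <- if (length(entries)) do.call(rbind, entries)
         else data.frame(arm = character(), enter_s = numeric(),
                         exit_s = numeric())
  list(traj = traj, arena = arena, entries = ent,
       open_entry_times = ent$enter_s[grepl("^open", ent$arm)])
}

# double-exponential calcium indicator impulse response, normalized to unit
# (discrete) area so that a sustained drive passes through with its own
# amplitude and brief transients are attenuated by the indicator's slowness
calcium_kernel <- function(rise_s, decay_s, fs_hz) {
  tk <- seq(0, 6 * decay_s, by = 1 / fs_hz)
  h <- (1 - exp(-tk / rise_s)) * exp(-tk / decay_s)
  h / sum(h)
}

#' Simulate a fiber-photometry fluorescence trace from a trajectory
#'
#' Latent drive `distance_gain * max(0, 1 - dist/dist_max)` (proximity to
#' the object, active only during the post-object epoch) is convolved with
#' a peak-normalized double-exponential indicator kernel; fluorescence is
#' `exp(-t/bleach_tau) * F_baseline * (1 + drive (*) kernel)` plus Gaussian
#' noise.  `distance_gain = 0` gives an EYFP-like control (bleaching and
#' noise only).  A custom `drive` vector (e.g. open-arm occupancy on the
#' plus maze) may replace the distance drive.
#'
#' @param traj a [trajectory()].
#' @param cfg a [sim_config()].
#' @param arena arena providing `object_xy` (required unless `drive`
#'   given).
#' @param object_epoch `c(start_s, end_s)` during which the distance drive
#'   is active; `NULL` activates it for the whole recording.
#' @param drive optional custom drive sampled at the photometry rate.
#' @param bouts optional ground-truth `bout_table`; when given, the peak
#'   convolved drive near each approach's turning point is recorded.
#' @return list: `trace` ([fluor_trace()]), `ground_truth` (per-approach
#'   `turn_s`, `peak_amp`, `peak_s`), `drive` (convolved drive),
#'   `n_clipped`.
#' @export
simulate_calcium <- function(traj, cfg, arena = NULL, object_epoch = NULL,
                             drive = NULL, bouts = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seeds(cfg$seed, "calcium"))
  cal <- cfg$calcium
  fs <- cfg$session$photometry_rate_hz
  dur <- traj$time_s[nrow(traj)]
  tt <- seq(0, dur, by = 1 / fs)
  if (is.null(drive)) {
    if (is.null(arena) || is.null(arena$object_xy))
      stop("simulate_calcium needs an arena with object_xy (or a custom drive)")
    x <- stats::approx(traj$time_s, traj$x_cm, tt, rule = 2)$y
    y <- stats::approx(traj$time_s, traj$y_cm, tt, rule = 2)$y
    d <- sqrt((x - arena$object_xy[1])^2 + (y - arena$object_xy[2])^2)
    # proximity is scaled by the object-to-nearest-wall distance so the
    # drive is ~0 while the animal hugs the wall and ramps during approaches
    dmax <- min(arena$object_xy[1], arena$bbox[1] - arena$object_xy[1],
                arena$object_xy[2], arena$bbox[2] - arena$object_xy[2])
    drive <- cal$distance_gain * pmax(0, 1 - d / dmax)
    if (!is.null(object_epoch))
      drive[tt < object_epoch[1] | tt > object_epoch[2]] <- 0
  } else stopifnot(length(drive) == length(tt))
  h <- calcium_kernel(cal$kernel_rise_s, cal$kernel_decay_s, fs)
  conv <- if (any(drive != 0)) causal_conv(drive, h) else drive
  f <- exp(-tt / cal$bleach_tau_s) * cal$F_baseline * (1 + conv) +
    stats::rnorm(length(tt), 0, cal$noise_sd)
  n_clipped <- sum(f < 0)
  if (n_clipped > 0.001 * length(f))
    warning(sprintf("%.2f%% of samples clipped at zero", 100 * n_clipped / length(f)))
  f[f < 0] <- 0
  gt <- NULL
  if (!is.null(bouts) && any(bouts$label == "approach")) {
    app <- bouts[bouts$label == "approach", ]
    gt <- do.call(rbind, lapply(seq_len(nrow(app)), function(i) {
      sel <- tt >= app$start_s[i] & tt <= app$end_s[i] + 2
      j <- which(sel)[which.max(conv[sel])]
      data.frame(turn_s = app$end_s[i], peak_amp = conv[j], peak_s = tt[j])
    }))
  }
  list(trace = fluor_trace(tt, f), ground_truth = gt, drive = conv,
       n_clipped = n_clipped)
}

#' Simulate plus-maze photometry with an open-arm drive
#'
#' Builds a drive proportional to open-arm occupancy, optionally ramping
#' linearly across the session (progressive engagement), and feeds it to
#' [simulate_calcium()].  The drive amplitude is
#' `calcium$distance_gain * ramp(t)` while the animal is on an open arm and
#' 0 elsewhere.
#'
#' @param epm result of [simulate_epm_session()].
#' @param cfg a [sim_config()].
#' @param ramp length-2 numeric: drive multiplier at session start and end.
#' @return as [simulate_calcium()].
#' @export
simulate_epm_calcium <- function(epm, cfg, ramp = c(1, 1)) {
  zones <- assign_zones(epm$traj, epm$arena)
  fs <- cfg$session$photometry_rate_hz
  dur <- epm$traj$time_s[nrow(epm$traj)]
  tt <- seq(0, dur, by = 1 / fs)
  open <- !is.na(zones$zone) & grepl("^open", zones$zone)
  ind <- stats::approx(epm$traj$time_s, as.numeric(open), tt,
                       method = "constant", rule = 2)$y
  drive <- cfg$calcium$distance_gain * ind *
    (ramp[1] + (ramp[2] - ramp[1]) * tt / dur)
  simulate_calcium(epm$traj, cfg, drive = drive)
}

#' Simulate single-unit spike trains with controlled ensemble overlap
#'
#' Each unit fires as an inhomogeneous Poisson process simulated by
#' thinning: baseline `baseline_rate_hz`, multiplied by `event_gain` for
#' `gain_duration_s` after each onset of the event label(s) the unit is
#' tuned to.  Ensemble membership: B is drawn with probability
#' `tuned_fraction_B`; a B unit also belongs to A with probability
#' `overlap_rho`, a non-B unit with the probability that preserves the
#' marginal `tuned_fraction_A`.
#'
#' @param events named list: event label -> onset times (s).  The first
#'   element is ensemble A's label, the second (if present) ensemble B's.
#' @param cfg a [sim_config()].
#' @param duration_s session duration.
#' @return list: `spikes` (a `spike_set`), `labels` (data frame
#'   `unit_id`, `in_A`, `in_B`).
#' @export
simulate_spikes <- function(events, cfg, duration_s) {
  stopifnot(inherits(cfg, "sim_config"), length(events) >= 1)
  set.seed(derive_seeds(cfg$seed, "spikes"))
  sp <- cfg$spikes
  fA <- sp$tuned_fraction_A; fB <- sp$tuned_fraction_B; rho <- sp$overlap_rho
  n <- sp$n_units
  two <- length(events) >= 2
  in_B <- if (two) stats::runif(n) < fB else rep(FALSE, n)
  pA_notB <- if (two) (fA - rho * fB) / (1 - fB) else fA
  if (two && (pA_notB < 0 || pA_notB > 1))
    stop(sprintf("infeasible overlap: need 0 <= (fA - rho*fB)/(1 - fB) <= 1, got %.3f",
                 pA_notB))
  in_A <- ifelse(in_B, stats::runif(n) < rho, stats::runif(n) < pA_notB)
  label_A <- names(events)[1]
  label_B <- if (two) names(events)[2] else NA_character_
  gain_windows <- function(unit) {
    w <- NULL
    if (in_A[unit]) w <- rbind(w, cbind(events[[label_A]],
                                        events[[label_A]] + sp$gain_duration_s))
    if (two && in_B[unit]) w <- rbind(w, cbind(events[[label_B]],
                                               events[[label_B]] + sp$gain_duration_s))
    w
  }
  rmax <- sp$baseline_rate_hz * max(sp$event_gain, 1)
  trains <- lapply(seq_len(n), function(u) {
    m <- stats::rpois(1, rmax * duration_s)
    tt <- sort(stats::runif(m, 0, duration_s))
    w <- gain_windows(u)
    rate <- rep(sp$baseline_rate_hz, length(tt))
    if (!is.null(w)) {
      inw <- rep(FALSE, length(tt))
      for (i in seq_len(nrow(w))) inw <- inw | (tt >= w[i, 1] & tt < w[i, 2])
      rate[inw] <- sp$baseline_rate_hz * sp$event_gain
    }
    keep <- stats::runif(length(tt)) < rate / rmax   # thinning
    tt <- tt[keep]
    # absolute refractory period, as in any well-isolated sorted unit
    if (length(tt) > 1 && sp$refractory_s > 0) {
      ok <- c(TRUE, diff(tt) >= sp$refractory_s)
      while (!all(ok)) {
        tt <- tt[ok]
        ok <- c(TRUE, diff(tt) >= sp$refractory_s)
      }
    }
    tt
  })
  names(trains) <- sprintf("unit_%03d", seq_len(n))
  list(spikes = spike_set(trains, duration_s),
       labels = data.frame(unit_id = names(trains), in_A = in_A,
                           in_B = in_B, stringsAsFactors = FALSE))
}

#' Simulate catFISH activation counts
#'
#' Two-epoch Bernoulli activation per cell: second-epoch (intron+) with
#' probability `p_second_marginal`; first-epoch (exon+) with probability
#' `conditional_overlap_q` given intron+, and with the probability that
#' preserves the marginal `p_first` otherwise.  Setting
#' `conditional_overlap_q = p_first` gives independence, under which the
#' convergence rate equals the chance level in expectation.
#'
#' @param cfg a [sim_config()].
#' @param groups group labels recycled over animals.
#' @return a [catfish_counts()] with one row per animal, plus attribute
#'   `truth` (the generating probabilities).
#' @export
simulate_catfish <- function(cfg, groups = c("O-F", "F-O", "O-O")) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seeds(cfg$seed, "catfish"))
  cf <- cfg$catfish
  p0 <- (cf$p_first - cf$conditional_overlap_q * cf$p_second_marginal) /
    (1 - cf$p_second_marginal)
  if (p0 < 0)
    stop("infeasible: conditional_overlap_q * p_second_marginal > p_first")
  if (p0 > 1)
    stop("infeasible: p_first - q*p_second > 1 - p_second")
  rows <- lapply(seq_len(cf$n_animals), function(a) {
    n <- cf$n_cells
    n_intron <- stats::rbinom(1, n, cf$p_second_marginal)
    n_both <- stats::rbinom(1, n_intron, cf$conditional_overlap_q)
    n_exon <- n_both + stats::rbinom(1, n - n_intron, p0)
    data.frame(animal_id = sprintf("animal_%d", a),
               group = groups[(a - 1) %% length(groups) + 1],
               n_vgat = n, n_exon = n_exon, n_intron = n_intron,
               n_both = n_both, stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  out <- catfish_counts(d$animal_id, d$group, d$n_vgat, d$n_exon,
                        d$n_intron, d$n_both)
  attr(out, "truth") <- cf
  out
}

#' Write a complete fixture bundle to disk
#'
#' Simulates one animal's open-field session (trajectory, ground-truth
#' bouts, fluorescence), a plus-maze session, a spike session with events,
#' and a catFISH cohort, and writes everything as header-bearing CSV plus
#' a ground-truth JSON and a manifest recording the seed, configuration
#' and per-file row counts.  Regeneration with the same configuration is
#' byte-identical.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory.
#' @param overwrite overwrite an existing directory.
#' @return invisibly, the manifest list.
#' @export
make_fixture_bundle <- function(cfg, dir, overwrite = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite)
    stop("output directory exists; use overwrite = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  of <- simulate_open_field_session(cfg)
  cal <- simulate_calcium(of$traj, cfg, of$arena, of$object_epoch,
                          bouts = of$bouts)
  epm <- simulate_epm_session(cfg)
  app <- of$bouts[of$bouts$label == "approach", ]
  events <- list(object_approach = app$start_s,
                 open_arm_entry = epm$open_entry_times + 1e-9 +
                   cfg$session$duration_s)  # placed after the OF epoch
  spk <- simulate_spikes(events, cfg,
                         duration_s = cfg$session$duration_s +
                           cfg$session$epm_duration_s)
  cat_tab <- simulate_catfish(cfg)
  files <- list()
  wr <- function(name, writer, obj) {
    path <- file.path(dir, name)
    writer(obj, path)
    files[[name]] <<- if (is.data.frame(obj)) nrow(obj)
                      else if (inherits(obj, "spike_set"))
                        sum(vapply(obj$spikes, length, 1L)) else NA
    path
  }
  wr("trajectory.csv", write_trajectory, of$traj)
  wr("bouts.csv", write_bouts, of$bouts)
  wr("fluorescence.csv", function(o, p)
    utils::write.csv(format_num_df(as.data.frame(o)), p,
                     row.names = FALSE, quote = FALSE), cal$trace)
  wr("epm_trajectory.csv", write_trajectory, epm$traj)
  wr("spikes.csv", write_spikes, spk$spikes)
  ev <- data.frame(label = rep(names(events), lengths(events)),
                   onset_s = unlist(events, use.names = FALSE))
  wr("events.csv", function(o, p)
    utils::write.csv(format_num_df(o), p, row.names = FALSE, quote = FALSE), ev)
  wr("catfish.csv", function(o, p)
    utils::write.csv(as.data.frame(o), p, row.names = FALSE, quote = FALSE),
    cat_tab)
  truth <- list(bouts = as.data.frame(of$bouts),
                calcium_peaks = cal$ground_truth,
                epm_entries = epm$entries,
                spike_labels = spk$labels)
  jsonlite::write_json(signif_list(truth), file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  manifest <- list(seed = cfg$seed, config = unclass(cfg), files = files)
  jsonlite::write_json(signif_list(manifest), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
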