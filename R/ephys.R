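EVENT_LABELS <- c("object_approach", "fox_urine_in", "fox_urine_sniff",
                  "open_arm_entry")

# per-label peri-event analysis windows (s pre, s post) and decision windows
# (s post-onset): behaviors use 5/5 with a 2-s decision window, discrete
# events 5/10 with 10 s (urine in) or 7.5 s (open-arm entry)
peth_windows <- function(label) {
  switch(label,
    object_approach = list(pre_s = 5, post_s = 5, decision_s = 2),
    fox_urine_sniff = list(pre_s = 5, post_s = 5, decision_s = 2),
    fox_urine_in    = list(pre_s = 5, post_s = 10, decision_s = 10),
    open_arm_entry  = list(pre_s = 5, post_s = 10, decision_s = 7.5),
    stop("unknown event label: ", label))
}

#' Spike set
#'
#' Spike times per unit over one session.
#'
#' @param spikes named list, one sorted numeric vector of spike times (s)
#'   per unit.
#' @param duration_s session duration.
#' @return list of class `spike_set`.
#' @export
spike_set <- function(spikes, duration_s) {
  stopifnot(is.list(spikes), duration_s > 0)
  if (is.null(names(spikes)) || any(!nzchar(names(spikes))))
    names(spikes) <- paste0("unit_", seq_along(spikes))
  for (u in names(spikes)) {
    s <- spikes[[u]]
    if (length(s) && (is.unsorted(s, strictly = TRUE) ||
                      s[1] < 0 || s[length(s)] > duration_s))
      stop("unit ", u, ": spike times must be strictly increasing within [0, duration]")
  }
  structure(list(spikes = spikes, duration_s = duration_s),
            class = "spike_set")
}

#' @export
print.spike_set <- function(x, ...) {
  cat(sprintf("<spike_set> %d units, %.0f s, %.1f Hz grand mean\n",
              length(x$spikes), x$duration_s,
              mean(vapply(x$spikes, length, 1)) / x$duration_s))
  invisible(x)
}

#' Read / write spikes CSV (long format: unit_id,spike_time_s)
#' @param path file path.
#' @param duration_s session duration.
#' @return a `spike_set`.
#' @export
read_spikes <- function(path, duration_s) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  spike_set(split(d$spike_time_s, d$unit_id), duration_s)
}

#' @rdname read_spikes
#' @param spikes a `spike_set`.
#' @export
write_spikes <- function(spikes, path) {
  d <- data.frame(
    unit_id = rep(names(spikes$spikes), vapply(spikes$spikes, length, 1L)),
    spike_time_s = unlist(spikes$spikes, use.names = FALSE))
  # spike times need full precision so that reread trains stay strictly sorted
  utils::write.csv(format_num_df(d, digits = 10), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Event-aligned binned firing rates for one unit
#'
#' Counts spikes in 250-ms bins around each event onset and converts to Hz.
#' Windows that would extend past the session edges are dropped.
#'
#' @param spike_times sorted numeric vector of one unit's spike times (s).
#' @param onsets event onset times (s).
#' @param pre_s,post_s window around each onset.
#' @param bin_width_s bin width (default 0.25); must divide both `pre_s`
#'   and `post_s`.
#' @param duration_s session duration used for the edge check (default:
#'   no check beyond `pre_s`).
#' @return matrix events x bins of rates in Hz, with `bin_centers_s`
#'   attribute (times relative to onset).
#' @export
bin_rates <- function(spike_times, onsets, pre_s = 5, post_s = 5,
                      bin_width_s = 0.25, duration_s = Inf) {
  nb_pre <- pre_s / bin_width_s; nb_post <- post_s / bin_width_s
  if (abs(nb_pre - round(nb_pre)) > 1e-9 || abs(nb_post - round(nb_post)) > 1e-9)
    stop("bin_width_s must divide pre_s and post_s")
  nb <- as.integer(round(nb_pre + nb_post))
  ok <- onsets - pre_s >= 0 & onsets + post_s <= duration_s
  onsets <- onsets[ok]
  if (!length(onsets)) stop("no complete event windows")
  edges_rel <- seq(-pre_s, post_s, by = bin_width_s)
  m <- t(vapply(onsets, function(o) {
    idx <- findInterval(spike_times, o + edges_rel, left.open = TRUE)
    tabulate(idx[idx >= 1 & idx <= nb], nbins = nb) / bin_width_s
  }, numeric(nb)))
  attr(m, "bin_centers_s") <- edges_rel[-length(edges_rel)] + bin_width_s / 2
  attr(m, "pre_s") <- pre_s; attr(m, "bin_width_s") <- bin_width_s
  m
}

#' Peri-event time histogram with Z-scored rates
#'
#' Averages the binned rates across events, then Z-scores every bin against
#' the mean and population SD of the pre-onset bins of that event-averaged
#' trace.  Units whose pre-onset SD is zero are marked unclassifiable (a
#' category distinct from "none", keeping classification denominators
#' honest).
#'
#' @param rates matrix from [bin_rates()] (events x bins).
#' @param pre_s pre-onset span in seconds (defaults to the matrix
#'   attribute).
#' @return list of class `peth`: `bin_centers_s`, `rate_hz` (event
#'   average), `z`, `pre_s`, `bin_width_s`, `n_events`, `sigma_pre`,
#'   `unclassifiable`.
#' @export
compute_peth_z <- function(rates, pre_s = attr(rates, "pre_s")) {
  bw <- attr(rates, "bin_width_s")
  centers <- attr(rates, "bin_centers_s")
  avg <- colMeans(rates)
  pre <- avg[centers < 0]
  if (length(pre) < 2) stop("need at least 2 pre-onset bins")
  mu <- mean(pre)
  sigma <- sqrt(mean((pre - mu)^2))   # population SD
  unclass <- sigma == 0
  z <- if (unclass) rep(NA_real_, length(avg)) else (avg - mu) / sigma
  structure(list(bin_centers_s = centers, rate_hz = avg, z = z,
                 pre_s = pre_s, bin_width_s = bw, n_events = nrow(rates),
                 mu_pre = mu, sigma_pre = sigma,
                 unclassifiable = unclass),
            class = "peth")
}

#' @export
print.peth <- function(x, ...) {
  cat(sprintf("<peth> %d bins of %g s, %d events%s\n",
              length(x$rate_hz), x$bin_width_s, x$n_events,
              if (x$unclassifiable) " [unclassifiable]" else ""))
  invisible(x)
}

#' Classify a unit as excited/inhibited/none for an event
#'
#' A unit is excited when its PETH Z-score exceeds 2 in at least two
#' consecutive 250-ms bins within the event-specific decision window
#' (2 s post-onset for object approach and urine sniff, 10 s for urine
#' introduction, 7.5 s for open-arm entry), inhibited when Z < -2 likewise.
#' If both criteria fire, excited takes precedence and the dual call is
#' flagged.
#'
#' @param peth a [compute_peth_z()] result.
#' @param label event label (see `EVENT_LABELS`).
#' @param unit_id optional identifier carried into the call.
#' @return list of class `tuning_call`: `unit_id`, `label`, `class`
#'   (`"excited"`, `"inhibited"`, `"none"` or `"unclassifiable"`),
#'   `decision_window_s`, `dual`.
#' @export
classify_tuning <- function(peth, label, unit_id = NA_character_) {
  w <- peth_windows(label)
  post_cov <- max(peth$bin_centers_s) + peth$bin_width_s / 2
  if (w$decision_s > post_cov + 1e-9)
    stop("decision window exceeds the PETH window")
  if (peth$unclassifiable) {
    cls <- "unclassifiable"; dual <- FALSE
  } else {
    sel <- peth$bin_centers_s > 0 & peth$bin_centers_s < w$decision_s
    z <- peth$z[sel]
    exc <- two_consecutive(z > 2)
    inh <- two_consecutive(z < -2)
    dual <- exc && inh
    if (dual) message("dual-criterion unit ", unit_id,
                      ": excited takes precedence")
    cls <- if (exc) "excited" else if (inh) "inhibited" else "none"
  }
  structure(list(unit_id = unit_id, label = label, class = cls,
                 decision_window_s = w$decision_s, dual = dual),
            class = "tuning_call")
}

two_consecutive <- function(b) {
  length(b) >= 2 && any(b[-length(b)] & b[-1])
}

#' PETH + tuning classification for every unit of a spike set
#'
#' Convenience wrapper: bins each unit around the events of `label` using
#' the label's analysis window, Z-scores and classifies.
#'
#' @param spikes a `spike_set`.
#' @param onsets event onset times.
#' @param label event label.
#' @param bin_width_s bin width (default 0.25 s).
#' @return data frame `unit_id`, `class`, `dual`, plus a `peths` attribute
#'   (named list of `peth` objects).
#' @export
classify_all_units <- function(spikes, onsets, label, bin_width_s = 0.25) {
  w <- peth_windows(label)
  peths <- lapply(spikes$spikes, function(s) {
    r <- bin_rates(s, onsets, w$pre_s, w$post_s, bin_width_s,
                   duration_s = spikes$duration_s)
    compute_peth_z(r)
  })
  calls <- lapply(names(peths), function(u)
    classify_tuning(peths[[u]], label, u))
  out <- data.frame(
    unit_id = names(peths),
    class = vapply(calls, `[[`, character(1), "class"),
    dual = vapply(calls, `[[`, logical(1), "dual"),
    stringsAsFactors = FALSE)
  attr(out, "peths") <- peths
  attr(out, "label") <- label
  out
}

#' Mean firing rate per unit per labeled epoch
#'
#' @param spikes a `spike_set`.
#' @param epochs data frame `label`, `start_s`, `end_s`.
#' @return matrix units x epochs of rates in Hz.
#' @export
epoch_firing_rates <- function(spikes, epochs) {
  stopifnot(inherits(spikes, "spike_set"))
  if (any(epochs$end_s <= epochs$start_s)) stop("zero-length epoch")
  if (any(epochs$start_s < 0) || any(epochs$end_s > spikes$duration_s))
    stop("epochs must lie within the session")
  m <- t(vapply(spikes$spikes, function(s)
    vapply(seq_len(nrow(epochs)), function(i)
      sum(s >= epochs$start_s[i] & s < epochs$end_s[i]) /
        (epochs$end_s[i] - epochs$start_s[i]), numeric(1)),
    numeric(nrow(epochs))))
  colnames(m) <- epochs$label
  m
}

#' Inter-spike-interval violation ratio
#'
#' Fraction of inter-spike intervals below `threshold_s` (2 ms default);
#' single-unit quality control passes when the fraction is below 1%.
#'
#' @param spike_times sorted spike times of one unit.
#' @param threshold_s refractory threshold (default 0.002).
#' @return list `ratio`, `qc_pass`, `n_isi`; ratio is `NA` (flagged) with
#'   fewer than 2 spikes.
#' @export
isi_violation_ratio <- function(spike_times, threshold_s = 0.002) {
  if (length(spike_times) < 2)
    return(list(ratio = NA_real_, qc_pass = NA, n_isi = 0L))
  isi <- diff(spike_times)
  ratio <- mean(isi < threshold_s)
  list(ratio = ratio, qc_pass = ratio < 0.01, n_isi = length(isi))
}

#' Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration
#'
#' Enumerates the hypergeometric distribution over the table's support at
#' fixed margins and sums the probabilities of all tables no more probable
#' than the observed one (the standard two-sided convention).
#'
#' @param a,b,c,d cell counts: `a` = both, `b` = first only, `c` = second
#'   only, `d` = neither.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return p-value.
#' @export
fisher_exact_p <- function(a, b, c, d, alternative = "two.sided") {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + b          # row-1 margin
  k <- a + c          # col-1 margin
  n <- a + b + c + d
  support <- max(0, m + k - n):min(m, k)
  logp <- lchoose(m, support) + lchoose(n - m, k - support) - lchoose(n, k)
  p <- exp(logp)
  obs <- which(support == a)
  switch(alternative,
    two.sided = sum(p[p <= p[obs] * (1 + 1e-7)]),
    greater = sum(p[support >= a]),
    less = sum(p[support <= a]),
    stop("unknown alternative"))
}

#' Overlap between two tuned ensembles with Fisher exact test
#'
#' Builds the 2x2 membership table of two tuned-unit sets over a common
#' unit population and reports the overlap percentage (share of B-tuned
#' units also A-tuned), the independence expectation `n_A * n_B / n_total`,
#' and the exact hypergeometric p.
#'
#' @param tuned_A,tuned_B logical vectors named by unit id (TRUE = tuned),
#'   or character vectors of tuned unit ids (then `all_units` is required).
#' @param all_units character vector of the full unit set (required when
#'   the tuned sets are given as id vectors).
#' @param alternative sidedness of the Fisher test (two-sided default).
#' @return list of class `overlap_result`: `n_total`, `n_A`, `n_B`,
#'   `n_AB`, `overlap_pct`, `expected_chance`, `chance_pct`, `table`,
#'   `fisher_p`.
#' @export
ensemble_overlap_test <- function(tuned_A, tuned_B, all_units = NULL,
                                  alternative = "two.sided") {
  if (is.character(tuned_A)) {
    if (is.null(all_units)) stop("all_units required with id vectors")
    tuned_A <- stats::setNames(all_units %in% tuned_A, all_units)
    tuned_B <- stats::setNames(all_units %in% tuned_B, all_units)
  }
  if (!identical(names(tuned_A), names(tuned_B)))
    stop("tuned_A and tuned_B must cover the same unit set")
  n_total <- length(tuned_A)
  n_AB <- sum(tuned_A & tuned_B)
  n_A <- sum(tuned_A); n_B <- sum(tuned_B)
  tab <- matrix(c(n_AB, n_A - n_AB, n_B - n_AB,
                  n_total - n_A - n_B + n_AB), 2, 2,
                dimnames = list(A = c("in_A", "out_A"),
                                B = c("in_B", "out_B")))
  p <- fisher_exact_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2],
                      alternative)
  structure(list(n_total = n_total, n_A = n_A, n_B = n_B, n_AB = n_AB,
                 overlap_pct = if (n_B > 0) 100 * n_AB / n_B else NA_real_,
                 expected_chance = n_A * n_B / n_total,
                 chance_pct = 100 * n_A / n_total,
                 table = tab, fisher_p = p),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap> %d/%d B-tuned units also A-tuned (%.1f%%), chance %.1f%%, Fisher p = %.3g\n",
              x$n_AB, x$n_B, x$overlap_pct, x$chance_pct, x$fisher_p))
  invisible(x)
}
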