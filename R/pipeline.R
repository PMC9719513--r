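#' End-to-end open-field photometry analysis for one animal
#'
#' Composes the module operations in the order the experiment demands:
#' detrend the raw fluorescence, compute dF/F against the pre-object
#' baseline, assign zones and tally occupancy before/after the object,
#' detect approach-retreat bouts and drop close pairs, correlate the
#' 2-SD-binarized signal with the frame-wise bout mask, extract
#' approach-end dF/F values and latencies, and run the per-trial summary
#' correlations.  Every stage's output is kept in the returned bundle; with
#' `out_dir` set, intermediates are persisted as CSV and the summary as
#' JSON (floats at 6 significant digits, so reruns are byte-identical).
#'
#' @param traj a [trajectory()].
#' @param fluor a raw [fluor_trace()].
#' @param arena an [open_field_arena()].
#' @param object_in_s object introduction time (s).
#' @param min_gap_s inter-bout exclusion threshold (default 1 s).
#' @param k_sd binarization threshold (default 2 SD).
#' @param out_dir optional output directory.
#' @param animal_id identifier recorded in the bundle.
#' @return list of class `report_bundle`.
#' @export
run_openfield_analysis <- function(traj, fluor, arena = open_field_arena(),
                                   object_in_s = 600, min_gap_s = 1,
                                   k_sd = 2, out_dir = NULL,
                                   animal_id = "animal_1") {
  stage <- "detrend"
  res <- try({
    adj <- detrend_trace(fluor)
    stage <- "dff"
    dff <- compute_dff(adj, baseline_spec("open_field_pre_object",
                                          stimulus_in_s = object_in_s))
    stage <- "zones"
    zones <- assign_zones(traj, arena)
    dur <- traj$time_s[nrow(traj)]
    occ <- occupancy_summary(zones, data.frame(
      label = c("pre_object", "post_object"),
      start_s = c(0, object_in_s), end_s = c(object_in_s, dur)))
    stage <- "bouts"
    bouts <- detect_approach_retreat(traj, arena)
    # only post-object excursions are object-directed approaches
    bouts <- bouts[bouts$start_s >= object_in_s, , drop = FALSE]
    class(bouts) <- c("bout_table", "data.frame")
    kept <- enforce_min_interval(bouts, min_gap_s)
    stage <- "binarized_correlation"
    sig_frames <- binarize_signal(adj)[nearest_index(traj$time_s, adj$time_s)]
    post_sel <- traj$time_s >= object_in_s
    beh_mask <- bouts_to_mask(kept, traj$time_s)
    corr_bin <- binarized_activity_correlation(sig_frames[post_sel],
                                               beh_mask[post_sel])
    stage <- "approach_end"
    ends <- approach_end_series(dff, kept)
    stage <- "summary_correlations"
    corr_latency <- if (sum(is.finite(ends$latency_s)) >= 3)
      summary_correlation(ends$dff_end[is.finite(ends$latency_s)],
                          ends$latency_s[is.finite(ends$latency_s)],
                          "spearman") else NULL
    post_occ <- occ[occ$epoch == "post_object", ]
    list(animal_id = animal_id, arena = arena,
         dff = dff, zones = zones, occupancy = occ,
         bouts = bouts, bouts_kept = kept,
         zone_dff_post = zone_mean_dff(dff, zones, c(object_in_s, dur)),
         zone_dff_pre = zone_mean_dff(dff, zones, c(0, object_in_s)),
         binarized_r = corr_bin,
         approach_ends = ends,
         corr_end_vs_latency = corr_latency,
         mean_approach_end_dff = mean(ends$dff_end),
         peripheral_time_post_s =
           post_occ$duration_s[post_occ$zone == "peripheral"],
         peripheral_time_pre_s =
           occ$duration_s[occ$epoch == "pre_object" & occ$zone == "peripheral"],
         F0 = attr(dff, "F0"))
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    stop("open-field pipeline failed at stage '", stage, "' for ",
         animal_id, ": ", attr(res, "condition")$message)
  class(res) <- "report_bundle"
  if (!is.null(out_dir)) persist_bundle(res, out_dir, "openfield")
  res
}

#' End-to-end plus-maze photometry analysis for one animal
#'
#' dF/F against the whole-trial baseline; open- vs closed-arm mean dF/F;
#' first- vs second-half open-arm dF/F (progressive engagement); open- and
#' closed-arm occupancy; spatial heatmap.
#'
#' @param traj a [trajectory()] on the plus maze.
#' @param fluor a raw [fluor_trace()].
#' @param arena an [epm_arena()].
#' @param out_dir optional output directory.
#' @param animal_id identifier recorded in the bundle.
#' @return list of class `report_bundle`.
#' @export
run_epm_analysis <- function(traj, fluor, arena = epm_arena(),
                             out_dir = NULL, animal_id = "animal_1") {
  stage <- "detrend"
  res <- try({
    adj <- detrend_trace(fluor)
    stage <- "dff"
    dur <- traj$time_s[nrow(traj)]
    dff <- compute_dff(adj, baseline_spec("epm_whole_trial",
                                          trial_end_s = dur))
    stage <- "zones"
    zones <- assign_zones(traj, arena)
    zd <- zone_durations(zones)
    stage <- "arm_means"
    zm <- zone_mean_dff(dff, zones)
    open_mean <- stats::weighted.mean(
      zm[c("open_arm_1", "open_arm_2")],
      zd[c("open_arm_1", "open_arm_2")], na.rm = TRUE)
    closed_mean <- stats::weighted.mean(
      zm[c("closed_arm_1", "closed_arm_2")],
      zd[c("closed_arm_1", "closed_arm_2")], na.rm = TRUE)
    stage <- "halves"
    half <- dur / 2
    open_by_half <- vapply(list(c(0, half), c(half, dur)), function(ep) {
      z <- zone_mean_dff(dff, zones, ep)
      zdh <- table(factor(zones$zone[zones$time_s >= ep[1] &
                                     zones$time_s < ep[2]],
                          levels = names(zm)))
      stats::weighted.mean(z[c("open_arm_1", "open_arm_2")],
                           as.numeric(zdh[c("open_arm_1", "open_arm_2")]),
                           na.rm = TRUE)
    }, numeric(1))
    stage <- "heatmap"
    hm <- spatial_heatmap(dff, traj, bin_cm = 1, arena = arena)
    list(animal_id = animal_id, arena = arena, dff = dff, zones = zones,
         zone_dff = zm,
         open_arm_dff = open_mean, closed_arm_dff = closed_mean,
         open_arm_dff_first_half = open_by_half[1],
         open_arm_dff_second_half = open_by_half[2],
         open_arm_time_s = sum(zd[c("open_arm_1", "open_arm_2")]),
         closed_arm_time_s = sum(zd[c("closed_arm_1", "closed_arm_2")]),
         heatmap = hm, F0 = attr(dff, "F0"))
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    stop("EPM pipeline failed at stage '", stage, "' for ", animal_id,
         ": ", attr(res, "condition")$message)
  class(res) <- "report_bundle"
  if (!is.null(out_dir)) persist_bundle(res, out_dir, "epm")
  res
}

persist_bundle <- function(bundle, out_dir, prefix) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(out_dir, paste0(prefix, "_", bundle$animal_id))
  utils::write.csv(format_num_df(as.data.frame(bundle$dff)),
                   paste0(base, "_dff.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(bundle$occupancy))
    utils::write.csv(format_num_df(bundle$occupancy),
                     paste0(base, "_occupancy.csv"), row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(signif_list(bundle_summary(bundle)),
                       paste0(base, "_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(base)
}

bundle_summary <- function(b) {
  num <- Filter(function(x) is.numeric(x) && length(x) <= 10 &&
                  !is.matrix(x), unclass(b))
  c(list(animal_id = b$animal_id), num,
    if (!is.null(b$binarized_r)) list(binarized_r = b$binarized_r$r),
    if (!is.null(b$corr_end_vs_latency))
      list(end_vs_latency_r = b$corr_end_vs_latency$r,
           end_vs_latency_p = b$corr_end_vs_latency$p))
}

#' Aggregate per-animal report bundles into a group report
#'
#' Cross-animal aggregation follows the nested-averaging convention: each
#' animal contributes one value (its own mean) and the group statistic is
#' the mean +/- SEM of those.  For open-field cohorts the across-animal
#' correlation between mean approach-end dF/F and post-object
#' peripheral-zone time (Pearson, as r^2) is computed when at least three
#' animals carry both values; for plus-maze cohorts, open-arm dF/F vs
#' closed-arm time.
#'
#' @param bundles list of `report_bundle`s of one kind.
#' @param out_file optional JSON output path.
#' @return list with per-animal table and group means +/- SEM.
#' @export
run_report <- function(bundles, out_file = NULL) {
  stopifnot(length(bundles) >= 1)
  fields <- names(Filter(function(x) is.numeric(x) && length(x) == 1,
                         unclass(bundles[[1]])))
  per_animal <- do.call(rbind, lapply(bundles, function(b) {
    v <- lapply(fields, function(f)
      if (!is.null(b[[f]])) as.numeric(b[[f]]) else NA_real_)
    names(v) <- fields
    cbind(data.frame(animal_id = b$animal_id, stringsAsFactors = FALSE),
          as.data.frame(v))
  }))
  if ("binarized_r" %in% names(bundles[[1]]))
    per_animal$binarized_r <- vapply(bundles, function(b)
      b$binarized_r$r, numeric(1))
  group <- lapply(setdiff(names(per_animal), "animal_id"), function(f)
    list(mean = mean(per_animal[[f]], na.rm = TRUE),
         sem = sem(per_animal[[f]])))
  names(group) <- setdiff(names(per_animal), "animal_id")
  out <- list(per_animal = per_animal, group = group,
              n_animals = nrow(per_animal))
  if (all(c("mean_approach_end_dff", "peripheral_time_post_s") %in%
          names(per_animal)) && nrow(per_animal) >= 3) {
    ok <- stats::complete.cases(per_animal[, c("mean_approach_end_dff",
                                               "peripheral_time_post_s")])
    if (sum(ok) >= 3)
      out$end_dff_vs_peripheral <- summary_correlation(
        per_animal$mean_approach_end_dff[ok],
        per_animal$peripheral_time_post_s[ok], "pearson")
  }
  if (all(c("open_arm_dff", "closed_arm_time_s") %in% names(per_animal)) &&
      nrow(per_animal) >= 3)
    out$open_dff_vs_closed_time <- summary_correlation(
      per_animal$open_arm_dff, per_animal$closed_arm_time_s, "pearson")
  if (!is.null(out_file)) {
    ser <- out
    ser$per_animal <- format_num_df(per_animal)
    ser$end_dff_vs_peripheral <- unclass(ser$end_dff_vs_peripheral)
    ser$open_dff_vs_closed_time <- unclass(ser$open_dff_vs_closed_time)
    jsonlite::write_json(signif_list(ser), out_file, auto_unbox = TRUE,
                         digits = NA, dataframe = "columns")
  }
  out
}
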