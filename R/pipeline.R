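#' Run a full analysis session from a manifest
#'
#' Orchestrates the analysis stages over the inputs a session manifest
#' provides: kinematics (joint angles, gait events, normalized cycle
#' ensemble, swing-phase CV, gait metrics, hip-ankle coupling), EMG
#' (threshold, spikes, bursts, step cycles, flexor/extensor
#' alternation), evoked responses (per-pulse classification and
#' summary), and open-field initiation. Stages whose inputs are absent
#' are skipped with a notice; a stage error is recorded in the report
#' and the remaining stages still run.
#'
#' @param manifest a list (or path to a JSON file) with any of:
#'   * `markers`: a [marker_series()] or path for [read_markers()]
#'     (with `frame_rate` in `params`);
#'   * `events`: a [gait_events()] or path for [read_gait_events()];
#'   * `segs`: [segment_lengths()] or `c(femur_cm, tibia_cm)`;
#'   * `emg`: an [emg_record()] or path for [read_emg()];
#'   * `protocol`: a [stim_protocol()] or path for
#'     [read_stim_protocol()];
#'   * `trajectories`: a list of [trajectory2d()] (or paths);
#'   * `metadata`: animal id, group (`CnF`/`PPN`/`sham`), week post
#'     injury, `locomotor_score` in \[0, 20\], limb side labels;
#'   * `params`: overrides for stage parameters (`frame_rate`,
#'     `n_bins`, `threshold_factor`, `highpass_hz`, `window_s`,
#'     `tolerance`, `radius_cm`, `horizon_s`, `heading_window_s`,
#'     `rotation_radius_cm`, `flexor_channel`, `extensor_channel`).
#' @return object of class `analysis_report`: one element per executed
#'   stage, `skipped` and `errors` records, and a `provenance` block
#'   (parameters, metadata, package version).
#' @export
run_session <- function(manifest) {
  if (is.character(manifest) && length(manifest) == 1L) {
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  }
  stopifnot(is.list(manifest))
  md <- manifest$metadata %||% list()
  if (!is.null(md$locomotor_score)) {
    stopifnot(md$locomotor_score >= 0, md$locomotor_score <= 20)
  }
  p <- utils::modifyList(
    list(frame_rate = 250, n_bins = 512L, threshold_factor = 5,
         highpass_hz = 100, window_s = 0.050, tolerance = 0,
         radius_cm = 10, horizon_s = 3, heading_window_s = 0.500,
         rotation_radius_cm = 5, flexor_channel = "LTA",
         extensor_channel = "LGL"),
    manifest$params %||% list())
  report <- list(skipped = character(0), errors = list())
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      report$errors[[name]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) report[[name]] <<- res
    invisible(res)
  }

  segs <- manifest$segs
  if (is.numeric(segs)) segs <- segment_lengths(segs[1], segs[2])

  markers <- manifest$markers
  if (is.character(markers)) markers <- read_markers(markers, p$frame_rate)
  events <- manifest$events
  if (is.character(events)) events <- read_gait_events(events)

  if (!is.null(markers)) {
    run_stage("kinematics", {
      angles <- compute_joint_angles(markers, segs = segs)
      if (is.null(events)) events <- detect_gait_events(markers)
      ens <- normalize_cycles(angles, events, n_bins = p$n_bins)
      cvs <- lapply(c(hip = "hip", knee = "knee", ankle = "ankle"),
                    function(j) swing_cv(ens, j)$pooled)
      list(angles = angles, events = events, ensemble = ens,
           swing_cv = cvs,
           metrics = gait_metrics(markers, events, segs = segs,
                                  angles = angles,
                                  baseline_window = p$baseline_window),
           coupling = intralimb_coupling(angles, events))
    })
  } else report$skipped <- c(report$skipped, "kinematics")

  emg <- manifest$emg
  if (is.character(emg)) emg <- read_emg(emg)
  spikes <- NULL; partition <- NULL
  if (!is.null(emg)) {
    run_stage("emg", {
      out <- list()
      for (ch in names(emg$channels)) {
        thr <- estimate_threshold(emg, ch, factor = p$threshold_factor,
                                  highpass_hz = p$highpass_hz)
        tr <- extract_spikes(emg, ch, thr, highpass_hz = p$highpass_hz)
        bs <- tryCatch(detect_bursts(tr, record = emg, channel = ch,
                                     highpass_hz = p$highpass_hz),
                       error = function(e) NULL)
        out[[ch]] <- list(threshold_mV = thr, spikes = tr, bursts = bs)
      }
      spikes <- out
      fx <- out[[p$flexor_channel]]
      if (!is.null(fx) && !is.null(fx$bursts) &&
          nrow(fx$bursts$bursts) >= 2L) {
        partition <- segment_cycles(fx$bursts)
      }
      alt <- NULL
      ex <- out[[p$extensor_channel]]
      if (!is.null(fx$bursts) && !is.null(ex$bursts) &&
          nrow(fx$bursts$bursts) > 0L && nrow(ex$bursts$bursts) > 0L) {
        alt <- burst_alternation(fx$bursts, ex$bursts)
      }
      list(channels = out, partition = partition, alternation = alt)
    })
  } else report$skipped <- c(report$skipped, "emg")

  protocol <- manifest$protocol
  if (is.character(protocol)) protocol <- read_stim_protocol(protocol)
  if (!is.null(protocol) && !is.null(spikes)) {
    run_stage("stim_response", {
      span <- c(0, emg$n_samples / emg$sample_rate)
      resp <- do.call(rbind, lapply(names(spikes), function(ch) {
        pulse_responses(spikes[[ch]]$spikes, protocol,
                        partition = partition, record_span = span,
                        window_s = p$window_s, tolerance = p$tolerance)
      }))
      list(responses = resp, summary = summarize_session(resp))
    })
  } else if (!is.null(protocol)) {
    report$skipped <- c(report$skipped, "stim_response")
  }

  trajs <- manifest$trajectories
  if (!is.null(trajs)) {
    if (is.character(trajs)) trajs <- lapply(trajs, read_trajectory)
    if (inherits(trajs, "trajectory2d")) trajs <- list(trajs)
    run_stage("openfield", {
      bouts <- lapply(trajs, detect_initiation, radius_cm = p$radius_cm,
                      horizon_s = p$horizon_s)
      heads <- lapply(trajs, heading_classification,
                      heading_window_s = p$heading_window_s,
                      rotation_radius_cm = p$rotation_radius_cm,
                      radius_cm = p$radius_cm, horizon_s = p$horizon_s)
      list(bouts = bouts, headings = heads,
           stats = session_initiation_stats(bouts),
           speed = lapply(trajs, speed_profile))
    })
  } else report$skipped <- c(report$skipped, "openfield")

  report$provenance <- list(
    parameters = p, metadata = md,
    package_version = as.character(utils::packageVersion("locokit")))
  structure(report, class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  stages <- setdiff(names(x), c("skipped", "errors", "provenance"))
  cat(sprintf("<analysis_report> stages: %s\n",
              paste(stages, collapse = ", ")))
  if (length(x$skipped)) cat("  skipped:", paste(x$skipped, collapse = ", "), "\n")
  for (nm in names(x$errors)) cat("  error in", nm, ":", x$errors[[nm]], "\n")
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Tables as tab-delimited text, the structured report (summaries and
#' provenance) as JSON. Output is deterministic: no timestamps, fixed
#' column order, so a rerun on unchanged inputs is byte-identical.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put_tsv <- function(df, name) {
    path <- file.path(dir, paste0(name, ".tsv"))
    utils::write.table(format(df, digits = 10, trim = TRUE), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, path)
  }
  if (!is.null(report$kinematics)) {
    put_tsv(report$kinematics$metrics$per_cycle, "gait_metrics")
    ens <- report$kinematics$ensemble
    prof <- data.frame(bin = seq_len(ens$n_bins))
    for (j in ens$joints) {
      prof[[paste0(j, "_mean")]] <- ens$mean[[j]]
      prof[[paste0(j, "_sd")]] <- ens$sd[[j]]
      prof[[paste0(j, "_cv")]] <- ens$cv[[j]]
    }
    put_tsv(prof, "cycle_profiles")
  }
  if (!is.null(report$emg)) {
    for (ch in names(report$emg$channels)) {
      tr <- report$emg$channels[[ch]]$spikes
      put_tsv(data.frame(time_s = tr$spike_times_s,
                         amplitude_mV = tr$amplitudes_mV,
                         channel = ch), paste0("spikes_", ch))
      bs <- report$emg$channels[[ch]]$bursts
      if (!is.null(bs)) put_tsv(bs$bursts, paste0("bursts_", ch))
    }
  }
  if (!is.null(report$stim_response)) {
    put_tsv(report$stim_response$responses, "pulse_responses")
    put_tsv(report$stim_response$summary$strata, "response_summary")
  }
  summary_json <- list(
    provenance = report$provenance,
    skipped = report$skipped,
    errors = report$errors,
    openfield = if (!is.null(report$openfield)) {
      report$openfield$stats
    },
    swing_cv_mean = if (!is.null(report$kinematics)) {
      lapply(report$kinematics$swing_cv, mean)
    }
  )
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(summary_json, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  paths <- c(paths, jp)
  invisible(paths)
}

#' Aggregate per-session change classifications into cohort tables
#'
#' Builds the "percentage of mice with significant decrease
#' (deterioration), increase (improvement), or absence of change"
#' summaries from per-session [classify_change()] results, grouped by
#' metadata keys, plus a tidy table ready for score correlations.
#'
#' @param sessions data frame with one row per session x metric:
#'   columns `metric`, `category` (improvement / deficit / no_change),
#'   optional grouping columns (e.g. `group`), and optional
#'   `locomotor_score` plus response-metric columns.
#' @param grouping character vector of grouping column names (besides
#'   `metric`).
#' @return data frame: one row per group x metric with `n`,
#'   `pct_improvement`, `pct_deficit`, `pct_no_change`.
#' @export
aggregate_changes <- function(sessions, grouping = character(0)) {
  stopifnot(is.data.frame(sessions),
            all(c("metric", "category") %in% names(sessions)))
  keys <- c(grouping, "metric")
  idx <- interaction(sessions[keys], drop = TRUE)
  rows <- lapply(split(sessions, idx), function(s) {
    n <- nrow(s)
    cbind(s[1, keys, drop = FALSE],
          data.frame(n = n,
                     pct_improvement = 100 * sum(s$category == "improvement") / n,
                     pct_deficit = 100 * sum(s$category == "deficit") / n,
                     pct_no_change = 100 * sum(s$category == "no_change") / n))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
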