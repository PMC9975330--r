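#' Normalize step cycles onto a fixed number of bins
#'
#' Each complete stance-to-stance cycle is linearly time-warped onto
#' `n_bins` equally spaced points (512 by default), giving per-cycle
#' angle profiles that can be averaged bin by bin. Per-bin mean, SD and
#' coefficient of variation (CV = SD / |mean|, undefined where the mean
#' is zero) are computed per joint across cycles. The swing-start bin
#' is located at the maximal opening of the hip angle, taken by default
#' on the across-cycle mean hip profile so that all cycles share one
#' swing window (set `swing_from = "cycle"` for per-cycle argmax, whose
#' median is then used).
#'
#' Cycles with fewer than `min_samples` frames or containing missing
#' angles are rejected and counted in `n_rejected`.
#'
#' @param angles a `joint_angles` object from [compute_joint_angles()].
#' @param events a [gait_events()] object with at least two stance onsets.
#' @param n_bins number of bins per normalized cycle.
#' @param min_samples minimum frames a cycle must span.
#' @param swing_from `"mean"` (default) or `"cycle"`, see above.
#' @return an object of class `cycle_ensemble`: per-joint cycle-by-bin
#'   matrices, per-bin `mean`, `sd`, `cv`, the `swing_start_bin`
#'   (1-based), cycle start/end times and the rejected-cycle count.
#' @export
normalize_cycles <- function(angles, events, n_bins = 512L,
                             min_samples = 8L,
                             swing_from = c("mean", "cycle")) {
  swing_from <- match.arg(swing_from)
  stopifnot(inherits(angles, "joint_angles"), inherits(events, "gait_events"))
  cyc <- gait_cycles(events)
  if (nrow(cyc) == 0L) stop("no cycles")
  joints <- c("hip", "knee", "ankle")
  t <- angles$time_s
  u_out <- seq(0, 1, length.out = n_bins)
  mats <- lapply(joints, function(j) {
    matrix(NA_real_, nrow = nrow(cyc), ncol = n_bins)
  })
  names(mats) <- joints
  ok <- logical(nrow(cyc))
  for (k in seq_len(nrow(cyc))) {
    idx <- cycle_frames(t, cyc$start[k], cyc$end[k])
    if (length(idx) < min_samples) next
    if (any(angles$missing[idx])) next
    u <- pmax(0, (t[idx] - cyc$start[k]) / (cyc$end[k] - cyc$start[k]))
    ok[k] <- TRUE
    for (j in joints) {
      y <- angles[[paste0(j, "_deg")]][idx]
      mats[[j]][k, ] <- stats::approx(u, y, xout = u_out, rule = 2)$y
    }
  }
  if (!any(ok)) stop("no cycles")
  mats <- lapply(mats, function(m) m[ok, , drop = FALSE])
  summ <- lapply(mats, function(m) {
    mu <- colMeans(m)
    sdv <- apply(m, 2, stats::sd)
    cv <- ifelse(mu != 0, sdv / abs(mu), NA_real_)
    list(mean = mu, sd = sdv, cv = cv)
  })
  swing_start_bin <- if (swing_from == "mean") {
    which.max(summ$hip$mean)
  } else {
    as.integer(round(stats::median(apply(mats$hip, 1, which.max))))
  }
  structure(
    list(n_bins = as.integer(n_bins), joints = joints, cycles = mats,
         mean = lapply(summ, `[[`, "mean"), sd = lapply(summ, `[[`, "sd"),
         cv = lapply(summ, `[[`, "cv"),
         swing_start_bin = swing_start_bin,
         n_cycles = sum(ok), n_rejected = sum(!ok),
         cycle_start = cyc$start[ok], cycle_end = cyc$end[ok]),
    class = "cycle_ensemble"
  )
}

#' @export
print.cycle_ensemble <- function(x, ...) {
  cat(sprintf(
    "<cycle_ensemble> %d cycles x %d bins (%d rejected), swing from bin %d\n",
    x$n_cycles, x$n_bins, x$n_rejected, x$swing_start_bin))
  invisible(x)
}

#' Swing-phase coefficient of variation
#'
#' Per-bin CV of a joint's normalized angle profile over the swing
#' window, from the maximal opening of the hip angle (beginning of the
#' swing) to the end of the step cycle (foot contact). The pooled CV
#' vector is treated as a parameter and compared across conditions by
#' the statistical policy.
#'
#' @param ensemble a `cycle_ensemble` from [normalize_cycles()] built
#'   from at least two cycles.
#' @param joint `"hip"`, `"knee"` or `"ankle"`.
#' @return list with `pooled` (CV values over swing bins, undefined bins
#'   dropped), `per_bin_cv` (full-cycle CV vector) and `bins` (the swing
#'   bin indices).
#' @export
swing_cv <- function(ensemble, joint = c("hip", "knee", "ankle")) {
  joint <- match.arg(joint)
  stopifnot(inherits(ensemble, "cycle_ensemble"))
  if (ensemble$n_cycles < 2L) stop("variability undefined")
  bins <- seq.int(ensemble$swing_start_bin, ensemble$n_bins)
  cv <- ensemble$cv[[joint]]
  pooled <- cv[bins]
  list(pooled = pooled[!is.na(pooled)], per_bin_cv = cv, bins = bins)
}
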