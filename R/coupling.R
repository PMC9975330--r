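#' Intralimb phase coupling between two joint angles
#'
#' For each complete step cycle, the coupling phase is the lag of one
#' joint's angular maximum behind the other's, as a fraction of the
#' cycle duration (modulo 1). The per-cycle phases are summarized by
#' their circular mean and resultant length R (1 = perfectly consistent
#' coupling, 0 = no preferred phase). Cycles in which either joint's
#' angle is flat (no unique maximum) are skipped and counted.
#'
#' @param angles a `joint_angles` object.
#' @param events a [gait_events()] object defining stance-to-stance cycles.
#' @param joint_a reference joint (default `"hip"`).
#' @param joint_b coupled joint (default `"ankle"`); the phase is the
#'   lag of `joint_b`'s maximum after `joint_a`'s.
#' @param flat_tol angle range (deg) below which a cycle counts as flat.
#' @return object of class `phase_coupling`: per-cycle `phases`,
#'   `circular_mean_phase`, `resultant_R`, `n_cycles`, `n_skipped`.
#' @export
intralimb_coupling <- function(angles, events, joint_a = "hip",
                               joint_b = "ankle", flat_tol = 1e-9) {
  stopifnot(inherits(angles, "joint_angles"), inherits(events, "gait_events"))
  cyc <- gait_cycles(events)
  if (nrow(cyc) == 0L) stop("no cycles")
  t <- angles$time_s
  ya <- angles[[paste0(joint_a, "_deg")]]
  yb <- angles[[paste0(joint_b, "_deg")]]
  phases <- numeric(0)
  skipped <- 0L
  for (k in seq_len(nrow(cyc))) {
    idx <- cycle_frames(t, cyc$start[k], cyc$end[k])
    if (length(idx) < 2L || any(angles$missing[idx])) { skipped <- skipped + 1L; next }
    a <- ya[idx]; b <- yb[idx]
    if (diff(range(a)) <= flat_tol || diff(range(b)) <= flat_tol) {
      skipped <- skipped + 1L; next
    }
    t_a <- t[idx][which.max(a)]
    t_b <- t[idx][which.max(b)]
    phases <- c(phases, ((t_b - t_a) / cyc$duration[k]) %% 1)
  }
  new_phase_coupling(phases, skipped)
}

new_phase_coupling <- function(phases, skipped = 0L) {
  cs <- circular_phase_stats(phases)
  structure(list(phases = phases,
                 circular_mean_phase = cs$mean_phase,
                 resultant_R = cs$R,
                 n_cycles = length(phases), n_skipped = skipped),
            class = "phase_coupling")
}

#' @export
print.phase_coupling <- function(x, ...) {
  cat(sprintf(
    "<phase_coupling> n = %d cycles (%d skipped): mean phase %.3f, R = %.3f\n",
    x$n_cycles, x$n_skipped, x$circular_mean_phase, x$resultant_R))
  invisible(x)
}

#' Interlimb phase coupling from stance onsets
#'
#' Anchored on the reference limb: each reference stance-to-stance
#' cycle contributes the phase (cycle fraction) at which the other
#' limb's stance onset falls. Strict alternation gives a mean phase of
#' 0.5, synchrony a mean phase of 0. Reference cycles containing no
#' other-limb onset are skipped and counted.
#'
#' @param events_ref reference-limb [gait_events()].
#' @param events_other other-limb [gait_events()].
#' @return a `phase_coupling` object, as for [intralimb_coupling()].
#' @export
interlimb_coupling <- function(events_ref, events_other) {
  stopifnot(inherits(events_ref, "gait_events"),
            inherits(events_other, "gait_events"))
  cyc <- gait_cycles(events_ref)
  if (nrow(cyc) == 0L) stop("no cycles")
  other <- events_other$stance_onsets
  phases <- numeric(0)
  skipped <- 0L
  for (k in seq_len(nrow(cyc))) {
    hit <- other[other >= cyc$start[k] & other < cyc$end[k]]
    if (length(hit) == 0L) { skipped <- skipped + 1L; next }
    phases <- c(phases, (hit[1] - cyc$start[k]) / cyc$duration[k])
  }
  new_phase_coupling(phases, skipped)
}
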