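#' Age-predicted maximal heart rate
#'
#' Uses the population formula for women, \code{206.9 - 0.67 * age}.
#'
#' @param age Age in years (> 0 for real subjects; the intercept at age 0
#'   is 206.9 bpm by construction).
#' @return Predicted maximal heart rate in bpm.
#' @examples
#' predicted_mhr(23.6)  # 191.088
#' @export
predicted_mhr <- function(age) {
  if (any(age < 0)) stop_config("age must be nonnegative")
  206.9 - 0.67 * age
}

#' Immersion-adjusted maximal heart rate
#'
#' Immersion shifts heart rate; the predicted maximum is corrected by the
#' observed resting-rate shift:
#' \code{MHR_water = MHR_predicted - (RHR_land - RHR_water)}.  The shift
#' may take either sign.
#'
#' @param mhr_predicted Age-predicted maximal heart rate (bpm).
#' @param rhr_land,rhr_water Resting heart rates on land and in water (bpm).
#' @return Water-adjusted maximal heart rate (bpm).
#' @export
water_adjusted_mhr <- function(mhr_predicted, rhr_land, rhr_water) {
  if (any(c(mhr_predicted, rhr_land, rhr_water) <= 0))
    stop_config("heart rates must be positive")
  mhr_predicted - (rhr_land - rhr_water)
}

#' Karvonen heart-rate-reserve target
#'
#' \code{target = (MHR_water - RHR_water) * fraction + RHR_water}.
#' Affine and strictly increasing in \code{fraction}; equals
#' \code{mhr_water} at fraction 1 and approaches \code{rhr_water} as the
#' fraction goes to 0.
#'
#' @param mhr_water Water-adjusted maximal heart rate (bpm).
#' @param rhr_water Resting heart rate in water (bpm).
#' @param fraction Heart-rate-reserve fraction in (0, 1]; the protocol
#'   uses 0.50, 0.65 and 0.80.
#' @return Target heart rate (bpm), vectorised over \code{fraction}.
#' @examples
#' karvonen_target(180, 60, 0.5)  # 120
#' @export
karvonen_target <- function(mhr_water, rhr_water, fraction) {
  if (any(mhr_water <= rhr_water))
    stop_config("mhr_water must exceed rhr_water")
  if (any(fraction <= 0 | fraction > 1))
    stop_config("fraction must lie in (0, 1]")
  (mhr_water - rhr_water) * fraction + rhr_water
}

#' Resting heart rate from a quiet-standing trace
#'
#' The subject stands quietly (5 min by default); the resting rate is the
#' mean of the last minute of the standing window.
#'
#' @param hr_trace Heart-rate samples at 1 Hz (bpm).
#' @param stand_duration Standing-window length in seconds (and samples).
#' @param window_s Averaging window at the end of the stand (s).
#' @return Mean heart rate over the final window (bpm).
#' @export
resting_hr <- function(hr_trace, stand_duration = 300, window_s = 60) {
  if (length(hr_trace) < stand_duration)
    stop_config("hr_trace shorter than the standing window (",
                stand_duration, " samples needed)")
  mean(hr_trace[(stand_duration - window_s + 1L):stand_duration])
}

#' Intensity targets for one subject
#'
#' Combines the age-predicted maximum, the immersion adjustment and the
#' Karvonen formula into the per-phase heart-rate targets.
#'
#' @param subject A \code{\link{generate_subject}} profile.
#' @param fractions Heart-rate-reserve fractions, named by intensity label.
#' @return List of class \code{"intensity_targets"}: \code{mhr_predicted},
#'   \code{delta_hr}, \code{mhr_water} and \code{target_hr} (named bpm
#'   vector).
#' @export
intensity_targets <- function(subject,
                              fractions = c("50" = 0.50, "65" = 0.65, "80" = 0.80)) {
  stopifnot(inherits(subject, "subject_profile"))
  mhr_p <- predicted_mhr(subject$age)
  mhr_w <- water_adjusted_mhr(mhr_p, subject$rhr_land, subject$rhr_water)
  structure(list(
    mhr_predicted = mhr_p,
    delta_hr = subject$rhr_land - subject$rhr_water,
    mhr_water = mhr_w,
    target_hr = karvonen_target(mhr_w, subject$rhr_water, fractions)
  ), class = "intensity_targets")
}

#' @export
print.intensity_targets <- function(x, ...) {
  cat(sprintf("MHR predicted %.1f bpm, immersion shift %.1f, MHR water %.1f\n",
              x$mhr_predicted, x$delta_hr, x$mhr_water))
  cat("targets:", paste(sprintf("%s%% HRR -> %.1f bpm", names(x$target_hr),
                                x$target_hr), collapse = ", "), "\n")
  invisible(x)
}

#' Cadence ramp schedule
#'
#' The jump cadence starts at 80 beats/min and rises by 5 beats every
#' 20 s until the phase's heart-rate target is reached; five further
#' jumps are then performed at the final cadence.
#'
#' @param start_cadence Starting cadence (beats/min).
#' @param increment Cadence increase per step (beats/min).
#' @param step_s Step duration (s).
#' @param terminal_jumps Jumps performed after the target is reached.
#' @return List of class \code{"cadence_schedule"}.
#' @export
cadence_schedule <- function(start_cadence = 80, increment = 5,
                             step_s = 20, terminal_jumps = 5) {
  if (start_cadence <= 0 || increment < 0 || step_s <= 0 || terminal_jumps < 1)
    stop_config("invalid cadence schedule")
  structure(list(start_cadence = start_cadence, increment = increment,
                 step_s = step_s, terminal_jumps = terminal_jumps),
            class = "cadence_schedule")
}

# Cadence of each of n consecutive jumps under the ramp, given the phase
# start cadence.  Returns cadence (bpm) and start time (s, phase-local)
# per jump.
ramp_cadences <- function(n, schedule, start_cadence = schedule$start_cadence) {
  cad <- numeric(n); t0 <- numeric(n); t <- 0
  for (j in seq_len(n)) {
    cad[j] <- start_cadence + schedule$increment * floor(t / schedule$step_s)
    t0[j] <- t
    t <- t + 60 / cad[j]
  }
  list(cadence = cad, start_s = t0, duration = t)
}

#' Label jumps by the heart-rate crossing rule
#'
#' Within each phase, the first heart-rate sample at or above the phase
#' target opens a terminal window: the next \code{terminal_jumps} jumps
#' carry the phase's intensity label, all earlier jumps are labelled
#' \code{"ramp"}.  If the target is never reached the phase yields no
#' labelled jumps and a warning is raised.
#'
#' @param session A \code{\link{generate_session}} object.
#' @param targets An \code{\link{intensity_targets}} object; defaults to
#'   the session subject's targets.
#' @param terminal_jumps Number of jumps labelled after the crossing.
#' @return Character vector over the session's jumps: \code{"ramp"} or
#'   the phase label (e.g. \code{"80"}).
#' @export
label_intensity <- function(session, targets = NULL, terminal_jumps = 5) {
  stopifnot(inherits(session, "cmj_session"))
  if (is.null(targets)) targets <- intensity_targets(session$subject)
  jumps <- session$jumps
  labels <- rep("ramp", nrow(jumps))
  hr_t <- seq_along(session$hr) - 1  # 1 Hz samples at integer seconds
  for (i in seq_len(nrow(session$phases))) {
    ph <- session$phases[i, ]
    tgt <- targets$target_hr[[ph$label]]
    in_ph <- hr_t >= ph$start_s & hr_t <= ph$end_s
    cross <- which(in_ph & session$hr >= tgt)
    if (!length(cross)) {
      warning("phase ", ph$label, "%: heart-rate target never reached; ",
              "no jumps labelled", call. = FALSE)
      next
    }
    t_cross <- hr_t[cross[1L]]
    cand <- which(jumps$phase == ph$label & jumps$start_s >= t_cross)
    cand <- cand[seq_len(min(terminal_jumps, length(cand)))]
    labels[cand] <- ph$label
  }
  labels
}
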