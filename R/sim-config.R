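#' Simulation configuration for synthetic water-CMJ sessions
#'
#' Collects every tunable of the synthetic-session generator in one
#' validated list.  Defaults are anchored to the study conditions the
#' package emulates: per-intensity landing-peak ground reaction force
#' (GRF) means of 0.64 / 0.67 / 0.73 body weight (BW) at 50 / 65 / 80%
#' heart-rate reserve (HRR), peak resultant accelerations of roughly
#' 1.5--1.65 g depending on wear position, signals sampled at 1000 Hz and
#' heart rate at 1 Hz.
#'
#' The acceleration--force link is linear per wear position:
#' \code{peak_acc = alpha0 + alpha1 * peak_grf + N(0, sigma)}.  Default
#' slopes and intercepts are solved from the per-intensity marginal means
#' (e.g. for C7: \code{alpha1 = (1.61 - 1.51) / (0.73 - 0.64)}), and the
#' link noise \code{sigma} is set so the implied marginal SD of peak
#' acceleration matches the 50% HRR row.  This gives the simulator known
#' ground truth for regression-recovery tests while keeping its marginals
#' realistic.
#'
#' @param fs_force_acc Sampling rate of force and acceleration traces (Hz).
#' @param fs_hr Heart-rate sampling rate (Hz); heart-rate monitors with
#'   chest straps typically report at 1 Hz.
#' @param buoyancy_fraction Fraction of land body weight supported by
#'   buoyancy during quiet standing in water; apparent (water) body weight
#'   is \code{(1 - buoyancy_fraction)} BW.
#' @param grf_mean_bw,grf_sd_bw Named numeric vectors (names "50", "65",
#'   "80") giving the per-intensity mean and SD of the landing-peak GRF in
#'   BW units.  Means must be nondecreasing over intensity.
#' @param acc_link Named list (positions \code{c7}, \code{l5}, \code{ta}),
#'   each a numeric vector \code{c(alpha0, alpha1, sigma)} of the linear
#'   acceleration link in g, g/BW and g.
#' @param acc_mean_g,acc_sd_g Per-position, per-intensity marginal peak
#'   resultant acceleration means and SDs (g); used when records are drawn
#'   directly at the jump level rather than through the acceleration link.
#' @param jn_mean,jn_sd Mean and SD of the number of jumps per intensity
#'   phase (ramp plus the five terminal jumps).
#' @param landing_ms Duration of the half-sine landing impulse (ms).
#' @param flight_ms Nominal flight duration (ms); both are capped at 30%
#'   of the jump period at high cadence.
#' @param force_noise_sd_bw White measurement noise SD on the force trace,
#'   in BW units.
#' @param acc_noise_sd_g White per-axis accelerometer noise SD (g).
#' @param off_axis_frac Fraction of the resultant carried by the two
#'   off-vertical axes (direction fixed within a jump).
#' @param hr_headroom_bpm Asymptote of the first-order heart-rate approach
#'   within a phase, in bpm above the phase target; the approach time
#'   constant is solved per phase so the target is crossed during the
#'   instructor cue gap between ramp and terminal jumps.
#' @param hr_recovery_tau_s Time constant of heart-rate recovery during
#'   rest (s).
#' @param hr_noise_sd Additive heart-rate sample noise SD (bpm).  The
#'   default of 0 reflects that 1 Hz strap output is already smoothed.
#' @param rest_s Rest duration between intensity phases (s).
#' @param cue_gap_s Pause between the heart-rate target being reached and
#'   the five terminal jumps (s); models the instructor's cue.
#' @param lead_in_s Quiet-standing lead-in used to measure water body
#'   weight (s).
#' @param tail_s Quiet-standing tail after the final landing (s).
#'
#' @return A validated list of class \code{"sim_config"}.
#' @examples
#' cfg <- sim_config()
#' cfg$acc_link$c7
#' @export
sim_config <- function(fs_force_acc = 1000,
                       fs_hr = 1,
                       buoyancy_fraction = 0.55,
                       grf_mean_bw = c("50" = 0.64, "65" = 0.67, "80" = 0.73),
                       grf_sd_bw = c("50" = 0.088, "65" = 0.075, "80" = 0.099),
                       acc_link = NULL,
                       acc_mean_g = NULL,
                       acc_sd_g = NULL,
                       jn_mean = c("50" = 34.0, "65" = 45.3, "80" = 52.7),
                       jn_sd = c("50" = 2.88, "65" = 3.74, "80" = 3.23),
                       landing_ms = 120,
                       flight_ms = 150,
                       force_noise_sd_bw = 0.005,
                       acc_noise_sd_g = 0.01,
                       off_axis_frac = 0.15,
                       hr_headroom_bpm = 8,
                       hr_recovery_tau_s = 45,
                       hr_noise_sd = 0,
                       rest_s = 45,
                       cue_gap_s = 2,
                       lead_in_s = 2,
                       tail_s = 2) {
  if (is.null(acc_mean_g)) {
    acc_mean_g <- list(
      c7 = c("50" = 1.51, "65" = 1.53, "80" = 1.61),
      l5 = c("50" = 1.47, "65" = 1.48, "80" = 1.55),
      ta = c("50" = 1.55, "65" = 1.56, "80" = 1.65)
    )
  }
  if (is.null(acc_sd_g)) {
    acc_sd_g <- list(
      c7 = c("50" = 0.099, "65" = 0.105, "80" = 0.125),
      l5 = c("50" = 0.092, "65" = 0.095, "80" = 0.119),
      ta = c("50" = 0.158, "65" = 0.140, "80" = 0.162)
    )
  }
  if (is.null(acc_link)) {
    dg <- grf_mean_bw[["80"]] - grf_mean_bw[["50"]]
    acc_link <- lapply(acc_mean_g, function(m) {
      a1 <- (m[["80"]] - m[["50"]]) / dg
      c(alpha0 = m[["50"]] - a1 * grf_mean_bw[["50"]], alpha1 = a1, sigma = NA_real_)
    })
    # link noise chosen so the implied 50%-HRR marginal SD matches acc_sd_g
    for (pos in names(acc_link)) {
      v <- acc_sd_g[[pos]][["50"]]^2 -
        (acc_link[[pos]][["alpha1"]] * grf_sd_bw[["50"]])^2
      acc_link[[pos]][["sigma"]] <- sqrt(max(v, 1e-4))
    }
  }

  cfg <- list(
    fs_force_acc = fs_force_acc, fs_hr = fs_hr,
    buoyancy_fraction = buoyancy_fraction,
    grf_mean_bw = grf_mean_bw, grf_sd_bw = grf_sd_bw,
    acc_link = acc_link, acc_mean_g = acc_mean_g, acc_sd_g = acc_sd_g,
    jn_mean = jn_mean, jn_sd = jn_sd,
    landing_ms = landing_ms, flight_ms = flight_ms,
    force_noise_sd_bw = force_noise_sd_bw, acc_noise_sd_g = acc_noise_sd_g,
    off_axis_frac = off_axis_frac,
    hr_headroom_bpm = hr_headroom_bpm,
    hr_recovery_tau_s = hr_recovery_tau_s,
    hr_noise_sd = hr_noise_sd,
    rest_s = rest_s, cue_gap_s = cue_gap_s,
    lead_in_s = lead_in_s, tail_s = tail_s
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$fs_force_acc <= 0 || cfg$fs_hr <= 0)
    stop_config("sampling rates must be positive")
  if (cfg$buoyancy_fraction < 0 || cfg$buoyancy_fraction >= 1)
    stop_config("buoyancy_fraction must lie in [0, 1)")
  lv <- c("50", "65", "80")
  for (nm in c("grf_mean_bw", "grf_sd_bw", "jn_mean", "jn_sd"))
    if (!all(lv %in% names(cfg[[nm]])))
      stop_config(nm, " must be named over intensities 50/65/80")
  if (is.unsorted(cfg$grf_mean_bw[lv]))
    stop_config("grf_mean_bw must be nondecreasing over 50% < 65% < 80% HRR")
  if (any(cfg$grf_sd_bw < 0) || any(cfg$jn_sd < 0))
    stop_config("spreads must be nonnegative")
  for (pos in c("c7", "l5", "ta")) {
    lk <- cfg$acc_link[[pos]]
    if (is.null(lk) || !all(c("alpha0", "alpha1", "sigma") %in% names(lk)))
      stop_config("acc_link$", pos, " must supply alpha0, alpha1, sigma")
    if (lk[["sigma"]] < 0) stop_config("acc_link sigma must be nonnegative")
  }
  if (cfg$landing_ms <= 0 || cfg$flight_ms <= 0)
    stop_config("landing_ms and flight_ms must be positive")
  if (cfg$hr_headroom_bpm <= 0)
    stop_config("hr_headroom_bpm must be positive")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Water-CMJ session simulator configuration\n")
  cat(sprintf("  sampling: force/acc %g Hz, heart rate %g Hz\n",
              x$fs_force_acc, x$fs_hr))
  cat(sprintf("  apparent weight: %.2f BW (buoyancy fraction %.2f)\n",
              1 - x$buoyancy_fraction, x$buoyancy_fraction))
  cat("  landing-peak GRF (BW): ",
      paste(sprintf("%s%%: %.2f +/- %.3f", names(x$grf_mean_bw),
                    x$grf_mean_bw, x$grf_sd_bw), collapse = ", "), "\n", sep = "")
  for (pos in c("c7", "l5", "ta")) {
    lk <- x$acc_link[[pos]]
    cat(sprintf("  %s link: acc = %.3f + %.3f * grf + N(0, %.3f) g\n",
                toupper(pos), lk[["alpha0"]], lk[["alpha1"]], lk[["sigma"]]))
  }
  invisible(x)
}
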