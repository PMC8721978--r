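# Segment sample counts for one jump period.  The landing impulse and the
# flight are capped at 30% of the period each so that high cadences still
# leave room for stance, countermovement dip and push-off.
jump_segment_samples <- function(cadence, config) {
  fs <- config$fs_force_acc
  period <- 60 / cadence
  land_d <- min(config$landing_ms / 1000, 0.30 * period)
  flight_d <- min(config$flight_ms / 1000, 0.30 * period)
  rem <- period - land_d - flight_d
  bounds <- cumsum(c(stance = 0.40 * rem, dip = 0.35 * rem,
                     push = 0.25 * rem, flight = flight_d, landing = land_d))
  n <- diff(c(0L, round(bounds * fs)))
  names(n) <- names(bounds)
  n
}

# Mid-sample positions u in (0, 1) for a segment of n samples.
seg_u <- function(n) if (n > 0) (seq_len(n) - 0.5) / n else numeric(0)

# Piecewise force template for one jump period, in BW units.  All phase
# boundaries are continuous: the landing impulse is a half-sine starting
# and ending at zero force, and the following period's stance begins with
# a short reweighting ramp back up to the apparent weight (`reweight`;
# disabled when the period follows quiet standing rather than a landing).
# Returns the force vector plus the acceleration base profile (load
# factor; the landing window is filled per wear position later).
jump_profiles <- function(peak_grf_bw, apparent_weight_bw, cadence, config,
                          reweight = TRUE) {
  aw <- apparent_weight_bw
  fs <- config$fs_force_acc
  n <- jump_segment_samples(cadence, config)
  dip_min <- 0.75 * aw
  push_peak <- 1.03 * aw

  f_stance <- rep(aw, n[["stance"]])
  if (reweight) {
    n_rw <- min(round(0.040 * fs), n[["stance"]])
    f_stance[seq_len(n_rw)] <- aw * (1 - cos(pi * seg_u(n_rw))) / 2
  }
  u <- seg_u(n[["dip"]])
  f_dip <- dip_min + (aw - dip_min) * (1 + cos(pi * u)) / 2
  n_up <- round(0.6 * n[["push"]]); n_dn <- n[["push"]] - n_up
  f_push <- c(dip_min + (push_peak - dip_min) * sin(pi / 2 * seg_u(n_up)),
              push_peak * (1 + cos(pi * seg_u(n_dn))) / 2)
  f_flight <- rep(0, n[["flight"]])
  s_land <- sin(pi * seg_u(n[["landing"]]))
  f_land <- peak_grf_bw * s_land

  force <- c(f_stance, f_dip, f_push, f_flight, f_land)
  ground <- c(f_stance, f_dip, f_push) / aw   # load factor before takeoff
  land_start <- length(force) - n[["landing"]] + 1L
  list(force = force,
       acc_base = c(ground, rep(0, n[["flight"]])),
       land_sine = s_land,
       land_start = land_start,
       peak_index = land_start - 1L + which.max(f_land),
       n = length(force))
}

#' Synthesize one countermovement-jump force period
#'
#' Emits one jump period of vertical force in body-weight (BW) units:
#' quiet stance at the apparent (water) body weight (reached through a
#' brief reweighting ramp, since the period tiles after a landing), a
#' countermovement dip, a push-off rise falling to zero at takeoff, a
#' flight phase at zero force, and a half-sine landing impulse whose
#' maximum equals \code{peak_grf_bw} up to one-sample discretisation
#' error.  The force is continuous and nonnegative throughout and every
#' flight sample lies far below the 10% contact-detection threshold.
#'
#' @param peak_grf_bw Landing-peak force in BW; must exceed the apparent
#'   weight, otherwise the landing would not be the contact's peak.
#' @param apparent_weight_bw Quiet-standing force in water, in BW (0, 1).
#' @param cadence Jump cadence in beats (jumps) per minute, 60--200.
#' @param config A \code{\link{sim_config}}.
#' @return Numeric force vector (BW) for one period of \code{60/cadence}
#'   seconds, with attributes \code{peak_index} (sample of the landing
#'   peak) and \code{landing_start}.
#' @examples
#' f <- synthesize_jump_waveform(0.73, 0.45, 120, sim_config())
#' max(f)  # ~0.73
#' @export
synthesize_jump_waveform <- function(peak_grf_bw, apparent_weight_bw,
                                     cadence, config = sim_config()) {
  if (apparent_weight_bw <= 0 || apparent_weight_bw >= 1)
    stop_config("apparent_weight_bw must lie in (0, 1)")
  if (cadence < 60 || cadence > 200)
    stop_config("cadence must lie in [60, 200] beats/min")
  if (peak_grf_bw <= apparent_weight_bw)
    stop_config("peak_grf_bw must exceed the apparent weight; ",
                "the landing would be undetectable as the contact peak")
  p <- jump_profiles(peak_grf_bw, apparent_weight_bw, cadence, config)
  structure(p$force, peak_index = p$peak_index, landing_start = p$land_start)
}

#' Session protocol
#'
#' Describes the intensity phases of a session: labels, heart-rate-reserve
#' fractions, the cadence schedule, and (optionally) fixed per-phase jump
#' counts.  When \code{n_jumps} is \code{NULL} counts are drawn per phase
#' from the configured jump-number distribution.
#'
#' @param labels Phase labels (percent HRR as character).
#' @param fractions Heart-rate-reserve fractions, same length.
#' @param schedule A \code{\link{cadence_schedule}}.
#' @param n_jumps Optional integer vector of total jumps per phase
#'   (ramp + terminal); each must be at least the terminal-jump count.
#' @return List of class \code{"session_protocol"}.
#' @export
session_protocol <- function(labels = c("50", "65", "80"),
                             fractions = c(0.50, 0.65, 0.80),
                             schedule = cadence_schedule(),
                             n_jumps = NULL) {
  if (!length(labels)) stop_config("protocol must contain at least one phase")
  if (length(fractions) != length(labels))
    stop_config("fractions must match labels")
  if (!is.null(n_jumps)) {
    if (length(n_jumps) != length(labels))
      stop_config("n_jumps must match labels")
    if (any(n_jumps < schedule$terminal_jumps))
      stop_config("each phase needs at least ", schedule$terminal_jumps, " jumps")
  }
  structure(list(labels = labels,
                 fractions = stats::setNames(fractions, labels),
                 schedule = schedule, n_jumps = n_jumps),
            class = "session_protocol")
}

#' Simulate a continuous water-CMJ session
#'
#' Generates synchronized force-plate and triaxial accelerometer traces
#' (1000 Hz) plus a 1 Hz heart-rate trace for one subject jumping through
#' the intensity protocol.  Per phase the cadence ramps up on the
#' configured schedule; once the simulated heart rate crosses the phase's
#' Karvonen target (mid-way through a short instructor cue gap) exactly
#' \code{terminal_jumps} more jumps are performed.  Landing peaks are
#' drawn from the per-intensity distributions; peak resultant
#' accelerations follow the linear link
#' \code{alpha0 + alpha1 * peak_grf + N(0, sigma)} per wear position and
#' are spread over three axes with a fixed dominant-vertical direction.
#' Heart rate follows a first-order approach to each phase's asymptote
#' and recovers exponentially during rests.
#'
#' @param subject A \code{\link{generate_subject}} profile.
#' @param protocol A \code{\link{session_protocol}}.
#' @param config A \code{\link{sim_config}}.
#' @param seed Integer seed; identical (subject, protocol, config, seed)
#'   reproduce the session exactly.
#' @return List of class \code{"cmj_session"}: \code{force_n} (N),
#'   \code{acc} (per position, n x 3 matrices in g), \code{hr} (bpm at
#'   1 Hz), \code{fs}, \code{fs_hr}, \code{subject}, \code{phases}
#'   (per-phase window and target), and \code{jumps} -- the ground-truth
#'   table with one row per jump (landing peak sample index, true peak
#'   GRF in BW, true peak resultant acceleration per position in g,
#'   cadence, phase and terminal flag).
#' @export
generate_session <- function(subject, protocol = session_protocol(),
                             config = sim_config(), seed = NULL) {
  stopifnot(inherits(subject, "subject_profile"),
            inherits(protocol, "session_protocol"))
  validate_sim_config(config)
  with_seed(seed, generate_session_impl(subject, protocol, config))
}

generate_session_impl <- function(subject, protocol, config) {
  fs <- config$fs_force_acc
  aw <- 1 - subject$buoyancy_fraction
  sch <- protocol$schedule
  targets <- intensity_targets(subject, protocol$fractions)

  force <- list(); rbase <- list()      # BW-unit force, load-factor base
  land_fill <- list()                   # landing windows needing acc peaks
  jumps <- list()
  hr_seg <- list()                      # (t0, t1, fun) heart-rate pieces
  phases <- list()
  t_samp <- 0L                          # samples emitted so far
  hr_cur <- subject$rhr_water

  # Quiet standing; `reweight` ramps force back up from zero when the
  # stance directly follows a landing impulse.
  emit_stance <- function(dur_s, reweight = FALSE) {
    n <- round(dur_s * fs)
    f <- rep(aw, n)
    if (reweight) {
      n_rw <- min(round(0.040 * fs), n)
      f[seq_len(n_rw)] <- aw * (1 - cos(pi * seg_u(n_rw))) / 2
    }
    force[[length(force) + 1L]] <<- f
    rbase[[length(rbase) + 1L]] <<- f / aw
    t_samp <<- t_samp + n
  }
  emit_hr_decay <- function(t0, t1, target, tau) {
    h0 <- hr_cur
    fun <- function(t) target + (h0 - target) * exp(-(t - t0) / tau)
    hr_seg[[length(hr_seg) + 1L]] <<- list(t0 = t0, t1 = t1, fun = fun)
    hr_cur <<- fun(t1)
  }

  emit_stance(config$lead_in_s)
  emit_hr_decay(0, t_samp / fs, subject$rhr_water, config$hr_recovery_tau_s)

  start_cad <- sch$start_cadence
  jump_idx <- 0L
  for (i in seq_along(protocol$labels)) {
    lab <- protocol$labels[i]
    tgt <- targets$target_hr[[lab]]
    n_j <- if (!is.null(protocol$n_jumps)) protocol$n_jumps[i] else
      max(sch$terminal_jumps + 1L,
          round(stats::rnorm(1, config$jn_mean[[lab]], config$jn_sd[[lab]])))
    n_ramp <- n_j - sch$terminal_jumps
    ramp <- ramp_cadences(n_ramp, sch, start_cad)
    term_cad <- start_cad + sch$increment * floor(ramp$duration / sch$step_s)
    cadences <- c(ramp$cadence, rep(term_cad, sch$terminal_jumps))
    terminal <- c(rep(FALSE, n_ramp), rep(TRUE, sch$terminal_jumps))

    t_phase0 <- t_samp / fs
    # Heart rate: first-order approach to an asymptote a little above the
    # phase target, with the time constant solved so the continuous
    # crossing of the target falls mid-way through the cue gap between
    # ramp and terminal jumps -- the 1 Hz trace then crosses before the
    # terminal five start.
    h0 <- min(hr_cur, tgt - 5)
    hd <- config$hr_headroom_bpm
    dt_c <- ramp$duration + config$cue_gap_s / 2
    tau_eff <- dt_c / log((tgt + hd - h0) / hd)
    hfun <- local({
      t0 <- t_phase0; hi <- tgt + hd; hh <- h0; tau <- tau_eff
      function(t) hi - (hi - hh) * exp(-(t - t0) / tau)
    })

    for (j in seq_len(n_j)) {
      if (j == n_ramp + 1L)
        emit_stance(config$cue_gap_s, reweight = j > 1L)  # instructor cue
      jump_idx <- jump_idx + 1L
      pk_grf <- rnorm_clamped(1, config$grf_mean_bw[[lab]],
                              config$grf_sd_bw[[lab]], lower = aw + 0.04)
      pk_acc <- vapply(c("c7", "l5", "ta"), function(pos) {
        lk <- config$acc_link[[pos]]
        rnorm_clamped(1, lk[["alpha0"]] + lk[["alpha1"]] * pk_grf,
                      lk[["sigma"]], lower = 1.1)
      }, numeric(1))
      p <- jump_profiles(pk_grf, aw, cadences[j], config,
                         reweight = j > 1L && j != n_ramp + 1L)
      start_s <- t_samp / fs
      force[[length(force) + 1L]] <- p$force
      rbase[[length(rbase) + 1L]] <- c(p$acc_base, rep(NA_real_,
                                                       length(p$land_sine)))
      land_fill[[length(land_fill) + 1L]] <-
        list(at = t_samp + p$land_start, sine = p$land_sine, peaks = pk_acc)
      jumps[[jump_idx]] <- data.frame(
        subject_id = subject$subject_id, jump_index = jump_idx, phase = lab,
        terminal = terminal[j], cadence = cadences[j], start_s = start_s,
        landing_peak_index = t_samp + p$peak_index,
        peak_grf_bw = pk_grf,
        peak_acc_c7 = pk_acc[["c7"]], peak_acc_l5 = pk_acc[["l5"]],
        peak_acc_ta = pk_acc[["ta"]], stringsAsFactors = FALSE)
      t_samp <- t_samp + p$n
    }

    t_phase1 <- t_samp / fs
    hr_seg[[length(hr_seg) + 1L]] <- list(t0 = t_phase0, t1 = t_phase1,
                                          fun = hfun)
    hr_cur <- hfun(t_phase1)
    phases[[i]] <- data.frame(label = lab, fraction = protocol$fractions[[lab]],
                              target_hr = tgt, start_s = t_phase0,
                              end_s = t_phase1, stringsAsFactors = FALSE)
    start_cad <- term_cad
    if (i < length(protocol$labels)) {
      t0 <- t_samp / fs
      emit_stance(config$rest_s, reweight = TRUE)
      emit_hr_decay(t0, t_samp / fs, subject$rhr_water + 10,
                    config$hr_recovery_tau_s)
    }
  }
  t0 <- t_samp / fs
  emit_stance(config$tail_s, reweight = TRUE)
  emit_hr_decay(t0, t_samp / fs, subject$rhr_water, config$hr_recovery_tau_s)

  force_bw <- unlist(force, use.names = FALSE)
  rbase <- unlist(rbase, use.names = FALSE)
  n <- length(force_bw)

  # Fill per-position resultant profiles (landing windows differ by the
  # position's linked peak), decompose onto axes, add sensor noise.
  acc <- list()
  eps <- config$off_axis_frac
  for (pos in c("c7", "l5", "ta")) {
    r <- rbase
    for (lf in land_fill) {
      idx <- lf$at:(lf$at + length(lf$sine) - 1L)
      r[idx] <- lf$peaks[[pos]] * lf$sine
    }
    phi <- stats::runif(1, 0, 2 * pi)
    u <- c(eps * cos(phi), eps * sin(phi), sqrt(1 - eps^2))
    m <- cbind(x = r * u[1], y = r * u[2], z = r * u[3])
    if (config$acc_noise_sd_g > 0)
      m <- m + matrix(stats::rnorm(3L * n, 0, config$acc_noise_sd_g), ncol = 3)
    acc[[pos]] <- m
  }

  bw_n <- subject$mass_land * .g0
  force_n <- force_bw * bw_n
  if (config$force_noise_sd_bw > 0)
    force_n <- force_n + stats::rnorm(n, 0, config$force_noise_sd_bw * bw_n)
  force_n <- pmax(force_n, 0)

  n_hr <- floor(t_samp / fs)
  hr_t <- seq_len(n_hr) - 1
  hr <- numeric(n_hr)
  for (sg in hr_seg) {
    sel <- hr_t >= sg$t0 & hr_t < sg$t1
    hr[sel] <- sg$fun(hr_t[sel])
  }
  if (config$hr_noise_sd > 0)
    hr <- hr + stats::rnorm(n_hr, 0, config$hr_noise_sd)

  structure(list(
    force_n = force_n, acc = acc, hr = hr,
    fs = fs, fs_hr = config$fs_hr,
    subject = subject, targets = targets,
    phases = do.call(rbind, phases),
    jumps = do.call(rbind, jumps),
    config = config
  ), class = "cmj_session")
}

#' @export
print.cmj_session <- function(x, ...) {
  cat(sprintf("Water-CMJ session for %s: %.1f s at %g Hz, %d jumps (%s)\n",
              x$subject$subject_id, length(x$force_n) / x$fs, x$fs,
              nrow(x$jumps),
              paste(sprintf("%s%%: %d", x$phases$label,
                            tabulate(factor(x$jumps$phase, x$phases$label))),
                    collapse = ", ")))
  invisible(x)
}

#' Simulate a cohort of sessions
#'
#' Draws \code{n_subjects} profiles and one session each; returns the
#' sessions plus the pooled ground-truth jump table.  With default jump
#' numbers a 12-subject cohort yields roughly
#' \code{12 * (34 + 45 + 53) ~ 1584} jump records.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param config A \code{\link{sim_config}}.
#' @param seed Integer seed; runs with the same seed are identical.
#' @param params A \code{\link{cohort_params}}.
#' @param protocol A \code{\link{session_protocol}}.
#' @return List with \code{sessions} (list of \code{cmj_session}) and
#'   \code{jumps} (pooled ground-truth data frame).
#' @export
generate_cohort <- function(n_subjects, config = sim_config(), seed = NULL,
                            params = cohort_params(),
                            protocol = session_protocol()) {
  if (n_subjects < 1) stop_config("n_subjects must be >= 1")
  with_seed(seed, {
    sessions <- lapply(seq_len(n_subjects), function(i) {
      subj <- generate_subject(params = params,
                               subject_id = sprintf("S%02d", i),
                               buoyancy_fraction = config$buoyancy_fraction)
      generate_session(subj, protocol, config)
    })
    list(sessions = sessions,
         jumps = do.call(rbind, lapply(sessions, `[[`, "jumps")))
  })
}
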