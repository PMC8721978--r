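#' Zero-phase low-pass Butterworth filter
#'
#' Sixth-order low-pass Butterworth filtering at a 50 Hz cut-off, applied
#' forward and backward so that peaks are not delayed.  The signal is
#' extended by odd reflection at both ends before filtering so start-up
#' transients never reach the returned samples; output length equals
#' input length and the DC gain is exactly 1.  Because the filter is run
#' twice, the effective magnitude response is the squared sixth-order
#' response, \code{1 / (1 + (f/cutoff)^12)}.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz); must exceed twice the cut-off.
#' @param cutoff Cut-off frequency (Hz).
#' @param order Filter order of each pass.
#' @return Filtered signal, same length as \code{x}.
#' @examples
#' t <- (0:999) / 1000
#' x <- sin(2 * pi * 5 * t) + sin(2 * pi * 200 * t)
#' y <- lowpass_filter(x, fs = 1000)          # 200 Hz tone removed
#' @export
lowpass_filter <- function(x, fs, cutoff = 50, order = 6) {
  if (fs <= 2 * cutoff)
    stop_config("cutoff (", cutoff, " Hz) must lie below the Nyquist ",
                "frequency ", fs / 2, " Hz")
  n <- length(x)
  if (n <= 3 * order)
    stop_config("signal too short to filter (need > ", 3 * order, " samples)")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  np <- min(n - 1L, max(3L * (order + 1L), 250L))
  pre <- 2 * x[1] - x[(np + 1L):2]
  post <- 2 * x[n] - x[(n - 1L):(n - np)]
  y <- signal::filtfilt(bf, c(pre, x, post))
  y[(np + 1L):(np + n)]
}

#' Resultant (three-axis) acceleration
#'
#' Element-wise Euclidean norm \code{sqrt(ax^2 + ay^2 + az^2)} of the
#' three accelerometer axes.  In the processing pipeline each axis is
#' low-pass filtered first and the resultant is taken afterwards (the two
#' orders of operation differ because the norm is nonlinear).
#'
#' @param ax,ay,az Axis signals (g), equal lengths; alternatively pass an
#'   n x 3 matrix as \code{ax}.
#' @return Nonnegative resultant signal (g).
#' @examples
#' resultant_acceleration(3, 4, 0)  # 5
#' @export
resultant_acceleration <- function(ax, ay = NULL, az = NULL) {
  if (is.matrix(ax) && is.null(ay)) {
    if (ncol(ax) != 3L) stop_config("matrix input must have 3 columns")
    return(sqrt(rowSums(ax^2)))
  }
  if (length(ay) != length(ax) || length(az) != length(ax))
    stop_config("axis signals must have equal lengths")
  sqrt(ax^2 + ay^2 + az^2)
}

#' Water body weight from quiet standing
#'
#' Mean vertical force over a quiet-standing window.  Buoyancy makes this
#' smaller than the land body weight; 10% of it is the contact-detection
#' threshold used by \code{\link{segment_contacts}}.
#'
#' @param force_v Vertical force trace (N).
#' @param quiet_window Two-element sample interval \code{c(start, end)}
#'   (inclusive) covering at least \code{min_s} seconds of quiet standing.
#' @param fs Sampling rate (Hz).
#' @param min_s Minimum window length in seconds.
#' @return Mean force over the window (N).
#' @export
water_body_weight <- function(force_v, quiet_window, fs = 1000, min_s = 0.5) {
  w <- as.integer(quiet_window)
  if (length(w) != 2L || w[1] < 1L || w[2] > length(force_v) || w[1] >= w[2])
    stop_config("quiet_window must be a valid sample interval")
  if ((w[2] - w[1] + 1L) < min_s * fs)
    stop_config("quiet window must span at least ", min_s, " s")
  seg <- force_v[w[1]:w[2]]
  if (min(seg) < 0.5 * mean(seg))
    warning("quiet window appears to overlap a flight phase", call. = FALSE)
  mean(seg)
}

#' Segment landing contacts from a vertical force trace
#'
#' Contacts are maximal runs of samples where the vertical ground
#' reaction force exceeds 10% of the water body weight.  Sub-threshold
#' gaps shorter than \code{min_flight_ms} are treated as chatter and
#' merged; gaps of at least \code{min_flight_ms} count as flight phases.
#' Contacts shorter than \code{min_contact_ms} are discarded (this also
#' drops a clipped partial contact at the end of a recording).  A jump
#' landing is a contact preceded by a flight, which excludes the initial
#' quiet stance.
#'
#' Sample intervals are 1-based and inclusive.
#'
#' @param grf_v Vertical force trace (N), ideally already low-pass
#'   filtered.
#' @param wbw Water body weight (N), > 0.
#' @param threshold_frac Contact threshold as a fraction of \code{wbw}.
#' @param min_flight_ms Minimum sub-threshold gap recognised as flight.
#' @param min_contact_ms Minimum contact duration retained.
#' @param fs Sampling rate (Hz).
#' @return Data frame with one row per contact: \code{start_index},
#'   \code{end_index}, \code{preceded_by_flight}, \code{peak_force_index}
#'   and \code{peak_force} (N).  May have zero rows.
#' @export
segment_contacts <- function(grf_v, wbw, threshold_frac = 0.10,
                             min_flight_ms = 80, min_contact_ms = 50,
                             fs = 1000) {
  if (wbw <= 0) stop_config("water body weight must be positive")
  thr <- threshold_frac * wbw
  above <- grf_v > thr
  min_flight <- max(1L, round(min_flight_ms / 1000 * fs))
  min_contact <- max(1L, round(min_contact_ms / 1000 * fs))

  r <- rle(above)
  # debounce: short sub-threshold dips inside a contact are not flights
  interior <- !r$values & r$lengths < min_flight &
    seq_along(r$values) > 1L & seq_along(r$values) < length(r$values)
  r$values[interior] <- TRUE
  above2 <- inverse.rle(r)
  r <- rle(above2)

  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_contact)
  if (!length(keep))
    return(data.frame(start_index = integer(0), end_index = integer(0),
                      preceded_by_flight = logical(0),
                      peak_force_index = integer(0), peak_force = numeric(0)))
  out <- lapply(keep, function(k) {
    s <- starts[k]; e <- ends[k]
    flight_before <- k > 1L && !r$values[k - 1L] &&
      r$lengths[k - 1L] >= min_flight
    pk <- s - 1L + which.max(grf_v[s:e])
    data.frame(start_index = s, end_index = e,
               preceded_by_flight = flight_before,
               peak_force_index = pk, peak_force = grf_v[pk])
  })
  do.call(rbind, out)
}

#' Normalise force to land body weight
#'
#' Divides a vertical force by the land body weight
#' \code{mass_land * 9.80665}, yielding BW units.  Normalising water
#' forces by the land weight removes buoyancy's effect on the
#' denominator, so values are comparable across immersion levels.
#'
#' @param force_v Force in Newtons (scalar or vector).
#' @param mass_land Body mass measured on land (kg).
#' @return Force in land body-weight (BW) units.
#' @examples
#' normalize_grf(380.2, 53.1)  # ~0.730 BW
#' @export
normalize_grf <- function(force_v, mass_land) {
  if (mass_land <= 0) stop_config("mass_land must be positive")
  force_v / (mass_land * .g0)
}

#' Extract per-jump features from segmented contacts
#'
#' For each landing contact, takes the maximum normalised vertical force
#' and the maximum filtered resultant acceleration per wear position
#' within the contact window, and attaches the subject covariates used by
#' the prediction model (PWDH in percent, age, land mass).
#'
#' @param force_bw Filtered vertical force in BW units.
#' @param res_acc Named list (\code{c7}, \code{l5}, \code{ta}) of filtered
#'   resultant acceleration traces (g), same length as \code{force_bw}.
#' @param events Landing contacts from \code{\link{segment_contacts}}
#'   (rows with \code{preceded_by_flight = TRUE}).
#' @param subject The \code{subject_profile}.
#' @param intensity Optional per-event intensity labels.
#' @param cadence Optional per-event cadences.
#' @return Data frame with one row per landing: \code{subject_id},
#'   \code{jump_index}, \code{intensity}, \code{cadence},
#'   \code{grf_v_l_bw} (BW), \code{c7acc}, \code{l5acc}, \code{taacc}
#'   (g), \code{pwdh} (%), \code{age} (y), \code{weight} (kg), plus the
#'   peak sample indices.
#' @export
extract_jump_features <- function(force_bw, res_acc, events, subject,
                                  intensity = NULL, cadence = NULL) {
  if (!nrow(events)) stop_config("no landing events supplied")
  if (events$end_index[nrow(events)] > length(force_bw))
    stop_config("event outside trace")
  n <- nrow(events)
  if (is.null(intensity)) intensity <- rep(NA_character_, n)
  if (is.null(cadence)) cadence <- rep(NA_real_, n)
  rows <- lapply(seq_len(n), function(i) {
    s <- events$start_index[i]; e <- events$end_index[i]
    w <- s:e
    pk_f <- s - 1L + which.max(force_bw[w])
    pk <- vapply(c("c7", "l5", "ta"),
                 function(pos) max(res_acc[[pos]][w]), numeric(1))
    data.frame(subject_id = subject$subject_id, jump_index = i,
               intensity = intensity[i], cadence = cadence[i],
               grf_v_l_bw = force_bw[pk_f],
               c7acc = pk[["c7"]], l5acc = pk[["l5"]], taacc = pk[["ta"]],
               pwdh = pwdh(subject), age = subject$age,
               weight = subject$mass_land,
               peak_force_index = pk_f,
               start_index = s, end_index = e,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Process a session into per-jump records
#'
#' The full signal-processing chain: low-pass filter the force and each
#' acceleration axis (50 Hz, sixth order, zero phase), compute resultant
#' accelerations, measure the water body weight over the quiet lead-in,
#' segment landing contacts at 10% of the water body weight, and extract
#' one feature record per jump landing.  When the session carries a
#' ground-truth jump table of matching length, phase labels, terminal
#' flags and cadences are transferred onto the records.
#'
#' @param session A \code{\link{generate_session}} object (or one read
#'   back from CSV with a \code{subject} attached).
#' @param cutoff,order Filter parameters (Hz, -).
#' @param threshold_frac Contact threshold as a fraction of water body
#'   weight.
#' @param min_flight_ms,min_contact_ms Segmentation debounce durations.
#' @return A per-jump feature data frame (see
#'   \code{\link{extract_jump_features}}), with \code{intensity} and
#'   \code{terminal} columns when ground truth is available.
#' @export
process_session <- function(session, cutoff = 50, order = 6,
                            threshold_frac = 0.10, min_flight_ms = 80,
                            min_contact_ms = 50) {
  stopifnot(inherits(session, "cmj_session"))
  subject <- session$subject
  fs <- session$fs
  f_filt <- lowpass_filter(session$force_n, fs, cutoff, order)
  quiet <- c(round(0.2 * fs), round(
    max(0.7, session$config$lead_in_s - 0.3) * fs))
  wbw <- water_body_weight(f_filt, quiet, fs)
  ev <- segment_contacts(f_filt, wbw, threshold_frac,
                         min_flight_ms, min_contact_ms, fs)
  land <- ev[ev$preceded_by_flight, , drop = FALSE]
  if (!nrow(land)) stop_config("no jump landings detected")
  res <- lapply(session$acc, function(m) {
    resultant_acceleration(cbind(
      lowpass_filter(m[, 1], fs, cutoff, order),
      lowpass_filter(m[, 2], fs, cutoff, order),
      lowpass_filter(m[, 3], fs, cutoff, order)))
  })
  intensity <- NULL; cadence <- NULL; terminal <- NULL
  if (!is.null(session$jumps) && nrow(session$jumps) == nrow(land)) {
    intensity <- session$jumps$phase
    cadence <- session$jumps$cadence
    terminal <- session$jumps$terminal
  }
  rec <- extract_jump_features(normalize_grf(f_filt, subject$mass_land),
                               res, land, subject, intensity, cadence)
  if (!is.null(terminal)) rec$terminal <- terminal
  rec
}
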