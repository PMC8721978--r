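#' Cohort anthropometric distribution
#'
#' Normal distributions from which synthetic subjects are drawn, with
#' physiologic clamps applied by redrawing.  Defaults describe a cohort of
#' healthy young women (age 23.6 +/- 1.83 y, height 158.2 +/- 5.33 cm,
#' land mass 53.1 +/- 7.50 kg) tested in 1 m of water.  Resting heart
#' rates on land and in water are drawn jointly: immersion typically
#' lowers resting heart rate by a few bpm, but the difference is drawn
#' with its own spread and may take either sign.
#'
#' @param age_mean,age_sd Age distribution (years); clamped to 18--45.
#' @param height_mean,height_sd Height distribution (cm); clamped to
#'   140--185.
#' @param mass_mean,mass_sd Land body-mass distribution (kg); clamped to
#'   35--90.
#' @param rhr_land_mean,rhr_land_sd Resting heart rate on land (bpm).
#' @param delta_rhr_mean,delta_rhr_sd Land-minus-water resting heart-rate
#'   difference (bpm).
#' @param water_depth Pool depth (cm).
#'
#' @return A list of class \code{"cohort_params"}.
#' @export
cohort_params <- function(age_mean = 23.6, age_sd = 1.83,
                          height_mean = 158.2, height_sd = 5.33,
                          mass_mean = 53.1, mass_sd = 7.50,
                          rhr_land_mean = 70, rhr_land_sd = 6,
                          delta_rhr_mean = 5, delta_rhr_sd = 3,
                          water_depth = 100) {
  sds <- c(age_sd, height_sd, mass_sd, rhr_land_sd, delta_rhr_sd)
  if (any(sds < 0)) stop_config("distribution spreads must be nonnegative")
  if (water_depth <= 0) stop_config("water_depth must be positive")
  structure(list(age_mean = age_mean, age_sd = age_sd,
                 height_mean = height_mean, height_sd = height_sd,
                 mass_mean = mass_mean, mass_sd = mass_sd,
                 rhr_land_mean = rhr_land_mean, rhr_land_sd = rhr_land_sd,
                 delta_rhr_mean = delta_rhr_mean, delta_rhr_sd = delta_rhr_sd,
                 water_depth = water_depth),
            class = "cohort_params")
}

#' Draw a synthetic subject profile
#'
#' Draws one subject's anthropometrics and resting heart rates from the
#' cohort distributions.  Draws are deterministic for a fixed seed and
#' clamped to physiologic ranges (age 18--45 y, height 140--185 cm, mass
#' 35--90 kg) by redrawing.
#'
#' @param seed Integer seed; \code{NULL} uses the current RNG state.
#' @param params A \code{\link{cohort_params}} object.
#' @param subject_id Identifier stored in the profile.
#' @param buoyancy_fraction Fraction of land body weight supported by
#'   buoyancy at the immersion depth (see \code{\link{sim_config}}).
#'
#' @return A list of class \code{"subject_profile"} with fields
#'   \code{subject_id}, \code{age} (y), \code{height} (cm),
#'   \code{mass_land} (kg), \code{rhr_land}, \code{rhr_water} (bpm),
#'   \code{water_depth} (cm) and \code{buoyancy_fraction}.
#' @examples
#' s <- generate_subject(seed = 1)
#' pwdh(s)  # water depth as % of height
#' @export
generate_subject <- function(seed = NULL, params = cohort_params(),
                             subject_id = "S01",
                             buoyancy_fraction = 0.55) {
  stopifnot(inherits(params, "cohort_params"))
  with_seed(seed, {
    age <- rnorm_clamped(1, params$age_mean, params$age_sd, 18, 45)
    height <- rnorm_clamped(1, params$height_mean, params$height_sd, 140, 185)
    mass <- rnorm_clamped(1, params$mass_mean, params$mass_sd, 35, 90)
    rhr_land <- rnorm_clamped(1, params$rhr_land_mean, params$rhr_land_sd, 40, 110)
    rhr_water <- rnorm_clamped(
      1, rhr_land - params$delta_rhr_mean, params$delta_rhr_sd, 35, 110)
    new_subject(subject_id, age, height, mass, rhr_land, rhr_water,
                params$water_depth, buoyancy_fraction)
  })
}

new_subject <- function(subject_id, age, height, mass_land, rhr_land,
                        rhr_water, water_depth, buoyancy_fraction) {
  if (age <= 0 || height <= 0 || mass_land <= 0)
    stop_config("age, height and mass_land must be positive")
  if (water_depth <= 0 || water_depth > height)
    stop_config("water_depth must lie in (0, height]")
  if (rhr_land <= 20 || rhr_land >= 220 || rhr_water <= 20 || rhr_water >= 220)
    stop_config("resting heart rates must lie in (20, 220) bpm")
  structure(list(subject_id = subject_id, age = age, height = height,
                 mass_land = mass_land, rhr_land = rhr_land,
                 rhr_water = rhr_water, water_depth = water_depth,
                 buoyancy_fraction = buoyancy_fraction),
            class = "subject_profile")
}

#' Draw a cohort of subject profiles
#'
#' @param n Number of subjects (>= 1).
#' @inheritParams generate_subject
#' @return List of \code{\link{generate_subject}} profiles with ids
#'   \code{"S01"}, \code{"S02"}, ...
#' @export
generate_subjects <- function(n, seed = NULL, params = cohort_params(),
                              buoyancy_fraction = 0.55) {
  if (n < 1) stop_config("n must be >= 1")
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      generate_subject(seed = NULL, params = params,
                       subject_id = sprintf("S%02d", i),
                       buoyancy_fraction = buoyancy_fraction)
    })
  })
}

#' Water depth as a percentage of body height (PWDH)
#'
#' PWDH proxies immersion level and therefore buoyancy; it enters the
#' prediction equation in percent units (0--100 scale).
#'
#' @param subject A \code{subject_profile}, or a numeric water depth (cm)
#'   if \code{height} is given.
#' @param height Body height in cm (when \code{subject} is numeric).
#' @return Percent of height under water.
#' @examples
#' pwdh(100, 158.2)  # 63.2%
#' @export
pwdh <- function(subject, height = NULL) {
  if (inherits(subject, "subject_profile"))
    return(subject$water_depth / subject$height * 100)
  if (is.null(height)) stop_config("supply height when giving a numeric depth")
  subject / height * 100
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("Subject %s: %.1f y, %.1f cm, %.1f kg\n",
              x$subject_id, x$age, x$height, x$mass_land))
  cat(sprintf("  resting HR %.0f bpm (land) / %.0f bpm (water), depth %.0f cm (PWDH %.1f%%)\n",
              x$rhr_land, x$rhr_water, x$water_depth, pwdh(x)))
  invisible(x)
}
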