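#' Simulate per-jump records directly
#'
#' Draws a cohort's per-jump feature records without synthesising
#' waveforms -- the fast path for studying the model-development and
#' validation stages.  Two generative modes are available:
#' \describe{
#'   \item{\code{"link"}}{the physical story: the landing-peak GRF is
#'     drawn from its per-intensity distribution and each position's peak
#'     acceleration follows the linear link
#'     \code{alpha0 + alpha1 * grf + N(0, sigma)}.}
#'   \item{\code{"reference"}}{the regression-recovery design: peak C7
#'     acceleration is drawn from its per-intensity marginal and the GRF
#'     is computed from the published reference equation plus
#'     \code{N(0, sigma_ref)} noise, so the true coefficients are known
#'     exactly.}
#' }
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed.
#' @param config A \code{\link{sim_config}}.
#' @param params A \code{\link{cohort_params}}.
#' @param grf_from \code{"link"} or \code{"reference"}.
#' @param sigma_ref Residual SD (BW) of the GRF in \code{"reference"}
#'   mode.
#' @param model Prediction model used in \code{"reference"} mode;
#'   defaults to \code{\link{grf_reference_model}()}.
#' @return Data frame with one row per jump: \code{subject_id},
#'   \code{intensity}, \code{c7acc}, \code{l5acc}, \code{taacc},
#'   \code{grf_v_l_bw}, \code{pwdh}, \code{age}, \code{weight}.
#' @examples
#' rec <- simulate_records(3, seed = 1)
#' aggregate(grf_v_l_bw ~ intensity, rec, mean)
#' @export
simulate_records <- function(n_subjects = 12, seed = NULL,
                             config = sim_config(),
                             params = cohort_params(),
                             grf_from = c("link", "reference"),
                             sigma_ref = 0.07,
                             model = grf_reference_model()) {
  grf_from <- match.arg(grf_from)
  if (n_subjects < 1) stop_config("n_subjects must be >= 1")
  with_seed(seed, {
    subjects <- generate_subjects(n_subjects,
                                  params = params,
                                  buoyancy_fraction = config$buoyancy_fraction)
    out <- lapply(subjects, function(subj) {
      per_phase <- lapply(names(config$jn_mean), function(lab) {
        nj <- max(1L, round(stats::rnorm(1, config$jn_mean[[lab]],
                                         config$jn_sd[[lab]])))
        if (grf_from == "link") {
          grf <- stats::rnorm(nj, config$grf_mean_bw[[lab]],
                              config$grf_sd_bw[[lab]])
          accs <- lapply(config$acc_link, function(lk) {
            lk[["alpha0"]] + lk[["alpha1"]] * grf +
              stats::rnorm(nj, 0, lk[["sigma"]])
          })
        } else {
          accs <- lapply(c(c7 = "c7", l5 = "l5", ta = "ta"), function(pos) {
            stats::rnorm(nj, config$acc_mean_g[[pos]][[lab]],
                         config$acc_sd_g[[pos]][[lab]])
          })
          grf <- predict_grf(accs$c7, pwdh(subj), subj$age, subj$mass_land,
                             model = model) +
            stats::rnorm(nj, 0, sigma_ref)
        }
        data.frame(subject_id = subj$subject_id, intensity = lab,
                   c7acc = accs$c7, l5acc = accs$l5, taacc = accs$ta,
                   grf_v_l_bw = grf, pwdh = pwdh(subj), age = subj$age,
                   weight = subj$mass_land, stringsAsFactors = FALSE)
      })
      do.call(rbind, per_phase)
    })
    do.call(rbind, out)
  })
}
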