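session_csv_cols <- c("time_s", "grf_v_N",
                      "c7_x_g", "c7_y_g", "c7_z_g",
                      "l5_x_g", "l5_y_g", "l5_z_g",
                      "ta_x_g", "ta_y_g", "ta_z_g", "hr_bpm")

#' Write / read a session as CSV
#'
#' One row per force/acceleration sample with columns \code{time_s},
#' \code{grf_v_N}, per-position axis columns (\code{c7_x_g}, ...) and the
#' step-held 1 Hz heart rate \code{hr_bpm}.  Comma-separated, "." decimal
#' point, UTF-8, header row.  A written session reads back identically to
#' within float-to-text precision (better than 1e-9 relative).
#'
#' @param session A \code{cmj_session}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_session_csv <- function(session, path) {
  stopifnot(inherits(session, "cmj_session"))
  n <- length(session$force_n)
  t <- (seq_len(n) - 1L) / session$fs
  hr_idx <- pmin(floor(t * session$fs_hr) + 1L, length(session$hr))
  dt <- data.table::data.table(
    time_s = t, grf_v_N = session$force_n,
    c7_x_g = session$acc$c7[, 1], c7_y_g = session$acc$c7[, 2],
    c7_z_g = session$acc$c7[, 3],
    l5_x_g = session$acc$l5[, 1], l5_y_g = session$acc$l5[, 2],
    l5_z_g = session$acc$l5[, 3],
    ta_x_g = session$acc$ta[, 1], ta_y_g = session$acc$ta[, 2],
    ta_z_g = session$acc$ta[, 3],
    hr_bpm = session$hr[hr_idx])
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_session_csv
#' @param subject Optional \code{subject_profile} to attach to the
#'   session read back (e.g. from \code{\link{read_subject_json}}).
#' @return \code{read_session_csv}: a \code{cmj_session} (without
#'   ground-truth jump table).
#' @export
read_session_csv <- function(path, subject = NULL) {
  dt <- data.table::fread(path)
  if (!nrow(dt)) stop_config("parse error: '", path, "' has no data rows")
  miss <- setdiff(session_csv_cols, names(dt))
  if (length(miss))
    stop_config("parse error: missing column(s) ", paste(miss, collapse = ", "))
  t <- dt$time_s
  steps <- diff(t)
  if (any(steps <= 0)) {
    bad <- which(steps <= 0)[1L] + 1L
    stop_config("parse error: time not strictly increasing at line ", bad + 1L)
  }
  if (length(steps) > 1L && diff(range(steps)) > 1e-6 * steps[1L])
    stop_config("parse error: non-uniform time step")
  fs <- 1 / stats::median(steps)
  sec <- floor(t)
  first_of_sec <- !duplicated(sec)
  # one heart-rate sample per whole second of signal
  n_hr <- floor(nrow(dt) / round(fs))
  hr <- dt$hr_bpm[first_of_sec]
  hr <- hr[seq_len(min(n_hr, length(hr)))]
  structure(list(
    force_n = dt$grf_v_N,
    acc = list(
      c7 = cbind(x = dt$c7_x_g, y = dt$c7_y_g, z = dt$c7_z_g),
      l5 = cbind(x = dt$l5_x_g, y = dt$l5_y_g, z = dt$l5_z_g),
      ta = cbind(x = dt$ta_x_g, y = dt$ta_y_g, z = dt$ta_z_g)),
    hr = hr,
    fs = round(fs), fs_hr = 1,
    subject = subject, phases = NULL, jumps = NULL,
    config = sim_config(fs_force_acc = round(fs))
  ), class = "cmj_session")
}

#' Write / read a subject profile as JSON
#'
#' @param subject A \code{subject_profile}.
#' @param path JSON path.
#' @return The path (write) or the profile (read).
#' @export
write_subject_json <- function(subject, path) {
  stopifnot(inherits(subject, "subject_profile"))
  jsonlite::write_json(unclass(subject), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_subject_json
#' @export
read_subject_json <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_subject(s$subject_id, s$age, s$height, s$mass_land, s$rhr_land,
              s$rhr_water, s$water_depth, s$buoyancy_fraction)
}

#' Write / read per-jump records as CSV
#'
#' @param records Per-jump record data frame.
#' @param path CSV path.
#' @export
write_jump_records <- function(records, path) {
  data.table::fwrite(data.table::as.data.table(records), path)
  invisible(path)
}

#' @rdname write_jump_records
#' @export
read_jump_records <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Serialise a prediction model to JSON
#'
#' Stores term names, coefficients, p-values, adjusted R-squared and the
#' number of observations.
#'
#' @param model A \code{grf_model}.
#' @param path JSON path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "grf_model"))
  obj <- list(source = model$source,
              coefficients = as.list(model$coefficients),
              p_values = if (is.null(model$p_values)) NULL else
                as.list(model$p_values),
              r2 = model$r2, adjusted_r2 = model$adjusted_r2,
              n_obs = model$n_obs,
              units = list(c7acc = "g", pwdh = "percent", age = "years",
                           weight = "kg", response = "BW"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_grf_model(coefficients = unlist(obj$coefficients),
                p_values = if (is.null(obj$p_values)) NULL else
                  unlist(obj$p_values),
                r2 = obj$r2 %||% NA_real_,
                adjusted_r2 = obj$adjusted_r2 %||% NA_real_,
                n_obs = obj$n_obs %||% NA_integer_,
                source = obj$source %||% "fitted")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline configuration
#'
#' Bundles every stage parameter of \code{\link{run_pipeline}}.
#'
#' @param out_dir Output directory for artifacts.
#' @param n_subjects Cohort size.
#' @param seed Top-level seed; all stage randomness derives from it.
#' @param sim A \code{\link{sim_config}}.
#' @param params A \code{\link{cohort_params}}.
#' @param protocol A \code{\link{session_protocol}}.
#' @param cutoff,order,threshold_frac Signal-processing parameters.
#' @param ratio,stratify_by Split parameters.
#' @param alpha_remove Backward-elimination threshold.
#' @param ba_k Bland-Altman limit half-width.
#' @param make_plots Emit PNG plots of the validation agreement.
#' @return List of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(out_dir, n_subjects = 12, seed = 1,
                            sim = sim_config(), params = cohort_params(),
                            protocol = session_protocol(),
                            cutoff = 50, order = 6, threshold_frac = 0.10,
                            ratio = 2 / 3, stratify_by = NULL,
                            alpha_remove = 0.10, ba_k = 1.96,
                            make_plots = FALSE) {
  if (ratio <= 0 || ratio >= 1) stop_config("ratio must lie in (0, 1)")
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop_config("threshold_frac must lie in (0, 1)")
  structure(list(out_dir = out_dir, n_subjects = n_subjects, seed = seed,
                 sim = sim, params = params, protocol = protocol,
                 cutoff = cutoff, order = order,
                 threshold_frac = threshold_frac,
                 ratio = ratio, stratify_by = stratify_by,
                 alpha_remove = alpha_remove, ba_k = ba_k,
                 make_plots = make_plots),
            class = "pipeline_config")
}

#' Run the full simulate-process-develop-validate pipeline
#'
#' Simulates a cohort of water-CMJ sessions, processes each into per-jump
#' records, splits them into development and validation sets, develops a
#' prediction equation by backward elimination on the development set,
#' and validates it with the agreement battery on the held-out set.
#' Writes \code{jumps.csv}, \code{model.json} and \code{report.json}
#' (plus optional plots) into the output directory; reruns with the same
#' configuration reproduce \code{jumps.csv} byte for byte.  If any stage
#' fails, partially written artifacts are removed and the error names the
#' stage.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return Invisibly, a list with \code{records}, \code{split},
#'   \code{model}, \code{agreement} and the artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  stage <- "setup"
  timings <- list()
  on_fail <- function(e) {
    unlink(written)
    stop_config("pipeline stage '", stage, "' failed: ", conditionMessage(e))
  }
  tryCatch({
    stage <- "simulate"
    t0 <- proc.time()[["elapsed"]]
    cohort <- generate_cohort(config$n_subjects, config$sim, config$seed,
                              config$params, config$protocol)
    timings$simulate <- proc.time()[["elapsed"]] - t0

    stage <- "process"
    t0 <- proc.time()[["elapsed"]]
    records <- do.call(rbind, lapply(cohort$sessions, function(s) {
      process_session(s, config$cutoff, config$order, config$threshold_frac)
    }))
    timings$process <- proc.time()[["elapsed"]] - t0
    jumps_path <- file.path(config$out_dir, "jumps.csv")
    write_jump_records(records, jumps_path)
    written <- c(written, jumps_path)

    stage <- "develop"
    t0 <- proc.time()[["elapsed"]]
    split <- split_dd_vd(records, config$ratio, seed = config$seed + 1L,
                         stratify_by = config$stratify_by)
    model <- fit_grf_model(split$dd, alpha_remove = config$alpha_remove)
    timings$develop <- proc.time()[["elapsed"]] - t0
    model_path <- file.path(config$out_dir, "model.json")
    write_model_json(model, model_path)
    written <- c(written, model_path)

    stage <- "validate"
    t0 <- proc.time()[["elapsed"]]
    pred <- predict(model, split$vd)
    agr <- agreement_report(split$vd$grf_v_l_bw, pred, k = config$ba_k)
    timings$validate <- proc.time()[["elapsed"]] - t0

    cfg_path <- file.path(config$out_dir, "config.json")
    jsonlite::write_json(config_summary(config), cfg_path,
                         auto_unbox = TRUE, digits = NA)
    written <- c(written, cfg_path)
    cfg_hash <- unname(tools::md5sum(cfg_path))

    report <- list(
      package_version = as.character(utils::packageVersion("aquagrf")),
      config_hash = cfg_hash,
      counts = list(subjects = config$n_subjects, records = nrow(records),
                    dd = nrow(split$dd), vd = nrow(split$vd)),
      model = list(coefficients = as.list(model$coefficients),
                   adjusted_r2 = model$adjusted_r2, n_obs = model$n_obs),
      agreement = list(
        paired_t = agr$paired_t, pearson_r = agr$pearson_r, ccc = agr$ccc,
        bias = agr$bland_altman$bias,
        loa = c(agr$bland_altman$loa_low, agr$bland_altman$loa_high),
        pct_outside = agr$bland_altman$pct_outside,
        bias_percent = agr$bias_percent),
      timings_s = timings)
    report_path <- file.path(config$out_dir, "report.json")
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)
    written <- c(written, report_path)

    if (config$make_plots) {
      for (nm in c("concordance", "bland_altman")) {
        p <- file.path(config$out_dir, paste0(nm, ".png"))
        grDevices::png(p, width = 900, height = 700, res = 120)
        plot(agr, which = nm)
        grDevices::dev.off()
        written <- c(written, p)
      }
    }

    invisible(list(records = records, split = split, model = model,
                   agreement = agr,
                   paths = list(jumps = jumps_path, model = model_path,
                                report = report_path)))
  }, error = on_fail)
}

config_summary <- function(config) {
  list(n_subjects = config$n_subjects, seed = config$seed,
       sim = unclass(config$sim), params = unclass(config$params),
       protocol = list(labels = config$protocol$labels,
                       fractions = config$protocol$fractions,
                       schedule = unclass(config$protocol$schedule),
                       n_jumps = config$protocol$n_jumps),
       cutoff = config$cutoff, order = config$order,
       threshold_frac = config$threshold_frac, ratio = config$ratio,
       stratify_by = config$stratify_by,
       alpha_remove = config$alpha_remove, ba_k = config$ba_k)
}
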