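#' Split records into development and validation sets
#'
#' Randomly allocates per-jump records: a uniform permutation is drawn
#' and the first \code{floor(ratio * n)} records form the development set
#' (DD), the rest the validation set (VD).  Because records within a
#' subject are correlated, an optional stratification column (typically
#' \code{subject_id}) applies the floor rule within each stratum instead.
#'
#' @param records Per-jump record data frame (>= 10 rows).
#' @param ratio Development fraction in (0, 1); the study design used
#'   two-thirds.
#' @param seed Integer seed for the permutation.
#' @param stratify_by Optional column name to stratify on.
#' @return List of class \code{"dd_vd_split"} with \code{dd}, \code{vd},
#'   \code{ratio} and \code{seed}.  \code{dd} and \code{vd} are disjoint
#'   and their union is the input.
#' @export
split_dd_vd <- function(records, ratio = 2 / 3, seed = NULL,
                        stratify_by = NULL) {
  n <- nrow(records)
  if (n < 10L) stop_config("need at least 10 records to split")
  if (ratio <= 0 || ratio >= 1) stop_config("ratio must lie in (0, 1)")
  idx_dd <- with_seed(seed, {
    if (is.null(stratify_by)) {
      perm <- sample.int(n)
      sort(perm[seq_len(floor(ratio * n))])
    } else {
      if (!stratify_by %in% names(records))
        stop_config("stratify_by column '", stratify_by, "' not found")
      groups <- split(seq_len(n), records[[stratify_by]])
      sort(unlist(lapply(groups, function(g) {
        perm <- g[sample.int(length(g))]
        perm[seq_len(floor(ratio * length(g)))]
      }), use.names = FALSE))
    }
  })
  structure(list(dd = records[idx_dd, , drop = FALSE],
                 vd = records[-idx_dd, , drop = FALSE],
                 ratio = ratio, seed = seed),
            class = "dd_vd_split")
}

#' @export
print.dd_vd_split <- function(x, ...) {
  cat(sprintf("Record split: %d development / %d validation (ratio %.3f)\n",
              nrow(x$dd), nrow(x$vd), x$ratio))
  invisible(x)
}

new_grf_model <- function(coefficients, p_values, r2, adjusted_r2, n_obs,
                          fit = NULL, trail = NULL, call = NULL,
                          source = "fitted") {
  structure(list(coefficients = coefficients, p_values = p_values,
                 r2 = r2, adjusted_r2 = adjusted_r2, n_obs = n_obs,
                 terms = setdiff(names(coefficients), "(Intercept)"),
                 fit = fit, trail = trail, call = call, source = source),
            class = "grf_model")
}

grf_model_from_lm <- function(fit, n_obs, trail = NULL, call = NULL) {
  sm <- summary(fit)
  cf <- stats::coef(sm)
  new_grf_model(coefficients = cf[, "Estimate"],
                p_values = cf[, "Pr(>|t|)"],
                r2 = sm$r.squared, adjusted_r2 = sm$adj.r.squared,
                n_obs = n_obs, fit = fit, trail = trail, call = call)
}

check_design <- function(y, X) {
  X <- as.data.frame(X)
  if (is.null(names(X)) || any(!nzchar(names(X))))
    stop_config("predictors must be named")
  if (length(y) != nrow(X)) stop_config("y and X lengths differ")
  n <- length(y); p <- ncol(X)
  if (n <= p + 1L)
    stop_config("need more observations (", n, ") than predictors + 1 (",
                p + 1L, ")")
  const <- vapply(X, function(v) stats::var(v) == 0, logical(1))
  if (any(const))
    stop_config("constant predictor(s): ", paste(names(X)[const], collapse = ", "))
  M <- cbind(`(Intercept)` = 1, as.matrix(X))
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    bad <- colnames(M)[qrM$pivot[(qrM$rank + 1L):ncol(M)]]
    stop_config("rank-deficient design; collinear column(s): ",
                paste(bad, collapse = ", "))
  }
  X
}

#' Fit the full linear prediction model
#'
#' Ordinary least squares with intercept of the response on all supplied
#' predictors, with per-term two-sided t-test p-values and
#' \code{adjusted R^2 = 1 - (1 - R^2)(n - 1)/(n - p - 1)}.
#'
#' @param y Response vector (peak GRF in BW).
#' @param X Data frame or matrix of named predictors.
#' @return A \code{grf_model} object.
#' @seealso \code{\link{backward_eliminate}}, \code{\link{fit_grf_model}}
#' @export
fit_linear_model <- function(y, X) {
  X <- check_design(y, X)
  dat <- data.frame(.y = y, X, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = dat)
  grf_model_from_lm(fit, length(y), call = match.call())
}

#' Backward stepwise elimination
#'
#' Starts from the full ordinary-least-squares model and iteratively
#' removes the predictor with the largest p-value while that p-value
#' exceeds \code{alpha_remove}; the intercept is never removed.  Exact
#' p-value ties are broken by removing the later column in the design.
#' If every predictor is eliminated an intercept-only model is returned
#' with a warning.
#'
#' @param y Response vector.
#' @param X Data frame or matrix of named predictors.
#' @param alpha_remove Removal threshold on the per-term p-value.
#' @return A \code{grf_model}; its \code{trail} element records the
#'   removed term and its p-value at each step.
#' @export
backward_eliminate <- function(y, X, alpha_remove = 0.10) {
  X <- check_design(y, X)
  keep <- names(X)
  trail <- list()
  repeat {
    if (!length(keep)) {
      warning("all predictors eliminated; returning intercept-only model",
              call. = FALSE)
      fit <- stats::lm(y ~ 1)
      m <- grf_model_from_lm(fit, length(y),
                             trail = do.call(rbind, trail),
                             call = match.call())
      m$r2 <- 0; m$adjusted_r2 <- 0
      return(m)
    }
    dat <- data.frame(.y = y, X[, keep, drop = FALSE], check.names = FALSE)
    fit <- stats::lm(.y ~ ., data = dat)
    pv <- stats::coef(summary(fit))[, "Pr(>|t|)"]
    pv <- pv[names(pv) != "(Intercept)"]
    names(pv) <- keep   # lm may backtick nonsyntactic names
    pv[is.nan(pv)] <- 0  # zero-residual fit: every term is exact
    if (max(pv) <= alpha_remove) break
    worst <- max(which(pv == max(pv)))   # tie-break: later column goes
    trail[[length(trail) + 1L]] <-
      data.frame(step = length(trail) + 1L, removed = keep[worst],
                 p_value = pv[[worst]], stringsAsFactors = FALSE)
    keep <- keep[-worst]
  }
  grf_model_from_lm(fit, length(y),
                    trail = if (length(trail)) do.call(rbind, trail) else
                      data.frame(step = integer(0), removed = character(0),
                                 p_value = numeric(0)),
                    call = match.call())
}

#' Develop a GRF prediction model from jump records
#'
#' The package's central fitting function: takes per-jump records (from
#' \code{\link{process_session}} or \code{\link{simulate_records}}),
#' regresses the landing-peak GRF on the candidate predictors -- peak C7
#' resultant acceleration, PWDH, age and body weight by default -- and
#' runs backward elimination.
#'
#' @param records Per-jump record data frame.
#' @param response Response column name.
#' @param predictors Candidate predictor column names.
#' @param alpha_remove Backward-elimination removal threshold; set to
#'   \code{NULL} to keep the full model.
#' @return A \code{grf_model} with \code{print}, \code{summary},
#'   \code{coef}, \code{predict} and \code{residuals} methods.
#' @examples
#' rec <- simulate_records(4, seed = 2)
#' m <- fit_grf_model(rec)
#' coef(m)
#' @export
fit_grf_model <- function(records, response = "grf_v_l_bw",
                          predictors = c("c7acc", "pwdh", "age", "weight"),
                          alpha_remove = 0.10) {
  miss <- setdiff(c(response, predictors), names(records))
  if (length(miss))
    stop_config("missing column(s): ", paste(miss, collapse = ", "))
  y <- records[[response]]
  X <- records[, predictors, drop = FALSE]
  m <- if (is.null(alpha_remove)) fit_linear_model(y, X) else
    backward_eliminate(y, X, alpha_remove)
  m$call <- match.call()
  m
}

#' The published reference prediction equation
#'
#' The prediction equation developed on the original force-plate data:
#' \deqn{GRF = -1.712 + 0.658\,C7ACC + 0.016\,PWDH + 0.008\,age +
#'   0.003\,weight}
#' with C7ACC in g, PWDH in percent (0--100), age in years and weight in
#' kg, returning GRF in land body-weight units.  The published fit
#' reported an adjusted R-squared of 0.592 on its own data; no fit
#' diagnostics are attached here because the underlying recordings are
#' not part of this package.
#'
#' @return A \code{grf_model} holding the published coefficients.
#' @examples
#' predict_grf(1.568, 63.2, 23.6, 53.1)  # ~0.679 BW
#' @export
grf_reference_model <- function() {
  new_grf_model(
    coefficients = c(`(Intercept)` = -1.712, c7acc = 0.658,
                     pwdh = 0.016, age = 0.008, weight = 0.003),
    p_values = NULL, r2 = NA_real_, adjusted_r2 = NA_real_,
    n_obs = NA_integer_, source = "reference")
}

#' @export
coef.grf_model <- function(object, ...) object$coefficients

#' Predict GRF from a fitted or reference model
#'
#' @param object A \code{grf_model}.
#' @param newdata Data frame containing the model's term columns.
#' @param ... Unused.
#' @return Predicted GRF in BW units.
#' @export
predict.grf_model <- function(object, newdata, ...) {
  miss <- setdiff(object$terms, names(newdata))
  if (length(miss))
    stop_config("newdata lacks column(s): ", paste(miss, collapse = ", "))
  if ("pwdh" %in% object$terms && all(newdata$pwdh <= 1))
    warning("pwdh values are all <= 1; PWDH must be in percent (0-100 scale)",
            call. = FALSE)
  b <- object$coefficients
  out <- rep(b[["(Intercept)"]], nrow(as.data.frame(newdata)))
  for (tm in object$terms) out <- out + b[[tm]] * newdata[[tm]]
  out
}

#' Evaluate a GRF prediction equation at given inputs
#'
#' Convenience wrapper around \code{\link{predict.grf_model}} for the
#' standard four predictors.
#'
#' @param c7acc Peak resultant C7 acceleration (g).
#' @param pwdh Water depth as percent of height (0--100 scale).
#' @param age Age (years).
#' @param weight Body mass on land (kg).
#' @param model A \code{grf_model}; defaults to the published reference
#'   equation.
#' @return Predicted GRF (BW).
#' @examples
#' predict_grf(1.5, 60, 25, 55)  # 0.600
#' @export
predict_grf <- function(c7acc, pwdh, age, weight,
                        model = grf_reference_model()) {
  if (!all(is.finite(c(c7acc, pwdh, age, weight))))
    stop_config("inputs must be finite")
  predict(model, data.frame(c7acc = c7acc, pwdh = pwdh,
                            age = age, weight = weight))
}

#' @export
residuals.grf_model <- function(object, ...) {
  if (is.null(object$fit)) stop_config("no fitted values: reference model")
  stats::residuals(object$fit)
}

#' @export
print.grf_model <- function(x, digits = 3, ...) {
  cat("GRF prediction model (", x$source, ")\n", sep = "")
  b <- x$coefficients
  terms <- sprintf("%+.3f*%s", b[x$terms], x$terms)
  cat(sprintf("  GRF_BW = %.3f %s\n", b[["(Intercept)"]],
              paste(terms, collapse = " ")))
  if (!is.na(x$adjusted_r2))
    cat(sprintf("  n = %d, adjusted R^2 = %.3f\n", x$n_obs, x$adjusted_r2))
  invisible(x)
}

#' @export
summary.grf_model <- function(object, ...) {
  print(object)
  if (!is.null(object$p_values)) {
    cat("per-term p-values:\n")
    print(signif(object$p_values, 3))
  }
  if (!is.null(object$trail) && nrow(object$trail)) {
    cat("eliminated:\n")
    print(object$trail, row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.grf_model <- function(x, records = NULL, ...) {
  if (is.null(x$fit)) stop_config("no fitted values: reference model")
  obs <- stats::model.frame(x$fit)[[1L]]
  pred <- stats::fitted(x$fit)
  graphics::plot(pred, obs, xlab = "predicted GRF (BW)",
                 ylab = "measured GRF (BW)",
                 main = "Model fit", pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.5), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Compare development and validation groups
#'
#' Independent two-sample t-tests (pooled variance) per outcome variable,
#' used to confirm that the random split did not unbalance the groups.
#'
#' @param dd,vd Development and validation record data frames.
#' @param variables Columns to compare.
#' @return Data frame with group means, \code{t}, \code{df} and \code{p}
#'   per variable.
#' @export
compare_groups <- function(dd, vd,
                           variables = c("grf_v_l_bw", "c7acc", "age",
                                         "weight")) {
  if (nrow(dd) < 2L || nrow(vd) < 2L)
    stop_config("both groups need at least 2 records")
  rows <- lapply(variables, function(v) {
    tt <- stats::t.test(dd[[v]], vd[[v]], var.equal = TRUE)
    data.frame(variable = v, mean_dd = mean(dd[[v]]), mean_vd = mean(vd[[v]]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
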