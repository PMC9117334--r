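# Empirical calibration mathematics: saturating-exponential and sigmoid
# calibration curves, weighted nonlinear least-squares fits, closed-form
# inversion, the relative luminescence efficiency and the quenching
# correction.

#' Construct a calibration fit object
#'
#' Two empirical forms are supported, both monotone and invertible on
#' x > 0:
#'
#' * `sat_exp`: f(x) = a1 (1 - exp(-a2 x)) + a3, with a2 > 0;
#' * `sigmoid`: f(x) = a2 + (a1 - a2) / (1 + a3 x^a4), with a3 > 0,
#'   a4 > 0 and a1 != a2 (increasing when a2 > a1, decreasing when
#'   a1 > a2; f(0) = a1, f(Inf) = a2).
#'
#' @param model `"sat_exp"` or `"sigmoid"`.
#' @param coefficients Named numeric vector `a1..a3` (`sat_exp`) or
#'   `a1..a4` (`sigmoid`).
#' @param vcov Optional coefficient covariance matrix.
#' @param residuals Optional fit residuals.
#' @param x_range Range of the calibration data on the x axis.
#' @return An object of class `"calibration_fit"`.
#' @export
calibration_fit <- function(model = c("sat_exp", "sigmoid"), coefficients,
                            vcov = NULL, residuals = NULL, x_range = NULL) {
  model <- match.arg(model)
  a <- coefficients
  if (model == "sat_exp") {
    stopifnot(length(a) >= 3L)
    if (a[2L] <= 0) stop("sat_exp requires a2 > 0")
    a <- stats::setNames(as.numeric(a[1:3]), c("a1", "a2", "a3"))
  } else {
    stopifnot(length(a) == 4L)
    if (a[3L] <= 0 || a[4L] <= 0) stop("sigmoid requires a3 > 0 and a4 > 0")
    if (a[1L] == a[2L]) stop("sigmoid requires a1 != a2")
    a <- stats::setNames(as.numeric(a), c("a1", "a2", "a3", "a4"))
  }
  structure(
    list(model = model, coefficients = a, vcov = vcov,
         residuals = residuals, x_range = x_range),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> %s: %s\n", x$model,
    paste(sprintf("%s = %.6g", names(x$coefficients), x$coefficients),
          collapse = ", ")
  ))
  invisible(x)
}

#' Evaluate a calibration curve
#'
#' @param fit A [calibration_fit()].
#' @param x Non-negative evaluation points.
#' @return Model values f(x).
#' @export
eval_model <- function(fit, x) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (any(x < 0)) stop("x must be non-negative")
  a <- fit$coefficients
  if (fit$model == "sat_exp") {
    a[["a1"]] * (1 - exp(-a[["a2"]] * x)) + a[["a3"]]
  } else {
    a[["a2"]] + (a[["a1"]] - a[["a2"]]) / (1 + a[["a3"]] * x^a[["a4"]])
  }
}

# df/dx, used by the delta-method uncertainty propagation
eval_model_deriv <- function(fit, x) {
  a <- fit$coefficients
  if (fit$model == "sat_exp") {
    a[["a1"]] * a[["a2"]] * exp(-a[["a2"]] * x)
  } else {
    den <- (1 + a[["a3"]] * x^a[["a4"]])^2
    -(a[["a1"]] - a[["a2"]]) * a[["a3"]] * a[["a4"]] * x^(a[["a4"]] - 1) / den
  }
}

#' Invert a calibration curve
#'
#' Closed forms:
#' `sat_exp`: x = -log(1 - (y - a3) / a1) / a2;
#' `sigmoid`: x = (((a1 - a2) / (y - a2) - 1) / a3)^(1 / a4).
#' y must lie strictly between the model's asymptotic bounds
#' (a3 and a1 + a3 for `sat_exp`; a1 and a2 for `sigmoid`).
#'
#' @param fit A [calibration_fit()].
#' @param y Observed curve values.
#' @return The x solving f(x) = y.
#' @export
invert_model <- function(fit, y) {
  stopifnot(inherits(fit, "calibration_fit"))
  a <- fit$coefficients
  if (fit$model == "sat_exp") {
    lo <- min(a[["a3"]], a[["a1"]] + a[["a3"]])
    hi <- max(a[["a3"]], a[["a1"]] + a[["a3"]])
    if (any(y <= lo) || any(y >= hi)) {
      stop(sprintf(
        "value %.6g outside the invertible range (%.6g, %.6g)",
        y[which(y <= lo | y >= hi)[1L]], lo, hi
      ))
    }
    -log(1 - (y - a[["a3"]]) / a[["a1"]]) / a[["a2"]]
  } else {
    lo <- min(a[["a1"]], a[["a2"]])
    hi <- max(a[["a1"]], a[["a2"]])
    if (any(y <= lo) || any(y >= hi)) {
      stop(sprintf(
        "value %.6g outside the invertible range (%.6g, %.6g)",
        y[which(y <= lo | y >= hi)[1L]], lo, hi
      ))
    }
    (((a[["a1"]] - a[["a2"]]) / (y - a[["a2"]]) - 1) / a[["a3"]])^(1 / a[["a4"]])
  }
}

#' Fit a calibration curve by weighted nonlinear least squares
#'
#' Levenberg-Marquardt least squares with scale-free initial guesses:
#' `sat_exp` starts at a1 = max(y) - min(y), a2 = 1 / median(x),
#' a3 = min(y); `sigmoid` starts at a1 = y at the smallest x, a2 = y at the
#' largest x, a3 = 1, a4 = 1. Weights, when given, are applied as
#' 1 / uncertainty^2. The coefficient covariance is taken from the
#' Jacobian at the optimum.
#'
#' @param x Non-negative predictor values.
#' @param y Observed responses.
#' @param uncertainties Optional per-point uncertainties; any non-finite or
#'   non-positive entries disable weighting (unweighted fit).
#' @param model `"sat_exp"` or `"sigmoid"`.
#' @return A [calibration_fit()].
#' @export
fit_calibration <- function(x, y, uncertainties = NULL,
                            model = c("sat_exp", "sigmoid")) {
  model <- match.arg(model)
  n_par <- if (model == "sat_exp") 3L else 4L
  if (length(x) < n_par) {
    stop(sprintf("need at least %d points to fit %s", n_par, model))
  }
  stopifnot(length(x) == length(y))
  if (any(x < 0)) stop("x must be non-negative")
  w <- NULL
  if (!is.null(uncertainties) &&
      all(is.finite(uncertainties)) && all(uncertainties > 0)) {
    w <- 1 / uncertainties^2
  }
  x_scale <- stats::median(x[x > 0])
  if (model == "sat_exp") {
    # scale-free principal start plus rate variations against local minima
    starts <- lapply(c(1, 0.3, 3), function(f) {
      c(a1 = max(y) - min(y), a2 = f / x_scale, a3 = min(y))
    })
    fun <- function(p) p[1L] * (1 - exp(-p[2L] * x)) + p[3L]
    lower <- c(-Inf, 1e-12, -Inf)
  } else {
    starts <- list()
    for (a4 in c(1, 2)) {
      for (f in c(1, 0.2, 5)) {
        starts[[length(starts) + 1L]] <- c(
          a1 = y[which.min(x)], a2 = y[which.max(x)],
          a3 = f / x_scale^a4, a4 = a4
        )
      }
    }
    fun <- function(p) p[2L] + (p[1L] - p[2L]) / (1 + p[3L] * x^p[4L])
    lower <- c(-Inf, -Inf, 1e-12, 1e-12)
  }
  sw <- if (is.null(w)) rep(1, length(x)) else sqrt(w)
  out <- NULL
  for (start in starts) {
    cand <- minpack.lm::nls.lm(
      par = start,
      fn = function(p) sw * (y - fun(p)),
      lower = lower,
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                           ptol = 1e-15)
    )
    if (cand$info %in% c(0L, 5L)) next
    if (is.null(out) || cand$deviance < out$deviance) out <- cand
  }
  if (is.null(out)) stop("calibration fit did not converge")
  co <- out$par
  # covariance from the Jacobian at the optimum: (J'J)^-1 * s^2
  dof <- length(x) - n_par
  vc <- NULL
  if (dof > 0) {
    jtj <- out$hessian / 2
    vc <- tryCatch(
      solve(jtj) * out$deviance / dof,
      error = function(e) NULL
    )
  }
  calibration_fit(model, co, vcov = vc,
                  residuals = y - fun(co), x_range = range(x))
}

#' Dose calibration from the reference-corrected blue response
#'
#' Fits the saturating exponential to S/S_R of the blue band versus the
#' delivered dose of the calibration series (0.1-1.1 Gy at the 230 MeV
#' calibration condition).
#'
#' @param response Blue-band S/S_R values (package means).
#' @param doses Delivered doses in Gy.
#' @param uncertainties Optional per-point uncertainties (package SEM).
#' @return A [calibration_fit()] of kind `sat_exp`.
#' @export
calibrate_dose <- function(response, doses, uncertainties = NULL) {
  if (any(doses < 0.05) || any(doses > 1.5)) {
    warning("doses outside the 0.1-1.1 Gy calibration span")
  }
  fit_calibration(doses, response, uncertainties, model = "sat_exp")
}

#' Quenched dose from the blue-band response
#'
#' Inverts the dose calibration at the measured S/S_R: the blue emission is
#' related to the ionization-quenched dose through the calibration curve.
#'
#' @param dose_fit A [calibrate_dose()] fit.
#' @param response Measured blue S/S_R value(s).
#' @return Quenched dose(s) D_OSLD,water in Gy.
#' @export
estimate_quenched_dose <- function(dose_fit, response) {
  invert_model(dose_fit, response)
}

#' LET calibration from UV/blue ratios
#'
#' Relates UV/blue ratios to the simulated fluence-averaged LET at the
#' irradiation positions. Reference-corrected ratios are fitted with the
#' sigmoid form, uncorrected ratios with the saturating exponential, the
#' forms found to represent each data set.
#'
#' @param ratios UV/blue ratios (package means).
#' @param lets True (simulated) fluence-averaged LET values in keV/um,
#'   spanning at least a factor 2.
#' @param uncertainties Optional per-point uncertainties (package SEM).
#' @param corrected Whether `ratios` are reference-corrected.
#' @return A [calibration_fit()].
#' @export
calibrate_let <- function(ratios, lets, uncertainties = NULL,
                          corrected = TRUE) {
  if (max(lets) / min(lets) < 2) {
    stop("LET calibration needs values spanning at least a factor 2")
  }
  fit_calibration(lets, ratios, uncertainties,
                  model = if (corrected) "sigmoid" else "sat_exp")
}

#' Estimate the LET from measured UV/blue ratios
#'
#' Inverts the LET calibration curve at each measured ratio. Ratios outside
#' the invertible range raise an error carrying the offending value.
#'
#' @param let_fit A [calibrate_let()] fit.
#' @param ratios Measured UV/blue ratios.
#' @return Estimated LET values in keV/um.
#' @export
estimate_let <- function(let_fit, ratios) {
  invert_model(let_fit, ratios)
}

#' Delta-method LET uncertainty
#'
#' Propagates a ratio standard error through the inverse calibration:
#' SEM_LET = SEM_ratio / |f'(x)| at the estimated LET.
#'
#' @param let_fit A [calibrate_let()] fit.
#' @param ratio Measured ratio.
#' @param ratio_sem Standard error of the ratio.
#' @return Standard error of the LET estimate.
#' @export
propagate_let_uncertainty <- function(let_fit, ratio, ratio_sem) {
  x <- invert_model(let_fit, ratio)
  d <- eval_model_deriv(let_fit, x)
  if (any(d == 0)) stop("zero calibration slope: uncertainty undefined")
  abs(ratio_sem / d)
}

#' Relative luminescence efficiency curve
#'
#' The efficiency of each calibration point is the quenched OSLD dose over
#' the delivered dose, eta_i = D_OSLD,water,i / D_water,i; the points are
#' fitted as a monotone-decreasing sigmoid of the reference-corrected
#' UV/blue ratio (so applying the correction needs no beam model), and the
#' curve is normalized to exactly 1 at the calibration condition's ratio.
#'
#' Point sets that are non-monotone beyond a 2% tolerance trigger a
#' warning; the fit proceeds.
#'
#' @param quenched_doses Quenched doses in Gy.
#' @param delivered_doses Delivered doses in Gy.
#' @param ratios Corrected UV/blue ratios of the same points.
#' @param cal_ratio Ratio at the calibration condition (efficiency 1).
#' @return An object of class `"efficiency_curve"`.
#' @export
build_efficiency <- function(quenched_doses, delivered_doses, ratios,
                             cal_ratio) {
  eta <- quenched_doses / delivered_doses
  ord <- order(ratios)
  if (any(diff(eta[ord]) > 0.02)) {
    warning("efficiency points are non-monotone beyond the noise tolerance")
  }
  pts_r <- c(ratios, cal_ratio)
  pts_e <- c(eta, 1)
  fit <- fit_calibration(pts_r, pts_e, model = "sigmoid")
  scale <- eval_model(fit, cal_ratio)
  structure(
    list(fit = fit, scale = scale, cal_ratio = cal_ratio,
         points = data.frame(ratio = pts_r, eta = pts_e)),
    class = "efficiency_curve"
  )
}

#' @export
print.efficiency_curve <- function(x, ...) {
  cat(sprintf(
    "<efficiency_curve> %d points, eta(cal ratio %.4g) = %.6g\n",
    nrow(x$points), x$cal_ratio, efficiency_at(x, x$cal_ratio)
  ))
  invisible(x)
}

#' Evaluate the efficiency curve
#'
#' @param curve An [build_efficiency()] result.
#' @param ratio Corrected UV/blue ratio(s).
#' @return Relative luminescence efficiency, exactly 1 at the calibration
#'   ratio.
#' @export
efficiency_at <- function(curve, ratio) {
  stopifnot(inherits(curve, "efficiency_curve"))
  eval_model(curve$fit, ratio) / curve$scale
}

#' Quenching-corrected dose
#'
#' Scales the quenched dose by the inverse relative luminescence
#' efficiency: D_water = D_OSLD,water / eta.
#'
#' @param quenched_dose Quenched dose(s) in Gy.
#' @param eta Relative luminescence efficiency, 0 < eta <= 1.05.
#' @return Corrected dose(s) in Gy.
#' @export
correct_dose <- function(quenched_dose, eta) {
  if (any(eta <= 0)) stop("efficiency must be positive")
  if (any(eta > 1.05)) stop("efficiency above the physical bound 1.05")
  quenched_dose / eta
}

#' Serialize calibration fits to JSON
#'
#' @param fit A [calibration_fit()].
#' @param path Output path.
#' @param created_from Free-text provenance note.
#' @return The path, invisibly.
#' @export
write_calibration <- function(fit, path, created_from = "") {
  stopifnot(inherits(fit, "calibration_fit"))
  obj <- list(
    model = fit$model,
    coefficients = as.list(fit$coefficients),
    covariance = if (is.null(fit$vcov)) NULL else unclass(as.matrix(fit$vcov)),
    x_range = fit$x_range,
    created_from = created_from
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a calibration fit written by [write_calibration()]
#'
#' @param path JSON path.
#' @return A [calibration_fit()].
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_fit(
    obj$model, unlist(obj$coefficients),
    vcov = obj$covariance, x_range = obj$x_range
  )
}
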