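#' Calcium-selective electrode model (Nikolsky-Eisenman response)
#'
#' Parameters of the electrode response
#' `dE = E0 + s * log10([Ca]_F + Sigma)` where potentials are expressed
#' relative to a reference calibration solution (so `E0` is the
#' intrinsic potential in that referenced frame), `s` is the slope per
#' decade, and `Sigma` is the lumped interference constant describing
#' the response floor at low free calcium.
#'
#' @param E0_mV intrinsic potential (mV) in the referenced frame.
#' @param s_mV_per_decade electrode slope (> 0).
#' @param sigma_M lumped interference constant (M, >= 0).
#' @return A list of class `"electrode_model"`.
#' @export
electrode_model <- function(E0_mV, s_mV_per_decade, sigma_M = 0) {
  if (s_mV_per_decade <= 0) stop("slope must be > 0")
  if (sigma_M < 0) stop("sigma_M must be >= 0")
  structure(list(E0_mV = E0_mV, s_mV_per_decade = s_mV_per_decade,
                 sigma_M = sigma_M), class = "electrode_model")
}

#' Single-site calcium buffer model
#'
#' @param name buffer name (`"BAPTA"`, `"HEDTA"`, `"NTA"`, or other).
#' @param Kd_M calcium dissociation constant (M, > 0).
#' @param BT_M total buffer concentration (M, > 0).
#' @return A list of class `"buffer_model"`.
#' @export
buffer_model <- function(name, Kd_M, BT_M) {
  if (Kd_M <= 0 || BT_M <= 0) stop("Kd_M and BT_M must be > 0")
  structure(list(name = name, Kd_M = Kd_M, BT_M = BT_M),
            class = "buffer_model")
}

#' Electrode calibration series
#'
#' Bundles buffer-free calibration rows (total calcium equals free
#' calcium; these constrain `E0` and the slope) with buffered rows
#' (these constrain `BT`, `Kd`, and `Sigma`).
#'
#' @param calibration data frame (`Ca_total_M`, `delta_E_mV`) of
#'   buffer-free solutions; the design spans 0.5-10 mM total calcium.
#' @param buffered data frame (`Ca_total_M`, `delta_E_mV`) of buffered
#'   solutions.
#' @return A list of class `"calibration_series"`.
#' @export
calibration_series <- function(calibration, buffered) {
  for (d in list(calibration, buffered)) {
    if (!all(c("Ca_total_M", "delta_E_mV") %in% names(d)))
      stop("rows need columns Ca_total_M, delta_E_mV")
    if (any(d$Ca_total_M <= 0)) stop("Ca_total_M must be > 0")
  }
  structure(list(calibration = calibration, buffered = buffered),
            class = "calibration_series")
}

#' Free calcium from a measured relative potential
#'
#' Inverts the Nikolsky-Eisenman response:
#' `[Ca]_F = 10^((dE - E0)/s) - Sigma`.  Values that invert to below
#' zero (possible with measurement noise near the response floor) are
#' clamped at 0 with a `clamped` attribute set.
#'
#' @param delta_E_mV measured relative potential(s), mV.
#' @param model an [electrode_model()].
#' @return Free calcium concentration(s) in M.
#' @export
#' @examples
#' m <- electrode_model(0, 30, 0)
#' free_from_potential(-180, m)  # 1e-6 M
free_from_potential <- function(delta_E_mV, model) {
  stopifnot(inherits(model, "electrode_model"))
  f <- 10^((delta_E_mV - model$E0_mV) / model$s_mV_per_decade) -
    model$sigma_M
  clamped <- f < 0
  f[clamped] <- 0
  attr(f, "clamped") <- any(clamped)
  f
}

#' Relative potential of a free-calcium concentration
#'
#' `dE = E0 + s * log10([Ca]_F + Sigma)`; the inverse of
#' [free_from_potential()].
#'
#' @param Ca_free_M free calcium (M, >= 0).
#' @param model an [electrode_model()].
#' @return Relative potential(s) in mV.
#' @export
potential_from_free <- function(Ca_free_M, model) {
  stopifnot(inherits(model, "electrode_model"))
  if (any(Ca_free_M < 0)) stop("Ca_free_M must be >= 0")
  arg <- Ca_free_M + model$sigma_M
  if (any(arg <= 0)) stop("Ca_free + sigma must be > 0")
  model$E0_mV + model$s_mV_per_decade * log10(arg)
}

#' Total calcium needed for a target free calcium
#'
#' Single-site buffering:
#' `[Ca]_T = [Ca]_F * ([B]_T + [Ca]_F + Kd) / ([Ca]_F + Kd)`.
#'
#' @param Ca_free_M target free calcium (M).
#' @param buffer a [buffer_model()].
#' @return Total calcium (M).
#' @export
#' @examples
#' total_from_free(1e-8, buffer_model("BAPTA", 1.44e-7, 1e-2))  # ~6.49e-4
total_from_free <- function(Ca_free_M, buffer) {
  stopifnot(inherits(buffer, "buffer_model"))
  Ca_free_M * (buffer$BT_M + Ca_free_M + buffer$Kd_M) /
    (Ca_free_M + buffer$Kd_M)
}

#' Free calcium in a buffered solution of known total calcium
#'
#' Positive root of the single-site binding quadratic
#' `F^2 + (BT + Kd - T) F - Kd T = 0`; exact inverse of
#' [total_from_free()].
#'
#' @param Ca_total_M total calcium (M, >= 0).
#' @param buffer a [buffer_model()].
#' @return Free calcium (M).
#' @export
free_from_total <- function(Ca_total_M, buffer) {
  stopifnot(inherits(buffer, "buffer_model"))
  if (any(Ca_total_M < 0)) stop("Ca_total_M must be >= 0")
  b <- buffer$BT_M + buffer$Kd_M - Ca_total_M
  disc <- b^2 + 4 * buffer$Kd_M * Ca_total_M
  # cancellation-free form of the positive root for either sign of b
  ifelse(b >= 0,
         2 * buffer$Kd_M * Ca_total_M / (b + sqrt(disc)),
         (-b + sqrt(disc)) / 2)
}

#' Joint calibration of electrode and buffer parameters
#'
#' Least-squares fit of the composite model to a calibration series:
#' buffer-free rows are predicted as
#' `dE = E0 + s log10(Ca_total + Sigma)` and buffered rows as
#' `dE = E0 + s log10(free_from_total(Ca_total; BT, Kd) + Sigma)`,
#' optimizing all five parameters (`E0`, `s`, `Sigma`, `BT`, `Kd`)
#' jointly by Levenberg-Marquardt with `Sigma`, `BT`, and `Kd` on the
#' log scale.  This is the calibration step that corrects, e.g., total
#' buffer concentrations overestimated because of buffer hydration.
#'
#' @param series a [calibration_series()].
#' @param init a [buffer_model()] providing starting `BT` and `Kd`
#'   (typically nominal weighed-in values).
#' @param sigma0_M starting interference constant (M).
#' @return List of class `"lom_fit"`: `electrode` (an
#'   [electrode_model()]), `buffer` (a [buffer_model()]), and
#'   `residuals_mV`.
#' @export
fit_lom <- function(series, init, sigma0_M = 1e-8) {
  stopifnot(inherits(series, "calibration_series"),
            inherits(init, "buffer_model"))
  if (nrow(series$buffered) == 0)
    stop("unidentifiable design: no buffered rows")
  if (nrow(series$calibration) < 2)
    stop("unidentifiable design: need >= 2 buffer-free calibration rows")
  cal <- series$calibration; buf <- series$buffered

  # slope/intercept start from a line through the buffer-free rows
  l0 <- stats::lm(delta_E_mV ~ log10(Ca_total_M), data = cal)
  start <- c(E0 = unname(coef(l0)[1]), s = max(unname(coef(l0)[2]), 1),
             log_sigma = log(sigma0_M), log_BT = log(init$BT_M),
             log_Kd = log(init$Kd_M))

  resid_fn <- function(p) {
    em <- electrode_model(p["E0"], max(p["s"], 1e-6), exp(p["log_sigma"]))
    bm <- buffer_model(init$name, exp(p["log_Kd"]), exp(p["log_BT"]))
    pred_cal <- potential_from_free(cal$Ca_total_M, em)
    pred_buf <- potential_from_free(free_from_total(buf$Ca_total_M, bm), em)
    c(pred_cal - cal$delta_E_mV, pred_buf - buf$delta_E_mV)
  }
  fit <- minpack.lm::nls.lm(start, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  p <- fit$par
  structure(list(
    electrode = electrode_model(unname(p["E0"]), unname(p["s"]),
                                unname(exp(p["log_sigma"]))),
    buffer = buffer_model(init$name, unname(exp(p["log_Kd"])),
                          unname(exp(p["log_BT"]))),
    residuals_mV = fit$fvec, fit = fit),
    class = "lom_fit")
}

#' @export
print.lom_fit <- function(x, ...) {
  cat(sprintf(
    "LOM fit: E0 = %.3f mV, s = %.3f mV/decade, Sigma = %.3g M\n       %s: Kd = %.3g M, BT = %.3g M  (RMS residual %.3g mV)\n",
    x$electrode$E0_mV, x$electrode$s_mV_per_decade, x$electrode$sigma_M,
    x$buffer$name, x$buffer$Kd_M, x$buffer$BT_M,
    sqrt(mean(x$residuals_mV^2))))
  invisible(x)
}

lom_default_buffers <- function() {
  list(BAPTA = buffer_model("BAPTA", 1.44e-7, 1e-2),
       HEDTA = buffer_model("HEDTA", 2.24e-6, 1e-2),
       NTA = buffer_model("NTA", 8.15e-5, 1e-2))
}

#' Buffer recipe for a target free-calcium concentration
#'
#' Selects the buffer whose dissociation constant is closest to the
#' target by the standard range rule -- BAPTA below 1 uM free calcium,
#' HEDTA for 1-10 uM, NTA above 10 uM -- and computes the total calcium
#' to add via [total_from_free()].
#'
#' @param target_Ca_free_M target free calcium (M, > 0).
#' @param buffers named list of [buffer_model()]s for the three ranges
#'   (override with LOM-optimized `BT`/`Kd` values when available).
#' @return List of class `"buffer_recipe"`: `buffer` (the chosen
#'   [buffer_model()]), `Ca_total_M`, `target_Ca_free_M`.
#' @export
#' @examples
#' recipe(1e-7)$buffer$name  # BAPTA
#' recipe(5e-5)$buffer$name  # NTA
recipe <- function(target_Ca_free_M, buffers = lom_default_buffers()) {
  if (target_Ca_free_M <= 0) stop("target must be > 0")
  bname <- if (target_Ca_free_M < 1e-6) "BAPTA"
           else if (target_Ca_free_M <= 1e-5) "HEDTA"
           else "NTA"
  b <- buffers[[bname]]
  structure(list(buffer = b,
                 Ca_total_M = total_from_free(target_Ca_free_M, b),
                 target_Ca_free_M = target_Ca_free_M),
            class = "buffer_recipe")
}
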