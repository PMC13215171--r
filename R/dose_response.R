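hill_fraction <- function(conc, ic50, nH) 1 / (1 + (conc / ic50)^nH)

#' Hill fit of concentration-inhibition data
#'
#' Least-squares fit of `I_Blocker / I_Glu = 1 / (1 + ([B]/IC50)^nH)`
#' with IC50 and the Hill coefficient free.  The fitted curve passes
#' through 0.5 at the IC50 by construction.
#'
#' @param table data frame with columns `blocker_uM` and `fraction`
#'   (e.g. from [inhibition_table()]); at least 3 positive
#'   concentrations spanning the inflection.
#' @param nH_max upper bound on the Hill coefficient (default 6).
#' @param ic50_span IC50 is bounded within the data's concentration span
#'   times this factor range, preventing runaway fits.
#' @return List of class `"hill_fit"`: `ic50_uM`, `n_H`, `fitted`
#'   prediction function.
#' @export
#' @examples
#' d <- data.frame(blocker_uM = c(0.25, 0.5, 1, 2, 4, 8, 16),
#'                 fraction = 1 / (1 + (c(0.25, 0.5, 1, 2, 4, 8, 16) / 2)))
#' fit_hill(d)$ic50_uM  # 2
fit_hill <- function(table, nH_max = 6, ic50_span = c(0.01, 100)) {
  x <- table$blocker_uM
  y <- table$fraction
  pos <- x > 0
  if (sum(pos) < 3) stop("need at least 3 positive blocker concentrations")
  if (all(y[pos] > 0.95) || all(y[pos] < 0.05))
    stop("degenerate inhibition data (no inflection in range)")
  lo <- c(ic50 = min(x[pos]) * ic50_span[1], nH = 1e-3)
  hi <- c(ic50 = max(x[pos]) * ic50_span[2], nH = nH_max)
  start <- c(ic50 = exp(stats::approx(y[pos], log(x[pos]), xout = 0.5,
                                      rule = 2, ties = "ordered")$y),
             nH = 1)
  fit <- minpack.lm::nlsLM(
    fraction ~ 1 / (1 + (blocker_uM / ic50)^nH),
    data = data.frame(blocker_uM = x, fraction = y),
    start = as.list(start), lower = lo, upper = hi,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14))
  ic50 <- unname(coef(fit)["ic50"]); nH <- unname(coef(fit)["nH"])
  structure(list(ic50_uM = ic50, n_H = nH,
                 fitted = function(conc) hill_fraction(conc, ic50, nH),
                 fit = fit),
            class = "hill_fit")
}

#' Fit the intracellular-calcium dependence of a quantity
#'
#' Least-squares fit of
#' `Y = min + (max - min) / (1 + ([Ca]_i / CaEC50)^nH)` to observations
#' of Y (e.g. blocker IC50 or I_ss/I_peak) at clamped `[Ca]_i` values.
#' Nominally calcium-free ("< 1 nM") points enter at `ca = 0`, where the
#' model evaluates exactly to `max`.  The fitted curve passes through
#' `(min + max) / 2` at `CaEC50`.
#'
#' @param rows data frame with columns `ca_i_uM` and `Y`; at least 4
#'   points including a low-calcium anchor.
#' @param anchor_max `"free"` (default) fits the upper plateau; or
#'   `"lowest"` pins it to the observation at the lowest calcium.
#' @return List of class `"ca_dependence_fit"`: `y_min`, `y_max`,
#'   `CaEC50_uM`, `n_H`, `midpoint` (= (y_min + y_max)/2), `fitted`.
#' @export
fit_ca_dependence <- function(rows, anchor_max = c("free", "lowest")) {
  anchor_max <- match.arg(anchor_max)
  if (nrow(rows) < 4) stop("need at least 4 calcium levels")
  o <- order(rows$ca_i_uM)
  ca <- rows$ca_i_uM[o]; y <- rows$Y[o]
  if (!any(ca <= 1e-3))
    warning("no low-calcium anchor point (<= 1 nM); upper plateau poorly constrained")
  if (any(diff(y) > 0)) message("non-monotone Y values; fit proceeds")
  ymax0 <- y[1]; ymin0 <- min(y)
  start <- list(ymin = ymin0, CaEC50 = max(min(ca[ca > 0]), 1e-3), nH = 1)
  lo <- c(ymin = -Inf, CaEC50 = 1e-6, nH = 1e-3)
  hi <- c(ymin = Inf, CaEC50 = max(ca) * 100, nH = 6)
  d <- data.frame(ca = ca, y = y)
  if (anchor_max == "lowest") {
    fit <- minpack.lm::nlsLM(
      y ~ ymin + (ymax0 - ymin) / (1 + (ca / CaEC50)^nH), data = d,
      start = start, lower = lo, upper = hi,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14))
    cf <- c(coef(fit), ymax = unname(ymax0))
  } else {
    fit <- minpack.lm::nlsLM(
      y ~ ymin + (ymax - ymin) / (1 + (ca / CaEC50)^nH), data = d,
      start = c(start, ymax = ymax0),
      lower = c(lo, ymax = -Inf), upper = c(hi, ymax = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14))
    cf <- coef(fit)
  }
  ymin <- unname(cf["ymin"]); ymax <- unname(cf["ymax"])
  ec50 <- unname(cf["CaEC50"]); nH <- unname(cf["nH"])
  structure(list(y_min = ymin, y_max = ymax,
                 CaEC50_uM = ec50, n_H = nH,
                 midpoint = (ymin + ymax) / 2,
                 fitted = function(ca_uM)
                   ymin + (ymax - ymin) / (1 + (ca_uM / ec50)^nH),
                 fit = fit),
            class = "ca_dependence_fit")
}

#' Amplitude-weighted time constant of a double exponential
#'
#' `tau_w = (tau_fast A_fast + tau_slow A_slow) / (A_fast + A_slow)`,
#' used to compare double- with single-exponential recovery fits.
#'
#' @param tau_fast_s,A_fast,tau_slow_s,A_slow time constants (s) and
#'   amplitudes of the two components.
#' @return Weighted time constant in seconds.
#' @export
#' @examples
#' tau_weighted(1, 1, 3, 1)  # 2
tau_weighted <- function(tau_fast_s, A_fast, tau_slow_s, A_slow) {
  (tau_fast_s * A_fast + tau_slow_s * A_slow) / (A_fast + A_slow)
}

#' Exponential fit of recovery from desensitization
#'
#' Fits normalized peak vs. interapplication interval with
#' `1 - A exp(-t/tau)` (single) and
#' `1 - A_f exp(-t/tau_f) - A_s exp(-t/tau_s)` (double); the double
#' exponential is retained only when it improves the corrected AIC.
#' For double fits, the amplitude-weighted [tau_weighted()] constant is
#' reported for comparison with single-exponential time constants.
#'
#' @param rows data frame with columns `interval_s` and `peak_norm`
#'   (e.g. from [rfd_peak_series()]); at least 5 intervals.
#' @return List of class `"rfd_fit"`: `kind` ("single"/"double"),
#'   component fields (`tau_s`, or `tau_fast_s`, `A_fast`, `tau_slow_s`,
#'   `A_slow`), `tau_w_s`, and `fitted`.
#' @export
fit_rfd <- function(rows) {
  if (nrow(rows) < 5) stop("need at least 5 intervals")
  t <- rows$interval_s; y <- rows$peak_norm
  if (stats::cor(t, y) < 0) stop("non-recovering data (peaks decrease with interval)")
  d <- data.frame(t = t, y = y)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-14,
                                     ptol = 1e-14)
  A0 <- max(1 - min(y), 0.05)
  tau0 <- max(stats::approx(y, t, xout = 1 - A0 * exp(-1), rule = 2,
                            ties = "ordered")$y, min(t[t > 0]))
  single <- minpack.lm::nlsLM(y ~ 1 - A * exp(-t / tau), data = d,
                              start = list(A = A0, tau = tau0),
                              lower = c(A = 0, tau = 1e-6), control = ctrl)
  double <- tryCatch(
    minpack.lm::nlsLM(y ~ 1 - Af * exp(-t / tf) - As * exp(-t / ts),
                      data = d,
                      start = list(Af = A0 / 2, tf = tau0 / 4,
                                   As = A0 / 2, ts = tau0 * 4),
                      lower = c(Af = 0, tf = 1e-6, As = 0, ts = 1e-6),
                      control = ctrl),
    error = function(e) NULL)
  aicc <- function(fit, k) {
    n <- length(y)
    rss <- sum(stats::resid(fit)^2)
    n * log(rss / n) + 2 * k + if (n - k - 1 > 0) 2 * k * (k + 1) / (n - k - 1) else Inf
  }
  use_double <- !is.null(double) && aicc(double, 4) < aicc(single, 2)
  if (use_double) {
    cf <- coef(double)
    # order components so that tau_fast <= tau_slow
    if (cf["tf"] > cf["ts"]) cf <- cf[c("As", "ts", "Af", "tf")]
    names(cf) <- c("Af", "tf", "As", "ts")
    tf <- unname(cf["tf"]); ts_ <- unname(cf["ts"])
    af <- unname(cf["Af"]); as_ <- unname(cf["As"])
    structure(list(kind = "double",
                   tau_fast_s = tf, A_fast = af,
                   tau_slow_s = ts_, A_slow = as_,
                   tau_w_s = tau_weighted(tf, af, ts_, as_),
                   fitted = function(t) 1 - af * exp(-t / tf) -
                     as_ * exp(-t / ts_),
                   fit = double),
              class = "rfd_fit")
  } else {
    tau <- unname(coef(single)["tau"]); A <- unname(coef(single)["A"])
    structure(list(kind = "single", tau_s = tau,
                   A = A, tau_w_s = tau,
                   fitted = function(t) 1 - A * exp(-t / tau),
                   fit = single),
              class = "rfd_fit")
  }
}

#' Normalize LDH release against vehicle and full-insult controls
#'
#' `(treatment - vehicle) / (nmda_only - vehicle)`: 0 means complete
#' protection (vehicle-level cell death), 1 means the full excitotoxic
#' insult.
#'
#' @param treatment,vehicle,nmda_only raw LDH readings; `nmda_only` must
#'   exceed `vehicle`.
#' @return Normalized LDH value(s).
#' @export
normalize_ldh <- function(treatment, vehicle, nmda_only) {
  if (any(nmda_only <= vehicle))
    stop("nmda_only must exceed vehicle LDH release")
  (treatment - vehicle) / (nmda_only - vehicle)
}

#' Hill fit of normalized-LDH neuroprotection curves
#'
#' Least-squares fit of
#' `LDH_norm = min + (1 - min) / (1 + ([B]/IC50)^nH)` with the floor,
#' IC50 (half-maximal neuroprotection concentration), and Hill
#' coefficient free.  The curve is pinned to 1 at zero blocker.
#'
#' @param rows data frame with columns `blocker_uM` and `ldh_norm`; at
#'   least 4 concentrations (the assay grid 0.3, 1, 3, 10, 30, 100 uM is
#'   typical).
#' @return List of class `"ldh_fit"`: `min_ldh_norm`, `ic50_uM`, `n_H`,
#'   `fitted`.
#' @export
fit_ldh <- function(rows) {
  x <- rows$blocker_uM; y <- rows$ldh_norm
  pos <- x > 0
  if (sum(pos) < 4) stop("need at least 4 positive blocker concentrations")
  if (max(y) - min(y) < 0.05) stop("degenerate (flat) neuroprotection data")
  lo <- c(minl = 0, ic50 = min(x[pos]) * 0.01, nH = 1e-3)
  hi <- c(minl = 1 - 1e-9, ic50 = max(x[pos]) * 100, nH = 6)
  resid_fn <- function(p)
    p["minl"] + (1 - p["minl"]) / (1 + (x / p["ic50"])^p["nH"]) - y
  fit <- minpack.lm::nls.lm(
    par = c(minl = max(min(y), 0.01), ic50 = stats::median(x[pos]), nH = 1),
    lower = lo, upper = hi, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14))
  cf <- fit$par
  minl <- unname(cf["minl"]); ic50 <- unname(cf["ic50"]); nH <- unname(cf["nH"])
  structure(list(min_ldh_norm = minl, ic50_uM = ic50, n_H = nH,
                 fitted = function(conc)
                   minl + (1 - minl) / (1 + (conc / ic50)^nH),
                 fit = fit),
            class = "ldh_fit")
}
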