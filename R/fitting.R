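#' Lognormal jitter of optimization starting values
#'
#' Each entry of the (positive) starting vector is multiplied by an
#' independent lognormal factor `exp(N(0, sigma^2))`, spreading the
#' multistart trials over a broad but positive parameter space.
#'
#' @param v0 positive numeric vector of starting values.
#' @param sigma SD of the Gaussian on the log scale (default 1.2).
#' @return Jittered vector of the same length; draws come from the
#'   current RNG state, so results are deterministic under a set seed.
#' @export
jitter_start <- function(v0, sigma = 1.2) {
  if (any(v0 <= 0)) stop("all starting values must be > 0")
  if (sigma < 0) stop("sigma must be >= 0")
  v0 * exp(rnorm(length(v0), 0, sigma))
}

#' Sum of squared differences between two traces
#'
#' Traces are compared pointwise on a common grid; if the grids differ,
#' the simulated trace is linearly resampled onto the data grid.  Pass
#' `normalize = TRUE` to normalize each trace to its own steady state
#' first (making the comparison scale-invariant).
#'
#' @param sim,data `"nmdar_trace"` objects (or plain numeric vectors of
#'   equal length).
#' @param normalize normalize both traces via [normalize_trace()] first.
#' @return Scalar sum of squared differences.
#' @export
trace_sse <- function(sim, data, normalize = FALSE) {
  if (is.numeric(sim) && is.numeric(data)) {
    if (length(sim) != length(data)) stop("length mismatch")
    return(sum((sim - data)^2))
  }
  if (normalize) {
    sim <- normalize_trace(sim)
    data <- normalize_trace(data)
  }
  y_sim <- sim$current_pA
  if (length(sim$time_s) != length(data$time_s) ||
      max(abs(sim$time_s - data$time_s)) > 1e-9) {
    y_sim <- approx(sim$time_s, sim$current_pA, xout = data$time_s,
                    rule = 2)$y
  }
  sum((y_sim - data$current_pA)^2)
}

#' Free parameters of each staged fitting step
#'
#' Step 1 fits Ca-independent desensitization (`k_d_plus`, `k_d_minus`)
#' to a Ca-free agonist step; step 2 fits memantine unbinding and
#' blocked-arm desensitization entry (`k_M_minus`, `k_dM_plus`) to a
#' Ca-free concentration-inhibition protocol; step 3 fits CDD entry/exit
#' (`k_cdd_plus`, `k_cdd_minus`) to a high-calcium agonist step; step 4
#' fits the memantine-bound CDD rates (`k_cddM_plus`, `k_cddM_minus`) to
#' a high-calcium concentration-inhibition protocol.  The amplitude
#' scale N is free in every fit (profiled analytically) and excluded
#' from ensemble intervals.  At most two kinetic parameters are free in
#' any step.
#'
#' @param step_id integer 1-4.
#' @return Character vector of free rate-constant names.
#' @export
fit_step_params <- function(step_id) {
  switch(as.character(step_id),
         "1" = c("k_d_plus", "k_d_minus"),
         "2" = c("k_M_minus", "k_dM_plus"),
         "3" = c("k_cdd_plus", "k_cdd_minus"),
         "4" = c("k_cddM_plus", "k_cddM_minus"),
         stop("step_id must be 1, 2, 3, or 4"))
}

#' Multistart fitting configuration
#'
#' @param n_trials independent optimization trials (>= 2 so that the
#'   across-trial t-interval is defined; default 10).
#' @param n_restarts chained optimizer runs per trial, each warm-started
#'   from the best parameters of the previous run (default 5).
#' @param jitter_sigma lognormal jitter SD applied to each trial's
#'   starting values (default 1.2).
#' @param seed base seed; trial `i` uses `seed + i`.
#' @param maxit Nelder-Mead iteration cap per run.
#' @param reltol Nelder-Mead relative convergence tolerance.
#' @param abstol absolute convergence tolerance on the SSE (the traces
#'   compared are normalized, so machine-level SSE is ~1e-14).
#' @return A list of class `"fit_config"`.
#' @export
fit_config <- function(n_trials = 10, n_restarts = 5, jitter_sigma = 1.2,
                       seed = 1, maxit = 400, reltol = 1e-10,
                       abstol = 1e-14) {
  if (n_trials < 2) stop("n_trials must be >= 2 for interval computation")
  if (jitter_sigma < 0) stop("jitter_sigma must be >= 0")
  structure(list(n_trials = n_trials, n_restarts = n_restarts,
                 jitter_sigma = jitter_sigma, seed = seed, maxit = maxit,
                 reltol = reltol, abstol = abstol), class = "fit_config")
}

# SSE objective over log-rates; amplitude N is profiled in closed form
# (SSE is quadratic in N, so the optimum N = <data, shape> / <shape, shape>).
step_objective <- function(data_trace, free, rates_fixed, dt_s,
                           statistical_factors = TRUE) {
  y <- data_trace$current_pA
  prot <- data_trace$protocol
  params1 <- current_params(N = 1)
  force(free); force(rates_fixed)
  function(theta_log) {
    r <- unclass(rates_fixed)
    r[free] <- exp(theta_log)
    r["k_dM_minus"] <- r["k_d_minus"]       # tied by convention
    scheme <- build_scheme(as_rate_set(r), statistical_factors)
    s <- tryCatch(
      simulate_protocol(scheme, prot, params1, dt_s)$current_pA,
      error = function(e) NULL)
    if (is.null(s) || any(!is.finite(s))) return(1e12)
    nhat <- sum(y * s) / sum(s * s)
    sum((y - nhat * s)^2)
  }
}

#' Run one multistart trial: jittered start, chained local minimizations
#'
#' Starting values are jittered by [jitter_start()], then a derivative-
#' free local minimizer is run `n_restarts` times, each warm-started
#' from the best parameters found so far.  The first run opens with a
#' coarse log-grid scan (unit spacing, full factorial over the one or
#' two free rates, spanning `grid_span` log units around the start);
#' later runs open with Brent line minimizations along each coordinate.
#' Every run finishes with a Nelder-Mead simplex polish.  The opening
#' scan is what lets trials escape the flat "pathway-off" plateaus that
#' arise when a wild jitter effectively disables a kinetic pathway -- a
#' simplex started there stalls or drifts along the plateau.  The log
#' transform enforces rate positivity without explicit constraints.
#'
#' @param objective function of the log-rate vector returning the SSE.
#' @param v0 named vector of starting values for the free rates.
#' @param config a [fit_config()].
#' @param trial_index integer; the trial RNG seed is
#'   `config$seed + trial_index`.
#' @param axis_span half-width (in log units) of the per-coordinate
#'   line searches on later runs.
#' @param grid_span half-width (in log units) of the opening grid scan.
#' @return List with `par` (named rates), `sse`, `sse_path` (best SSE
#'   after each chained run), and `converged`.
#' @export
run_trial <- function(objective, v0, config, trial_index = 1,
                      axis_span = 3, grid_span = 5) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + trial_index)
  start <- jitter_start(v0, config$jitter_sigma)
  theta <- log(start)
  best <- list(par = theta, value = objective(theta))
  sse_path <- numeric(config$n_restarts)
  conv <- FALSE
  npar <- length(theta)
  brent <- function(f, center) {
    # coarse tolerance: this stage only locates the basin, the simplex
    # polish supplies the precision
    stats::optimize(f, interval = center + c(-1, 1) * axis_span,
                    tol = 1e-3)
  }
  for (r in seq_len(config$n_restarts)) {
    cur <- best
    if (r == 1) {
      # opening scan: unit-spaced log grid centered on the jittered start
      offsets <- seq(-grid_span, grid_span, by = 1)
      grid <- as.matrix(do.call(expand.grid,
                                rep(list(offsets), npar)))
      for (g in seq_len(nrow(grid))) {
        th <- theta + grid[g, ]
        val <- objective(th)
        if (val < cur$value) cur <- list(par = th, value = val)
      }
      names(cur$par) <- names(theta)
    } else {
      # later runs: line minimization along each coordinate in turn
      for (j in seq_len(npar)) {
        opt <- brent(function(x) {
          th <- cur$par; th[j] <- x; objective(th)
        }, cur$par[j])
        if (opt$objective < cur$value) {
          cur$par[j] <- opt$minimum
          cur$value <- opt$objective
        }
      }
    }
    if (cur$value <= best$value) best <- cur
    if (npar > 1) {
      fit <- optim(best$par, objective, method = "Nelder-Mead",
                   control = list(maxit = config$maxit,
                                  reltol = config$reltol,
                                  abstol = config$abstol %||% 1e-14))
      if (fit$value <= best$value) best <- fit[c("par", "value")]
      conv <- fit$convergence == 0
    } else {
      opt <- brent(function(x) objective(x), best$par[1])
      if (opt$objective < best$value)
        best <- list(par = setNames(opt$minimum, names(theta)),
                     value = opt$objective)
      conv <- TRUE
    }
    sse_path[r] <- best$value
  }
  list(par = setNames(exp(best$par), names(v0)), sse = best$value,
       sse_path = sse_path, converged = conv)
}

#' Multistart ensemble fit of one staged step
#'
#' Runs `n_trials` independent trials ([run_trial()]) and summarizes the
#' resulting parameter ensemble: per-parameter mean and two-sided 95%
#' t-based interval, `mean +/- t_{0.975, n-1} * SE`.
#'
#' @param step_id fitting step (1-4), defining the free parameters.
#' @param data_trace averaged normalized `"nmdar_trace"` for this step.
#' @param rates_fixed [rate_set()] supplying all non-free rates and the
#'   trials' common starting values for the free ones.
#' @param config a [fit_config()].
#' @param dt_s simulation grid step.
#' @param statistical_factors passed to [build_scheme()].
#' @return Object of class `"fit_ensemble"`: `params` (trial x parameter
#'   matrix), `sse`, `mean`, `se`, `interval` (2 x parameter), `config`.
#' @export
multistart_fit <- function(step_id, data_trace, rates_fixed = rate_set(),
                           config = fit_config(), dt_s = 1e-3,
                           statistical_factors = TRUE) {
  free <- fit_step_params(step_id)
  rates_fixed <- as_rate_set(rates_fixed)
  obj <- step_objective(data_trace, free, rates_fixed, dt_s,
                        statistical_factors)
  v0 <- setNames(unclass(rates_fixed)[free], free)
  trials <- lapply(seq_len(config$n_trials),
                   function(i) run_trial(obj, v0, config, i))
  params <- do.call(rbind, lapply(trials, `[[`, "par"))
  sse <- vapply(trials, `[[`, 0, "sse")
  m <- colMeans(params)
  se <- apply(params, 2, sd) / sqrt(nrow(params))
  tq <- qt(0.975, df = nrow(params) - 1)
  interval <- rbind(lower = m - tq * se, upper = m + tq * se)
  structure(list(step_id = step_id, params = params, sse = sse,
                 mean = m, se = se, interval = interval,
                 t_multiplier = tq, config = config,
                 converged = vapply(trials, `[[`, TRUE, "converged")),
            class = "fit_ensemble")
}

#' @export
print.fit_ensemble <- function(x, ...) {
  cat(sprintf("fitting step %d: %d trials, best SSE %.4g\n",
              x$step_id, nrow(x$params), min(x$sse)))
  for (p in colnames(x$params))
    cat(sprintf("  %-13s %.4g  [%.4g, %.4g]\n", p, x$mean[p],
                x$interval["lower", p], x$interval["upper", p]))
  invisible(x)
}

#' Staged four-step fitting pipeline
#'
#' Executes the four fitting steps in order on the four datasets
#' (see [make_fit_datasets()]), fixing each step's ensemble means before
#' the next step.  Throughout, `k_dM_minus` is tied to `k_d_minus`, and
#' the calcium binding rates are held fixed (arbitrarily fast, ratio
#' 0.082 uM).  No more than two kinetic parameters are free in any step.
#'
#' @param datasets named list `step1`..`step4` of averaged normalized
#'   traces.
#' @param rates0 starting [rate_set()] (all fixed rates plus starting
#'   values for free ones).
#' @param config a [fit_config()]; each step uses `seed + 100*step_id`
#'   as its base seed so step ensembles are independent.
#' @param dt_s simulation grid step.
#' @param steps which steps to run (default all four, in order).
#' @return List with `rates` (final [rate_set()]) and `ensembles`
#'   (per-step [multistart_fit()] results).
#' @export
fit_pipeline <- function(datasets, rates0 = rate_set(),
                         config = fit_config(), dt_s = 1e-3,
                         steps = 1:4) {
  need <- paste0("step", steps)
  miss <- setdiff(need, names(datasets))
  if (length(miss)) stop("missing dataset(s): ", paste(miss, collapse = ", "))
  rates <- as_rate_set(rates0)
  ensembles <- list()
  for (s in steps) {
    cfg <- config
    cfg$seed <- config$seed + 100 * s
    ens <- multistart_fit(s, datasets[[paste0("step", s)]], rates, cfg,
                          dt_s)
    r <- unclass(rates)
    r[names(ens$mean)] <- ens$mean
    r["k_dM_minus"] <- r["k_d_minus"]
    rates <- as_rate_set(r)
    ensembles[[paste0("step", s)]] <- ens
  }
  list(rates = rates, ensembles = ensembles)
}

#' Equilibrium constant from forward and reverse rate constants
#'
#' @param k_fwd,k_rev forward and reverse rate constants (same units);
#'   `k_rev` must be > 0.
#' @return `K = k_fwd / k_rev` (dimensionless for unimolecular pairs).
#' @export
#' @examples
#' equilibrium_constant(1.75, 0.304)   # ~5.76, CDD with memantine bound
#' equilibrium_constant(0.737, 0.692)  # ~1.07, CDD without memantine
equilibrium_constant <- function(k_fwd, k_rev) {
  if (any(k_rev <= 0)) stop("k_rev must be > 0")
  k_fwd / k_rev
}

#' Gibbs free energy of an equilibrium constant
#'
#' `dG = -R T ln K` with R = 1.9872e-3 kcal/mol/K.
#'
#' @param K equilibrium constant (> 0).
#' @param T_K absolute temperature (default 298.15 K).
#' @return List of class `"thermo_result"`: `K`, `T_K`,
#'   `dG_kcal_mol`, `R`.
#' @export
#' @examples
#' free_energy(5.76)$dG_kcal_mol   # about -1.04 kcal/mol
free_energy <- function(K, T_K = 298.15) {
  if (any(K <= 0)) stop("K must be > 0")
  R <- 1.9872e-3
  structure(list(K = K, T_K = T_K, R = R,
                 dG_kcal_mol = -R * T_K * log(K)),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("K = %.4g  =>  dG = %.4g kcal/mol at %.2f K\n",
              x$K, x$dG_kcal_mol, x$T_K))
  invisible(x)
}

#' Stabilization free energy between two equilibria
#'
#' `ddG = dG(K1) - dG(K2) = -R T ln(K1 / K2)`: the free-energy change by
#' which the first equilibrium is deepened relative to the second.
#'
#' @inheritParams free_energy
#' @param K1,K2 equilibrium constants.
#' @return Stabilization energy in kcal/mol (negative when `K1 > K2`).
#' @export
stabilization_energy <- function(K1, K2, T_K = 298.15) {
  free_energy(K1, T_K)$dG_kcal_mol - free_energy(K2, T_K)$dG_kcal_mol
}
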