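#' Synthetic whole-cell recording specification
#'
#' Ground truth plus noise model for generating surrogate patch-clamp
#' traces: per-cell lognormal amplitude scatter (cell-to-cell variability
#' is confined to the amplitude scale; rate constants are shared),
#' additive Gaussian current noise scaled to the peak, and a linear
#' baseline drift.
#'
#' @param rates ground-truth [rate_set()].
#' @param prot an [protocol()] object.
#' @param n_cells number of cells (>= 1).
#' @param noise_sd_frac Gaussian noise SD as a fraction of the peak
#'   current.
#' @param baseline_drift_pA_per_s linear drift slope.
#' @param amplitude_sd SD of the per-cell lognormal amplitude factor.
#' @param seed integer seed; generation is a pure function of
#'   (spec, seed).
#' @param dt_s simulation grid step.
#' @param params a [current_params()] for the clean simulation.
#' @param statistical_factors passed to [build_scheme()].
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(rates = rate_set(), prot, n_cells = 5,
                           noise_sd_frac = 0.02,
                           baseline_drift_pA_per_s = 0,
                           amplitude_sd = 0.3, seed = 1, dt_s = 1e-3,
                           params = current_params(N = 100),
                           statistical_factors = TRUE) {
  stopifnot(inherits(prot, "nmdar_protocol"))
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (noise_sd_frac < 0) stop("noise_sd_frac must be >= 0")
  structure(list(rates = as_rate_set(rates), prot = prot, n_cells = n_cells,
                 noise_sd_frac = noise_sd_frac,
                 baseline_drift_pA_per_s = baseline_drift_pA_per_s,
                 amplitude_sd = amplitude_sd, seed = seed, dt_s = dt_s,
                 params = params,
                 statistical_factors = statistical_factors),
            class = "synthetic_spec")
}

#' Generate noisy synthetic traces from a ground-truth scheme
#'
#' Each cell's trace is `amplitude * clean + noise + drift`, where
#' `clean` is the deterministic simulation of the spec's protocol,
#' `amplitude` is a per-cell lognormal factor, and `noise` is iid
#' Gaussian with SD `noise_sd_frac` times the cell's peak current.
#' Output is deterministic given the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @return List of `"nmdar_trace"` objects (one per cell).
#' @export
generate_traces <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  scheme <- build_scheme(spec$rates, spec$statistical_factors)
  clean <- simulate_protocol(scheme, spec$prot, spec$params, spec$dt_s)
  peak <- max(abs(clean$current_pA))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  lapply(seq_len(spec$n_cells), function(cell) {
    amp <- exp(rnorm(1, 0, spec$amplitude_sd))
    cur <- amp * clean$current_pA
    if (spec$noise_sd_frac > 0)
      cur <- cur + rnorm(length(cur), 0, spec$noise_sd_frac * amp * peak)
    cur <- cur + spec$baseline_drift_pA_per_s * clean$time_s
    tr <- clean
    tr$current_pA <- cur
    tr$meta$cell <- cell
    tr$meta$seed <- spec$seed
    tr
  })
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

norm_segment <- function(prot) {
  seg <- prot$segments
  i <- which(seg$glu_uM > 0 & seg$mem_uM == 0)
  if (!length(i)) i <- which(seg$glu_uM > 0)
  if (!length(i)) stop("no agonist segment to normalize to")
  i[1]
}

#' Normalize a trace to its own steady state
#'
#' Divides the current by the magnitude of the steady-state current of
#' the first agonist(-only) application, preserving the inward sign:
#' the plateau of a normalized inward trace is -1.
#'
#' @param trace an `"nmdar_trace"`.
#' @return The normalized trace (`meta$normalized = TRUE`,
#'   `meta$norm_value` holding the divisor's signed value in pA).
#' @export
normalize_trace <- function(trace) {
  seg <- norm_segment(trace$protocol)
  ss <- measure_steady_state(trace, seg)
  if (abs(ss) < .Machine$double.eps) stop("zero steady-state current")
  trace$current_pA <- trace$current_pA / abs(ss)
  trace$meta$normalized <- TRUE
  trace$meta$norm_value <- ss
  trace
}

#' Normalize traces to their own steady states and average
#'
#' Each trace is normalized by [normalize_trace()], then the traces are
#' averaged pointwise.  All traces must come from the same protocol and
#' grid.
#'
#' @param traces list of `"nmdar_trace"` objects.
#' @return One averaged, normalized `"nmdar_trace"`
#'   (`meta$n_traces` records the count).
#' @export
normalize_and_average <- function(traces) {
  if (!length(traces)) stop("no traces supplied")
  ref <- traces[[1]]
  for (tr in traces[-1]) {
    if (!isTRUE(all.equal(tr$protocol$segments, ref$protocol$segments)) ||
        length(tr$time_s) != length(ref$time_s))
      stop("traces have inconsistent protocols or grids")
  }
  normed <- lapply(traces, normalize_trace)
  avg <- normed[[1]]
  avg$current_pA <- rowMeans(do.call(cbind, lapply(normed, `[[`, "current_pA")))
  avg$meta$n_traces <- length(traces)
  avg$meta$cell <- NULL
  avg
}

#' Write / read a trace as CSV with a JSON protocol sidecar
#'
#' The CSV holds columns `time_s`, `current_pA`; the sidecar
#' (`<path>.json`) holds the protocol segments and metadata.
#'
#' @param trace an `"nmdar_trace"`.
#' @param path CSV path; the sidecar is written next to it.
#' @return `write_trace()` returns `path` invisibly; `read_trace()`
#'   returns the reconstructed trace.
#' @export
write_trace <- function(trace, path) {
  write.csv(data.frame(time_s = trace$time_s,
                       current_pA = trace$current_pA),
            path, row.names = FALSE)
  sidecar <- paste0(path, ".json")
  meta <- trace$meta
  meta$params <- unclass(meta$params)
  jsonlite::write_json(
    list(segments = trace$protocol$segments,
         label = trace$protocol$label,
         intervals_s = trace$protocol$intervals_s,
         meta = meta),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing protocol sidecar: ", sidecar)
  d <- read.csv(path)
  if (!all(c("time_s", "current_pA") %in% names(d)))
    stop("malformed trace CSV ", path, ": need columns time_s, current_pA")
  if (is.unsorted(d$time_s, strictly = TRUE))
    stop("malformed trace CSV ", path, ": time_s must be strictly increasing")
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  prot <- protocol(side$segments, label = side$label %||% "")
  if (!is.null(side$intervals_s)) prot$intervals_s <- side$intervals_s
  meta <- side$meta
  if (!is.null(meta$params)) meta$params <- do.call(current_params, meta$params)
  structure(list(time_s = d$time_s, current_pA = d$current_pA,
                 protocol = prot, meta = meta),
            class = "nmdar_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic electrode calibration series
#'
#' Emulates the ligand-optimization-method solution design: buffer-free
#' calibration solutions with total calcium 0.5-10 mM (constraining the
#' electrode slope and intrinsic potential) and buffered solutions whose
#' free calcium spans the buffer's dissociation constant (constraining
#' the buffer total concentration, Kd, and the interference constant).
#' Relative potentials come from the Nikolsky-Eisenman response of the
#' ground-truth electrode plus Gaussian measurement noise.
#'
#' @param electrode ground-truth [electrode_model()].
#' @param buffer ground-truth [buffer_model()].
#' @param noise_mV measurement noise SD (mV).
#' @param seed integer seed.
#' @param cal_total_M buffer-free total-calcium series (M).
#' @param buf_free_M free-calcium targets of the buffered series (M).
#' @return A [calibration_series()].
#' @export
generate_electrode_series <- function(electrode, buffer, noise_mV = 0,
                                      seed = 1,
                                      cal_total_M = c(5e-4, 1e-3, 2e-3,
                                                      3e-3, 5e-3, 7.5e-3,
                                                      1e-2),
                                      buf_free_M = 10^seq(-9, -6,
                                                          length.out = 10)) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  de_cal <- potential_from_free(cal_total_M, electrode)
  buf_total <- total_from_free(buf_free_M, buffer)
  de_buf <- potential_from_free(buf_free_M, electrode)
  if (noise_mV > 0) {
    de_cal <- de_cal + rnorm(length(de_cal), 0, noise_mV)
    de_buf <- de_buf + rnorm(length(de_buf), 0, noise_mV)
  }
  calibration_series(
    calibration = data.frame(Ca_total_M = cal_total_M, delta_E_mV = de_cal),
    buffered = data.frame(Ca_total_M = buf_total, delta_E_mV = de_buf))
}

#' Build the four staged-fitting datasets from a ground-truth rate set
#'
#' Produces the averaged, normalized traces the pipeline fits: an
#' agonist step and a concentration-inhibition protocol, each at
#' calcium-free and at high (10 uM) pipette calcium.
#'
#' @param rates ground-truth [rate_set()].
#' @param ca_high_uM the high-calcium condition (uM).
#' @param n_cells cells per condition (averaged after per-trace
#'   normalization).
#' @param noise_sd_frac per-trace Gaussian noise (0 for noiseless).
#' @param seed integer seed.
#' @param dt_s simulation grid step.
#' @param blocker_concs_uM blocker series of the IC50 protocols.
#' @param app_s application duration (s).
#' @return Named list of traces: `step1` (agonist step, Ca-free),
#'   `step2` (IC50, Ca-free), `step3` (agonist step, high Ca),
#'   `step4` (IC50, high Ca).
#' @export
make_fit_datasets <- function(rates = rate_set(), ca_high_uM = 10,
                              n_cells = 1, noise_sd_frac = 0, seed = 1,
                              dt_s = 1e-3,
                              blocker_concs_uM = c(0.1, 0.3, 1, 3, 10, 50),
                              app_s = 15) {
  step_prot <- function(ca) protocol(data.frame(
    duration_s = c(2, app_s, 10), glu_uM = c(0, 1000, 0), mem_uM = 0,
    ca_i_uM = ca), label = sprintf("glu step ca_i=%g", ca))
  protos <- list(
    step1 = step_prot(0),
    step2 = make_ic50_protocol(blocker_concs_uM = blocker_concs_uM,
                               app_s = app_s, ca_i_uM = 0),
    step3 = step_prot(ca_high_uM),
    step4 = make_ic50_protocol(blocker_concs_uM = blocker_concs_uM,
                               app_s = app_s, ca_i_uM = ca_high_uM))
  out <- lapply(seq_along(protos), function(i) {
    spec <- synthetic_spec(rates = rates, prot = protos[[i]],
                           n_cells = n_cells,
                           noise_sd_frac = noise_sd_frac,
                           amplitude_sd = if (n_cells > 1) 0.3 else 0,
                           seed = seed + i, dt_s = dt_s)
    normalize_and_average(generate_traces(spec))
  })
  names(out) <- names(protos)
  out
}
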