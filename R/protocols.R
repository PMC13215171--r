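#' Stimulation protocol: piecewise-constant ligand time course
#'
#' A protocol is an ordered list of segments, each with a duration and
#' constant glutamate/memantine concentrations.  Intracellular calcium is
#' clamped by the pipette and must be identical across segments.
#'
#' @param segments data frame with columns `duration_s`, `glu_uM`,
#'   `mem_uM`, `ca_i_uM` (one row per segment).
#' @param label free-text protocol label.
#' @return An object of class `"nmdar_protocol"`.
#' @export
protocol <- function(segments, label = "") {
  segments <- as.data.frame(segments)
  need <- c("duration_s", "glu_uM", "mem_uM", "ca_i_uM")
  miss <- setdiff(need, names(segments))
  if (length(miss)) stop("missing segment column(s): ", paste(miss, collapse = ", "))
  segments <- segments[, need]
  segments[] <- lapply(segments, as.numeric)
  if (nrow(segments) == 0) stop("protocol needs at least one segment")
  if (any(segments$duration_s <= 0)) stop("segment durations must be > 0")
  if (any(segments$glu_uM < 0) || any(segments$mem_uM < 0) ||
      any(segments$ca_i_uM < 0)) stop("concentrations must be >= 0")
  if (length(unique(segments$ca_i_uM)) != 1)
    stop("ca_i_uM must be identical across segments (pipette-clamped)")
  structure(list(segments = segments, label = label),
            class = "nmdar_protocol")
}

#' @export
print.nmdar_protocol <- function(x, ...) {
  cat(sprintf("protocol '%s': %d segments, %.1f s total, ca_i = %g uM\n",
              x$label, nrow(x$segments), sum(x$segments$duration_s),
              x$segments$ca_i_uM[1]))
  invisible(x)
}

#' Concentration-inhibition (IC50) protocol
#'
#' Baseline (agonist-free), an agonist application to steady state, one
#' segment per blocker concentration applied back-to-back in the
#' continued presence of agonist, and a final agonist-only recovery
#' segment.
#'
#' @param glu_uM agonist concentration (default 1000 uM, saturating).
#' @param blocker_concs_uM strictly increasing blocker concentrations.
#' @param app_s duration of each blocker application (s); the 10-30 s
#'   range covers the steady-level-of-inhibition requirement.
#' @param ca_i_uM clamped intracellular calcium (uM).
#' @param baseline_s,recovery_s durations of the agonist-free baseline
#'   and the agonist-only segments.
#' @return An `"nmdar_protocol"`.
#' @export
make_ic50_protocol <- function(glu_uM = 1000,
                               blocker_concs_uM = c(0.1, 0.3, 1, 3, 10, 50),
                               app_s = 15, ca_i_uM = 0,
                               baseline_s = 2, recovery_s = app_s) {
  if (length(blocker_concs_uM) == 0) stop("blocker concentration list is empty")
  if (is.unsorted(blocker_concs_uM, strictly = TRUE))
    stop("blocker concentrations must be strictly increasing")
  if (app_s < 10 || app_s > 30)
    warning("app_s outside the 10-30 s range used experimentally")
  seg <- data.frame(
    duration_s = c(baseline_s, app_s, rep(app_s, length(blocker_concs_uM)),
                   recovery_s),
    glu_uM = c(0, rep(glu_uM, length(blocker_concs_uM) + 2)),
    mem_uM = c(0, 0, blocker_concs_uM, 0),
    ca_i_uM = ca_i_uM)
  protocol(seg, label = sprintf("IC50 ca_i=%g", ca_i_uM))
}

#' Recovery-from-desensitization (RfD) protocol
#'
#' A baseline, a conditioning agonist application, then one agonist-free
#' interval plus agonist application per entry of `intervals_s`.  When
#' `mem_uM > 0` the blocker is present in every segment (co-application
#' condition).  Peaks are later normalized to the application following
#' the 200-s interval, so the default interval order is decreasing.
#'
#' @param intervals_s interapplication intervals in seconds, applied in
#'   the order given (default `c(200, 100, 50, 20, 10, 5, 2, 1)`).
#' @param app_s duration of each agonist application (default 15 s).
#' @param glu_uM agonist concentration (uM).
#' @param mem_uM blocker concentration present throughout (uM).
#' @param ca_i_uM clamped intracellular calcium (uM).
#' @param baseline_s agonist-free pre-equilibration segment duration.
#' @return An `"nmdar_protocol"`.
#' @export
make_rfd_protocol <- function(intervals_s = c(200, 100, 50, 20, 10, 5, 2, 1),
                              app_s = 15, glu_uM = 1000, mem_uM = 0,
                              ca_i_uM = 0, baseline_s = 5) {
  if (length(intervals_s) == 0) stop("intervals_s must be non-empty")
  n <- length(intervals_s)
  seg <- data.frame(
    duration_s = c(baseline_s, app_s, rbind(intervals_s, rep(app_s, n))),
    glu_uM = c(0, glu_uM, rbind(rep(0, n), rep(glu_uM, n))),
    mem_uM = mem_uM,
    ca_i_uM = ca_i_uM)
  p <- protocol(seg, label = sprintf("RfD mem=%g ca_i=%g", mem_uM, ca_i_uM))
  p$intervals_s <- intervals_s
  p
}

segment_ligands <- function(prot, i) {
  s <- prot$segments[i, ]
  ligand_context(glu_uM = s$glu_uM, mem_uM = s$mem_uM, ca_i_uM = s$ca_i_uM)
}

#' Simulate a current trace for a protocol
#'
#' Propagates the scheme across the protocol's segments by piecewise
#' matrix-exponential stepping on a uniform grid.  The initial occupancy
#' is the steady state of the first segment's ligand context (receptors
#' pre-equilibrate with the pipette calcium before stimulation).
#'
#' @param scheme a [build_scheme()] object.
#' @param prot an [protocol()] object.
#' @param params a [current_params()].
#' @param dt_s grid step in seconds (default 1e-3; second-scale kinetics
#'   do not require the experimental 20-kHz rate).
#' @param keep_occupancy keep the full occupancy matrix on the trace.
#' @return An object of class `"nmdar_trace"`: list with `time_s`,
#'   `current_pA`, `protocol`, `meta`, and optionally `occupancy`.
#' @export
simulate_protocol <- function(scheme, prot, params = current_params(),
                              dt_s = 1e-3, keep_occupancy = FALSE) {
  stopifnot(inherits(scheme, "kinetic_scheme"), inherits(prot, "nmdar_protocol"))
  if (dt_s <= 0) stop("dt_s must be > 0")
  occ0 <- steady_state(scheme, segment_ligands(prot, 1))
  Qs <- lapply(seq_len(nrow(prot$segments)),
               function(i) rate_matrix(scheme, segment_ligands(prot, i)))
  nsteps <- as.integer(round(prot$segments$duration_s / dt_s))
  nsteps <- pmax(nsteps, 1L)
  sim <- cpp_simulate_segments(Qs, nsteps, dt_s, as.numeric(occ0),
                               which(scheme$states$conducting),
                               keep_occupancy)
  time_s <- seq(0, by = dt_s, length.out = length(sim$po))
  tr <- structure(list(
    time_s = time_s,
    current_pA = current(as.numeric(sim$po), params, conducting = NA),
    protocol = prot,
    meta = list(normalized = FALSE, dt_s = dt_s, params = params)),
    class = "nmdar_trace")
  if (keep_occupancy) {
    colnames(sim$occupancy) <- scheme$states$label
    tr$occupancy <- sim$occupancy
  }
  tr
}

#' @export
print.nmdar_trace <- function(x, ...) {
  cat(sprintf("trace: %d samples over %.1f s (%s, %snormalized)\n",
              length(x$time_s), max(x$time_s), x$protocol$label,
              if (isTRUE(x$meta$normalized)) "" else "not "))
  invisible(x)
}

segment_bounds <- function(trace) {
  dt <- trace$meta$dt_s
  nsteps <- pmax(as.integer(round(trace$protocol$segments$duration_s / dt)), 1L)
  ends <- 1L + cumsum(nsteps)          # sample index of each segment's end
  starts <- c(2L, utils::head(ends, -1) + 1L)
  data.frame(start = starts, end = ends)
}

segment_samples <- function(trace, segment) {
  b <- segment_bounds(trace)
  if (segment < 1 || segment > nrow(b)) stop("segment index out of range")
  seq(b$start[segment], b$end[segment])
}

#' Peak current of an application segment
#'
#' Mean current over a window (default 30 ms) centered on the extremum of
#' the segment; sign-aware, taking the most negative value for inward
#' currents.  The search is restricted to the first `search_s` seconds of
#' the segment to avoid chasing plateau noise; the averaging window is
#' truncated at segment bounds (with a `truncated` attribute set).
#'
#' @param trace an `"nmdar_trace"`.
#' @param segment segment index of the application.
#' @param window_ms averaging window width in ms.
#' @param search_s portion of the segment searched for the extremum.
#' @return Peak current in pA.
#' @export
measure_peak <- function(trace, segment, window_ms = 30, search_s = 2) {
  idx <- segment_samples(trace, segment)
  cur <- trace$current_pA
  tseg <- trace$time_s[idx] - trace$time_s[idx[1]]
  search <- idx[tseg <= search_s]
  inward <- sum(cur[search]) <= 0
  ipk <- if (inward) search[which.min(cur[search])] else search[which.max(cur[search])]
  half <- window_ms / 2000 / trace$meta$dt_s
  lo <- max(idx[1], floor(ipk - half))
  hi <- min(idx[length(idx)], ceiling(ipk + half))
  out <- mean(cur[lo:hi])
  attr(out, "truncated") <- (ipk - half) < idx[1] || (ipk + half) > idx[length(idx)]
  out
}

#' Steady-state current of a segment
#'
#' Mean current over the final `window_s` (default 1 s) of the segment,
#' with the baseline current subtracted.  The baseline is the mean over
#' the final second of the first agonist-free segment (0 if none).
#'
#' @inheritParams measure_peak
#' @param window_s averaging window (s); the segment must be at least
#'   this long.
#' @param subtract_baseline subtract the agonist-free baseline current.
#' @return Baseline-subtracted steady-state current in pA.
#' @export
measure_steady_state <- function(trace, segment, window_s = 1,
                                 subtract_baseline = TRUE) {
  if (trace$protocol$segments$duration_s[segment] < window_s)
    stop("segment shorter than the steady-state window")
  idx <- segment_samples(trace, segment)
  nwin <- max(1L, as.integer(round(window_s / trace$meta$dt_s)))
  iss <- mean(trace$current_pA[utils::tail(idx, nwin)])
  base <- 0
  if (subtract_baseline) {
    b0 <- which(trace$protocol$segments$glu_uM == 0)
    if (length(b0) && b0[1] != segment) {
      idx0 <- segment_samples(trace, b0[1])
      nw0 <- min(length(idx0), nwin)
      base <- mean(trace$current_pA[utils::tail(idx0, nw0)])
    }
  }
  iss - base
}

ic50_segment_roles <- function(prot) {
  seg <- prot$segments
  blocker <- which(seg$mem_uM > 0 & seg$glu_uM > 0)
  if (!length(blocker)) stop("trace is not from an IC50 protocol (no blocker segments)")
  pre <- max(which(seg$glu_uM > 0 & seg$mem_uM == 0 &
                     seq_len(nrow(seg)) < min(blocker)))
  post <- which(seg$glu_uM > 0 & seg$mem_uM == 0 &
                  seq_len(nrow(seg)) > max(blocker))
  if (!length(post)) stop("IC50 protocol lacks a recovery segment")
  list(pre = pre, blocker = blocker, post = post[1])
}

#' Concentration-inhibition table from an IC50-protocol trace
#'
#' For each blocker segment, `I_Blocker` is the mean steady-state current
#' over its final second; `I_Glu` is the average of the steady states of
#' the agonist application preceding the blocker series and of the
#' agonist application following recovery.  Traces whose recovery current
#' is below 85% of the pre-blocker steady state are rejected, mirroring
#' the experimental exclusion criterion.
#'
#' @param trace an `"nmdar_trace"` from [make_ic50_protocol()].
#' @param recovery_min minimum recovery fraction for acceptance.
#' @return Data frame of class `"inhibition_table"` with columns
#'   `blocker_uM` and `fraction` (= I_Blocker / I_Glu).
#' @export
inhibition_table <- function(trace, recovery_min = 0.85) {
  roles <- ic50_segment_roles(trace$protocol)
  iss_pre <- measure_steady_state(trace, roles$pre)
  iss_post <- measure_steady_state(trace, roles$post)
  if (abs(iss_post) < recovery_min * abs(iss_pre))
    stop(sprintf(
      "trace rejected: recovery %.1f%% of pre-blocker steady state (< %.0f%%)",
      100 * abs(iss_post) / abs(iss_pre), 100 * recovery_min))
  i_glu <- mean(c(iss_pre, iss_post))
  fr <- vapply(roles$blocker,
               function(s) measure_steady_state(trace, s) / i_glu, 0)
  out <- data.frame(blocker_uM = trace$protocol$segments$mem_uM[roles$blocker],
                    fraction = fr)
  class(out) <- c("inhibition_table", "data.frame")
  out
}

#' Desensitization extent I_ss / I_peak
#'
#' Ratio of steady-state to peak current of a single agonist application,
#' the operational measure of desensitization.
#'
#' @param trace an `"nmdar_trace"`.
#' @param segment application segment; default is the first segment with
#'   agonist present.
#' @return The I_ss / I_peak ratio.
#' @export
iss_over_ipeak <- function(trace, segment = NULL) {
  if (is.null(segment)) {
    segment <- which(trace$protocol$segments$glu_uM > 0)
    if (!length(segment)) stop("no agonist application in protocol")
    segment <- segment[1]
  }
  pk <- measure_peak(trace, segment)
  if (abs(pk) < .Machine$double.eps) stop("zero peak current")
  measure_steady_state(trace, segment) / as.numeric(pk)
}

#' Normalized peak series from an RfD-protocol trace
#'
#' Measures the peak of the agonist application following each
#' interapplication interval and normalizes to the peak following the
#' 200-s interval.  Traces in which any normalized peak exceeds 1.2 are
#' excluded (error), mirroring the experimental criterion.
#'
#' @param trace an `"nmdar_trace"` from [make_rfd_protocol()].
#' @param norm_interval_s interval whose peak defines full recovery.
#' @param max_norm exclusion threshold on normalized peaks.
#' @return Data frame with columns `interval_s` and `peak_norm`, sorted
#'   by interval.
#' @export
rfd_peak_series <- function(trace, norm_interval_s = 200, max_norm = 1.2) {
  prot <- trace$protocol
  if (is.null(prot$intervals_s)) stop("trace is not from an RfD protocol")
  intervals <- prot$intervals_s
  if (!norm_interval_s %in% intervals)
    stop("protocol lacks the ", norm_interval_s, "-s normalization interval")
  # applications after intervals are segments 4, 6, 8, ... (baseline,
  # conditioning app, then interval/app pairs)
  app_seg <- 2 + 2 * seq_along(intervals)
  peaks <- vapply(app_seg, function(s) as.numeric(measure_peak(trace, s)), 0)
  ref <- peaks[match(norm_interval_s, intervals)]
  norm <- peaks / ref
  if (any(norm > max_norm))
    stop("trace excluded: normalized peak exceeds ", max_norm)
  out <- data.frame(interval_s = intervals, peak_norm = norm)
  out[order(out$interval_s), , drop = FALSE]
}
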