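default_occ0 <- function(scheme) {
  occ <- numeric(nrow(scheme$states))
  occ[1] <- 1   # upper-plane, unblocked, unliganded receptor
  occ
}

check_occ <- function(occ, n) {
  if (length(occ) != n) stop("occupancy vector has wrong length")
  if (any(occ < -1e-12)) stop("occupancy entries must be >= 0")
  if (abs(sum(occ) - 1) > 1e-9) stop("occupancy must sum to 1 (within 1e-9)")
  invisible(occ)
}

#' Propagate occupancy under constant ligand concentrations
#'
#' Evolves the state occupancy on a uniform time grid by stepping with the
#' exact matrix-exponential propagator of the (constant) generator.  This
#' is unconditionally stable, which matters because the scheme is stiff:
#' calcium exchange rates are orders of magnitude faster than the
#' desensitization rates of interest.
#'
#' @param scheme a [build_scheme()] object.
#' @param ligands a [ligand_context()], constant over the interval.
#' @param occ0 initial occupancy vector (length 22, sums to 1).  Default:
#'   all receptors unliganded and Ca-free.
#' @param duration_s interval length in seconds (> 0).
#' @param dt_s grid step in seconds (default 1e-3).
#' @return A list with `time_s` (length `n`) and `occupancy`
#'   (`n` x 22 matrix, one row per time point, `conducting` attribute
#'   giving the conducting-state columns).
#' @export
propagate <- function(scheme, ligands, occ0 = default_occ0(scheme),
                      duration_s, dt_s = 1e-3) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (dt_s <= 0) stop("dt_s must be > 0")
  check_occ(occ0, nrow(scheme$states))
  Q <- rate_matrix(scheme, ligands)
  nsteps <- max(1L, as.integer(round(duration_s / dt_s)))
  occ <- cpp_propagate(Q, occ0, nsteps, dt_s)
  colnames(occ) <- scheme$states$label
  attr(occ, "conducting") <- which(scheme$states$conducting)
  list(time_s = seq(0, by = dt_s, length.out = nsteps + 1), occupancy = occ)
}

reachable_states <- function(Q, from) {
  n <- nrow(Q)
  adj <- abs(Q) > 0
  diag(adj) <- FALSE
  seen <- logical(n)
  seen[from] <- TRUE
  frontier <- from
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  which(seen)
}

#' Stationary occupancy of a generator matrix
#'
#' Low-level solver: returns the probability vector `p` with `p Q = 0`,
#' `sum(p) = 1`.  Uses the Grassmann-Taksar-Heyman state-elimination
#' algorithm, which involves no subtractions and therefore stays
#' accurate even for the stiff generators this scheme produces (rate
#' constants spanning eight orders of magnitude).  The chain restricted
#' to `Q` must be irreducible.
#'
#' @param Q a square generator matrix (rows sum to zero).
#' @return Stationary probability vector.
#' @export
#' @examples
#' # two-state open <-> closed toy: P_open = f / (f + r)
#' f <- 3; r <- 7
#' Q <- matrix(c(-f, f, r, -r), 2, 2, byrow = TRUE)
#' stationary_distribution(Q)[2]  # 0.3
stationary_distribution <- function(Q) {
  n <- nrow(Q)
  if (n == 1) return(1)
  A <- Q
  diag(A) <- 0          # work with off-diagonal rates only
  S <- numeric(n)       # elimination normalizers
  for (k in n:2) {
    below <- seq_len(k - 1)
    S[k] <- sum(A[k, below])
    if (S[k] <= 0)
      stop("chain is reducible on this component; ",
           "stationary distribution is not unique")
    for (i in below) {
      if (A[i, k] > 0) {
        w <- A[i, k] / S[k]
        A[i, below] <- A[i, below] + w * A[k, below]
      }
    }
  }
  p <- numeric(n)
  p[1] <- 1
  for (k in 2:n) {
    below <- seq_len(k - 1)
    p[k] <- sum(p[below] * A[below, k]) / S[k]
  }
  p / sum(p)
}

#' Steady-state occupancy of the scheme at fixed ligand concentrations
#'
#' Solves `p Q = 0` on the component reachable from the support of
#' `occ0`.  Restricting to the reachable component resolves the ligand
#' contexts under which parts of the graph are disconnected (e.g. at
#' `ca_i = 0` the Ca-bound plane is unreachable and carries zero weight).
#' If the reachable component itself splits into several closed classes
#' (possible only in degenerate contexts such as `glu = 0` with blocked
#' states occupied), the limit is taken by long-time propagation from
#' `occ0` instead.
#'
#' @inheritParams propagate
#' @param occ0 occupancy whose support defines the reachable component
#'   (default: the unliganded Ca-free state).
#' @param t_long fallback horizon (s) for degenerate contexts.
#' @return Occupancy vector (length 22, `conducting` attribute attached).
#' @export
steady_state <- function(scheme, ligands, occ0 = default_occ0(scheme),
                         t_long = 1e4) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  check_occ(occ0, nrow(scheme$states))
  Q <- rate_matrix(scheme, ligands)
  reach <- reachable_states(Q, which(occ0 > 0))
  p <- numeric(nrow(Q))
  res <- tryCatch(stationary_distribution(Q[reach, reach, drop = FALSE]),
                  error = function(e) e)
  if (inherits(res, "error")) {
    # several absorbing classes: the limit depends on occ0; integrate it out
    occ <- cpp_propagate(Q, occ0, 8L, t_long / 8)
    p <- occ[9, ]
  } else {
    p[reach] <- res
  }
  names(p) <- scheme$states$label
  attr(p, "conducting") <- which(scheme$states$conducting)
  p
}

#' Open probability of an occupancy vector or matrix
#'
#' Sums occupancy over the conducting (unblocked open) states.
#'
#' @param occ occupancy vector or matrix as returned by [propagate()] or
#'   [steady_state()]; the conducting indices are read from its
#'   `conducting` attribute unless supplied.
#' @param conducting integer indices of the conducting states.
#' @return Scalar or vector of open probabilities.
#' @export
open_probability <- function(occ, conducting = attr(occ, "conducting")) {
  if (is.null(conducting))
    stop("no 'conducting' attribute on occ; pass conducting indices")
  if (is.matrix(occ)) rowSums(occ[, conducting, drop = FALSE])
  else sum(occ[conducting])
}

#' Whole-cell current from state occupancy
#'
#' `I = N * P_open * gamma_pS * (Vm_mV - Vrev_mV) * 1e-3` in pA
#' (pS x mV = 1e-3 pA).  Inward current is negative for `Vm < Vrev`.
#'
#' @param occ occupancy vector/matrix (with `conducting` attribute), or a
#'   bare open probability if `conducting = NA`.
#' @param params a [current_params()].
#' @param conducting conducting-state indices; `NA` means `occ` already
#'   is an open probability.
#' @return Current in pA.
#' @export
#' @examples
#' current(1, current_params(), conducting = NA)           # -3.25 pA
#' current(0.13, current_params(N = 100), conducting = NA) # -42.25 pA
current <- function(occ, params = current_params(),
                    conducting = attr(occ, "conducting")) {
  stopifnot(inherits(params, "current_params"))
  po <- if (length(conducting) == 1 && is.na(conducting)) occ
        else open_probability(occ, conducting)
  params$N * po * params$gamma_pS * (params$Vm_mV - params$Vrev_mV) * 1e-3
}
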