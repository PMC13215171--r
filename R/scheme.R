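#' Ligand context for a recording segment
#'
#' Concentrations (uM) of glutamate, memantine, and intracellular free
#' calcium.  Intracellular calcium is clamped by the pipette solution and
#' therefore held fixed within a recording; nominally calcium-free
#' ("< 1 nM") solutions are represented as `ca_i_uM = 0`.
#'
#' @param glu_uM,mem_uM,ca_i_uM concentrations in uM, all `>= 0`.
#' @return A list of class `"ligand_context"`.
#' @export
ligand_context <- function(glu_uM = 0, mem_uM = 0, ca_i_uM = 0) {
  x <- list(glu_uM = glu_uM, mem_uM = mem_uM, ca_i_uM = ca_i_uM)
  for (v in names(x)) {
    if (!is.numeric(x[[v]]) || length(x[[v]]) != 1 || !is.finite(x[[v]]) ||
        x[[v]] < 0)
      stop(v, " must be a single finite value >= 0")
  }
  structure(x, class = "ligand_context")
}

#' Whole-cell current parameters
#'
#' Parameters of the current equation
#' `I = N * P_open * gamma * (Vm - Vrev) * 1e-3` (pA), where `P_open` is
#' the summed occupancy of the conducting states.
#'
#' @param N dimensionless amplitude scale (nominally the receptor count).
#' @param gamma_pS single-channel conductance in pS (default 50).
#' @param Vm_mV holding potential in mV (default -65).
#' @param Vrev_mV reversal potential in mV (default 0).
#' @return A list of class `"current_params"`.
#' @export
current_params <- function(N = 1, gamma_pS = 50, Vm_mV = -65, Vrev_mV = 0) {
  if (!is.finite(gamma_pS) || gamma_pS <= 0) stop("gamma_pS must be > 0")
  structure(list(N = N, gamma_pS = gamma_pS, Vm_mV = Vm_mV,
                 Vrev_mV = Vrev_mV), class = "current_params")
}

core_states <- c("R", "RA", "RA2", "RA2open", "dRA2", "cddRA2")

state_label <- function(plane, arm, core) {
  base <- switch(core,
                 R = "R", RA = "RA", RA2 = "RA2", RA2open = "RA2*",
                 dRA2 = "dRA2", cddRA2 = "cddRA2")
  if (plane == "Ca-bound") {
    base <- switch(core,
                   R = "CaR", RA = "CaRA", RA2 = "CaRA2", RA2open = "CaRA2*",
                   dRA2 = "dCaRA2", cddRA2 = "cddCaRA2")
  }
  if (arm == "blocked") base <- paste0("M", base)
  base
}

#' Build the two-plane kinetic scheme of NMDAR gating, block, and CDD
#'
#' Constructs the 22-state continuous-time Markov scheme.  States live on
#' two "planes" -- an upper plane of Ca2+-free receptors and a lower plane
#' of Ca2+-bound receptors -- each split into an unblocked (left) and a
#' memantine-blocked (right) arm.  Each arm carries the activation chain
#' `R <-> RA <-> RA2 <-> RA2*` plus a Ca-independent desensitized state
#' `dRA2`; the Ca-bound plane additionally carries the Ca2+-dependent
#' desensitized state `cddRA2`, reachable only from the fully
#' agonist-bound closed state.  Memantine binds only to open channels
#' (trapping block): the sole block/unblock edges connect `RA2*` to
#' `MRA2*` within each plane.  Every Ca-free state exchanges with its
#' Ca-bound counterpart with common rates `k_Ca_plus`/`k_Ca_minus`.
#' Conducting states are the two unblocked open states (`RA2*`,
#' `CaRA2*`).
#'
#' @param rates a [rate_set()].
#' @param statistical_factors logical; if `TRUE` (default) the two
#'   sequential, identical glutamate binding steps carry the standard
#'   statistical factors (2 k_a_plus for the first binding, 2 k_a_minus
#'   for the second unbinding).
#' @return A list of class `"kinetic_scheme"` with elements `states`
#'   (data frame: `plane`, `arm`, `core`, `label`, `conducting`), `edges`
#'   (data frame: `from`, `to`, `rate`, `ligand`, `factor`), `rates`, and
#'   `options`.
#' @export
#' @examples
#' sch <- build_scheme(rate_set())
#' nrow(sch$states)          # 22
#' sum(sch$states$conducting) # 2
build_scheme <- function(rates = rate_set(), statistical_factors = TRUE) {
  rates <- as_rate_set(rates)

  blocks <- list(
    list(plane = "Ca-free",  arm = "unblocked"),
    list(plane = "Ca-free",  arm = "blocked"),
    list(plane = "Ca-bound", arm = "unblocked"),
    list(plane = "Ca-bound", arm = "blocked"))

  states <- do.call(rbind, lapply(blocks, function(b) {
    cores <- if (b$plane == "Ca-bound") core_states else core_states[1:5]
    data.frame(plane = b$plane, arm = b$arm, core = cores,
               label = vapply(cores, state_label, "",
                              plane = b$plane, arm = b$arm),
               stringsAsFactors = FALSE)
  }))
  states$conducting <- states$core == "RA2open" & states$arm == "unblocked"
  rownames(states) <- NULL

  idx <- function(plane, arm, core) {
    which(states$plane == plane & states$arm == arm & states$core == core)
  }

  f1 <- if (statistical_factors) 2 else 1   # first binding / second unbinding
  e <- list()
  add <- function(from, to, rate, ligand = "none", factor = 1) {
    e[[length(e) + 1L]] <<- data.frame(from = from, to = to, rate = rate,
                                       ligand = ligand, factor = factor,
                                       stringsAsFactors = FALSE)
  }

  for (b in blocks) {
    p <- b$plane; a <- b$arm
    M <- a == "blocked"
    ka_p <- if (M) "k_aM_plus" else "k_a_plus"
    ka_m <- if (M) "k_aM_minus" else "k_a_minus"
    kg_p <- if (M) "k_gM_plus" else "k_g_plus"
    kg_m <- if (M) "k_gM_minus" else "k_g_minus"
    kd_p <- if (M) "k_dM_plus" else "k_d_plus"
    kd_m <- if (M) "k_dM_minus" else "k_d_minus"

    add(idx(p, a, "R"),   idx(p, a, "RA"),  ka_p, "glu", f1)
    add(idx(p, a, "RA"),  idx(p, a, "R"),   ka_m)
    add(idx(p, a, "RA"),  idx(p, a, "RA2"), ka_p, "glu", 1)
    add(idx(p, a, "RA2"), idx(p, a, "RA"),  ka_m, "none", f1)
    add(idx(p, a, "RA2"), idx(p, a, "RA2open"), kg_p)
    add(idx(p, a, "RA2open"), idx(p, a, "RA2"), kg_m)
    add(idx(p, a, "RA2"), idx(p, a, "dRA2"), kd_p)
    add(idx(p, a, "dRA2"), idx(p, a, "RA2"), kd_m)
    if (p == "Ca-bound") {
      kc_p <- if (M) "k_cddM_plus" else "k_cdd_plus"
      kc_m <- if (M) "k_cddM_minus" else "k_cdd_minus"
      add(idx(p, a, "RA2"), idx(p, a, "cddRA2"), kc_p)
      add(idx(p, a, "cddRA2"), idx(p, a, "RA2"), kc_m)
    }
  }

  # trapping block: memantine binds/unbinds only via the open states
  for (p in c("Ca-free", "Ca-bound")) {
    add(idx(p, "unblocked", "RA2open"), idx(p, "blocked", "RA2open"),
        "k_M_plus", "mem", 1)
    add(idx(p, "blocked", "RA2open"), idx(p, "unblocked", "RA2open"),
        "k_M_minus")
  }

  # calcium binding squares: every Ca-free state pairs with its Ca-bound twin
  for (a in c("unblocked", "blocked")) {
    for (core in core_states[1:5]) {
      add(idx("Ca-free", a, core), idx("Ca-bound", a, core),
          "k_Ca_plus", "ca_i", 1)
      add(idx("Ca-bound", a, core), idx("Ca-free", a, core), "k_Ca_minus")
    }
  }

  edges <- do.call(rbind, e)
  structure(list(states = states, edges = edges, rates = rates,
                 options = list(statistical_factors = statistical_factors)),
            class = "kinetic_scheme")
}

#' Replace the rate constants of a scheme
#'
#' The topology is unchanged; only the rate lookup table is swapped.
#'
#' @param scheme a [build_scheme()] object.
#' @param rates a [rate_set()] or named overrides applied to the scheme's
#'   current rates.
#' @return The updated scheme.
#' @export
set_rates <- function(scheme, rates) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (inherits(rates, "rate_set")) {
    scheme$rates <- rates
  } else {
    r <- unclass(scheme$rates)
    rates <- unlist(rates)
    bad <- setdiff(names(rates), names(r))
    if (length(bad)) stop("unknown rate constant(s): ", paste(bad, collapse = ", "))
    r[names(rates)] <- rates
    scheme$rates <- as_rate_set(r)
  }
  scheme
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat(sprintf("kinetic scheme: %d states (%d conducting), %d directed edges\n",
              nrow(x$states), sum(x$states$conducting), nrow(x$edges)))
  invisible(x)
}

#' Generator (Q) matrix of a scheme at a given ligand context
#'
#' Off-diagonal entry (i, j) is the transition rate i -> j: rate constant
#' times ligand concentration (for bimolecular edges) times the
#' statistical factor.  Diagonal entries are minus the row sums, so every
#' row sums to zero.  Occupancy evolves by the row-vector convention
#' `dp/dt = p Q`.
#'
#' @param scheme a [build_scheme()] object.
#' @param ligands a [ligand_context()].
#' @return A 22 x 22 numeric matrix (s^-1), with state labels as dimnames.
#' @export
rate_matrix <- function(scheme, ligands) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (!inherits(ligands, "ligand_context")) ligands <- do.call(ligand_context, ligands)
  n <- nrow(scheme$states)
  r <- unclass(scheme$rates)
  ed <- scheme$edges
  bad <- setdiff(unique(ed$rate), names(r))
  if (length(bad)) stop("unknown rate constant name(s): ", paste(bad, collapse = ", "))
  conc <- c(none = 1, glu = ligands$glu_uM, mem = ligands$mem_uM,
            ca_i = ligands$ca_i_uM)
  val <- unname(r[ed$rate]) * conc[ed$ligand] * ed$factor
  Q <- matrix(0, n, n, dimnames = list(scheme$states$label, scheme$states$label))
  Q[cbind(ed$from, ed$to)] <- val
  diag(Q) <- -rowSums(Q)
  diag(Q) <- diag(Q) - rowSums(Q)   # second pass trims summation residue
  Q
}
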