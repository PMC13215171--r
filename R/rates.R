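#' Rate constants of the two-plane NMDAR block model
#'
#' Constructs the named vector of rate constants that parameterizes the
#' two-plane kinetic scheme built by [build_scheme()].  Units are s^-1 for
#' unimolecular transitions and uM^-1 s^-1 for ligand-binding transitions
#' (`k_Ca_plus`, `k_M_plus`, `k_a_plus`, `k_aM_plus`).
#'
#' Defaults are the GluN1/2A estimates obtained at -65 mV with saturating
#' (1 mM) glutamate: agonist binding/unbinding and gating rates from
#' published activation schemes, calcium association rates set arbitrarily
#' fast with `k_Ca_minus / k_Ca_plus` equal to the 82 nM intracellular
#' Ca2+ dissociation constant, and desensitization/block rates from the
#' staged fitting pipeline ([fit_pipeline()]).  `k_dM_minus` is tied to
#' `k_d_minus` by convention (see [fit_pipeline()]).
#'
#' @param ... named rate overrides, e.g. `rate_set(k_M_minus = 100)`.
#' @return A named numeric vector of class `"rate_set"` with 20 entries.
#' @export
#' @examples
#' r <- rate_set()
#' r[["k_Ca_minus"]] / r[["k_Ca_plus"]]  # 0.082 uM = 82 nM
rate_set <- function(...) {
  defaults <- c(
    k_Ca_plus   = 1e6,    # uM^-1 s^-1, arbitrarily fast
    k_Ca_minus  = 8.2e4,  # s^-1; ratio to k_Ca_plus fixed at 0.082 uM
    k_M_plus    = 30,     # uM^-1 s^-1, memantine binding to the open channel
    k_M_minus   = 143,    # s^-1
    k_a_plus    = 5,      # uM^-1 s^-1, glutamate binding (per site)
    k_a_minus   = 25,     # s^-1
    k_aM_plus   = 5,
    k_aM_minus  = 25,
    k_g_plus    = 71,     # s^-1, channel opening
    k_g_minus   = 305,
    k_gM_plus   = 71,
    k_gM_minus  = 305,
    k_d_plus    = 0.135,  # s^-1, Ca-independent desensitization
    k_d_minus   = 0.243,
    k_dM_plus   = 0.520,  # entry is faster with memantine bound
    k_dM_minus  = 0.243,  # tied to k_d_minus
    k_cdd_plus  = 0.737,  # s^-1, Ca-dependent desensitization
    k_cdd_minus = 0.692,
    k_cddM_plus = 1.75,
    k_cddM_minus = 0.304
  )
  over <- c(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("rate overrides must be named")
    bad <- setdiff(names(over), names(defaults))
    if (length(bad)) stop("unknown rate constant(s): ", paste(bad, collapse = ", "))
    defaults[names(over)] <- over
  }
  validate_rate_set(defaults)
  structure(defaults, class = "rate_set")
}

validate_rate_set <- function(r) {
  stopifnot(is.numeric(r), length(r) == 20)
  if (any(!is.finite(r)) || any(r < 0))
    stop("all rate constants must be finite and >= 0")
  invisible(r)
}

#' Coerce a named vector or list to a rate set
#'
#' Unnamed rates fall back to the defaults of [rate_set()].
#'
#' @param x named numeric vector or list of rate constants.
#' @return A `"rate_set"` vector.
#' @export
as_rate_set <- function(x) {
  if (inherits(x, "rate_set")) return(x)
  x <- unlist(x)
  do.call(rate_set, as.list(x))
}

#' @export
print.rate_set <- function(x, ...) {
  cat("NMDAR block model rate constants (uM, s units):\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Read / write model configuration as JSON
#'
#' The serialized form is `{"rates": {name: value}, "options":
#' {"statistical_factors": true/false}}` with fixed units (uM, s, pS, mV).
#'
#' @param path file path.
#' @param rates a [rate_set()].
#' @param statistical_factors logical; stored alongside the rates and used
#'   by [build_scheme()].
#' @return `read_rates()` returns a list with elements `rates` (a
#'   `rate_set`) and `statistical_factors`; `write_rates()` returns `path`
#'   invisibly.
#' @export
write_rates <- function(rates, path, statistical_factors = TRUE) {
  obj <- list(rates = as.list(unclass(as_rate_set(rates))),
              options = list(statistical_factors = statistical_factors))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rates
#' @export
read_rates <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$rates)) stop("no 'rates' entry in ", path)
  list(rates = as_rate_set(obj$rates),
       statistical_factors = isTRUE(obj$options$statistical_factors))
}
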