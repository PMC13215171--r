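# Shared fixtures, built in code at load time.

default_scheme <- build_scheme(rate_set())

glu_step_protocol <- function(ca_i_uM = 0, app_s = 15) {
  protocol(data.frame(duration_s = c(2, app_s, 10),
                      glu_uM = c(0, 1000, 0), mem_uM = 0,
                      ca_i_uM = ca_i_uM),
           label = sprintf("glu step ca_i=%g", ca_i_uM))
}

# random rate sets within a multiplicative band of the defaults
random_rate_set <- function(band = 3) {
  r <- unclass(rate_set())
  jit <- exp(stats::runif(length(r), -log(band), log(band)))
  jit[names(r) %in% c("k_Ca_plus", "k_Ca_minus")] <- 1  # keep Ca exchange fast
  r <- r * jit
  r["k_dM_minus"] <- r["k_d_minus"]
  as_rate_set(r)
}

random_ligands <- function() {
  ligand_context(glu_uM = stats::runif(1, 100, 2000),
                 mem_uM = stats::runif(1, 0, 10),
                 ca_i_uM = stats::runif(1, 0, 20))
}

steady_block_fraction <- function(scheme, mem_uM, ca_i_uM, glu_uM = 1000) {
  ctl <- open_probability(steady_state(scheme, ligand_context(glu_uM, 0, ca_i_uM)))
  blk <- open_probability(steady_state(scheme, ligand_context(glu_uM, mem_uM, ca_i_uM)))
  blk / ctl
}

# steady-state concentration-inhibition curve + Hill fit, no time course
steady_ic50 <- function(scheme, ca_i_uM,
                        concs = c(0.1, 0.3, 1, 3, 10, 50)) {
  fr <- vapply(concs, function(m) steady_block_fraction(scheme, m, ca_i_uM), 0)
  fit_hill(data.frame(blocker_uM = concs, fraction = fr))$ic50_uM
}
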