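test_that("IC50 protocol construction follows the baseline/agonist/blockers/recovery layout", {
  p <- make_ic50_protocol(blocker_concs_uM = c(0.1, 0.3, 1, 3, 10, 50),
                          app_s = 15, ca_i_uM = 0)
  expect_equal(nrow(p$segments), 9)
  expect_equal(p$segments$glu_uM, c(0, rep(1000, 8)))
  expect_equal(p$segments$mem_uM, c(0, 0, 0.1, 0.3, 1, 3, 10, 50, 0))
  expect_error(make_ic50_protocol(blocker_concs_uM = numeric(0)), "empty")
  expect_error(make_ic50_protocol(blocker_concs_uM = c(3, 1)),
               "strictly increasing")
  expect_equal(nrow(make_ic50_protocol(blocker_concs_uM = 1)$segments), 4)
})

test_that("RfD protocol alternates applications and intervals with blocker throughout", {
  p <- make_rfd_protocol()
  # baseline + conditioning app + 8 (interval, application) pairs
  expect_equal(nrow(p$segments), 2 + 2 * 8)
  expect_equal(sum(p$segments$glu_uM > 0), 9)  # conditioning + 8 test apps
  expect_setequal(p$intervals_s, c(1, 2, 5, 10, 20, 50, 100, 200))
  p1 <- make_rfd_protocol(intervals_s = 200)
  expect_equal(sum(p1$segments$glu_uM > 0), 2)
  pm <- make_rfd_protocol(mem_uM = 3)
  expect_true(all(pm$segments$mem_uM == 3))
  expect_error(make_rfd_protocol(intervals_s = numeric(0)), "non-empty")
})

test_that("protocol segments round-trip bit-exactly through the JSON sidecar", {
  sch <- default_scheme
  tr <- simulate_protocol(sch, make_ic50_protocol(blocker_concs_uM = c(1, 3),
                                                  app_s = 12),
                          current_params(N = 50))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_identical(back$protocol$segments, tr$protocol$segments)
  expect_equal(back$time_s, tr$time_s)
  expect_equal(back$current_pA, tr$current_pA)
})

test_that("trace IO rejects malformed inputs with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = c(0, 1e-3, 2e-3),
                       current_pA = c(0, -1, -2)), path, row.names = FALSE)
  expect_error(read_trace(path), "sidecar")
  tr <- simulate_protocol(default_scheme, glu_step_protocol(),
                          current_params())
  write_trace(tr, path)
  d <- read.csv(path)
  d$time_s[2] <- d$time_s[1]          # break monotonicity
  write.csv(d, path, row.names = FALSE)
  expect_error(read_trace(path), "strictly increasing")
})

test_that("simulated agonist step shows fast rise then sag to a plateau", {
  tr <- simulate_protocol(default_scheme, glu_step_protocol(),
                          current_params(N = 100))
  ipk <- measure_peak(tr, 2)
  iss <- measure_steady_state(tr, 2)
  expect_lt(ipk, 0)                        # inward
  expect_lt(abs(iss), abs(ipk))            # desensitizing
  r <- iss_over_ipeak(tr, 2)
  expect_gt(r, 0.4); expect_lt(r, 1)
  # all-zero-glutamate protocol gives identically zero current
  p0 <- protocol(data.frame(duration_s = c(1, 1), glu_uM = 0, mem_uM = 0,
                            ca_i_uM = 0))
  expect_equal(max(abs(simulate_protocol(default_scheme, p0,
                                         current_params())$current_pA)), 0)
})

test_that("peak and steady-state measures behave on constructed traces", {
  tr <- simulate_protocol(default_scheme, glu_step_protocol(),
                          current_params())
  pflat <- protocol(data.frame(duration_s = 2, glu_uM = 1000, mem_uM = 0,
                               ca_i_uM = 0))
  flat <- structure(list(time_s = seq(0, 2, by = 1e-3),
                         current_pA = rep(-10, 2001), protocol = pflat,
                         meta = list(dt_s = 1e-3, normalized = FALSE)),
                    class = "nmdar_trace")
  expect_equal(as.numeric(measure_peak(flat, 1)), -10)
  expect_equal(iss_over_ipeak(flat, 1), 1)
  # baseline subtraction: shift the whole trace by -5 pA
  shifted <- tr
  shifted$current_pA <- tr$current_pA - 5
  expect_equal(measure_steady_state(shifted, 2),
               measure_steady_state(tr, 2), tolerance = 1e-10)
  # a triangular peak is attenuated by window averaging
  tri <- tr
  idx <- blockstate:::segment_samples(tri, 2)
  apex <- idx[100]
  tri$current_pA[] <- 0
  tri$current_pA[idx] <- -pmax(0, 1 - abs(idx - apex) * 0.01)
  expect_lt(abs(measure_peak(tri, 2)), 1)
  expect_gt(abs(measure_peak(tri, 2)), 0.8)
  expect_error(measure_steady_state(tr, 1, window_s = 5), "shorter")
})

test_that("window-averaged peak of a noisy flat trace has the predicted precision", {
  # mean over a 30-ms window at 20 kHz averages 600 samples: sd/sqrt(600)
  set.seed(5)
  p <- protocol(data.frame(duration_s = 1, glu_uM = 1000, mem_uM = 0,
                           ca_i_uM = 0))
  ests <- replicate(200, {
    tr <- structure(list(time_s = seq(0, 1, by = 5e-5),
                         current_pA = -10 + rnorm(20001, 0, 1),
                         protocol = p,
                         meta = list(dt_s = 5e-5, normalized = FALSE)),
                    class = "nmdar_trace")
    # search window = full segment; extremum chasing biases the mean, so
    # measure at a fixed apex by making one sample clearly extreme
    tr$current_pA[10000] <- tr$current_pA[10000] - 6
    as.numeric(measure_peak(tr, 1, window_ms = 30, search_s = 1))
  })
  expect_lt(sd(ests), 3 * 1 / sqrt(600))
})

test_that("inhibition tables accept recovering traces and reject poor recovery", {
  tr <- simulate_protocol(default_scheme,
                          make_ic50_protocol(ca_i_uM = 0),
                          current_params(N = 100))
  it <- inhibition_table(tr)
  expect_true(all(it$fraction > 0 & it$fraction < 1))
  expect_true(all(diff(it$fraction) < 0))   # more blocker, less current
  expect_equal(it$blocker_uM, c(0.1, 0.3, 1, 3, 10, 50))

  # scale the recovery segment to 80% -> excluded
  bad <- tr
  roles <- blockstate:::ic50_segment_roles(bad$protocol)
  idx <- blockstate:::segment_samples(bad, roles$post)
  bad$current_pA[idx] <- 0.8 * bad$current_pA[idx]
  expect_error(inhibition_table(bad), "recovery")
})

test_that("IC50-protocol steady states approach the per-segment equilibrium for long applications", {
  expect_warning(
    p <- make_ic50_protocol(blocker_concs_uM = c(1, 10), app_s = 200,
                            ca_i_uM = 0, baseline_s = 2),
    "app_s")
  tr <- simulate_protocol(default_scheme, p, current_params(N = 1),
                          dt_s = 5e-3)
  for (seg in 3:4) {
    lig <- blockstate:::segment_ligands(p, seg)
    po <- open_probability(steady_state(default_scheme, lig))
    expect_equal(measure_steady_state(tr, seg),
                 current(po, current_params(N = 1), conducting = NA),
                 tolerance = 1e-4)
  }
})

test_that("higher pipette calcium deepens fractional block and desensitization", {
  tr0 <- simulate_protocol(default_scheme, make_ic50_protocol(ca_i_uM = 0),
                           current_params(N = 100))
  tr10 <- simulate_protocol(default_scheme, make_ic50_protocol(ca_i_uM = 10),
                            current_params(N = 100))
  it0 <- inhibition_table(tr0); it10 <- inhibition_table(tr10)
  expect_true(all(it10$fraction < it0$fraction))
  s0 <- simulate_protocol(default_scheme, glu_step_protocol(0),
                          current_params(N = 100))
  s10 <- simulate_protocol(default_scheme, glu_step_protocol(10),
                           current_params(N = 100))
  expect_lt(iss_over_ipeak(s10, 2), iss_over_ipeak(s0, 2))
})

test_that("RfD peak series is self-normalized, monotone, and applies the 1.2 exclusion", {
  tr <- simulate_protocol(default_scheme, make_rfd_protocol(ca_i_uM = 0),
                          current_params(N = 100))
  rs <- rfd_peak_series(tr)
  expect_equal(rs$peak_norm[rs$interval_s == 200], 1)
  expect_true(all(diff(rs$peak_norm) >= -1e-6))  # non-decreasing with interval
  bad <- tr
  idx <- blockstate:::segment_samples(bad, nrow(bad$protocol$segments))
  bad$current_pA[idx] <- 2 * bad$current_pA[idx]
  expect_error(rfd_peak_series(bad), "exceeds 1.2")
})

test_that("a non-desensitizing scheme keeps I_ss/I_peak at 1", {
  sch <- build_scheme(rate_set(k_d_plus = 0, k_dM_plus = 0,
                               k_cdd_plus = 0, k_cddM_plus = 0))
  tr <- simulate_protocol(sch, glu_step_protocol(10), current_params(N = 10))
  expect_equal(iss_over_ipeak(tr, 2), 1, tolerance = 1e-3)
})
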