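test_that("scheme has 22 states, 2 conducting, and the trapping topology", {
  sch <- default_scheme
  expect_equal(nrow(sch$states), 22)
  expect_equal(sum(sch$states$conducting), 2)
  expect_setequal(sch$states$label[sch$states$conducting],
                  c("RA2*", "CaRA2*"))
  # 5 + 5 upper states, 6 + 6 lower states
  expect_equal(as.vector(table(sch$states$plane)[c("Ca-free", "Ca-bound")]),
               c(10, 12))
  # cddRA2 cores exist only in the Ca-bound plane
  expect_true(all(sch$states$plane[sch$states$core == "cddRA2"] == "Ca-bound"))

  # memantine binding only from conducting states to their blocked twins
  mem_edges <- sch$edges[sch$edges$ligand == "mem", ]
  expect_true(all(sch$states$conducting[mem_edges$from]))
  expect_true(all(sch$states$core[mem_edges$to] == "RA2open" &
                    sch$states$arm[mem_edges$to] == "blocked"))
  # no block/unblock edge touches a desensitized state
  d_idx <- which(sch$states$core %in% c("dRA2", "cddRA2"))
  cross <- sch$states$arm[sch$edges$from] != sch$states$arm[sch$edges$to]
  expect_false(any(cross & (sch$edges$from %in% d_idx |
                              sch$edges$to %in% d_idx)))

  # every Ca-free state has exactly one Ca-binding edge, sharing rates
  ca_edges <- sch$edges[sch$edges$ligand == "ca_i", ]
  expect_equal(sort(ca_edges$from), which(sch$states$plane == "Ca-free"))
  expect_true(all(ca_edges$rate == "k_Ca_plus"))

  # cddRA2 connects only to RA2 of the same plane/arm
  for (i in which(sch$states$core == "cddRA2")) {
    nb <- c(sch$edges$to[sch$edges$from == i], sch$edges$from[sch$edges$to == i])
    expect_true(all(sch$states$core[unique(nb)] == "RA2"))
    expect_true(all(sch$states$arm[unique(nb)] == sch$states$arm[i]))
  }
})

test_that("plane-crossing squares satisfy detailed balance when in-plane rates are plane-symmetric", {
  # oracle: enumerate all 4-cycles through Ca edges and compare the
  # clockwise/counterclockwise rate products
  sch <- default_scheme
  lig <- ligand_context(500, 2, 7)
  Q <- rate_matrix(sch, lig)
  ca_edges <- sch$edges[sch$edges$ligand == "ca_i", ]
  n_squares <- 0
  for (i in seq_len(nrow(ca_edges))) {
    for (j in seq_len(nrow(ca_edges))) {
      if (i == j) next
      a <- ca_edges$from[i]; b <- ca_edges$to[i]   # upper a -> lower b
      c_ <- ca_edges$from[j]; d <- ca_edges$to[j]  # upper c -> lower d
      if (Q[a, c_] > 0 && Q[b, d] > 0) {           # horizontal edges exist
        n_squares <- n_squares + 1
        cw <- Q[a, c_] * Q[c_, d] * Q[d, b] * Q[b, a]
        ccw <- Q[a, b] * Q[b, d] * Q[d, c_] * Q[c_, a]
        expect_equal(cw, ccw, tolerance = 1e-12)
      }
    }
  }
  expect_gt(n_squares, 0)
})

test_that("generator rows sum to zero and closed ligand contexts stay closed", {
  set.seed(11)
  for (k in 1:10) {
    Q <- rate_matrix(default_scheme, random_ligands())
    expect_lt(max(abs(rowSums(Q))) / max(abs(Q)), 1e-14)
  }
  # mem = 0: no entry into blocked arms
  Q0 <- rate_matrix(default_scheme, ligand_context(1000, 0, 10))
  blocked <- which(default_scheme$states$arm == "blocked")
  unblocked <- setdiff(seq_len(22), blocked)
  expect_true(all(Q0[unblocked, blocked] == 0))
  # ca = 0: no entry into the Ca-bound plane
  Qc <- rate_matrix(default_scheme, ligand_context(1000, 5, 0))
  lower <- which(default_scheme$states$plane == "Ca-bound")
  upper <- setdiff(seq_len(22), lower)
  expect_true(all(Qc[upper, lower] == 0))
})

test_that("propagation conserves occupancy and fixes steady states", {
  lig <- ligand_context(1000, 1, 10)
  pr <- propagate(default_scheme, lig, duration_s = 5, dt_s = 1e-3)
  expect_gte(min(rowSums(pr$occupancy)), 1 - 1e-9)
  expect_lte(max(rowSums(pr$occupancy)), 1 + 1e-9)
  expect_true(all(pr$occupancy > -1e-12))

  ss <- steady_state(default_scheme, lig)
  pr2 <- propagate(default_scheme, lig, occ0 = as.numeric(ss),
                   duration_s = 1, dt_s = 1e-2)
  expect_lt(max(abs(sweep(pr2$occupancy, 2, ss))), 1e-8)
})

test_that("matrix-exponential stepping matches a fine-tolerance ODE oracle", {
  skip_if_not_installed("deSolve")
  lig <- ligand_context(1000, 1, 0.1)
  Q <- rate_matrix(default_scheme, lig)
  occ0 <- c(1, rep(0, 21))
  pr <- propagate(default_scheme, lig, occ0, duration_s = 2, dt_s = 1e-3)
  sol <- deSolve::lsoda(occ0, times = pr$time_s,
                        func = function(t, y, p) list(as.numeric(y %*% Q)),
                        rtol = 1e-11, atol = 1e-12)
  expect_lt(max(abs(sol[, -1] - pr$occupancy)), 1e-6)
})

test_that("steady_state agrees with long-time propagation across random models", {
  set.seed(21)
  for (k in 1:20) {
    sch <- build_scheme(random_rate_set())
    lig <- random_ligands()
    ss <- steady_state(sch, lig)
    pr <- propagate(sch, lig, duration_s = 400, dt_s = 2)
    expect_lt(max(abs(pr$occupancy[nrow(pr$occupancy), ] - ss)), 1e-6)
  }
})

test_that("two-state stationary solve gives the closed form f/(f+r)", {
  f <- 3; r <- 7
  Q <- matrix(c(-f, f, r, -r), 2, 2, byrow = TRUE)
  expect_equal(stationary_distribution(Q), c(r, f) / (f + r))
})

test_that("occupancy stays confined to reachable planes/arms", {
  # ca_i = 0: lower plane never populated
  pr <- propagate(default_scheme, ligand_context(1000, 5, 0),
                  duration_s = 5, dt_s = 1e-2)
  lower <- which(default_scheme$states$plane == "Ca-bound")
  expect_equal(max(abs(pr$occupancy[, lower])), 0)
  # mem = 0 with unblocked start: blocked arm never populated
  pr2 <- propagate(default_scheme, ligand_context(1000, 0, 10),
                   duration_s = 5, dt_s = 1e-2)
  blocked <- which(default_scheme$states$arm == "blocked")
  expect_equal(max(abs(pr2$occupancy[, blocked])), 0)
})

test_that("high intracellular calcium lowers steady-state open probability", {
  po0 <- open_probability(steady_state(default_scheme,
                                       ligand_context(1000, 0, 0)))
  po10 <- open_probability(steady_state(default_scheme,
                                        ligand_context(1000, 0, 10)))
  expect_lt(po10, po0)
})

test_that("current follows I = N * P_open * gamma * (Vm - Vrev) * 1e-3", {
  expect_equal(current(1, current_params(), conducting = NA), -3.25)
  expect_equal(current(0, current_params(), conducting = NA), 0)
  expect_equal(current(0.13, current_params(N = 100), conducting = NA),
               -42.25)
  ss <- steady_state(default_scheme, ligand_context(1000, 0, 0))
  expect_equal(current(ss, current_params(N = 2)),
               2 * open_probability(ss) * 50 * (-65) * 1e-3)
})

test_that("rate-set construction validates and round-trips as JSON", {
  r <- rate_set()
  expect_equal(r[["k_Ca_minus"]] / r[["k_Ca_plus"]], 0.082)
  expect_equal(r[["k_dM_minus"]], r[["k_d_minus"]])
  expect_error(rate_set(k_M_minus = -1), "must be finite and >= 0")
  expect_error(rate_set(bogus = 1), "unknown rate constant")
  path <- withr::local_tempfile(fileext = ".json")
  write_rates(rate_set(k_M_minus = 99.5), path, statistical_factors = FALSE)
  back <- read_rates(path)
  expect_equal(unclass(back$rates), unclass(rate_set(k_M_minus = 99.5)))
  expect_false(back$statistical_factors)
})

test_that("statistical factors double the first binding and second unbinding only", {
  sch2 <- build_scheme(rate_set(), statistical_factors = TRUE)
  sch1 <- build_scheme(rate_set(), statistical_factors = FALSE)
  Q2 <- rate_matrix(sch2, ligand_context(100, 0, 0))
  Q1 <- rate_matrix(sch1, ligand_context(100, 0, 0))
  expect_equal(Q2["R", "RA"], 2 * Q1["R", "RA"])
  expect_equal(Q2["RA", "RA2"], Q1["RA", "RA2"])
  expect_equal(Q2["RA2", "RA"], 2 * Q1["RA2", "RA"])
  expect_equal(Q2["RA", "R"], Q1["RA", "R"])
})
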