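test_that("zero-flux system stays constant", {
  p <- rate_params(0, 0, 0, 0, 0)
  tr <- simulate_full(p, compartment_state(10, 5, 0), c(0, 7, 100, 2000))
  expect_equal(tr$r_s, rep(10, 4))
  expect_equal(tr$r_i, rep(5, 4))
  expect_equal(tr$r_f, rep(0, 4))
  expect_equal(tr$r_t, rep(15, 4))
})

test_that("fixed point stays fixed and the shed pool grows linearly", {
  p <- rate_params(100, 0.01, 0.01, 0.01, 0.001)
  ss <- steady_state(p)
  expect_equal(ss$r_s, 16666.6667, tolerance = 1e-6)
  expect_equal(ss$r_i, 8333.3333, tolerance = 1e-6)
  tr <- simulate_full(p, compartment_state(ss$r_s, ss$r_i, 0), c(0, 10, 1440))
  expect_equal(tr$r_s, rep(ss$r_s, 3), tolerance = 1e-9)
  expect_equal(tr$r_i, rep(ss$r_i, 3), tolerance = 1e-9)
  ## dr_f/dt = k_shed * r_s* = 16.667/min
  expect_equal(tr$r_f, 0.001 * ss$r_s * c(0, 10, 1440), tolerance = 1e-9)
})

test_that("steady state matches the two-step series when recycling and shedding vanish", {
  p <- rate_params(50, 0.02, 0.005, 0, 0)
  ss <- steady_state(p)
  expect_equal(ss$r_s, 50 / 0.005)
  expect_equal(ss$r_i, 50 / 0.02)
})

test_that("steady state is rejected when nothing drains the cell", {
  expect_error(steady_state(rate_params(10, 0, 0.01, 0.02, 0)),
               "no steady state")
  expect_error(steady_state(rate_params(0, 0.01, 0.01, 0.01, 0.001)),
               "p_syn > 0")
})

test_that("closed form matches an independent integrator on random systems", {
  set.seed(41)
  for (i in 1:25) {
    p <- random_params(); x0 <- random_state()
    times <- sort(runif(6, 1, 500))
    tr <- simulate_full(p, x0, times)
    or <- oracle_traj(p, x0, times)
    expect_equal(tr$r_s, or$r_s, tolerance = 1e-6)
    expect_equal(tr$r_i, or$r_i, tolerance = 1e-6)
    expect_equal(tr$r_t, or$r_t, tolerance = 1e-6)
  }
})

test_that("simulation converges to the analytic steady state", {
  set.seed(42)
  for (i in 1:5) {
    p <- random_params()
    ss <- tryCatch(steady_state(p), error = function(e) NULL)
    if (is.null(ss)) next
    tr <- simulate_full(p, compartment_state(1, 1, 0), c(1e6))
    expect_equal(tr$r_s, ss$r_s, tolerance = 1e-6)
    expect_equal(tr$r_i, ss$r_i, tolerance = 1e-6)
  }
})

test_that("pulse chase ignores synthesis and decays monotonically", {
  p <- rate_params(500, 0.01, 0.02, 0.01, 0.001)
  tr <- simulate_pulse_chase(p, compartment_state(1, 0, 0), c(5, 20, 45, 75, 90))
  expect_true(all(diff(tr$r_t) <= 1e-12))
  expect_true(all(tr$r_s >= 0 & tr$r_i >= 0 & tr$r_f >= 0))
  ## no-flux labeled pool is conserved
  tr0 <- simulate_pulse_chase(rate_params(0, 0, 0, 0, 0),
                              compartment_state(1, 0, 0), c(1, 10, 100))
  expect_equal(tr0$r_t, rep(1, 3))
  expect_equal(tr0$r_i, rep(0, 3))
})

test_that("pure endocytosis gives the scalar exponential solution", {
  p <- rate_params(0, 0, 0.05, 0, 0)
  tr <- simulate_pulse_chase(p, compartment_state(1, 0, 0), 20)
  expect_equal(tr$r_i, 1 - exp(-1), tolerance = 1e-9)
  expect_equal(tr$r_t, 1, tolerance = 1e-12)
})

test_that("pulse-chase trajectories are linear in the initial label", {
  set.seed(43)
  p <- random_params()
  x1 <- compartment_state(0.8, 0.2, 0)
  x2 <- compartment_state(1.6, 0.4, 0)
  t1 <- simulate_pulse_chase(p, x1, c(5, 50, 90))
  t2 <- simulate_pulse_chase(p, x2, c(5, 50, 90))
  expect_equal(2 * t1$r_s, t2$r_s, tolerance = 1e-10)
  expect_equal(2 * t1$r_i, t2$r_i, tolerance = 1e-10)
  expect_equal(2 * t1$r_f, t2$r_f, tolerance = 1e-10)
})

test_that("mass balance holds along random trajectories", {
  ## d(r_t + r_f)/dt = P_syn - k_deg * r_i, checked by central differences
  set.seed(44)
  h <- 1e-3
  for (i in 1:20) {
    p <- random_params(); x0 <- random_state()
    tq <- sort(runif(4, 1, 300))
    times <- sort(c(tq - h, tq, tq + h))
    tr <- simulate_full(p, x0, times)
    iq <- match(tq, tr$time_min)
    lhs <- ((tr$r_t + tr$r_f)[iq + 1] - (tr$r_t + tr$r_f)[iq - 1]) / (2 * h)
    rhs <- p[["p_syn"]] - p[["k_deg"]] * tr$r_i[iq]
    expect_equal(lhs, rhs, tolerance = 1e-6)
  }
})

test_that("normalizing and simulating commute for the labeled pool", {
  set.seed(45)
  p <- random_params()
  x0 <- compartment_state(123, 45, 0)
  tr <- simulate_pulse_chase(p, x0, c(5, 20, 90))
  xn <- compartment_state(123 / 168, 45 / 168, 0)
  trn <- simulate_pulse_chase(p, xn, c(5, 20, 90))
  expect_equal(tr$r_t / 168, trn$r_t, tolerance = 1e-12)
  expect_equal(tr$r_i / 168, trn$r_i, tolerance = 1e-12)
})

test_that("invalid inputs are rejected", {
  expect_error(rate_params(-1, 0.01, 0.01, 0.01, 0.001), "non-negative")
  expect_error(rate_params(NA, 0.01, 0.01, 0.01, 0.001), "finite")
  expect_error(compartment_state(-1, 0, 0), "non-negative")
  p <- rate_params(1, 0.01, 0.01, 0.01, 0.001)
  expect_error(simulate_full(p, compartment_state(1, 1, 0), c(5, 5)),
               "strictly increasing")
  expect_error(log10_params(rate_params(0, .01, .01, .01, .001)), "> 0")
})

test_that("derived observables report shed and surface fractions", {
  tr <- structure(data.frame(time_min = 0, r_s = 75, r_i = 25, r_f = 10,
                             r_t = 100),
                  class = c("rtk_trajectory", "data.frame"))
  d <- derived_observables(tr)
  expect_equal(d$percent_shed, 0.10)
  expect_equal(d$surface_fraction, 0.75)
  tr$r_f <- 0
  expect_equal(derived_observables(tr)$percent_shed, 0)
  ## 24 h from the worked fixed point: 24000 shed over 25000 in the cell
  p <- rate_params(100, 0.01, 0.01, 0.01, 0.001)
  ss <- steady_state(p)
  traj <- simulate_full(p, compartment_state(ss$r_s, ss$r_i, 0), 1440)
  expect_equal(derived_observables(traj)$percent_shed, 0.96, tolerance = 1e-9)
})

test_that("trajectories round-trip through CSV", {
  p <- rate_params(100, 0.01, 0.01, 0.01, 0.001)
  tr <- simulate_full(p, compartment_state(1000, 100, 0), c(0, 60, 1440))
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_equal(as.data.frame(back), as.data.frame(tr), tolerance = 1e-12)
  unlink(f)
})
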