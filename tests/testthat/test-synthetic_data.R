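zero_sigma <- c(endpoint_lysate = 0, endpoint_supernatant = 0,
                timecourse_total = 0, timecourse_internal = 0)

test_that("noiseless replicates equal the model truth", {
  sc <- scenario(c("control", "mek_like"), sigma = zero_sigma)
  ep <- generate_endpoint(sc, "Axl", "mek_like", seed = 1)
  expect_equal(ep$lysate, rep(ep$truth$lysate, 12))
  expect_equal(ep$supernatant, rep(ep$truth$supernatant, 12))
  ## manifest parameters reproduce the data under the model
  p <- ep$params
  fi <- rtktraffic:::.internal_fraction(p[["k_deg"]], p[["k_end"]],
                                        p[["k_rec"]])
  tr <- simulate_full(p, compartment_state(ep$truth$rt0 * (1 - fi),
                                           ep$truth$rt0 * fi, 0), 1440)
  expect_equal(ep$truth$lysate, tr$r_t, tolerance = 1e-10)
  expect_equal(ep$truth$supernatant, tr$r_f, tolerance = 1e-10)
  tc <- generate_timecourse(sc, "Axl", "mek_like", seed = 1)
  pc <- simulate_pulse_chase(p, compartment_state(1, 0, 0), sc$times_tc)
  expect_equal(tc$total[, 1], pc$r_t / pc$r_t[1], tolerance = 1e-10)
  expect_equal(tc$internal[, 1], pc$r_i / pc$r_t[1], tolerance = 1e-10)
})

test_that("generation is a pure function of scenario and seed", {
  sc <- scenario(c("control", "mek_like"))
  a <- generate_endpoint(sc, "Met", "mek_like", seed = 5)
  b <- generate_endpoint(sc, "Met", "mek_like", seed = 5)
  expect_identical(a, b)
  c_ <- generate_endpoint(sc, "Met", "mek_like", seed = 6)
  expect_false(identical(a$lysate, c_$lysate))
  s1 <- make_study(sc, seed = 2)
  s2 <- make_study(sc, seed = 2)
  expect_identical(s1$data, s2$data)
})

test_that("replicate spread matches the configured noise at large n", {
  sc <- scenario("control", n_endpoint = 1500)
  ep <- generate_endpoint(sc, "Axl", "control", seed = 9)
  expect_equal(sd(log10(ep$lysate)), sc$sigma[["endpoint_lysate"]],
               tolerance = 0.05)
  expect_equal(sd(log10(ep$supernatant)), sc$sigma[["endpoint_supernatant"]],
               tolerance = 0.05)
})

test_that("time courses are normalized to the first-time-point total mean", {
  sc <- scenario("control")
  tc <- generate_timecourse(sc, "EGFR", "control", seed = 3)
  expect_equal(mean(tc$total[1, ]), 1, tolerance = 1e-12)
  ## an inert labeled pool stays at its normalized level
  frozen <- scenario("control",
                     rtks = list(X = rate_params(0, 0, 0, 0, 0)),
                     sigma = zero_sigma)
  tcf <- generate_timecourse(frozen, "X", "control", seed = 1)
  expect_equal(as.numeric(tcf$total), rep(1, length(tcf$total)))
})

test_that("late-time internal fraction approaches the quasi-equilibrium split", {
  p <- rate_params(0, 1e-4, 0.02, 0.01, 1e-4)
  sc <- scenario("control", rtks = list(X = p), sigma = zero_sigma,
                 times_tc = c(5, 500, 1000, 2000))
  tc <- generate_timecourse(sc, "X", "control", seed = 1)
  frac <- tc$internal[4, 1] / tc$total[4, 1]
  ## oracle: long-horizon simulation of the label split
  o <- oracle_traj(p, compartment_state(1, 0, 0), 2000, synthesis = FALSE)
  expect_equal(frac, o$r_i / o$r_t, tolerance = 1e-6)
  ## near the equilibrium ratio k_end/(k_end + k_rec + k_deg) when losses
  ## are slow
  expect_equal(frac, 0.02 / (0.02 + 0.01 + 1e-4), tolerance = 0.05)
})

test_that("treatment presets move the intended parameters", {
  sc <- scenario(c("control", "mek_like", "egf_like", "batimastat_like",
                   "erk_tki_like"))
  ctrl <- true_params(sc, "Axl", "control")
  mek <- true_params(sc, "Axl", "mek_like")
  expect_gt(mek[["p_syn"]], ctrl[["p_syn"]])
  expect_lt(mek[["k_deg"]], ctrl[["k_deg"]])
  expect_lt(mek[["k_end"]], ctrl[["k_end"]])
  egf <- true_params(sc, "EGFR", "egf_like")
  expect_equal(egf[["k_end"]],
               3 * true_params(sc, "EGFR", "control")[["k_end"]])
  bat <- true_params(sc, "Met", "batimastat_like")
  expect_equal(bat[["k_shed"]], 0.2 * true_params(sc, "Met", "control")[["k_shed"]])
  erk <- true_params(sc, "Her2", "erk_tki_like")
  expect_equal(erk[["p_syn"]], 2 * true_params(sc, "Her2", "control")[["p_syn"]])
  expect_error(scenario("no_such_preset"), "unknown treatment preset")
})

test_that("the Her2 analog supernatant is censored below the LLOQ", {
  sc <- scenario("control")
  ep <- generate_endpoint(sc, "Her2", "control", seed = 4)
  expect_true(ep$supernatant_censored)
  expect_true(all(is.na(ep$supernatant)))
  expect_lt(ep$truth$supernatant, sc$lloq * 24)
  ## abundant sheds are not censored
  expect_false(generate_endpoint(sc, "Met", "control",
                                 seed = 4)$supernatant_censored)
})

test_that("standard-curve generation round-trips and is seeded", {
  dat <- generate_standard_curve(100, 30000, 50, 1.2, 1, noise_sd = 0)
  std <- dat[!dat$is_background, ]
  fit <- fit_5pl(std$concentration_pg, std$mfu)
  expect_equal(fit$c, 50, tolerance = 1e-6)
  a <- generate_standard_curve(100, 30000, 50, 1.2, 1, noise_sd = 50, seed = 8)
  b <- generate_standard_curve(100, 30000, 50, 1.2, 1, noise_sd = 50, seed = 8)
  expect_identical(a, b)
})

test_that("a study bundle passes table validation", {
  sc <- scenario(c("control", "mek_like"),
                 rtks = .subset(scenario("control")$rtks, c("Axl", "Met")))
  st <- make_study(sc, seed = 11)
  dir <- tempfile()
  paths <- write_study(st, dir)
  expect_identical(validate_tables(as.list(paths[c("endpoint", "timecourse")])),
                   character(0))
  ## reading back reproduces the replicate structure
  back <- read_study(dir)
  expect_equal(back$mek_like$Axl$endpoint_lysate,
               st$data$mek_like$Axl$endpoint_lysate, tolerance = 1e-12)
  expect_equal(back$control$Met$timecourse_internal,
               st$data$control$Met$timecourse_internal,
               ignore_attr = TRUE, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
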