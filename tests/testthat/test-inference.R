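## independently coded likelihood oracle: simulates with deSolve and sums
## normal log-densities term by term
oracle_loglik <- function(params, data, inits) {
  fi_num <- params[["k_end"]]
  fi_den <- params[["k_end"]] + params[["k_rec"]] + params[["k_deg"]]
  ratio <- if (params[["k_rec"]] + params[["k_deg"]] > 0) {
    params[["k_end"]] / (params[["k_rec"]] + params[["k_deg"]])
  } else if (params[["k_end"]] > 0) Inf else 0
  fi <- if (is.infinite(ratio)) 1 else ratio / (1 + ratio)
  ep <- oracle_traj(params,
                    compartment_state(inits[["rt0"]] * (1 - fi),
                                      inits[["rt0"]] * fi, 0),
                    data$endpoint_duration_min)
  s <- data$sigma
  ll <- sum(dnorm(log10(data$endpoint_lysate), log10(ep$r_t),
                  s[["endpoint_lysate"]], log = TRUE))
  if (data$supernatant_censored) {
    lloq_ep <- data$lloq * data$endpoint_duration_min / 60
    if (ep$r_f > lloq_ep) {
      ll <- ll - length(data$endpoint_supernatant) *
        (log10(ep$r_f) - log10(lloq_ep))^2 /
        (2 * s[["endpoint_supernatant"]]^2)
    }
  } else {
    ll <- ll + sum(dnorm(log10(data$endpoint_supernatant), log10(ep$r_f),
                         s[["endpoint_supernatant"]], log = TRUE))
  }
  pc <- oracle_traj(params,
                    compartment_state(inits[["tc_rt0"]] - inits[["tc_ri0"]],
                                      inits[["tc_ri0"]], 0),
                    data$times_tc, synthesis = FALSE)
  for (j in seq_along(data$times_tc)) {
    ll <- ll + sum(dnorm(log10(data$timecourse_total[j, ]), log10(pc$r_t[j]),
                         s[["timecourse_total"]], log = TRUE)) +
      sum(dnorm(log10(data$timecourse_internal[j, ]), log10(pc$r_i[j]),
                s[["timecourse_internal"]], log = TRUE))
  }
  ll
}

test_that("likelihood matches an independently coded density sum", {
  set.seed(21)
  for (i in 1:8) {
    d <- tiny_experiment_set(censored = i %% 3 == 0)
    p <- random_params()
    inits <- c(rt0 = mean(d$endpoint_lysate),
               tc_ri0 = mean(d$timecourse_internal[1, ]),
               tc_rt0 = mean(d$timecourse_total[1, ]))
    expect_equal(log_likelihood(p, d, inits), oracle_loglik(p, d, inits),
                 tolerance = 1e-8)
  }
})

test_that("identical replicates contribute additively", {
  set.seed(22)
  d1 <- tiny_experiment_set(n_ep = 1, n_tc = 1)
  dK <- d1
  K <- 4
  dK$endpoint_lysate <- rep(d1$endpoint_lysate, K)
  dK$endpoint_supernatant <- rep(d1$endpoint_supernatant, K)
  dK$timecourse_total <- d1$timecourse_total[, rep(1, K), drop = FALSE]
  dK$timecourse_internal <- d1$timecourse_internal[, rep(1, K), drop = FALSE]
  p <- random_params()
  expect_equal(log_likelihood(p, dK), K * log_likelihood(p, d1),
               tolerance = 1e-9)
})

test_that("non-positive predictions where data exist give -Inf", {
  set.seed(23)
  d <- tiny_experiment_set()
  p <- rate_params(1, 0.01, 0.01, 0.01, 0)  # no shedding -> r_f = 0
  expect_identical(log_likelihood(p, d), -Inf)
})

test_that("log posterior composes likelihood and prior", {
  set.seed(24)
  d <- tiny_experiment_set()
  pri <- default_priors()
  th <- c(p_syn = 1.2, k_deg = -2.1, k_end = -1.9, k_rec = -2.4,
          k_shed = -3.5)
  inits <- c(rt0 = mean(d$endpoint_lysate),
             tc_ri0 = mean(d$timecourse_internal[1, ]),
             tc_rt0 = mean(d$timecourse_total[1, ]))
  lp <- log_posterior(c(th, inits), d, pri, fs_prior = NULL,
                      init_priors = NULL)
  expect_equal(lp,
               log_likelihood(params_from_log10(th), d, inits) +
                 log_prior(as.list(th), pri),
               tolerance = 1e-10)
  ## flat priors: posterior equals likelihood
  flat <- lapply(th, function(...) prior_spec("uniform", bounds = c(-10, 10)))
  expect_equal(log_posterior(c(th, inits), d, flat, NULL, NULL),
               log_likelihood(params_from_log10(th), d, inits),
               tolerance = 1e-10)
  ## out-of-bounds value propagates -Inf
  th_bad <- th; th_bad[["k_deg"]] <- 0.5
  expect_identical(log_posterior(c(th_bad, inits), d, pri, NULL, NULL), -Inf)
})

test_that("the fast fitting posterior equals the public composition", {
  set.seed(25)
  d <- tiny_experiment_set()
  pri <- default_priors()
  fsp <- prior_spec("truncnormal", 0.85, 0.1, c(0, 1))
  inits0 <- rtktraffic:::.default_inits(d)
  scl <- pmax(inits0, 1e-12)
  ip <- list(rt0 = prior_spec("truncnormal", inits0[["rt0"]],
                              sd(d$endpoint_lysate), c(0, Inf)),
             tc_ri0 = prior_spec("truncnormal", inits0[["tc_ri0"]], 10,
                                 c(0, Inf)),
             tc_rt0 = prior_spec("truncnormal", inits0[["tc_rt0"]], 10,
                                 c(0, Inf)))
  fast <- rtktraffic:::.make_logpost_z(d, pri, fsp, ip, inits0, scl, TRUE)
  for (i in 1:10) {
    z <- c(runif(1, 0, 3), runif(4, -5, -1), exp(rnorm(3, 0, 0.1)))
    th <- setNames(c(z[1:5], z[6:8] * scl),
                   c("p_syn", "k_deg", "k_end", "k_rec", "k_shed",
                     "rt0", "tc_ri0", "tc_rt0"))
    expect_equal(fast(z), log_posterior(th, d, pri, fsp, ip),
                 tolerance = 1e-8)
  }
})

test_that("noise scales are the median replicate-group sd of log10 data", {
  set.seed(26)
  sets <- replicate(3, tiny_experiment_set(n_ep = 6, n_tc = 5),
                    simplify = FALSE)
  sig <- estimate_sigma(sets)
  ## oracle for one experiment type
  man <- median(vapply(sets, function(s) sd(log10(s$endpoint_lysate)),
                       numeric(1)))
  expect_equal(sig[["endpoint_lysate"]], man, tolerance = 1e-12)
  man_tc <- median(unlist(lapply(sets, function(s)
    apply(s$timecourse_total, 1, function(r) sd(log10(r))))))
  expect_equal(sig[["timecourse_total"]], man_tc, tolerance = 1e-12)
})

test_that("latin hypercube starts stratify every dimension", {
  s <- lhs_starts(4, 0, 4, seed = 1)
  expect_equal(sort(floor(s)), 0:3)
  s5 <- lhs_starts(100, rep(-6, 5), rep(0, 5), seed = 2)
  for (j in 1:5) {
    bins <- floor((s5[, j] + 6) / 6 * 100)
    expect_equal(sort(bins), 0:99)
  }
  expect_identical(lhs_starts(20, rep(0, 3), rep(1, 3), seed = 3),
                   lhs_starts(20, rep(0, 3), rep(1, 3), seed = 3))
  expect_error(lhs_starts(5, 1, 0), "bounds")
})

test_that("pattern search finds interior and boundary optima", {
  r <- pattern_search(function(x) (x + 3)^2, 0, -6, 0)
  expect_equal(r$par, -3, tolerance = 1e-5)
  expect_true(r$converged)
  ## monotone objective ends at the boundary
  r2 <- pattern_search(function(x) sum(x), c(0.5, 0.5), c(0, 0), c(1, 1))
  expect_equal(r2$par, c(0, 0), tolerance = 1e-5)
})

test_that("multistart pattern search finds the deeper of two basins", {
  two_basin <- function(x) {
    ## minima near x = -4 (depth -2) and x = -1 (depth -3)
    -2 * exp(-8 * (x + 4)^2) - 3 * exp(-8 * (x + 1)^2)
  }
  grid <- seq(-6, 0, by = 1e-4)
  x_star <- grid[which.min(two_basin(grid))]
  starts <- lhs_starts(20, -6, 0, seed = 4)
  best <- Inf; best_x <- NA
  for (s in starts) {
    r <- pattern_search(two_basin, s, -6, 0)
    if (r$value < best) { best <- r$value; best_x <- r$par }
  }
  expect_equal(best_x, x_star, tolerance = 1e-3)
})

test_that("adaptive Metropolis samples a gaussian target reproducibly", {
  lp <- function(x) -0.5 * sum(x^2)
  cfg <- am_config(n_iter = 4000, burn_in = 1000, n_chains = 2, seed = 5)
  ch1 <- adaptive_metropolis(lp, c(0.1, -0.1), cfg)
  ch2 <- adaptive_metropolis(lp, c(0.1, -0.1), cfg)
  expect_identical(ch1$chains, ch2$chains)  # bit-identical under the seed
  samp <- posterior_samples(ch1)
  expect_equal(nrow(samp), 2 * 3000)
  expect_lt(max(abs(colMeans(samp))), 0.15)
  expect_equal(unname(apply(samp, 2, var)), c(1, 1), tolerance = 0.2)
  expect_true(all(ch1$acceptance > 0.1 & ch1$acceptance < 0.9))
})

test_that("proposals before the adaptation onset use the fixed covariance", {
  ## on a flat target every proposal is accepted, so increments are raw
  ## proposal draws: their variance must equal C0 before t0
  cfg <- am_config(C0 = 0.01, t0 = 10000, n_iter = 5000, burn_in = 100,
                   n_chains = 1, start_cv = 0, seed = 6)
  ch <- adaptive_metropolis(function(x) 0, c(0, 0), cfg)
  inc <- diff(ch$chains[[1]])
  expect_equal(unname(apply(inc, 2, var)), c(0.01, 0.01), tolerance = 0.05)
  expect_equal(mean(ch$accepted[[1]]), 1)
})

test_that("Gelman-Rubin statistic matches its defining formula", {
  set.seed(27)
  x <- matrix(rnorm(200), 100, 2)
  ## two identical chains: B = 0, R-hat = sqrt((n-1)/n)
  r <- gelman_rubin(list(x, x))
  expect_equal(unname(r), rep(sqrt(99 / 100), 2), tolerance = 1e-12)
  ## well-mixed chains from one sampler
  chains <- replicate(4, matrix(rnorm(500), 500, 1), simplify = FALSE)
  expect_lt(gelman_rubin(chains)[1], 1.1)
  ## separated chains
  far <- list(matrix(rnorm(100, 0, 0.01), 100, 1),
              matrix(rnorm(100, 5, 0.01), 100, 1))
  expect_gt(gelman_rubin(far)[1], 10)
  expect_error(gelman_rubin(list(x)), "at least 2")
})

test_that("Gelman-Rubin agrees with the coda reference implementation", {
  skip_if_not_installed("coda")
  set.seed(28)
  chains <- replicate(3, matrix(rnorm(600, 0, 1.3), 200, 3), simplify = FALSE)
  ours <- gelman_rubin(chains)
  ref <- coda::gelman.diag(coda::mcmc.list(lapply(chains, coda::mcmc)),
                           autoburnin = FALSE)$psrf[, 1]
  expect_equal(unname(ours), unname(ref), tolerance = 0.02)
})

test_that("fitting noiseless data recovers the generating parameters", {
  sc <- scenario("control",
                 sigma = c(endpoint_lysate = 1e-12,
                           endpoint_supernatant = 1e-12,
                           timecourse_total = 1e-12,
                           timecourse_internal = 1e-12))
  truth <- log10_params(true_params(sc, "Met", "control"))
  ep <- generate_endpoint(sc, "Met", "control", seed = 1)
  tc <- generate_timecourse(sc, "Met", "control", seed = 1)
  d <- experiment_set(ep$lysate, ep$supernatant, tc$total, tc$internal,
                      sigma = c(endpoint_lysate = 0.05,
                                endpoint_supernatant = 0.05,
                                timecourse_total = 0.05,
                                timecourse_internal = 0.05),
                      lloq = sc$lloq)
  fit <- suppressWarnings(fit_condition(
    d, default_priors(), am_config(n_iter = 600, burn_in = 200, seed = 1),
    n_starts = 15, ps_max_evals = 8000, fs_prior = NULL, seed = 31))
  ## identifiable parameters (recycling is the weakly identified one)
  idx <- c("p_syn", "k_deg", "k_end", "k_shed")
  expect_lt(max(abs(fit$map[idx] - truth[idx])), 0.05)
})

test_that("duplicating every replicate leaves the flat-prior optimum unchanged", {
  set.seed(32)
  d1 <- tiny_experiment_set(n_ep = 4, n_tc = 3)
  d2 <- d1
  d2$endpoint_lysate <- rep(d1$endpoint_lysate, 2)
  d2$endpoint_supernatant <- rep(d1$endpoint_supernatant, 2)
  d2$timecourse_total <- d1$timecourse_total[, rep(1:3, 2)]
  d2$timecourse_internal <- d1$timecourse_internal[, rep(1:3, 2)]
  flat <- lapply(default_priors(), function(s)
    prior_spec("uniform", bounds = s$bounds))
  cfg <- am_config(n_iter = 500, burn_in = 100, n_chains = 2, seed = 1)
  f1 <- fit_condition(d1, flat, cfg, n_starts = 12, ps_max_evals = 2500,
                      estimate_inits = FALSE, fs_prior = NULL, seed = 33)
  f2 <- fit_condition(d2, flat, cfg, n_starts = 12, ps_max_evals = 2500,
                      estimate_inits = FALSE, fs_prior = NULL, seed = 33)
  expect_equal(f1$map, f2$map, tolerance = 1e-4)
})
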