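## Shared fixtures: random parameter draws, an independent ODE oracle, and
## small synthetic datasets. Everything is generated in code at test time.

random_params <- function() {
  rate_params(p_syn = 10^runif(1, 0, 3),
              k_deg = 10^runif(1, -4, -1),
              k_end = 10^runif(1, -4, -1),
              k_rec = 10^runif(1, -4, -1),
              k_shed = 10^runif(1, -6, -2))
}

random_state <- function() {
  compartment_state(r_s = runif(1, 1, 1e5), r_i = runif(1, 1, 1e5),
                    r_f = runif(1, 0, 1e3))
}

## independent integration oracle: deSolve on the raw ODE right-hand side
oracle_traj <- function(params, init, times, synthesis = TRUE) {
  p <- as.list(unclass(params))
  if (!synthesis) p$p_syn <- 0
  rhs <- function(t, y, parms) {
    list(c(p$k_end * y[2] - (p$k_rec + p$k_deg) * y[1],
           p$p_syn + p$k_rec * y[1] - (p$k_end + p$k_shed) * y[2],
           p$k_shed * y[2]))
  }
  tt <- times; pre <- FALSE
  if (tt[1] > 0) { tt <- c(0, tt); pre <- TRUE }
  sol <- deSolve::lsoda(c(init[["r_i"]], init[["r_s"]], init[["r_f"]]),
                        tt, rhs, NULL, rtol = 1e-11, atol = 1e-11)
  if (pre) sol <- sol[-1, , drop = FALSE]
  data.frame(time_min = times, r_i = sol[, 2], r_s = sol[, 3],
             r_f = sol[, 4], r_t = sol[, 2] + sol[, 3])
}

## tiny experiment set with arbitrary (not model-generated) data, for
## likelihood plumbing tests
tiny_experiment_set <- function(n_ep = 3, n_tc = 2, censored = FALSE,
                                sigma = c(endpoint_lysate = 0.1,
                                          endpoint_supernatant = 0.2,
                                          timecourse_total = 0.1,
                                          timecourse_internal = 0.15)) {
  times <- c(5, 20, 45)
  experiment_set(
    endpoint_lysate = 10^rnorm(n_ep, 5, 0.1),
    endpoint_supernatant = if (censored) rep(NA_real_, n_ep) else
      10^rnorm(n_ep, 3.5, 0.1),
    timecourse_total = matrix(10^rnorm(length(times) * n_tc, 0, 0.05),
                              length(times), n_tc),
    timecourse_internal = matrix(10^rnorm(length(times) * n_tc, -1, 0.05),
                                 length(times), n_tc),
    times_tc = times, sigma = sigma,
    supernatant_censored = censored, lloq = 89)
}

## gaussian pseudo-posterior sample matrices for PCA / prior-update tests
gaussian_fit_samples <- function(mu, sd = 0.05, n = 400) {
  kin <- c("p_syn", "k_deg", "k_end", "k_rec", "k_shed")
  m <- sapply(seq_along(kin), function(j) rnorm(n, mu[j], sd))
  colnames(m) <- kin
  m
}

## nested cell-line/treatment/receptor structure of pseudo-posteriors; the
## optional shift moves named parameters of receptor R1 under treatment
make_fits <- function(shift = NULL, sd = 0.05, n = 400) {
  mu <- c(p_syn = 2, k_deg = -2, k_end = -2.5, k_rec = -1.7, k_shed = -4)
  rtks <- c("R1", "R2")
  out <- list(cellA = list(control = list(), treated = list()))
  for (r in rtks) {
    out$cellA$control[[r]] <- gaussian_fit_samples(mu, sd, n)
    mu_t <- mu
    if (!is.null(shift) && r == "R1") {
      mu_t[names(shift)] <- mu_t[names(shift)] + shift
    }
    out$cellA$treated[[r]] <- gaussian_fit_samples(mu_t, sd, n)
  }
  out
}
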