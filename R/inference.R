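## Joint Bayesian inference over end-point and pulse-chase data:
## posterior evaluation, 100-start latin-hypercube pattern search, and
## Haario-style adaptive Metropolis with Gelman-Rubin diagnostics.

.theta_names <- c("p_syn", "k_deg", "k_end", "k_rec", "k_shed",
                  "rt0", "tc_ri0", "tc_rt0")

#' Replicated observations for one receptor / treatment / cell line
#'
#' Packs the two experiment families the model is fit to: 24-h end-point
#' lysate and supernatant abundances (molecules/cell) and pulse-chase
#' time-course total/internal labeled signal (normalized units) at a common
#' set of chase times.
#'
#' @param endpoint_lysate replicate lysate values, molecules/cell
#' @param endpoint_supernatant replicate supernatant values, molecules/cell
#'   accumulated over the end-point window (may be `NA` when censored)
#' @param timecourse_total,timecourse_internal matrices of normalized labeled
#'   signal, one row per chase time, one column per replicate
#' @param times_tc chase times, minutes, sorted increasing
#' @param sigma named per-experiment-type noise sds on the log10 scale
#'   (`endpoint_lysate`, `endpoint_supernatant`, `timecourse_total`,
#'   `timecourse_internal`); may be `NULL` and set later via
#'   [estimate_sigma()]
#' @param supernatant_censored `TRUE` when the supernatant analyte was below
#'   the assay LLOQ (e.g. Her2); censored observations enter the likelihood
#'   through a one-sided penalty
#' @param lloq assay LLOQ, molecules cell^-1 h^-1
#' @param endpoint_duration_min end-point window, minutes (default 1440)
#' @return object of class `experiment_set`
#' @export
experiment_set <- function(endpoint_lysate, endpoint_supernatant,
                           timecourse_total, timecourse_internal,
                           times_tc = c(5, 20, 45, 75, 90),
                           sigma = NULL, supernatant_censored = FALSE,
                           lloq = NA_real_, endpoint_duration_min = 1440) {
  timecourse_total <- as.matrix(timecourse_total)
  timecourse_internal <- as.matrix(timecourse_internal)
  if (is.unsorted(times_tc, strictly = TRUE)) stop("times_tc must be strictly increasing")
  if (nrow(timecourse_total) != length(times_tc) ||
      nrow(timecourse_internal) != length(times_tc)) {
    stop("time-course matrices need one row per chase time")
  }
  if (!is.null(sigma)) {
    need <- c("endpoint_lysate", "endpoint_supernatant",
              "timecourse_total", "timecourse_internal")
    if (!all(need %in% names(sigma)) || any(sigma[need] <= 0)) {
      stop("sigma must be a named vector of positive sds for all four experiment types")
    }
  }
  structure(list(endpoint_lysate = as.numeric(endpoint_lysate),
                 endpoint_supernatant = as.numeric(endpoint_supernatant),
                 timecourse_total = timecourse_total,
                 timecourse_internal = timecourse_internal,
                 times_tc = as.numeric(times_tc),
                 sigma = sigma,
                 supernatant_censored = isTRUE(supernatant_censored),
                 lloq = lloq,
                 endpoint_duration_min = endpoint_duration_min,
                 n = c(endpoint = length(endpoint_lysate),
                       timecourse = ncol(timecourse_total))),
            class = "experiment_set")
}

#' Per-experiment-type noise scale from replicate spread
#'
#' For every experiment type, computes the sd of the log10-transformed
#' replicates within each replicate group (per condition, and per time point
#' for time courses), then takes the median across all groups and
#' conditions. The resulting four sds are frozen during fitting.
#'
#' @param sets a list of [experiment_set()] (or a single one)
#' @return named numeric vector of sds on the log10 scale
#' @export
estimate_sigma <- function(sets) {
  if (inherits(sets, "experiment_set")) sets <- list(sets)
  grab <- function(field) {
    unlist(lapply(sets, function(s) {
      x <- s[[field]]
      if (is.matrix(x)) {
        apply(x, 1, function(r) sd(log10(r[is.finite(r) & r > 0])))
      } else {
        sd(log10(x[is.finite(x) & x > 0]))
      }
    }))
  }
  out <- vapply(c("endpoint_lysate", "endpoint_supernatant",
                  "timecourse_total", "timecourse_internal"),
                function(f) median(grab(f), na.rm = TRUE), numeric(1))
  if (any(!is.finite(out) | out <= 0)) {
    stop("could not estimate a positive sigma for every experiment type")
  }
  out
}

.default_inits <- function(data) {
  c(rt0 = mean(data$endpoint_lysate),
    tc_ri0 = mean(data$timecourse_internal[1, ]),
    tc_rt0 = mean(data$timecourse_total[1, ]))
}

## normal log-density sums on the log10 scale; y already log10-transformed
.ll_block <- function(log10_yhat, log10_y, sigma) {
  -sum((log10_yhat - log10_y)^2) / (2 * sigma^2) -
    length(log10_y) * (log(sigma) + 0.5 * log(2 * pi))
}

#' Log-likelihood of the trafficking model for one condition
#'
#' Simulates the 24-h end point (full model, lysate total split between
#' surface and internal pools by the steady-state internal fraction implied
#' by the candidate parameters) and the pulse-chase time course (labeled
#' pool, no synthesis), then scores all replicates under independent normal
#' errors on the log10 scale with per-experiment-type sds. A censored
#' (below-LLOQ) supernatant contributes nothing while the prediction stays
#' below the LLOQ and a one-sided squared penalty above it.
#'
#' @param params a [rate_params()] object (raw scale)
#' @param data an [experiment_set()] with `sigma` set
#' @param inits optional named vector `(rt0, tc_ri0, tc_rt0)`: end-point
#'   initial lysate total and time-course initial internal/total label;
#'   defaults to the data means (t = first chase time for the time course)
#' @return scalar log-likelihood; `-Inf` when a prediction is non-positive
#'   where data exist
#' @export
log_likelihood <- function(params, data, inits = NULL) {
  stopifnot(inherits(data, "experiment_set"))
  if (is.null(data$sigma)) stop("data$sigma not set; see estimate_sigma()")
  if (!inherits(params, "rate_params")) params <- do.call(rate_params, as.list(params))
  if (is.null(inits)) inits <- .default_inits(data)
  p_syn <- params[["p_syn"]]; k_deg <- params[["k_deg"]]
  k_end <- params[["k_end"]]; k_rec <- params[["k_rec"]]
  k_shed <- params[["k_shed"]]
  sig <- data$sigma

  ## end point: 1440-min full simulation from the candidate steady-state split
  rt0 <- inits[["rt0"]]
  if (rt0 < 0) return(-Inf)
  fi <- .internal_fraction(k_deg, k_end, k_rec)
  ep <- .traj_core(p_syn, k_deg, k_end, k_rec, k_shed,
                   ri0 = rt0 * fi, rs0 = rt0 * (1 - fi), rf0 = 0,
                   times = data$endpoint_duration_min)
  lys_hat <- ep$ri[1] + ep$rs[1]
  sup_hat <- ep$rf[1]
  if (!is.finite(lys_hat) || lys_hat <= 0) return(-Inf)
  ll <- .ll_block(log10(lys_hat), log10(data$endpoint_lysate),
                  sig[["endpoint_lysate"]])

  if (data$supernatant_censored) {
    n_cens <- length(data$endpoint_supernatant)
    lloq_ep <- data$lloq * data$endpoint_duration_min / 60
    if (is.finite(lloq_ep) && sup_hat > lloq_ep) {
      ll <- ll - n_cens * (log10(sup_hat) - log10(lloq_ep))^2 /
        (2 * sig[["endpoint_supernatant"]]^2)
    }
  } else {
    if (!is.finite(sup_hat) || sup_hat <= 0) return(-Inf)
    ll <- ll + .ll_block(log10(sup_hat), log10(data$endpoint_supernatant),
                         sig[["endpoint_supernatant"]])
  }

  ## pulse chase: labeled pool only, initial conditions in normalized units
  tc_ri0 <- inits[["tc_ri0"]]; tc_rt0 <- inits[["tc_rt0"]]
  if (tc_ri0 < 0 || tc_rt0 < tc_ri0) return(-Inf)
  pc <- .traj_core(0, k_deg, k_end, k_rec, k_shed,
                   ri0 = tc_ri0, rs0 = tc_rt0 - tc_ri0, rf0 = 0,
                   times = data$times_tc)
  tot_hat <- pc$ri + pc$rs
  int_hat <- pc$ri
  if (any(!is.finite(tot_hat)) || any(tot_hat <= 0) ||
      any(!is.finite(int_hat)) || any(int_hat <= 0)) return(-Inf)
  lt <- log10(tot_hat); li <- log10(int_hat)
  for (j in seq_along(data$times_tc)) {
    ll <- ll + .ll_block(lt[j], log10(data$timecourse_total[j, ]),
                         sig[["timecourse_total"]]) +
      .ll_block(li[j], log10(data$timecourse_internal[j, ]),
                sig[["timecourse_internal"]])
  }
  ll
}

#' Log-posterior of the trafficking model
#'
#' Sum of [log_likelihood()] and the prior terms: per-parameter priors on
#' the log10 kinetic rates, an optional truncated-normal prior on the
#' model's steady-state surface fraction, and truncated-normal priors on the
#' initial conditions. `-Inf` propagates from any term.
#'
#' @param theta named vector: log10 kinetic parameters
#'   (`p_syn, k_deg, k_end, k_rec, k_shed`) and raw initial conditions
#'   (`rt0, tc_ri0, tc_rt0`); the three inits may be omitted to use data
#'   means
#' @param data an [experiment_set()]
#' @param priors named list of [prior_spec()] for the five kinetic
#'   parameters (log10 scale)
#' @param fs_prior optional `truncnormal` [prior_spec()] applied to the
#'   steady-state surface fraction implied by `theta`; `NULL` disables it
#' @param init_priors optional named list of `truncnormal` [prior_spec()]
#'   for `rt0`, `tc_ri0`, `tc_rt0`; `NULL` disables those terms
#' @return scalar log posterior density (unnormalized)
#' @export
log_posterior <- function(theta, data, priors, fs_prior = NULL,
                          init_priors = NULL) {
  kin <- theta[c("p_syn", "k_deg", "k_end", "k_rec", "k_shed")]
  lp <- log_prior(as.list(kin), priors)
  if (!is.finite(lp)) return(-Inf)
  params <- params_from_log10(kin)
  if (!is.null(fs_prior)) {
    fi <- .internal_fraction(params[["k_deg"]], params[["k_end"]],
                             params[["k_rec"]])
    lp <- lp + dtruncnorm_log(1 - fi, fs_prior$mu, fs_prior$sigma,
                              fs_prior$bounds[1], fs_prior$bounds[2])
    if (!is.finite(lp)) return(-Inf)
  }
  inits <- NULL
  if (all(c("rt0", "tc_ri0", "tc_rt0") %in% names(theta))) {
    inits <- theta[c("rt0", "tc_ri0", "tc_rt0")]
    if (!is.null(init_priors)) {
      for (nm in names(init_priors)) {
        sp <- init_priors[[nm]]
        lp <- lp + dtruncnorm_log(theta[[nm]], sp$mu, sp$sigma,
                                  sp$bounds[1], sp$bounds[2])
      }
      if (!is.finite(lp)) return(-Inf)
    }
  }
  ll <- log_likelihood(params, data, inits)
  if (!is.finite(ll)) return(-Inf)
  lp + ll
}

#' Latin-hypercube start sites
#'
#' Generates `n` points in a box, each coordinate stratified into `n` equal
#' bins with exactly one point per bin.
#'
#' @param n number of starts
#' @param lower,upper per-dimension bounds (equal length)
#' @param seed RNG seed
#' @return `n` x `length(lower)` matrix
#' @export
lhs_starts <- function(n, lower, upper, seed = NULL) {
  stopifnot(n >= 1, length(lower) == length(upper))
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(upper <= lower)) {
    stop("bounds must be finite with upper > lower")
  }
  u <- with_seed(seed, lhs::randomLHS(n, length(lower)))
  sweep(sweep(u, 2, upper - lower, `*`), 2, lower, `+`)
}

#' Derivative-free generalized pattern search
#'
#' Box-constrained minimization by coordinate polling: from the incumbent,
#' all `2 d` mesh points `x +- delta e_i` are evaluated; the best improving
#' point becomes the incumbent and the mesh expands by 2, otherwise the mesh
#' contracts by 0.5. Stops when the mesh size falls below `tol` (relative to
#' the box) or the evaluation budget is exhausted.
#'
#' @param objective function of a numeric vector, to minimize; must be
#'   finite at `start`
#' @param start initial point (inside the box)
#' @param lower,upper box constraints
#' @param tol relative mesh tolerance (default 1e-6)
#' @param max_evals evaluation budget (default 20000)
#' @param step0 initial mesh size as a fraction of the box (default 0.25)
#' @return list with `par`, `value`, `evals`, `converged`
#' @export
pattern_search <- function(objective, start, lower, upper,
                           tol = 1e-6, max_evals = 20000, step0 = 0.25) {
  d <- length(start)
  x <- pmin(pmax(as.numeric(start), lower), upper)
  fx <- objective(x)
  if (!is.finite(fx)) stop("objective not finite at start")
  range_ <- upper - lower
  delta <- step0 * range_
  evals <- 1L
  while (max(delta / range_) >= tol && evals < max_evals) {
    best_f <- fx; best_x <- NULL
    for (i in seq_len(d)) {
      for (s in c(1, -1)) {
        xi <- x
        xi[i] <- min(max(x[i] + s * delta[i], lower[i]), upper[i])
        if (xi[i] == x[i]) next
        fi <- objective(xi)
        evals <- evals + 1L
        if (is.finite(fi) && fi < best_f) { best_f <- fi; best_x <- xi }
        if (evals >= max_evals) break
      }
      if (evals >= max_evals) break
    }
    if (!is.null(best_x)) {
      x <- best_x; fx <- best_f
      delta <- pmin(delta * 2, step0 * range_)
    } else {
      delta <- delta * 0.5
    }
  }
  list(par = x, value = fx, evals = evals,
       converged = max(delta / range_) < tol)
}

#' Adaptive Metropolis configuration
#'
#' Defaults follow the study configuration: initial proposal covariance
#' `C0 = 0.01 * I` until step `t0 = 100`, thereafter `s_d * (Cov + eps I)`
#' with `s_d = 0.2` and `eps = 1e-20`; 4 chains of 100,000 iterations with a
#' 20,000-step burn-in, chain starts drawn around the global optimum with a
#' 5 percent coefficient of variation.
#'
#' @param C0 initial proposal covariance scale
#' @param t0 adaptation onset (steps)
#' @param s_d covariance scaling factor
#' @param eps covariance regularization
#' @param n_iter iterations per chain
#' @param n_chains number of chains
#' @param burn_in steps discarded per chain
#' @param start_cv coefficient of variation for chain start jitter
#' @param seed RNG seed
#' @return list of class `am_config`
#' @export
am_config <- function(C0 = 0.01, t0 = 100, s_d = 0.2, eps = 1e-20,
                      n_iter = 100000, n_chains = 4, burn_in = 20000,
                      start_cv = 0.05, seed = NULL) {
  stopifnot(C0 > 0, t0 > 0, s_d > 0, eps > 0, n_chains >= 1,
            burn_in > 0, burn_in < n_iter, start_cv >= 0)
  structure(list(C0 = C0, t0 = t0, s_d = s_d, eps = eps, n_iter = n_iter,
                 n_chains = n_chains, burn_in = burn_in,
                 start_cv = start_cv, seed = seed),
            class = "am_config")
}

## one Haario chain; returns samples (n_iter x d), log posts, accept flags
.am_chain <- function(log_post, x0, cfg) {
  d <- length(x0)
  n <- cfg$n_iter
  out <- matrix(NA_real_, n, d)
  lps <- numeric(n)
  acc <- logical(n)
  x <- x0
  lp <- log_post(x)
  if (!is.finite(lp)) stop("log posterior not finite at chain start")
  m <- x                      # running mean
  C <- matrix(0, d, d)        # running sample covariance
  R0 <- diag(sqrt(cfg$C0), d) # fixed pre-adaptation proposal chol
  sqeps <- cfg$eps
  for (t in seq_len(n)) {
    if (t <= cfg$t0) {
      prop <- x + R0 %*% rnorm(d)
    } else {
      Cp <- cfg$s_d * (C + diag(sqeps, d))
      R <- tryCatch(chol(Cp), error = function(e) NULL)
      prop <- if (is.null(R)) x + R0 %*% rnorm(d) else x + crossprod(R, rnorm(d))
    }
    prop <- as.numeric(prop)
    lpp <- log_post(prop)
    if (is.finite(lpp) && log(runif(1)) < lpp - lp) {
      x <- prop; lp <- lpp; acc[t] <- TRUE
    }
    out[t, ] <- x
    lps[t] <- lp
    ## recursive sample mean / covariance of the history x_1..x_t
    dm <- x - m
    m <- m + dm / t
    if (t >= 2) {
      C <- C * ((t - 2) / (t - 1)) + tcrossprod(dm) / t
    }
  }
  list(samples = out, log_post = lps, accepted = acc)
}

#' Adaptive Metropolis sampler
#'
#' Haario-style random-walk Metropolis: the proposal is `N(x, C0 I)` for the
#' first `t0` steps and `N(x, s_d (Cov(history) + eps I))` afterwards, with
#' the history covariance updated recursively. Each chain starts at a draw
#' from `N(start, (start_cv |start|)^2)` (componentwise), so chains explore
#' the neighborhood of the supplied optimum.
#'
#' @param log_post function returning the log posterior of a numeric vector
#' @param start center of the chain start distribution (e.g. the global
#'   optimum from [pattern_search()]); must have finite `log_post`
#' @param cfg an [am_config()]
#' @return object of class `rtk_chains`: list with `chains` (list of
#'   per-chain sample matrices), `log_post`, `accepted`, `burn_in`,
#'   `acceptance` (post-burn-in fraction per chain), and `cfg`
#' @export
adaptive_metropolis <- function(log_post, start, cfg = am_config()) {
  start <- as.numeric(start)
  run <- function() {
    chains <- vector("list", cfg$n_chains)
    for (k in seq_len(cfg$n_chains)) {
      x0 <- start
      for (try in 1:50) {
        cand <- rnorm(length(start), start, cfg$start_cv * abs(start))
        if (is.finite(log_post(cand))) { x0 <- cand; break }
      }
      chains[[k]] <- .am_chain(log_post, x0, cfg)
    }
    chains
  }
  chains <- with_seed(cfg$seed, run())
  post <- seq(cfg$burn_in + 1, cfg$n_iter)
  accep <- vapply(chains, function(ch) mean(ch$accepted[post]), numeric(1))
  if (any(accep == 0)) warning("a chain accepted no proposals after burn-in")
  structure(list(chains = lapply(chains, `[[`, "samples"),
                 log_post = lapply(chains, `[[`, "log_post"),
                 accepted = lapply(chains, `[[`, "accepted"),
                 burn_in = cfg$burn_in, acceptance = accep, cfg = cfg),
            class = "rtk_chains")
}

#' Pooled post-burn-in samples
#'
#' @param x a `rtk_chains` or `rtk_fit` object
#' @return matrix of samples, chains stacked, burn-in discarded
#' @export
posterior_samples <- function(x) {
  if (inherits(x, "rtk_fit")) x <- x$chains
  stopifnot(inherits(x, "rtk_chains"))
  post <- seq(x$burn_in + 1, nrow(x$chains[[1]]))
  do.call(rbind, lapply(x$chains, function(s) s[post, , drop = FALSE]))
}

#' Gelman-Rubin potential scale reduction
#'
#' \deqn{\hat R = \sqrt{((n-1)/n \, W + B/n) / W}}
#' with `W` the mean within-chain variance and `B` the between-chain
#' variance of the chain means (times `n`). Computed on post-burn-in
#' samples.
#'
#' @param chains a `rtk_chains` object, or a list of equal-length sample
#'   matrices (no burn-in removal applied in that case)
#' @return named (if column names exist) vector of per-parameter R-hat;
#'   `NaN` where the within-chain variance is zero
#' @export
gelman_rubin <- function(chains) {
  if (inherits(chains, "rtk_chains")) {
    post <- seq(chains$burn_in + 1, nrow(chains$chains[[1]]))
    mats <- lapply(chains$chains, function(s) s[post, , drop = FALSE])
  } else {
    mats <- lapply(chains, as.matrix)
  }
  m <- length(mats)
  if (m < 2) stop("need at least 2 chains")
  n <- unique(vapply(mats, nrow, integer(1)))
  if (length(n) != 1) stop("chains must have equal length")
  d <- ncol(mats[[1]])
  vapply(seq_len(d), function(j) {
    xs <- vapply(mats, function(s) mean(s[, j]), numeric(1))
    W <- mean(vapply(mats, function(s) var(s[, j]), numeric(1)))
    B <- n * var(xs)
    if (W == 0) return(NaN)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1)) |>
    setNames(colnames(mats[[1]]))
}

## Precomputed fast equivalent of log_posterior() on the scaled sampler
## space; agreement with the public composition is asserted in the tests.
.make_logpost_z <- function(data, priors, fs_prior, init_priors, inits0,
                            init_scale, estimate_inits) {
  kin_names <- c("p_syn", "k_deg", "k_end", "k_rec", "k_shed")
  kind <- vapply(priors[kin_names], `[[`, character(1), "kind")
  is_ln <- kind == "lognormal10"
  mu_p <- vapply(priors[kin_names], function(s) s$mu %||% 0, numeric(1))
  sd_p <- vapply(priors[kin_names], function(s) s$sigma %||% 1, numeric(1))
  lo_p <- vapply(priors[kin_names], function(s) s$bounds[1], numeric(1))
  hi_p <- vapply(priors[kin_names], function(s) s$bounds[2], numeric(1))
  mu_p[!is_ln] <- 0; sd_p[!is_ln] <- 1
  half <- 0.5 * log(2 * pi)
  prior_const <- -sum(log(sd_p[is_ln])) - sum(is_ln) * half

  tn_logz <- function(sp) log(pnorm(sp$bounds[2], sp$mu, sp$sigma) -
                                pnorm(sp$bounds[1], sp$mu, sp$sigma))
  fs_mu <- fs_prior$mu %||% NA_real_
  fs_sd <- fs_prior$sigma %||% NA_real_
  fs_logz <- if (!is.null(fs_prior)) tn_logz(fs_prior) else 0
  ip <- init_priors
  ip_mu <- unname(vapply(ip, `[[`, numeric(1), "mu"))
  ip_sd <- unname(vapply(ip, `[[`, numeric(1), "sigma"))
  ip_logz <- unname(vapply(ip, tn_logz, numeric(1)))

  sig <- data$sigma
  stats <- function(y) {
    ly <- log10(y)
    c(n = length(ly), s1 = sum(ly), s2 = sum(ly * ly))
  }
  st_ly <- stats(data$endpoint_lysate)
  censored <- data$supernatant_censored
  st_sup <- if (!censored) stats(data$endpoint_supernatant) else NULL
  n_cens <- length(data$endpoint_supernatant)
  lloq_ep <- data$lloq * data$endpoint_duration_min / 60
  st_tot <- t(apply(data$timecourse_total, 1, stats))
  st_int <- t(apply(data$timecourse_internal, 1, stats))
  times_tc <- data$times_tc
  horizon <- data$endpoint_duration_min
  s_ly <- sig[["endpoint_lysate"]]; s_sup <- sig[["endpoint_supernatant"]]
  s_tot <- sig[["timecourse_total"]]; s_int <- sig[["timecourse_internal"]]
  blk <- function(m, st, s) {
    -(st[["n"]] * m * m - 2 * m * st[["s1"]] + st[["s2"]]) / (2 * s * s) -
      st[["n"]] * (log(s) + half)
  }

  function(z) {
    kin <- z[1:5]
    if (any(kin < lo_p) || any(kin > hi_p)) return(-Inf)
    lp <- prior_const - sum(((kin - mu_p)^2 / (2 * sd_p^2))[is_ln])
    p_syn <- 10^kin[1]; k_deg <- 10^kin[2]; k_end <- 10^kin[3]
    k_rec <- 10^kin[4]; k_shed <- 10^kin[5]
    fi <- .internal_fraction(k_deg, k_end, k_rec)
    if (!is.na(fs_mu)) {
      fs <- 1 - fi
      lp <- lp - (fs - fs_mu)^2 / (2 * fs_sd^2) - log(fs_sd) - half - fs_logz
    }
    if (estimate_inits) {
      rt0 <- z[6] * init_scale[1]
      tc_ri0 <- z[7] * init_scale[2]
      tc_rt0 <- z[8] * init_scale[3]
      if (rt0 < 0 || tc_ri0 < 0 || tc_rt0 < tc_ri0) return(-Inf)
      x <- c(rt0, tc_ri0, tc_rt0)
      lp <- lp + sum(-(x - ip_mu)^2 / (2 * ip_sd^2) - log(ip_sd) - half -
                       ip_logz)
    } else {
      rt0 <- inits0[["rt0"]]; tc_ri0 <- inits0[["tc_ri0"]]
      tc_rt0 <- inits0[["tc_rt0"]]
    }

    ep <- .traj_core(p_syn, k_deg, k_end, k_rec, k_shed,
                     rt0 * fi, rt0 * (1 - fi), 0, horizon)
    lys <- ep$ri[1] + ep$rs[1]
    if (!is.finite(lys) || lys <= 0) return(-Inf)
    ll <- blk(log10(lys), st_ly, s_ly)
    sup <- ep$rf[1]
    if (censored) {
      if (is.finite(lloq_ep) && sup > lloq_ep) {
        ll <- ll - n_cens * (log10(sup) - log10(lloq_ep))^2 / (2 * s_sup^2)
      }
    } else {
      if (!is.finite(sup) || sup <= 0) return(-Inf)
      ll <- ll + blk(log10(sup), st_sup, s_sup)
    }

    pc <- .traj_core(0, k_deg, k_end, k_rec, k_shed,
                     tc_ri0, tc_rt0 - tc_ri0, 0, times_tc)
    tot <- pc$ri + pc$rs
    if (any(!is.finite(tot)) || any(tot <= 0) || any(pc$ri <= 0)) return(-Inf)
    lt <- log10(tot); li <- log10(pc$ri)
    for (j in seq_along(times_tc)) {
      ll <- ll + blk(lt[j], st_tot[j, ], s_tot) + blk(li[j], st_int[j, ], s_int)
    }
    unname(lp + ll)
  }
}

#' Fit the trafficking model to one condition
#'
#' The study's two-stage scheme: latin-hypercube start sites, a
#' derivative-free pattern search from every start (the best final value is
#' taken as the global optimum; ties break by first-found start), then
#' adaptive Metropolis chains seeded around the optimum. The sampled vector
#' is `(log10 P_syn, log10 k_deg, log10 k_end, log10 k_rec, log10 k_shed,
#' rt0, tc_ri0, tc_rt0)`; when `estimate_inits = FALSE` the three initial
#' conditions are fixed at the data means and only the five kinetic
#' parameters are sampled. Internally the end-point initial total `rt0` is
#' rescaled by the lysate data mean so every sampler coordinate is O(1)
#' under the fixed initial proposal covariance; reported samples are on the
#' natural scale.
#'
#' @param data an [experiment_set()]; if `sigma` is unset it is estimated
#'   from this set alone
#' @param priors named list of [prior_spec()] for the kinetic parameters
#'   (default [default_priors()])
#' @param cfg an [am_config()]
#' @param n_starts pattern-search start sites (default 100)
#' @param ps_max_evals pattern-search evaluation budget per start
#' @param estimate_inits sample initial conditions jointly with the kinetics
#'   (default `TRUE`)
#' @param fs_prior truncated-normal prior on the steady-state surface
#'   fraction; default mean 0.85, sd 0.1 on [0, 1]; `NULL` disables
#' @param rt0_prior list `(mean, sd)` for the end-point initial lysate
#'   total. This is the pre-treatment cell state, so when fitting a treated
#'   condition pass the control condition's lysate mean and sd; the default
#'   (the fitted condition's own replicates) is only appropriate for
#'   control fits
#' @param seed RNG seed (overrides `cfg$seed`)
#' @return object of class `rtk_fit`: `chains` (`rtk_chains`, natural
#'   scale), `map`, `map_value` (log posterior at the optimum), `summary`
#'   (per-parameter mean/sd/quantiles), `rhat`, `acceptance`, `sigma`,
#'   `priors`, `start_values` (pattern-search optima per start)
#' @export
fit_condition <- function(data, priors = default_priors(), cfg = am_config(),
                          n_starts = 100, ps_max_evals = 2000,
                          estimate_inits = TRUE,
                          fs_prior = prior_spec("truncnormal", 0.85, 0.1,
                                                c(0, 1)),
                          rt0_prior = NULL, seed = NULL) {
  stopifnot(inherits(data, "experiment_set"))
  if (is.null(data$sigma)) data$sigma <- estimate_sigma(data)
  seed <- seed %||% cfg$seed %||% 1L
  inits0 <- .default_inits(data)
  if (is.null(rt0_prior)) {
    rt0_prior <- list(mean = mean(data$endpoint_lysate),
                      sd = sd(data$endpoint_lysate))
  }
  inits0[["rt0"]] <- rt0_prior$mean
  rt_scale <- inits0[["rt0"]]
  rt_sd <- max(rt0_prior$sd, 1e-6 * rt_scale)
  init_priors <- list(
    rt0 = prior_spec("truncnormal", inits0[["rt0"]], rt_sd, c(0, Inf)),
    tc_ri0 = prior_spec("truncnormal", inits0[["tc_ri0"]], 10, c(0, Inf)),
    tc_rt0 = prior_spec("truncnormal", inits0[["tc_rt0"]], 10, c(0, Inf)))

  ## search box: prior bounds where finite, else the study's optimization
  ## bounds ([-6, 0] log10 rates, [0, 5] log10 synthesis)
  kin_names <- c("p_syn", "k_deg", "k_end", "k_rec", "k_shed")
  box_lo <- c(p_syn = 0, k_deg = -6, k_end = -6, k_rec = -6, k_shed = -6)
  box_hi <- c(p_syn = 5, k_deg = 0, k_end = 0, k_rec = 0, k_shed = 0)
  lower_kin <- vapply(kin_names, function(nm) {
    b <- priors[[nm]]$bounds[1]
    if (is.finite(b)) b else box_lo[[nm]]
  }, numeric(1))
  upper_kin <- vapply(kin_names, function(nm) {
    b <- priors[[nm]]$bounds[2]
    if (is.finite(b)) b else box_hi[[nm]]
  }, numeric(1))

  if (estimate_inits) {
    ## sampler space: log10 kinetics + initial conditions rescaled by their
    ## data means so every coordinate is O(1) under the fixed C0
    init_scale <- pmax(inits0, 1e-12)
    to_theta <- function(z) {
      setNames(c(z[1:5], z[6:8] * init_scale), .theta_names)
    }
    lower <- c(lower_kin, max(1e-3, 1 - 5 * rt_sd / rt_scale), 1e-3, 1e-3)
    upper <- c(upper_kin, 1 + 5 * rt_sd / rt_scale, 5, 5)
  } else {
    to_theta <- function(z) {
      setNames(c(z[1:5], inits0), .theta_names)
    }
    lower <- lower_kin
    upper <- upper_kin
  }
  log_post_z <- .make_logpost_z(data, priors, fs_prior, init_priors, inits0,
                                if (estimate_inits) init_scale else NULL,
                                estimate_inits)
  obj <- function(z) -log_post_z(z)

  starts <- lhs_starts(n_starts, lower, upper,
                       seed = derive_seed(seed, "lhs"))
  if (estimate_inits) {
    ## anchor the nuisance coordinates at their data means for the search
    starts[, 6:8] <- 1
  }
  results <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    fi <- obj(starts[i, ])
    if (!is.finite(fi)) { results[[i]] <- list(value = Inf); next }
    results[[i]] <- pattern_search(obj, starts[i, ], lower, upper,
                                   max_evals = ps_max_evals)
  }
  values <- vapply(results, `[[`, numeric(1), "value")
  if (all(!is.finite(values))) stop("no pattern-search start had a finite posterior")
  best <- which.min(values)   # first-found tie break
  z_opt <- results[[best]]$par

  cfg$seed <- derive_seed(seed, "am")
  chains_z <- adaptive_metropolis(log_post_z, z_opt, cfg)

  ## back to the natural scale for reporting
  nat_names <- if (estimate_inits) .theta_names else kin_names
  chains_nat <- lapply(chains_z$chains, function(s) {
    if (estimate_inits) {
      s[, 6:8] <- sweep(s[, 6:8, drop = FALSE], 2, init_scale, `*`)
    }
    colnames(s) <- nat_names
    s
  })
  chains <- chains_z
  chains$chains <- chains_nat

  samp <- posterior_samples(chains)
  qs <- t(apply(samp, 2, quantile, c(0.05, 0.5, 0.95)))
  summary_df <- data.frame(parameter = colnames(samp),
                           mean = colMeans(samp),
                           sd = apply(samp, 2, sd),
                           q05 = qs[, 1], median = qs[, 2], q95 = qs[, 3],
                           row.names = NULL)
  map_theta <- to_theta(z_opt)
  structure(list(chains = chains,
                 map = map_theta[nat_names],
                 map_value = -values[best],
                 start_values = -values,
                 summary = summary_df,
                 rhat = gelman_rubin(chains),
                 acceptance = chains$acceptance,
                 sigma = data$sigma,
                 priors = priors,
                 estimate_inits = estimate_inits),
            class = "rtk_fit")
}

#' @export
print.rtk_fit <- function(x, ...) {
  cat("Trafficking model fit (", length(x$chains$chains), " chains, ",
      nrow(x$chains$chains[[1]]), " iterations, burn-in ",
      x$chains$burn_in, ")\n", sep = "")
  cat("acceptance:", paste(signif(x$acceptance, 3), collapse = " "), "\n")
  cat("max R-hat:", signif(max(x$rhat, na.rm = TRUE), 4), "\n\n")
  print(x$summary, digits = 4)
  invisible(x)
}
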