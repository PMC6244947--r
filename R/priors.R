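## Prior construction for the trafficking parameters: literature-anchored
## log10-normal priors, the Monte-Carlo data-derived shedding prior, the
## censored-analyte uniform shedding prior, truncated-normal nonparametric
## priors (surface fraction, initial conditions), and treatment-prior
## updates from control posteriors.

#' Build a single prior specification
#'
#' @param kind one of `"lognormal10"` (normal on the log10-transformed
#'   value), `"uniform"` (flat on log10 between `bounds`), or
#'   `"truncnormal"` (normal on the raw value truncated to `bounds`)
#' @param mu location: mean log10 value for `lognormal10`, raw-scale mean
#'   for `truncnormal`, ignored for `uniform`
#' @param sigma spread (must be > 0 for the normal kinds)
#' @param bounds length-2 inclusive support limits
#' @return object of class `prior_spec`
#' @export
prior_spec <- function(kind = c("lognormal10", "uniform", "truncnormal"),
                       mu = NA_real_, sigma = NA_real_,
                       bounds = c(-Inf, Inf)) {
  kind <- match.arg(kind)
  if (kind %in% c("lognormal10", "truncnormal")) {
    if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0 for ", kind)
    if (!is.finite(mu)) stop("mu must be finite for ", kind)
  }
  if (kind == "uniform" && !(bounds[1] < bounds[2])) {
    stop("uniform prior needs bounds[1] < bounds[2]")
  }
  structure(list(kind = kind, mu = mu, sigma = sigma,
                 bounds = as.numeric(bounds)),
            class = "prior_spec")
}

#' Default literature-anchored priors for the kinetic parameters
#'
#' Wide log10-normal priors centered on low-end literature estimates for
#' receptor trafficking: 10^-2 min^-1 for degradation, endocytosis and
#' recycling, and 10^2 molecules cell^-1 min^-1 for synthesis. The default
#' spread of 2 decades reflects ignorance of the true rate for any given
#' receptor and condition.
#'
#' @param sigma_p prior sd in log10 decades (default 2)
#' @param kshed optional `prior_spec` for the shedding rate (usually from
#'   [estimate_kshed_prior()] or [censored_kshed_prior()]); defaults to the
#'   same anchor as the other rates
#' @return named list of `prior_spec`, one per kinetic parameter
#' @export
default_priors <- function(sigma_p = 2, kshed = NULL) {
  rate_bounds <- c(-6, 0)    # log10 min^-1
  syn_bounds <- c(0, 5)      # log10 molecules/cell/min
  list(
    p_syn  = prior_spec("lognormal10", mu = 2,  sigma = sigma_p, bounds = syn_bounds),
    k_deg  = prior_spec("lognormal10", mu = -2, sigma = sigma_p, bounds = rate_bounds),
    k_end  = prior_spec("lognormal10", mu = -2, sigma = sigma_p, bounds = rate_bounds),
    k_rec  = prior_spec("lognormal10", mu = -2, sigma = sigma_p, bounds = rate_bounds),
    k_shed = kshed %||%
      prior_spec("lognormal10", mu = -2, sigma = sigma_p, bounds = rate_bounds)
  )
}

#' Data-derived Monte-Carlo prior for the shedding rate
#'
#' Under a time-invariant surface pool the shed fraction integrates to
#' \deqn{k_{shed} = r_f / (r_t f_s \Delta t)}
#' so a prior for `k_shed` follows by propagating the replicate variability
#' of the end-point supernatant (`r_f`) and lysate (`r_t`) measurements and
#' the surface-fraction distribution `f_s` (truncated normal, mean 0.85,
#' sd 0.1, support [0, 1]) through this relation by Monte Carlo. The log10
#' draws are summarized as a `lognormal10` prior.
#'
#' @param rf_mean,rf_sd mean and sd of the supernatant replicates,
#'   molecules/cell accumulated over the end-point window
#' @param rt_mean,rt_sd mean and sd of the lysate replicates, molecules/cell
#' @param dt_min end-point duration, minutes (default 1440)
#' @param fs_mean,fs_sd surface-fraction distribution
#' @param n_iter Monte-Carlo draws (default 10000)
#' @param seed RNG seed
#' @return a `lognormal10` [prior_spec()] with the mean and sd of the valid
#'   log10 draws
#' @export
estimate_kshed_prior <- function(rf_mean, rf_sd, rt_mean, rt_sd,
                                 dt_min = 1440, fs_mean = 0.85, fs_sd = 0.1,
                                 n_iter = 10000, seed = NULL) {
  if (rt_mean <= 0) stop("lysate mean must be > 0")
  if (dt_min <= 0) stop("end-point duration must be > 0")
  with_seed(seed, {
    fs <- rtruncnorm(n_iter, fs_mean, fs_sd, 0, 1)
    rf <- rnorm(n_iter, rf_mean, rf_sd)
    rt <- rnorm(n_iter, rt_mean, rt_sd)
    k <- rf / (rt * fs * dt_min)
    k <- k[is.finite(k) & k > 0]
    if (length(k) == 0) stop("no valid k_shed draws (all non-positive)")
    lk <- log10(k)
    prior_spec("lognormal10", mu = mean(lk),
               sigma = max(sd(lk), .Machine$double.eps),
               bounds = c(-6, 0))
  })
}

#' Uniform shedding prior for a censored (below-LLOQ) analyte
#'
#' When no supernatant signal is detected, the hourly shedding flux is
#' modeled as Uniform(1, LLOQ) molecules cell^-1 h^-1 and propagated to
#' `k_shed = flux / (60 r_t f_s)` per minute. The minimum and maximum of the
#' sampled log10 rates become the bounds of a uniform prior.
#'
#' @param lloq assay LLOQ, molecules cell^-1 h^-1 (must exceed 1)
#' @param rt_mean,rt_sd lysate replicate mean and sd, molecules/cell
#' @param fs_mean,fs_sd surface-fraction distribution
#' @param n_iter Monte-Carlo draws
#' @param seed RNG seed
#' @return a `uniform` [prior_spec()] on log10 `k_shed`
#' @export
censored_kshed_prior <- function(lloq, rt_mean, rt_sd,
                                 fs_mean = 0.85, fs_sd = 0.1,
                                 n_iter = 10000, seed = NULL) {
  if (!is.finite(lloq) || lloq <= 1) stop("LLOQ must exceed 1 molecule/cell/h")
  if (rt_mean <= 0) stop("lysate mean must be > 0")
  with_seed(seed, {
    flux <- runif(n_iter, 1, lloq)                # molecules/cell/h
    fs <- rtruncnorm(n_iter, fs_mean, fs_sd, 0, 1)
    rt <- rnorm(n_iter, rt_mean, rt_sd)
    k <- flux / (60 * rt * fs)                    # min^-1
    k <- k[is.finite(k) & k > 0]
    if (length(k) == 0) stop("no valid k_shed draws")
    prior_spec("uniform", bounds = range(log10(k)))
  })
}

#' Log prior density of a parameter vector
#'
#' Sums per-parameter contributions: for `lognormal10` kinds the normal
#' log-density of the log10 value, for `uniform` kinds 0 inside the support
#' and -Inf outside, and for `truncnormal` kinds the truncated-normal
#' log-density of the raw value. Hard bounds return -Inf when violated.
#'
#' @param theta named numeric vector; entries for `lognormal10`/`uniform`
#'   priors are log10 values, entries for `truncnormal` priors raw values
#' @param priors named list of [prior_spec()] matching `theta`
#' @return scalar log density (up to the uniform kinds' normalizing constant)
#' @export
log_prior <- function(theta, priors) {
  total <- 0
  for (nm in names(priors)) {
    sp <- priors[[nm]]
    x <- theta[[nm]]
    if (x < sp$bounds[1] || x > sp$bounds[2]) return(-Inf)
    total <- total + switch(sp$kind,
      lognormal10 = -((x - sp$mu)^2) / (2 * sp$sigma^2) - log(sp$sigma) -
        0.5 * log(2 * pi),
      uniform = 0,
      truncnormal = dtruncnorm_log(x, sp$mu, sp$sigma, sp$bounds[1],
                                   sp$bounds[2]))
  }
  total
}

#' Update priors from a control-condition posterior
#'
#' For comparative (treated) conditions the kinetic priors are re-centered
#' on the control posterior: per parameter the new location is the posterior
#' mean of the log10 value and the new spread is twice the posterior sd,
#' loose enough to follow treatment-induced shifts while anchoring to the
#' control estimate. Uniform priors keep their bounds.
#'
#' @param priors named list of [prior_spec()] (the control priors)
#' @param posterior matrix of post-burn-in log10 parameter samples with
#'   columns named as `priors`, or a `rtk_fit` object
#' @param rhat optional named vector of Gelman-Rubin statistics; a warning is
#'   issued if any exceeds `rhat_threshold`
#' @param rhat_threshold convergence cut (default 1.1)
#' @return updated named list of `prior_spec`
#' @export
update_treatment_priors <- function(priors, posterior, rhat = NULL,
                                    rhat_threshold = 1.1) {
  if (inherits(posterior, "rtk_fit")) {
    if (is.null(rhat)) rhat <- posterior$rhat
    posterior <- posterior_samples(posterior)
  }
  if (!is.null(rhat) && any(rhat > rhat_threshold, na.rm = TRUE)) {
    warning("control chains not converged (max R-hat = ",
            signif(max(rhat, na.rm = TRUE), 4), "); priors updated anyway")
  }
  out <- priors
  for (nm in names(priors)) {
    if (!nm %in% colnames(posterior)) next
    if (priors[[nm]]$kind == "uniform") next
    s <- sd(posterior[, nm])
    if (!is.finite(s) || s == 0) stop("degenerate posterior for ", nm,
                                      ": zero sd would give an improper prior")
    out[[nm]] <- prior_spec(priors[[nm]]$kind,
                            mu = mean(posterior[, nm]), sigma = 2 * s,
                            bounds = priors[[nm]]$bounds)
  }
  out
}

#' Serialize / deserialize a prior set
#'
#' Priors round-trip through a plain named-list config block suitable for
#' YAML or JSON.
#'
#' @param priors named list of [prior_spec()]
#' @param config named list as produced by `priors_to_config`
#' @return `priors_to_config`: a plain list; `priors_from_config`: a named
#'   list of `prior_spec`
#' @export
priors_to_config <- function(priors) {
  lapply(priors, function(sp) list(kind = sp$kind, mu = sp$mu,
                                   sigma = sp$sigma, bounds = sp$bounds))
}

#' @rdname priors_to_config
#' @export
priors_from_config <- function(config) {
  lapply(config, function(x) prior_spec(x$kind, x$mu %||% NA_real_,
                                        x$sigma %||% NA_real_,
                                        unlist(x$bounds)))
}
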