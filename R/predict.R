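## Mechanistic attribution of treatment-induced abundance changes:
## single-parameter-substitution fold changes, posterior-resampled data
## envelopes, and the distribution-overlap metric.

## 24-h lysate total from a parameter set, starting from rt0 split by the
## candidate steady-state internal fraction (rt0 = 0 starts from empty cells)
.lysate_at <- function(params, rt0, horizon) {
  fi <- .internal_fraction(params[["k_deg"]], params[["k_end"]],
                           params[["k_rec"]])
  tr <- .traj_core(params[["p_syn"]], params[["k_deg"]], params[["k_end"]],
                   params[["k_rec"]], params[["k_shed"]],
                   ri0 = rt0 * fi, rs0 = rt0 * (1 - fi), rf0 = 0,
                   times = horizon)
  tr$ri[1] + tr$rs[1]
}

#' Single-parameter-substitution fold changes
#'
#' Attributes a treatment's predicted lysate change to individual rates:
#' each treated parameter mean is substituted, one at a time, into the
#' control parameter vector; the 24-h simulated lysate under the hybrid
#' vector divided by the control-simulated lysate is that parameter's
#' predicted fold change. The full substitution (all five at once)
#' reproduces the treated simulation.
#'
#' @param control_means,treated_means [rate_params()] (typically posterior
#'   means of log10 parameters back-transformed; see [posterior_means()])
#' @param rt0 initial lysate total, molecules/cell (0 starts from empty
#'   cells)
#' @param horizon simulation horizon, minutes (default 1440)
#' @return data frame with one row per parameter plus a `"all"` row for the
#'   full substitution; columns `parameter`, `fold_change`
#' @export
single_param_substitution <- function(control_means, treated_means, rt0,
                                      horizon = 1440) {
  if (!inherits(control_means, "rate_params")) {
    control_means <- do.call(rate_params, as.list(control_means))
  }
  if (!inherits(treated_means, "rate_params")) {
    treated_means <- do.call(rate_params, as.list(treated_means))
  }
  base <- .lysate_at(control_means, rt0, horizon)
  if (!is.finite(base) || base <= 0) stop("control-simulated lysate is not positive")
  nms <- names(control_means)
  fc <- vapply(nms, function(nm) {
    hybrid <- unclass(control_means)
    hybrid[nm] <- treated_means[[nm]]
    .lysate_at(do.call(rate_params, as.list(hybrid)), rt0, horizon) / base
  }, numeric(1))
  full <- .lysate_at(treated_means, rt0, horizon) / base
  data.frame(parameter = c(nms, "all"),
             fold_change = c(fc, full), row.names = NULL)
}

#' Posterior means of the kinetic parameters
#'
#' Reduces a fit to a single parameter vector: the mean of the sampled log10
#' values back-transformed (default, consistent with the sampled space), or
#' the arithmetic mean of the raw values.
#'
#' @param fit a `rtk_fit` (or a sample matrix with kinetic columns)
#' @param scale `"log10"` (geometric mean) or `"raw"`
#' @return a [rate_params()] object
#' @export
posterior_means <- function(fit, scale = c("log10", "raw")) {
  scale <- match.arg(scale)
  samp <- if (is.matrix(fit)) fit else posterior_samples(fit)
  kin <- samp[, c("p_syn", "k_deg", "k_end", "k_rec", "k_shed"), drop = FALSE]
  v <- if (scale == "log10") 10^colMeans(kin) else colMeans(10^kin)
  rate_params(v[["p_syn"]], v[["k_deg"]], v[["k_end"]], v[["k_rec"]],
              v[["k_shed"]])
}

#' Resampled simulation envelopes
#'
#' Draws a fraction of whole post-burn-in parameter vectors (never
#' per-coordinate, preserving parameter covariation), simulates every
#' experiment type under each draw, and returns the min/max and quantile
#' envelopes per observable and time point — the simulated-data ranges
#' plotted against experimental replicates.
#'
#' @param fit a `rtk_fit` from [fit_condition()]
#' @param data the [experiment_set()] the fit used (defines time points and
#'   the end-point horizon)
#' @param fraction fraction of post-burn-in samples to draw (default 0.10)
#' @param probs quantiles to report alongside the range
#' @param seed RNG seed
#' @return data frame with columns `observable, time_min, min, max` and one
#'   column per quantile
#' @export
resample_envelope <- function(fit, data, fraction = 0.10,
                              probs = c(0.025, 0.975), seed = NULL) {
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  samp <- posterior_samples(fit)
  n_draw <- max(1L, floor(fraction * nrow(samp)))
  idx <- with_seed(seed, sample.int(nrow(samp), n_draw))
  has_inits <- all(c("rt0", "tc_ri0", "tc_rt0") %in% colnames(samp))
  inits0 <- .default_inits(data)
  sims <- lapply(idx, function(i) {
    th <- samp[i, ]
    params <- params_from_log10(th[c("p_syn", "k_deg", "k_end", "k_rec",
                                     "k_shed")])
    rt0 <- if (has_inits) th[["rt0"]] else inits0[["rt0"]]
    tci <- if (has_inits) th[["tc_ri0"]] else inits0[["tc_ri0"]]
    tct <- if (has_inits) th[["tc_rt0"]] else inits0[["tc_rt0"]]
    fi <- .internal_fraction(params[["k_deg"]], params[["k_end"]],
                             params[["k_rec"]])
    ep <- .traj_core(params[["p_syn"]], params[["k_deg"]], params[["k_end"]],
                     params[["k_rec"]], params[["k_shed"]],
                     rt0 * fi, rt0 * (1 - fi), 0,
                     data$endpoint_duration_min)
    pc <- .traj_core(0, params[["k_deg"]], params[["k_end"]],
                     params[["k_rec"]], params[["k_shed"]],
                     tci, tct - tci, 0, data$times_tc)
    c(endpoint_lysate = ep$ri[1] + ep$rs[1],
      endpoint_supernatant = ep$rf[1],
      setNames(pc$ri + pc$rs, paste0("timecourse_total@", data$times_tc)),
      setNames(pc$ri, paste0("timecourse_internal@", data$times_tc)))
  })
  mat <- do.call(rbind, sims)
  keys <- strsplit(colnames(mat), "@", fixed = TRUE)
  out <- data.frame(
    observable = vapply(keys, `[`, character(1), 1),
    time_min = vapply(keys, function(k) {
      if (length(k) > 1) as.numeric(k[2]) else data$endpoint_duration_min
    }, numeric(1)),
    min = apply(mat, 2, min),
    max = apply(mat, 2, max), row.names = NULL)
  for (p in probs) out[[paste0("q", p)]] <- apply(mat, 2, quantile, p)
  out
}

#' Overlap fraction between two posterior distributions
#'
#' Forms `n` random paired differences (treated minus control) and returns
#' the smaller of the fractions above and below zero — 0.5 for identical
#' continuous distributions, 0 for fully separated ones. Used as the
#' unchanged-parameter criterion in the PCA variable matrices.
#'
#' @param control_samples,treated_samples numeric sample vectors
#' @param n number of paired differences (default 10000)
#' @param seed RNG seed
#' @return overlap fraction in [0, 0.5]
#' @export
overlap_fraction <- function(control_samples, treated_samples, n = 10000,
                             seed = NULL) {
  stopifnot(length(control_samples) > 0, length(treated_samples) > 0)
  with_seed(seed, {
    d <- sample(treated_samples, n, replace = TRUE) -
      sample(control_samples, n, replace = TRUE)
    min(mean(d > 0), mean(d < 0))
  })
}
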