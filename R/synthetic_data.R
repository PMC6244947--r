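## Ground-truth-parameterized synthetic datasets with the study design:
## four receptor analogs, 24-h end points (n = 12), pulse-chase time courses
## (n = 18, t = 5/20/45/75/90 min, normalized to the first-time-point total
## mean), log-normal measurement noise with experiment-type-specific spread,
## LLOQ censoring, and 5PL standard curves with background wells.

.default_rtks <- function() {
  list(
    Axl  = rate_params(p_syn = 200, k_deg = 0.010, k_end = 0.006,
                       k_rec = 0.020, k_shed = 2e-4),
    Met  = rate_params(p_syn = 300, k_deg = 0.012, k_end = 0.008,
                       k_rec = 0.025, k_shed = 1.2e-3),
    EGFR = rate_params(p_syn = 250, k_deg = 0.008, k_end = 0.005,
                       k_rec = 0.015, k_shed = 5e-5),
    Her2 = rate_params(p_syn = 30,  k_deg = 0.010, k_end = 0.004,
                       k_rec = 0.018, k_shed = 1e-5)
  )
}

.preset_effects <- function(name, rtks) {
  one <- function() setNames(rep(1, 5), c("p_syn", "k_deg", "k_end",
                                          "k_rec", "k_shed"))
  eff <- setNames(lapply(rtks, function(...) one()), rtks)
  mod <- function(rtk, ...) {
    ch <- c(...)
    eff[[rtk]][names(ch)] <<- ch
  }
  switch(name,
    control = NULL,
    egf_like = {           # ligand stimulation: faster EGFR/Her2 endocytosis
      mod("EGFR", k_end = 3); mod("Her2", k_end = 3)
    },
    batimastat_like = {    # metalloprotease inhibition: Axl/Met shedding down
      mod("Axl", k_shed = 0.2); mod("Met", k_shed = 0.2)
    },
    mek_like = {           # Mek inhibition: Axl/Her2 synthesis up, broad
                           # endocytosis decrease, Axl/Met degradation and
                           # shedding down
      mod("Axl", p_syn = 2.5, k_deg = 0.4, k_end = 0.5, k_shed = 0.5)
      mod("Her2", p_syn = 2.5, k_deg = 0.5, k_end = 0.6)
      mod("Met", k_deg = 0.6, k_end = 0.6, k_shed = 0.5)
      mod("EGFR", k_end = 0.6)
    },
    erk_tki_like = {       # Erk TKI: synthesis up across receptors
      for (r in rtks) mod(r, p_syn = 2)
    },
    stop("unknown treatment preset: ", name))
  eff
}

#' Synthetic study scenario
#'
#' Defines the ground truth of a simulated experiment: per-receptor control
#' trafficking rates, per-treatment multiplicative parameter effects, noise
#' scales, replicate counts, chase times, and the assay LLOQ. Presets mirror
#' the qualitative effect directions of the perturbations studied:
#' `egf_like` (endocytosis up for EGFR/Her2), `batimastat_like` (shedding
#' down for Axl/Met), `mek_like` (synthesis up and degradation/endocytosis
#' down for Axl/Her2, broad endocytosis decrease), `erk_tki_like`
#' (synthesis up only).
#'
#' @param treatments character vector of treatment presets to include
#'   (always includes `"control"`)
#' @param rtks named list of [rate_params()]; defaults to four receptor
#'   analogs with realistic abundances (1e5-1e6 molecules/cell for
#'   Axl/Met/EGFR), hourly shed fractions near 1 and 6 percent for the
#'   Axl/Met analogs, a surface fraction near 0.85, and a Her2 analog whose
#'   supernatant falls below the LLOQ
#' @param sigma named log10-scale noise sds per experiment type
#' @param n_endpoint end-point replicates (default 12)
#' @param n_timecourse time-course replicates per time point (default 18)
#' @param times_tc chase times, minutes
#' @param lloq assay LLOQ, molecules cell^-1 h^-1 (default 89)
#' @param fs_mean,fs_sd surface-fraction distribution used by the priors
#' @param effects optional custom effects overriding the presets: nested
#'   named list `effects[[treatment]][[rtk]]` of multipliers
#' @return object of class `rtk_scenario`
#' @export
scenario <- function(treatments = c("control", "mek_like"),
                     rtks = .default_rtks(),
                     sigma = c(endpoint_lysate = 0.10,
                               endpoint_supernatant = 0.15,
                               timecourse_total = 0.06,
                               timecourse_internal = 0.10),
                     n_endpoint = 12, n_timecourse = 18,
                     times_tc = c(5, 20, 45, 75, 90),
                     lloq = 89, fs_mean = 0.85, fs_sd = 0.1,
                     effects = NULL) {
  treatments <- union("control", treatments)
  eff <- lapply(setNames(treatments, treatments), function(trt) {
    if (!is.null(effects) && trt %in% names(effects)) {
      lapply(effects[[trt]], unlist)
    } else if (trt == "control") {
      lapply(rtks, function(...) setNames(rep(1, 5), c("p_syn", "k_deg",
                                                       "k_end", "k_rec",
                                                       "k_shed")))
    } else {
      .preset_effects(trt, names(rtks))
    }
  })
  for (trt in treatments) {
    bad <- unlist(eff[[trt]]) <= 0
    if (any(bad)) stop("treatment effects must be > 0")
  }
  structure(list(treatments = treatments, rtks = rtks, effects = eff,
                 sigma = sigma, n_endpoint = n_endpoint,
                 n_timecourse = n_timecourse, times_tc = times_tc,
                 lloq = lloq, fs_mean = fs_mean, fs_sd = fs_sd),
            class = "rtk_scenario")
}

#' True parameters of one receptor under one treatment
#' @param sc a [scenario()]
#' @param rtk,treatment names within the scenario
#' @return a [rate_params()] object
#' @export
true_params <- function(sc, rtk, treatment) {
  stopifnot(inherits(sc, "rtk_scenario"))
  base <- unclass(sc$rtks[[rtk]])
  mult <- sc$effects[[treatment]][[rtk]]
  do.call(rate_params, as.list(base * mult[names(base)]))
}

.noisy_log10 <- function(truth, n, sigma) {
  10^(log10(truth) + rnorm(n, 0, sigma))
}

#' Simulate a 24-h end-point experiment
#'
#' Cells start at the control steady state (the pre-treatment state); the
#' treated parameter set then acts for 1440 min. The lysate total is split
#' between surface and internal pools by the steady-state fraction of the
#' simulating parameters, matching the convention used by the likelihood.
#' Replicates are drawn log-normally around the simulated truth; a
#' supernatant whose true accumulation falls below the LLOQ is reported as
#' censored (`NA` values).
#'
#' @param sc a [scenario()]
#' @param rtk,treatment condition to simulate
#' @param seed RNG seed
#' @return list with `lysate`, `supernatant` (replicate vectors),
#'   `supernatant_censored`, `truth` (noiseless lysate/supernatant and
#'   `rt0`), and `params`
#' @export
generate_endpoint <- function(sc, rtk, treatment, seed = NULL) {
  p <- true_params(sc, rtk, treatment)
  rt0 <- steady_state(sc$rtks[[rtk]])$r_t
  fi <- .internal_fraction(p[["k_deg"]], p[["k_end"]], p[["k_rec"]])
  tr <- .traj_core(p[["p_syn"]], p[["k_deg"]], p[["k_end"]], p[["k_rec"]],
                   p[["k_shed"]], rt0 * fi, rt0 * (1 - fi), 0, 1440)
  lys <- tr$ri[1] + tr$rs[1]
  sup <- tr$rf[1]
  lloq_ep <- sc$lloq * 24
  with_seed(seed, {
    lys_rep <- .noisy_log10(lys, sc$n_endpoint, sc$sigma[["endpoint_lysate"]])
    censored <- sup < lloq_ep
    sup_rep <- if (censored) rep(NA_real_, sc$n_endpoint) else
      .noisy_log10(sup, sc$n_endpoint, sc$sigma[["endpoint_supernatant"]])
    list(lysate = lys_rep, supernatant = sup_rep,
         supernatant_censored = censored,
         truth = list(lysate = lys, supernatant = sup, rt0 = rt0),
         params = p)
  })
}

#' Simulate a pulse-chase time-course experiment
#'
#' The labeled cohort starts as one unit of surface label; the treated
#' parameter set traffics it over the chase times. Noisy total and internal
#' replicates are drawn log-normally, then every replicate is divided by the
#' mean measured total signal at the first time point, so the normalized
#' total at t = `times_tc[1]` has mean 1 by construction.
#'
#' @inheritParams generate_endpoint
#' @return list with `total`, `internal` (time x replicate matrices,
#'   normalized), `times`, `truth` (noiseless normalized trajectories), and
#'   `params`
#' @export
generate_timecourse <- function(sc, rtk, treatment, seed = NULL) {
  p <- true_params(sc, rtk, treatment)
  tr <- .traj_core(0, p[["k_deg"]], p[["k_end"]], p[["k_rec"]], p[["k_shed"]],
                   ri0 = 0, rs0 = 1, rf0 = 0, times = sc$times_tc)
  tot <- tr$ri + tr$rs
  int <- tr$ri
  nt <- length(sc$times_tc); nr <- sc$n_timecourse
  with_seed(seed, {
    tot_m <- matrix(.noisy_log10(rep(tot, nr), nt * nr,
                                 sc$sigma[["timecourse_total"]]), nt, nr)
    int_m <- matrix(.noisy_log10(rep(int, nr), nt * nr,
                                 sc$sigma[["timecourse_internal"]]), nt, nr)
    norm <- mean(tot_m[1, ])
    list(total = tot_m / norm, internal = int_m / norm,
         times = sc$times_tc,
         truth = list(total = tot / tot[1], internal = int / tot[1]),
         params = p)
  })
}

#' Simulate a standard curve with background wells
#'
#' 5PL readouts at a concentration grid plus blank wells, with additive
#' normal noise, in the standard-curve CSV dialect.
#'
#' @param a,d,c,b,g 5PL parameters (see [fit_5pl()])
#' @param concentrations standard concentrations, pg
#' @param n_rep replicates per standard
#' @param noise_sd additive readout noise, MFU
#' @param n_background blank wells
#' @param background_mean mean blank readout, MFU
#' @param analyte analyte label
#' @param seed RNG seed
#' @return data frame with columns `analyte, concentration_pg, mfu,
#'   is_background`
#' @export
generate_standard_curve <- function(a, d, c, b, g,
                                    concentrations = 2^(0:9) * 1,
                                    n_rep = 2, noise_sd = 0,
                                    n_background = 4, background_mean = a,
                                    analyte = "analyte", seed = NULL) {
  with_seed(seed, {
    x <- rep(concentrations, each = n_rep)
    y <- .eval_5pl(x, a, d, c, b, g) + rnorm(length(x), 0, noise_sd)
    bg <- rep(background_mean, n_background) + rnorm(n_background, 0, noise_sd)
    rbind(data.frame(analyte = analyte, concentration_pg = x, mfu = y,
                     is_background = FALSE),
          data.frame(analyte = analyte, concentration_pg = 0, mfu = bg,
                     is_background = TRUE))
  })
}

#' Generate a full synthetic study bundle
#'
#' Simulates every receptor x treatment combination of a scenario (end
#' point and time course), packs each condition into an [experiment_set()],
#' and records a ground-truth manifest for recovery scoring.
#'
#' @param sc a [scenario()]
#' @param seed RNG seed; per-condition seeds are derived deterministically
#' @return list of class `rtk_study`: `data[[treatment]][[rtk]]`
#'   ([experiment_set()]), `manifest` (true parameters and noiseless
#'   observables per condition), `scenario`, `sigma_hat` (noise scales
#'   estimated from the generated replicates, as used for fitting)
#' @export
make_study <- function(sc, seed = 1) {
  stopifnot(inherits(sc, "rtk_scenario"))
  data <- list(); manifest <- list()
  for (trt in sc$treatments) {
    data[[trt]] <- list()
    manifest[[trt]] <- list()
    for (rtk in names(sc$rtks)) {
      ep <- generate_endpoint(sc, rtk, trt,
                              seed = derive_seed(seed, paste("ep", trt, rtk)))
      tc <- generate_timecourse(sc, rtk, trt,
                                seed = derive_seed(seed, paste("tc", trt, rtk)))
      data[[trt]][[rtk]] <- experiment_set(
        endpoint_lysate = ep$lysate,
        endpoint_supernatant = ep$supernatant,
        timecourse_total = tc$total,
        timecourse_internal = tc$internal,
        times_tc = sc$times_tc,
        supernatant_censored = ep$supernatant_censored,
        lloq = sc$lloq)
      manifest[[trt]][[rtk]] <- list(
        params = as.list(unclass(ep$params)),
        rt0 = ep$truth$rt0,
        endpoint_truth = ep$truth[c("lysate", "supernatant")],
        timecourse_truth = tc$truth)
    }
  }
  sigma_hat <- estimate_sigma(unlist(data, recursive = FALSE))
  for (trt in names(data)) {
    for (rtk in names(data[[trt]])) data[[trt]][[rtk]]$sigma <- sigma_hat
  }
  structure(list(data = data, manifest = manifest, scenario = sc,
                 sigma_hat = sigma_hat),
            class = "rtk_study")
}
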