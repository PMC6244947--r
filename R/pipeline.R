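## Orchestration and file dialects: write/read the study CSV formats,
## validate tables, and run the full simulate -> priors -> fit -> predict ->
## PCA pipeline from a single seeded config.

#' Write a synthetic study bundle to CSV + JSON
#'
#' End-point measurements go to `endpoint.csv` (columns `cell_line,
#' treatment, rtk, compartment, replicate, value`), time courses to
#' `timecourse.csv` (columns `cell_line, treatment, rtk, readout, time_min,
#' replicate, value`), and the ground-truth manifest to `manifest.json`.
#'
#' @param study a `rtk_study` from [make_study()]
#' @param dir output directory (created if missing)
#' @param cell_line label used in the tables
#' @return named vector of file paths, invisibly
#' @export
write_study <- function(study, dir, cell_line = "cellA") {
  stopifnot(inherits(study, "rtk_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ep <- list(); tc <- list()
  for (trt in names(study$data)) {
    for (rtk in names(study$data[[trt]])) {
      d <- study$data[[trt]][[rtk]]
      ep[[length(ep) + 1L]] <- data.frame(
        cell_line = cell_line, treatment = trt, rtk = rtk,
        compartment = rep(c("lysate", "supernatant"), each = d$n[["endpoint"]]),
        replicate = rep(seq_len(d$n[["endpoint"]]), 2),
        value = c(d$endpoint_lysate, d$endpoint_supernatant))
      nt <- length(d$times_tc); nr <- d$n[["timecourse"]]
      tc[[length(tc) + 1L]] <- data.frame(
        cell_line = cell_line, treatment = trt, rtk = rtk,
        readout = rep(c("total", "internal"), each = nt * nr),
        time_min = rep(rep(d$times_tc, nr), 2),
        replicate = rep(rep(seq_len(nr), each = nt), 2),
        value = c(as.numeric(d$timecourse_total),
                  as.numeric(d$timecourse_internal)))
    }
  }
  paths <- c(endpoint = file.path(dir, "endpoint.csv"),
             timecourse = file.path(dir, "timecourse.csv"),
             manifest = file.path(dir, "manifest.json"))
  write.csv(do.call(rbind, ep), paths[["endpoint"]], row.names = FALSE)
  write.csv(do.call(rbind, tc), paths[["timecourse"]], row.names = FALSE)
  jsonlite::write_json(study$manifest, paths[["manifest"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Validate study table files
#'
#' Checks column schemas (header-keyed, any order), replicate counts,
#' strictly increasing time points, and value sanity (no negative
#' concentrations or readout times).
#'
#' @param paths named list/vector with any of `endpoint`, `timecourse`,
#'   `standard_curve` pointing to CSV files
#' @return character vector of diagnostics; empty when all checks pass
#' @export
validate_tables <- function(paths) {
  diags <- character(0)
  note <- function(...) diags <<- c(diags, paste0(...))
  check <- function(path, need, what) {
    if (!file.exists(path)) { note(what, ": file not found: ", path); return(NULL) }
    d <- read.csv(path)
    missing <- setdiff(need, names(d))
    if (length(missing)) {
      note(what, ": missing columns: ", paste(missing, collapse = ", "))
      return(NULL)
    }
    d
  }
  if (!is.null(paths[["endpoint"]])) {
    d <- check(paths[["endpoint"]],
               c("cell_line", "treatment", "rtk", "compartment", "replicate",
                 "value"), "endpoint")
    if (!is.null(d)) {
      if (!all(d$compartment %in% c("lysate", "supernatant"))) {
        note("endpoint: compartment must be lysate or supernatant")
      }
      if (any(d$value < 0, na.rm = TRUE)) note("endpoint: negative values")
      cnt <- table(d$cell_line, d$treatment, d$rtk, d$compartment)
      if (length(unique(cnt[cnt > 0])) > 1) {
        note("endpoint: unbalanced replicate counts across conditions")
      }
    }
  }
  if (!is.null(paths[["timecourse"]])) {
    d <- check(paths[["timecourse"]],
               c("cell_line", "treatment", "rtk", "readout", "time_min",
                 "replicate", "value"), "timecourse")
    if (!is.null(d)) {
      if (any(d$time_min < 0)) note("timecourse: negative time points")
      if (any(d$value < 0, na.rm = TRUE)) note("timecourse: negative values")
      for (key in split(d, list(d$cell_line, d$treatment, d$rtk, d$readout,
                                d$replicate), drop = TRUE)) {
        if (is.unsorted(sort(unique(key$time_min)), strictly = TRUE)) {
          note("timecourse: non-increasing time points")
          break
        }
      }
    }
  }
  if (!is.null(paths[["standard_curve"]])) {
    d <- check(paths[["standard_curve"]],
               c("analyte", "concentration_pg", "mfu", "is_background"),
               "standard_curve")
    if (!is.null(d)) {
      if (any(d$concentration_pg < 0)) {
        note("standard_curve: negative concentrations")
      }
      if (any(!d$is_background & d$concentration_pg <= 0)) {
        note("standard_curve: non-background standards must have concentration > 0")
      }
    }
  }
  diags
}

#' Read a study bundle back from CSV
#'
#' Inverse of [write_study()] for a single cell line: reconstructs one
#' [experiment_set()] per treatment x receptor.
#'
#' @param dir directory holding `endpoint.csv` and `timecourse.csv`
#' @param lloq assay LLOQ passed through to the sets
#' @return nested list `data[[treatment]][[rtk]]`
#' @export
read_study <- function(dir, lloq = 89) {
  ep <- read.csv(file.path(dir, "endpoint.csv"))
  tc <- read.csv(file.path(dir, "timecourse.csv"))
  out <- list()
  for (trt in unique(ep$treatment)) {
    out[[trt]] <- list()
    for (rtk in unique(ep$rtk[ep$treatment == trt])) {
      e <- ep[ep$treatment == trt & ep$rtk == rtk, ]
      t_ <- tc[tc$treatment == trt & tc$rtk == rtk, ]
      times <- sort(unique(t_$time_min))
      getmat <- function(readout) {
        s <- t_[t_$readout == readout, ]
        s <- s[order(s$replicate, s$time_min), ]
        matrix(s$value, nrow = length(times))
      }
      sup <- e$value[e$compartment == "supernatant"]
      out[[trt]][[rtk]] <- experiment_set(
        endpoint_lysate = e$value[e$compartment == "lysate"],
        endpoint_supernatant = sup,
        timecourse_total = getmat("total"),
        timecourse_internal = getmat("internal"),
        times_tc = times,
        supernatant_censored = all(is.na(sup)),
        lloq = lloq)
    }
  }
  out
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> noise-scale estimation -> prior construction ->
#' per-condition fitting -> mechanistic attribution -> PCA from a single
#' config, writing artifacts and a run manifest under `out_dir`. Every
#' stochastic stage derives its seed deterministically from the global
#' `seed`, so two runs with the same config are numerically identical.
#'
#' @param config named list (or path to a YAML file) with fields:
#'   `out_dir`; `seed`; `treatments` (character, default
#'   `c("control", "mek_like")`); `rtks` (subset of the scenario receptors,
#'   default all); `am` (list overriding [am_config()] fields); `n_starts`;
#'   `estimate_inits`; `overlap_cut`; `cell_line`
#' @return list of class `rtk_report`: `fits`, `attribution`, `pca`,
#'   `rhat`, `paths`, `config`
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  seed <- config$seed %||% 1L
  treatments <- config$treatments %||% c("control", "mek_like")
  cell_line <- config$cell_line %||% "cellA"
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## simulate
  sc <- stage("simulate", scenario(treatments = treatments))
  if (!is.null(config$rtks)) sc$rtks <- sc$rtks[config$rtks]
  study <- stage("simulate", make_study(sc, seed = derive_seed(seed, "study")))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- write_study(study, file.path(config$out_dir, "data"), cell_line)

  ## priors: shedding prior from control end-point data, literature anchors
  ## for the remaining rates; treated conditions re-anchored on the control
  ## posterior
  amc <- do.call(am_config, config$am %||% list())
  n_starts <- config$n_starts %||% 100
  estimate_inits <- config$estimate_inits %||% TRUE
  fits <- list()
  fits[[cell_line]] <- list()
  for (trt in sc$treatments) fits[[cell_line]][[trt]] <- list()
  for (rtk in names(sc$rtks)) {
    ctrl_data <- study$data[["control"]][[rtk]]
    kshed_prior <- stage("priors", {
      if (ctrl_data$supernatant_censored) {
        censored_kshed_prior(sc$lloq, mean(ctrl_data$endpoint_lysate),
                             sd(ctrl_data$endpoint_lysate),
                             sc$fs_mean, sc$fs_sd,
                             seed = derive_seed(seed, paste("kshed", rtk)))
      } else {
        estimate_kshed_prior(mean(ctrl_data$endpoint_supernatant),
                             sd(ctrl_data$endpoint_supernatant),
                             mean(ctrl_data$endpoint_lysate),
                             sd(ctrl_data$endpoint_lysate),
                             fs_mean = sc$fs_mean, fs_sd = sc$fs_sd,
                             seed = derive_seed(seed, paste("kshed", rtk)))
      }
    })
    priors <- default_priors(kshed = kshed_prior)
    ctrl_fit <- stage("fit", fit_condition(
      ctrl_data, priors, amc, n_starts = n_starts,
      estimate_inits = estimate_inits,
      seed = derive_seed(seed, paste("fit control", rtk))))
    fits[[cell_line]][["control"]][[rtk]] <- ctrl_fit
    for (trt in setdiff(sc$treatments, "control")) {
      trt_priors <- stage("priors",
                          update_treatment_priors(priors, ctrl_fit))
      fits[[cell_line]][[trt]][[rtk]] <- stage("fit", fit_condition(
        study$data[[trt]][[rtk]], trt_priors, amc, n_starts = n_starts,
        estimate_inits = estimate_inits,
        rt0_prior = list(mean = mean(ctrl_data$endpoint_lysate),
                         sd = sd(ctrl_data$endpoint_lysate)),
        seed = derive_seed(seed, paste("fit", trt, rtk))))
    }
  }

  rhat <- do.call(rbind, lapply(names(fits[[cell_line]]), function(trt) {
    do.call(rbind, lapply(names(fits[[cell_line]][[trt]]), function(rtk) {
      f <- fits[[cell_line]][[trt]][[rtk]]
      data.frame(treatment = trt, rtk = rtk,
                 max_rhat = max(f$rhat, na.rm = TRUE),
                 acceptance = mean(f$acceptance))
    }))
  }))

  ## predict + pca (skipped for control-only runs)
  attribution <- NULL; pca <- NULL
  if (length(sc$treatments) > 1) {
    attribution <- stage("predict", {
      do.call(rbind, lapply(setdiff(sc$treatments, "control"), function(trt) {
        do.call(rbind, lapply(names(sc$rtks), function(rtk) {
          cm <- posterior_means(fits[[cell_line]][["control"]][[rtk]])
          tm <- posterior_means(fits[[cell_line]][[trt]][[rtk]])
          rt0 <- study$manifest[["control"]][[rtk]]$rt0
          fc <- single_param_substitution(cm, tm, rt0)
          cbind(treatment = trt, rtk = rtk, fc)
        }))
      }))
    })
    pca <- stage("pca", {
      vm <- build_matrix(fits, mode = "param_means",
                         overlap_cut = config$overlap_cut %||% 0.25,
                         seed = derive_seed(seed, "overlap"))
      run_pca(zscore_by_cellline(vm))
    })
    write.csv(attribution, file.path(config$out_dir, "attribution.csv"),
              row.names = FALSE)
    write.csv(data.frame(row = rownames(pca$scores), pca$scores),
              file.path(config$out_dir, "pca_scores.csv"), row.names = FALSE)
    write.csv(data.frame(variable = rownames(pca$loadings), pca$loadings),
              file.path(config$out_dir, "pca_loadings.csv"),
              row.names = FALSE)
  } else {
    message("control-only run: predict and PCA stages skipped")
  }
  write.csv(rhat, file.path(config$out_dir, "rhat.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, treatments = sc$treatments, rtks = names(sc$rtks),
         sigma = as.list(study$sigma_hat),
         am = config$am %||% list(), n_starts = n_starts),
    file.path(config$out_dir, "run_manifest.json"),
    auto_unbox = TRUE, digits = NA)

  structure(list(fits = fits, attribution = attribution, pca = pca,
                 rhat = rhat, paths = paths, config = config,
                 study = study),
            class = "rtk_report")
}
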