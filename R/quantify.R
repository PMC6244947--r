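## Absolute receptor quantification: bead-ELISA mean-fluorescence readouts ->
## pg via a five-parameter logistic (5PL) standard curve -> molecules/cell via
## unit conversion, with LLOQ determination and control-offset normalization.

.eval_5pl <- function(x, a, d, c, b, g) {
  d + (a - d) / (1 + (x / c)^b)^g
}

#' Fit a five-parameter logistic standard curve
#'
#' Least-squares fit of the 5PL model
#' \deqn{y = d + (a - d) / (1 + (x/c)^b)^g}
#' to replicated standard readouts. `a` is the readout at zero concentration,
#' `d` the saturating asymptote, `c` the inflection concentration, `b` the
#' slope, and `g > 0` the asymmetry. Initial values come from asymptote and
#' midpoint heuristics; on failure the fit is retried from jittered starts.
#'
#' @param concentration standard concentrations, pg (strictly positive,
#'   replicates allowed)
#' @param mfu readouts (mean fluorescence units), same length
#' @param background optional vector of blank-well readouts, stored with the
#'   curve for LLOQ determination
#' @param n_restarts number of jittered restarts on non-convergence
#' @return object of class `standard_curve`: list with the five coefficients,
#'   `residual_norm`, and the data
#' @export
fit_5pl <- function(concentration, mfu, background = numeric(0),
                    n_restarts = 10) {
  stopifnot(length(concentration) == length(mfu))
  if (any(concentration <= 0)) stop("standard concentrations must be > 0")
  if (length(unique(concentration)) < 6) {
    stop("need at least 6 distinct standard concentrations")
  }
  if (sd(mfu) == 0) stop("degenerate standards: constant readouts")
  d0 <- data.frame(x = concentration, y = mfu)
  lo <- mean(mfu[concentration == min(concentration)])
  hi <- mean(mfu[concentration == max(concentration)])
  ## b > 0 puts asymptote a at x -> 0 and d at x -> Inf; starting on the
  ## right branch avoids the (a, d, b) <-> (d, a, -b) reflection
  start0 <- list(a = lo, d = hi, c = exp(mean(log(range(concentration)))),
                 b = 1.5, g = 1)
  fit <- NULL
  for (k in seq_len(n_restarts + 1)) {
    st <- start0
    if (k > 1) {
      jit <- function(v) v * exp(rnorm(1, 0, 0.3))
      st <- list(a = start0$a + rnorm(1, 0, 0.1 * abs(hi - lo) + 1e-6),
                 d = start0$d + rnorm(1, 0, 0.1 * abs(hi - lo) + 1e-6),
                 c = jit(start0$c), b = start0$b * exp(rnorm(1, 0, 0.3)),
                 g = jit(start0$g))
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ d + (a - d) / (1 + (x / c)^b)^g,
                        data = d0, start = st,
                        lower = c(a = -Inf, d = -Inf, c = 1e-12, b = -Inf,
                                  g = 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("5PL fit failed to converge after restarts")
  cf <- coef(fit)
  structure(list(a = unname(cf["a"]), d = unname(cf["d"]),
                 c = unname(cf["c"]), b = unname(cf["b"]),
                 g = unname(cf["g"]),
                 residual_norm = sqrt(sum(resid(fit)^2)),
                 concentration = concentration, mfu = mfu,
                 background = background),
            class = "standard_curve")
}

#' Predict readout from a fitted standard curve
#' @param curve a `standard_curve`
#' @param concentration pg values
#' @return predicted MFU
#' @export
predict_5pl <- function(curve, concentration) {
  stopifnot(inherits(curve, "standard_curve"))
  .eval_5pl(concentration, curve$a, curve$d, curve$c, curve$b, curve$g)
}

#' Invert a five-parameter logistic curve
#'
#' Analytic inverse of the 5PL: maps a readout back to concentration.
#' Readouts at or beyond the asymptotes cannot be inverted and are returned
#' as `NA` with a censoring flag.
#'
#' @param curve a `standard_curve` from [fit_5pl()]
#' @param mfu readouts to invert
#' @return data frame with columns `mfu`, `concentration_pg`, `censored`
#' @export
invert_5pl <- function(curve, mfu) {
  stopifnot(inherits(curve, "standard_curve"))
  a <- curve$a; d <- curve$d; b <- curve$b; g <- curve$g; cc <- curve$c
  lo <- min(a, d); hi <- max(a, d)
  out <- rep(NA_real_, length(mfu))
  ok <- mfu > lo & mfu < hi
  ratio <- (a - d) / (mfu[ok] - d)
  out[ok] <- cc * (ratio^(1 / g) - 1)^(1 / b)
  data.frame(mfu = mfu, concentration_pg = out, censored = !ok)
}

#' Convert analyte mass to receptor molecules per cell
#'
#' Unit conversion from pg of analyte in a measured aliquot to absolute
#' receptor abundance:
#' \deqn{r = m_r \, dil \, prot_{cell} \, N_A / (c_{prot} \, MW \, v_{lys})}
#' where `m_r` is in pg, `dil` the measured fraction of the sample,
#' `prot_cell` the protein content per cell (default 300 pg/cell),
#' `c_prot * v_lys` the total lysate protein in pg, and `MW` the standard's
#' molecular weight in g/mol.
#'
#' @param m_r analyte mass, pg (vectorized)
#' @param dil measured fraction of the lysate/supernatant, dimensionless
#' @param c_prot lysate total-protein concentration, pg per microliter
#' @param v_lys lysate volume, microliters
#' @param mw molecular weight of the recombinant standard, g/mol
#' @param prot_cell protein content per cell, pg/cell
#' @param n_avg Avogadro's number, mol^-1
#' @return receptor abundance, molecules/cell
#' @export
mass_to_molecules <- function(m_r, dil, c_prot, v_lys, mw,
                              prot_cell = 300, n_avg = 6.022e23) {
  ctx <- c(dil = dil, c_prot = c_prot, v_lys = v_lys, mw = mw,
           prot_cell = prot_cell, n_avg = n_avg)
  if (any(!is.finite(ctx)) || any(ctx <= 0)) {
    stop("all conversion context values must be finite and > 0")
  }
  if (any(m_r < 0)) stop("analyte mass must be non-negative")
  ## m_r pg -> g carries the 1e-12; prot_cell/(c_prot*v_lys) is pg/pg
  (m_r * 1e-12) * dil * prot_cell * n_avg / (c_prot * mw * v_lys)
}

#' Lower limit of quantitation of a standard curve
#'
#' The LLOQ is the lowest standard concentration whose mean readout exceeds
#' five times the mean background readout AND whose back-fitted concentration
#' is within 20 percent of its true value. Optionally converted from pg to a
#' molecules cell^-1 h^-1 shedding-flux equivalent via [mass_to_molecules()]
#' and the experiment duration.
#'
#' @param curve a `standard_curve` carrying background wells
#' @param quant_context optional list with fields `dil, c_prot, v_lys, mw,
#'   prot_cell, n_avg` passed to the unit conversion; well cell counts and
#'   volumes enter through `c_prot` and `v_lys`
#' @param duration_h experiment duration in hours used for the flux
#'   conversion (default 24)
#' @param background_factor multiple of mean background a standard must
#'   exceed (default 5)
#' @param backfit_tol relative back-fit accuracy required (default 0.2)
#' @return list with `lloq_pg` and, when a context is given,
#'   `lloq_molecules_per_cell_h`
#' @export
compute_lloq <- function(curve, quant_context = NULL, duration_h = 24,
                         background_factor = 5, backfit_tol = 0.2) {
  stopifnot(inherits(curve, "standard_curve"))
  if (length(curve$background) == 0) stop("no background wells recorded")
  bg <- mean(curve$background)
  concs <- sort(unique(curve$concentration))
  pass <- vapply(concs, function(x) {
    m <- mean(curve$mfu[curve$concentration == x])
    if (m <= background_factor * bg) return(FALSE)
    back <- invert_5pl(curve, m)
    !back$censored && is.finite(back$concentration_pg) &&
      abs(back$concentration_pg - x) <= backfit_tol * x
  }, logical(1))
  if (!any(pass)) stop("assay not quantitative: no standard passes the LLOQ rules")
  lloq_pg <- min(concs[pass])
  out <- list(lloq_pg = lloq_pg)
  if (!is.null(quant_context)) {
    qc <- quant_context
    mol <- mass_to_molecules(lloq_pg, qc$dil %||% 1, qc$c_prot, qc$v_lys,
                             qc$mw, qc$prot_cell %||% 300,
                             qc$n_avg %||% 6.022e23)
    out$lloq_molecules_per_cell_h <- mol / duration_h
  }
  out
}

#' Anchor a measurement batch to an absolute reference
#'
#' Multiplies every measurement in a batch (all treatments of one
#' experiment) by `reference_absolute / control_median`, the fold change
#' between the absolute quantitation value and the in-experiment control
#' median. Applied exactly once per batch; applying it twice compounds the
#' offset.
#'
#' @param values numeric vector of measurements, molecules/cell
#' @param control_median in-experiment median of the vehicle-control
#'   measurements
#' @param reference_absolute absolute quantitation value of the control
#'   condition
#' @return rescaled measurements
#' @export
apply_control_offset <- function(values, control_median, reference_absolute) {
  if (!is.finite(control_median) || control_median <= 0) {
    stop("control median must be finite and > 0")
  }
  if (!is.finite(reference_absolute) || reference_absolute <= 0) {
    stop("reference absolute value must be finite and > 0")
  }
  values * (reference_absolute / control_median)
}
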