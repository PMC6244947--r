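#' Five-rate trafficking parameter set
#'
#' Bundles the kinetic parameters of one receptor under one condition:
#' zeroth-order synthesis onto the cell surface and the four first-order
#' transport/loss rates between compartments.
#'
#' @param p_syn synthesis flux, molecules cell^-1 min^-1
#' @param k_deg degradation rate from the internal pool, min^-1
#' @param k_end endocytosis rate (surface -> internal), min^-1
#' @param k_rec recycling rate (internal -> surface), min^-1
#' @param k_shed ectodomain shedding rate (surface -> supernatant), min^-1
#' @return an object of class `rate_params` (named numeric vector)
#' @export
rate_params <- function(p_syn, k_deg, k_end, k_rec, k_shed) {
  p <- c(p_syn = p_syn, k_deg = k_deg, k_end = k_end,
         k_rec = k_rec, k_shed = k_shed)
  if (any(!is.finite(p))) stop("rate parameters must be finite")
  if (any(p < 0)) stop("rate parameters must be non-negative")
  structure(p, class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat("Trafficking rates (P_syn molecules/cell/min, others min^-1):\n")
  print(unclass(x))
  invisible(x)
}

## log10 representation; only defined for strictly positive rates
#' Convert rate parameters to/from log10 space
#'
#' The inference machinery operates on log10-transformed parameters;
#' these helpers move between the two representations.
#'
#' @param params a [rate_params()] object (all entries > 0)
#' @param theta numeric vector of length 5 in the order
#'   (log10 P_syn, log10 k_deg, log10 k_end, log10 k_rec, log10 k_shed)
#' @return `log10_params` returns the numeric log10 vector;
#'   `params_from_log10` returns a [rate_params()] object.
#' @export
log10_params <- function(params) {
  if (any(params <= 0)) stop("log10 representation requires all rates > 0")
  setNames(log10(as.numeric(params)),
           c("p_syn", "k_deg", "k_end", "k_rec", "k_shed"))
}

#' @rdname log10_params
#' @export
params_from_log10 <- function(theta) {
  stopifnot(length(theta) == 5L, all(is.finite(theta)))
  v <- 10^as.numeric(theta)
  rate_params(v[1], v[2], v[3], v[4], v[5])
}

#' Compartment state of one receptor
#'
#' @param r_s surface receptor, molecules/cell (or normalized label units)
#' @param r_i internal receptor, same units
#' @param r_f free shed ectodomain in the supernatant, same units
#' @return object of class `compartment_state`; the derived total
#'   `r_t = r_s + r_i` is stored alongside.
#' @export
compartment_state <- function(r_s, r_i, r_f = 0) {
  s <- c(r_s = r_s, r_i = r_i, r_f = r_f)
  if (any(!is.finite(s))) stop("compartment state must be finite")
  if (any(s < 0)) stop("compartment state must be non-negative")
  structure(c(s, r_t = r_s + r_i), class = "compartment_state")
}

## ---------------------------------------------------------------------------
## Core linear solver.
##
## State x = (r_i, r_s) obeys dx/dt = A x + b with
##   A = [ -(k_rec + k_deg)   k_end            ]
##       [  k_rec            -(k_end + k_shed) ],  b = (0, P_syn).
## A has real eigenvalues (its discriminant is (a11 - a22)^2 + 4 k_end k_rec
## >= 0), so the generic solution is a sum of two real exponentials about the
## fixed point -A^-1 b.  r_f follows by exact quadrature of k_shed * r_s(t).
## Degenerate cases (singular A with synthesis, near-coincident eigenvalues)
## fall back to a stiff integrator at tight tolerance; the closed form is
## validated against an independent integrator in the test suite.
## ---------------------------------------------------------------------------
.traj_core <- function(p_syn, k_deg, k_end, k_rec, k_shed,
                       ri0, rs0, rf0, times) {
  a11 <- -(k_rec + k_deg); a12 <- k_end
  a21 <- k_rec;            a22 <- -(k_end + k_shed)
  tr <- a11 + a22
  det <- a11 * a22 - a12 * a21
  disc <- tr * tr - 4 * det

  scale <- max(abs(a11), abs(a12), abs(a21), abs(a22), 1e-300)
  near_defective <- sqrt(max(disc, 0)) < 1e-9 * scale && scale > 1e-12
  singular <- abs(det) < 1e-14 * scale * scale

  if ((singular && p_syn > 0) || near_defective) {
    return(.traj_desolve(p_syn, k_deg, k_end, k_rec, k_shed,
                         ri0, rs0, rf0, times))
  }

  if (scale <= 1e-12) {
    ## all first-order rates zero: r_i constant, r_s grows linearly, r_f frozen
    ri <- rep(ri0, length(times))
    rs <- rs0 + p_syn * times
    rf <- rep(rf0, length(times))
    return(list(ri = ri, rs = rs, rf = rf))
  }

  ## particular solution (fixed point); zero vector for homogeneous systems
  if (p_syn > 0) {
    xp_i <- (a12 * p_syn) / det     # solve A x = -b
    xp_s <- (-a11 * p_syn) / det
  } else {
    xp_i <- 0; xp_s <- 0
  }

  sq <- sqrt(disc)
  l1 <- (tr + sq) / 2
  l2 <- (tr - sq) / 2

  ## eigenvectors (a12, l - a11), falling back to (l - a22, a21) when the
  ## first row is decoupled
  evec <- function(l) {
    v <- c(a12, l - a11)
    if (max(abs(v)) < 1e-12 * scale) v <- c(l - a22, a21)
    v / max(abs(v))
  }
  v1 <- evec(l1); v2 <- evec(l2)
  dv <- v1[1] * v2[2] - v2[1] * v1[2]
  if (abs(dv) < 1e-12) {
    return(.traj_desolve(p_syn, k_deg, k_end, k_rec, k_shed,
                         ri0, rs0, rf0, times))
  }
  d0_i <- ri0 - xp_i
  d0_s <- rs0 - xp_s
  c1 <- (d0_i * v2[2] - d0_s * v2[1]) / dv
  c2 <- (v1[1] * d0_s - v1[2] * d0_i) / dv

  e1 <- exp(l1 * times)
  e2 <- exp(l2 * times)
  ri <- xp_i + c1 * v1[1] * e1 + c2 * v2[1] * e2
  rs <- xp_s + c1 * v1[2] * e1 + c2 * v2[2] * e2

  ## r_f(t) = rf0 + k_shed * int_0^t r_s ; phi(l,t) = (e^{lt}-1)/l
  phi <- function(l, t) if (abs(l) < 1e-300) t else expm1(l * t) / l
  b1 <- c1 * v1[2]; b2 <- c2 * v2[2]
  rf <- rf0 + k_shed * (xp_s * times + b1 * phi(l1, times) + b2 * phi(l2, times))

  list(ri = ri, rs = rs, rf = rf)
}

.traj_desolve <- function(p_syn, k_deg, k_end, k_rec, k_shed,
                          ri0, rs0, rf0, times) {
  rhs <- function(t, y, parms) {
    list(c(k_end * y[2] - (k_rec + k_deg) * y[1],
           p_syn + k_rec * y[1] - (k_end + k_shed) * y[2],
           k_shed * y[2]))
  }
  tt <- times
  pre <- FALSE
  if (tt[1] > 0) { tt <- c(0, tt); pre <- TRUE }
  sol <- deSolve::lsoda(c(ri0, rs0, rf0), tt, rhs, NULL,
                        rtol = 1e-11, atol = 1e-11)
  if (pre) sol <- sol[-1, , drop = FALSE]
  list(ri = sol[, 2], rs = sol[, 3], rf = sol[, 4])
}

.check_sim_inputs <- function(params, init, times) {
  if (!inherits(params, "rate_params")) params <- do.call(rate_params, as.list(params))
  if (!inherits(init, "compartment_state")) {
    init <- compartment_state(init[["r_s"]], init[["r_i"]],
                              if ("r_f" %in% names(init)) init[["r_f"]] else 0)
  }
  if (length(times) < 1 || any(!is.finite(times)) || times[1] < 0 ||
      any(diff(times) <= 0)) {
    stop("times must be finite, strictly increasing, and start at >= 0")
  }
  list(params = params, init = init, times = as.numeric(times))
}

.as_trajectory <- function(times, core) {
  ## the exact solution is non-negative for non-negative inputs; snap
  ## rounding-level negatives to zero
  snap <- function(x) {
    eps <- 1e-9 * (1 + max(abs(x)))
    x[x < 0 & x > -eps] <- 0
    x
  }
  core <- lapply(core, snap)
  out <- data.frame(time_min = times,
                    r_s = core$rs, r_i = core$ri, r_f = core$rf,
                    r_t = core$rs + core$ri)
  class(out) <- c("rtk_trajectory", "data.frame")
  out
}

#' Simulate the full (synthesizing) trafficking model
#'
#' Solves the linear three-compartment system
#' \deqn{dr_i/dt = k_{end} r_s - (k_{rec} + k_{deg}) r_i}
#' \deqn{dr_s/dt = P_{syn} + k_{rec} r_i - (k_{end} + k_{shed}) r_s}
#' \deqn{dr_f/dt = k_{shed} r_s}
#' in closed form (real-eigenvalue decomposition of the 2x2 block plus exact
#' quadrature for the shed pool). Time is in minutes throughout; a 24-h
#' end-point experiment corresponds to `times = 1440`.
#'
#' @param params a [rate_params()] object
#' @param init a [compartment_state()] giving the state at `times[1]`'s origin
#'   (t = 0)
#' @param times strictly increasing simulation times, minutes
#' @return a `rtk_trajectory` data frame with columns
#'   `time_min, r_s, r_i, r_f, r_t`
#' @seealso [simulate_pulse_chase()], [steady_state()]
#' @export
simulate_full <- function(params, init, times) {
  z <- .check_sim_inputs(params, init, times)
  p <- z$params
  core <- .traj_core(p[["p_syn"]], p[["k_deg"]], p[["k_end"]], p[["k_rec"]],
                     p[["k_shed"]], z$init[["r_i"]], z$init[["r_s"]],
                     z$init[["r_f"]], z$times)
  .as_trajectory(z$times, core)
}

#' Simulate the labeled pool of a pulse-chase experiment
#'
#' Pulse-chase surface biotinylation tracks a labeled cohort only, so no new
#' (unlabeled) synthesis enters the labeled pool: the system is solved with
#' `P_syn = 0` regardless of `params`. The labeled total `r_t` is
#' non-increasing whenever `k_deg, k_shed >= 0`.
#'
#' @inheritParams simulate_full
#' @return a `rtk_trajectory` data frame
#' @export
simulate_pulse_chase <- function(params, init, times) {
  z <- .check_sim_inputs(params, init, times)
  p <- z$params
  core <- .traj_core(0, p[["k_deg"]], p[["k_end"]], p[["k_rec"]],
                     p[["k_shed"]], z$init[["r_i"]], z$init[["r_s"]],
                     z$init[["r_f"]], z$times)
  .as_trajectory(z$times, core)
}

#' Steady state of the trafficking model
#'
#' Solves the 2x2 linear system obtained by setting the surface and internal
#' time derivatives to zero. A finite fixed point exists iff the effective
#' drain `k_end + k_shed - k_end k_rec / (k_rec + k_deg)` is positive: some
#' receptor must irreversibly leave the cell. The shed pool grows without
#' bound, so `r_f` is reported as its accumulation rate `k_shed * r_s*`
#' (molecules cell^-1 min^-1).
#'
#' @param params a [rate_params()] object with `p_syn > 0`
#' @return list with elements `r_s`, `r_i`, `r_t`, `surface_fraction`, and
#'   `r_f_rate`
#' @export
steady_state <- function(params) {
  if (!inherits(params, "rate_params")) params <- do.call(rate_params, as.list(params))
  p_syn <- params[["p_syn"]]
  if (p_syn <= 0) stop("steady state requires p_syn > 0")
  k_deg <- params[["k_deg"]]; k_end <- params[["k_end"]]
  k_rec <- params[["k_rec"]]; k_shed <- params[["k_shed"]]
  denom <- k_rec + k_deg
  drain <- if (denom > 0) k_end + k_shed - k_end * k_rec / denom else k_shed
  if (!is.finite(drain) || drain <= 0) {
    stop("no steady state: effective drain k_end + k_shed - k_end*k_rec/(k_rec + k_deg) is not positive")
  }
  r_s <- p_syn / drain
  r_i <- if (denom > 0) k_end * r_s / denom else 0
  if (denom == 0 && k_end > 0) stop("no steady state: internal pool has no exit")
  list(r_s = r_s, r_i = r_i, r_t = r_s + r_i,
       surface_fraction = r_s / (r_s + r_i),
       r_f_rate = k_shed * r_s)
}

## steady-state internal fraction r_i*/r_t*; well-defined for all
## non-negative rates (used to split an observed lysate total)
.internal_fraction <- function(k_deg, k_end, k_rec) {
  denom <- k_rec + k_deg
  if (denom <= 0) return(if (k_end > 0) 1 else 0)
  ratio <- k_end / denom              # r_i / r_s at steady state
  ratio / (1 + ratio)
}

#' Observables derived from a trajectory
#'
#' Maps a simulated trajectory onto the measured quantities: total lysate
#' `r_t`, supernatant `r_f`, percent shed `r_f / r_t`, and surface fraction
#' `r_s / r_t`.
#'
#' @param traj a `rtk_trajectory` from [simulate_full()] or
#'   [simulate_pulse_chase()]
#' @return data frame with columns `time_min, r_t, r_f, percent_shed,
#'   surface_fraction`
#' @export
derived_observables <- function(traj) {
  stopifnot(inherits(traj, "rtk_trajectory"))
  if (any(traj$r_t <= 0)) stop("percent shed undefined where r_t = 0")
  data.frame(time_min = traj$time_min,
             r_t = traj$r_t,
             r_f = traj$r_f,
             percent_shed = traj$r_f / traj$r_t,
             surface_fraction = traj$r_s / traj$r_t)
}

#' Export / import trajectories as tidy CSV
#'
#' @param traj a `rtk_trajectory`
#' @param path file path
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a `rtk_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "rtk_trajectory"))
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  d <- read.csv(path)
  need <- c("time_min", "r_s", "r_i", "r_f", "r_t")
  if (!all(need %in% names(d))) stop("trajectory CSV must have columns ",
                                     paste(need, collapse = ", "))
  d <- d[, need]
  class(d) <- c("rtk_trajectory", "data.frame")
  d
}
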