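#' @keywords internal
"_PACKAGE"

#' @importFrom stats dnorm pnorm qnorm rnorm runif sd var median quantile
#'   setNames rbinom coef resid nls.control
#' @importFrom utils read.csv write.csv
NULL

## Deterministic sub-seed derivation: every stochastic stage of the pipeline
## pulls its own seed from the global one so stages can be re-run in isolation.
## Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- 0
  for (ch in utf8ToInt(as.character(stage))) {
    h <- (h * 31 + ch) %% 1014623L
  }
  as.integer((as.integer(seed) %% 1014623L) * 2099L + h) %% 2147483629L
}

## Evaluate a function under a local RNG state so callers' streams are
## untouched; seed = NULL means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## Truncated-normal draws by inverse-CDF; used for the surface-fraction
## distribution (mean 0.85, sd 0.1, support [0, 1]).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

## log-density of the truncated normal (normalized over [lower, upper])
dtruncnorm_log <- function(x, mean, sd, lower = -Inf, upper = Inf) {
  out <- rep(-Inf, length(x))
  ok <- x >= lower & x <= upper
  z <- pnorm(upper, mean, sd) - pnorm(lower, mean, sd)
  out[ok] <- dnorm(x[ok], mean, sd, log = TRUE) - log(z)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
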