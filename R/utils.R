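# Internal helpers shared across modules.

# Gas constant in cal mol^-1 K^-1 and the Celsius -> Kelvin offset.
# All public interfaces take temperatures in degrees Celsius and enthalpies
# in kcal/mol; conversion to K and cal/mol happens at the point of model
# evaluation.
.R_CAL <- 1.9872
.T0_K <- 273.15

celsius_to_kelvin <- function(t_celsius) t_celsius + .T0_K
kelvin_to_celsius <- function(t_kelvin) t_kelvin - .T0_K

#' @title Physical constants used by the package
#' @description Returns the gas constant (cal mol^-1 K^-1) and the
#'   Celsius-to-Kelvin offset used in every thermodynamic formula.
#' @return Named list with elements `R_cal` and `kelvin_offset`.
#' @export
physical_constants <- function() {
  list(R_cal = .R_CAL, kelvin_offset = .T0_K)
}

# Classed error so callers can distinguish failure modes programmatically.
dscfit_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "dscfit_error")))
}

stopifnot_positive <- function(x, name, class = "dscfit_invalid_input") {
  if (!all(is.finite(x)) || any(x <= 0)) {
    dscfit_stop(sprintf("`%s` must be finite and strictly positive", name),
                class)
  }
  invisible(x)
}

# Trapezoidal integral of y over x (x need not be uniform).
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Cumulative trapezoidal integral, same length as x, starting at 0.
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2)
}

# Run `expr` under a given RNG seed without disturbing the caller's RNG
# stream; generators are pure functions of (spec, seed).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Central-difference Jacobian of vector-valued f at x.
num_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(abs(x[j]), 1)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}
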