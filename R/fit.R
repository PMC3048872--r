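# Nonlinear least-squares estimation of the two-state, CD-melt and
# titration models. All fits use bounded Levenberg-Marquardt
# (minpack.lm::nls.lm) started from data-driven initial guesses; parameter
# uncertainties are Gauss-Newton standard errors from the Jacobian at the
# optimum. Scan-rate metadata never enters any fit: the analysis is an
# equilibrium one.

.FIT_CONTROL <- function() {
  minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10, ptol = 1e-10)
}

# Gauss-Newton standard errors for residual function f at optimum par.
gn_std_errors <- function(f, par, rss, n) {
  p <- length(par)
  J <- num_jacobian(f, par)
  dof <- max(n - p, 1)
  JtJ <- crossprod(J)
  # a numerically singular Jacobian means some parameter is not
  # identifiable from the data: report infinite uncertainty for it
  if (!all(is.finite(JtJ)) || rcond(JtJ) < 1e-12) {
    return(list(se = rep(Inf, p), cov = matrix(NA_real_, p, p)))
  }
  cov <- solve(JtJ) * rss / dof
  list(se = sqrt(pmax(diag(cov), 0)), cov = cov)
}

new_thermofit <- function(subclass, params, std_errors, cov, rss,
                          converged, n_points, data, fitted, call) {
  structure(list(params = params, std_errors = std_errors, cov = cov,
                 rss = rss, converged = converged, n_points = n_points,
                 data = data, fitted = fitted,
                 residuals = data$y - fitted, call = call),
            class = c(subclass, "thermofit"))
}

#' Data-driven initial guess for a two-state DSC fit
#'
#' The transition temperature starts at the peak position (ties broken
#' toward the lowest temperature), the calorimetric enthalpy at the
#' trapezoidal area under the curve, and the van't Hoff enthalpy by
#' inverting the peak-height identity
#' \eqn{C_p^{ex}(T_m) = \Delta H \Delta H^{VH} / (4 R T_m^2)}.
#'
#' @param excess an `excess`-stage [thermogram()] with a single dominant
#'   interior peak.
#' @return A [two_state_params()] object.
#' @export
guess_two_state <- function(excess) {
  if (excess$stage != "excess") {
    dscfit_stop("initial guess requires an excess-stage thermogram",
                "dscfit_invalid_input")
  }
  tt <- excess$temperature
  y <- excess$cp
  cp_max <- max(y)
  if (!is.finite(cp_max) || cp_max <= 0) {
    dscfit_stop("no positive unfolding peak found", "dscfit_no_transition")
  }
  i <- which(y == cp_max)[1]
  if (i == 1 || i == length(y)) {
    dscfit_stop("peak lies at the grid edge; no interior transition",
                "dscfit_no_transition")
  }
  tm <- tt[i]
  dh_cal <- trapz(tt, y)
  if (dh_cal <= 0) {
    dscfit_stop("non-positive peak area; no transition",
                "dscfit_no_transition")
  }
  dh_vh <- 4 * .R_CAL * celsius_to_kelvin(tm)^2 * cp_max / (dh_cal * 1000)
  two_state_params(tm, dh_cal, dh_vh)
}

#' Fit the two-state model to an excess thermogram
#'
#' Least-squares fit of [two_state_excess_cp()] to an excess heat-capacity
#' curve, estimating the transition temperature, the calorimetric enthalpy
#' and the van't Hoff enthalpy. Starting values come from
#' [guess_two_state()]; enthalpies are constrained positive. The fit is
#' deterministic given the data.
#'
#' @param excess an `excess`-stage [thermogram()].
#' @return An object of classes `dsc_fit`, `thermofit`: fitted
#'   [two_state_params()] in `$params`, Gauss-Newton standard errors
#'   (degC, kcal/mol) in `$std_errors`, plus `rss`, `converged`,
#'   `n_points` and the usual accessor methods (`coef`, `summary`,
#'   `predict`, `residuals`, `plot`, `simulate`).
#' @examples
#' p <- two_state_params(62.5, 111.6, 96.3)
#' tg <- simulate_thermogram(p, noise_sd = 0, seed = 1)
#' fit <- fit_two_state(tg)
#' coef(fit)
#' @export
fit_two_state <- function(excess) {
  g <- guess_two_state(excess)
  tt <- excess$temperature
  y <- excess$cp
  resid_fn <- function(par) {
    y - two_state_excess_cp(tt, two_state_params(par[1], par[2], par[3]))
  }
  fit <- minpack.lm::nls.lm(
    par = c(tm = g$tm, dh_cal = g$dh_cal, dh_vh = g$dh_vh),
    lower = c(kelvin_to_celsius(1e-3), 1e-6, 1e-6),
    fn = resid_fn, control = .FIT_CONTROL())
  par <- fit$par
  rss <- sum(fit$fvec^2)
  se <- gn_std_errors(resid_fn, par, rss, length(y))
  params <- two_state_params(par[["tm"]], par[["dh_cal"]], par[["dh_vh"]])
  new_thermofit(
    "dsc_fit", params,
    std_errors = stats::setNames(se$se, names(par)), cov = se$cov,
    rss = rss, converged = fit$info %in% 1:4, n_points = length(y),
    data = list(x = tt, y = y), fitted = y - fit$fvec,
    call = match.call())
}

#' Calorimetric to van't Hoff enthalpy ratio
#'
#' The ratio \eqn{\Delta H / \Delta H^{VH}} diagnoses the unfolding
#' cooperativity: values near one indicate a two-state transition of the
#' monomer, values well below one intermolecular cooperation
#' (oligomer unfolding), values well above one intermediates or partial
#' unfolding.
#'
#' @param params a [two_state_params()] object or a `dsc_fit`.
#' @return Dimensionless ratio.
#' @export
vant_hoff_ratio <- function(params) {
  if (inherits(params, "thermofit")) params <- params$params
  params$dh_cal / params$dh_vh
}

#' Fit a two-state CD melt with sloping baselines
#'
#' Six-parameter least-squares fit of [cd_two_state_signal()]: apparent
#' midpoint, apparent van't Hoff enthalpy, and intercept/slope of the
#' native and denatured baselines. Starting baselines come from the outer
#' 15\% of the temperature range; the midpoint starts at the half-height
#' crossing of the baseline-corrected signal.
#'
#' @param melt a data frame with columns `temperature` (degC) and
#'   `signal`, at least 20 points spanning the transition (e.g. from
#'   [simulate_cd_melt()]).
#' @return An object of classes `cd_fit`, `thermofit` with a
#'   [cd_melt_params()] in `$params`; standard errors are ordered
#'   (tm_app, dh_vh_app, native intercept/slope, denatured
#'   intercept/slope).
#' @export
fit_cd_melt <- function(melt) {
  stopifnot(is.data.frame(melt),
            all(c("temperature", "signal") %in% names(melt)))
  tt <- melt$temperature
  y <- melt$signal
  if (length(tt) < 20) {
    dscfit_stop("need at least 20 points spanning the transition",
                "dscfit_invalid_input")
  }
  rng <- range(tt)
  lo <- tt <= rng[1] + 0.15 * diff(rng)
  hi <- tt >= rng[2] - 0.15 * diff(rng)
  nat <- stats::coef(stats::lm(y[lo] ~ tt[lo]))
  den <- stats::coef(stats::lm(y[hi] ~ tt[hi]))
  # fraction-converted estimate -> half-height crossing for tm guess
  bn <- nat[1] + nat[2] * tt
  bd <- den[1] + den[2] * tt
  frac <- (y - bn) / ifelse(abs(bd - bn) < 1e-12, 1, bd - bn)
  tm0 <- tt[which.min(abs(frac - 0.5))]
  resid_fn <- function(par) {
    y - cd_two_state_signal(
      tt, cd_melt_params(par[1], par[2], par[3:4], par[5:6]))
  }
  par0 <- c(tm_app = tm0, dh_vh_app = 100,
            nat_b0 = unname(nat[1]), nat_b1 = unname(nat[2]),
            den_b0 = unname(den[1]), den_b1 = unname(den[2]))
  fit <- minpack.lm::nls.lm(
    par = par0,
    lower = c(kelvin_to_celsius(1e-3), 1e-6, -Inf, -Inf, -Inf, -Inf),
    fn = resid_fn, control = .FIT_CONTROL())
  par <- fit$par
  rss <- sum(fit$fvec^2)
  se <- gn_std_errors(resid_fn, par, rss, length(y))
  params <- cd_melt_params(par[["tm_app"]], par[["dh_vh_app"]],
                           c(par[["nat_b0"]], par[["nat_b1"]]),
                           c(par[["den_b0"]], par[["den_b1"]]))
  new_thermofit(
    "cd_fit", params,
    std_errors = stats::setNames(se$se, names(par)), cov = se$cov,
    rss = rss, converged = fit$info %in% 1:4, n_points = length(y),
    data = list(x = tt, y = y), fitted = y - fit$fvec,
    call = match.call())
}

#' Fit the single-site linkage model to a Tm titration series
#'
#' Least-squares fit of [ligand_shifted_tm()] to (ligand concentration,
#' melting temperature) pairs, estimating the ligand-free transition
#' temperature and the dissociation constant. The unfolding enthalpy at
#' `tm0` is fixed to the calorimetric value supplied by the caller (it is
#' not identifiable from the shift curve alone). `kd` is fitted on the
#' log scale to enforce positivity; its standard error is mapped back by
#' the delta method. When the series carries no information (all
#' temperatures equal), the `kd` standard error exceeds the estimate,
#' flagging non-identifiability.
#'
#' @param series data frame with columns `conc` (mol/L) and `tm` (degC),
#'   at least 4 rows; a zero-concentration anchor is recommended (a
#'   warning is emitted without one).
#' @param dh0 unfolding enthalpy at `tm0`, kcal/mol, fixed during the fit
#'   (typically the apo calorimetric enthalpy from DSC).
#' @return An object of classes `titration_fit`, `thermofit` with a
#'   [linkage_params()] in `$params` and standard errors for
#'   `tm0` (degC) and `kd` (mol/L).
#' @export
fit_titration <- function(series, dh0) {
  stopifnot(is.data.frame(series),
            all(c("conc", "tm") %in% names(series)))
  stopifnot_positive(dh0, "dh0")
  if (nrow(series) < 4) {
    dscfit_stop("need at least 4 (conc, tm) pairs", "dscfit_invalid_input")
  }
  if (!any(series$conc == 0)) {
    warning("no zero-concentration anchor; tm0 is extrapolated")
  }
  L <- series$conc
  tm_obs <- series$tm
  tm0_init <- if (any(L == 0)) mean(tm_obs[L == 0]) else min(tm_obs)
  pos <- L[L > 0]
  kd_init <- if (length(pos)) exp(mean(log(pos))) else 1e-6
  resid_fn <- function(par) {
    tm_obs - ligand_shifted_tm(L, linkage_params(par[1], dh0, exp(par[2])))
  }
  fit <- minpack.lm::nls.lm(
    par = c(tm0 = tm0_init, log_kd = log(kd_init)),
    fn = resid_fn, control = .FIT_CONTROL())
  par <- fit$par
  rss <- sum(fit$fvec^2)
  se <- gn_std_errors(resid_fn, par, rss, length(tm_obs))
  kd <- exp(par[["log_kd"]])
  se_out <- c(tm0 = se$se[1], kd = kd * se$se[2])  # delta method
  params <- linkage_params(par[["tm0"]], dh0, kd)
  new_thermofit(
    "titration_fit", params,
    std_errors = se_out, cov = se$cov,
    rss = rss, converged = fit$info %in% 1:4, n_points = length(tm_obs),
    data = list(x = L, y = tm_obs), fitted = tm_obs - fit$fvec,
    call = match.call())
}

# ---- methods ----------------------------------------------------------

#' @export
coef.thermofit <- function(object, ...) {
  p <- object$params
  switch(class(object)[1],
    dsc_fit = c(tm = p$tm, dh_cal = p$dh_cal, dh_vh = p$dh_vh),
    cd_fit = c(tm_app = p$tm_app, dh_vh_app = p$dh_vh_app,
               nat_b0 = p$native[1], nat_b1 = p$native[2],
               den_b0 = p$denatured[1], den_b1 = p$denatured[2]),
    titration_fit = c(tm0 = p$tm0, kd = p$kd))
}

#' @export
vcov.thermofit <- function(object, ...) object$cov

#' @export
fitted.thermofit <- function(object, ...) object$fitted

#' @export
residuals.thermofit <- function(object, ...) object$residuals

model_curve <- function(object, x) {
  switch(class(object)[1],
    dsc_fit = two_state_excess_cp(x, object$params),
    cd_fit = cd_two_state_signal(x, object$params),
    titration_fit = ligand_shifted_tm(x, object$params))
}

#' @export
predict.thermofit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x
       else if (is.data.frame(newdata)) newdata[[1]]
       else newdata
  model_curve(object, x)
}

#' @export
simulate.thermofit <- function(object, nsim = 1, seed = NULL, ...) {
  sd <- sqrt(object$rss / max(object$n_points - length(coef(object)), 1))
  sims <- with_seed(seed %||% 0, {
    replicate(nsim, object$fitted + stats::rnorm(object$n_points, 0, sd),
              simplify = FALSE)
  })
  out <- as.data.frame(sims, col.names = paste0("sim_", seq_len(nsim)))
  attr(out, "seed") <- seed %||% 0
  out
}

#' @export
print.thermofit <- function(x, ...) {
  lab <- switch(class(x)[1],
                dsc_fit = "Two-state DSC fit",
                cd_fit = "Two-state CD melt fit",
                titration_fit = "Single-site linkage fit")
  cat(lab, if (!x$converged) "(NOT converged)", "\n")
  print(x$params)
  cat(sprintf("  rss = %.4g on %d points\n", x$rss, x$n_points))
  invisible(x)
}

#' @export
summary.thermofit <- function(object, ...) {
  est <- coef(object)
  k <- length(object$std_errors)
  tab <- cbind(Estimate = est[seq_len(k)],
               `Std. Error` = unname(object$std_errors))
  out <- list(fit = object, table = tab,
              ratio = if (inherits(object, "dsc_fit"))
                vant_hoff_ratio(object) else NULL)
  class(out) <- "summary.thermofit"
  out
}

#' @export
print.summary.thermofit <- function(x, ...) {
  print(x$fit)
  cat("\nParameters (temperatures degC, enthalpies kcal/mol):\n")
  stats::printCoefmat(x$table)
  if (!is.null(x$ratio)) {
    cat(sprintf("\ndH_cal/dH_vH = %.2f (two-state band: 0.8-1.2)\n",
                x$ratio))
  }
  invisible(x)
}

#' @export
plot.thermofit <- function(x, n_curve = 400, ...) {
  labs <- switch(class(x)[1],
    dsc_fit = c("Temperature (degC)", "Cp_ex (kcal/mol/K)"),
    cd_fit = c("Temperature (degC)", "Signal"),
    titration_fit = c("Ligand (M)", "Tm (degC)"))
  graphics::plot(x$data$x, x$data$y, pch = 16, cex = 0.4,
                 xlab = labs[1], ylab = labs[2], ...)
  xx <- seq(min(x$data$x), max(x$data$x), length.out = n_curve)
  graphics::lines(xx, model_curve(x, xx), col = 2, lwd = 2)
  invisible(x)
}
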