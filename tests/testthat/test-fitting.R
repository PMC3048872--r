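# Nonlinear least-squares fits: DSC two-state, CD melt, titration, and
# the estimator's statistical behaviour.

test_that("initial guess lands within 5% of truth on noiseless curves", {
  for (p in list(apo_params(), camp_params(),
                 two_state_params(45, 80, 70))) {
    tg <- simulate_thermogram(p, noise_sd = 0)
    g <- guess_two_state(tg)
    expect_equal(g$tm, p$tm, tolerance = 0.05)
    expect_equal(g$dh_cal, p$dh_cal, tolerance = 0.05)
    expect_equal(g$dh_vh, p$dh_vh, tolerance = 0.05)
  }
  tt <- seq(15, 95, by = 0.1)
  flat <- thermogram(tt, rep(0, length(tt)), stage = "excess")
  expect_error(guess_two_state(flat), class = "dscfit_no_transition")
  # a peak at the grid edge is not an interior transition
  edge <- thermogram(tt, two_state_excess_cp(tt + 50, apo_params()),
                     stage = "excess")
  expect_error(guess_two_state(edge), class = "dscfit_no_transition")
})

test_that("noiseless two-state curves are recovered to 1e-6 relative", {
  for (p in list(apo_params(), camp_params(), g325d_params())) {
    fit <- fit_two_state(simulate_thermogram(p, noise_sd = 0))
    expect_true(fit$converged)
    expect_equal(fit$params$tm, p$tm, tolerance = 1e-6)
    expect_equal(fit$params$dh_cal, p$dh_cal, tolerance = 1e-6)
    expect_equal(fit$params$dh_vh, p$dh_vh, tolerance = 1e-6)
  }
})

test_that("noisy refits recover the generating parameters on average", {
  p <- apo_params()
  fits <- lapply(0:19, function(s) {
    fit_two_state(simulate_thermogram(p, noise_sd = 0.1, seed = s))
  })
  tm_hat <- sapply(fits, function(f) f$params$tm)
  dh_hat <- sapply(fits, function(f) f$params$dh_cal)
  vh_hat <- sapply(fits, function(f) f$params$dh_vh)
  expect_lt(abs(mean(tm_hat) - 62.5), 0.1)
  expect_lt(abs(mean(dh_hat) - 111.6) / 111.6, 0.03)
  expect_lt(abs(mean(vh_hat) - 96.3) / 96.3, 0.03)
  # standard errors are positive and commensurate with the spread
  expect_true(all(sapply(fits, function(f) all(f$std_errors > 0))))
})

test_that("the calorimetric/van't Hoff ratio reproduces the printed diagnostics", {
  expect_equal(vant_hoff_ratio(two_state_params(60, 100, 100)), 1.0)
  r_apo <- vant_hoff_ratio(apo_params())
  r_camp <- vant_hoff_ratio(camp_params())
  expect_equal(r_apo, 111.6 / 96.3, tolerance = 1e-12)
  expect_equal(r_camp, 120.4 / 139.9, tolerance = 1e-12)
  expect_true(r_apo > 0.8 && r_apo < 1.2)
  expect_true(r_camp > 0.8 && r_camp < 1.2)
})

test_that("scan-rate metadata never enters the fit and grids can be refined", {
  p <- apo_params()
  tg1 <- simulate_thermogram(p, noise_sd = 0.1, seed = 9, scan_rate = 1.5)
  tg2 <- tg1
  tg2$scan_rate <- 0.25
  expect_identical(coef(fit_two_state(tg1)), coef(fit_two_state(tg2)))
  # noiseless fit invariant under grid refinement
  c1 <- coef(fit_two_state(simulate_thermogram(p, grid = c(15, 95, 0.1),
                                               noise_sd = 0)))
  c2 <- coef(fit_two_state(simulate_thermogram(p, grid = c(15, 95, 0.05),
                                               noise_sd = 0)))
  expect_equal(c1, c2, tolerance = 1e-4)
})

test_that("the Tm estimator is effectively unbiased at instrument noise", {
  p <- apo_params()
  tm_hat <- sapply(0:99, function(s) {
    fit_two_state(simulate_thermogram(p, grid = c(15, 95, 0.2),
                                      noise_sd = 0.1, seed = s))$params$tm
  })
  expect_lt(abs(mean(tm_hat) - 62.5), 0.02)
})

test_that("CD melts are fitted to machine precision without noise and robustly with it", {
  truth <- cd_melt_params(68, 90, c(-12, 0.02), c(-2, -0.01))
  fit0 <- fit_cd_melt(simulate_cd_melt(truth, noise_sd = 0))
  expect_true(fit0$converged)
  expect_equal(fit0$params$tm_app, 68, tolerance = 1e-6)
  expect_equal(fit0$params$dh_vh_app, 90, tolerance = 1e-6)
  expect_equal(fit0$params$native, truth$native, tolerance = 1e-5)
  # flat-baseline melt: midpoint at the half-height temperature
  flat <- cd_melt_params(57.5, 80, c(0, 0), c(1, 0))
  fitf <- fit_cd_melt(simulate_cd_melt(flat, grid = c(20, 95, 0.25),
                                       noise_sd = 0))
  expect_equal(fitf$params$tm_app, 57.5, tolerance = 1e-6)
  # 2%-of-amplitude noise over 20 seeds: mean midpoint within 0.5 degC
  tm_hat <- sapply(0:19, function(s) {
    m <- simulate_cd_melt(truth, noise_sd = 0.02 * 10, seed = s)
    fit_cd_melt(m)$params$tm_app
  })
  expect_lt(abs(mean(tm_hat) - 68), 0.5)
  expect_error(fit_cd_melt(data.frame(temperature = 1:5, signal = 1:5)),
               class = "dscfit_invalid_input")
})

test_that("titration fits recover (tm0, kd) and flag degenerate series", {
  lp <- linkage_params(62.5, 111.6, 8e-6)
  concs <- c(0, 10^seq(-7.5, -3, length.out = 9))
  fit0 <- fit_titration(simulate_titration(lp, concs), dh0 = 111.6)
  expect_true(fit0$converged)
  expect_equal(fit0$params$tm0, 62.5, tolerance = 1e-3)
  expect_equal(fit0$params$kd, 8e-6, tolerance = 1e-3)
  # all-equal series: kd unidentifiable, standard error dwarfs estimate
  flat <- data.frame(conc = c(0, 1e-6, 1e-5, 1e-4), tm = rep(62.5, 4))
  fit_flat <- fit_titration(flat, dh0 = 111.6)
  expect_gt(fit_flat$std_errors[["kd"]], fit_flat$params$kd)
  # noisy series over 20 seeds: kd within a factor of 2
  kd_hat <- sapply(0:19, function(s) {
    fit_titration(simulate_titration(lp, concs, noise_sd_tm = 0.2,
                                     seed = s), dh0 = 111.6)$params$kd
  })
  expect_true(all(kd_hat > 8e-6 / 2 & kd_hat < 8e-6 * 2))
  # no zero anchor warns but proceeds
  expect_warning(fit_titration(simulate_titration(lp, concs[-1]),
                               dh0 = 111.6), "anchor")
})

test_that("thermofit accessor methods are coherent", {
  p <- apo_params()
  tg <- simulate_thermogram(p, noise_sd = 0.1, seed = 2)
  fit <- fit_two_state(tg)
  expect_named(coef(fit), c("tm", "dh_cal", "dh_vh"))
  expect_equal(fitted(fit) + residuals(fit), tg$cp)
  expect_equal(predict(fit), fitted(fit), tolerance = 1e-12)
  expect_equal(predict(fit, 62.5), two_state_excess_cp(62.5, fit$params))
  expect_equal(dim(vcov(fit)), c(3L, 3L))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_identical(sims, simulate(fit, nsim = 2, seed = 1))
  expect_equal(ncol(sims), 2L)
  out <- capture.output(print(summary(fit)))
  expect_true(any(grepl("dH_cal/dH_vH", out)))
})
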