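test_that("noise-free in-family responses are recovered exactly", {
  true <- c(A0 = 0, A1 = 200, tau1 = 0.03, A2 = 150, tau2 = 0.3, k = 10,
            t0 = 0)
  cm <- sim_step_cell(A0 = 0, A1 = 200, tau1 = 0.03, A2 = 150, tau2 = 0.3,
                      k = 10, t0 = 0)
  fit <- fit_flash_response(cm, 0.5)
  cf <- coef(fit)
  expect_true(fit$converged)
  for (p in c("A1", "tau1", "A2", "tau2", "k"))
    expect_lt(rel_err(cf[[p]], true[[p]]), 1e-6)
  expect_lt(abs(cf[["A0"]]), 1e-4)   # true baseline is zero
  expect_lt(abs(cf[["t0"]]), 1e-6)

  # nonzero baseline and on-grid delay
  cm2 <- sim_step_cell(A0 = 4000, A1 = 180, tau1 = 0.025, A2 = 120,
                       tau2 = 0.4, k = 15, t0 = 0.012)
  cf2 <- coef(fit_flash_response(cm2, 0.5))
  truth2 <- c(A0 = 4000, A1 = 180, tau1 = 0.025, A2 = 120, tau2 = 0.4,
              k = 15, t0 = 0.012)
  for (p in names(truth2)) expect_lt(rel_err(cf2[[p]], truth2[[p]]), 1e-6)
})

test_that("a flat trace yields an empty burst with flagged taus", {
  tr <- new_trace(seq(0, 2, 0.002), rep(3000, 1001), "fF")
  fit <- fit_flash_response(tr, 0.5)
  cf <- coef(fit)
  expect_true(fit$converged)
  expect_false(fit$identifiable)
  expect_equal(cf[["A1"]], 0)
  expect_equal(cf[["A2"]], 0)
  expect_equal(cf[["k"]], 0)
  expect_true(is.na(cf[["tau1"]]) && is.na(cf[["tau2"]]))
})

test_that("noisy responses are recovered with small median error", {
  errs_a1 <- errs_tau1 <- numeric(50)
  for (i in 1:50) {
    cm <- sim_step_cell(A0 = 0, A1 = 200, tau1 = 0.03, A2 = 150,
                        tau2 = 0.3, k = 10, t0 = 0, noise_sd = 2, seed = i)
    cf <- coef(fit_flash_response(cm, 0.5))
    errs_a1[i] <- rel_err(cf[["A1"]], 200)
    errs_tau1[i] <- rel_err(cf[["tau1"]], 0.03)
  }
  expect_lt(median(errs_a1), 0.05)
  expect_lt(median(errs_tau1), 0.05)
})

test_that("recovery error grows with noise (rank check on a noise grid)", {
  med_err <- vapply(c(0.5, 2, 8), function(ns) {
    errs <- vapply(1:15, function(i) {
      cm <- sim_step_cell(A0 = 0, A1 = 200, tau1 = 0.03, A2 = 150,
                          tau2 = 0.3, k = 10, noise_sd = ns, seed = 100 + i)
      rel_err(coef(fit_flash_response(cm, 0.5))[["A1"]], 200)
    }, 0)
    median(errs)
  }, 0)
  expect_true(all(diff(med_err) >= 0))
})

test_that("fitted delay tracks the generating delay within one sample", {
  dt <- 0.002
  for (d in c(0.004, 0.01, 0.03)) {
    cm <- sim_step_cell(A0 = 0, A1 = 250, tau1 = 0.04, A2 = 100,
                        tau2 = 0.35, k = 8, t0 = d, dt = dt)
    cf <- coef(fit_flash_response(cm, 0.5))
    expect_lt(abs(cf[["t0"]] - d), dt)
  }
})

test_that("component classification labels the faster pool as RRP", {
  cm <- sim_step_cell(A0 = 0, A1 = 200, tau1 = 0.03, A2 = 150, tau2 = 0.3,
                      k = 10)
  fit <- fit_flash_response(cm, 0.5)
  pools <- classify_components(fit)
  expect_equal(pools$RRP, 200, tolerance = 1e-6)
  expect_equal(pools$SRP, 150, tolerance = 1e-6)
  expect_equal(pools$EB, pools$RRP + pools$SRP)

  # labeling invariance: a permissive fit with swapped component order
  swapped <- structure(list(
    coefficients = c(A0 = 0, A1 = 150, tau1 = 0.3, A2 = 200, tau2 = 0.03,
                     k = 10, t0 = 0),
    converged = TRUE, identifiable = TRUE), class = "flash_fit")
  pools2 <- classify_components(swapped)
  expect_equal(pools2$RRP, 200)
  expect_equal(pools2$tauRRP, 0.03)

  empty <- structure(list(
    coefficients = c(A0 = 5, A1 = 0, tau1 = NA, A2 = 0, tau2 = NA, k = 0,
                     t0 = 0),
    converged = TRUE, identifiable = FALSE), class = "flash_fit")
  expect_equal(classify_components(empty)$EB, 0)

  unconverged <- structure(list(converged = FALSE), class = "flash_fit")
  expect_error(classify_components(unconverged), "refused")
})

test_that("flash_fit methods are mutually consistent", {
  cm <- sim_step_cell(A0 = 100, A1 = 200, tau1 = 0.03, A2 = 150,
                      tau2 = 0.3, k = 10, noise_sd = 2, seed = 4)
  fit <- fit_flash_response(cm, 0.5)
  expect_equal(fit$v - predict(fit), residuals(fit))
  expect_equal(sum(residuals(fit)^2), fit$rss, tolerance = 1e-8)
  expect_output(print(fit), "Flash-evoked")
  expect_output(print(summary(fit)), "RRP")
})

test_that("premature secretion measures gain, tonic rate and mean calcium", {
  t <- seq(0, 120, 0.05)
  ca <- new_trace(t, rep(0.5, length(t)), "uM")

  flat <- new_trace(t, rep(4000, length(t)), "fF")
  ps0 <- measure_premature_secretion(flat, ca, c(0, 120))
  expect_equal(ps0$delta_cm, 0)
  expect_equal(ps0$tonic_rate, 0, tolerance = 1e-12)

  lin <- new_trace(t, 4000 + 5 * t, "fF")
  ps <- measure_premature_secretion(lin, ca, c(0, 120), rate_subwindow = 30)
  expect_equal(ps$delta_cm, 600)
  expect_equal(ps$tonic_rate, 5, tolerance = 1e-9)
  expect_equal(ps$mean_ca, 0.5)

  expect_error(measure_premature_secretion(lin, ca, c(0, 500)),
               "invalid window")
  expect_error(measure_premature_secretion(lin, ca, c(10, 10)), "start")
})

test_that("simulated loading phase reproduces the generating tonic rate", {
  proto <- make_flash_protocol(0.5, 0.5, 60, 120, 0.05)
  p <- cell_params(C0 = 4000, B1 = 0, B2 = 0, k_sus_max = 15, n_sus = 1,
                   K_sus = 2, noise_sd = 2)   # 15 * 0.2 = 3 fF/s at 0.5 uM
  cm <- simulate_cell(p, proto, seed = 8)
  ps <- measure_premature_secretion(cm, proto, c(0, 120))
  expect_equal(ps$tonic_rate, 3, tolerance = 0.05)
  expect_equal(ps$delta_cm, 360, tolerance = 15)
})
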