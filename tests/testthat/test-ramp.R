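logistic_trace <- function(amp = 500, mid = 30, width = 4, base = 0,
                           dur = 60, dt = 0.01, noise = 0, seed = 1) {
  t <- seq(0, dur, by = dt)
  v <- base + amp / (1 + exp(-(t - mid) / width))
  if (noise > 0) { set.seed(seed); v <- v + rnorm(length(v), 0, noise) }
  new_trace(t, v, "fF")
}

test_that("polynomial smoothing projects exactly onto its own family", {
  t <- seq(0, 10, 0.01)
  cub <- new_trace(t, 5 + 2 * t - 0.3 * t^2 + 0.05 * t^3, "fF")
  sm <- smooth_cm(cub, order = 3)
  expect_lt(max(abs(sm$v - cub$v)) / diff(range(cub$v)), 1e-9)

  # order 0 on a non-constant input: RSS reports the (poor) fit quality
  lin <- new_trace(t, t, "fF")
  sm0 <- smooth_cm(lin, order = 0)
  expect_equal(attr(sm0, "rss"), sum((t - mean(t))^2), tolerance = 1e-8)

  expect_error(smooth_cm(new_trace(c(0, 1, 2), 1:3, "fF"), order = 5),
               "order \\+ 2")
})

test_that("smoothing a noisy sigmoid beats the noise floor", {
  noisy <- logistic_trace(width = 6, noise = 2, seed = 2)
  clean <- logistic_trace(width = 6)
  sm <- smooth_cm(noisy, order = 8)
  rms <- sqrt(mean((sm$v - clean$v)^2))
  expect_lt(rms, 2)
})

test_that("burst size is read off a saturated sigmoid", {
  for (m in c("tail", "plateau", "final")) {
    eb <- estimate_burst_size(logistic_trace(amp = 500, base = 4000),
                              method = m)
    expect_equal(as.numeric(eb), 500, tolerance = 0.01 * 500)
  }
  const <- new_trace(seq(0, 60, 0.01), rep(4000, 6001), "fF")
  expect_equal(as.numeric(estimate_burst_size(const)), 0)

  # still-rising trace: saturation check refuses
  rising <- logistic_trace(mid = 58, width = 6)
  expect_error(estimate_burst_size(rising), "non-saturating")
})

test_that("tail extrapolation corrects an unfinished plateau", {
  # depletion reaches only ~97.5% at the end of the window
  t <- seq(0, 60, 0.01)
  ca <- 0.3 + (8 - 0.3) * t / 60
  k <- hill_rate(ca, 15, 2.07, 58.13)
  v <- 400 * (1 - exp(-c(0, cumsum(k * 0.01)[-length(k)])))
  tr <- new_trace(t, 4000 + v, "fF")
  eb_tail <- as.numeric(estimate_burst_size(tr, method = "tail"))
  eb_plat <- as.numeric(estimate_burst_size(tr, method = "plateau",
                                            saturation_frac = 0.2))
  expect_lt(abs(eb_tail - 400) / 400, 0.01)
  expect_gt(abs(eb_plat - 400) / 400, abs(eb_tail - 400) / 400)
})

test_that("constant-rate depletion returns the generating rate", {
  dt <- 0.001
  t <- seq(0, 20, dt)
  ca <- new_trace(t, rep(2, length(t)), "uM")
  for (r in c(0.1, 1, 10)) {
    cm <- new_trace(t, 400 * (1 - exp(-r * t)), "fF")
    prof <- compute_depletion_profile(cm, ca, interval = 0.04,
                                      eb_size = 400, baseline = 0)
    rate <- prof$rate[prof$valid]
    # allowed: the analytic forward-difference discretization bias
    bias_bound <- (exp(r * 0.04) - 1) / 0.04 - r
    expect_lt(max(abs(rate - r)), bias_bound + 1e-9)
    # centered pairing does far better than the one-sided bound
    expect_lt(median(abs(rate - r)) / r, 0.01)
  }
})

test_that("depletion profile masks depleted intervals and handles flat traces", {
  dt <- 0.001
  t <- seq(0, 20, dt)
  ca <- new_trace(t, rep(2, length(t)), "uM")
  cm <- new_trace(t, 400 * (1 - exp(-1 * t)), "fF")
  prof <- compute_depletion_profile(cm, ca, eb_size = 400, baseline = 0)
  expect_true(all(prof$remaining[prof$valid] > 0.05 * 400))
  expect_true(any(!prof$valid))
  expect_true(all(is.na(prof$rate[!prof$valid])))

  flat <- new_trace(t, rep(100, length(t)), "fF")
  pf <- compute_depletion_profile(flat, ca, eb_size = 50, baseline = 100)
  expect_true(all(pf$slope == 0))
  expect_true(all(pf$rate[pf$valid] == 0))

  expect_error(compute_depletion_profile(cm, ca, eb_size = -1), "positive")
  expect_error(compute_depletion_profile(cm, ca, interval = 0.001,
                                         eb_size = 400), "2 samples")
})

test_that("40 ms intervals span 4 samples at 10 ms and use midpoints", {
  dt <- 0.01
  t <- seq(0, 10, dt)
  ca <- new_trace(t, seq(0.3, 3, length.out = length(t)), "uM")
  cm <- new_trace(t, 100 * t, "fF")
  prof <- compute_depletion_profile(cm, ca, interval = 0.04, eb_size = 2000,
                                    baseline = 0)
  expect_equal(diff(prof$t_mid)[1], 0.04, tolerance = 1e-9)
  expect_equal(prof$t_mid[1], 0.02, tolerance = 1e-9)  # midpoint of [0, 0.04]
  expect_equal(prof$ca_mid[1], ca$v[t == 0.02], tolerance = 1e-12)
})

test_that("gridding interpolates linearly with 50 nM spacing and no extrapolation", {
  # rate exactly linear in ca: gridded values on the same line
  prof <- structure(
    data.frame(t_mid = 1:20, ca_mid = seq(0.31, 4.2, length.out = 20),
               slope = 1, remaining = 100,
               rate = 2 * seq(0.31, 4.2, length.out = 20) + 0.1,
               valid = TRUE),
    eb_size = 200, interval = 0.04, baseline = 0,
    class = c("depletion_profile", "data.frame"))
  g <- interpolate_to_ca_grid(prof, grid_step = 0.05)
  expect_equal(diff(g$ca), rep(0.05, nrow(g) - 1), tolerance = 1e-12)
  expect_lt(max(abs(g$rate - (2 * g$ca + 0.1))), 1e-9)
  expect_gte(min(g$ca), min(prof$ca_mid))
  expect_lte(max(g$ca), max(prof$ca_mid))

  # reliability cutoff truncates the grid
  g2 <- interpolate_to_ca_grid(prof, ca_max = 3)
  expect_lte(max(g2$ca), 3)

  # non-monotone calcium: interpolation restricted to the longest
  # strictly-increasing run (the tail), ignoring the decreasing head
  prof2 <- prof
  prof2$ca_mid <- c(3.90, 3.95, seq(0.31, 2, length.out = 18))
  prof2$rate <- c(99, 99, rep(1, 18))
  g4 <- interpolate_to_ca_grid(prof2)
  expect_lte(max(g4$ca), 2)
  expect_true(all(g4$rate == 1))

  prof$valid <- c(TRUE, rep(FALSE, 19))
  expect_error(interpolate_to_ca_grid(prof), "fewer than 2")
})

test_that("cross-cell averaging tracks coverage and SEM arithmetic", {
  mk <- function(ca, rate) structure(data.frame(ca = ca, rate = rate),
                                     grid_step = 0.05,
                                     class = c("gridded_rates", "data.frame"))
  a <- mk(seq(0.5, 1, 0.05), rep(2, 11))
  b <- mk(seq(0.5, 1, 0.05), rep(4, 11))
  avg <- average_across_cells(list(a, b), min_cells = 2)
  expect_equal(avg$mean_rate, rep(3, 11))
  expect_equal(avg$sem_rate, rep(1, 11))   # sd = sqrt(2), /sqrt(2)
  expect_equal(avg$n_cells, rep(2L, 11))

  # disjoint coverage is reflected per point
  cdis <- mk(seq(1.5, 2, 0.05), rep(9, 11))
  avg2 <- average_across_cells(list(a, b, cdis), min_cells = 1)
  expect_equal(avg2$n_cells[avg2$ca == 0.5], 2L)
  expect_equal(avg2$n_cells[avg2$ca == 2], 1L)
  expect_true(is.na(avg2$sem_rate[avg2$ca == 2]))

  # single cell: mean equals the cell, SEM undefined
  avg1 <- average_across_cells(list(a), min_cells = 1)
  expect_equal(avg1$mean_rate, a$rate)
  expect_true(all(is.na(avg1$sem_rate)))
})

test_that("Hill fit recovers noise-free parameters and flags extrapolation", {
  ca <- seq(0.3, 6, by = 0.05)
  g <- structure(data.frame(ca = ca,
                            mean_rate = hill_rate(ca, 15, 2.03, 38.2)),
                 class = c("gridded_rates", "data.frame"))
  fit <- fit_hill(g)
  cf <- coef(fit)
  expect_lt(rel_err(cf[["n"]], 2.03), 0.02)
  expect_lt(rel_err(cf[["kd"]], 38.2), 0.02)
  expect_true(fit$kd_extrapolated)   # KD far above the gridded range

  # midpoint identity with the coefficient fixed
  ca2 <- seq(0.5, 8, 0.05)
  g2 <- structure(data.frame(ca = ca2, mean_rate = hill_rate(ca2, 1, 2, 2)),
                  class = c("gridded_rates", "data.frame"))
  cf2 <- coef(fit_hill(g2, fix_n = 2))
  expect_equal(cf2[["kd"]], 2, tolerance = 1e-6)
  expect_false(fit_hill(g2)$kd_extrapolated)

  # degenerate constant grid
  gc <- structure(data.frame(ca = ca2, mean_rate = rep(1, length(ca2))),
                  class = c("gridded_rates", "data.frame"))
  expect_warning(fc <- fit_hill(gc), "not identifiable")
  expect_false(fc$converged)

  expect_error(fit_hill(g[1:3, ]), "at least 5")
})

test_that("hill_fit methods are mutually consistent", {
  ca <- seq(0.5, 8, 0.05)
  set.seed(9)
  g <- structure(data.frame(ca = ca,
                            mean_rate = hill_rate(ca, 10, 2, 3) +
                              rnorm(length(ca), 0, 0.05)),
                 class = c("gridded_rates", "data.frame"))
  fit <- fit_hill(g)
  expect_equal(residuals(fit), fit$data$rate - predict(fit))
  expect_output(print(fit), "Hill fit")
  expect_output(print(summary(fit)), "Std. Error")
  expect_true(all(is.finite(fit$se)))
})

test_that("pool depletion curve crosses one half at the analytic P50", {
  mkprof <- function(scale = 1) {
    ca <- seq(0.5, 40, length.out = 200)
    rf <- 1 / (1 + (ca / 20)^2)
    structure(data.frame(t_mid = seq_along(ca), ca_mid = ca, slope = 1,
                         remaining = 300 * scale * rf,
                         rate = 1, valid = TRUE),
              eb_size = 300 * scale, interval = 0.04, baseline = 0,
              class = c("depletion_profile", "data.frame"))
  }
  pd <- compute_pool_depletion(list(mkprof(), mkprof(), mkprof()),
                               n_boot = 200, seed = 2)
  expect_equal(pd$p50, 20, tolerance = 0.02)
  expect_equal(pd$p50_se, 0)   # identical cells

  shallow <- mkprof()
  shallow$remaining <- 300 * (0.6 + 0.4 / (1 + (shallow$ca_mid / 20)^2))
  expect_error(compute_pool_depletion(list(shallow, shallow, shallow)),
               "p50 undefined")
})

test_that("full ramp chain recovers Hill parameters when the ramp covers KD", {
  # single noise-free cell; depletion slow enough that the automatic
  # reliability cutoff (25% pool remaining) still lies above KD, so the
  # rate-calcium relation is sampled through its half-maximal region
  proto <- make_ramp_protocol(0.3, 8, 60, 0.01)
  p <- ramp_pool_params(rmax = 0.15, n = 2, kd = 2.5, noise_sd = 0)
  cm <- simulate_cell(p, proto)
  ra <- analyze_ramp(list(list(cm = cm, ca = proto)), min_cells = 1,
                     n_boot = 0)
  cf <- coef(ra$hill)
  expect_lt(rel_err(cf[["n"]], 2), 0.05)
  expect_lt(rel_err(cf[["kd"]], 2.5), 0.05)
})
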