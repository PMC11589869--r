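test_that("empty machinery yields a constant trace at baseline", {
  ca <- make_flash_protocol(0.5, 20, 0.5, 2, 0.002)
  p <- cell_params(C0 = 4200, B1 = 0, B2 = 0, k_sus_max = 0, noise_sd = 0)
  cm <- simulate_cell(p, ca)
  expect_true(all(cm$v == 4200))
})

test_that("step-protocol simulation matches the closed-form flash response", {
  set.seed(7)
  for (i in 1:5) {
    pars <- list(A0 = runif(1, 0, 5000), A1 = runif(1, 50, 400),
                 tau1 = runif(1, 0.02, 0.08), A2 = runif(1, 30, 300),
                 tau2 = runif(1, 0.15, 0.8), k = runif(1, 2, 30),
                 t0 = sample(c(0, 0.004, 0.012), 1))
    cm <- do.call(sim_step_cell, pars)
    expected <- flash_curve(cm$t, 0.5, pars$A0, pars$A1, pars$tau1,
                            pars$A2, pars$tau2, pars$k, pars$t0)
    expect_lt(max(abs(cm$v - expected)), 1e-8)
  }
})

test_that("simulation is bit-reproducible for a fixed seed", {
  ca <- make_ramp_protocol(0.3, 8, 10, 0.01)
  p <- cell_params(noise_sd = 2)
  a <- simulate_cell(p, ca, seed = 11)
  b <- simulate_cell(p, ca, seed = 11)
  c <- simulate_cell(p, ca, seed = 12)
  expect_identical(a$v, b$v)
  expect_false(identical(a$v, c$v))
})

test_that("noise-free secretion is non-decreasing and pools conserve mass", {
  ca <- make_ramp_protocol(0.3, 8, 30, 0.01)
  p <- cell_params(C0 = 5000, B1 = 250, B2 = 150, k_sus_max = 0,
                   noise_sd = 0)
  cm <- simulate_cell(p, ca)
  expect_true(all(diff(cm$v) >= -1e-12))
  expect_true(all(cm$v - 5000 <= 250 + 150 + 1e-9))
})

test_that("constant-calcium depletion follows the single-exponential law", {
  ca <- make_flash_protocol(2, 2, 1, 20, 0.01)  # held at 2 uM throughout
  p <- cell_params(C0 = 0, B1 = 300, rmax1 = 1, n1 = 2, KD1 = 2, B2 = 0,
                   t0 = 0, k_sus_max = 0, noise_sd = 0)
  cm <- simulate_cell(p, ca)
  r <- hill_rate(2, 1, 2, 2)  # 0.5
  expect_lt(max(abs(cm$v - 300 * (1 - exp(-r * ca$t)))), 1e-9)
})

test_that("group simulation reproduces means, CV structure and seeds", {
  proto <- make_flash_protocol(0.5, 20, 0.5, 1.2, 0.005)

  # zero variability: all cells identical to the means
  spec0 <- group_spec("g0", 4, means = cell_params(noise_sd = 0), cv = 0,
                      seed = 3)
  cells0 <- simulate_group(spec0, proto)
  expect_length(cells0, 4)
  expect_identical(cells0[[1]]$cm$v, cells0[[4]]$cm$v)

  # determinism
  cellsA <- simulate_group(group_spec("g", 5, cv = 0.2, seed = 21), proto)
  cellsB <- simulate_group(group_spec("g", 5, cv = 0.2, seed = 21), proto)
  expect_identical(cellsA[[3]]$cm$v, cellsB[[3]]$cm$v)
  expect_identical(cellsA[[2]]$params, cellsB[[2]]$params)

  # sampler calibration: realized mean within 3 SE of the spec mean
  spec <- group_spec("big", 200, means = cell_params(B1 = 200),
                     cv = c(B1 = 0.3), seed = 5)
  cells <- simulate_group(spec, proto)
  b1 <- vapply(cells, function(cl) cl$params$B1, 0)
  se <- 0.3 * 200 / sqrt(200)
  expect_lt(abs(mean(b1) - 200), 3 * se)
  expect_true(all(b1 > 0))
})
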