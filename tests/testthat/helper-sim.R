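# Shared fixtures: all synthetic, generated in code.

# closed-form flash response (the fit family itself)
flash_curve <- function(t, t_flash, A0, A1, tau1, A2, tau2, k, t0 = 0) {
  s <- pmax(t - t_flash - t0, 0)
  A0 + A1 * (1 - exp(-s / tau1)) + A2 * (1 - exp(-s / tau2)) + k * s
}

# cell_params whose step response at ca_post equals the flash curve with
# the given target parameters (Hill midpoint trick: n = 1, KD = ca_post
# gives rate rmax/2 at the step level)
step_cell_params <- function(A0 = 0, A1 = 200, tau1 = 0.03, A2 = 150,
                             tau2 = 0.3, k = 10, t0 = 0, ca_post = 20,
                             noise_sd = 0) {
  cell_params(C0 = A0, B1 = A1, rmax1 = 2 / tau1, n1 = 1, KD1 = ca_post,
              B2 = A2, rmax2 = 2 / tau2, n2 = 1, KD2 = ca_post,
              t0 = t0, k_sus_max = 2 * k, n_sus = 1, K_sus = ca_post,
              noise_sd = noise_sd)
}

sim_step_cell <- function(..., ca_post = 20, t_flash = 0.5, duration = 1.7,
                          dt = 0.002, seed = 1) {
  ca <- make_flash_protocol(0, ca_post, t_flash, duration, dt)
  simulate_cell(step_cell_params(..., ca_post = ca_post), ca, seed = seed)
}

# one-pool ramp population matching the ramp recovery study conditions
ramp_pool_params <- function(rmax, n, kd, B = 400, C0 = 5000, noise_sd = 2)
  cell_params(C0 = C0, B1 = B, rmax1 = rmax, n1 = n, KD1 = kd,
              B2 = 0, rmax2 = 0, t0 = 0, k_sus_max = 0, noise_sd = noise_sd)

simulate_ramp_group <- function(name, rmax, n, kd, n_cells = 15, cv = 0.2,
                                seed = 1, dt = 0.01, ca_start = 0.3,
                                ca_end = 8, duration = 60) {
  proto <- make_ramp_protocol(ca_start, ca_end, duration, dt)
  spec <- group_spec(name, n_cells, means = ramp_pool_params(rmax, n, kd),
                     cv = c(B1 = cv), seed = seed)
  simulate_group(spec, proto)
}

# companion flash recordings for the same parameter set (the anchor
# experiment: a near-saturating 40 uM step)
simulate_anchor_group <- function(name, rmax, n, kd, n_cells = 15, cv = 0.2,
                                  seed = 1, ca_post = 40) {
  proto <- make_flash_protocol(0.5, ca_post, t_flash = 0.5, duration = 2,
                               dt = 0.002)
  spec <- group_spec(name, n_cells, means = ramp_pool_params(rmax, n, kd),
                     cv = c(B1 = cv), seed = seed)
  simulate_group(spec, proto)
}

# full anchored ramp recovery for one parameter set
ramp_recovery <- function(rmax, n, kd, ca_max, seed, n_cells = 15,
                          n_boot = 0) {
  ramp <- simulate_ramp_group("g", rmax, n, kd, n_cells = n_cells,
                              seed = seed)
  flash <- simulate_anchor_group("g", rmax, n, kd, n_cells = n_cells,
                                 seed = seed + 5000L)
  anchor <- flash_rate_anchor(flash)
  analyze_ramp(ramp, ca_max = ca_max, anchor = anchor, n_boot = n_boot)
}

rel_err <- function(est, true) abs(est - true) / abs(true)
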