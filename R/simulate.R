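#' Hill-type calcium dependence of the vesicle fusion rate
#'
#' Saturating rate law `rate(Ca) = rmax * Ca^n / (Ca^n + kd^n)`: the apparent
#' calcium sensitivity of the fusion machinery, with cooperativity `n` and
#' half-maximal calcium `kd`.
#'
#' @param ca free calcium (uM), scalar or vector, non-negative.
#' @param rmax maximal fusion rate constant (1/s).
#' @param n Hill coefficient (> 0).
#' @param kd half-maximal calcium (uM, > 0).
#' @return Fusion rate constant(s) in 1/s, in `[0, rmax]`.
#' @examples
#' hill_rate(5, rmax = 1, n = 2, kd = 10)  # 0.2
#' hill_rate(10, rmax = 1, n = 2, kd = 10) # midpoint: rmax/2
#' @export
hill_rate <- function(ca, rmax, n, kd) {
  if (any(!is.finite(c(rmax, n, kd))) || n <= 0 || kd <= 0 || rmax < 0)
    stop("invalid Hill parameters: need rmax >= 0, n > 0, kd > 0",
         call. = FALSE)
  if (any(ca < 0)) stop("ca must be non-negative", call. = FALSE)
  s <- (ca / kd)^n
  rmax * s / (1 + s)
}

#' Generative parameters of one simulated cell
#'
#' The forward model underlying all simulated recordings: two depleting
#' primed vesicle pools (the fast pool maps to the RRP, the slow pool to the
#' SRP) whose fusion rate constants follow Hill-type calcium dependences,
#' plus a non-depleting sustained/tonic component whose membrane-addition
#' rate saturates with calcium, a pure secretory onset delay `t0`, and
#' additive Gaussian recording noise on capacitance.
#'
#' Defaults give a wild-type-like chromaffin cell: ~5 pF baseline, a 200 fF
#' fast pool with ~25 ms time constant at ~20 uM calcium, a 150 fF slow pool
#' at ~250 ms, a sustained rate of a few fF/s at the 0.5 uM loading level,
#' and 2 fF recording noise.
#'
#' @param C0 baseline membrane capacitance (fF).
#' @param B1,B2 fast (RRP) and slow (SRP) pool sizes (fF).
#' @param rmax1,rmax2 maximal fusion rate constants of the two pools (1/s).
#' @param n1,n2 Hill coefficients of the two pools.
#' @param KD1,KD2 half-maximal calcium of the two pools (uM).
#' @param t0 secretory onset delay (s): the calcium signal seen by the
#'   fusion machinery is the command signal shifted by `t0`.
#' @param k_sus_max maximal sustained membrane-addition rate (fF/s).
#' @param n_sus,K_sus Hill parameters of the sustained rate's calcium
#'   dependence.
#' @param noise_sd additive Gaussian capacitance noise SD (fF).
#' @return A named list of class `"cell_params"`.
#' @export
cell_params <- function(C0 = 5000, B1 = 200, B2 = 150,
                        rmax1 = 50, n1 = 2, KD1 = 10,
                        rmax2 = 5,  n2 = 2, KD2 = 10,
                        t0 = 0.002, k_sus_max = 30, n_sus = 1, K_sus = 2,
                        noise_sd = 2) {
  p <- list(C0 = C0, B1 = B1, B2 = B2, rmax1 = rmax1, n1 = n1, KD1 = KD1,
            rmax2 = rmax2, n2 = n2, KD2 = KD2, t0 = t0,
            k_sus_max = k_sus_max, n_sus = n_sus, K_sus = K_sus,
            noise_sd = noise_sd)
  stopifnot(all(vapply(p, is.numeric, TRUE)))
  if (p$B1 < 0 || p$B2 < 0 || p$rmax1 < 0 || p$rmax2 < 0 ||
      p$k_sus_max < 0 || p$noise_sd < 0 || p$t0 < 0)
    stop("pool sizes, rates, delay and noise_sd must be non-negative",
         call. = FALSE)
  if (p$n1 <= 0 || p$n2 <= 0 || p$n_sus <= 0 ||
      p$KD1 <= 0 || p$KD2 <= 0 || p$K_sus <= 0)
    stop("Hill coefficients and KD values must be positive", call. = FALSE)
  class(p) <- "cell_params"
  p
}

#' Specification of a simulated cell population
#'
#' Stands in for one experimental group (genotype/rescue): `n_cells` cells
#' whose generative parameters are drawn around `means` with per-field
#' coefficients of variation `cv` (mean-preserving log-normal draws, so
#' positivity constraints survive).
#'
#' @param name group label.
#' @param n_cells number of cells (>= 1).
#' @param means a [cell_params] object of population means.
#' @param cv coefficient of variation: scalar (applied to every positive
#'   parameter except `noise_sd`) or a named vector/list for selected fields,
#'   e.g. `c(B1 = 0.2)`.
#' @param seed integer seed controlling both the parameter draws and the
#'   per-cell noise streams.
#' @return A list of class `"group_spec"`.
#' @export
group_spec <- function(name, n_cells, means = cell_params(), cv = 0,
                       seed = 1) {
  if (!inherits(means, "cell_params")) means <- do.call(cell_params, means)
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  varying <- setdiff(names(unclass(means)), "noise_sd")
  if (is.null(names(cv)) && length(cv) == 1L) {
    cv <- stats::setNames(rep(as.numeric(cv), length(varying)), varying)
  } else {
    cv <- unlist(cv)
    bad <- setdiff(names(cv), names(unclass(means)))
    if (length(bad))
      stop("unknown cv fields: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(cv < 0)) stop("cv must be non-negative", call. = FALSE)
  structure(list(name = as.character(name), n_cells = as.integer(n_cells),
                 means = means, cv = cv, seed = as.integer(seed)),
            class = "group_spec")
}

# internal: delayed calcium signal (clamped at the left edge)
delayed_ca <- function(ca, t0) {
  if (t0 <= 0) return(ca$v)
  stats::approx(ca$t, ca$v, xout = ca$t - t0, rule = 2)$y
}

#' Simulate the capacitance response of one cell
#'
#' Forward-integrates the two-pool + sustained secretion model along an
#' arbitrary calcium protocol. Each depleting pool obeys
#' `dF/dt = k(Ca) * (B - F)` with `k` the Hill-type fusion rate; within a
#' sample the calcium (hence `k`) is held constant and the exact exponential
#' update is used, so the integration is exact for piecewise-constant
#' calcium and bit-reproducible. The sustained component integrates a
#' non-depleting, calcium-saturating membrane-addition rate. Gaussian noise
#' is added to the capacitance only.
#'
#' For a step protocol with negligible pre-step rates this reduces exactly to
#' `C0 + B1*(1-exp(-t'/tau1)) + B2*(1-exp(-t'/tau2)) + k*t'` with
#' `t' = t - t_flash - t0` and `tau_i = 1/k_i(ca_post)` -- the model family
#' used by [fit_flash_response()].
#'
#' @param params a [cell_params] object.
#' @param ca calcium protocol, a `"uM"` trace.
#' @param seed integer seed for the noise stream.
#' @return A `"fF"` trace sharing the protocol time base; `meta` carries
#'   the protocol annotations.
#' @export
simulate_cell <- function(params, ca, seed = 1) {
  if (!inherits(params, "cell_params")) stop("params must be cell_params",
                                             call. = FALSE)
  check_trace(ca, "uM")
  dt <- trace_dt(ca)
  cad <- delayed_ca(ca, params$t0)
  n <- length(cad)

  pool <- function(B, rmax, nh, kd) {
    if (B <= 0 || rmax <= 0) return(numeric(n))
    k <- hill_rate(cad, rmax, nh, kd)
    B * (1 - exp(-c(0, cumsum(k * dt)[-n])))
  }
  F1 <- pool(params$B1, params$rmax1, params$n1, params$KD1)
  F2 <- pool(params$B2, params$rmax2, params$n2, params$KD2)
  Fs <- if (params$k_sus_max > 0) {
    shape <- hill_rate(cad, 1, params$n_sus, params$K_sus)
    params$k_sus_max * c(0, cumsum(shape * dt)[-n])
  } else numeric(n)
  eps <- if (params$noise_sd > 0) {
    set.seed(seed)
    stats::rnorm(n, 0, params$noise_sd)
  } else numeric(n)
  new_trace(ca$t, params$C0 + F1 + F2 + Fs + eps, "fF", meta = ca$meta)
}

# internal: deterministic child seed derivation (kept below 2^31)
child_seed <- function(seed, i, stream = 0L) {
  (abs(seed) * 1009 + stream * 97 + i) %% 2147483647L
}

# internal: mean-preserving log-normal draw
rlnorm_mean_cv <- function(k, mean, cv) {
  if (mean == 0 || cv == 0) return(rep(mean, k))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(k, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a population of cells
#'
#' Draws per-cell parameters around the group means (log-normal,
#' mean-preserving, per-field CV) and simulates each cell along the shared
#' protocol. All randomness derives from `spec$seed`; re-running with the
#' same spec reproduces the population bit-for-bit.
#'
#' @param spec a [group_spec].
#' @param protocol the shared calcium protocol (`"uM"` trace).
#' @return A list of class `"cell_population"`; one element per cell, each a
#'   list with `cell_id`, `cm` (capacitance trace), `ca` (calcium trace) and
#'   `params` (the realized ground-truth [cell_params]).
#' @export
simulate_group <- function(spec, protocol) {
  if (!inherits(spec, "group_spec")) stop("spec must be a group_spec",
                                          call. = FALSE)
  check_trace(protocol, "uM")
  means <- unclass(spec$means)
  k <- spec$n_cells
  set.seed(spec$seed)
  drawn <- lapply(names(means), function(f) {
    cvf <- if (f %in% names(spec$cv)) spec$cv[[f]] else 0
    rlnorm_mean_cv(k, means[[f]], cvf)
  })
  names(drawn) <- names(means)
  cells <- lapply(seq_len(k), function(i) {
    p <- do.call(cell_params, lapply(drawn, `[`, i))
    cm <- simulate_cell(p, protocol, seed = child_seed(spec$seed, i))
    list(cell_id = sprintf("%s_%02d", spec$name, i), cm = cm, ca = protocol,
         params = p)
  })
  structure(cells, class = "cell_population", group = spec$name,
            seed = spec$seed)
}
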