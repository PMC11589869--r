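# Calcium-ramp analysis: polynomial smoothing, burst-size (EB) estimation,
# interval-wise depletion profile, calcium gridding and pool-depletion P50.

#' Polynomial smoothing of a ramp capacitance trace
#'
#' Least-squares polynomial approximation of the sigmoid capacitance rise
#' over the ramp window, evaluated back on the original time base. Used
#' before interval-wise slope computation so that 40-ms slopes are not
#' dominated by recording noise.
#'
#' @param cm capacitance trace (fF).
#' @param order polynomial order (>= 1). Order 8 follows the conventional
#'   choice; the ramp pipeline default is higher (see [analyze_ramp()]),
#'   because low orders leave systematic slope bias on steep sigmoids.
#' @param window optional `c(start, end)` restricting the fit (s); the
#'   returned trace covers only this window.
#' @return The smoothed `"fF"` trace; attributes `rss` and `order` carry
#'   the fit diagnostics.
#' @export
smooth_cm <- function(cm, order = 8, window = NULL) {
  check_trace(cm, "fF")
  t <- cm$t; v <- cm$v
  if (!is.null(window)) {
    sel <- t >= window[1] & t <= window[2]
    t <- t[sel]; v <- v[sel]
  }
  if (order < 0 || order != round(order))
    stop("order must be a non-negative integer", call. = FALSE)
  if (length(t) < order + 2)
    stop("smoothing error: need at least order + 2 points", call. = FALSE)
  X <- if (order == 0) matrix(1, length(t)) else
    cbind(1, stats::poly(t, degree = order))
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("smoothing error: ill-conditioned polynomial fit; lower the order",
         call. = FALSE)
  fitv <- drop(X %*% qr.coef(qrX, v))
  out <- new_trace(t, fitv, "fF", meta = cm$meta)
  attr(out, "rss") <- sum((v - fitv)^2)
  attr(out, "order") <- order
  out
}

#' RSS-versus-order diagnostic for ramp smoothing
#'
#' Residual sum of squares of the polynomial approximation as a function of
#' order, to judge where extra flexibility stops paying.
#'
#' @param cm capacitance trace.
#' @param orders integer vector of candidate orders.
#' @return data.frame with columns `order`, `rss`.
#' @export
smooth_order_diagnostic <- function(cm, orders = 2:16) {
  data.frame(order = orders,
             rss = vapply(orders, function(o)
               attr(smooth_cm(cm, o), "rss"), 0))
}

# internal: asymptote of the depletion tail.
# Fits y ~ A - R * exp(-(a*s + b*s^2/2)) over the terminal fraction of the
# trace (profiled: (a, b) by Nelder-Mead, (A, R) linear). The quadratic
# exponent captures the accelerating depletion along a rising ramp. Falls
# back to the terminal median when the tail is flat (fully depleted) or the
# extrapolation is untrustworthy.
tail_asymptote <- function(t, y, frac = 0.25) {
  n <- length(y)
  i <- which(t >= t[n] - frac * (t[n] - t[1]))
  s <- t[i] - t[i][1]; yy <- y[i]
  L <- s[length(s)]
  m_end <- stats::median(yy[s >= 0.8 * L])
  m_start <- stats::median(yy[s <= 0.2 * L])
  rise <- m_end - m_start
  sdr <- stats::mad(diff(yy)) / sqrt(2)
  rss_ab <- function(p) {
    x <- exp(-(exp(p[1]) * s + exp(p[2]) * s^2 / 2))
    sum(qr.resid(qr(cbind(1, x)), yy)^2)
  }
  best <- NULL
  for (st in list(c(log(0.2), log(0.01)), c(log(1 / L), log(1e-3)))) {
    o <- try(stats::optim(st, rss_ab, method = "Nelder-Mead",
                          control = list(maxit = 500, reltol = 1e-12)),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  A <- NA_real_
  if (!is.null(best)) {
    x <- exp(-(exp(best$par[1]) * s + exp(best$par[2]) * s^2 / 2))
    A <- unname(qr.coef(qr(cbind(1, x)), yy)[1])
  }
  if (!is.finite(A) || A < m_end - 3 * sdr ||
      A > m_end + max(2 * rise, 3 * sdr)) A <- m_end
  A
}

#' Estimate the exocytotic-burst size from a ramp trace
#'
#' The sigmoid capacitance rise during a slow calcium ramp reflects
#' progressive depletion of the primed vesicle pool; its total amplitude
#' estimates the exocytotic-burst (EB) size. The estimate is plateau minus
#' baseline, where the baseline is the median over the initial
#' `baseline_frac` of the window and the plateau depends on `method`:
#' \describe{
#'   \item{`"tail"`}{(default) exponential-asymptote extrapolation of the
#'     terminal `tail_frac` of the trace; corrects the bias of the plain
#'     plateau median when the ramp ends short of complete depletion.}
#'   \item{`"plateau"`}{median of the final `plateau_frac` of the window.}
#'   \item{`"final"`}{the last sample.}
#' }
#' A saturation check refuses traces still rising steeply at the end
#' (terminal slope above `saturation_frac` of the peak slope), for which no
#' pool estimate is possible.
#'
#' @param cm capacitance trace (fF), raw or smoothed.
#' @param method plateau estimator, see above.
#' @param baseline_frac initial fraction of the window taken as baseline
#'   (default 0.01; tonic secretion makes long baseline windows biased).
#' @param plateau_frac terminal fraction for `method = "plateau"`.
#' @param tail_frac terminal fraction for `method = "tail"`.
#' @param saturation_frac maximal terminal/peak slope ratio accepted.
#'   Default 0.05 for `"plateau"`/`"final"`, which need a genuinely flat
#'   plateau; 0.2 for `"tail"`, which only needs the decay to be well into
#'   its tail and extrapolates the rest.
#' @return EB size (fF), with the baseline value as attribute `baseline`.
#' @export
estimate_burst_size <- function(cm, method = c("tail", "plateau", "final"),
                                baseline_frac = 0.01, plateau_frac = 0.1,
                                tail_frac = 0.25, saturation_frac = NULL) {
  check_trace(cm, "fF")
  method <- match.arg(method)
  if (is.null(saturation_frac))
    saturation_frac <- if (method == "tail") 0.2 else 0.05
  t <- cm$t; v <- cm$v; n <- length(v)
  span <- t[n] - t[1]
  base <- stats::median(v[t <= t[1] + baseline_frac * span])

  # saturation check on 1-s (or 20-bin) binned medians: terminal slope must
  # be a small fraction of the peak slope
  nb <- max(min(60, floor(span)), 20)
  bins <- cut(t, nb)
  bm <- tapply(v, bins, stats::median)
  bt <- tapply(t, bins, stats::median)
  sl <- diff(bm) / diff(bt)
  if (max(sl) > 0 && utils::tail(sl, 1) > saturation_frac * max(sl))
    stop(paste("non-saturating trace: terminal slope exceeds",
               saturation_frac, "of peak slope; EB not estimable"),
         call. = FALSE)

  plateau <- switch(method,
    tail = tail_asymptote(t, v, tail_frac),
    plateau = stats::median(v[t >= t[n] - plateau_frac * span]),
    final = v[n])
  structure(max(plateau - base, 0), baseline = base)
}

#' Interval-wise depletion profile along a calcium ramp
#'
#' Implements the standard ramp decomposition: over consecutive fixed
#' intervals (default 40 ms, matching the cadence of ratiometric calcium
#' measurements) compute the capacitance slope, the remaining primed pool
#' `eb_size - (CM(mid) - baseline)`, and the fusion rate constant
#' `rate = slope / remaining`. Slope, remaining pool and calcium are all
#' referenced to the interval midpoint. Intervals whose remaining pool has
#' fallen below `floor_frac` of the burst size are masked: near-complete
#' depletion makes the ratio unreliable.
#'
#' @param cm_smooth smoothed capacitance trace (see [smooth_cm()]).
#' @param ca calcium trace on the same time base.
#' @param interval interval width (s), default 0.040; must span >= 2
#'   samples.
#' @param eb_size burst-size estimate (fF), see [estimate_burst_size()].
#' @param baseline baseline capacitance (fF); defaults to the `baseline`
#'   attribute of `eb_size`, else the median over the first 1% of the
#'   trace.
#' @param floor_frac remaining-pool floor as a fraction of `eb_size`.
#' @return A data.frame of class `"depletion_profile"` with columns
#'   `t_mid`, `ca_mid`, `slope` (fF/s), `remaining` (fF), `rate` (1/s),
#'   `valid`; attributes `eb_size`, `interval`, `baseline`.
#' @export
compute_depletion_profile <- function(cm_smooth, ca, interval = 0.040,
                                      eb_size, baseline = NULL,
                                      floor_frac = 0.05) {
  check_trace(cm_smooth, "fF"); check_trace(ca, "uM")
  if (eb_size <= 0) stop("eb_size must be positive", call. = FALSE)
  dt <- trace_dt(cm_smooth)
  if (interval < 2 * dt - 1e-12)
    stop("interval must span at least 2 samples", call. = FALSE)
  if (is.null(baseline)) baseline <- attr(eb_size, "baseline")
  n <- length(cm_smooth$t)
  if (is.null(baseline))
    baseline <- stats::median(cm_smooth$v[
      cm_smooth$t <= cm_smooth$t[1] + 0.01 * (cm_smooth$t[n] - cm_smooth$t[1])])
  # align calcium onto the capacitance time base
  cav <- if (length(ca$t) == n && max(abs(ca$t - cm_smooth$t)) < 1e-9)
    ca$v else stats::approx(ca$t, ca$v, xout = cm_smooth$t, rule = 2)$y

  m <- round(interval / dt)
  i0 <- seq(1L, n - m, by = m)
  v <- cm_smooth$v
  slope <- (v[i0 + m] - v[i0]) / (m * dt)
  # midpoint; for odd sample counts average the two bracketing samples
  if (m %% 2L == 0L) {
    vm <- v[i0 + m %/% 2L]; cam <- cav[i0 + m %/% 2L]
    tm <- cm_smooth$t[i0 + m %/% 2L]
  } else {
    vm <- (v[i0 + m %/% 2L] + v[i0 + m %/% 2L + 1L]) / 2
    cam <- (cav[i0 + m %/% 2L] + cav[i0 + m %/% 2L + 1L]) / 2
    tm <- (cm_smooth$t[i0 + m %/% 2L] + cm_smooth$t[i0 + m %/% 2L + 1L]) / 2
  }
  remaining <- as.numeric(eb_size) - (vm - baseline)
  valid <- remaining > floor_frac * as.numeric(eb_size)
  rate <- ifelse(valid, slope / remaining, NA_real_)
  if (!any(valid)) stop("empty profile: all intervals masked", call. = FALSE)
  out <- data.frame(t_mid = tm, ca_mid = cam, slope = slope,
                    remaining = remaining, rate = rate, valid = valid)
  attr(out, "eb_size") <- as.numeric(eb_size)
  attr(out, "interval") <- interval
  attr(out, "baseline") <- baseline
  class(out) <- c("depletion_profile", "data.frame")
  out
}

# internal: longest strictly-increasing run of x (indices)
longest_increasing_run <- function(x) {
  if (length(x) < 2L) return(seq_along(x))
  up <- c(TRUE, diff(x) > 0)
  r <- rle(up)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (!length(runs)) return(1L)
  # a TRUE-run of length L covers L+... include the element before the run
  lens <- r$lengths[runs] + ifelse(starts[runs] > 1L, 1L, 0L)
  b <- runs[which.max(lens)]
  s <- if (starts[b] > 1L) starts[b] - 1L else starts[b]
  s:ends[b]
}

#' Interpolate a depletion profile onto a regular calcium grid
#'
#' Linear interpolation of the fusion rate onto a calcium axis with fixed
#' spacing (default 50 nM), restricted to the cell's observed calcium range
#' (no extrapolation), to valid intervals, and to calcium below the
#' reliability cutoff `ca_max`. Non-monotone measured calcium is handled by
#' restricting to the longest strictly increasing run.
#'
#' @param profile a [compute_depletion_profile()] result.
#' @param grid_step grid spacing (uM), default 0.05.
#' @param ca_max reliability cutoff (uM): rates at higher calcium are
#'   dropped (excessive pool depletion makes them unreliable).
#' @return data.frame of class `"gridded_rates"` with columns `ca`, `rate`.
#' @export
interpolate_to_ca_grid <- function(profile, grid_step = 0.05, ca_max = Inf) {
  if (!inherits(profile, "depletion_profile"))
    stop("profile must be a depletion_profile", call. = FALSE)
  ok <- profile$valid & is.finite(profile$rate)
  ca <- profile$ca_mid[ok]; rate <- profile$rate[ok]
  run <- longest_increasing_run(ca)
  ca <- ca[run]; rate <- rate[run]
  keep <- ca <= ca_max
  ca <- ca[keep]; rate <- rate[keep]
  if (length(ca) < 2L)
    stop("interpolation error: fewer than 2 valid intervals", call. = FALSE)
  ki <- seq(ceiling(ca[1] / grid_step - 1e-9),
            floor(ca[length(ca)] / grid_step + 1e-9))
  grid <- ki * grid_step
  out <- data.frame(ca = grid,
                    rate = stats::approx(ca, rate, xout = grid)$y)
  attr(out, "grid_step") <- grid_step
  class(out) <- c("gridded_rates", "data.frame")
  out
}

#' Average gridded fusion rates across cells
#'
#' Per grid point, the mean and SEM of the per-cell rates over the cells
#' whose observed calcium range covers that point; points supported by
#' fewer than `min_cells` cells are dropped.
#'
#' @param gridded list of per-cell [interpolate_to_ca_grid()] results
#'   sharing the same grid definition.
#' @param min_cells minimal number of contributing cells per point.
#' @return data.frame of class `"gridded_rates"` with columns `ca`,
#'   `mean_rate`, `sem_rate`, `n_cells`.
#' @export
average_across_cells <- function(gridded, min_cells = 3) {
  if (!length(gridded)) stop("no cells to average", call. = FALSE)
  steps <- vapply(gridded, function(g) attr(g, "grid_step"), 0)
  if (max(steps) - min(steps) > 1e-12)
    stop("cells do not share a grid definition", call. = FALSE)
  step <- steps[1]
  keys <- lapply(gridded, function(g) as.integer(round(g$ca / step)))
  allk <- sort(unique(unlist(keys)))
  M <- vapply(seq_along(gridded), function(i) {
    v <- rep(NA_real_, length(allk))
    v[match(keys[[i]], allk)] <- gridded[[i]]$rate
    v
  }, numeric(length(allk)))
  M <- matrix(M, nrow = length(allk))
  n <- rowSums(!is.na(M))
  mean_rate <- rowMeans(M, na.rm = TRUE)
  sem <- apply(M, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) >= 2L) stats::sd(r) / sqrt(length(r)) else NA_real_
  })
  keep <- n >= min_cells
  if (!any(keep)) stop("no grid point supported by min_cells cells",
                       call. = FALSE)
  out <- data.frame(ca = allk[keep] * step, mean_rate = mean_rate[keep],
                    sem_rate = sem[keep], n_cells = n[keep])
  attr(out, "grid_step") <- step
  class(out) <- c("gridded_rates", "data.frame")
  out
}

#' Pool-depletion curve and P50 across cells
#'
#' For each cell, the remaining pool fraction `remaining / eb_size` is
#' interpolated onto the common calcium grid; the cross-cell mean curve is
#' the group's depletion profile and P50 is the calcium at which it crosses
#' one half (local linear interpolation between bracketing grid points).
#' The P50 standard error is estimated by a seeded bootstrap over cells.
#'
#' @param profiles list of [compute_depletion_profile()] results (one per
#'   cell, each carrying its `eb_size`).
#' @param grid_step calcium grid spacing (uM).
#' @param min_cells minimal cells per retained grid point.
#' @param n_boot bootstrap resamples for the P50 SE (0 to skip).
#' @param seed bootstrap seed.
#' @return List of class `"pool_depletion"`: `ca`, `remaining_fraction`,
#'   `n_cells`, `p50`, `p50_se`, `n_boot_defined`.
#' @export
compute_pool_depletion <- function(profiles, grid_step = 0.05,
                                   min_cells = 3, n_boot = 1000, seed = 1) {
  if (!length(profiles)) stop("no profiles", call. = FALSE)
  cells <- lapply(profiles, function(p) {
    eb <- attr(p, "eb_size")
    if (is.null(eb) || eb <= 0) stop("profile without valid eb_size",
                                     call. = FALSE)
    ok <- p$valid
    ca <- p$ca_mid[ok]; rf <- p$remaining[ok] / eb
    run <- longest_increasing_run(ca)
    ca <- ca[run]; rf <- pmin(pmax(rf[run], 0), 1)
    ki <- seq(ceiling(ca[1] / grid_step - 1e-9),
              floor(ca[length(ca)] / grid_step + 1e-9))
    list(key = ki, rf = stats::approx(ca, rf, xout = ki * grid_step)$y)
  })
  allk <- sort(unique(unlist(lapply(cells, `[[`, "key"))))
  M <- vapply(cells, function(cl) {
    v <- rep(NA_real_, length(allk))
    v[match(cl$key, allk)] <- cl$rf
    v
  }, numeric(length(allk)))
  M <- matrix(M, nrow = length(allk))

  curve_p50 <- function(cols) {
    sub <- M[, cols, drop = FALSE]
    n <- rowSums(!is.na(sub))
    keep <- n >= min(min_cells, length(cols))
    ca <- allk[keep] * grid_step
    mu <- rowMeans(sub, na.rm = TRUE)[keep]
    below <- which(mu <= 0.5)
    if (!length(below) || below[1] == 1L) return(list(ca = ca, mu = mu,
                                                      n = n[keep],
                                                      p50 = NA_real_))
    i <- below[1]
    p50 <- ca[i - 1] + (0.5 - mu[i - 1]) * (ca[i] - ca[i - 1]) /
      (mu[i] - mu[i - 1])
    list(ca = ca, mu = mu, n = n[keep], p50 = p50)
  }
  full <- curve_p50(seq_len(ncol(M)))
  if (is.na(full$p50))
    stop("p50 undefined: mean depletion curve never crosses 0.5",
         call. = FALSE)
  p50_se <- NA_real_; n_def <- 0L
  if (n_boot > 0 && ncol(M) > 1L) {
    set.seed(seed)
    bs <- vapply(seq_len(n_boot), function(b)
      curve_p50(sample.int(ncol(M), replace = TRUE))$p50, 0)
    bs <- bs[is.finite(bs)]
    n_def <- length(bs)
    p50_se <- if (n_def >= 2L) stats::sd(bs) else NA_real_
  } else if (ncol(M) == 1L) p50_se <- NA_real_
  structure(list(ca = full$ca, remaining_fraction = full$mu,
                 n_cells = full$n, p50 = full$p50, p50_se = p50_se,
                 n_boot_defined = n_def),
            class = "pool_depletion")
}

#' @export
print.pool_depletion <- function(x, ...) {
  cat(sprintf("Pool depletion over [%g, %g] uM: P50 = %.3f uM (SE %.3f, %d cells max)\n",
              min(x$ca), max(x$ca), x$p50, x$p50_se, max(x$n_cells)))
  invisible(x)
}

#' Full ramp analysis for one group of cells
#'
#' Runs the whole ramp pipeline: polynomial smoothing, burst-size
#' estimation, 40-ms depletion profile, gridding onto the 50-nM calcium
#' axis below the reliability cutoff, cross-cell averaging, Hill fit of the
#' mean rate-calcium relation and the pool-depletion P50.
#'
#' An `anchor` rate point (typically the flash-derived maximal rate
#' `1/tauRRP` at the post-flash calcium, see [fit_hill()]) can be supplied
#' to pin the saturating branch of the Hill relation, which the ramp itself
#' does not reach.
#'
#' @param cells a `"cell_population"` (see [simulate_group()]) or list of
#'   `list(cm = , ca = )` pairs.
#' @param ca_max per-group reliability cutoff (uM); `NULL` for the
#'   automatic default: the calcium at which the mean remaining pool falls
#'   below 25% of EB.
#' @param poly_order smoothing order (default 12; see the package vignette
#'   for why this exceeds the conventional 8).
#' @param interval profile interval (s).
#' @param grid_step calcium grid spacing (uM).
#' @param min_cells minimal cells per grid point.
#' @param eb_method burst-size estimator, see [estimate_burst_size()].
#' @param anchor optional `c(ca, rate)` high-calcium anchor for the Hill
#'   fit.
#' @param weighted 1/SEM^2 weighting for the Hill fit.
#' @param n_boot,seed bootstrap settings for the P50 SE.
#' @return List of class `"ramp_analysis"`: `gridded` (group mean rates),
#'   `hill` ([fit_hill()] result), `depletion` ([compute_pool_depletion()]
#'   result), `profiles`, `eb_sizes`, `ca_max`.
#' @export
analyze_ramp <- function(cells, ca_max = NULL, poly_order = 12,
                         interval = 0.040, grid_step = 0.05, min_cells = 3,
                         eb_method = "tail", anchor = NULL,
                         weighted = FALSE, n_boot = 1000, seed = 1) {
  if (!length(cells)) stop("no cells", call. = FALSE)
  profiles <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    cm <- cells[[i]]$cm; ca <- cells[[i]]$ca
    cms <- smooth_cm(cm, poly_order)
    eb <- estimate_burst_size(cm, method = eb_method)
    profiles[[i]] <- compute_depletion_profile(cms, ca, interval = interval,
                                               eb_size = eb)
  }
  eb_sizes <- vapply(profiles, attr, 0, "eb_size")
  if (is.null(ca_max)) {
    # automatic cutoff: calcium at which the remaining pool falls below 25%
    cuts <- vapply(profiles, function(p) {
      frac <- p$remaining / attr(p, "eb_size")
      i <- which(frac < 0.25)
      if (length(i)) p$ca_mid[i[1]] else max(p$ca_mid)
    }, 0)
    ca_max <- stats::median(cuts)
  }
  gridded <- lapply(profiles, interpolate_to_ca_grid, grid_step = grid_step,
                    ca_max = ca_max)
  gavg <- average_across_cells(gridded, min_cells = min_cells)
  hill <- fit_hill(gavg, weighted = weighted, anchor = anchor)
  depletion <- compute_pool_depletion(profiles, grid_step = grid_step,
                                      min_cells = min_cells,
                                      n_boot = n_boot, seed = seed)
  structure(list(gridded = gavg, hill = hill, depletion = depletion,
                 profiles = profiles, eb_sizes = eb_sizes, ca_max = ca_max),
            class = "ramp_analysis")
}

#' @export
print.ramp_analysis <- function(x, ...) {
  cat(sprintf("Ramp analysis of %d cells (EB %.0f +/- %.0f fF, cutoff %.2f uM)\n",
              length(x$profiles), mean(x$eb_sizes),
              stats::sd(x$eb_sizes) / sqrt(length(x$eb_sizes)), x$ca_max))
  print(x$hill)
  print(x$depletion)
  invisible(x)
}
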