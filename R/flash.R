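# Flash-response decomposition: double-exponential burst + sustained rate.

# model: A0 + [A1*(1-exp(-s/tau1)) + A2*(1-exp(-s/tau2)) + k*s]_{s>0},
# s = t - t_flash - t0. Stimulus-evoked terms are zero before onset.
flash_model <- function(t, t_flash, A0, A1, tau1, A2, tau2, k, t0) {
  s <- t - t_flash - t0
  on <- s > 0
  out <- rep(A0, length(t))
  s <- s[on]
  out[on] <- A0 + A1 * (1 - exp(-s / tau1)) + A2 * (1 - exp(-s / tau2)) +
    k * s
  out
}

# linear profile: given (tau1, tau2, t0), solve (A0, A1, A2, k) by OLS
flash_linear_solve <- function(t, v, t_flash, tau1, tau2, t0) {
  s <- pmax(t - t_flash - t0, 0)
  X <- cbind(1, 1 - exp(-s / tau1), 1 - exp(-s / tau2), s)
  qrX <- qr(X)
  cf <- qr.coef(qrX, v)
  cf[!is.finite(cf)] <- 0
  rss <- sum((v - X %*% cf)^2)
  list(coef = cf, rss = rss)
}

#' Decompose a flash-evoked capacitance response
#'
#' Fits the standard burst model
#' `f(t') = A0 + A1*(1 - exp(-(t'-t0)/tau1)) + A2*(1 - exp(-(t'-t0)/tau2)) +
#' k*(t'-t0)` to the capacitance trace after a calcium step, with the
#' stimulus-evoked terms clamped to zero before the secretory onset
#' `t_flash + t0`. The two exponentials are the fast (RRP) and slow (SRP)
#' burst components, `k` the sustained rate and `t0` the secretory delay.
#'
#' The double-exponential surface is multimodal, so the fitter runs a grid
#' of log-spaced time-constant seeds (amplitudes solved linearly at each
#' seed) followed by Levenberg-Marquardt refinement of all seven parameters;
#' the best-RSS solution is kept and components are relabeled so that
#' `tau1 < tau2`. Components whose fitted amplitude falls below `amp_floor`
#' have their time constant reported as `NA` (unidentifiable).
#'
#' @param cm capacitance trace (fF) covering the fit window.
#' @param t_flash flash time (s); taken from `cm$meta$t_flash` when missing.
#' @param fit_window seconds of response after the flash included in the
#'   fit (default 1 s).
#' @param baseline_window seconds of pre-flash baseline included so that
#'   `A0` is estimated jointly (default 0.2 s; set 0 to fit from the flash
#'   only).
#' @param max_delay upper bound for the secretory delay `t0` (s).
#' @param amp_floor amplitude (fF) below which a burst component is deemed
#'   unidentifiable and its tau reported `NA`.
#' @param components `2` (default) for the standard two-pool burst model;
#'   `1` fits a single burst exponential (`A2` fixed at 0), appropriate for
#'   recordings known to have one kinetic component, where a free second
#'   exponential would only soak up noise.
#' @return An object of class `"flash_fit"` with coefficients `A0, A1, tau1,
#'   A2, tau2, k, t0`, the residual sum of squares, a convergence flag and
#'   the fitted window; has `coef`, `predict`, `residuals`, `fitted`,
#'   `plot`, `print` and `summary` methods, and maps onto pool readouts via
#'   [classify_components()].
#' @examples
#' ca <- make_flash_protocol(0, 20, 0.5, 2, 0.002)
#' p <- cell_params(C0 = 0, B1 = 200, rmax1 = 2 / 0.03, n1 = 1, KD1 = 20,
#'                  B2 = 150, rmax2 = 2 / 0.3, n2 = 1, KD2 = 20, t0 = 0,
#'                  k_sus_max = 20, n_sus = 1, K_sus = 20, noise_sd = 0)
#' cm <- simulate_cell(p, ca)
#' fit <- fit_flash_response(cm, 0.5)
#' coef(fit)
#' @export
fit_flash_response <- function(cm, t_flash = NULL, fit_window = 1,
                               baseline_window = 0.2, max_delay = 0.05,
                               amp_floor = 1, components = 2) {
  if (!components %in% c(1L, 2L))
    stop("components must be 1 or 2", call. = FALSE)
  check_trace(cm, "fF")
  if (is.null(t_flash)) t_flash <- cm$meta$t_flash
  if (is.null(t_flash)) stop("t_flash not given and not found in meta",
                             call. = FALSE)
  sel <- cm$t >= t_flash - baseline_window & cm$t <= t_flash + fit_window
  t <- cm$t[sel]; v <- cm$v[sel]
  if (length(t) < 8L)
    stop("insufficient data: fewer points than needed for a 7-parameter fit",
         call. = FALSE)
  if (max(cm$t) < t_flash + 0.5 * fit_window)
    stop("trace does not cover the fit window", call. = FALSE)
  dt <- trace_dt(cm)
  scale2 <- max(sum((v - mean(v))^2), .Machine$double.eps)

  # flat trace: no burst, nothing to fit
  if (stats::sd(v) < 1e-12 * max(1, abs(mean(v)))) {
    return(new_flash_fit(c(A0 = mean(v), A1 = 0, tau1 = NA_real_, A2 = 0,
                           tau2 = NA_real_, k = 0, t0 = 0),
                         rss = 0, converged = TRUE, identifiable = FALSE,
                         t = t, v = v, t_flash = t_flash,
                         max_delay = max_delay, amp_floor = amp_floor))
  }

  taus <- c(0.01, 0.03, 0.1, 0.3, 1)
  t0s <- unique(pmin(c(0, 2 * dt, 10 * dt), max_delay))
  cand <- list()
  if (components == 2L) {
    for (t0 in t0s) for (i in seq_along(taus)) for (j in seq_along(taus)) {
      if (j <= i) next
      ls <- flash_linear_solve(t, v, t_flash, taus[i], taus[j], t0)
      cand[[length(cand) + 1L]] <- list(tau1 = taus[i], tau2 = taus[j],
                                        t0 = t0, coef = ls$coef,
                                        rss = ls$rss)
    }
  } else {
    taus1 <- c(0.005, taus, 3)
    for (t0 in t0s) for (tau in taus1) {
      s <- pmax(t - t_flash - t0, 0)
      X <- cbind(1, 1 - exp(-s / tau), s)
      cf <- qr.coef(qr(X), v)
      cf[!is.finite(cf)] <- 0
      cand[[length(cand) + 1L]] <- list(
        tau1 = tau, tau2 = NA_real_, t0 = t0,
        coef = c(cf[1], cf[2], 0, cf[3]),
        rss = sum((v - X %*% cf)^2))
    }
  }
  cand <- cand[order(vapply(cand, `[[`, 0, "rss"))]

  best <- NULL
  for (cd in cand[seq_len(min(4L, length(cand)))]) {
    fit <- if (components == 2L) {
      try(suppressWarnings(minpack.lm::nlsLM(
        v ~ flash_model(t, t_flash, A0, A1, tau1, A2, tau2, k, t0),
        start = list(A0 = cd$coef[1], A1 = max(cd$coef[2], 0),
                     tau1 = cd$tau1, A2 = max(cd$coef[3], 0),
                     tau2 = cd$tau2, k = max(cd$coef[4], 0), t0 = cd$t0),
        lower = c(-Inf, 0, 1e-4, 0, 1e-4, 0, 0),
        upper = c(Inf, Inf, 100, Inf, 100, Inf, max_delay),
        control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-15,
                                             ptol = 1e-15))), silent = TRUE)
    } else {
      try(suppressWarnings(minpack.lm::nlsLM(
        v ~ flash_model(t, t_flash, A0, A1, tau1, 0, 1, k, t0),
        start = list(A0 = cd$coef[1], A1 = max(cd$coef[2], 0),
                     tau1 = cd$tau1, k = max(cd$coef[4], 0), t0 = cd$t0),
        lower = c(-Inf, 0, 1e-4, 0, 0),
        upper = c(Inf, Inf, 100, Inf, max_delay),
        control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-15,
                                             ptol = 1e-15))), silent = TRUE)
    }
    if (inherits(fit, "try-error")) next
    rss <- sum(stats::residuals(fit)^2)
    cf <- stats::coef(fit)
    if (components == 1L)
      cf <- c(cf[c("A0", "A1", "tau1")], A2 = 0, tau2 = NA_real_,
              cf[c("k", "t0")])
    # tie-break: prefer smaller tau1 at numerically equal RSS
    if (is.null(best) || rss < best$rss * (1 - 1e-9) ||
        (rss < best$rss * (1 + 1e-9) &&
         isTRUE(cf[["tau1"]] < best$coef[["tau1"]]))) {
      best <- list(rss = rss, coef = cf)
    }
    if (rss < 1e-18 * scale2) break
  }
  if (is.null(best))
    return(new_flash_fit(c(A0 = mean(v), A1 = 0, tau1 = NA_real_, A2 = 0,
                           tau2 = NA_real_, k = 0, t0 = 0),
                         rss = Inf, converged = FALSE, identifiable = FALSE,
                         t = t, v = v, t_flash = t_flash,
                         max_delay = max_delay, amp_floor = amp_floor))

  cf <- best$coef
  # enforce fast-first labeling
  if (isTRUE(cf[["tau1"]] > cf[["tau2"]])) {
    cf[c("A1", "tau1", "A2", "tau2")] <- cf[c("A2", "tau2", "A1", "tau1")]
  }
  identifiable <- TRUE
  if (cf[["A1"]] < amp_floor) { cf[["tau1"]] <- NA_real_; identifiable <- FALSE }
  if (components == 2L && cf[["A2"]] < amp_floor) {
    cf[["tau2"]] <- NA_real_; identifiable <- FALSE
  }
  new_flash_fit(cf, rss = best$rss, converged = TRUE,
                identifiable = identifiable, t = t, v = v,
                t_flash = t_flash, max_delay = max_delay,
                amp_floor = amp_floor)
}

new_flash_fit <- function(coef, rss, converged, identifiable, t, v, t_flash,
                          max_delay, amp_floor) {
  structure(list(coefficients = coef, rss = rss, converged = converged,
                 identifiable = identifiable, n_points = length(t),
                 t = t, v = v, t_flash = t_flash, max_delay = max_delay,
                 amp_floor = amp_floor),
            class = "flash_fit")
}

#' @export
coef.flash_fit <- function(object, ...) object$coefficients

#' @export
print.flash_fit <- function(x, ...) {
  cf <- x$coefficients
  cat("Flash-evoked capacitance decomposition\n")
  cat(sprintf("  A0 = %.1f fF, A1 = %.1f fF (tau1 = %s s), A2 = %.1f fF (tau2 = %s s)\n",
              cf[["A0"]], cf[["A1"]], format(cf[["tau1"]], digits = 3),
              cf[["A2"]], format(cf[["tau2"]], digits = 3)))
  cat(sprintf("  sustained k = %.2f fF/s, delay t0 = %.1f ms\n",
              cf[["k"]], 1000 * cf[["t0"]]))
  cat(sprintf("  RSS = %.3g fF^2 over %d points; converged: %s\n",
              x$rss, x$n_points, x$converged))
  invisible(x)
}

#' @export
summary.flash_fit <- function(object, ...) {
  pools <- if (object$converged && object$identifiable)
    classify_components(object) else NULL
  out <- list(fit = object, pools = pools,
              sigma = sqrt(object$rss / max(object$n_points - 7, 1)))
  class(out) <- "summary.flash_fit"
  out
}

#' @export
print.summary.flash_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$pools)) {
    cat(sprintf("  RRP = %.1f fF (tau %.3g s), SRP = %.1f fF (tau %.3g s), EB = %.1f fF\n",
                x$pools$RRP, x$pools$tauRRP, x$pools$SRP, x$pools$tauSRP,
                x$pools$EB))
  }
  cat(sprintf("  residual SD = %.2f fF\n", x$sigma))
  invisible(x)
}

#' @export
predict.flash_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$t else
    if (inherits(newdata, "trace")) newdata$t else as.numeric(newdata)
  cf <- object$coefficients
  tau1 <- ifelse(is.na(cf[["tau1"]]), Inf, cf[["tau1"]])
  tau2 <- ifelse(is.na(cf[["tau2"]]), Inf, cf[["tau2"]])
  flash_model(t, object$t_flash, cf[["A0"]], cf[["A1"]], tau1,
              cf[["A2"]], tau2, cf[["k"]], cf[["t0"]])
}

#' @export
residuals.flash_fit <- function(object, ...) object$v - predict(object)

#' @export
fitted.flash_fit <- function(object, ...) predict(object)

#' @export
plot.flash_fit <- function(x, ...) {
  graphics::plot(x$t, x$v, pch = ".", xlab = "time (s)",
                 ylab = "capacitance (fF)", ...)
  graphics::lines(x$t, predict(x), col = 2, lwd = 2)
  graphics::abline(v = x$t_flash, lty = 3)
  invisible(x)
}

#' Label burst components as RRP / SRP and derive pool readouts
#'
#' Maps a converged [flash_fit] onto the standard readouts: the faster
#' exponential is the readily releasable pool (RRP), the slower the slowly
#' releasable pool (SRP), their sum the exocytotic burst (EB), `k` the
#' sustained rate (SR) and `t0` the secretory delay.
#'
#' @param fit a converged `"flash_fit"`.
#' @return A list with `RRP`, `SRP`, `SR`, `tauRRP`, `tauSRP`, `delay`, `EB`.
#' @export
classify_components <- function(fit) {
  if (!inherits(fit, "flash_fit")) stop("fit must be a flash_fit",
                                        call. = FALSE)
  if (!fit$converged)
    stop("classification refused: fit did not converge", call. = FALSE)
  cf <- fit$coefficients
  a <- c(cf[["A1"]], cf[["A2"]])
  tau <- c(cf[["tau1"]], cf[["tau2"]])
  # fit_flash_response already enforces tau1 < tau2, but accept permissive
  # orderings from elsewhere
  if (all(is.finite(tau)) && tau[1] > tau[2]) { a <- rev(a); tau <- rev(tau) }
  list(RRP = a[1], SRP = a[2], SR = cf[["k"]], tauRRP = tau[1],
       tauSRP = tau[2], delay = cf[["t0"]], EB = a[1] + a[2])
}

#' Quantify premature (tonic) secretion during the loading phase
#'
#' During the ~2 min infusion at submicromolar calcium preceding the
#' stimulus, vesicles that escape the fusion clamp add membrane
#' prematurely. This measures the total capacitance gain over the loading
#' window and the tonic exocytosis rate (OLS slope over the final
#' `rate_subwindow` seconds), together with the mean calcium over the
#' window.
#'
#' @param cm capacitance trace (fF).
#' @param ca calcium trace (uM) on the same time base.
#' @param window `c(start, end)` of the loading phase (s).
#' @param rate_subwindow length (s) of the terminal sub-window used for the
#'   tonic-rate slope (default 30 s, capped at the window length).
#' @return A list of class `"premature_secretion"`: `delta_cm` (fF),
#'   `tonic_rate` (fF/s), `mean_ca` (uM), `window`.
#' @export
measure_premature_secretion <- function(cm, ca, window,
                                        rate_subwindow = 30) {
  check_trace(cm, "fF"); check_trace(ca, "uM")
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be c(start, end) with start < end", call. = FALSE)
  if (window[1] < min(cm$t) - 1e-9 || window[2] > max(cm$t) + 1e-9)
    stop("invalid window: outside the trace extent", call. = FALSE)
  rate_subwindow <- min(rate_subwindow, diff(window))
  sel <- cm$t >= window[1] & cm$t <= window[2]
  tw <- cm$t[sel]; vw <- cm$v[sel]
  delta_cm <- vw[length(vw)] - vw[1]
  rsel <- tw >= window[2] - rate_subwindow
  tonic_rate <- unname(stats::coef(stats::lm(vw[rsel] ~ tw[rsel]))[2])
  mean_ca <- mean(ca$v[ca$t >= window[1] & ca$t <= window[2]])
  structure(list(delta_cm = delta_cm, tonic_rate = tonic_rate,
                 mean_ca = mean_ca, window = window),
            class = "premature_secretion")
}

#' Flash-derived anchor point for the Hill fit of ramp rates
#'
#' Fits each flash recording of a group, takes the RRP rate constant
#' `1/tauRRP` of every identifiable cell and returns the mean rate plotted
#' at the post-flash calcium -- the conventional high-calcium anchor of the
#' fusion-rate vs calcium relation, which the ramp data (restricted to low
#' calcium by the depletion-reliability cutoff) cannot constrain by
#' themselves.
#'
#' @param cells a `"cell_population"` or list of `list(cm, ca)` recorded
#'   under a step (flash) protocol.
#' @param t_flash flash time (s); default from the first cell's protocol
#'   metadata.
#' @param ca_post post-flash calcium (uM); default from protocol metadata.
#' @param components burst components fitted per cell (default 1: anchor
#'   experiments target the dominant kinetic component; a spurious free
#'   second exponential would distort `1/tau`).
#' @param ... passed to [fit_flash_response()].
#' @return Numeric `c(ca, rate)` usable as the `anchor` of [fit_hill()] /
#'   [analyze_ramp()].
#' @export
flash_rate_anchor <- function(cells, t_flash = NULL, ca_post = NULL,
                              components = 1, ...) {
  if (!length(cells)) stop("no cells", call. = FALSE)
  meta <- cells[[1]]$ca$meta
  if (is.null(t_flash)) t_flash <- meta$t_flash
  if (is.null(ca_post)) ca_post <- meta$ca_post
  if (is.null(t_flash) || is.null(ca_post))
    stop("t_flash / ca_post not given and not found in protocol metadata",
         call. = FALSE)
  rates <- vapply(cells, function(cl) {
    fit <- fit_flash_response(cl$cm, t_flash, components = components, ...)
    if (!fit$converged) return(NA_real_)
    tau <- classify_components(fit)$tauRRP
    if (is.finite(tau)) 1 / tau else NA_real_
  }, 0)
  rates <- rates[is.finite(rates)]
  if (!length(rates)) stop("no identifiable flash kinetics in this group",
                           call. = FALSE)
  c(ca = ca_post, rate = mean(rates))
}

#' @export
print.premature_secretion <- function(x, ...) {
  cat(sprintf(
    "Premature secretion over [%g, %g] s: dCM = %.1f fF, tonic rate = %.2f fF/s at %.3f uM\n",
    x$window[1], x$window[2], x$delta_cm, x$tonic_rate, x$mean_ca))
  invisible(x)
}
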