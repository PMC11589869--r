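# Hill fit of the fusion rate vs calcium relation.

#' Fit a Hill equation to mean fusion rates
#'
#' Least squares of `rate(Ca) = rmax * Ca^n / (Ca^n + KD^n)` to the
#' cross-cell mean rates on the calcium grid, with multi-start seeding over
#' Hill coefficients `n` in 1..4 and several KD scales (the amplitude is
#' solved linearly at each seed) followed by Levenberg-Marquardt
#' refinement. Standard errors come from the local quadratic approximation
#' at the optimum.
#'
#' Because ramp rates are only reliable well below saturation, `rmax` and
#' `KD` are nearly collinear on ramp data alone; supplying a high-calcium
#' `anchor` point -- conventionally the flash-evoked RRP rate constant
#' `1/tauRRP` plotted at the post-flash calcium, which in published ramp
#' analyses is the extrapolation target of the rate relation -- pins the
#' saturating branch and makes `KD` identifiable. A fitted `KD` beyond 10x
#' the largest (non-anchor) calcium is flagged as extrapolated.
#'
#' @param grid a `"gridded_rates"` data.frame (per-cell `rate` or group
#'   `mean_rate` column).
#' @param weighted logical: weight by `1/sem_rate^2` where available.
#' @param anchor optional numeric `c(ca, rate)` appended as an additional
#'   observation.
#' @param fix_n optional fixed Hill coefficient (then only `rmax`, `KD` are
#'   free).
#' @return Object of class `"hill_fit"` with elements `coefficients`
#'   (`rmax`, `n`, `kd`), `se`, `rss`, `converged`, `kd_extrapolated`
#'   (`TRUE` when the fitted KD lies beyond the gridded calcium range, i.e.
#'   rests on extrapolation), `data`; methods: print, summary, coef,
#'   predict, residuals, plot.
#' @examples
#' ca <- seq(0.5, 8, by = 0.05)
#' g <- structure(data.frame(ca = ca, mean_rate = hill_rate(ca, 10, 2, 3)),
#'                class = c("gridded_rates", "data.frame"))
#' coef(fit_hill(g))
#' @export
fit_hill <- function(grid, weighted = FALSE, anchor = NULL, fix_n = NULL) {
  rate <- if ("mean_rate" %in% names(grid)) grid$mean_rate else grid$rate
  ca <- grid$ca
  ok <- is.finite(ca) & is.finite(rate)
  ca <- ca[ok]; rate <- rate[ok]
  w <- rep(1, length(ca))
  if (weighted && "sem_rate" %in% names(grid)) {
    s <- grid$sem_rate[ok]
    w <- ifelse(is.finite(s) & s > 0, 1 / s^2, NA)
    w[!is.finite(w)] <- max(w[is.finite(w)], 1)
  }
  if (length(ca) < 5L)
    stop("need at least 5 grid points for a Hill fit", call. = FALSE)
  ca_data_max <- max(ca)
  if (max(ca) / min(ca[ca > 0]) < 4)
    stop("grid spans less than a 4-fold calcium range", call. = FALSE)
  if (!is.null(anchor)) {
    if (length(anchor) != 2L || any(!is.finite(anchor)) || any(anchor <= 0))
      stop("anchor must be c(ca, rate), positive", call. = FALSE)
    ca <- c(ca, anchor[1]); rate <- c(rate, anchor[2])
    w <- c(w, stats::median(w))
  }
  if (max(rate) <= 0 || stats::sd(rate) < 1e-12 * max(abs(rate), 1)) {
    out <- structure(list(coefficients = c(rmax = mean(rate), n = NA_real_,
                                           kd = NA_real_),
                          se = c(rmax = NA_real_, n = NA_real_,
                                 kd = NA_real_),
                          rss = sum(w * (rate - mean(rate))^2),
                          converged = FALSE, kd_extrapolated = FALSE,
                          data = data.frame(ca = ca, rate = rate, w = w)),
                     class = "hill_fit")
    warning("rate grid is constant: Hill parameters not identifiable; ",
            "returning an rmax-only fit", call. = FALSE)
    return(out)
  }

  n_seeds <- if (is.null(fix_n)) 1:4 else fix_n
  kd_seeds <- ca_data_max * c(0.5, 1, 3, 10)
  best <- NULL
  for (n0 in n_seeds) for (kd0 in kd_seeds) {
    f <- ca^n0 / (ca^n0 + kd0^n0)
    r0 <- sum(w * f * rate) / sum(w * f^2)
    if (!is.finite(r0) || r0 <= 0) r0 <- max(rate)
    fit <- if (is.null(fix_n)) {
      try(suppressWarnings(minpack.lm::nlsLM(
        rate ~ rmax * ca^n / (ca^n + kd^n),
        start = list(rmax = r0, n = n0, kd = kd0), weights = w,
        lower = c(1e-8, 1e-3, 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 800, ftol = 1e-15,
                                             ptol = 1e-15))), silent = TRUE)
    } else {
      nfix <- fix_n
      try(suppressWarnings(minpack.lm::nlsLM(
        rate ~ rmax * ca^nfix / (ca^nfix + kd^nfix),
        start = list(rmax = r0, kd = kd0), weights = w,
        lower = c(1e-8, 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 800, ftol = 1e-15,
                                             ptol = 1e-15))), silent = TRUE)
    }
    if (inherits(fit, "try-error")) next
    rss <- sum(w * stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss * (1 - 1e-12)) {
      best <- list(rss = rss, fit = fit)
    }
  }
  if (is.null(best))
    stop("Hill fit failed to converge from any start", call. = FALSE)
  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  if (is.null(fix_n)) {
    coefs <- c(rmax = unname(cf["rmax"]), n = unname(cf["n"]),
               kd = unname(cf["kd"]))
    ses <- c(rmax = unname(se["rmax"]), n = unname(se["n"]),
             kd = unname(se["kd"]))
  } else {
    coefs <- c(rmax = unname(cf["rmax"]), n = fix_n, kd = unname(cf["kd"]))
    ses <- c(rmax = unname(se["rmax"]), n = NA_real_, kd = unname(se["kd"]))
  }
  structure(list(coefficients = coefs, se = ses, rss = best$rss,
                 converged = TRUE,
                 kd_extrapolated = coefs[["kd"]] > ca_data_max,
                 data = data.frame(ca = ca, rate = rate, w = w)),
            class = "hill_fit")
}

#' @export
coef.hill_fit <- function(object, ...) object$coefficients

#' @export
print.hill_fit <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("Hill fit: rmax = %.3g 1/s, n = %.3g, KD = %.3g uM%s\n",
              cf[["rmax"]], cf[["n"]], cf[["kd"]],
              if (isTRUE(x$kd_extrapolated)) " (KD extrapolated)" else ""))
  cat(sprintf("  RSS = %.3g over %d points; converged: %s\n",
              x$rss, nrow(x$data), x$converged))
  invisible(x)
}

#' @export
summary.hill_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se)
  out <- list(fit = object, table = tab)
  class(out) <- "summary.hill_fit"
  out
}

#' @export
print.summary.hill_fit <- function(x, ...) {
  print(x$fit)
  stats::printCoefmat(x$table, na.print = "-")
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  ca <- if (is.null(newdata)) object$data$ca else
    if (is.data.frame(newdata)) newdata$ca else as.numeric(newdata)
  cf <- object$coefficients
  hill_rate(ca, cf[["rmax"]], cf[["n"]], cf[["kd"]])
}

#' @export
residuals.hill_fit <- function(object, ...)
  object$data$rate - predict(object)

#' @export
plot.hill_fit <- function(x, log = "xy", ...) {
  d <- x$data
  graphics::plot(d$ca, d$rate, log = log, xlab = "[Ca]i (uM)",
                 ylab = "fusion rate (1/s)", ...)
  cg <- exp(seq(log(min(d$ca)), log(max(d$ca)), length.out = 200))
  graphics::lines(cg, predict(x, cg), col = 2, lty = 2, lwd = 2)
  invisible(x)
}
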