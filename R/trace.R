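#' Uniformly sampled recording trace
#'
#' Container for one channel of a whole-cell recording: membrane capacitance
#' (fF) or intracellular free calcium (uM) on a strictly increasing, uniform
#' time base.
#'
#' @param t numeric vector of sample times in seconds; strictly increasing,
#'   uniform step.
#' @param v numeric vector of sample values, same length as `t`; fF for
#'   capacitance, uM for calcium.
#' @param unit `"fF"` or `"uM"`.
#' @param meta named list of protocol annotations (e.g. `t_flash`, ramp
#'   window) carried along with the trace.
#'
#' @return An object of class `"trace"`: a list with elements `t`, `v`,
#'   `unit`, `meta` and a `dt` attribute (the common sampling step).
#' @examples
#' tr <- new_trace(seq(0, 1, by = 0.01), rep(0.5, 101), "uM")
#' print(tr)
#' @export
new_trace <- function(t, v, unit = c("fF", "uM"), meta = list()) {
  unit <- match.arg(unit)
  t <- as.numeric(t)
  v <- as.numeric(v)
  if (length(t) != length(v))
    stop("t and v must have the same length", call. = FALSE)
  if (length(t) < 2L)
    stop("a trace needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(t)) || !all(is.finite(v)))
    stop("trace contains non-finite values", call. = FALSE)
  steps <- diff(t)
  dt <- stats::median(steps)
  if (dt <= 0)
    stop("time base must be strictly increasing", call. = FALSE)
  # uniform sampling: tolerate only float rounding of the grid itself
  if (max(abs(steps - dt)) > 1e-9 * dt + 1e-12)
    stop("time base is not uniformly sampled", call. = FALSE)
  if (unit == "uM" && any(v < 0))
    stop("calcium concentrations must be non-negative", call. = FALSE)
  structure(list(t = t, v = v, unit = unit, meta = meta),
            dt = dt, class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %d samples, dt = %g s, unit = %s, range [%g, %g]\n",
              length(x$t), attr(x, "dt"), x$unit, min(x$v), max(x$v)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.trace <- function(x) length(x$t)

# internal: sampling step
trace_dt <- function(x) attr(x, "dt")

# internal: assert a trace of the given unit
check_trace <- function(x, unit, arg = deparse(substitute(x))) {
  if (!inherits(x, "trace"))
    stop(sprintf("%s must be a trace object", arg), call. = FALSE)
  if (!missing(unit) && x$unit != unit)
    stop(sprintf("%s must be a %s trace, got %s", arg, unit, x$unit),
         call. = FALSE)
  invisible(x)
}

#' Step (flash photolysis) calcium protocol
#'
#' Builds the intracellular calcium time course of a flash-uncaging
#' experiment: a constant submicromolar loading level that steps to a high
#' post-flash level at `t_flash`. With `ca_pre == ca_post` this degenerates
#' to a constant loading-phase protocol.
#'
#' @param ca_pre pre-flash free calcium (uM), typically ~0.5-0.8.
#' @param ca_post post-flash free calcium (uM), typically tens of uM.
#' @param t_flash flash time (s), strictly inside `(0, duration)`.
#' @param duration total protocol duration (s).
#' @param dt sampling step (s).
#' @return A `"uM"` trace with `meta$t_flash` set.
#' @examples
#' ca <- make_flash_protocol(0.5, 20, t_flash = 0.5, duration = 2, dt = 0.002)
#' @export
make_flash_protocol <- function(ca_pre, ca_post, t_flash, duration, dt) {
  if (dt <= 0 || duration <= 0)
    stop("dt and duration must be positive", call. = FALSE)
  if (ca_pre < 0 || ca_post < 0)
    stop("calcium levels must be non-negative", call. = FALSE)
  if (t_flash <= 0 || t_flash >= duration)
    stop("t_flash must lie strictly inside the protocol", call. = FALSE)
  t <- seq(0, duration, by = dt)
  v <- ifelse(t < t_flash, ca_pre, ca_post)
  new_trace(t, v, "uM", meta = list(kind = "flash", t_flash = t_flash,
                                ca_pre = ca_pre, ca_post = ca_post))
}

#' Linear calcium-ramp protocol
#'
#' Calcium time course of a slow-uncaging ramp experiment: free calcium
#' rising linearly from `ca_start` to `ca_end` over `duration`.
#'
#' @param ca_start starting free calcium (uM).
#' @param ca_end final free calcium (uM), must exceed `ca_start`.
#' @param duration ramp duration (s).
#' @param dt sampling step (s).
#' @return A `"uM"` trace with the ramp window in `meta`.
#' @examples
#' ca <- make_ramp_protocol(0.3, 8, duration = 60, dt = 0.01)
#' @export
make_ramp_protocol <- function(ca_start, ca_end, duration, dt) {
  if (dt <= 0 || duration <= 0)
    stop("dt and duration must be positive", call. = FALSE)
  if (ca_start < 0)
    stop("calcium levels must be non-negative", call. = FALSE)
  if (ca_end <= ca_start)
    stop("ca_end must exceed ca_start", call. = FALSE)
  t <- seq(0, duration, by = dt)
  v <- ca_start + (ca_end - ca_start) * t / duration
  new_trace(t, v, "uM", meta = list(kind = "ramp", ca_start = ca_start,
                                ca_end = ca_end, duration = duration))
}
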