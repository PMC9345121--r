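#' Fit activation/inactivation time constants with the exponential product
#'
#' Fits the baseline-subtracted, sign-rectified test-pulse current with the
#' product of a single-exponential activation and a single-exponential
#' decay,
#' \deqn{I(t) = C (1 - e^{-(t - t_0)/\tau_{act}}) e^{-(t - t_0)/\tau_{inact}},}
#' where `C` is the y-intercept scale and `t0` the pulse-onset delay.
#' Initial guesses: `t0` at the pulse onset, `tau_inact` from a log-linear
#' regression of the decay tail, and `tau_act` by solving the time-to-peak
#' identity \eqn{t_{peak} = \tau_{act} \ln(1 + \tau_{inact}/\tau_{act})}
#' for the observed peak time.
#'
#' @param sweep A `cav_sweep` containing a depolarizing test segment (e.g.
#'   from [protocol_kinetics()]).
#' @param window Optional `c(start, end)` ms of the test segment; defaults
#'   to the annotated test segment.
#' @return A `kinetics_fit`: list with `tau_act`, `tau_inact` (ms),
#'   `amplitude_c` (pA), `t0` (ms), `rss`, `converged`.
#' @export
#' @examples
#' p <- cav33_fixtures()$WT
#' sw <- simulate_recording(p, protocol_kinetics(), noise_sd = 0)$sweeps[[1]]
#' fit_kinetics(sw)
fit_kinetics <- function(sweep, window = NULL) {
  seg <- attr(sweep, "segments")
  if (is.null(window)) {
    if (is.null(seg)) stop("window must be given for unannotated sweeps")
    ts <- attr(sweep, "test_segment")
    if (is.null(ts)) ts <- which(seg$voltage > seg$voltage[1])[1]
    if (is.na(ts)) stop("sweep has no depolarizing segment")
    window <- c(seg$start[ts], seg$end[ts])
  }
  pm <- peak_current(sweep, window = window)
  inw <- sweep$time >= window[1] & sweep$time <= window[2]
  t <- sweep$time[inw] - window[1]
  y <- -(sweep$current[inw] - pm$baseline)    # rectified: inward -> positive
  if (pm$i_peak > 0) y <- -y                  # outward transient

  out <- list(tau_act = NA_real_, tau_inact = NA_real_,
              amplitude_c = NA_real_, t0 = NA_real_, rss = NA_real_,
              converged = FALSE)
  class(out) <- "kinetics_fit"

  kpk <- which.max(y)
  t_peak <- t[kpk]
  y_peak <- y[kpk]
  if (!is.finite(y_peak) || y_peak <= 0) return(out)

  # tail log-linear regression for tau_inact
  tail_i <- t > min(2 * t_peak, max(t) * 0.5) & y > y_peak * 1e-3
  tau_i0 <- if (sum(tail_i) > 5) {
    b <- unname(stats::coef(stats::lm(log(y[tail_i]) ~ t[tail_i]))[2])
    if (is.finite(b) && b < 0) -1 / b else 5 * t_peak
  } else 5 * t_peak
  # invert t_peak = tau_a * log(1 + tau_i / tau_a)
  g <- function(ta) ta * log1p(tau_i0 / ta) - t_peak
  tau_a0 <- tryCatch(
    stats::uniroot(g, lower = 1e-4, upper = 10 * t_peak + 1)$root,
    error = function(e) max(t_peak / 2, 0.5))
  c0 <- y_peak / ((1 - exp(-t_peak / tau_a0)) * exp(-t_peak / tau_i0))

  df <- data.frame(t = t, y = y)
  run_fit <- function(start) tryCatch(
    minpack.lm::nlsLM(
      y ~ C * (1 - exp(-pmax(t - t0, 0) / tau_a)) *
        exp(-pmax(t - t0, 0) / tau_i),
      data = df, start = start,
      lower = c(C = 0, tau_a = 1e-4, tau_i = 1e-4, t0 = -2),
      upper = c(C = Inf, tau_a = Inf, tau_i = Inf, t0 = max(t) / 2),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  fit <- run_fit(list(C = c0, tau_a = tau_a0, tau_i = tau_i0, t0 = 0))
  if (is.null(fit))  # near-exact guesses can degenerate the numeric
    fit <- run_fit(list(C = c0 * 1.1, tau_a = tau_a0 * 1.15,
                        tau_i = tau_i0 * 0.9, t0 = 0.05))
  if (is.null(fit)) return(out)
  cf <- stats::coef(fit)
  out$tau_act <- unname(cf["tau_a"])
  out$tau_inact <- unname(cf["tau_i"])
  out$amplitude_c <- unname(cf["C"])
  out$t0 <- unname(cf["t0"])
  out$rss <- sum(stats::resid(fit)^2)
  out$converged <- is.finite(out$rss)
  out
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("<kinetics_fit> tau_act = %.2f ms, tau_inact = %.2f ms, C = %.1f pA (%s)\n",
              x$tau_act, x$tau_inact, x$amplitude_c,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Window-current area under overlapping activation/inactivation curves
#'
#' The window current is the sustained Ca2+ influx in the voltage band where
#' the activation and availability curves overlap. It is quantified here as
#' the area under the pointwise minimum of the two fitted normalized
#' Boltzmann curves, integrated by the trapezoid rule over `v_range` at
#' `grid_step` spacing (units: mV x normalized fraction).
#'
#' @param act A `boltzmann_fit` with orientation `"activation"` (or a list
#'   with `v05` and `slope`).
#' @param inact A `boltzmann_fit` with orientation `"inactivation"`.
#' @param v_range Integration bounds `c(low, high)`, mV. The default
#'   \[-90, +20\] is the conditioning-prepulse range.
#' @param grid_step Quadrature step, mV.
#' @return A `window_result`: list with `area`, `v_range`, `grid_step` and
#'   `v_peak` (voltage maximizing the overlap, i.e. the curve crossing).
#' @export
#' @examples
#' act <- list(v05 = -20.6, slope = 5.8)
#' inact <- list(v05 = -47.1, slope = 6.9)
#' window_area(act, inact)$area
window_area <- function(act, inact, v_range = c(-90, 20), grid_step = 0.01) {
  if (length(v_range) != 2 || v_range[1] >= v_range[2])
    stop("invalid integration range")
  if (grid_step <= 0) stop("grid_step must be > 0")
  v <- seq(v_range[1], v_range[2], by = grid_step)
  a <- 1 / (1 + exp((act$v05 - v) / act$slope))
  h <- 1 / (1 + exp((v - inact$v05) / inact$slope))
  y <- pmin(a, h)
  area <- sum((y[-1] + y[-length(y)]) / 2) * grid_step
  # last partial panel if the range is not a multiple of the step
  last <- v[length(v)]
  if (last < v_range[2]) {
    a2 <- 1 / (1 + exp((act$v05 - v_range[2]) / act$slope))
    h2 <- 1 / (1 + exp((v_range[2] - inact$v05) / inact$slope))
    area <- area + (min(a2, h2) + y[length(y)]) / 2 * (v_range[2] - last)
  }
  structure(list(area = area, v_range = v_range, grid_step = grid_step,
                 v_peak = v[which.max(y)]),
            class = "window_result")
}

#' Ratio of a variant's window area to a reference (wild type)
#'
#' @param variant,reference `window_result` objects computed on the same
#'   voltage range and grid.
#' @return Dimensionless area ratio.
#' @export
window_ratio <- function(variant, reference) {
  if (!isTRUE(all.equal(variant$v_range, reference$v_range)) ||
      !isTRUE(all.equal(variant$grid_step, reference$grid_step)))
    stop("window areas must share v_range and grid_step")
  if (reference$area <= 0) stop("reference window area is zero")
  variant$area / reference$area
}

#' @export
print.window_result <- function(x, ...) {
  cat(sprintf("<window_result> area = %.4f mV over [%g, %g] mV (peak at %.1f mV)\n",
              x$area, x$v_range[1], x$v_range[2], x$v_peak))
  invisible(x)
}
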