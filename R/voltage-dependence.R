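#' Peak current of a sweep
#'
#' Measures the peak current amplitude within a time window, after
#' subtracting a baseline estimated from the holding segment that precedes
#' the window. The peak is the extremum of the baseline-subtracted current,
#' sign preserved: for inward Ca2+ currents this is the minimum.
#'
#' @param sweep A `cav_sweep` (or data frame with `time` and `current`).
#' @param window Numeric `c(start, end)` in ms; defaults to the sweep's test
#'   segment when it carries segment annotations.
#' @param baseline_window Optional `c(start, end)` for the baseline mean;
#'   defaults to all samples before `window[1]` at the initial command
#'   voltage (the holding segment).
#' @param smooth_ms Width (ms) of the centered running-mean filter applied
#'   inside the window before peak detection, emulating the low-pass
#'   filtering applied to experimental records; it suppresses the upward
#'   bias of taking the extremum of many noisy samples. 0 disables.
#' @return List with `i_peak` (pA, signed), `baseline` (pA), `peak_time`
#'   (ms) and `window`.
#' @export
#' @examples
#' p <- cav33_fixtures()$WT
#' sw <- simulate_sweep(data.frame(duration = c(10, 100, 10),
#'                                 voltage = c(-90, -10, -90)), p)
#' peak_current(sw, window = c(10, 110))$i_peak
peak_current <- function(sweep, window = NULL, baseline_window = NULL,
                         smooth_ms = 0.5) {
  if (is.null(window)) {
    seg <- attr(sweep, "segments")
    if (is.null(seg)) stop("window must be given for unannotated sweeps")
    ts <- attr(sweep, "test_segment")
    if (is.null(ts)) ts <- 2L
    window <- c(seg$start[ts], seg$end[ts])
  }
  if (window[1] < min(sweep$time) || window[2] > max(sweep$time) ||
      window[1] >= window[2])
    stop("peak window outside the sweep time range")
  if (all(is.na(sweep$current))) stop("sweep current is all NA")

  if (is.null(baseline_window)) {
    pre <- sweep$time < window[1]
    if ("command" %in% names(sweep))
      pre <- pre & sweep$command == sweep$command[1]
    if (!any(pre)) pre <- sweep$time < window[1]
  } else {
    pre <- sweep$time >= baseline_window[1] & sweep$time < baseline_window[2]
  }
  baseline <- if (any(pre)) mean(sweep$current[pre], na.rm = TRUE) else 0

  inw <- sweep$time >= window[1] & sweep$time <= window[2]
  y <- sweep$current[inw] - baseline
  if (smooth_ms > 0 && length(y) > 3) {
    dt <- attr(sweep, "sample_interval")
    if (is.null(dt)) dt <- stats::median(diff(sweep$time))
    w <- max(1L, round(smooth_ms / dt))
    if (w > 1) {
      ys <- stats::filter(y, rep(1 / w, w), sides = 2)
      y <- ifelse(is.na(ys), y, ys)  # keep raw values at the edges
    }
  }
  k <- which.max(abs(y))
  list(i_peak = y[k], baseline = baseline,
       peak_time = sweep$time[inw][k], window = window)
}

# Peak for sweep i measured over the protocol's test segment.
test_peak <- function(rec, i) {
  sw <- rec$sweeps[[i]]
  seg <- attr(sw, "segments")
  ts <- rec$protocol$test_segment
  peak_current(sw, window = c(seg$start[ts], seg$end[ts]))
}

#' Current density of a cell
#'
#' Peak current magnitude at the -10 mV density pulse divided by the cell
#' capacitance, in pA/pF: a proxy for functional channel density at the
#' membrane. Accepts a density-pulse recording or an I-V recording that
#' contains a -10 mV sweep.
#'
#' @param rec A `cav_recording` under [protocol_density()] or
#'   [protocol_iv()].
#' @return Data frame row: `cell_id`, `construct`, `density` (pA/pF,
#'   magnitude), `i_peak` (pA), `capacitance`, `replicate_batch`,
#'   `hours_post_transfection`.
#' @export
current_density <- function(rec) {
  if (rec$capacitance <= 0) stop("capacitance must be > 0")
  i <- which(vapply(seq_along(rec$sweeps), function(k) {
    seg <- attr(rec$sweeps[[k]], "segments")
    isTRUE(all.equal(seg$voltage[rec$protocol$test_segment], -10))
  }, logical(1)))
  if (length(i) == 0) stop("recording has no -10 mV test sweep")
  pm <- test_peak(rec, i[1])
  data.frame(cell_id = rec$cell_id, construct = rec$construct_label,
             density = abs(pm$i_peak) / rec$capacitance,
             i_peak = pm$i_peak, capacitance = rec$capacitance,
             replicate_batch = rec$replicate_batch,
             hours_post_transfection = rec$hours_post_transfection,
             stringsAsFactors = FALSE)
}

#' Normalized conductance-voltage (G-V) curve of one cell
#'
#' Converts the peak current at each test voltage of an I-V family to a
#' chord conductance \eqn{G(V) = I_{peak}/(V - E_{rev})} and normalizes by
#' the maximal conductance over the family. Voltages within `exclude_mv` of
#' the reversal potential are excluded (the chord conductance degenerates
#' there).
#'
#' @param rec A `cav_recording` under [protocol_iv()].
#' @param erev Reversal potential used for the driving force, mV.
#' @param exclude_mv Half-width of the exclusion band around `erev`, mV.
#' @return Data frame with `voltage` (mV) and `value` (G/Gmax); max value
#'   is exactly 1.
#' @export
build_gv <- function(rec, erev = rec$params$erev, exclude_mv = 5) {
  volts <- rec$protocol$sweep_voltages
  keep <- abs(volts - erev) > exclude_mv
  if (!any(keep)) stop("all sweeps fall in the exclusion band around erev")
  g <- vapply(which(keep), function(i) {
    test_peak(rec, i)$i_peak / (volts[i] - erev)
  }, numeric(1))
  gmax <- max(g)
  if (gmax <= 0) stop("non-positive maximal conductance")
  data.frame(voltage = volts[keep], value = g / gmax)
}

#' Channel availability curve (steady-state inactivation) of one cell
#'
#' Normalized peak test-pulse current versus conditioning prepulse voltage:
#' the fraction of channels still available after a 1-s prepulse, measured
#' by the fixed -20 mV test pulse and normalized to the largest peak in the
#' prepulse family (fully available at -90 mV).
#'
#' @param rec A `cav_recording` under [protocol_ssi()].
#' @return Data frame with `voltage` (prepulse mV) and `value` (I/Imax);
#'   max value is exactly 1.
#' @export
build_availability <- function(rec) {
  if (is.null(rec$protocol$test_segment) ||
      rec$protocol$test_segment > nrow(rec$protocol$segments))
    stop("protocol has no test-pulse segment")
  volts <- rec$protocol$sweep_voltages
  amp <- vapply(seq_along(volts), function(i) abs(test_peak(rec, i)$i_peak),
                numeric(1))
  data.frame(voltage = volts, value = amp / max(amp))
}

#' Fit a Boltzmann function to a normalized curve
#'
#' Least-squares fit of the orientation-appropriate logistic:
#' increasing \eqn{1/(1+\exp((V_{0.5}-V)/d))} for activation, decreasing
#' \eqn{1/(1+\exp((V-V_{0.5})/d))} for inactivation, with slope factor
#' \eqn{d > 0}. Initial guesses come from linear interpolation of the 0.5
#' crossing and the 0.25-0.75 voltage span. Optimizer failures and
#' degenerate inputs set `converged = FALSE` rather than raising.
#'
#' @param points Data frame with `voltage` and `value`.
#' @param orientation `"activation"` or `"inactivation"`.
#' @return A `boltzmann_fit`: list with `v05`, `slope`, `orientation`,
#'   `rss`, `converged`, `n_points`.
#' @export
#' @examples
#' v <- seq(-90, 10, 5)
#' pts <- data.frame(voltage = v, value = 1 / (1 + exp((-20.6 - v) / 5.8)))
#' fit_boltzmann(pts, "activation")
fit_boltzmann <- function(points, orientation = c("activation",
                                                  "inactivation")) {
  orientation <- match.arg(orientation)
  points <- points[is.finite(points$voltage) & is.finite(points$value), ]
  if (nrow(points) < 5) stop("at least 5 points are required")
  out <- list(v05 = NA_real_, slope = NA_real_, orientation = orientation,
              rss = NA_real_, converged = FALSE, n_points = nrow(points))
  class(out) <- "boltzmann_fit"
  if (stats::sd(points$value) == 0) return(out)

  # the data must trend in the fitted orientation
  trend <- stats::cor(points$voltage, points$value, method = "spearman")
  if ((orientation == "activation" && trend < 0) ||
      (orientation == "inactivation" && trend > 0)) return(out)

  init <- boltzmann_init(points, orientation)
  form <- if (orientation == "activation") {
    value ~ 1 / (1 + exp((v05 - voltage) / slope))
  } else {
    value ~ 1 / (1 + exp((voltage - v05) / slope))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = points, start = init,
                      lower = c(v05 = -Inf, slope = 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(out)
  cf <- stats::coef(fit)
  out$v05 <- unname(cf["v05"])
  out$slope <- unname(cf["slope"])
  out$rss <- sum(stats::resid(fit)^2)
  out$converged <- is.finite(out$rss)
  out
}

# Initial guesses from the 0.5 crossing and the 0.25-0.75 span of the
# monotone interpolated curve.
boltzmann_init <- function(points, orientation) {
  o <- order(points$voltage)
  v <- points$voltage[o]
  y <- points$value[o]
  if (orientation == "inactivation") y <- rev(y)  # make increasing in index
  vv <- if (orientation == "inactivation") rev(-v) else v
  cross <- function(level) {
    k <- which(y >= level)[1]
    if (is.na(k) || k == 1) return(stats::median(vv))
    vv[k - 1] + (level - y[k - 1]) * (vv[k] - vv[k - 1]) /
      max(y[k] - y[k - 1], 1e-12)
  }
  v50 <- cross(0.5)
  span <- abs(cross(0.75) - cross(0.25))
  slope0 <- max(span / (2 * log(3)), 0.5)
  v05 <- if (orientation == "inactivation") -v50 else v50
  c(v05 = v05, slope = slope0)
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit> %s: V0.5 = %.2f mV, slope = %.2f mV (%s, n = %d)\n",
              x$orientation, x$v05, x$slope,
              if (x$converged) "converged" else "NOT converged", x$n_points))
  invisible(x)
}

# Evaluate a fitted Boltzmann curve.
boltzmann_curve <- function(fit, v) {
  if (fit$orientation == "activation") {
    1 / (1 + exp((fit$v05 - v) / fit$slope))
  } else {
    1 / (1 + exp((v - fit$v05) / fit$slope))
  }
}
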