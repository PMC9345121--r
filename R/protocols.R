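#' Voltage-clamp stimulation protocols
#'
#' Constructors for the five stimulation protocols used throughout the
#' package. All hold the cell at -90 mV, sample at 0.1 ms, and describe each
#' sweep as an ordered list of (duration, voltage) segments; a segment with
#' `NA` voltage takes its value from `sweep_voltages`, one sweep per entry.
#'
#' * `protocol_iv()`: 100-ms steps from -90 to +60 mV (5 mV increments,
#'   0.2 Hz) for the current-voltage / activation family.
#' * `protocol_ssi()`: 1-s conditioning prepulses from -90 to +20 mV (5 mV
#'   increments) followed by a 50-ms test pulse to -20 mV (0.1 Hz) for
#'   steady-state inactivation.
#' * `protocol_kinetics()`: a single 100-ms depolarization to 0 mV (0.1 Hz)
#'   for time-constant fitting.
#' * `protocol_density()`: a single 100-ms pulse to -10 mV for current
#'   density.
#' * `protocol_ph()`: repeated 200-ms pulses to -20 mV (0.1 Hz) recorded
#'   under one pH condition.
#'
#' @param step Voltage increment (mV) for sweep families.
#' @param n_sweeps Number of repeated pulses for `protocol_ph()`.
#' @param sample_interval Sampling interval (ms).
#' @return A `voltage_protocol` object: a list with `name`, `holding`,
#'   `segments` (data.frame of `duration`, `voltage`), `sweep_voltages`,
#'   `test_segment` (index of the segment whose current is measured),
#'   `inter_sweep_interval` (s) and `sample_interval` (ms).
#' @name protocols
#' @examples
#' pr <- protocol_iv()
#' pr$sweep_voltages
NULL

new_protocol <- function(name, segments, sweep_voltages, test_segment,
                         inter_sweep_interval, sample_interval = 0.1,
                         holding = -90) {
  stopifnot(all(segments$duration > 0), sample_interval > 0)
  if (name %in% c("iv_activation", "ssi") &&
      length(sweep_voltages) > 1 && any(diff(sweep_voltages) <= 0))
    stop("sweep_voltages must be strictly increasing")
  structure(list(name = name, holding = holding, segments = segments,
                 sweep_voltages = sweep_voltages,
                 test_segment = test_segment,
                 inter_sweep_interval = inter_sweep_interval,
                 sample_interval = sample_interval),
            class = "voltage_protocol")
}

#' @rdname protocols
#' @export
protocol_iv <- function(step = 5, sample_interval = 0.1) {
  new_protocol("iv_activation",
               data.frame(duration = c(10, 100, 10),
                          voltage = c(-90, NA, -90)),
               sweep_voltages = seq(-90, 60, by = step),
               test_segment = 2, inter_sweep_interval = 5,
               sample_interval = sample_interval)
}

#' @rdname protocols
#' @export
protocol_ssi <- function(step = 5, sample_interval = 0.1) {
  new_protocol("ssi",
               data.frame(duration = c(10, 1000, 50, 10),
                          voltage = c(-90, NA, -20, -90)),
               sweep_voltages = seq(-90, 20, by = step),
               test_segment = 3, inter_sweep_interval = 10,
               sample_interval = sample_interval)
}

#' @rdname protocols
#' @export
protocol_kinetics <- function(sample_interval = 0.1) {
  new_protocol("kinetics_pulse",
               data.frame(duration = c(10, 100, 10),
                          voltage = c(-90, 0, -90)),
               sweep_voltages = 0, test_segment = 2,
               inter_sweep_interval = 10, sample_interval = sample_interval)
}

#' @rdname protocols
#' @export
protocol_density <- function(sample_interval = 0.1) {
  new_protocol("density_pulse",
               data.frame(duration = c(10, 100, 10),
                          voltage = c(-90, -10, -90)),
               sweep_voltages = -10, test_segment = 2,
               inter_sweep_interval = 5, sample_interval = sample_interval)
}

#' @rdname protocols
#' @export
protocol_ph <- function(n_sweeps = 5, sample_interval = 0.1) {
  new_protocol("ph_pulse_train",
               data.frame(duration = c(10, 200, 10),
                          voltage = c(-90, -20, -90)),
               sweep_voltages = rep(-20, n_sweeps), test_segment = 2,
               inter_sweep_interval = 10, sample_interval = sample_interval)
}

# Concrete (duration, voltage) table for sweep i of a protocol.
sweep_segments <- function(protocol, i) {
  seg <- protocol$segments
  if (protocol$name == "ph_pulse_train") {
    # pulse train: the varying index just repeats the same pulse
    return(seg)
  }
  v <- protocol$sweep_voltages[i]
  seg$voltage[is.na(seg$voltage)] <- v
  seg
}

n_sweeps <- function(protocol) length(protocol$sweep_voltages)

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf("<voltage_protocol> %s: %d sweep(s), hold %d mV, dt %.2g ms\n",
              x$name, n_sweeps(x), x$holding, x$sample_interval))
  invisible(x)
}
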