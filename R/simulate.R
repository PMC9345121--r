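#' Steady-state activation and availability curves
#'
#' The two gates of the channel model relax toward voltage-dependent steady
#' states. Activation is the increasing Boltzmann
#' \eqn{m_\infty(V) = 1/(1 + \exp((V_{0.5} - V)/d))}; availability
#' (steady-state inactivation) is the decreasing Boltzmann
#' \eqn{h_\infty(V) = 1/(1 + \exp((V - V_{0.5})/d))}. Both are total
#' functions of voltage, bounded in \[0, 1\].
#'
#' @param v Membrane voltage(s), mV.
#' @param p A [gating_params] object.
#' @return Fraction(s) in \[0, 1\], same length as `v`.
#' @export
#' @examples
#' p <- cav33_fixtures()$WT
#' steady_state_activation(p$act_v05, p)        # 0.5
#' steady_state_availability(p$inact_v05, p)    # 0.5
steady_state_activation <- function(v, p) {
  1 / (1 + exp((p$act_v05 - v) / p$act_slope))
}

#' @rdname steady_state_activation
#' @export
steady_state_availability <- function(v, p) {
  1 / (1 + exp((v - p$inact_v05) / p$inact_slope))
}

#' Simulate one voltage-clamp sweep
#'
#' Forward model of the whole-cell current: two first-order gates,
#' activation `m` with time constant `tau_act` and inactivation `h` with
#' `tau_inact`, relax exponentially toward the steady states of the current
#' command segment. The relaxation is integrated exactly per sample
#' (analytic exponential update), so there is no ODE solver error. The
#' current is \eqn{I(t) = g_{max} m(t) h(t) (V - E_{rev})} in pA for
#' `gmax` in nS and voltages in mV; below the reversal potential
#' depolarization-evoked currents are therefore inward (negative).
#' Optional additive Gaussian noise emulates recording noise. Gates start
#' at steady state for the first segment's (holding) voltage.
#'
#' @param segments Data frame with columns `duration` (ms) and `voltage`
#'   (mV), one row per command segment.
#' @param p A [gating_params] object.
#' @param noise_sd Standard deviation of additive Gaussian noise, pA.
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   sweeps.
#' @param sample_interval Sampling interval, ms.
#' @return A data frame of class `cav_sweep` with columns `time` (ms,
#'   uniform, starting at 0), `command` (mV) and `current` (pA), and a
#'   `segments` attribute recording segment boundaries.
#' @export
#' @examples
#' p <- cav33_fixtures()$WT
#' seg <- data.frame(duration = c(10, 100, 10), voltage = c(-90, -10, -90))
#' sw <- simulate_sweep(seg, p, noise_sd = 0)
#' min(sw$current)  # peak inward current, pA
simulate_sweep <- function(segments, p, noise_sd = 0, seed = NULL,
                           sample_interval = 0.1) {
  validate_gating_params(p)
  if (is.null(segments) || nrow(segments) == 0) stop("empty segment list")
  if (sample_interval <= 0) stop("non-positive sample interval")
  if (any(segments$duration <= 0)) stop("segment durations must be > 0")
  if (!is.null(seed)) set.seed(seed)

  dt <- sample_interval
  v0 <- segments$voltage[1]
  m <- steady_state_activation(v0, p)
  h <- steady_state_availability(v0, p)

  time_l <- vector("list", nrow(segments))
  cmd_l <- vector("list", nrow(segments))
  cur_l <- vector("list", nrow(segments))
  t_off <- 0
  starts <- numeric(nrow(segments))
  for (i in seq_len(nrow(segments))) {
    v <- segments$voltage[i]
    n <- max(1L, round(segments$duration[i] / dt))
    tt <- dt * seq_len(n)
    m_inf <- steady_state_activation(v, p)
    h_inf <- steady_state_availability(v, p)
    m_t <- m_inf + (m - m_inf) * exp(-tt / p$tau_act)
    h_t <- h_inf + (h - h_inf) * exp(-tt / p$tau_inact)
    cur_l[[i]] <- p$gmax * m_t * h_t * (v - p$erev)
    cmd_l[[i]] <- rep(v, n)
    time_l[[i]] <- t_off + tt
    starts[i] <- t_off
    t_off <- t_off + n * dt
    m <- m_t[n]
    h <- h_t[n]
  }
  time <- c(0, unlist(time_l))
  command <- c(v0, unlist(cmd_l))
  current <- c(p$gmax * steady_state_activation(v0, p) *
                 steady_state_availability(v0, p) * (v0 - p$erev),
               unlist(cur_l))
  if (noise_sd > 0) current <- current + stats::rnorm(length(current),
                                                      sd = noise_sd)
  sw <- data.frame(time = time, command = command, current = current)
  attr(sw, "segments") <- cbind(segments, start = starts,
                                end = starts + round(segments$duration / dt) * dt)
  attr(sw, "sample_interval") <- dt
  class(sw) <- c("cav_sweep", "data.frame")
  sw
}

#' Simulate a whole-cell recording under a protocol
#'
#' Runs every sweep of a [protocols] object through [simulate_sweep()] and
#' packages the result with the cell metadata the downstream analysis needs
#' (capacitance, transfection batch, recording time point, pH).
#'
#' @param p A [gating_params] object (the cell's true parameters).
#' @param protocol A `voltage_protocol`.
#' @param capacitance Cell capacitance, pF (> 0).
#' @param noise_sd Additive Gaussian recording noise, pA.
#' @param cell_id,replicate_batch,hours_post_transfection Cell metadata.
#' @param ph Extracellular pH label stored with the recording.
#' @param seed Optional integer seed for the noise stream.
#' @return A `cav_recording`: list with the metadata fields plus `sweeps`
#'   (list of `cav_sweep`), `protocol`, `params` and `rng_seed`.
#' @export
simulate_recording <- function(p, protocol, capacitance = 12, noise_sd = 5,
                               cell_id = "cell1", replicate_batch = "TD1",
                               hours_post_transfection = 48, ph = 7.4,
                               seed = NULL) {
  if (capacitance <= 0) stop("capacitance must be > 0")
  if (!is.null(seed)) set.seed(seed)
  sweeps <- lapply(seq_len(n_sweeps(protocol)), function(i) {
    simulate_sweep(sweep_segments(protocol, i), p, noise_sd = noise_sd,
                   sample_interval = protocol$sample_interval)
  })
  structure(list(cell_id = cell_id, construct_label = p$construct_label,
                 capacitance = capacitance, ph = ph, sweeps = sweeps,
                 replicate_batch = replicate_batch,
                 hours_post_transfection = hours_post_transfection,
                 protocol = protocol, params = p,
                 rng_seed = if (is.null(seed)) NA_integer_ else seed),
            class = "cav_recording")
}

#' @export
print.cav_recording <- function(x, ...) {
  cat(sprintf("<cav_recording> %s (%s), %d sweep(s) of %s, C = %.1f pF, pH %s\n",
              x$cell_id, x$construct_label, length(x$sweeps),
              x$protocol$name, x$capacitance, format_ph(x$ph)))
  invisible(x)
}

#' Default cell-to-cell variability of a simulated cohort
#'
#' @param gmax_cv Lognormal coefficient of variation of the maximal
#'   conductance across cells.
#' @param cap_mean,cap_sd Mean and sd (pF) of the positive-truncated normal
#'   capacitance distribution.
#' @param v05_jitter_sd Per-cell normal jitter (mV) of both half-activation
#'   and half-inactivation voltages.
#' @return List of dispersion parameters for [generate_cohort()].
#' @export
cohort_variability <- function(gmax_cv = 0.3, cap_mean = 12, cap_sd = 3,
                               v05_jitter_sd = 1.5) {
  if (gmax_cv < 0 || cap_sd < 0 || v05_jitter_sd < 0 || cap_mean <= 0)
    stop("dispersion parameters must be non-negative (cap_mean > 0)")
  list(gmax_cv = gmax_cv, cap_mean = cap_mean, cap_sd = cap_sd,
       v05_jitter_sd = v05_jitter_sd)
}

# Draw per-cell true parameters. The RNG is consumed in a fixed order so a
# cohort is fully reproducible from its seed.
draw_cells <- function(p, n_cells, variability = cohort_variability(),
                       seed = NULL, batches = c("TD1", "TD2", "TD3")) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  sdlog <- sqrt(log(1 + variability$gmax_cv^2))
  lapply(seq_len(n_cells), function(i) {
    gmax_i <- stats::rlnorm(1, meanlog = log(p$gmax) - sdlog^2 / 2,
                            sdlog = sdlog)
    cap_i <- 0
    repeat {  # positive-truncated normal
      cap_i <- stats::rnorm(1, variability$cap_mean, variability$cap_sd)
      if (cap_i > 0) break
    }
    pc <- p
    pc$gmax <- gmax_i
    pc$act_v05 <- p$act_v05 + stats::rnorm(1, sd = variability$v05_jitter_sd)
    pc$inact_v05 <- p$inact_v05 + stats::rnorm(1, sd = variability$v05_jitter_sd)
    list(params = pc, capacitance = cap_i,
         cell_id = sprintf("%s_c%02d", p$construct_label, i),
         replicate_batch = batches[(i - 1L) %% length(batches) + 1L],
         hours_post_transfection = c(24, 48)[(i - 1L) %% 2L + 1L],
         seed = sample.int(.Machine$integer.max - 1L, 1))
  })
}

#' Generate a cohort of simulated recordings
#'
#' Emulates cell-to-cell biological variability across independent
#' transfections: per-cell maximal conductance is lognormal around the
#' fixture value, capacitance is positive-truncated normal, and both
#' half-maximal voltages receive normal jitter. Cells are assigned
#' round-robin to transfection-day batches and alternate 24/48 h recording
#' time points. Fully reproducible from `seed`.
#'
#' @param p A [gating_params] fixture (cohort-level truth).
#' @param protocol A `voltage_protocol` applied to every cell.
#' @param n_cells Number of cells (>= 1).
#' @param variability See [cohort_variability()]; all dispersions 0 with
#'   `n_cells = 1` reproduces the fixture exactly.
#' @param noise_sd Recording noise sd, pA.
#' @param seed Integer seed.
#' @return List of `cav_recording` objects.
#' @export
#' @examples
#' recs <- generate_cohort(cav33_fixtures()$WT, protocol_density(),
#'                         n_cells = 3, seed = 1)
#' sapply(recs, function(r) r$capacitance)
generate_cohort <- function(p, protocol, n_cells = 12,
                            variability = cohort_variability(),
                            noise_sd = 5, seed = NULL) {
  cells <- draw_cells(p, n_cells, variability, seed)
  lapply(cells, function(cl) {
    simulate_recording(cl$params, protocol, capacitance = cl$capacitance,
                       noise_sd = noise_sd, cell_id = cl$cell_id,
                       replicate_batch = cl$replicate_batch,
                       hours_post_transfection = cl$hours_post_transfection,
                       seed = cl$seed)
  })
}

#' Generate paired recordings at reference and test pH for each cell
#'
#' Each cell is recorded twice under the 200-ms -20 mV pulse-train protocol:
#' once at the reference pH 7.4 and once at `ph`, with the pH condition
#' applied to the same per-cell parameters via [apply_ph()]. This mirrors
#' the within-cell design of pH modulation experiments.
#'
#' @inheritParams generate_cohort
#' @param ph Test pH (must be characterized for the construct).
#' @param protocol pH pulse-train protocol.
#' @return List of `list(ref = , test = )` recording pairs.
#' @export
generate_ph_pairs <- function(p, ph, n_cells = 12,
                              variability = cohort_variability(),
                              noise_sd = 5, seed = NULL,
                              protocol = protocol_ph()) {
  apply_ph(p, ph)  # fail early on an uncharacterized pH
  cells <- draw_cells(p, n_cells, variability, seed)
  lapply(cells, function(cl) {
    ref <- simulate_recording(cl$params, protocol,
                              capacitance = cl$capacitance,
                              noise_sd = noise_sd, cell_id = cl$cell_id,
                              replicate_batch = cl$replicate_batch,
                              hours_post_transfection = cl$hours_post_transfection,
                              ph = 7.4, seed = cl$seed)
    test <- simulate_recording(apply_ph(cl$params, ph), protocol,
                               capacitance = cl$capacitance,
                               noise_sd = noise_sd, cell_id = cl$cell_id,
                               replicate_batch = cl$replicate_batch,
                               hours_post_transfection = cl$hours_post_transfection,
                               ph = ph, seed = cl$seed + 1L)
    list(ref = ref, test = test)
  })
}
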