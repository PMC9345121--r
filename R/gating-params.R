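#' Gating parameter set for a two-gate T-type channel construct
#'
#' Bundles the biophysical ground truth of one channel construct: maximal
#' conductance, reversal potential, Boltzmann parameters of steady-state
#' activation and inactivation, relaxation time constants, and per-pH
#' multiplicative factors for conductance and inactivation kinetics.
#'
#' Activation follows the increasing logistic
#' \eqn{m_\infty(V) = 1/(1 + \exp((V_{0.5,act} - V)/d_{act}))} and
#' availability the decreasing logistic
#' \eqn{h_\infty(V) = 1/(1 + \exp((V - V_{0.5,inact})/d_{inact}))}, both with
#' positive slope factors \eqn{d} in mV.
#'
#' @param construct_label Character label, e.g. `"WT"`.
#' @param gmax Maximal conductance (nS), > 0.
#' @param erev Reversal potential (mV). Default +45 mV, appropriate for a
#'   10 mM external Ca2+ recording solution with an ohmic driving force.
#' @param act_v05,act_slope Half-activation voltage (mV) and slope factor
#'   (mV, > 0).
#' @param inact_v05,inact_slope Half-inactivation voltage (mV) and slope
#'   factor (mV, > 0).
#' @param tau_act,tau_inact Activation and inactivation time constants (ms)
#'   at the test potential; `tau_inact > tau_act > 0`.
#' @param ph_conductance_factor Named numeric vector mapping pH (as character,
#'   e.g. `"6.5"`) to a multiplicative peak-conductance scale. Must contain
#'   the reference `"7.4" = 1`.
#' @param ph_tau_inact_factor Named numeric vector mapping pH to a
#'   multiplicative `tau_inact` scale. Must contain `"7.4" = 1`.
#' @param act_slope_imputed Logical flag marking that the activation slope
#'   was not measured for this construct and defaults to the wild-type value.
#'
#' @return An object of class `gating_params`.
#' @seealso [cav33_fixtures()], [apply_ph()]
#' @export
#' @examples
#' p <- gating_params("demo", gmax = 50, act_v05 = -20.6, act_slope = 5.8,
#'                    inact_v05 = -47.1, inact_slope = 6.9,
#'                    tau_act = 4.6, tau_inact = 40.9)
#' steady_state_activation(-20.6, p)  # 0.5 by construction
gating_params <- function(construct_label, gmax, erev = 45,
                          act_v05, act_slope,
                          inact_v05, inact_slope,
                          tau_act, tau_inact,
                          ph_conductance_factor = c("7.4" = 1),
                          ph_tau_inact_factor = c("7.4" = 1),
                          act_slope_imputed = FALSE) {
  p <- list(
    construct_label = as.character(construct_label),
    gmax = as.numeric(gmax), erev = as.numeric(erev),
    act_v05 = as.numeric(act_v05), act_slope = as.numeric(act_slope),
    inact_v05 = as.numeric(inact_v05), inact_slope = as.numeric(inact_slope),
    tau_act = as.numeric(tau_act), tau_inact = as.numeric(tau_inact),
    ph_conductance_factor = ph_conductance_factor,
    ph_tau_inact_factor = ph_tau_inact_factor,
    act_slope_imputed = isTRUE(act_slope_imputed)
  )
  class(p) <- "gating_params"
  validate_gating_params(p)
  p
}

validate_gating_params <- function(p) {
  stopifnot(inherits(p, "gating_params"))
  if (!is.finite(p$gmax) || p$gmax < 0)
    stop("gmax must be a finite non-negative conductance (nS)")
  if (p$act_slope <= 0 || p$inact_slope <= 0)
    stop("slope factors must be positive (mV)")
  if (p$tau_act <= 0 || p$tau_inact <= 0)
    stop("time constants must be positive (ms)")
  if (p$tau_inact <= p$tau_act)
    stop("tau_inact must exceed tau_act for a transient inward current")
  for (nm in c("ph_conductance_factor", "ph_tau_inact_factor")) {
    f <- p[[nm]]
    if (is.null(names(f)) || any(!nzchar(names(f))))
      stop(nm, " must be a named vector keyed by pH")
    if (any(!is.finite(f)) || any(f <= 0)) stop(nm, " entries must be > 0")
    if (!"7.4" %in% names(f) || abs(f[["7.4"]] - 1) > 1e-12)
      stop(nm, " must map the reference pH 7.4 to 1")
  }
  invisible(p)
}

#' @export
print.gating_params <- function(x, ...) {
  cat(sprintf("<gating_params> %s\n", x$construct_label))
  cat(sprintf("  gmax %.2f nS, erev %+.1f mV\n", x$gmax, x$erev))
  cat(sprintf("  activation   V0.5 %+.1f mV, slope %.1f mV%s\n", x$act_v05,
              x$act_slope, if (x$act_slope_imputed) " (imputed)" else ""))
  cat(sprintf("  inactivation V0.5 %+.1f mV, slope %.1f mV\n",
              x$inact_v05, x$inact_slope))
  cat(sprintf("  tau_act %.1f ms, tau_inact %.1f ms\n",
              x$tau_act, x$tau_inact))
  cat(sprintf("  pH keys: %s\n",
              paste(names(x$ph_conductance_factor), collapse = ", ")))
  invisible(x)
}

# Conductance needed so the noiseless -10 mV density pulse yields the target
# current density at the reference capacitance. Inverts the forward model
# once at unit conductance.
calibrate_gmax <- function(density_target, p, capacitance = 12) {
  p1 <- p
  p1$gmax <- 1
  sw <- simulate_sweep(density_pulse_segments(), p1, noise_sd = 0)
  peak1 <- max(abs(sw$current))
  density_target * capacitance / peak1
}

density_pulse_segments <- function() {
  data.frame(duration = c(10, 100, 10), voltage = c(-90, -10, -90))
}

#' Ground-truth parameter fixtures for the six Cav3.3 constructs
#'
#' Returns the study's construct panel (WT plus the five hemiplegic-migraine
#' associated variants R111G, M128L, D302G, R307H, Q1158H) with the measured
#' gating parameters: activation and inactivation Boltzmann parameters, time
#' constants at the test potential, and pH modulation factors for the
#' histidine-bearing constructs and WT. Activation slopes were only measured
#' for WT and M128L; the remaining constructs carry the WT slope with
#' `act_slope_imputed = TRUE`.
#'
#' Maximal conductances are calibrated at construction time so that the
#' noiseless 100-ms density pulse to -10 mV at the reference capacitance of
#' 12 pF reproduces each construct's measured current density (pA/pF).
#'
#' The pH conductance factors are defined as realized peak-current ratios at
#' the standard 200-ms -20 mV pH pulse (see [apply_ph()]).
#'
#' @param erev Reversal potential (mV) shared by all constructs.
#' @return Named list of [gating_params] objects
#'   (`WT`, `R111G`, `M128L`, `D302G`, `R307H`, `Q1158H`), with a
#'   `densities` attribute carrying the target current densities.
#' @export
#' @examples
#' fx <- cav33_fixtures()
#' names(fx)
#' fx$WT
cav33_fixtures <- function(erev = 45) {
  wt_slope <- 5.8
  tbl <- list(
    WT     = list(density = 208.4, act = c(-20.6, 5.8), imput = FALSE,
                  inact = c(-47.1, 6.9), tau = c(4.6, 40.9),
                  ph_g = c("7.4" = 1, "6.5" = 0.54, "8.0" = 1.29),
                  ph_t = c("7.4" = 1, "6.5" = 1, "8.0" = 1)),
    R111G  = list(density = 153.0, act = c(-21.3, wt_slope), imput = TRUE,
                  inact = c(-47.0, 7.2), tau = c(4.8, 35.6),
                  ph_g = c("7.4" = 1), ph_t = c("7.4" = 1)),
    M128L  = list(density = 196.0, act = c(-23.3, 5.1), imput = FALSE,
                  inact = c(-45.0, 6.8), tau = c(4.8, 45.3),
                  ph_g = c("7.4" = 1), ph_t = c("7.4" = 1)),
    D302G  = list(density = 120.5, act = c(-21.3, wt_slope), imput = TRUE,
                  inact = c(-49.5, 7.4), tau = c(5.9, 39.0),
                  ph_g = c("7.4" = 1), ph_t = c("7.4" = 1)),
    R307H  = list(density = 104.2, act = c(-19.8, wt_slope), imput = TRUE,
                  inact = c(-45.7, 7.2), tau = c(8.0, 60.3),
                  ph_g = c("7.4" = 1, "6.5" = 0.68, "8.0" = 1.25),
                  ph_t = c("7.4" = 1, "6.5" = 1, "8.0" = 1)),
    Q1158H = list(density = 133.1, act = c(-17.6, wt_slope), imput = TRUE,
                  inact = c(-43.3, 7.9), tau = c(7.3, 56.0),
                  ph_g = c("7.4" = 1, "6.5" = 0.75, "8.0" = 1.06),
                  ph_t = c("7.4" = 1, "6.5" = 1, "8.0" = 1.38))
  )
  out <- lapply(names(tbl), function(nm) {
    d <- tbl[[nm]]
    p <- gating_params(nm, gmax = 1, erev = erev,
                       act_v05 = d$act[1], act_slope = d$act[2],
                       inact_v05 = d$inact[1], inact_slope = d$inact[2],
                       tau_act = d$tau[1], tau_inact = d$tau[2],
                       ph_conductance_factor = d$ph_g,
                       ph_tau_inact_factor = d$ph_t,
                       act_slope_imputed = d$imput)
    p$gmax <- calibrate_gmax(d$density, p)
    p
  })
  names(out) <- names(tbl)
  attr(out, "densities") <- vapply(tbl, function(d) d$density, numeric(1))
  out
}

#' Apply an extracellular pH condition to a parameter set
#'
#' Scales `tau_inact` by the construct's pH tau factor and the conductance so
#' that the realized peak current at the standard 200-ms -20 mV pH pulse is
#' the construct's pH conductance factor times the reference peak. The
#' factors are measured peak-current ratios, so when a pH condition also
#' slows inactivation (which by itself enlarges the transient peak) the
#' conductance scale absorbs the kinetic peak gain; with
#' `calibrate_peak = FALSE` the conductance is scaled by the raw factor
#' instead.
#'
#' @param p A [gating_params] object.
#' @param ph Numeric pH; must be a key of the construct's factor maps
#'   (7.4, and for pH-characterized constructs 6.5 and 8.0).
#' @param calibrate_peak Compensate the conductance scale for the kinetic
#'   peak gain of a tau_inact change (default `TRUE`).
#' @return A [gating_params] object for the requested pH.
#' @export
#' @examples
#' fx <- cav33_fixtures()
#' acid <- apply_ph(fx$WT, 6.5)
#' acid$gmax / fx$WT$gmax  # 0.54: acidification halves the WT peak
apply_ph <- function(p, ph, calibrate_peak = TRUE) {
  validate_gating_params(p)
  key <- format_ph(ph)
  if (!key %in% names(p$ph_conductance_factor))
    stop(sprintf("pH %s is not characterized for construct %s (available: %s)",
                 key, p$construct_label,
                 paste(names(p$ph_conductance_factor), collapse = ", ")))
  g_fac <- p$ph_conductance_factor[[key]]
  t_fac <- p$ph_tau_inact_factor[[key]]
  out <- p
  out$tau_inact <- p$tau_inact * t_fac
  gain <- 1
  if (calibrate_peak && t_fac != 1) {
    seg <- ph_pulse_segments()
    ref <- p
    ref$gmax <- 1
    test <- out
    test$gmax <- 1
    peak_ref <- max(abs(simulate_sweep(seg, ref, noise_sd = 0)$current))
    peak_new <- max(abs(simulate_sweep(seg, test, noise_sd = 0)$current))
    gain <- peak_new / peak_ref
  }
  out$gmax <- p$gmax * g_fac / gain
  out
}

ph_pulse_segments <- function() {
  data.frame(duration = c(10, 200, 10), voltage = c(-90, -20, -90))
}

format_ph <- function(ph) {
  if (is.character(ph)) return(ph)
  format(round(as.numeric(ph), 1), nsmall = 1)
}
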