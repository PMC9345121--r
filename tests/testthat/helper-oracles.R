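# Independent oracles used across tests. These re-derive expected values
# from closed forms or brute-force grids and never call the code paths they
# check.

# Antiderivative-based integrals of the two logistic orientations.
act_integral <- function(v05, k, lo, hi) {
  k * (log1p(exp((hi - v05) / k)) - log1p(exp((lo - v05) / k)))
}
inact_integral <- function(v05, k, lo, hi) {
  k * (log1p(exp(-(lo - v05) / k)) - log1p(exp(-(hi - v05) / k)))
}

# Closed-form window area: the increasing and decreasing logistics cross
# where their exponents agree, v_c = (a*kh + b*ka)/(ka + kh); below v_c the
# activation curve is the minimum, above it the availability curve is.
window_area_oracle <- function(act_v05, act_k, inact_v05, inact_k,
                               lo = -90, hi = 20) {
  vc <- (act_v05 * inact_k + inact_v05 * act_k) / (act_k + inact_k)
  vc <- min(max(vc, lo), hi)
  act_integral(act_v05, act_k, lo, vc) +
    inact_integral(inact_v05, inact_k, vc, hi)
}

# Stationary point of (1 - exp(-t/ta)) * exp(-t/ti).
t_peak_oracle <- function(tau_a, tau_i) tau_a * log1p(tau_i / tau_a)

# Brute-force dense-time-grid peak of the noiseless two-gate current for a
# single voltage step from a holding potential.
step_peak_oracle <- function(p, v_hold, v_step, t_max = 100, dt = 1e-3) {
  logistic <- function(x) 1 / (1 + exp(x))
  m_inf <- function(v) logistic((p$act_v05 - v) / p$act_slope)
  h_inf <- function(v) logistic((v - p$inact_v05) / p$inact_slope)
  tt <- seq(0, t_max, by = dt)
  m <- m_inf(v_step) + (m_inf(v_hold) - m_inf(v_step)) * exp(-tt / p$tau_act)
  h <- h_inf(v_step) + (h_inf(v_hold) - h_inf(v_step)) * exp(-tt / p$tau_inact)
  i <- p$gmax * m * h * (v_step - p$erev)
  list(peak = i[which.max(abs(i))], t_peak = tt[which.max(abs(i))])
}

# Pearson chi-square from first principles on a 2x2 table.
pearson_chi2_oracle <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Small noiseless parameter set for fast unit tests.
toy_params <- function(gmax = 50, act_v05 = -20.6, act_slope = 5.8,
                       inact_v05 = -47.1, inact_slope = 6.9,
                       tau_act = 4.6, tau_inact = 40.9, erev = 45) {
  gating_params("toy", gmax = gmax, erev = erev, act_v05 = act_v05,
                act_slope = act_slope, inact_v05 = inact_v05,
                inact_slope = inact_slope, tau_act = tau_act,
                tau_inact = tau_inact)
}
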