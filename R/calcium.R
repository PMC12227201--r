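#' Advance a calcium trace by one step
#'
#' Exact-decay discrete update of the spike-driven calcium trace:
#' `C' = C * exp(-dt / tau_Ca) + spikes * beta_Ca` (decay first, influx
#' second, so the update is reproducible bit-for-bit regardless of where the
#' spikes fall inside the step).
#'
#' @param C Current calcium concentration(s); vectorised.
#' @param spikes Number of spikes emitted in this step (same length as `C`
#'   or scalar).
#' @param dt Step length (s).
#' @param params A [calcium_params()].
#' @return Updated concentration(s).
#' @export
update_calcium <- function(C, spikes, dt, params = calcium_params()) {
  stopifnot(all(C >= 0), dt > 0)
  C * exp(-dt / params$tau_Ca) + spikes * params$beta_Ca
}

#' Calcium trace of a spike train
#'
#' Evaluates the calcium trace on a regular grid from a list of spike times,
#' applying the same exact-decay update as the network engine.
#'
#' @param spike_times Spike times (s), sorted or not.
#' @param t_max End of the trace (s).
#' @param dt Sampling step (s).
#' @param params A [calcium_params()].
#' @param C0 Initial concentration.
#' @return A data.frame with columns `t` and `C` (trace sampled at the end of
#'   each step).
#' @export
calcium_trace <- function(spike_times, t_max, dt = 0.001,
                          params = calcium_params(), C0 = 0) {
  stopifnot(t_max > 0, dt > 0)
  n <- as.integer(round(t_max / dt))
  counts <- tabulate(pmin(n, floor(sort(spike_times) / dt) + 1L), nbins = n)
  dec <- exp(-dt / params$tau_Ca)
  C <- numeric(n)
  cur <- C0
  for (k in seq_len(n)) {
    cur <- cur * dec + counts[k] * params$beta_Ca
    C[k] <- cur
  }
  data.frame(t = seq_len(n) * dt, C = C)
}

#' Convert between firing rate and steady-state calcium
#'
#' In steady state the time-averaged calcium trace of a neuron firing at rate
#' r is `r * beta_Ca * tau_Ca`. With the default parameters the conversion
#' factor is 0.001, so the setpoints epsilon = 0.0079 and eta = 0.0007
#' correspond to 7.9 Hz and 0.7 Hz.
#'
#' @param rate Firing rate (Hz).
#' @param C Calcium concentration.
#' @param params A [calcium_params()].
#' @return The converted quantity.
#' @export
rate_to_calcium <- function(rate, params = calcium_params())
  rate * params$beta_Ca * params$tau_Ca

#' @rdname rate_to_calcium
#' @export
calcium_to_rate <- function(C, params = calcium_params())
  C / (params$beta_Ca * params$tau_Ca)

#' Growth rate of synaptic elements at a given calcium level
#'
#' Evaluates a structural-plasticity growth curve dz/dt (elements/s) at
#' calcium concentration `C`. See [growth_rule()] for the two functional
#' forms.
#'
#' @param C Calcium concentration(s); vectorised.
#' @param rule A [growth_rule()].
#' @return dz/dt in elements per second.
#' @export
growth_rate <- function(C, rule) {
  stopifnot(inherits(rule, "growth_rule"))
  if (rule$variant == "linear") {
    rule$nu * (1 - C / rule$epsilon)
  } else {
    rule$nu * (2 * exp(-((C - rule$xi) / rule$zeta)^2) - 1)
  }
}

#' Classify the growth regime at a calcium level
#'
#' Sign classification of the growth curve: `"grow"` where dz/dt > 0,
#' `"retract"` where dz/dt < 0, `"stationary"` within `tol` of zero.
#' Diagnostic only; the engine uses the signed rate itself. The default
#' dead band is a pure floating-point guard so that the setpoints
#' themselves classify as stationary.
#'
#' @param C Calcium concentration(s).
#' @param rule A [growth_rule()].
#' @param tol Dead-band half-width around zero (elements/s).
#' @return Character vector over `{"grow", "retract", "stationary"}`.
#' @export
growth_zone <- function(C, rule, tol = 1e-12) {
  r <- growth_rate(C, rule)
  out <- ifelse(abs(r) <= tol, "stationary", ifelse(r > 0, "grow", "retract"))
  out
}
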