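#' Point-neuron parameters
#'
#' Parameters of the current-based leaky integrate-and-fire neuron used for
#' both the excitatory and the inhibitory population. Defaults are the model's
#' reference values: membrane time constant 20 ms, absolute refractory period
#' 2 ms, resting (and initial) potential 0 mV, post-spike reset 10 mV, spike
#' threshold 20 mV, membrane capacitance 250 pF.
#'
#' @param tau_m Membrane time constant (ms).
#' @param t_ref Absolute refractory period (ms).
#' @param V_rest Resting / initial membrane potential (mV).
#' @param V_reset Post-spike reset potential (mV).
#' @param V_th Spike threshold (mV); may be `Inf` to disable spiking (useful
#'   for checking sub-threshold dynamics against the closed-form solution).
#' @param C_mem Membrane capacitance (pF).
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(tau_m = 20, t_ref = 2, V_rest = 0, V_reset = 10,
                          V_th = 20, C_mem = 250) {
  stopifnot(tau_m > 0, t_ref >= 0, C_mem > 0)
  if (V_reset >= V_th) stop("V_reset must be below V_th")
  structure(list(tau_m = tau_m, t_ref = t_ref, V_rest = V_rest,
                 V_reset = V_reset, V_th = V_th, C_mem = C_mem),
            class = "neuron_params")
}

#' Network architecture parameters
#'
#' An inhibition-dominated two-population network: `N_E` excitatory and `N_I`
#' inhibitory neurons. The I-I, I-E and E-I blocks are hard-wired at build
#' time with independent Bernoulli(`p_static`) draws per directed pair; the
#' E-E block starts empty and is governed by the structural-plasticity rules.
#' Every neuron receives an independent external Poisson spike train of rate
#' `r_ext` with excitatory jump `J_ext`.
#'
#' `J_E` is the PSP jump of recurrent excitatory synapses (E-E, and E-I for
#' the hard-wired block), `J_I` the (negative) jump of inhibitory synapses.
#' Defaults are the full-scale reference values (10000 + 2500 neurons, 10%
#' static wiring, 0.1 mV / -0.8 mV, 30 kHz). For desk-scale work see
#' [scaled_preset()].
#'
#' @param N_E,N_I Population sizes.
#' @param p_static Wiring probability of the static (I-I, I-E, E-I) blocks.
#' @param J_E Excitatory PSP amplitude (mV), used for E-E and E-I synapses.
#' @param J_I Inhibitory PSP amplitude (mV), must be negative.
#' @param J_ext PSP amplitude of external-drive spikes (mV).
#' @param r_ext External Poisson rate per neuron (Hz).
#' @param delay Synaptic transmission delay (ms).
#' @param dt Integration step (ms).
#' @return An object of class `network_config`.
#' @export
network_config <- function(N_E = 10000, N_I = 2500, p_static = 0.1,
                           J_E = 0.1, J_I = -0.8, J_ext = 0.1,
                           r_ext = 30000, delay = 1.0, dt = 0.1) {
  if (N_E < 1 || N_I < 1) stop("population sizes must be positive")
  if (p_static < 0 || p_static > 1) stop("p_static must be in [0, 1]")
  if (J_E <= 0) stop("J_E must be positive")
  if (J_I >= 0) stop("J_I must be negative")
  if (r_ext < 0) stop("r_ext must be non-negative")
  stopifnot(delay > 0, dt > 0)
  structure(list(N_E = as.integer(N_E), N_I = as.integer(N_I),
                 p_static = p_static, J_E = J_E, J_I = J_I, J_ext = J_ext,
                 r_ext = r_ext, delay = delay, dt = dt),
            class = "network_config")
}

#' Calcium-trace parameters
#'
#' The per-neuron calcium trace is a low-pass filter of the neuron's own
#' spiking: it decays exponentially with time constant `tau_Ca` and jumps by
#' `beta_Ca` at each spike. In steady state the time-averaged trace equals
#' `rate * beta_Ca * tau_Ca`, so with the defaults (10 s, 1e-4) a calcium
#' level of 0.0079 corresponds to 7.9 Hz.
#'
#' @param tau_Ca Calcium decay time constant (s).
#' @param beta_Ca Calcium influx per spike (arbitrary concentration units).
#' @return An object of class `calcium_params`.
#' @export
calcium_params <- function(tau_Ca = 10, beta_Ca = 1e-4) {
  stopifnot(tau_Ca > 0, beta_Ca > 0)
  structure(list(tau_Ca = tau_Ca, beta_Ca = beta_Ca), class = "calcium_params")
}

#' Structural-plasticity growth rule
#'
#' Maps a neuron's calcium trace C to the rate of change of its synaptic
#' element count, dz/dt (elements per second).
#'
#' * `variant = "linear"`: dz/dt = nu (1 - C / epsilon). Single stable
#'   setpoint at `epsilon`; growth below it, retraction above.
#' * `variant = "gaussian"`: dz/dt = nu (2 exp(-((C - xi)/zeta)^2) - 1) with
#'   xi = (eta + epsilon)/2 and zeta = (epsilon - eta)/(2 sqrt(log 2)), so
#'   the curve has zeros exactly at `eta` and `epsilon`, a maximum of +nu at
#'   the midpoint xi, and tends to -nu for large C. With `eta = 0` this is
#'   the "zero-Gaussian" rule (silent neurons keep their elements); with
#'   `eta > 0` the "biphasic" rule (retraction below `eta`).
#'
#' Defaults follow the reference parameter sets: nu = 0.00395 /s for the
#' linear rule and 0.004 /s for the Gaussian rules, epsilon = 0.0079, and
#' eta = 0.0007 for the biphasic variant.
#'
#' @param variant `"linear"` or `"gaussian"`.
#' @param nu Growth rate (elements/s); scales the whole curve.
#' @param epsilon Target calcium setpoint.
#' @param eta Lower setpoint (gaussian only); `0 <= eta < epsilon`.
#' @param nu_multiplier Dimensionless multiplier on `nu`, used by protocol
#'   presets (the "100%, 50%, 10%" growth-rate settings, and acceleration of
#'   scaled-down runs).
#' @return An object of class `growth_rule`.
#' @export
growth_rule <- function(variant = c("linear", "gaussian"),
                        nu = if (variant == "linear") 0.00395 else 0.004,
                        epsilon = 0.0079,
                        eta = 0,
                        nu_multiplier = 1) {
  variant <- match.arg(variant)
  if (epsilon <= 0) stop("epsilon must be positive")
  if (nu <= 0) stop("nu must be positive")
  if (variant == "gaussian" && (eta < 0 || eta >= epsilon))
    stop("gaussian rule requires 0 <= eta < epsilon")
  r <- list(variant = variant, nu = nu * nu_multiplier, epsilon = epsilon,
            eta = if (variant == "linear") NA_real_ else eta)
  if (variant == "gaussian") {
    r$xi <- (eta + epsilon) / 2
    r$zeta <- (epsilon - eta) / (2 * sqrt(log(2)))
  }
  structure(r, class = "growth_rule")
}

#' Biphasic-Gaussian rule with the reference setpoints
#'
#' Convenience constructors for the three rules studied with their default
#' parameter sets.
#' @param nu_multiplier Growth-rate multiplier (see [growth_rule()]).
#' @return A `growth_rule`.
#' @export
rule_linear <- function(nu_multiplier = 1)
  growth_rule("linear", nu = 0.00395, epsilon = 0.0079,
              nu_multiplier = nu_multiplier)

#' @rdname rule_linear
#' @export
rule_zero_gaussian <- function(nu_multiplier = 1)
  growth_rule("gaussian", nu = 0.004, epsilon = 0.0079, eta = 0,
              nu_multiplier = nu_multiplier)

#' @rdname rule_linear
#' @export
rule_biphasic <- function(nu_multiplier = 1)
  growth_rule("gaussian", nu = 0.004, epsilon = 0.0079, eta = 0.0007,
              nu_multiplier = nu_multiplier)

#' Homeostatic synaptic scaling parameters
#'
#' Multiplicative, cell-autonomous scaling of E-E synaptic weights driven by
#' the postsynaptic calcium trace: dw/dt = rho * w * (epsilon - C_post)
#' (the homeostatic sign: weights grow when activity is below the setpoint).
#' `sign = -1` selects the opposite (anti-homeostatic) convention.
#'
#' @param rho Scaling factor (per second per concentration unit); `0`
#'   disables scaling.
#' @param epsilon Target calcium setpoint (shared with the growth rules).
#' @param w_min Weight floor (mV).
#' @param sign `+1` for the homeostatic drive `(epsilon - C)`, `-1` for the
#'   reversed convention.
#' @param enabled_from Activation time (s); scaling is inactive before it.
#' @return An object of class `scaling_params`.
#' @export
scaling_params <- function(rho = 0, epsilon = 0.0079, w_min = 0, sign = 1,
                           enabled_from = 0) {
  stopifnot(rho >= 0, w_min >= 0, sign %in% c(-1, 1))
  structure(list(rho = rho, epsilon = epsilon, w_min = w_min, sign = sign,
                 enabled_from = enabled_from),
            class = "scaling_params")
}

#' Facilitating-current schedule
#'
#' A somatic current injected into all excitatory neurons that decays
#' linearly from `I0` to zero over `t_end_decay` seconds:
#' I(t) = I0 * max(0, 1 - t / t_end_decay). Used to promote network growth
#' under the biphasic rule (reference amplitude 750 pA, decaying over the
#' growth phase).
#'
#' @param I0 Initial amplitude (pA).
#' @param t_end_decay Time at which the current reaches zero (s).
#' @return An object of class `current_schedule`.
#' @export
current_schedule <- function(I0 = 750, t_end_decay = 4000) {
  stopifnot(I0 >= 0, t_end_decay > 0)
  structure(list(I0 = I0, t_end_decay = t_end_decay),
            class = "current_schedule")
}

#' Facilitating current at a given time
#'
#' @param schedule A [current_schedule()].
#' @param t Time(s) since the start of the schedule (s); vectorised.
#' @return Current amplitude(s) in pA.
#' @export
facilitating_current <- function(schedule, t) {
  stopifnot(inherits(schedule, "current_schedule"), all(t >= 0))
  schedule$I0 * pmax(0, 1 - t / schedule$t_end_decay)
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("LIF neuron: tau_m", x$tau_m, "ms, t_ref", x$t_ref, "ms, V_rest",
      x$V_rest, "mV, V_reset", x$V_reset, "mV, V_th", x$V_th, "mV, C_mem",
      x$C_mem, "pF\n")
  invisible(x)
}

#' @export
print.growth_rule <- function(x, ...) {
  cat(sprintf("growth rule [%s]: nu = %g /s, epsilon = %g", x$variant, x$nu,
              x$epsilon))
  if (x$variant == "gaussian") cat(sprintf(", eta = %g", x$eta))
  cat("\n")
  invisible(x)
}
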