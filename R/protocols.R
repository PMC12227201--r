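#' Desk-scale network preset
#'
#' A scaled-down version of the full-size network (10000 E + 2500 I) for
#' desk-scale simulation. Only the plastic excitatory population is scaled
#' down (divided by `scale`), with excitatory weights multiplied by `scale`
#' so that the excitatory mean drive to every target is unchanged; the
#' static inhibitory population is kept at full size with its original
#' weight. This preserves both the mean and -- to within ~15% -- the
#' variance of each population's synaptic input, so the desk-scale network
#' sits at the same operating point as the full-size model: the growth
#' rules steer the excitatory population to the target rate (7.9 Hz) at the
#' same equilibrium connection probability (about 10%), with about
#' 0.1 * N_E E-E input synapses per neuron. (A fully proportional scaling
#' with weights increased to preserve the mean alone would triple the
#' membrane noise and shift the 7.9 Hz operating point to a far sparser
#' equilibrium.)
#'
#' Growth-rate handling: the growth phase runs the printed rules accelerated
#' by `nu_growth`; perturbation phases use `nu_perturb`, and scaling
#' strengths are multiplied by `rho_mult` (protocols trade biological
#' duration against plasticity speed, as the reference protocols themselves
#' do with their 100%/50%/10% growth-rate settings). The facilitating
#' current for biphasic growth decays over `t_fac_decay` (two thirds of the
#' nominal growth span, mirroring the 4000 s / 6000 s full-scale protocol).
#'
#' @param scale Population division factor.
#' @param nu_growth Growth-rate multiplier for growth phases.
#' @param nu_perturb Growth-rate multiplier for perturbation phases.
#' @param rho_mult Scaling-strength multiplier for perturbation phases.
#' @param t_grow_max Maximum growth time before giving up on a plateau (s).
#' @param t_fac_decay Facilitating-current decay time (s).
#' @return A list of preset fields including a [network_config()].
#' @export
scaled_preset <- function(scale = 10, nu_growth = 150, nu_perturb = 300,
                          rho_mult = 100, t_grow_max = 900,
                          t_fac_decay = 300) {
  stopifnot(scale >= 1)
  list(
    config = network_config(
      N_E = round(10000 / scale), N_I = 2500,
      p_static = 0.1, J_E = 0.1 * scale, J_I = -0.8,
      J_ext = 0.1, r_ext = 30000),
    nu_growth = nu_growth, nu_perturb = nu_perturb, rho_mult = rho_mult,
    t_grow_max = t_grow_max, t_fac_decay = t_fac_decay)
}

#' Seeded choice of the perturbation subpopulation
#'
#' The first `ceiling(frac * N_E)` excitatory ids of a seeded permutation.
#'
#' @param n_e Number of excitatory neurons.
#' @param frac Subpopulation fraction (default 10%).
#' @param seed Seed for the permutation (optional; uses the current RNG
#'   state if `NULL`).
#' @return Sorted integer vector of excitatory ids.
#' @export
choose_subpop <- function(n_e, frac = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sort(sample.int(n_e, ceiling(frac * n_e)))
}

#' Grow a network from an empty E-E block
#'
#' Runs the growth protocol under one of the three structural-plasticity
#' rules until the E-E connectivity plateaus (or `t_max` is reached). The
#' linear and zero-Gaussian rules grow unaided; the biphasic rule is grown
#' with the linearly decaying facilitating current injected into all
#' excitatory neurons (reference amplitude 750 pA).
#'
#' The plateau is detected from the recorded connectivity trace: the run
#' stops once the mean E-E connectivity of the two most recent 50 s
#' half-windows differs by less than `plateau_tol` for two consecutive
#' 100 s chunks (and any facilitating current has fully decayed).
#'
#' @param rule `"linear"`, `"zero_gaussian"` or `"biphasic"` (or a
#'   [growth_rule()] object).
#' @param preset A [scaled_preset()] (or compatible list).
#' @param seed Master seed of the run.
#' @param current A [current_schedule()] or `NULL`; defaults to 750 pA over
#'   `preset$t_fac_decay` for the biphasic rule and `NULL` otherwise.
#' @param t_max Maximum growth time (s).
#' @param chunk Simulation chunk length between plateau checks (s).
#' @param subpop_frac Fraction of excitatory neurons earmarked as the
#'   (future) perturbation subpopulation; recorded in the trace from t = 0.
#' @param stop_at_plateau Stop early once the connectivity plateaus.
#' @param plateau_tol Plateau threshold on the half-window difference of
#'   E-E connectivity (fraction).
#' @param divergence_rate Sanity bound on the population rate (Hz); a run
#'   exceeding it is flagged (`diverged = TRUE`) but preserved.
#' @param ... Passed to [run_phase()] (e.g. `record_interval`).
#' @return The grown `hsp_network`, with extra fields `grown_at` (time of
#'   plateau, s) and `diverged`.
#' @export
grow_network <- function(rule = c("linear", "zero_gaussian", "biphasic"),
                         preset = scaled_preset(), seed = 1,
                         current = NULL, t_max = preset$t_grow_max,
                         chunk = 100, subpop_frac = 0.1,
                         stop_at_plateau = TRUE, plateau_tol = 0.001,
                         divergence_rate = 200, ...) {
  if (is.character(rule)) {
    rule <- match.arg(rule)
    if (is.null(current) && rule == "biphasic")
      current <- current_schedule(750, preset$t_fac_decay)
    rule <- switch(rule, linear = rule_linear(),
                   zero_gaussian = rule_zero_gaussian(),
                   biphasic = rule_biphasic())
  }
  set.seed(seed)
  net <- build_network(config = preset$config,
                       rule_axonal = rule, rule_dendritic = rule,
                       subpop = choose_subpop(preset$config$N_E, subpop_frac))
  fac_end <- if (is.null(current)) 0 else current$t_end_decay
  hits <- 0L
  repeat {
    net <- run_phase(net, chunk, current = current,
                     nu_multiplier = preset$nu_growth, ...)
    tr <- net$trace
    t_now <- net$state$t_now_s
    if (stop_at_plateau && t_now >= fac_end + 2 * chunk) {
      g <- tr$gamma_EE
      n <- length(g)
      half <- max(1L, as.integer(round(50 / diff(tr$t[1:2]))))
      if (n >= 2 * half) {
        d <- abs(mean(g[(n - half + 1):n]) -
                 mean(g[(n - 2 * half + 1):(n - half)]))
        hits <- if (d < plateau_tol) hits + 1L else 0L
        if (hits >= 2L) break
      }
    }
    if (t_now >= t_max) break
  }
  net$grown_at <- net$state$t_now_s
  net$diverged <- any(net$trace$rate_E > divergence_rate, na.rm = TRUE)
  net
}

#' Summary of the grown equilibrium
#'
#' Means over the trailing `window` seconds of the recorded trace: E-E
#' connection probability, population rates, and the per-neuron synapse
#' count implied by the connectivity.
#'
#' @param net A grown `hsp_network`.
#' @param window Averaging window (s).
#' @return A list with `gamma_EE`, `rate_E`, `rate_I`, `indegree`.
#' @export
equilibrium_summary <- function(net, window = 100) {
  tr <- net$trace
  keep <- tr$t > max(tr$t) - window
  list(gamma_EE = mean(tr$gamma_EE[keep]),
       rate_E = mean(tr$rate_E[keep]),
       rate_I = mean(tr$rate_I[keep]),
       indegree = mean(tr$gamma_EE[keep]) * (net$config$N_E - 1))
}

#' Perturb the external drive of the subpopulation
#'
#' Multiplies the external Poisson rate of the network's subpopulation by
#' `foi` (fold of original intensity) and continues the simulation:
#' `foi > 1` stimulates, `foi < 1` deprives, `foi = 0` silences. Structural
#' plasticity keeps running (at the preset's perturbation growth-rate
#' multiplier); synaptic scaling is activated if `rho > 0`.
#'
#' @param net A grown `hsp_network`.
#' @param foi Fold-of-original-intensity multiplier (>= 0).
#' @param duration Perturbation length (s).
#' @param preset The preset the network was grown with (for the
#'   perturbation-phase multipliers).
#' @param rho Synaptic-scaling strength (reference scale; multiplied by
#'   `preset$rho_mult`).
#' @param nu_multiplier Growth-rate multiplier (defaults to
#'   `preset$nu_perturb`).
#' @param seed Optional seed for the perturbation phase.
#' @param ... Passed to [run_phase()].
#' @return The perturbed network; `onset` holds the perturbation time (s).
#' @export
apply_foi <- function(net, foi, duration, preset = scaled_preset(),
                      rho = 0, nu_multiplier = preset$nu_perturb,
                      seed = NULL, ...) {
  stopifnot(foi >= 0)
  onset <- net$state$t_now_s
  net$scaling <- scaling_params(rho = rho, epsilon = net$scaling$epsilon,
                                w_min = net$scaling$w_min,
                                sign = net$scaling$sign,
                                enabled_from = onset)
  net <- run_phase(net, duration, foi = foi,
                   nu_multiplier = nu_multiplier,
                   scaling = rho > 0, rho_multiplier = preset$rho_mult,
                   seed = seed, ...)
  net$onset <- onset
  net
}

#' Silencing followed by external re-stimulation
#'
#' The rescue protocol: the subpopulation is silenced (FOI = 0) for
#' `t_silence`, then stimulated at `stim_foi` for `t_stim`, optionally with
#' synaptic scaling active throughout. The outcome is classified from the
#' final subpopulation rate: `"silent"` (below the lower-setpoint rate),
#' `"reactivated"` (between the setpoints' neighborhood), or
#' `"over_excited"` (far above the target rate).
#'
#' @inheritParams apply_foi
#' @param t_silence,t_stim Phase lengths (s).
#' @param stim_foi FOI of the stimulation phase (e.g. 1 for restoring the
#'   original drive; 2 for the doubled-intensity protocol).
#' @return The network, with fields `onset` and `outcome`.
#' @export
silencing_rescue <- function(net, t_silence, t_stim = 0, stim_foi = 1,
                             preset = scaled_preset(), rho = 0,
                             seed = NULL, ...) {
  net <- apply_foi(net, foi = 0, duration = t_silence, preset = preset,
                   rho = rho, seed = seed, ...)
  onset <- net$onset
  if (t_stim > 0)
    net <- run_phase(net, t_stim, foi = stim_foi,
                     nu_multiplier = preset$nu_perturb,
                     scaling = rho > 0, rho_multiplier = preset$rho_mult, ...)
  tr <- net$trace
  tail_rate <- mean(tr$rate_S[tr$t > max(tr$t) - 25])
  target <- calcium_to_rate(net$rule_axonal$epsilon, net$calcium)
  eta_rate <- if (is.na(net$rule_axonal$eta)) 0 else
    calcium_to_rate(net$rule_axonal$eta, net$calcium)
  net$onset <- onset
  net$outcome <- if (tail_rate <= max(eta_rate, 0.5)) "silent"
  else if (tail_rate > 3 * target) "over_excited"
  else "reactivated"
  net
}

#' Input connectivity of the subpopulation from a recorded trace
#'
#' Combines the within-subpopulation and external-to-subpopulation blocks of
#' the trace into the mean input connection probability of the deprived
#' neurons.
#'
#' @param net An `hsp_network` with a recorded trace and a subpopulation.
#' @return Numeric vector along the trace time grid.
#' @export
gamma_sub_input <- function(net) {
  tr <- net$trace
  nS <- length(net$subpop)
  NE <- net$config$N_E
  (tr$gamma_SS * (nS - 1) + tr$gamma_ES * (NE - nS)) / (NE - 1)
}

#' Growth-rate x scaling-strength sweep
#'
#' Repeats the silencing protocol from a grown reference state over a grid
#' of growth-rate multipliers (`nu_values`, relative to the preset's
#' perturbation multiplier) and scaling strengths (`rho_values`), with
#' `n_trials` seeded repetitions per cell, and scores each run by the signed
#' deviation areas of the subpopulation's input connectivity (target: the
#' equilibrium connection probability, 10%) and firing rate (target: the
#' setpoint rate) over the silencing period.
#'
#' @param base_net A grown `hsp_network` (see [grow_network()]).
#' @param nu_values Multipliers on `preset$nu_perturb`.
#' @param rho_values Scaling strengths (reference scale).
#' @param n_trials Seeded repetitions per cell.
#' @param t_silence Silencing length per run (s).
#' @param preset The preset used to grow `base_net`.
#' @param seed Base seed; trial t of cell (i, j) uses
#'   `seed + 1000 * i + 100 * j + t`.
#' @param gamma_target,rate_target Deviation targets.
#' @return A data.frame with one row per (nu, rho, trial):
#'   `dev_gamma` (fraction * s) and `dev_rate` (Hz * s).
#' @export
run_sweep <- function(base_net, nu_values = c(0.5, 1), rho_values = c(0, 0.02),
                      n_trials = 1, t_silence = 100,
                      preset = scaled_preset(), seed = 1,
                      gamma_target = 0.1, rate_target = 7.9) {
  stopifnot(n_trials >= 1)
  out <- list()
  for (i in seq_along(nu_values)) for (j in seq_along(rho_values))
    for (tt in seq_len(n_trials)) {
      run <- apply_foi(base_net, foi = 0, duration = t_silence,
                       preset = preset, rho = rho_values[j],
                       nu_multiplier = preset$nu_perturb * nu_values[i],
                       seed = seed + 1000 * i + 100 * j + tt)
      tr <- run$trace
      keep <- tr$t > run$onset
      g <- gamma_sub_input(run)
      out[[length(out) + 1]] <- data.frame(
        nu = nu_values[i], rho = rho_values[j], trial = tt,
        dev_gamma = deviation_area(tr$t[keep], g[keep], gamma_target),
        dev_rate = deviation_area(tr$t[keep], tr$rate_S[keep], rate_target))
    }
  do.call(rbind, out)
}

#' Deterministic miniature fixtures
#'
#' Small, seeded inputs for unit testing and illustration:
#'
#' * `"two_neuron"`: two excitatory neurons receiving the *identical*
#'   external Poisson realization (plus one disconnected inhibitory neuron);
#'   returns the shared spike train, the membrane traces, and calcium traces
#'   computed with two decay constants (`tau_Ca` 1 s and 10 s) -- identical
#'   spiking, diverging calcium.
#' * `"small_net"`: a 10 E + 4 I network with 10% static wiring.
#' * `"scripted_spikes"`: a periodic spike train at `rate` Hz.
#'
#' @param kind Fixture kind.
#' @param seed Seed.
#' @param duration Simulated / scripted time (s).
#' @param rate Rate of the scripted train (Hz).
#' @return Fixture-dependent list; see Details.
#' @export
make_fixture <- function(kind = c("two_neuron", "small_net", "scripted_spikes"),
                         seed = 1, duration = 10, rate = 7.9) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "scripted_spikes") {
    return(list(spike_times = seq(1 / rate, duration, by = 1 / rate),
                rate = rate, duration = duration))
  }
  if (kind == "small_net") {
    cfg <- network_config(N_E = 10, N_I = 4, p_static = 0.1, J_E = 0.1,
                          J_I = -0.8, r_ext = 30000)
    return(build_network(config = cfg, rule_axonal = rule_linear()))
  }
  # two_neuron
  cfg <- network_config(N_E = 2, N_I = 1, p_static = 0, r_ext = 30000)
  net <- build_network(config = cfg)
  net <- run_phase(net, duration, plasticity = FALSE,
                   record_interval = duration,
                   record_spikes = TRUE, record_V = c(1, 2),
                   ext_group = c(0L, 0L, NA))
  sp <- net$raster
  t1 <- sp$t_ms[sp$neuron == 1] / 1000
  t2 <- sp$t_ms[sp$neuron == 2] / 1000
  list(net = net,
       spikes = list(t1, t2),
       V_trace = net$V_trace,
       calcium = list(
         tau_1s = calcium_trace(t1, duration, dt = 0.01,
                                params = calcium_params(tau_Ca = 1)),
         tau_10s = calcium_trace(t1, duration, dt = 0.01,
                                 params = calcium_params(tau_Ca = 10))))
}
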