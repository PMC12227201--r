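#' Simulate one protocol phase
#'
#' Advances a network built with [build_network()] by `duration` seconds of
#' biological time under fixed phase settings: external-drive multipliers
#' (FOI) per subpopulation, an optional facilitating-current schedule,
#' structural plasticity on/off with a growth-rate multiplier, and synaptic
#' scaling on/off with a scaling-strength multiplier. Appends the recorded
#' population trace to `net$trace` and returns the updated network.
#'
#' @param net An `hsp_network`.
#' @param duration Phase length (s); must be a multiple of `record_interval`.
#' @param foi Fold-of-original-intensity multiplier applied to the external
#'   Poisson rate of the subpopulation `net$subpop` (1 leaves the drive
#'   untouched; 0 silences; 1.1 stimulates by 10%).
#' @param foi_all Optional multiplier applied to every neuron (rarely used).
#' @param current A [current_schedule()] for the facilitating somatic current
#'   injected into all excitatory neurons, or `NULL`. The schedule's clock
#'   continues across phases (see `net$fac_elapsed_s`).
#' @param plasticity Structural plasticity on/off for this phase.
#' @param nu_multiplier Growth-rate multiplier for this phase (on top of the
#'   rules' own `nu`).
#' @param scaling Synaptic scaling on/off for this phase.
#' @param rho_multiplier Multiplier on `net$scaling$rho` for this phase.
#' @param record_interval Trace recording window (s); population rates are
#'   averaged over this window.
#' @param struct_interval Structural-update interval (s).
#' @param record_spikes Record the full spike raster (memory-heavy on long
#'   runs; intended for small networks and short windows).
#' @param record_events Record the per-synapse formation/deletion event log.
#' @param record_V Integer vector of neuron ids whose membrane potential is
#'   recorded every step (empty = none).
#' @param ext_group Optional integer vector (length N) assigning neurons to
#'   shared external-input groups: neurons with the same non-NA group id
#'   receive the identical Poisson realization (used by fixtures); NA = own
#'   independent drive.
#' @param seed Optional seed set before the phase.
#' @return The updated `hsp_network`. New fields: `trace` (data.frame of
#'   population rates and block connectivities per window), and if requested
#'   `raster`, `events`, `V_trace` for this phase.
#' @export
run_phase <- function(net, duration,
                      foi = 1, foi_all = 1,
                      current = NULL,
                      plasticity = TRUE, nu_multiplier = 1,
                      scaling = FALSE, rho_multiplier = 1,
                      record_interval = 5, struct_interval = 0.1,
                      record_spikes = FALSE, record_events = FALSE,
                      record_V = integer(0),
                      ext_group = NULL,
                      seed = NULL) {
  stopifnot(inherits(net, "hsp_network"), duration > 0, foi >= 0)
  if (!is.null(seed)) set.seed(seed)
  cfg <- net$config
  N <- cfg$N_E + cfg$N_I
  if (abs(duration / record_interval - round(duration / record_interval)) > 1e-9)
    stop("duration must be a multiple of record_interval")

  lam <- rep(cfg$r_ext * cfg$dt * 1e-3, N) * foi_all
  if (length(net$subpop)) lam[net$subpop] <- lam[net$subpop] * foi

  if (is.null(ext_group)) {
    grp <- rep(-1L, N); has_groups <- FALSE
  } else {
    grp <- as.integer(ifelse(is.na(ext_group), -1L, ext_group))
    has_groups <- any(grp >= 0)
  }

  prm <- list(
    NE = cfg$N_E, NI = cfg$N_I, dt_ms = cfg$dt, delay_ms = cfg$delay,
    tau_m = net$neuron$tau_m, C_mem = net$neuron$C_mem,
    V_rest = net$neuron$V_rest, V_reset = net$neuron$V_reset,
    V_th = net$neuron$V_th, t_ref = net$neuron$t_ref,
    tau_ca_s = net$calcium$tau_Ca, beta_ca = net$calcium$beta_Ca,
    J_new = cfg$J_E, unit_w = 0.1,
    struct_interval_ms = struct_interval * 1000,
    record_interval_s = record_interval,
    adj_ptr = net$adj$ptr, adj_tgt = net$adj$tgt, adj_w = net$adj$w,
    sub = as.integer(net$subpop - 1L))

  scaling_active <- isTRUE(scaling) && net$scaling$rho > 0 &&
    net$state$t_now_s + duration > net$scaling$enabled_from

  ph <- list(
    duration_s = duration,
    ext_lambda = lam, ext_w = cfg$J_ext,
    ext_group = grp, has_groups = has_groups,
    fac_I0 = if (is.null(current)) 0 else current$I0,
    fac_t_end = if (is.null(current)) 1 else current$t_end_decay,
    fac_t0 = net$fac_elapsed_s,
    struct_on = isTRUE(plasticity), nu_mult = nu_multiplier,
    rule_A = unclass(net$rule_axonal), rule_D = unclass(net$rule_dendritic),
    scaling_on = scaling_active,
    rho = net$scaling$rho * rho_multiplier,
    scale_sign = net$scaling$sign, w_min = net$scaling$w_min,
    scale_eps = net$scaling$epsilon,
    record_spikes = record_spikes, record_events = record_events,
    record_V_ids = as.integer(record_V - 1L))

  st <- net$state
  st$syn_pre <- as.integer(st$syn_pre - 1L)
  st$syn_post <- as.integer(st$syn_post - 1L)
  out <- run_phase_cpp(st, prm, ph)

  net$state <- list(
    V = out$V, ref = out$ref, Ca = out$Ca, z_A = out$z_A, z_D = out$z_D,
    syn_pre = out$syn_pre + 1L, syn_post = out$syn_post + 1L,
    syn_w = out$syn_w, t_now_s = out$t_now_s)
  if (!is.null(current)) net$fac_elapsed_s <- net$fac_elapsed_s + duration
  tr <- as.data.frame(out$trace)
  net$trace <- if (is.null(net$trace)) tr else rbind(net$trace, tr)
  if (record_spikes)
    net$raster <- data.frame(neuron = out$raster_id + 1L,
                             t_ms = out$raster_t_ms)
  if (record_events)
    net$events <- data.frame(t = out$ev_t,
                             event = c("form", "delete")[out$ev_type + 1L],
                             pre = out$ev_pre + 1L, post = out$ev_post + 1L)
  if (length(record_V))
    net$V_trace <- out$V_trace
  net
}

#' Current E-E synapse store of a network
#'
#' @param net An `hsp_network`.
#' @return A `synapse_store` (see [synapse_store()]).
#' @export
network_store <- function(net)
  synapse_store(net$state$syn_pre, net$state$syn_post, net$state$syn_w)
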