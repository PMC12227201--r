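#' Build an initialized network
#'
#' Constructs the two-population LIF network: static I-I, I-E and E-I blocks
#' hard-wired at 10% (each neuron receives synapses from `p_static` of the
#' relevant presynaptic population; autapses excluded), an empty E-E block,
#' all membrane potentials at `V_rest`, zero calcium and zero synaptic
#' elements.
#'
#' Neuron ids are 1-based at the R surface: excitatory neurons are
#' `1..N_E`, inhibitory neurons `N_E+1..N_E+N_I`. File exports use 0-based
#' ids.
#'
#' @param config A [network_config()].
#' @param neuron A [neuron_params()].
#' @param calcium A [calcium_params()].
#' @param rule_axonal,rule_dendritic [growth_rule()]s for axonal boutons and
#'   dendritic spines. They are usually identical; supplying different lower
#'   setpoints reproduces the asymmetric eta_A != eta_D variant.
#' @param scaling A [scaling_params()].
#' @param subpop Integer vector of excitatory ids forming the perturbation
#'   subpopulation (may be empty; see [choose_subpop()]).
#' @param wiring `"fixed_indegree"` (default): every postsynaptic neuron
#'   receives from exactly `round(p_static * N_pre)` randomly chosen
#'   partners; `"bernoulli"`: independent Bernoulli(`p_static`) per directed
#'   pair.
#' @param seed Integer seed for the static wiring (and, through subsequent
#'   phases, the whole run).
#' @return An object of class `hsp_network` holding configuration, parameters
#'   and the full mutable state (membrane, calcium, elements, synapse store).
#' @export
build_network <- function(config = network_config(),
                          neuron = neuron_params(),
                          calcium = calcium_params(),
                          rule_axonal = rule_linear(),
                          rule_dendritic = rule_axonal,
                          scaling = scaling_params(),
                          subpop = integer(0),
                          wiring = c("fixed_indegree", "bernoulli"),
                          seed = NULL) {
  stopifnot(inherits(config, "network_config"), inherits(neuron, "neuron_params"))
  if (!is.null(seed)) set.seed(seed)
  NE <- config$N_E; NI <- config$N_I; N <- NE + NI
  adj <- build_static_wiring(NE, NI, config$p_static, config$J_E, config$J_I,
                             method = match.arg(wiring))
  if (length(subpop) &&
      (any(subpop < 1) || any(subpop > NE) || anyDuplicated(subpop)))
    stop("subpop must be distinct excitatory ids")

  structure(list(
    config = config, neuron = neuron, calcium = calcium,
    rule_axonal = rule_axonal, rule_dendritic = rule_dendritic,
    scaling = scaling,
    subpop = as.integer(subpop),
    adj = adj,
    state = list(
      V = rep(neuron$V_rest, N),
      ref = integer(N),
      Ca = numeric(NE),
      z_A = numeric(NE),
      z_D = numeric(NE),
      syn_pre = integer(0), syn_post = integer(0), syn_w = numeric(0),
      t_now_s = 0),
    fac_elapsed_s = 0,
    trace = NULL), class = "hsp_network")
}

# Static wiring in CSR-over-presynaptic form (0-based, ready for the engine).
# Directions: E->I with weight J_E, I->E and I->I with weight J_I.
#
# "fixed_indegree": every postsynaptic neuron receives from exactly
# round(p * N_pre) randomly chosen presynaptic partners ("receives synapses
# from 10% of the population"); "bernoulli": independent coin flip per
# directed pair. Fixed in-degree removes the quenched variance of the
# inhibitory drive, which at desk scale would otherwise dominate the
# per-neuron rate dispersion.
build_static_wiring <- function(NE, NI, p, J_E, J_I,
                                method = c("fixed_indegree", "bernoulli")) {
  method <- match.arg(method)
  N <- NE + NI
  srcs <- list(); tgts <- list(); ws <- list()
  blk <- function(n_pre, pre_offset, posts, J, self_offset = NA) {
    for (j in posts) {
      if (method == "fixed_indegree") {
        k <- round(p * n_pre)
        pool <- if (!is.na(self_offset) && (j - self_offset) <= n_pre)
          setdiff(seq_len(n_pre), j - self_offset) else seq_len(n_pre)
        s <- if (k > 0) sort(sample(pool, min(k, length(pool)))) else integer(0)
      } else {
        s <- which(stats::runif(n_pre) < p)
        if (!is.na(self_offset)) s <- s[s != j - self_offset]
      }
      if (length(s)) {
        i <- length(srcs) + 1L
        srcs[[i]] <<- s + pre_offset
        tgts[[i]] <<- rep(j, length(s))
        ws[[i]] <<- rep(J, length(s))
      }
    }
  }
  if (p > 0 && NI > 0) {
    blk(NE, 0L, NE + seq_len(NI), J_E)                 # E -> I
    blk(NI, NE, seq_len(NE), J_I)                      # I -> E
    blk(NI, NE, NE + seq_len(NI), J_I, self_offset = NE)  # I -> I, no autapse
  }
  src <- as.integer(unlist(srcs)); tgt <- as.integer(unlist(tgts))
  w <- as.numeric(unlist(ws))
  o <- order(src, tgt)
  src <- src[o]; tgt <- tgt[o]; w <- w[o]
  ptr <- c(0L, cumsum(tabulate(src, nbins = N)))
  list(ptr = as.integer(ptr), tgt = as.integer(tgt - 1L), w = w,
       n_static = length(src))
}

#' Draw external Poisson spike counts
#'
#' Per-neuron, per-step external spike counts, `counts ~ Poisson(rate * dt)`,
#' independent across neurons and steps, drawn by exact inversion of the
#' Poisson CDF (the same tabulated distribution the network engine samples).
#'
#' @param rate External rate (Hz) per neuron.
#' @param n_neurons Number of neurons.
#' @param dt Step (s).
#' @param steps Number of steps.
#' @return An `n_neurons x steps` integer matrix of counts.
#' @export
poisson_drive <- function(rate, n_neurons, dt, steps = 1) {
  if (rate < 0) stop("rate must be non-negative")
  stopifnot(n_neurons >= 1, dt > 0, steps >= 1)
  matrix(rpois_inv_cpp(n_neurons * steps, rate * dt),
         nrow = n_neurons, ncol = steps)
}

#' Advance LIF membrane potentials by one step
#'
#' Exact exponential-decay update of the membrane equation with delta-jump
#' synapses applied at the step boundary. Between inputs the potential
#' relaxes towards `V_rest + I * tau_m / C_mem`; each input spike adds its
#' weight (mV) instantaneously; crossing threshold emits a spike, resets the
#' potential and starts the refractory clock. Inputs arriving during
#' refractoriness are discarded. This is the same update the compiled engine
#' performs; the R version operates on plain vectors for small fixtures and
#' convergence checks.
#'
#' @param state List with numeric `V` (mV) and integer `ref_steps` (steps of
#'   refractoriness remaining).
#' @param dt Step (ms).
#' @param input Per-neuron summed synaptic jump (mV) arriving this step
#'   (external plus recurrent, already delayed).
#' @param current Injected current (pA), scalar or per-neuron.
#' @param neuron A [neuron_params()].
#' @return List with updated `V`, `ref_steps` and logical `spiked`.
#' @export
step_membrane <- function(state, dt, input = 0, current = 0,
                          neuron = neuron_params()) {
  stopifnot(dt > 0)
  V <- state$V
  ref <- state$ref_steps
  n <- length(V)
  input <- rep_len(input, n)
  mu <- neuron$V_rest + rep_len(current, n) * neuron$tau_m / neuron$C_mem
  alpha <- exp(-dt / neuron$tau_m)
  refractory <- ref > 0
  ref[refractory] <- ref[refractory] - 1L
  V[refractory] <- neuron$V_reset
  # threshold is evaluated at step boundaries: a state already at or above
  # threshold on entry is an unprocessed crossing and spikes immediately
  pre_spike <- !refractory & V >= neuron$V_th
  act <- !refractory & !pre_spike
  V[act] <- mu[act] + (V[act] - mu[act]) * alpha + input[act]
  if (any(!is.finite(V)))
    stop("non-finite membrane potential in step_membrane (neuron ",
         which(!is.finite(V))[1], ")")
  spiked <- pre_spike | (act & V >= neuron$V_th)
  V[spiked] <- neuron$V_reset
  ref[spiked] <- as.integer(round(neuron$t_ref / dt))
  list(V = V, ref_steps = ref, spiked = spiked)
}

#' @export
print.hsp_network <- function(x, ...) {
  cat(sprintf(
    "hsp_network: %d E + %d I neurons, %d static synapses, %d E-E synapses, t = %.1f s\n",
    x$config$N_E, x$config$N_I, x$adj$n_static, length(x$state$syn_pre),
    x$state$t_now_s))
  invisible(x)
}
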