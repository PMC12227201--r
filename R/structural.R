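#' Synapse store
#'
#' The dynamic multiset of directed E-E synapses. Each row is one synapse
#' (multiplicity is represented by repeated (pre, post) rows); weights are in
#' mV. Autapses (pre == post) are forbidden.
#'
#' @param pre,post 1-based excitatory neuron ids.
#' @param w Weights (mV), positive.
#' @return An object of class `synapse_store` (a list of the three vectors).
#' @export
synapse_store <- function(pre = integer(0), post = integer(0),
                          w = numeric(0)) {
  stopifnot(length(pre) == length(post), length(pre) == length(w))
  if (any(pre == post)) stop("autapses are not allowed")
  if (any(w <= 0)) stop("weights must be positive")
  structure(list(pre = as.integer(pre), post = as.integer(post),
                 w = as.numeric(w)), class = "synapse_store")
}

#' @export
print.synapse_store <- function(x, ...) {
  cat("synapse_store:", length(x$pre), "synapses\n")
  invisible(x)
}

#' Per-neuron element state
#'
#' Continuous axonal (`z_A`) and dendritic (`z_D`) synaptic-element counts
#' per excitatory neuron, with the integer counts of elements currently
#' bound in synapses derived from a store.
#'
#' @param z_A,z_D Non-negative numeric vectors (one entry per excitatory
#'   neuron).
#' @return An object of class `element_state`.
#' @export
element_state <- function(z_A, z_D = z_A) {
  stopifnot(length(z_A) == length(z_D), all(z_A >= 0), all(z_D >= 0))
  structure(list(z_A = as.numeric(z_A), z_D = as.numeric(z_D)),
            class = "element_state")
}

#' Bound-element counts of a store
#'
#' @param store A [synapse_store()].
#' @param n_e Number of excitatory neurons.
#' @return List with integer vectors `connected_A` (outgoing / axonal) and
#'   `connected_D` (incoming / dendritic).
#' @export
connected_counts <- function(store, n_e) {
  list(connected_A = tabulate(store$pre, nbins = n_e),
       connected_D = tabulate(store$post, nbins = n_e))
}

#' Euler step of the element counts
#'
#' `z <- max(0, z + dt * f(C))` per neuron and element type, where f is the
#' respective growth rule evaluated at the neuron's calcium concentration.
#'
#' @param elements An [element_state()].
#' @param C Per-neuron calcium concentrations.
#' @param dt Step (s).
#' @param rule_axonal,rule_dendritic [growth_rule()]s.
#' @return Updated `element_state`.
#' @export
integrate_elements <- function(elements, C, dt, rule_axonal,
                               rule_dendritic = rule_axonal) {
  stopifnot(inherits(elements, "element_state"), dt > 0)
  element_state(
    z_A = pmax(0, elements$z_A + dt * growth_rate(C, rule_axonal)),
    z_D = pmax(0, elements$z_D + dt * growth_rate(C, rule_dendritic)))
}

# shared driver over the compiled structural engine
structural_call <- function(elements, store, C,
                            rule_axonal, rule_dendritic,
                            dt, J_new, nu_multiplier,
                            do_integrate, do_delete, do_form,
                            scaling = NULL, snapshots = FALSE,
                            record_events = FALSE) {
  n_e <- length(elements$z_A)
  Cm <- matrix(C, nrow = n_e, ncol = if (is.matrix(C)) ncol(C) else 1)
  if (max(store$pre, store$post, 0L) > n_e)
    stop("store references neurons beyond the element state")
  res <- structural_run_cpp(
    elements$z_A, elements$z_D,
    store$pre - 1L, store$post - 1L, store$w,
    Cm, unclass(rule_axonal), unclass(rule_dendritic),
    dt, J_new, nu_multiplier,
    do_integrate, do_delete, do_form,
    do_scale = !is.null(scaling) && scaling$rho > 0,
    rho = if (is.null(scaling)) 0 else scaling$rho,
    scale_eps = if (is.null(scaling)) 0.0079 else scaling$epsilon,
    scale_sign = if (is.null(scaling)) 1 else scaling$sign,
    w_min = if (is.null(scaling)) 0 else scaling$w_min,
    snapshots = snapshots, record_events = record_events)
  out <- list(
    elements = element_state(res$z_A, res$z_D),
    store = synapse_store(res$pre + 1L, res$post + 1L, res$w),
    n_form = res$n_form, n_del = res$n_del)
  if (snapshots)
    out$snapshots <- lapply(res$snapshots, function(s)
      list(elements = element_state(s$z_A, s$z_D),
           store = synapse_store(s$pre + 1L, s$post + 1L, s$w)))
  if (record_events)
    out$events <- data.frame(t = res$ev_t,
                             event = c("form", "delete")[res$ev_type + 1L],
                             pre = res$ev_pre + 1L, post = res$ev_post + 1L)
  out
}

#' Delete surplus synapses
#'
#' For each neuron and element type, if the bound count exceeds
#' `floor(z)`, the surplus synapses are deleted, chosen uniformly at random
#' among that neuron's bound synapses of that type (axonal pass over all
#' neurons first, then dendritic). Each deletion frees the partner's element:
#' the partner's `z` is untouched, so its element returns to the free pool
#' and may be re-matched at the next formation step (this is what makes
#' rewiring, not just loss, possible).
#'
#' @inheritParams integrate_elements
#' @param store A [synapse_store()].
#' @return List with updated `store`, `n_deleted`, and `elements` (unchanged;
#'   returned for pipeline symmetry).
#' @export
delete_surplus <- function(elements, store, C = NULL,
                           rule_axonal = rule_linear(),
                           rule_dendritic = rule_axonal) {
  r <- structural_call(elements, store, numeric(length(elements$z_A)),
                       rule_axonal, rule_dendritic,
                       dt = 1, J_new = 0.1, nu_multiplier = 1,
                       do_integrate = FALSE, do_delete = TRUE,
                       do_form = FALSE)
  list(elements = r$elements, store = r$store, n_deleted = sum(r$n_del))
}

#' Form synapses by random matching of free elements
#'
#' Free axonal elements (`floor(z_A) - connected_A`, per neuron) and free
#' dendritic elements are pooled globally, both pools are shuffled uniformly,
#' and entries are paired sequentially. Pairs that would form an autapse are
#' rejected and re-drawn once among themselves; elements still unmatched stay
#' free until the next cycle. Each accepted pair creates one synapse of
#' weight `J_new` (0.1 mV by default).
#'
#' @inheritParams delete_surplus
#' @param J_new Weight of newly formed synapses (mV).
#' @return List with updated `store` and `n_formed`.
#' @export
form_synapses <- function(elements, store, J_new = 0.1) {
  r <- structural_call(elements, store, numeric(length(elements$z_A)),
                       rule_linear(), rule_linear(),
                       dt = 1, J_new = J_new, nu_multiplier = 1,
                       do_integrate = FALSE, do_delete = FALSE,
                       do_form = TRUE)
  list(elements = r$elements, store = r$store, n_formed = sum(r$n_form))
}

#' One full structural-plasticity cycle (or several)
#'
#' Runs `integrate -> delete -> form` (optionally followed by synaptic
#' scaling) once per column of `C`, using the calcium concentrations sampled
#' at each cycle boundary. This is the same compiled routine the network
#' engine invokes at every structural update.
#'
#' @inheritParams delete_surplus
#' @param C Numeric vector (one cycle) or `n_e x n_cycles` matrix of calcium
#'   concentrations.
#' @param dt Structural-update interval (s).
#' @param J_new Weight of newly formed synapses (mV).
#' @param nu_multiplier Growth-rate multiplier.
#' @param scaling Optional [scaling_params()] applied after each cycle.
#' @param snapshots Keep a per-cycle snapshot of elements and store.
#' @param record_events Keep the per-synapse event log.
#' @return List with final `elements`, `store`, per-cycle `n_form`/`n_del`,
#'   and optionally `snapshots` and `events`.
#' @export
structural_update <- function(elements, store, C, dt = 0.1,
                              rule_axonal = rule_linear(),
                              rule_dendritic = rule_axonal,
                              J_new = 0.1, nu_multiplier = 1,
                              scaling = NULL, snapshots = FALSE,
                              record_events = FALSE) {
  structural_call(elements, store, C, rule_axonal, rule_dendritic,
                  dt, J_new, nu_multiplier,
                  do_integrate = TRUE, do_delete = TRUE, do_form = TRUE,
                  scaling = scaling, snapshots = snapshots,
                  record_events = record_events)
}

# ---------------------------------------------------------------------------
# Independent reference implementation (naive R loops, same RNG contract as
# the compiled engine: insertion-ordered per-neuron lists with swap-with-last
# removal, uniform picks floor(runif(1) * n), top-down Fisher-Yates
# shuffles). Used as a brute-force oracle in the tests; deliberately simple
# and slow.

ref_shuffle <- function(v) {
  n <- length(v)
  if (n < 2) return(v)
  for (i in n:2) {
    j <- floor(stats::runif(1) * i) + 1
    if (j > i) j <- i
    tmp <- v[i]; v[i] <- v[j]; v[j] <- tmp
  }
  v
}

#' Brute-force reference of the structural engine
#'
#' A naive, loop-based re-implementation of [structural_update()] used as an
#' independent oracle: given the same RNG seed it must reproduce the compiled
#' engine's trajectory state-for-state.
#'
#' @inheritParams structural_update
#' @return Same shape as [structural_update()] with `snapshots`.
#' @keywords internal
#' @export
ref_structural_update <- function(elements, store, C, dt = 0.1,
                                  rule_axonal = rule_linear(),
                                  rule_dendritic = rule_axonal,
                                  J_new = 0.1, nu_multiplier = 1) {
  n_e <- length(elements$z_A)
  Cm <- matrix(C, nrow = n_e, ncol = if (is.matrix(C)) ncol(C) else 1)
  zA <- elements$z_A; zD <- elements$z_D
  rule_a <- rule_axonal; rule_a$nu <- rule_a$nu * nu_multiplier
  rule_d <- rule_dendritic; rule_d$nu <- rule_d$nu * nu_multiplier

  # slot-based store mirroring the engine's free-list semantics
  pre <- store$pre; post <- store$post; w <- store$w
  alive <- rep(TRUE, length(pre))
  axon <- lapply(seq_len(n_e), function(i) which(pre == i))
  dend <- lapply(seq_len(n_e), function(i) which(post == i))
  # enforce insertion order (slot order) as in the engine
  freelist <- integer(0)

  rm_syn <- function(id) {
    i <- pre[id]; j <- post[id]
    L <- axon[[i]]; k <- match(id, L); L[k] <- L[length(L)]
    axon[[i]] <<- L[-length(L)]
    L <- dend[[j]]; k <- match(id, L); L[k] <- L[length(L)]
    dend[[j]] <<- L[-length(L)]
    alive[id] <<- FALSE
    freelist <<- c(freelist, id)
  }
  add_syn <- function(i, j, ww) {
    if (length(freelist)) {
      id <- freelist[length(freelist)]
      freelist <<- freelist[-length(freelist)]
      pre[id] <<- i; post[id] <<- j; w[id] <<- ww; alive[id] <<- TRUE
    } else {
      id <- length(pre) + 1L
      pre[id] <<- i; post[id] <<- j; w[id] <<- ww; alive[id] <<- TRUE
    }
    axon[[i]] <<- c(axon[[i]], id)
    dend[[j]] <<- c(dend[[j]], id)
  }

  ncyc <- ncol(Cm)
  n_form <- integer(ncyc); n_del <- integer(ncyc)
  snaps <- vector("list", ncyc)
  for (cc in seq_len(ncyc)) {
    Ci <- Cm[, cc]
    zA <- pmax(0, zA + dt * growth_rate(Ci, rule_a))
    zD <- pmax(0, zD + dt * growth_rate(Ci, rule_d))
    # deletions: axonal pass, then dendritic pass
    for (i in seq_len(n_e)) {
      surplus <- length(axon[[i]]) - floor(zA[i])
      while (surplus > 0) {
        k <- min(floor(stats::runif(1) * length(axon[[i]])) + 1,
                 length(axon[[i]]))
        rm_syn(axon[[i]][k])
        n_del[cc] <- n_del[cc] + 1L
        surplus <- surplus - 1
      }
    }
    for (i in seq_len(n_e)) {
      surplus <- length(dend[[i]]) - floor(zD[i])
      while (surplus > 0) {
        k <- min(floor(stats::runif(1) * length(dend[[i]])) + 1,
                 length(dend[[i]]))
        rm_syn(dend[[i]][k])
        n_del[cc] <- n_del[cc] + 1L
        surplus <- surplus - 1
      }
    }
    # formation
    pa <- unlist(lapply(seq_len(n_e), function(i)
      rep(i, max(0, floor(zA[i]) - length(axon[[i]])))))
    pd <- unlist(lapply(seq_len(n_e), function(i)
      rep(i, max(0, floor(zD[i]) - length(dend[[i]])))))
    pa <- ref_shuffle(as.integer(pa)); pd <- ref_shuffle(as.integer(pd))
    np <- min(length(pa), length(pd))
    ra <- integer(0); rd <- integer(0)
    for (k in seq_len(np)) {
      if (pa[k] == pd[k]) { ra <- c(ra, pa[k]); rd <- c(rd, pd[k]); next }
      add_syn(pa[k], pd[k], J_new)
      n_form[cc] <- n_form[cc] + 1L
    }
    if (length(ra)) {
      ra <- ref_shuffle(ra); rd <- ref_shuffle(rd)
      for (k in seq_along(ra)) {
        if (ra[k] == rd[k]) next
        add_syn(ra[k], rd[k], J_new)
        n_form[cc] <- n_form[cc] + 1L
      }
    }
    snaps[[cc]] <- list(
      elements = element_state(zA, zD),
      store = synapse_store(pre[alive], post[alive], w[alive]))
  }
  list(elements = element_state(zA, zD),
       store = synapse_store(pre[alive], post[alive], w[alive]),
       n_form = n_form, n_del = n_del, snapshots = snaps)
}
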