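# Lazily computed, session-cached heavy simulation runs shared by the
# acceptance tests. Each run is computed once per test session on first use.

.run_cache <- new.env(parent = emptyenv())

run_cached <- function(name, expr) {
  if (!exists(name, envir = .run_cache))
    assign(name, expr, envir = .run_cache)
  get(name, envir = .run_cache)
}

acc_preset <- function() scaled_preset()

# grown networks (the growth protocols of the two quantitative criteria)
acc_grown_linear <- function()
  run_cached("grown_linear",
             grow_network("linear", preset = acc_preset(), seed = 101))

acc_grown_biphasic <- function()
  run_cached("grown_biphasic",
             grow_network("biphasic", preset = acc_preset(), seed = 202))

# perturbation continuations from the grown biphasic network
acc_perturbed <- function(tag, foi, duration, rho = 0, seed) {
  run_cached(tag, apply_foi(acc_grown_biphasic(), foi = foi,
                            duration = duration, preset = acc_preset(),
                            rho = rho, seed = seed))
}
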