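# LIF membrane integration, external drive, facilitating current

run_free_decay <- function(V0, t_ms, dt, current = 0,
                           neuron = neuron_params(V_th = Inf)) {
  st <- list(V = V0, ref_steps = 0L)
  for (k in seq_len(round(t_ms / dt)))
    st <- step_membrane(st, dt, current = current, neuron = neuron)
  st$V
}

test_that("membrane relaxation matches the closed-form exponential", {
  # V = 10 mV, no input: after one tau_m the potential is V/e
  expect_equal(run_free_decay(10, t_ms = 20, dt = 0.1), 3.67879441171,
               tolerance = 1e-9)
  # constant 750 pA from rest, threshold disabled: steady state
  # I * tau_m / C_mem = 750 * 20 / 250 = 60 mV (R = 80 MOhm)
  V <- run_free_decay(0, t_ms = 400, dt = 0.1, current = 750)
  expect_equal(V, 60, tolerance = 1e-6)
})

test_that("integrator error under a time-varying current is first order in dt", {
  # linearly decaying current sampled per step: O(dt) error against the
  # exact solution of the non-autonomous ODE
  tau <- 20; Cm <- 250; I0 <- 750; T <- 20
  exact <- function(t) {
    # solve dV/dt = (-V + R*I0*(1 - t/T)) / tau, V(0)=0, R*I0 = 60
    a <- 60
    a * (1 - t / T) - a * tau / T * (exp(-t / tau) - 1) - a * exp(-t / tau)
  }
  err <- sapply(c(0.1, 0.05, 0.025), function(dt) {
    st <- list(V = 0, ref_steps = 0L)
    n <- round(T / dt)
    for (k in seq_len(n))
      st <- step_membrane(st, dt, current = I0 * (1 - (k - 1) * dt / T),
                          neuron = neuron_params(V_th = Inf))
    abs(st$V - exact(T))
  })
  expect_equal(err[1] / err[2], 2, tolerance = 0.1)
  expect_equal(err[2] / err[3], 2, tolerance = 0.1)
})

test_that("threshold crossing resets to V_reset and enforces refractoriness", {
  nr <- neuron_params()
  st <- list(V = nr$V_th, ref_steps = 0L)
  st <- step_membrane(st, 0.1, neuron = nr)
  expect_true(st$spiked)
  expect_equal(st$V, 10)                       # reset potential
  expect_equal(st$ref_steps, 20L)              # 2 ms at dt = 0.1
  # inputs during refractoriness are discarded
  st <- step_membrane(st, 0.1, input = 100, neuron = nr)
  expect_false(st$spiked)
  expect_equal(st$V, nr$V_reset)
})

test_that("inter-spike intervals respect the refractory period in the engine", {
  cfg <- network_config(N_E = 5, N_I = 1, p_static = 0, r_ext = 60000)
  net <- build_network(config = cfg, seed = 7)
  net <- run_phase(net, 2, plasticity = FALSE, record_interval = 2,
                   record_spikes = TRUE)
  sp <- net$raster
  expect_gt(nrow(sp), 50)
  for (id in unique(sp$neuron)) {
    isi <- diff(sort(sp$t_ms[sp$neuron == id]))
    expect_true(all(isi > 2))   # strictly greater than t_ref
  }
})

test_that("an isolated neuron without drive never spikes from rest", {
  cfg <- network_config(N_E = 2, N_I = 1, p_static = 0, r_ext = 0)
  net <- build_network(config = cfg, seed = 1)
  net <- run_phase(net, 5, plasticity = FALSE, record_interval = 5,
                   record_spikes = TRUE)
  expect_equal(nrow(net$raster), 0)
  expect_equal(net$state$V, rep(0, 3))
})

test_that("poisson drive has the nominal mean and is reproducible", {
  expect_error(poisson_drive(-1, 10, 1e-4))
  expect_true(all(poisson_drive(0, 10, 1e-4, 50) == 0))
  set.seed(11)
  cnt <- poisson_drive(30000, 100, 1e-4, 400)   # lambda = 3 per step
  n <- length(cnt)
  m <- mean(cnt)
  expect_lt(abs(m - 3), 3 * sqrt(3 / n))        # 3 sigma of the mean
  expect_lt(abs(var(as.numeric(cnt)) / 3 - 1), 0.05)
  set.seed(11)
  expect_identical(cnt, poisson_drive(30000, 100, 1e-4, 400))
})

test_that("facilitating current decays linearly to zero", {
  sch <- current_schedule(I0 = 750, t_end_decay = 4000)
  expect_equal(facilitating_current(sch, 0), 750)
  expect_equal(facilitating_current(sch, 2000), 375)
  expect_equal(facilitating_current(sch, 4000), 0)
  expect_equal(facilitating_current(sch, 5000), 0)   # stays at zero
})

test_that("identical seed and configuration give bit-identical spike trains", {
  cfg <- network_config(N_E = 20, N_I = 5, p_static = 0.2, r_ext = 30000)
  run <- function() {
    net <- build_network(config = cfg, rule_axonal = rule_linear(),
                         seed = 99)
    run_phase(net, 3, nu_multiplier = 100, record_interval = 1,
              record_spikes = TRUE)
  }
  a <- run(); b <- run()
  expect_identical(a$raster, b$raster)
  expect_identical(a$trace, b$trace)
  expect_identical(a$state, b$state)
})

test_that("invalid network configurations are rejected", {
  expect_error(network_config(N_E = 0))
  expect_error(network_config(p_static = 1.5))
  expect_error(network_config(J_E = -0.1))
  expect_error(network_config(J_I = 0.8))
  expect_error(network_config(r_ext = -5))
})

test_that("static wiring respects p_static and excludes the E-E block", {
  # p = 0: no static synapses at all
  n0 <- build_network(config = network_config(N_E = 10, N_I = 4,
                                              p_static = 0), seed = 1)
  expect_equal(n0$adj$n_static, 0)
  expect_length(n0$state$syn_pre, 0)
  # fixed in-degree: every I neuron receives from exactly 10% of E
  cfg <- network_config(N_E = 400, N_I = 100, p_static = 0.1)
  net <- build_network(config = cfg, seed = 3)
  tgt <- net$adj$tgt + 1L
  src <- rep(seq_len(500), diff(net$adj$ptr))
  ei <- src <= 400 & tgt > 400
  indeg <- tabulate(tgt[ei] - 400L, nbins = 100)
  expect_true(all(indeg == 40))
  # no I-I autapses
  ii <- src > 400 & tgt > 400
  expect_true(all(src[ii] != tgt[ii]))
  # bernoulli wiring: binomial in-degree around p * N_E
  netb <- build_network(config = cfg, wiring = "bernoulli", seed = 3)
  tgtb <- netb$adj$tgt + 1L
  srcb <- rep(seq_len(500), diff(netb$adj$ptr))
  eib <- srcb <= 400 & tgtb > 400
  indegb <- tabulate(tgtb[eib] - 400L, nbins = 100)
  expect_lt(abs(mean(indegb) - 40), 3 * sqrt(40 * 0.9 / 100))
  expect_gt(stats::var(indegb), 0)
  # determinism of the wiring
  net2 <- build_network(config = cfg, seed = 42)
  net3 <- build_network(config = cfg, seed = 42)
  expect_identical(net2$adj, net3$adj)
})
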