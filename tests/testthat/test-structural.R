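# element bookkeeping, synapse deletion/formation, and the full structural
# engine against the brute-force reference

test_that("element integration follows the growth curve and clamps at zero", {
  el <- element_state(z_A = c(1, 1, 0.01))
  r <- rule_biphasic()
  # at the setpoint nothing changes
  e1 <- integrate_elements(el, C = rep(r$epsilon, 3), dt = 100, r)
  expect_equal(e1$z_A, el$z_A)
  # at the midpoint the curve is at its peak +nu: 100 s adds 0.4 elements
  e2 <- integrate_elements(el, C = rep(r$xi, 3), dt = 100, r)
  expect_equal(e2$z_A, el$z_A + 0.4, tolerance = 1e-12)
  # strong retraction never drives z below zero
  e3 <- integrate_elements(el, C = rep(1, 3), dt = 1000, r)
  expect_equal(e3$z_A, c(0, 0, 0))
})

test_that("delete_surplus removes exactly connected - floor(z) synapses", {
  set.seed(5)
  # neuron 1 has 3 axonal synapses but z_A = 2.7 -> exactly one deletion
  st <- synapse_store(pre = c(1, 1, 1), post = c(2, 3, 4), w = rep(0.1, 3))
  el <- element_state(z_A = c(2.7, 5, 5, 5), z_D = c(5, 5, 5, 5))
  r <- delete_surplus(el, st)
  expect_equal(r$n_deleted, 1)
  expect_equal(length(r$store$pre), 2)
  # z_A = 3.0 exactly: no deletion
  el2 <- element_state(z_A = c(3, 5, 5, 5), z_D = c(5, 5, 5, 5))
  expect_equal(delete_surplus(el2, st)$n_deleted, 0)
})

test_that("deletion frees the partner's element for rewiring", {
  # 3-neuron fixture: deleting 1->2 leaves neuron 2 with a free dendritic
  # element (its z_D is untouched), which can immediately rebind
  set.seed(2)
  st <- synapse_store(pre = 1, post = 2, w = 0.1)
  el <- element_state(z_A = c(0, 1, 1), z_D = c(1, 1, 0))
  # axonal surplus on neuron 1 forces deletion of its only synapse
  r <- delete_surplus(el, st)
  expect_equal(length(r$store$pre), 0)
  cc <- connected_counts(r$store, 3)
  free_D <- floor(el$z_D) - cc$connected_D
  expect_equal(free_D[2], 1)   # partner element back in the pool
  # formation re-matches the freed element (free_A pool: neurons 2 and 3;
  # free_D pool: neurons 1 and 2; only the 2->2 pairing is forbidden)
  f <- form_synapses(el, r$store)
  expect_gte(f$n_formed, 1)
  expect_true(all(f$store$pre != f$store$post))
  expect_true(2 %in% f$store$pre || 2 %in% f$store$post)
})

test_that("formation pairs min(free_A, free_D) elements and rejects autapses", {
  set.seed(9)
  # total free_A = 3 (neurons 1,2,3), free_D = 2 (neurons 4,5): 2 synapses
  el <- element_state(z_A = c(1, 1, 1, 0, 0), z_D = c(0, 0, 0, 1, 1))
  f <- form_synapses(el, synapse_store())
  expect_equal(f$n_formed, 2)
  expect_true(all(f$store$pre %in% 1:3), all(f$store$post %in% 4:5))
  expect_true(all(f$store$w == 0.1))
  # empty pools: store unchanged
  f0 <- form_synapses(element_state(z_A = c(0, 0)), synapse_store())
  expect_equal(f0$n_formed, 0)
  # the only possible pairing would be an autapse: forbidden
  f1 <- form_synapses(element_state(z_A = c(1, 0), z_D = c(1, 0)),
                      synapse_store())
  expect_equal(f1$n_formed, 0)
})

test_that("free-element matching is uniform across compatible partners", {
  # neuron 1 offers one axonal element; neurons 2..4 each offer one
  # dendritic element; over many seeded repetitions each partner should be
  # chosen equally often
  el <- element_state(z_A = c(1, 0, 0, 0), z_D = c(0, 1, 1, 1))
  set.seed(123)
  picks <- integer(3)
  n_rep <- 3000
  for (k in seq_len(n_rep)) {
    f <- form_synapses(el, synapse_store())
    picks[f$store$post[f$store$pre == 1] - 1L] <-
      picks[f$store$post[f$store$pre == 1] - 1L] + 1L
  }
  expect_equal(sum(picks), n_rep)
  chi <- sum((picks - n_rep / 3)^2 / (n_rep / 3))
  expect_lt(chi, qchisq(0.999, df = 2))
})

test_that("conservation and floor bounds hold at every structural boundary", {
  set.seed(21)
  n_e <- 8
  el <- element_state(z_A = runif(n_e, 0, 4), z_D = runif(n_e, 0, 4))
  # calcium schedule wandering through all three regimes of the curve
  Ca <- matrix(runif(n_e * 50, 0, 0.012), n_e, 50)
  r <- structural_update(el, synapse_store(), Ca, dt = 10,
                         rule_axonal = rule_biphasic(), nu_multiplier = 50,
                         snapshots = TRUE)
  for (s in r$snapshots) {
    cc <- connected_counts(s$store, n_e)
    expect_equal(sum(cc$connected_A), length(s$store$pre))
    expect_equal(sum(cc$connected_D), length(s$store$pre))
    expect_true(all(cc$connected_A <= floor(s$elements$z_A)))
    expect_true(all(cc$connected_D <= floor(s$elements$z_D)))
    expect_true(all(s$store$pre != s$store$post))
    expect_true(all(s$store$w > 0))
  }
})

test_that("a no-op cycle leaves the network untouched", {
  set.seed(4)
  st <- synapse_store(pre = c(1, 2), post = c(2, 3), w = c(0.1, 0.1))
  el <- element_state(z_A = c(1, 1, 0), z_D = c(0, 1, 1))
  r <- structural_update(el, st, C = rep(0.0079, 3), dt = 0.1,
                         rule_axonal = rule_biphasic())
  expect_equal(sum(r$n_form) + sum(r$n_del), 0)
  expect_equal(r$store$pre, st$pre)
  expect_equal(r$elements$z_A, el$z_A)
})

test_that("compiled structural engine matches the brute-force reference over 100 cycles", {
  for (seed in c(1, 17)) {
    set.seed(seed)
    n_e <- 3
    el <- element_state(z_A = runif(n_e, 0, 3), z_D = runif(n_e, 0, 3))
    Ca <- matrix(runif(n_e * 100, 0, 0.012), n_e, 100)
    set.seed(seed + 1000)
    a <- structural_update(el, synapse_store(), Ca, dt = 20,
                           rule_axonal = rule_biphasic(),
                           nu_multiplier = 25, snapshots = TRUE)
    set.seed(seed + 1000)
    b <- ref_structural_update(el, synapse_store(), Ca, dt = 20,
                               rule_axonal = rule_biphasic(),
                               nu_multiplier = 25)
    expect_equal(a$elements$z_A, b$elements$z_A)
    expect_equal(a$elements$z_D, b$elements$z_D)
    expect_equal(a$n_form, b$n_form)
    expect_equal(a$n_del, b$n_del)
    for (k in seq_along(a$snapshots)) {
      expect_identical(a$snapshots[[k]]$store$pre, b$snapshots[[k]]$store$pre)
      expect_identical(a$snapshots[[k]]$store$post, b$snapshots[[k]]$store$post)
    }
  }
})

test_that("silenced neuron under the biphasic rule loses its synapses monotonically", {
  set.seed(31)
  n_e <- 4
  # neuron 1 fully wired, silent (C = 0); others at the setpoint
  st <- synapse_store(pre = c(1, 1, 1, 2, 3, 4), post = c(2, 3, 4, 1, 1, 1),
                      w = rep(0.1, 6))
  el <- element_state(z_A = c(3, 1, 1, 1), z_D = c(3, 1, 1, 1))
  Ca <- matrix(rep(c(0, rep(0.0079, 3)), 40), n_e, 40)
  r <- structural_update(el, st, Ca, dt = 50,
                         rule_axonal = rule_biphasic(), snapshots = TRUE)
  deg1 <- sapply(r$snapshots, function(s)
    sum(s$store$pre == 1) + sum(s$store$post == 1))
  expect_true(all(diff(deg1) <= 0))
  expect_equal(deg1[length(deg1)], 0)   # fully disconnected
  # the partners keep their elements free (z untouched by deletion)
  expect_equal(r$elements$z_A[2:4], c(1, 1, 1))
})

test_that("structural trajectories are seed-reproducible", {
  n_e <- 5
  el <- element_state(z_A = rep(2.5, n_e), z_D = rep(2.5, n_e))
  Ca <- matrix(0.004, n_e, 20)
  set.seed(77)
  a <- structural_update(el, synapse_store(), Ca, dt = 30,
                         rule_axonal = rule_biphasic(), record_events = TRUE)
  set.seed(77)
  b <- structural_update(el, synapse_store(), Ca, dt = 30,
                         rule_axonal = rule_biphasic(), record_events = TRUE)
  expect_identical(a$events, b$events)
  expect_identical(a$store, b$store)
})
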