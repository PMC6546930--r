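pp <- function(n_e = 2, n_i = 1, params = neuron_params())
  population_params(params, n_e, n_i)

test_that("membrane at rest with zero conductances is a fixed point", {
  pop <- pp()
  st <- neuron_state(pop)
  for (k in 1:50) st <- integrate_membrane(st, pop, dt = 0.5, t_now = k * 0.5)
  expect_equal(st$v, pop$e_rest)
})

test_that("leak-only decay matches the closed-form exponential", {
  params <- neuron_params()
  pop <- pp(params = params)
  st <- neuron_state(pop)
  st$v <- pop$e_rest + 10
  dt <- 0.5
  n_steps <- 200
  for (k in 1:n_steps) st <- integrate_membrane(st, pop, dt, t_now = k * dt)
  expected <- pop$e_rest + 10 * exp(-(n_steps * dt) / pop$tau_mem)
  expect_equal(st$v, expected, tolerance = 1e-6)
})

test_that("constant strong excitation drives V to the algebraic fixed point", {
  pop <- pp()
  st <- neuron_state(pop)
  g <- 5
  st$g_e <- rep(g, 3)
  # integrate only (no decay, no threshold): V -> (e_rest + g e_exc)/(1 + g)
  for (k in 1:4000) st <- integrate_membrane(st, pop, 0.5, t_now = k * 0.5)
  expect_equal(st$v, (pop$e_rest + g * pop$e_exc) / (1 + g), tolerance = 1e-9)
})

test_that("integrate_membrane rejects non-finite state", {
  pop <- pp()
  st <- neuron_state(pop)
  st$v[1] <- NaN
  expect_error(integrate_membrane(st, pop, 0.5, 0.5), class = "numerical_state")
})

test_that("conductance decay is the exact exponential and a semigroup", {
  pop <- pp(params = neuron_params(tau_ge = 1, tau_gi = 2))
  st <- neuron_state(pop)
  st$g_e <- rep(1, 3)
  st$g_i <- rep(1, 3)
  one <- decay_conductances(st, pop, dt = 1)
  expect_identical(one$g_e, rep(exp(-1), 3))
  expect_identical(one$g_i, rep(exp(-0.5), 3))
  # zero stays zero
  z <- neuron_state(pop)
  expect_identical(decay_conductances(z, pop, 5)$g_e, numeric(3))
  # two half-steps equal one full step to machine precision
  half2 <- decay_conductances(decay_conductances(st, pop, 0.5), pop, 0.5)
  expect_equal(half2$g_e, one$g_e, tolerance = 1e-15)
})

test_that("threshold_and_reset fires, resets, and enforces refractoriness", {
  pop <- pp()
  st <- neuron_state(pop)
  res <- threshold_and_reset(st, pop, t_now = 1)
  expect_identical(res$fired, integer(0))
  expect_identical(res$state, st)

  st$v[2] <- pop$thresh[2]
  res <- threshold_and_reset(st, pop, t_now = 1)
  expect_identical(res$fired, 2L)
  expect_identical(res$state$v[2], pop$v_reset[2])
  expect_identical(res$state$refractory_until[2], 1 + pop$t_refrac[2])
  # cannot fire again before refractory end even at threshold
  st2 <- res$state
  st2$v[2] <- pop$thresh[2]
  res2 <- threshold_and_reset(st2, pop, t_now = 1.5)
  expect_identical(res2$fired, integer(0))
})

test_that("deliver_spikes adds weight-matrix columns additively", {
  pop <- pp(n_e = 3, n_i = 1)
  st <- neuron_state(pop)
  we <- matrix(1:12 / 12, 4, 3)
  wi <- matrix(1:4 / 4, 4, 1)
  expect_identical(deliver_spikes(st, we, wi, integer(0), integer(0)), st)
  one <- deliver_spikes(st, we, wi, 2L, integer(0))
  expect_identical(one$g_e, we[, 2])
  two <- deliver_spikes(st, we, wi, c(1L, 3L), 1L)
  expect_equal(two$g_e, we[, 1] + we[, 3])
  expect_identical(two$g_i, wi[, 1])
  expect_error(deliver_spikes(st, we, wi, 4L, integer(0)),
               class = "topology_mismatch")
})

test_that("zero input with all V at rest yields an empty spike record", {
  topo <- build_liquid(20, connectivity_spec(p_in_e = 50), n_inputs = 4,
                       seed = 3)
  empty <- spike_record(duration = 100, n_neurons = 4)
  for (eng in c("cpp", "r")) {
    out <- run_liquid(topo, empty, T = 100, engine = eng)
    expect_identical(n_spikes(out), 0L)
  }
})

test_that("run_liquid validates input dimension and step compatibility", {
  topo <- build_liquid(10, connectivity_spec(p_in_e = 50), n_inputs = 4,
                       seed = 1)
  bad <- spike_record(duration = 100, n_neurons = 5)
  expect_error(run_liquid(topo, bad, T = 100), class = "topology_mismatch")
  ok <- spike_record(duration = 100, n_neurons = 4)
  expect_error(run_liquid(topo, ok, T = 100.3), class = "invalid_params")
})

test_that("refractory invariant: no ISI below t_refrac under strong drive", {
  params <- neuron_params()
  topo <- build_liquid(25, connectivity_spec(p_in_e = 80), n_inputs = 10,
                       seed = 7)
  inp <- const_channel_input(0.5, 10, 400, seed = 11)
  out <- run_liquid(topo, inp, params = params)
  expect_gt(n_spikes(out), 50) # strong drive really does drive
  isi_e <- tapply(out$time[out$neuron <= topo$n_e],
                  out$neuron[out$neuron <= topo$n_e],
                  function(t) if (length(t) > 1) min(diff(t)) else Inf)
  isi_i <- tapply(out$time[out$neuron > topo$n_e],
                  out$neuron[out$neuron > topo$n_e],
                  function(t) if (length(t) > 1) min(diff(t)) else Inf)
  expect_true(all(isi_e >= params$t_refrac_e))
  expect_true(all(isi_i >= params$t_refrac_i))
})

test_that("identical arguments give bitwise-identical records (determinism)", {
  topo <- build_liquid(30, connectivity_spec(p_in_e = 40), n_inputs = 8,
                       seed = 5)
  inp <- const_channel_input(0.05, 8, 300, seed = 2)
  expect_identical(run_liquid(topo, inp), run_liquid(topo, inp))
})

test_that("cpp and r engines agree bitwise on random liquids", {
  for (seed in 1:3) {
    topo <- build_liquid(40, connectivity_spec(p_in_e = 60), n_inputs = 10,
                         seed = seed)
    inp <- const_channel_input(0.15, 10, 400, seed = seed + 100)
    a <- run_liquid(topo, inp, engine = "cpp")
    b <- run_liquid(topo, inp, engine = "r")
    expect_gt(n_spikes(a), 0)
    expect_identical(a, b)
  }
})

test_that("conductances stay non-negative throughout a run", {
  # run the R engine manually and inspect state (nonnegative-weight liquids)
  topo <- build_liquid(15, connectivity_spec(p_in_e = 60), n_inputs = 5,
                       seed = 9)
  pop <- population_params(neuron_params(), topo$n_e, topo$n_i)
  st <- neuron_state(pop)
  w <- rbind(topo$weights$e_e, topo$weights$e_i)
  wi <- rbind(topo$weights$i_e, topo$weights$i_i)
  for (k in 1:50) {
    st <- deliver_spikes(st, w, wi, sample(topo$n_e, 2), sample(topo$n_i, 1))
    st <- decay_conductances(st, pop, 0.5)
    st <- integrate_membrane(st, pop, 0.5, k * 0.5)
    st <- threshold_and_reset(st, pop, k * 0.5)$state
    expect_true(all(st$g_e >= 0) && all(st$g_i >= 0))
  }
})

test_that("hand-wired 3-neuron liquid matches an independent hand simulation", {
  # 2 E + 1 I, one input line wired to E1 only; E1 -> E2 and E1 -> I1.
  # Fast membranes so the two input spikes drive a spike cascade.
  params <- neuron_params(tau_mem_e = 10, tau_mem_i = 5)
  w_in <- matrix(c(8, 0), 2, 1)
  w_ee <- matrix(c(0, 6, 0, 0), 2, 2)
  w_ei <- matrix(c(6, 0), 1, 2)
  w_ie <- matrix(c(0.3, 0.3), 2, 1)
  w_ii <- matrix(0, 1, 1)
  topo <- hand_liquid(2, 1, 1, w_in, w_ee, w_ei, w_ie, w_ii)
  inp <- spike_record(c(1, 1), c(0.5, 1.0), duration = 10, n_neurons = 1)
  got <- run_liquid(topo, inp, T = 10, dt = 0.5, params = params)
  want <- naive_run_liquid(topo, inp, T = 10, dt = 0.5, params = params)
  expect_identical(got$neuron, want$neuron)
  expect_identical(got$time, want$time)
  expect_gt(n_spikes(got), 2) # the cascade reaches E2 and I1
})

test_that("run_ensemble simulates liquids independently", {
  spec <- connectivity_spec(p_in_e = 40)
  ens <- build_ensemble(40, 2, spec, n_inputs = 6, seed = 2)
  inp <- const_channel_input(0.1, 6, 300, seed = 4)
  recs <- run_ensemble(ens, inp)
  expect_s3_class(recs, "ensemble_spikes")
  expect_length(recs, 2)
  for (k in 1:2) {
    expect_identical(recs[[k]], run_liquid(ens$liquids[[k]], inp))
  }
})

test_that("spike record round-trips through CSV + sidecar", {
  topo <- build_liquid(10, connectivity_spec(p_in_e = 80), n_inputs = 4,
                       seed = 1)
  inp <- const_channel_input(0.3, 4, 200, seed = 5)
  out <- run_liquid(topo, inp)
  path <- tempfile(fileext = ".csv")
  write_spike_record(out, path)
  back <- read_spike_record(path)
  expect_equal(back$neuron, out$neuron)
  expect_equal(back$time, out$time)
  expect_identical(back$duration, out$duration)
  expect_identical(back$n_neurons, out$n_neurons)
})
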