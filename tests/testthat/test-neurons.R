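test_that("Izhikevich step matches an independent scalar reference", {
  neuron <- list(v = -65, u = 0.2 * -65,
                 izh = list(a = 0.02, b = 0.2, c = -65, d = 8), v_cut = 30)

  # subthreshold: no spikes in 1 s at I = 0
  n0 <- neuron
  spikes0 <- 0
  for (i in 1:1000) {
    st <- izh_step(n0, 0, 0.001)
    n0 <- st$neuron
    spikes0 <- spikes0 + sum(st$spiked)
  }
  expect_equal(spikes0, 0)

  # tonic firing at I = 10 reproduces the reference spike train exactly
  ref <- izh_scalar_reference(I = 10, n_ms = 1000)
  n1 <- neuron
  got <- integer(0)
  for (i in 1:1000) {
    st <- izh_step(n1, 10, 0.001)
    n1 <- st$neuron
    if (st$spiked) got <- c(got, i)
  }
  expect_gt(length(got), 5)
  expect_identical(got, ref)

  # reset rule applied when the cutoff is crossed: v -> c and u -> u + d
  # after the continuous two-half-step update (mirrored here)
  nr <- neuron
  nr$v <- 40
  v <- 40; u <- nr$u
  v <- v + 0.5 * (0.04 * v^2 + 5 * v + 140 - u)
  v <- v + 0.5 * (0.04 * v^2 + 5 * v + 140 - u)
  u_exp <- u + 0.02 * (0.2 * v - u) + 8
  st <- izh_step(nr, 0, 0.001)
  expect_true(st$spiked)
  expect_equal(st$neuron$v, -65)
  expect_equal(st$neuron$u, u_exp, tolerance = 1e-9)

  expect_error(izh_step(neuron, 0, dt = 0.002), "1 ms")
})

test_that("EPSC generation scales with pool gain and carries the configured noise", {
  pools <- motoneuron_pools(noise_sigma = 0)
  expect_equal(pools$n, 768)
  expect_equal(pools$n_pools, 6)

  expect_true(all(epsc_from_alpha(0, pools) == 0))

  # noise off: all neurons of one pool receive the same current, ordered by gain
  I <- epsc_from_alpha(10, pools)
  by_pool <- tapply(I, pools$pool_of, unique)
  expect_true(all(lengths(by_pool) == 1))
  expect_true(all(diff(unlist(by_pool)) < 0))

  # noise on: per-neuron sample variance close to sigma^2 (n = 768)
  pools_n <- motoneuron_pools(noise_sigma = 1.5)
  set.seed(42)
  In <- epsc_from_alpha(10, pools_n)
  expect_equal(var(In - I), 1.5^2, tolerance = 0.1 * 1.5^2)

  expect_error(motoneuron_pools(noise_sigma = -1), ">= 0")
  expect_error(motoneuron_pools(pool_gains = c(1, 0.5, 0.7, 0.3, 0.2, 0.1)),
               "ordered")
  expect_error(pool_step(pools, numeric(10)), "match")
})

test_that("pools recruit in size order under a slow ramp, monotone with drive", {
  cfg <- default_config()
  mk <- function() motoneuron_pools(noise_sigma = 0,
                                    pool_gains = cfg$neurons$pool_gains)
  # slow ramp 0 -> 20 mA over 3 s: first spike of pool p+1 never precedes pool p
  pools <- mk()
  first_spike <- rep(NA_real_, pools$n_pools)
  for (i in 1:3000) {
    a <- 20 * i / 3000
    st <- pool_step(pools, epsc_from_alpha(a, pools), 0)
    pools <- st$pools
    fired <- unique(pools$pool_of[st$spiked])
    for (p in fired) if (is.na(first_spike[p])) first_spike[p] <- i
  }
  seen <- which(!is.na(first_spike))
  expect_gte(length(seen), 4)
  expect_true(all(diff(first_spike[seen]) > 0))
  expect_true(all(seen == seq_along(seen)))  # no pool skipped

  # static drives: total spike count non-decreasing in alpha (noise off)
  count_at <- function(a) {
    p <- mk()
    total <- 0
    for (i in 1:500) {
      st <- pool_step(p, epsc_from_alpha(a, p), 0)
      p <- st$pools
      total <- total + sum(st$spiked)
    }
    total
  }
  counts <- vapply(c(4, 8, 12, 16, 20), count_at, numeric(1))
  expect_true(all(diff(counts) >= 0))
  # sanity rate bound: no unit can exceed one spike per model step
  expect_lt(max(counts), 768 * 500 + 1)
})

test_that("synaptic current follows the exponential kernel", {
  # silence decays to zero
  I <- 5
  for (i in 1:100) I <- synapse_current(I, 0, dt = 1e-3, tau_s = 5e-3)
  expect_lt(I, 1e-6)

  # single spike: peak = gain, integral = gain * tau (fine-step quadrature)
  dt <- 1e-5
  I <- synapse_current(0, 1, dt = dt, tau_s = 5e-3, gain = 0.4)
  expect_equal(I, 0.4)
  total <- I * dt
  for (i in 1:5000) {
    I <- synapse_current(I, 0, dt = dt, tau_s = 5e-3, gain = 0.4)
    total <- total + I * dt
  }
  expect_equal(total, 0.4 * 5e-3, tolerance = 0.01)

  # linear superposition: doubling simultaneous spikes doubles the current
  expect_equal(synapse_current(0, 6, gain = 0.4), 2 * synapse_current(0, 3, gain = 0.4))
})
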