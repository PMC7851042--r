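test_that("synthetic EMG has the drive-proportional envelope and band limit", {
  # zero drive produces a silent trace
  e0 <- synth_emg(rep(0, 1000), fs = 1000, seed = 1)
  expect_true(all(e0$samples == 0))

  # RMS scales with the drive level: same carrier, half the drive
  e_half <- synth_emg(rep(0.5, 5000), fs = 1000, seed = 7)
  e_full <- synth_emg(rep(1.0, 5000), fs = 1000, seed = 7)
  rms <- function(x) sqrt(mean(x^2))
  expect_equal(rms(e_half$samples) / rms(e_full$samples), 0.5,
               tolerance = 0.05)

  # >= 95% of spectral power inside the configured band (periodogram oracle)
  pg <- stats::spec.pgram(stats::ts(e_full$samples, frequency = 1000),
                          plot = FALSE, taper = 0)
  inband <- sum(pg$spec[pg$freq >= 30 & pg$freq <= 300]) / sum(pg$spec)
  expect_gt(inband, 0.95)

  # determinism and band validation
  expect_identical(synth_emg(rep(0.3, 500), 1000, seed = 3)$samples,
                   synth_emg(rep(0.3, 500), 1000, seed = 3)$samples)
  expect_error(synth_emg(rep(0.5, 100), fs = 1000, band = c(100, 600)),
               "Nyquist")
  expect_error(synth_emg(rep(2, 100), fs = 1000), "\\[0, 1\\]")
})

test_that("Bayesian decoder conserves mass, recovers constant drive, tracks steps", {
  st <- bayes_init()
  expect_equal(sum(st$posterior), 1, tolerance = 1e-12)

  # posterior mass conservation across many updates with varied observations
  set.seed(11)
  obs <- abs(rnorm(300, 0, 0.4))
  for (o in obs) {
    up <- bayes_update(st, o, dt = 1e-3)
    st <- up$state
    expect_lt(abs(sum(st$posterior) - 1), 1e-9)
    expect_true(all(st$posterior >= 0))
  }

  # sustained zero observation drives the MAP to the grid minimum
  st0 <- bayes_init()
  for (i in 1:200) {
    up <- bayes_update(st0, 0, dt = 1e-3)
    st0 <- up$state
  }
  expect_equal(up$map, 0)

  # constant drive 0.5: time-averaged MAP within 0.05 of the amplitude scale,
  # cross-checked against the closed-form RMS estimate of the envelope
  cfg <- default_config()
  e <- synth_emg(rep(0.5, 5000), fs = 1000, seed = 2)
  a <- decode_alpha(e, cfg$bayes)
  sigma_hat <- sqrt(mean(e$samples^2))   # maximum-likelihood envelope scale
  expect_equal(mean(a$map[1000:5000]), 0.5, tolerance = 0.05)
  expect_equal(mean(a$map[1000:5000]), sigma_hat, tolerance = 0.05)

  # a step 0.2 -> 0.8 is tracked within 100 ms; removing the jump term slows
  # the crossing
  e_step <- synth_emg(c(rep(0.2, 1000), rep(0.8, 1000)), fs = 1000, seed = 3)
  a_step <- decode_alpha(e_step, cfg$bayes)
  cross <- which(a_step$map[1001:2000] > 0.5)[1]
  expect_lt(cross, 100)
  slow <- cfg$bayes
  slow$jump <- 0
  slow$diffusion <- 1e-4
  a_slow <- decode_alpha(e_step, slow)
  cross_slow <- which(a_slow$map[1001:2000] > 0.5)[1]
  expect_true(is.na(cross_slow) || cross_slow > cross)
})

test_that("decoder output scales linearly to the 0-20 mA command range", {
  cfg <- default_config()
  e <- synth_emg(rep(0.6, 1500), fs = 1000, seed = 5)
  a <- decode_alpha(e, cfg$bayes)
  expect_true(all(a$values >= 0 & a$values <= 20))
  expect_equal(a$values, a$map * 20)

  # monotone under amplitude scaling: doubling the envelope never decreases
  # the time-averaged MAP
  e2 <- e
  e2$samples <- pmin(2 * e$samples, 1e6)
  a2 <- decode_alpha(e2, cfg$bayes)
  expect_gte(mean(a2$map[500:1500]), mean(a$map[500:1500]))

  expect_error(decode_alpha(structure(list(samples = numeric(0), fs = 1000),
                                      class = "emg_trace")),
               "empty")
})

test_that("EMG CSV round-trips", {
  e <- synth_emg(rep(0.4, 200), fs = 1000, seed = 9)
  p <- withr::local_tempfile(fileext = ".csv")
  write_emg_csv(e, p)
  e2 <- read_emg_csv(p)
  expect_equal(e2$samples, e$samples, tolerance = 1e-12)
  expect_equal(e2$fs, 1000, tolerance = 1e-6)
})
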