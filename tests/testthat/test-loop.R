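test_that("zero command leaves the hand open and the cable slack", {
  cfg <- default_config()
  cfg$loop$duration <- 0.8
  cfg$loop$record_spikes <- FALSE
  tr <- run_closed_loop(alpha_command(rep(0, 10), fs = 10 / 0.8), NULL, cfg)
  s <- tr$signals
  expect_true(all(s$aperture == 100))
  expect_true(all(s$theta == 0))
  # tension stays at the spontaneous-activity floor (< 1% of Fmax)
  expect_lt(max(s$tension), 0.01 * cfg$muscle$Fmax)
  expect_true(all(!s$contact))
})

test_that("a step command above the dead zone closes the hand; larger command closes more", {
  ap <- vapply(c(5.5, 6.5, 7.5), settled_aperture, numeric(1))
  expect_true(all(diff(ap) < 0))
  expect_true(all(ap < 95))
})

test_that("identical configuration and seed give bitwise-identical traces", {
  cfg <- default_config()
  cfg$loop$duration <- 0.5
  cfg$loop$seed <- 7
  cmd <- alpha_command(rep(6.5, 10), fs = 20)
  t1 <- run_closed_loop(cmd, NULL, cfg)
  t2 <- run_closed_loop(cmd, NULL, cfg)
  expect_identical(t1$signals, t2$signals)
  expect_identical(t1$mn_raster, t2$mn_raster)
  expect_identical(t1$ia_raster, t2$ia_raster)
})

test_that("group II afferents are computed but never enter the loop", {
  cfg <- default_config()
  cfg$loop$duration <- 0.6
  cfg$loop$seed <- 2
  cmd <- alpha_command(rep(6.5, 10), fs = 20)
  tr <- run_closed_loop(cmd, NULL, cfg)
  # II rates are recorded and non-negative...
  expect_true(all(tr$signals$ii_rate >= 0))
  expect_gt(max(tr$signals$ii_rate), 0)
  # ...and zeroing them (II encoding disabled) changes nothing in the loop
  cfg2 <- cfg
  cfg2$loop$feed_ii <- FALSE   # explicit default
  tr2 <- run_closed_loop(cmd, NULL, cfg2)
  expect_identical(tr$signals$tension, tr2$signals$tension)
  expect_identical(tr$signals$aperture, tr2$signals$aperture)
})

test_that("an imposed stretch is resisted more with Ia feedback than without", {
  p_off <- run_pull_test(ia_gain = 0)
  p_on <- run_pull_test(ia_gain = 25)
  # the reflex limits the yield of the cable under the same external pull
  expect_lt(p_on$stretch_cm, p_off$stretch_cm)
  # via Ia-driven recruitment (silent without feedback)
  expect_gt(p_on$activation, p_off$activation + 0.005)
  expect_gt(p_on$peak_ia, 20)
})

test_that("model-step refinement leaves the settled aperture unchanged (deterministic loop)", {
  cfg <- default_config(neurons = list(noise_sigma = 0),
                        spindle = list(encoder = "threshold"))
  cfg$loop$duration <- 1.5
  cfg$loop$seed <- 1
  cfg$loop$record_spikes <- FALSE
  cmd <- alpha_command(rep(10, 10), fs = 10 / 1.5)
  a1 <- run_closed_loop(cmd, NULL, cfg)$signals
  cfg$loop$dt_model <- 5e-4
  a2 <- run_closed_loop(cmd, NULL, cfg)$signals
  ap1 <- mean(a1$aperture[a1$t > 1.2])
  ap2 <- mean(a2$aperture[a2$t > 1.2])
  expect_lt(abs(ap1 - ap2), 2)  # aperture percentage points
})

test_that("the loop runs faster than real time at default sizes", {
  cfg <- default_config()
  cfg$loop$record_spikes <- FALSE
  wall <- system.time(
    run_closed_loop(alpha_command(rep(6.5, 10), fs = 10), NULL, cfg)
  )["elapsed"]
  expect_lt(wall, 10)  # 1 s of simulated loop
})

test_that("event detection orders the beam-press timeline and guards its inputs", {
  cfg <- default_config()
  cfg$loop$seed <- 4
  r <- exp_beam_press(6.5, 1, cfg, duration = 1.3, onset_s = 0.1)
  ev <- r$events
  expect_true(ev$t1 < ev$t2 && ev$t2 < ev$t3 && ev$t3 < ev$t4 && ev$t4 < ev$t5)
  expect_false(r$broken)

  # no contact: t3..t5 are absent, not zero
  cfg$loop$duration <- 1
  tr <- run_closed_loop(alpha_command(rep(5.5, 10), fs = 10), NULL, cfg)
  ev2 <- detect_events(tr, cfg$events)
  expect_false(is.na(ev2$t1))
  expect_true(is.na(ev2$t3) && is.na(ev2$t4) && is.na(ev2$t5))

  # zero-width thresholds are rejected
  bad <- cfg$events
  bad$tension_frac <- 0
  expect_error(detect_events(tr, bad), "nonzero width")

  # shrinking the hover gap shortens the free-travel phase t3 - t2
  cfg$loop$seed <- 4
  r0 <- exp_beam_press(6.5, hover_cm = 0.4, cfg, duration = 1.3,
                       onset_s = 0.1)
  expect_lt(r0$events$t3 - r0$events$t2, ev$t3 - ev$t2)
})

test_that("trace CSV export round-trips the signal table", {
  cfg <- default_config()
  cfg$loop$duration <- 0.2
  cfg$loop$record_spikes <- FALSE
  tr <- run_closed_loop(alpha_command(rep(6, 5), fs = 25), NULL, cfg)
  p <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, p)
  back <- utils::read.csv(p)
  expect_equal(nrow(back), nrow(tr$signals))
  expect_equal(back$tension, tr$signals$tension, tolerance = 1e-9)
})
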