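test_that("force-length law reproduces the printed piecewise branches", {
  expect_equal(fl_term(0.4), 0)
  expect_equal(fl_term(1.0), -1.67 + 2.672, tolerance = 1e-12)   # 1.002
  expect_equal(fl_term(0.999), -4.095 * 0.999^2 + 8.190 * 0.999 - 3.071)
  expect_equal(fl_term(1.6), 0, tolerance = 1e-12)
  expect_equal(fl_term(1.7), 0)
  # the printed branches do not meet exactly at L = 1; the discrepancy is
  # small and is kept as published, not re-fitted
  gap <- abs(fl_term(1 - 1e-9) - fl_term(1 + 1e-9))
  expect_lt(gap, 0.05)
  expect_gt(gap, 0.01)
  expect_error(fl_term(-0.1), ">= 0")
})

test_that("force-velocity law is linear with the 1.8 F0 cap", {
  expect_equal(fv_term(0, F0 = 1, F1 = 1.8, Vm = 1), 1)
  expect_equal(fv_term(1, F0 = 1, F1 = 1.8, Vm = 1), 1.8)
  expect_equal(fv_term(10, F0 = 1, F1 = 1.8, Vm = 1), 1.8)  # capped
  expect_equal(fv_term(0.5, F0 = 2, F1 = 3, Vm = 2), 2.25)
  expect_equal(fv_term(-100, F0 = 1, F1 = 1.8, Vm = 1), 0)  # shortening guard
  expect_error(fv_term(1, Vm = 0), "nonzero")
})

test_that("twitch activation follows first-order dynamics with quantal inputs", {
  # pure decay: A(30 ms) = exp(-1) from A(0) = 1
  A <- 1
  for (i in 1:30) A <- activation_step(A, 0, dt = 1e-3, tau_twitch = 0.03,
                                       quantal = 1e-3)
  expect_equal(A, exp(-1), tolerance = 1e-9)

  # single spike from rest peaks at the quantal increment then decays
  A1 <- activation_step(0, 1, dt = 1e-3, quantal = 2.5e-3)
  expect_equal(A1, 2.5e-3)
  expect_lt(activation_step(A1, 0, dt = 1e-3), A1)

  # periodic spikes at 100 Hz plateau at q / (1 - exp(-0.01/0.03))
  q <- 1e-3
  A <- 0
  for (i in 1:3000)
    A <- activation_step(A, as.numeric(i %% 10 == 0), dt = 1e-3,
                         tau_twitch = 0.03, quantal = q)
  expect_equal(A, q / (1 - exp(-0.01 / 0.03)), tolerance = 1e-6)

  expect_error(activation_step(0, -1), ">= 0")
})

test_that("static muscle force combines active, passive and damping terms", {
  p <- default_config()$muscle
  expect_equal(muscle_force(0, 1, 0, p), 0)
  expect_gt(muscle_force(0, 1.1, 0, p), 0)          # passive stretch only
  # outside FL support the active term vanishes; passive unchanged
  expect_equal(muscle_force(0.5, 0.4, 0, p), muscle_force(0, 0.4, 0, p))
  # tension is never negative (cables pull only)
  expect_equal(muscle_force(0.2, 0.9, -50, p), 0)
  # isometric force increases with activation on the FL support
  f <- muscle_force(c(0.1, 0.2, 0.4), 0.9, 0, p)
  expect_true(all(diff(f) > 0))
})

test_that("dynamic muscle responds elastically to imposed stretch and relaxes", {
  p <- default_config()$muscle
  st <- muscle_state_init(p)
  # quiescent muscle: cable shortening leaves the series element slack
  st2 <- muscle_dynamics_step(st, 0, -0.5, 1e-3, p)
  expect_equal(st2$tension, 0)
  # imposed MTU stretch at fixed activation raises tension immediately
  st_a <- muscle_state_init(p)
  for (i in 1:500) st_a <- muscle_dynamics_step(st_a, 0.2, 0, 1e-3, p)
  t_iso <- st_a$tension
  st_b <- st_a
  for (i in 1:300) st_b <- muscle_dynamics_step(st_b, 0.2, 0.25, 1e-3, p)
  expect_gt(st_b$tension, t_iso)
  # and with zero activation the stretched muscle sheds its active tension
  st_c <- st_b
  for (i in 1:2000) st_c <- muscle_dynamics_step(st_c, 0, 0.25, 1e-3, p)
  expect_lt(st_c$tension, st_b$tension)
})

test_that("isometric tension is monotone in mean firing rate", {
  # drive the twitch + dynamic muscle with regular spike trains of
  # increasing rate; settled tension must not decrease
  p <- default_config()$muscle
  settle <- function(rate_hz) {
    A <- 0
    st <- muscle_state_init(p)
    period <- round(1000 / rate_hz)
    for (i in 1:1500) {
      A <- activation_step(A, as.numeric(i %% period == 0) * 40, dt = 1e-3,
                           quantal = p$quantal)
      st <- muscle_dynamics_step(st, A, 0, 1e-3, p)
    }
    st$tension
  }
  tensions <- vapply(c(20, 40, 80, 160), settle, numeric(1))
  expect_true(all(diff(tensions) >= 0))
})
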