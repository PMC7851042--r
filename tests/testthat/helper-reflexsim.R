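# shared helpers: short, seeded closed-loop runs for the slower tests

settled_aperture <- function(alpha_mA, cfg = default_config(), duration = 2,
                             seed = 1) {
  cfg$loop$duration <- duration
  cfg$loop$seed <- seed
  cfg$loop$record_spikes <- FALSE
  cmd <- alpha_command(rep(alpha_mA, 10), fs = 10 / duration,
                       scale_mA = cfg$alpha$scale_mA)
  tr <- run_closed_loop(cmd, NULL, cfg)
  s <- tr$signals
  mean(s$aperture[s$t > duration - 0.3])
}

run_pull_test <- function(ia_gain, seed = 3, force_n = 6) {
  cfg <- default_config()
  cfg$loop$duration <- 1.5
  cfg$loop$seed <- seed
  cfg$loop$ia_gain <- ia_gain
  cfg$loop$record_spikes <- FALSE
  cfg$loop$external_pull <- list(start_s = 0.5, end_s = 1.5, force_n = force_n)
  cmd <- alpha_command(rep(0, 10), fs = 10 / 1.5)
  tr <- run_closed_loop(cmd, NULL, cfg)
  s <- tr$signals
  list(stretch_cm = max(s$lmtu) - cfg$geometry$lmtu0_cm,
       peak_ia = max(s$ia_rate),
       activation = mean(s$activation[s$t > 0.7]))
}

# independent scalar integration of one Izhikevich neuron (reference for the
# vectorized implementation)
izh_scalar_reference <- function(I, n_ms, a = 0.02, b = 0.2, c = -65, d = 8,
                                 v0 = -65, u0 = b * -65) {
  v <- v0; u <- u0
  spikes <- integer(0)
  for (i in seq_len(n_ms)) {
    v <- v + 0.5 * (0.04 * v^2 + 5 * v + 140 - u + I)
    v <- v + 0.5 * (0.04 * v^2 + 5 * v + 140 - u + I)
    u <- u + a * (b * v - u)
    if (v >= 30) {
      spikes <- c(spikes, i)
      v <- c
      u <- u + d
    }
  }
  spikes
}
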