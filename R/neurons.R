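#' Create a set of size-ranked motoneuron pools
#'
#' Builds the default population of 768 Izhikevich regular-spiking neurons in
#' 6 pools of 128. Recruitment order follows Henneman's size principle: each
#' pool scales the shared command current by its gain, and the gains descend
#' geometrically (default 1.0 down to 0.3), so low-gain (large) pools need a
#' larger command before they reach rheobase.
#'
#' @param n_pools number of pools.
#' @param pool_size neurons per pool.
#' @param k command-to-current scale: current delivered to a gain-1 neuron at
#'   full normalized drive.
#' @param noise_sigma SD of the per-neuron Gaussian EPSC noise that
#'   desynchronizes otherwise identical neurons.
#' @param pool_gains optional explicit vector of pool gains (strictly
#'   monotone); `NULL` gives the geometric ladder.
#' @param izh list of Izhikevich parameters `a`, `b`, `c`, `d`.
#' @param v_cut spike cutoff (mV).
#' @return a `motoneuron_pools` object holding per-neuron state vectors.
#' @export
motoneuron_pools <- function(n_pools = 6, pool_size = 128, k = 40,
                             noise_sigma = 2, pool_gains = NULL,
                             izh = list(a = 0.02, b = 0.2, c = -65, d = 8),
                             v_cut = 30) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (is.null(pool_gains))
    pool_gains <- 0.3^((seq_len(n_pools) - 1) / max(1, n_pools - 1)) # 1.0 .. 0.3
  if (length(pool_gains) != n_pools)
    stop("pool_gains length must equal n_pools")
  d <- diff(pool_gains)
  if (!(all(d > 0) || all(d < 0)))
    stop("pool_gains must be strictly ordered")
  n <- n_pools * pool_size
  structure(
    list(n = n, n_pools = n_pools, pool_size = pool_size,
         pool_of = rep(seq_len(n_pools), each = pool_size),
         pool_gains = pool_gains,
         gain = rep(pool_gains, each = pool_size),
         k = k, noise_sigma = noise_sigma,
         izh = izh, v_cut = v_cut,
         # membrane and adaptation states staggered over the adapted firing
         # band so a command step recruits the population progressively
         # instead of as one artificial synchronized volley
         v = izh$c + 15 * (seq_len(n) %% 97) / 97,
         u = izh$b * izh$c + izh$d * (2 + 3 * (seq_len(n) %% 89) / 89)),
    class = "motoneuron_pools"
  )
}

#' Advance Izhikevich neurons one step
#'
#' Two-variable quadratic model, forward Euler with the conventional pair of
#' half-steps on the membrane equation for stability, and the standard reset
#' (`v -> c`, `u -> u + d`) on crossing the cutoff. Operates on vectors, so a
#' single neuron is the length-1 case.
#'
#' @param neuron list with numeric `v`, `u` and parameters `izh`
#'   (`a`,`b`,`c`,`d`) and `v_cut`, e.g. a `motoneuron_pools` object.
#' @param I input current, scalar or per-neuron vector (model units; the
#'   model's native time base is ms).
#' @param dt step (s); must be <= 1 ms for stability.
#' @return list with the updated `neuron` and logical vector `spiked`.
#' @export
izh_step <- function(neuron, I, dt = 0.001) {
  if (dt > 0.001 + 1e-12) stop("izh_step requires dt <= 1 ms (got ", dt, " s)")
  dt_ms <- dt * 1000
  v <- neuron$v; u <- neuron$u
  p <- neuron$izh
  h <- dt_ms / 2
  v <- v + h * (0.04 * v^2 + 5 * v + 140 - u + I)
  v <- v + h * (0.04 * v^2 + 5 * v + 140 - u + I)
  u <- u + dt_ms * p$a * (p$b * v - u)
  if (any(!is.finite(v)) || any(!is.finite(u)))
    stop("Izhikevich state diverged (non-finite) at dt = ", dt,
         " s; reduce the step")
  spiked <- v >= neuron$v_cut
  if (any(spiked)) {
    v[spiked] <- p$c
    u[spiked] <- u[spiked] + p$d
  }
  neuron$v <- v; neuron$u <- u
  list(neuron = neuron, spiked = spiked)
}

#' Per-neuron EPSC from the alpha motor command
#'
#' Each neuron receives `k * alpha_norm * pool_gain` plus independent
#' Gaussian noise. `alpha` is given in mA of command and normalized by
#' `scale_mA` before scaling, matching the convention that the descending
#' drive is unit-less in \[0, 1\].
#'
#' @param alpha command level (mA), >= 0.
#' @param pools a `motoneuron_pools` object.
#' @param scale_mA full-scale command (mA).
#' @return numeric vector of per-neuron currents (model units). Draws from
#'   the current R RNG stream.
#' @export
epsc_from_alpha <- function(alpha, pools, scale_mA = 20) {
  if (alpha < 0) stop("alpha must be >= 0")
  base <- pools$k * (alpha / scale_mA) * pools$gain
  if (pools$noise_sigma > 0)
    base <- base + stats::rnorm(pools$n, 0, pools$noise_sigma)
  base
}

#' Advance all motoneuron pools one model step
#'
#' Adds the Ia feedback current (shared, excitatory, monosynaptic) to the
#' per-neuron EPSC and steps every neuron.
#'
#' @param pools a `motoneuron_pools` object.
#' @param epsc per-neuron current vector from [epsc_from_alpha()].
#' @param ia_current scalar Ia synaptic current added to every neuron.
#' @param dt step (s).
#' @return list with updated `pools` and logical `spiked` per neuron.
#' @export
pool_step <- function(pools, epsc, ia_current = 0, dt = 0.001) {
  if (length(epsc) != pools$n)
    stop("epsc length ", length(epsc), " does not match population ", pools$n)
  st <- izh_step(pools, epsc + ia_current, dt)
  list(pools = st$neuron, spiked = st$spiked)
}

#' Exponentially decaying synaptic current from afferent spikes
#'
#' Stateful single-exponential kernel: every spike adds `gain` to the
#' current, which decays with time constant `tau_s`. The integral of the
#' response to one spike is `gain * tau_s`.
#'
#' @param state previous current (scalar; start at 0).
#' @param n_spikes number of afferent spikes arriving this step.
#' @param dt step (s).
#' @param tau_s decay time constant (s).
#' @param gain current increment per spike.
#' @return updated current (scalar).
#' @export
synapse_current <- function(state, n_spikes, dt = 0.001, tau_s = 0.005,
                            gain = 0.5) {
  state * exp(-dt / tau_s) + gain * n_spikes
}

#' Collect a spike raster data frame
#'
#' @param spiked logical per-unit vector for one step.
#' @param t time of the step (s).
#' @return data.frame with `unit_id` and `t` (empty if no spikes).
#' @export
raster_slice <- function(spiked, t) {
  id <- which(spiked)
  data.frame(unit_id = id, t = rep(t, length(id)))
}

#' Write a spike raster as CSV (`unit_id,t_s`)
#'
#' @param raster data.frame with columns `unit_id`, `t`.
#' @param path file path.
#' @export
write_raster_csv <- function(raster, path) {
  utils::write.csv(data.frame(unit_id = raster$unit_id, t_s = raster$t),
                   path, row.names = FALSE)
  invisible(path)
}
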