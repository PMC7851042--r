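#' Force-length scaling of the active muscle force
#'
#' Three-branch piecewise quadratic in normalized contractile-element length
#' (units of optimal length): zero outside \[0.5, 1.6\],
#' `-4.095 L^2 + 8.190 L - 3.071` on \[0.5, 1) and `-1.67 L^2 + 2.672 L` on
#' \[1, 1.6\]. The two branches meet near (not exactly at) 1; the printed
#' coefficients are kept as published and the small discontinuity (~0.022)
#' is tolerated rather than re-fit.
#'
#' @param L normalized CE length, >= 0 (vectorized).
#' @return F_L, dimensionless.
#' @export
#' @examples
#' fl_term(1)    # 1.024
#' fl_term(1.6)  # 0
fl_term <- function(L) {
  if (any(L < 0)) stop("L must be >= 0")
  out <- numeric(length(L))
  lo <- L >= 0.5 & L < 1
  hi <- L >= 1 & L <= 1.6
  out[lo] <- -4.095 * L[lo]^2 + 8.190 * L[lo] - 3.071
  out[hi] <- -1.67 * L[hi]^2 + 2.672 * L[hi]
  out
}

#' Force-velocity scaling of the active muscle force
#'
#' Linear law `(F1 - F0)/Vm * V + F0` capped at `1.8 * F0`; lengthening
#' (`V > 0`) raises force above the isometric intercept `F0`, shortening
#' lowers it. Clamped below at 0 as a numerical guard for fast shortening.
#'
#' @param V CE velocity (optimal lengths per second; positive = lengthening).
#' @param F0 isometric intercept.
#' @param F1 value at `V = Vm`.
#' @param Vm reference velocity (nonzero).
#' @return F_V, dimensionless.
#' @export
fv_term <- function(V, F0 = 1, F1 = 1.8, Vm = 1) {
  if (Vm == 0) stop("Vm must be nonzero")
  pmax(0, pmin((F1 - F0) / Vm * V + F0, 1.8 * F0))
}

#' Advance the spike-driven twitch activation
#'
#' First-order twitch dynamics: activation decays exponentially with the
#' 30 ms twitch time constant and each motoneuron spike adds a quantal
#' increment, weighted by the rank of its source pool so that
#' later-recruited (larger) units contribute more force.
#'
#' @param A current activation (>= 0).
#' @param spikes weighted spike count this step (sum of pool weights of the
#'   neurons that fired; see [spike_weight()]).
#' @param dt step (s).
#' @param tau_twitch twitch time constant (s).
#' @param quantal activation increment per unit-weight spike.
#' @return updated activation.
#' @export
activation_step <- function(A, spikes, dt = 0.001, tau_twitch = 0.03,
                            quantal = 2.4e-4) {
  if (spikes < 0) stop("spike count must be >= 0")
  A * exp(-dt / tau_twitch) + quantal * spikes
}

#' Pool weighting of motoneuron spikes
#'
#' Quantal force contribution proportional to pool rank (1..n_pools),
#' normalized to mean 1 so the total drive scale is independent of the
#' number of pools.
#'
#' @param pools a `motoneuron_pools` object.
#' @return per-neuron weight vector.
#' @export
spike_weight <- function(pools) {
  w <- pools$pool_of
  w / mean(seq_len(pools$n_pools))
}

#' Muscle tension from activation, length and velocity
#'
#' Active force `Fmax * A * F_L(L) * F_V(V)` combined with the parallel
#' elastic element (engaged beyond optimal length) and contractile damping;
#' the series element transmits the tension to the cable unchanged, and the
#' result is clamped at zero because a cable can only pull.
#'
#' @param A activation (dimensionless, >= 0).
#' @param L normalized CE length.
#' @param V normalized CE velocity (lengths/s, positive = lengthening).
#' @param params muscle parameter list (see [default_config()]'s `muscle`
#'   block): uses `Fmax`, `F0`, `F1`, `Vm`, `Kpe`, `b_damp`.
#' @return tension (N), >= 0.
#' @export
muscle_force <- function(A, L, V, params = default_config()$muscle) {
  active <- A * fl_term(L) * fv_term(V, params$F0, params$F1, params$Vm)
  passive <- params$Kpe * pmax(L - 1, 0)
  damp <- params$b_damp * V
  pmax(0, params$Fmax * (active + passive + damp))
}

#' Initialize the dynamic muscle state
#'
#' The loop-level muscle keeps an internal contractile-element length and
#' derives cable tension from the stretch of the series-elastic element, so
#' that force depends on the muscle's history of length and velocity (an
#' imposed stretch raises tension through the series spring until the CE
#' yields).
#'
#' @param params muscle parameter list.
#' @return a `muscle_state` list: `l_ce` (normalized CE length), `v_ce`
#'   (lengths/s), `tension` (N).
#' @export
muscle_state_init <- function(params = default_config()$muscle) {
  structure(list(l_ce = 1, v_ce = 0, tension = 0), class = "muscle_state")
}

#' Advance the dynamic muscle one step
#'
#' Series-elastic tension `Kse_n * se_ext` drives the contractile element,
#' whose velocity follows from the force balance between the series tension
#' and the CE force (active force-length/force-velocity law, parallel
#' elastic, damping). The force-velocity law is linear in velocity, so the
#' balance has a closed-form solution and the update is unconditionally
#' stable.
#'
#' @param st a `muscle_state`.
#' @param A activation.
#' @param dlmtu_cm change of MTU (cable) length since the start, cm
#'   (negative when the winder coils cable in).
#' @param dt step (s).
#' @param params muscle parameter list; uses `Kse_n_per_cm`, `b_n_s_per_cm`,
#'   `Fmax`, `F0`, `F1`, `Vm`, `Kpe`, `lce_opt_cm`.
#' @return updated `muscle_state` (tension clamped at zero: cables pull
#'   only).
#' @export
muscle_dynamics_step <- function(st, A, dlmtu_cm, dt,
                                 params = default_config()$muscle) {
  lo <- params$lce_opt_cm
  se_ext <- dlmtu_cm + (1 - st$l_ce) * lo      # series stretch, cm
  t_se <- params$Kse_n_per_cm * se_ext
  if (t_se < 0) t_se <- 0
  fl <- fl_term(st$l_ce)
  s_fv <- (params$F1 - params$F0) / params$Vm
  pe <- params$Kpe * max(st$l_ce - 1, 0)
  # b*V + Fmax*A*FL*(F0 + s*V) + pe_force = t_se  (V in CE lengths/s)
  b_cm <- params$b_n_s_per_cm * lo             # damping per normalized vel
  denom <- b_cm + params$Fmax * A * fl * s_fv
  v <- (t_se - params$Fmax * (A * fl * params$F0 + pe)) / max(denom, 1e-6)
  if (params$F0 + s_fv * v < 0)   # beyond maximal shortening: active force 0
    v <- (t_se - params$Fmax * pe) / b_cm
  st$l_ce <- st$l_ce + dt * v
  if (st$l_ce < 0.1) st$l_ce <- 0.1            # hard floor, never reached
  st$v_ce <- v
  st$tension <- t_se
  st
}
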