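#' Load the intrafusal fiber constants
#'
#' Constants of the bag1/bag2/chain intrafusal model (tensions in the model's
#' internal force units, lengths in units of the muscle resting length) are
#' stored as a plain CSV shipped with the package rather than hard-coded.
#'
#' @return data.frame, one row per fiber.
#' @export
spindle_params <- function() {
  path <- system.file("extdata", "spindle_params.csv", package = "reflexsim")
  if (path == "") path <- file.path("inst", "extdata", "spindle_params.csv")
  utils::read.csv(path)
}

#' Initialize the spindle state at mechanical equilibrium
#'
#' Each intrafusal fiber is a sensory-region spring (stiffness `K_SR`) in
#' series with a polar region carrying the fusimotor-dependent contractile
#' machinery; the state per fiber is the sensory-region tension, its rate of
#' change, and the low-pass fusimotor activation. Starting at the static
#' equilibrium for the given length avoids an artificial onset transient.
#'
#' @param L0 initial normalized CE length (resting length = 1).
#' @param gamma_dyn,gamma_sta fusimotor drives (imp/s), constants.
#' @return a `spindle_state` list.
#' @export
spindle_init <- function(L0 = 1, gamma_dyn = 0, gamma_sta = 0) {
  par <- spindle_params()
  f <- vapply(seq_len(nrow(par)), function(i) {
    g <- if (par$fiber[i] == "bag1") gamma_dyn else gamma_sta
    g^par$p[i] / (g^par$p[i] + par$freq[i]^par$p[i])
  }, numeric(1))
  T0 <- vapply(seq_len(nrow(par)), function(i) {
    p <- par[i, ]
    gam <- p$Gamma1 * f[i] + p$Gamma2 * f[i]
    (p$K_PR * (L0 - p$L0_SR - p$L0_PR) + gam) / (1 + p$K_PR / p$K_SR)
  }, numeric(1))
  structure(
    list(par = par, T = T0, dT = rep(0, nrow(par)), f = f,
         gamma_dyn = gamma_dyn, gamma_sta = gamma_sta,
         L_prev = L0, V_prev = 0),
    class = "spindle_state"
  )
}

#' Advance the muscle spindle one step
#'
#' Integrates the second-order sensory-region tension dynamics of the three
#' intrafusal fibers (semi-implicit Euler, which is stable for the lightly
#' damped tension oscillator at 1 ms steps), then reads out the primary (Ia)
#' and secondary (II) afferent rates. Ia combines the bag1 ending with the
#' (bag2 + chain) ending through the standard partial-occlusion rule; II
#' stems from bag2 and chain secondary endings only. Rates are clamped at
#' zero.
#'
#' @param state a `spindle_state`.
#' @param Lce_norm CE length normalized to the resting length (> 0).
#' @param dt step (s), <= 1 ms.
#' @param V optional CE velocity (lengths/s); finite-differenced from the
#'   previous call when missing.
#' @return list with updated `state`, `ia_rate` and `ii_rate` (imp/s).
#' @export
spindle_step <- function(state, Lce_norm, dt = 0.001, V = NULL) {
  if (Lce_norm <= 0) stop("Lce_norm must be > 0")
  if (dt > 0.001 + 1e-12) stop("spindle_step requires dt <= 1 ms")
  par <- state$par
  L <- Lce_norm
  if (is.null(V)) V <- (L - state$L_prev) / dt
  Acc <- (V - state$V_prev) / dt
  occl <- 0.156
  is_b1 <- par$fiber == "bag1"
  g <- ifelse(is_b1, state$gamma_dyn, state$gamma_sta)
  f_inf <- g^par$p / (g^par$p + par$freq^par$p)
  f <- ifelse(par$tau > 1e-3,
              state$f + dt * (f_inf - state$f) / par$tau, f_inf)
  beta <- par$beta0 + par$beta1 * f + par$beta2 * f
  gam <- par$Gamma1 * f + par$Gamma2 * f
  Tn <- state$T; dTn <- state$dT
  # the sensory-region tension oscillator is fast (sqrt(K_SR/M) ~ 230 rad/s)
  # and the polar friction term is stiff near zero velocity: sub-step it
  n_sub <- 4L
  h <- dt / n_sub
  v0 <- 0.01  # velocity regularization: linear core below v0 lengths/s
              # avoids chatter of the fractional-power damping at rest
  for (k in seq_len(n_sub)) {
    vpol <- V - dTn / par$K_SR        # polar-region velocity
    C <- ifelse(vpol >= 0, par$C_L, par$C_S)
    vpow <- ifelse(abs(vpol) > v0, sign(vpol) * abs(vpol)^par$a,
                   vpol * v0^(par$a - 1))
    fric <- C * beta * vpow *
      (L - par$L0_SR - Tn / par$K_SR - par$R)
    elast <- par$K_PR * (L - par$L0_SR - Tn / par$K_SR - par$L0_PR)
    ddT <- (par$K_SR / par$M) * (fric + elast + par$M * Acc + gam - Tn)
    dTn <- dTn + h * ddT
    Tn <- Tn + h * dTn                # semi-implicit: uses updated dT
  }
  if (any(!is.finite(Tn)) || any(!is.finite(dTn)))
    stop("spindle state diverged (non-finite); reduce dt")
  state$T <- Tn; state$dT <- dTn; state$f <- f
  state$L_prev <- L
  state$V_prev <- V
  stretch <- state$T / par$K_SR - (par$L_N_SR - par$L0_SR)
  pri <- pmax(0, par$G_pri * stretch)
  b1 <- pri[par$fiber == "bag1"]
  b2c <- sum(pri[par$fiber != "bag1"])
  ia <- max(b1, b2c) + occl * min(b1, b2c)
  sec_rows <- par$fiber != "bag1"
  sec <- par$G_sec[sec_rows] *
    (par$X[sec_rows] * par$L_sec[sec_rows] / par$L0_SR[sec_rows] *
       stretch[sec_rows] +
     (1 - par$X[sec_rows]) * par$L_sec[sec_rows] / par$L0_PR[sec_rows] *
       (L - state$T[sec_rows] / par$K_SR[sec_rows] -
          par$L0_SR[sec_rows] - par$L_N_PR[sec_rows]))
  ii <- max(0, sum(pmax(0, sec)))
  list(state = state, ia_rate = max(0, ia), ii_rate = ii)
}

#' Encode an afferent rate into a population spike raster
#'
#' Each of `n_units` afferents emits spikes over the window `dt` either as an
#' independent Poisson process with intensity `ia_rate` (default) or with a
#' deterministic integrate-to-threshold encoder whose per-unit phase offsets
#' jitter the spike times.
#'
#' @param ia_rate afferent firing rate (imp/s), >= 0.
#' @param n_units population size.
#' @param dt window length (s).
#' @param encoder `"poisson"` or `"threshold"`.
#' @param phase integrator state for the threshold encoder: numeric vector of
#'   length `n_units` (returned in the `phase` field; pass it back in).
#' @return list with `raster` (data.frame `unit_id`, `t` with times inside
#'   \[0, dt\)) and `phase`. Poisson draws use the current R RNG stream.
#' @export
afferent_spikes <- function(ia_rate, n_units = 128, dt = 0.01,
                            encoder = "poisson", phase = NULL) {
  if (ia_rate < 0) stop("ia_rate must be >= 0")
  if (is.null(phase)) phase <- seq(0, 1 - 1 / n_units, length.out = n_units)
  if (encoder == "poisson") {
    counts <- stats::rpois(n_units, ia_rate * dt)
    id <- rep(seq_len(n_units), counts)
    t <- stats::runif(length(id), 0, dt)
  } else if (encoder == "threshold") {
    phase <- phase + ia_rate * dt
    counts <- floor(phase)
    phase <- phase - counts
    id <- rep(seq_len(n_units), counts)
    t <- rep(dt / 2, length(id))  # centered, deterministic
  } else stop("unknown encoder: ", encoder)
  list(raster = data.frame(unit_id = id, t = t), phase = phase)
}
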