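#' Run the closed reflex loop
#'
#' Wires every stage of the controller at two rates. Per model step
#' (default 1 kHz): Ia synaptic current decay/injection, motoneuron pool
#' step, twitch activation, muscle tension. Per plant step (default 100 Hz):
#' motor/cable/object update, reconstruction of the musculotendinous and
#' contractile-element lengths from motor rotation, spindle update
#' (sub-stepped at the model rate for numerical stability) and afferent
#' spike encoding for the next window.
#'
#' All randomness (EPSC noise, Poisson afferents) is drawn from the R RNG
#' seeded with `cfg$loop$seed` at entry, so identical configurations give
#' bitwise-identical traces.
#'
#' @param command an `alpha_command` (mA trace), an `emg_trace` (decoded
#'   first with the `cfg$bayes` parameters), or a policy function
#'   `function(t, state)` returning the command (mA) for the next plant
#'   window; `state` carries `tip_force`, `aperture`, `contact`, `broken`.
#' @param obj an [object_model()]; `NULL` uses `cfg$object`.
#' @param cfg configuration list, see [default_config()]. Optional
#'   `cfg$loop$external_pull = list(start_s=, end_s=, force_n=)` applies an
#'   external cable pull (imposed stretch). `cfg$loop$record_spikes = FALSE`
#'   drops the rasters for speed. `cfg$loop$feed_ii = TRUE` would add the
#'   Group II rate to the fed-back rate; it defaults to FALSE (Ia-only loop)
#'   and II is always computed and recorded.
#' @return a `loop_trace`: list with `signals` (data.frame on the model time
#'   base), `mn_raster`, `ia_raster`, and the configuration used.
#' @export
run_closed_loop <- function(command, obj = NULL, cfg = default_config()) {
  validate_config(cfg)
  if (inherits(command, "emg_trace"))
    command <- decode_alpha(command, cfg$bayes)
  policy <- NULL
  if (is.function(command)) {
    policy <- command
  } else if (!inherits(command, "alpha_command")) {
    stop("command must be an alpha_command, emg_trace or policy function")
  }
  if (is.null(obj)) obj <- do.call(object_model, cfg$object)

  set.seed(cfg$loop$seed)
  dt <- cfg$loop$dt_model
  dtp <- cfg$loop$dt_plant
  m <- as.integer(round(dtp / dt))
  n <- as.integer(round(cfg$loop$duration / dt))
  geom <- cable_geometry(cfg$geometry$lmtu0_cm, cfg$geometry$r_cm,
                         cfg$geometry$lrest_cm)
  mus <- cfg$muscle
  record_spikes <- !isFALSE(cfg$loop$record_spikes)
  feed_ii <- isTRUE(cfg$loop$feed_ii)
  pull <- cfg$loop$external_pull

  # EPSC noise is specified at the 1 kHz reference rate; rescale so its
  # spectral density is invariant under model-step refinement
  sigma_eff <- cfg$neurons$noise_sigma * sqrt(0.001 / dt)
  pools <- motoneuron_pools(cfg$neurons$n_pools, cfg$neurons$pool_size,
                            cfg$neurons$k, sigma_eff,
                            cfg$neurons$pool_gains, cfg$neurons$izh,
                            cfg$neurons$v_cut)
  w <- spike_weight(pools)
  sp <- spindle_init(1, cfg$spindle$gamma_dyn, cfg$spindle$gamma_sta)
  phase <- NULL

  # command resampled to the model time base
  if (is.null(policy)) {
    idx <- pmin(length(command$values),
                pmax(1L, ceiling(seq_len(n) * dt * command$fs)))
    alpha_t <- command$values[idx]
  } else {
    alpha_curr <- policy(0, list(tip_force = 0, aperture = 100,
                                 contact = FALSE, broken = FALSE))
  }

  # loop state
  I_syn <- 0; A <- 0; Tn <- 0
  motor <- motor_init()
  mu <- muscle_state_init(mus)    # dynamic muscle (internal CE + series spring)
  lmtu <- geom$lmtu0_cm
  dlce_cm <- 0                    # reconstructed CE displacement (cm)
  v_sp <- 0                       # reconstructed CE velocity, rest lengths/s
  ia_rate <- 0; ii_rate <- 0
  contact <- FALSE; broken <- FALSE
  travel <- 0; tip_force <- 0
  ia_counts <- integer(m)         # afferent spikes per model sub-step
  aperture <- 100

  sig <- list(t = numeric(n), alpha = numeric(n), i_ia = numeric(n),
              spikes = numeric(n), activation = numeric(n),
              tension = numeric(n), lmtu = numeric(n), lce_cm = numeric(n),
              lce_mu = numeric(n),
              ia_rate = numeric(n), ii_rate = numeric(n),
              theta = numeric(n), aperture = numeric(n),
              tip_force = numeric(n), contact = logical(n),
              broken = logical(n))
  mn_sp_t <- vector("list", n); mn_sp_id <- vector("list", n)
  ia_raster <- vector("list", ceiling(n / m))

  sub <- 0L
  for (i in seq_len(n)) {
    t_i <- i * dt
    sub <- sub + 1L
    a_mA <- if (is.null(policy)) alpha_t[i] else alpha_curr

    # ---- model-rate block -------------------------------------------------
    I_syn <- synapse_current(I_syn, ia_counts[sub], dt,
                             cfg$synapse$tau_s,
                             cfg$synapse$gain * cfg$loop$ia_gain)
    epsc <- epsc_from_alpha(a_mA, pools, cfg$alpha$scale_mA)
    st <- pool_step(pools, epsc, I_syn, dt)
    pools <- st$pools
    wsum <- sum(w[st$spiked])
    A <- activation_step(A, wsum, dt, mus$tau_twitch, mus$quantal)
    mu <- muscle_dynamics_step(mu, A, lmtu - geom$lmtu0_cm, dt, mus)
    Tn <- mu$tension
    if (record_spikes && any(st$spiked)) {
      mn_sp_id[[i]] <- which(st$spiked)
      mn_sp_t[[i]] <- t_i
    }

    # ---- plant-rate block -------------------------------------------------
    if (sub == m) {
      sub <- 0L
      pull_n <- 0
      if (!is.null(pull) && t_i >= pull$start_s && t_i < pull$end_s)
        pull_n <- pull$force_n
      ms <- motor_step(motor, Tn, a_mA, obj, broken, cfg$plant, geom,
                       external_pull_n = pull_n, dt = dtp, n_sub = m)
      motor <- ms$motor
      d_lmtu <- ms$lmtu - lmtu
      lmtu <- ms$lmtu
      travel <- ms$travel; tip_force <- ms$tip_force
      broken <- ms$broken
      pressing <- ms$contact && !broken
      frac <- if (pressing)
        lce_contact_fraction(min(1, a_mA / cfg$alpha$scale_mA),
                             lmtu / geom$lmtu0_cm, mus)
      else 1
      d_lce <- frac * d_lmtu
      contact <- ms$contact
      v_sp <- (d_lce / dtp) / geom$lrest_cm
      l_sp0 <- 1 + dlce_cm / geom$lrest_cm
      dlce_cm <- dlce_cm + d_lce
      # spindle sub-stepped along the interpolated length trajectory
      for (k in seq_len(m)) {
        lk <- l_sp0 + (k / m) * d_lce / geom$lrest_cm
        ss <- spindle_step(sp, lk, dt, V = v_sp)
        sp <- ss$state
      }
      ia_rate <- min(ss$ia_rate, cfg$spindle$rate_ceiling)
      ii_rate <- ss$ii_rate
      fed <- ia_rate + if (feed_ii) ii_rate else 0
      af <- afferent_spikes(fed, cfg$spindle$n_afferents, dtp,
                            cfg$spindle$encoder, phase)
      phase <- af$phase
      ia_counts <- tabulate(pmin(m, 1L + floor(af$raster$t / dt)), m)
      if (record_spikes && nrow(af$raster) > 0)
        ia_raster[[i / m]] <- data.frame(unit_id = af$raster$unit_id,
                                         t = t_i + af$raster$t)
      aperture <- aperture_from_lmtu(lmtu, cfg$geometry)
      if (!is.null(policy))
        alpha_curr <- min(max(policy(t_i, list(tip_force = tip_force,
                                               aperture = aperture,
                                               contact = contact,
                                               broken = broken)), 0),
                          cfg$alpha$scale_mA)
    }

    sig$t[i] <- t_i; sig$alpha[i] <- a_mA; sig$i_ia[i] <- I_syn
    sig$spikes[i] <- wsum; sig$activation[i] <- A; sig$tension[i] <- Tn
    sig$lmtu[i] <- lmtu; sig$lce_cm[i] <- geom$lrest_cm + dlce_cm
    sig$lce_mu[i] <- mu$l_ce
    sig$ia_rate[i] <- ia_rate; sig$ii_rate[i] <- ii_rate
    sig$theta[i] <- motor$theta; sig$aperture[i] <- aperture
    sig$tip_force[i] <- tip_force
    sig$contact[i] <- contact; sig$broken[i] <- broken
  }

  signals <- as.data.frame(sig)
  bad <- vapply(signals[vapply(signals, is.numeric, TRUE)],
                function(x) any(!is.finite(x)), TRUE)
  if (any(bad)) {
    col <- names(bad)[which(bad)[1]]
    t_bad <- signals$t[which(!is.finite(signals[[col]]))[1]]
    stop("non-finite signal '", col, "' at t = ", t_bad, " s")
  }
  mn_raster <- if (record_spikes) {
    keep <- !vapply(mn_sp_id, is.null, TRUE)
    data.frame(
      unit_id = unlist(mn_sp_id[keep], use.names = FALSE),
      t = rep(unlist(mn_sp_t[keep], use.names = FALSE),
              vapply(mn_sp_id[keep], length, 1L)))
  } else data.frame(unit_id = integer(), t = numeric())
  ia_r <- ia_raster[!vapply(ia_raster, is.null, TRUE)]
  ia_raster <- if (length(ia_r)) do.call(rbind, ia_r)
               else data.frame(unit_id = integer(), t = numeric())
  structure(list(signals = signals, mn_raster = mn_raster,
                 ia_raster = ia_raster, cfg = cfg),
            class = "loop_trace")
}

#' Detect the beam-press event timeline
#'
#' Finds, relative to command onset: `t1` first tension rise, `t2` first
#' cable-length change, `t3` contact onset, `t4` end of object deformation
#' (deformation rate below a fraction of its peak), `t5` settlement of the
#' fingertip force (entry into a band around the final value that is held
#' for a minimum duration). Events that require contact are reported as `NA`
#' when no contact occurred.
#'
#' @param trace a `loop_trace`.
#' @param thresholds list, see [default_config()]'s `events` block.
#' @return an `event_times` list with `t1`..`t5` (s from command onset) and
#'   `onset` (s, absolute).
#' @export
detect_events <- function(trace, thresholds = default_config()$events) {
  if (thresholds$tension_frac <= 0 || thresholds$length_cm <= 0 ||
      thresholds$deform_rate_frac <= 0 || thresholds$settle_frac <= 0)
    stop("event thresholds must have nonzero width")
  s <- trace$signals
  on_i <- which(s$alpha > 1e-6)[1]
  if (is.na(on_i)) {
    return(structure(list(t1 = NA_real_, t2 = NA_real_, t3 = NA_real_,
                          t4 = NA_real_, t5 = NA_real_, onset = NA_real_),
                     class = "event_times"))
  }
  t0 <- s$t[on_i]
  rel <- function(i) if (is.na(i)) NA_real_ else s$t[i] - t0
  after <- seq(on_i, nrow(s))

  i1 <- after[which(s$tension[after] >
                      thresholds$tension_frac * max(s$tension))[1]]
  i2 <- after[which(abs(s$lmtu[after] - s$lmtu[on_i]) >
                      thresholds$length_cm)[1]]
  i3 <- after[which(s$contact[after])[1]]

  i4 <- NA_integer_; i5 <- NA_integer_
  if (!is.na(i3)) {
    # deformation rate from a smoothed force series (the raw contact-impact
    # step would otherwise dominate the peak); the rate must stay below the
    # threshold for a short hold to count as "end of deformation"
    seg <- seq(i3, nrow(s))
    dt <- s$t[2] - s$t[1]
    k <- max(1L, round(0.025 / dt))
    f_sm <- stats::filter(s$tip_force[seg], rep(1 / k, k), sides = 1)
    f_sm[seq_len(min(k, length(f_sm)))] <- f_sm[min(k, length(f_sm))]
    rate <- abs(c(0, diff(as.numeric(f_sm)))) / dt
    pk <- max(rate, na.rm = TRUE)
    hold4 <- max(1L, round(0.03 / dt))
    if (pk > 0) {
      below <- rate < thresholds$deform_rate_frac * pk
      for (j in seq(2, length(below))) {
        if (all(below[j:min(length(below), j + hold4)])) {
          i4 <- seg[j]; break
        }
      }
    }
    f_end <- mean(s$tip_force[seq(max(1, nrow(s) - round(0.1 / dt)), nrow(s))])
    band <- thresholds$settle_frac * max(abs(f_end), 1e-9)
    hold <- round(thresholds$settle_hold_s / dt)
    inb <- abs(s$tip_force - f_end) <= band
    start <- (if (is.na(i4)) i3 else i4) + 1L  # settlement follows deformation
    for (j in seq(min(start, nrow(s)), nrow(s))) {
      if (all(inb[j:min(nrow(s), j + hold)])) { i5 <- j; break }
    }
  }
  structure(list(t1 = rel(i1), t2 = rel(i2), t3 = rel(i3),
                 t4 = rel(i4), t5 = rel(i5), onset = t0),
            class = "event_times")
}

#' Export the loop trace signals as CSV
#'
#' @param trace a `loop_trace`.
#' @param path file path.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace$signals, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.loop_trace <- function(x, ...) {
  s <- x$signals
  cat("loop_trace:", nrow(s), "model steps,",
      sprintf("%.3f s", max(s$t)), "\n")
  cat("  final aperture:", sprintf("%.1f%%", s$aperture[nrow(s)]),
      " tension:", sprintf("%.2f N", s$tension[nrow(s)]),
      " tip force:", sprintf("%.2f N", s$tip_force[nrow(s)]), "\n")
  cat("  motoneuron spikes:", nrow(x$mn_raster),
      " Ia spikes:", nrow(x$ia_raster), "\n")
  invisible(x)
}

#' @export
print.event_times <- function(x, ...) {
  cat("events (s from command onset): ",
      paste0("t", 1:5, "=",
             vapply(1:5, function(i) {
               v <- x[[paste0("t", i)]]
               if (is.na(v)) "NA" else sprintf("%.3f", v)
             }, character(1)), collapse = "  "), "\n")
  invisible(x)
}
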