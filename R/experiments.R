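#' Aperture-versus-command curve (virtual experiment 1)
#'
#' Runs the closed loop at each static command level from full extension,
#' lets the hand settle, and records the settled aperture; the hand is
#' released to full extension between levels (each level is an independent
#' run). A linear fit of settled aperture against command is returned for
#' the levels above the static-friction dead zone.
#'
#' @param alpha_levels command levels (mA).
#' @param cfg configuration list.
#' @param duration run length per level (s).
#' @param n_rep settled apertures are averaged over this many independent
#'   runs per level (seeds offset from `cfg$loop$seed`).
#' @return list with `table` (data.frame `alpha`, `aperture`, `settled`) and
#'   `fit` (list `slope`, `intercept`, `r2`, over settled rows above the
#'   dead zone).
#' @export
exp_aperture_curve <- function(alpha_levels, cfg = default_config(),
                               duration = 2, n_rep = 1) {
  cfg$object$kind <- "none"
  cfg$loop$duration <- duration
  cfg$loop$record_spikes <- FALSE
  base_seed <- cfg$loop$seed
  rows <- lapply(alpha_levels, function(a) {
    cmd <- alpha_command(rep(a, 10), fs = 10 / duration,
                         scale_mA = cfg$alpha$scale_mA)
    one <- vapply(seq_len(n_rep), function(r) {
      cfg$loop$seed <- base_seed + 1000 * (r - 1)
      tr <- run_closed_loop(cmd, NULL, cfg)
      s <- tr$signals
      tail_i <- s$t > max(s$t) - 0.2
      late_i <- s$t > max(s$t) - 0.4
      c(mean(s$aperture[tail_i]),
        diff(range(s$aperture[late_i])))
    }, numeric(2))
    data.frame(alpha = a, aperture = mean(one[1, ]),
               settled = all(one[2, ] < 1.5))
  })
  tab <- do.call(rbind, rows)
  # fit over the operating band: settled, above the dead zone, and not
  # saturated at either full extension or full closure
  use <- tab$settled & tab$alpha >= cfg$plant$friction_mA &
    tab$aperture > 0.5 & tab$aperture < 99.5
  fit <- list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_)
  if (sum(use) >= 3) {
    lmfit <- stats::lm(aperture ~ alpha, data = tab[use, ])
    fit <- list(slope = unname(stats::coef(lmfit)[2]),
                intercept = unname(stats::coef(lmfit)[1]),
                r2 = summary(lmfit)$r.squared)
  }
  list(table = tab, fit = fit)
}

#' Quasi-static fingertip stiffness grid (virtual experiment 2)
#'
#' For each command level and target aperture the index finger settles
#' against a rigid force gauge placed at that aperture; the gauge is then
#' elevated by 5 mm and the settled force change `dF` gives the stiffness
#' `dF / 0.005` N/m. Rows where the finger never reaches the gauge are
#' flagged. Also reports the relative flexibility
#' `(K_high - K_low) / K_low` over the unflagged grid.
#'
#' @param alphas command levels (mA), default the probed 6, 7, 8 mA.
#' @param apertures target apertures (%), default 9 values across the range
#'   reachable by all three command levels at desk scale.
#' @param cfg configuration list.
#' @param duration settle time per run (s).
#' @param n_rep force changes are averaged over this many independent
#'   probe pairs (seeds offset from `cfg$loop$seed`).
#' @return list with `table` (data.frame `alpha`, `aperture`, `dF_n`,
#'   `stiffness_n_per_m`, `contact`) and `flexibility`.
#' @export
exp_stiffness <- function(alphas = c(6, 7, 8),
                          apertures = seq(55, 87, length.out = 9),
                          cfg = default_config(), duration = 1.5,
                          n_rep = 1) {
  cfg$loop$duration <- duration
  cfg$loop$record_spikes <- FALSE
  geo <- cfg$geometry
  base_seed <- cfg$loop$seed
  settle_force <- function(a, gap_cm, seed) {
    cfg$object <- list(kind = "rigid", stiffness_n_per_cm = 1,
                       hover_gap_cm = gap_cm, breakage_n = Inf)
    cfg$loop$seed <- seed
    cmd <- alpha_command(rep(a, 10), fs = 10 / duration,
                         scale_mA = cfg$alpha$scale_mA)
    tr <- run_closed_loop(cmd, NULL, cfg)
    s <- tr$signals
    tail_i <- s$t > max(s$t) - 0.5
    list(force = mean(s$tip_force[tail_i]),
         contact = any(s$contact[tail_i]))
  }
  rows <- list()
  for (a in alphas) for (ap in apertures) {
    lmtu_target <- geo$lmtu_closed_cm +
      ap / 100 * (geo$lmtu0_cm - geo$lmtu_closed_cm)
    gap <- cfg$plant$ratio * (geo$lmtu0_cm - lmtu_target)
    dfs <- vapply(seq_len(n_rep), function(r) {
      sd_r <- base_seed + 1000 * (r - 1)
      s1 <- settle_force(a, gap, sd_r)
      s2 <- settle_force(a, gap - 0.5, sd_r)  # gauge elevated by 5 mm
      if (s1$contact && s2$contact) s2$force - s1$force else NA_real_
    }, numeric(1))
    ok <- all(!is.na(dfs))
    rows[[length(rows) + 1]] <- data.frame(
      alpha = a, aperture = ap,
      dF_n = if (ok) mean(dfs) else NA_real_,
      stiffness_n_per_m = if (ok) mean(dfs) / 0.005 else NA_real_,
      contact = ok)
  }
  tab <- do.call(rbind, rows)
  ks <- tab$stiffness_n_per_m[tab$contact]
  flex <- if (length(ks) > 1 && min(ks) > 0)
    (max(ks) - min(ks)) / min(ks) else NA_real_
  list(table = tab, flexibility = flex)
}

#' Beam-press timeline (virtual experiment 3)
#'
#' Issues a step command to the closed loop with the index finger hovering
#' above a bendable beam and returns the detected event timeline t1..t5
#' together with the full trace.
#'
#' @param alpha_step step command level (mA), default 6.5.
#' @param hover_cm hover distance above the beam (cm), default 1.
#' @param cfg configuration list.
#' @param duration run length (s).
#' @param onset_s command onset time (s).
#' @return list with `events` ([detect_events()] result), `trace`, and
#'   `broken` (whether the beam broke during the run).
#' @export
exp_beam_press <- function(alpha_step = 6.5, hover_cm = 1,
                           cfg = default_config(), duration = 1.2,
                           onset_s = 0.1) {
  cfg$loop$duration <- duration
  obj <- object_model("elastic_beam",
                      stiffness_n_per_cm = cfg$object$stiffness_n_per_cm,
                      hover_gap_cm = hover_cm,
                      breakage_n = cfg$object$breakage_n)
  fs <- 1 / cfg$loop$dt_model
  n <- round(duration * fs)
  vals <- ifelse(seq_len(n) / fs > onset_s, alpha_step, 0)
  cmd <- alpha_command(vals, fs = fs, scale_mA = cfg$alpha$scale_mA)
  tr <- run_closed_loop(cmd, obj, cfg)
  ev <- detect_events(tr, cfg$events)
  list(events = ev, trace = tr, broken = any(tr$signals$broken))
}

#' Fitts index of difficulty
#'
#' `ID = log2(2 D / W)`.
#'
#' @param D target distance (force units in the press-without-break task).
#' @param W target width.
#' @return index of difficulty (bits), vectorized.
#' @export
#' @examples
#' fitts_id(1.8, 0.1)  # 5.17
fitts_id <- function(D, W) {
  if (any(D <= 0 | W <= 0)) stop("D and W must be > 0")
  log2(2 * D / W)
}

#' Fitts-law metrics for a set of trials
#'
#' Computes the index of difficulty per trial and the information throughput
#' `TP = (1/N) * sum_i ID_i / CT_i`, where the sum runs over the `N`
#' distinct difficulty levels (trials sharing an ID are first averaged on
#' `ID/CT`). Only successful trials enter the throughput.
#'
#' @param trials data.frame with columns `D`, `W`, `CT` (completion time, s)
#'   and optionally `success` (default all successful).
#' @return list with `table` (per-trial, with `ID`), `per_id` (data.frame of
#'   distinct IDs with mean `ID/CT`), and `TP` (bit/s).
#' @export
fitts_metrics <- function(trials) {
  if (nrow(trials) == 0) stop("no trials")
  if (any(trials$CT <= 0)) stop("completion times must be > 0")
  if (is.null(trials$success)) trials$success <- TRUE
  trials$ID <- fitts_id(trials$D, trials$W)
  ok <- trials[trials$success, ]
  per_id <- do.call(rbind, lapply(split(ok, round(ok$ID, 10)), function(g)
    data.frame(ID = g$ID[1], rate = mean(g$ID / g$CT), n = nrow(g))))
  rownames(per_id) <- NULL
  list(table = trials, per_id = per_id, TP = mean(per_id$rate))
}

#' Synthetic press-without-break trials (demo policy)
#'
#' Generates FittsTrial-style data by running the closed loop under a simple
#' integral target-seeking command policy on the fingertip-force error
#' against an unbreakable beam. This stands in for a human operator solely
#' to produce demonstration trials; it is synthetic and is not a model of
#' human performance.
#'
#' @param targets data.frame with columns `D` (target force, N) and `W`
#'   (band width, N); defaults to the six canonical (D, W) pairs.
#' @param cfg configuration list.
#' @param gain policy gain (mA per N of force error per second).
#' @param hold_s dwell required inside the band (s).
#' @param max_s trial timeout (s).
#' @return data.frame `D`, `W`, `CT`, `success`.
#' @export
fitts_demo_trials <- function(targets = data.frame(
                                D = rep(c(1.8, 3.1), each = 3),
                                W = rep(c(0.1, 0.2, 0.3), 2)),
                              cfg = default_config(), gain = 4,
                              hold_s = 1, max_s = 8) {
  cfg$object <- list(kind = "elastic_beam",
                     stiffness_n_per_cm = cfg$object$stiffness_n_per_cm,
                     hover_gap_cm = 0.2, breakage_n = Inf)
  cfg$loop$duration <- max_s
  cfg$loop$record_spikes <- FALSE
  out <- lapply(seq_len(nrow(targets)), function(i) {
    D <- targets$D[i]; W <- targets$W[i]
    env <- new.env(); env$a <- 0
    policy <- function(t, state) {
      # integral seeking with a fast approach below the dead zone band
      err <- D - state$tip_force
      env$a <- min(12, max(0, env$a + gain * err * cfg$loop$dt_plant +
                                if (t < 0.05) 5.4 else 0))
      env$a
    }
    tr <- run_closed_loop(policy, NULL, cfg)
    s <- tr$signals
    inband <- abs(s$tip_force - D) <= W / 2
    hold_n <- round(hold_s / (s$t[2] - s$t[1]))
    ct <- NA_real_
    cand <- which(inband)
    for (k in cand) {
      if (k + hold_n > nrow(s)) break
      if (all(inband[k:(k + hold_n)])) { ct <- s$t[k + hold_n]; break }
    }
    data.frame(D = D, W = W, CT = if (is.na(ct)) max_s else ct,
               success = !is.na(ct))
  })
  do.call(rbind, out)
}
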