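#' Object model for contact experiments
#'
#' @param kind `"none"`, `"rigid"` (force gauge: travel clamps at the gap)
#'   or `"elastic_beam"` (Hookean reaction beyond the gap, latching breakage
#'   flag at the threshold).
#' @param stiffness_n_per_cm beam stiffness (N per cm of deformation).
#' @param hover_gap_cm free fingertip travel before contact (cm).
#' @param breakage_n fingertip force that breaks the object (N).
#' @return an `object_model` list.
#' @export
object_model <- function(kind = "none", stiffness_n_per_cm = 6,
                         hover_gap_cm = 1, breakage_n = 4.4) {
  kind <- match.arg(kind, c("none", "rigid", "elastic_beam"))
  if (kind == "elastic_beam" && stiffness_n_per_cm <= 0)
    stop("elastic object requires stiffness > 0")
  structure(list(kind = kind, stiffness_n_per_cm = stiffness_n_per_cm,
                 hover_gap_cm = hover_gap_cm, breakage_n = breakage_n),
            class = "object_model")
}

#' Fingertip reaction force from an object
#'
#' Zero before the hover gap is consumed. For an elastic beam the force is
#' `stiffness * (travel - gap)`. For the rigid gauge the travel is clamped at
#' the gap by the plant and the reaction equals whatever force the plant
#' delivers, so this function reports contact only. The breakage flag
#' latches once the elastic force reaches the threshold.
#'
#' @param obj an [object_model()].
#' @param travel fingertip travel from the start position (cm), >= 0.
#' @param broken previous breakage flag (latching).
#' @return list `force` (N), `contact`, `broken`.
#' @export
contact_force <- function(obj, travel, broken = FALSE) {
  if (travel < 0) stop("travel must be >= 0")
  if (obj$kind == "none")
    return(list(force = 0, contact = FALSE, broken = broken))
  pen <- travel - obj$hover_gap_cm
  if (pen <= 0) return(list(force = 0, contact = FALSE, broken = broken))
  if (obj$kind == "elastic_beam") {
    f <- obj$stiffness_n_per_cm * pen
    broken <- broken || f >= obj$breakage_n
    list(force = f, contact = TRUE, broken = broken)
  } else {
    list(force = 0, contact = TRUE, broken = broken)  # rigid: force set by plant
  }
}

#' Initialize the motor/cable state
#'
#' @return a `motor_state` list: accumulated rotation `theta` (rad), winder
#'   angular velocity `omega` (rad/s) and the lagged applied tension
#'   `t_applied` (N) of the motor's torque controller.
#' @export
motor_init <- function() {
  structure(list(theta = 0, omega = 0, t_applied = 0, stuck = TRUE),
            class = "motor_state")
}

#' Advance the torque motor and cable one plant step
#'
#' The motor is a tension source with a first-order velocity lag plus
#' Coulomb-style static friction. Below the friction threshold (expressed as
#' an equivalent alpha command, ~5 mA on the physical device) a resting motor
#' does not move at all; above it, the winder velocity relaxes toward
#' `mobility * net force` where the net cable force is commanded tension
#' minus the return-spring load, the reflected object reaction and kinetic
#' friction. The step is internally sub-stepped for stability against stiff
#' object contact.
#'
#' @param motor a `motor_state`.
#' @param tension_cmd commanded cable tension from the muscle model (N).
#' @param alpha_equiv current command level (mA), used for the static
#'   friction dead zone.
#' @param obj an [object_model()].
#' @param broken latched breakage flag (a broken object exerts no force).
#' @param plant plant parameter list (see [default_config()]'s `plant`
#'   block).
#' @param geom a [cable_geometry()].
#' @param external_pull_n extra force pulling the cable out (N), used to
#'   impose a stretch; allows `theta < 0` (hand pulled beyond rest).
#' @param dt plant step (s).
#' @param n_sub internal sub-steps.
#' @return list with updated `motor`, `lmtu` (cm), fingertip `travel` (cm),
#'   `tip_force` (N), `contact`, `broken`.
#' @export
motor_step <- function(motor, tension_cmd, alpha_equiv, obj, broken = FALSE,
                       plant = default_config()$plant,
                       geom = cable_geometry(), external_pull_n = 0,
                       dt = 0.01, n_sub = 10) {
  if (dt <= 0) stop("dt must be > 0")
  h <- dt / n_sub
  th <- motor$theta; om <- motor$omega; ta <- motor$t_applied
  fric_n <- plant$friction_n
  if (is.null(fric_n)) fric_n <- 0
  tau_vel <- plant$tau_vel_s
  if (is.null(tau_vel)) tau_vel <- 0.01
  # breakaway (static) friction exceeds kinetic friction: standard stiction
  # hysteresis, which lets the settled state freeze against command noise
  sratio <- plant$friction_static_ratio
  if (is.null(sratio)) sratio <- 1.25
  fric_break <- fric_n * sratio
  stuck <- isTRUE(motor$stuck)
  tip_force <- 0; contact <- FALSE
  for (s in seq_len(n_sub)) {
    # torque-controller bandwidth: applied tension lags the command
    ta <- ta + h * (tension_cmd - ta) / plant$tau_motor_s
    trav <- plant$ratio * geom$r_cm * th        # fingertip travel, cm
    cf <- contact_force(obj, max(0, trav), broken)
    broken <- cf$broken
    obj_cable <- 0
    if (!broken && cf$contact && obj$kind == "elastic_beam")
      obj_cable <- cf$force * plant$ratio
    spring <- plant$k_return_n_per_cm * geom$r_cm * th
    drive <- ta - spring - obj_cable - external_pull_n
    still <- abs(om) < 1e-3
    if (stuck) {
      # release only above the breakaway force and the command dead zone
      if (external_pull_n != 0 ||
          (alpha_equiv >= plant$friction_mA && abs(drive) > fric_break))
        stuck <- FALSE
    } else if (still && (abs(drive) <= fric_n ||
                         (alpha_equiv < plant$friction_mA &&
                          external_pull_n == 0))) {
      stuck <- TRUE                            # re-engage at kinetic level
    }
    if (stuck) {
      om <- 0                                  # static friction holds
    } else {
      dir <- if (abs(om) > 1e-3) sign(om) else sign(drive)
      eff <- drive - fric_n * dir              # kinetic Coulomb friction
      om_new <- om + h * (plant$mobility * eff - om) / tau_vel
      # a velocity zero-crossing under sub-kinetic drive sticks instead of
      # chattering across the Coulomb discontinuity
      if (om * om_new < 0 && abs(drive) <= fric_n) {
        om_new <- 0
        stuck <- TRUE
      }
      om <- om_new
    }
    th <- th + h * om
    if (external_pull_n == 0 && th < 0) { th <- 0; om <- max(0, om) }
    # rigid gauge: travel cannot exceed the gap
    if (!broken && obj$kind == "rigid") {
      th_max <- obj$hover_gap_cm / (plant$ratio * geom$r_cm)
      if (th >= th_max) {
        th <- th_max
        om <- min(om, 0)
        tip_force <- max(0, ta - spring - external_pull_n) / plant$ratio
        contact <- TRUE
      }
    }
  }
  trav <- plant$ratio * geom$r_cm * th
  cf <- contact_force(obj, max(0, trav), broken)
  broken <- cf$broken
  if (obj$kind == "elastic_beam" && !broken) {
    tip_force <- cf$force; contact <- cf$contact
  } else if (obj$kind == "elastic_beam" && broken) {
    tip_force <- 0; contact <- cf$contact
  } else if (obj$kind == "none") {
    tip_force <- 0; contact <- FALSE
  }
  motor$theta <- th; motor$omega <- om; motor$t_applied <- ta
  motor$stuck <- stuck
  list(motor = motor, lmtu = geom$lmtu0_cm - geom$r_cm * th,
       travel = max(0, trav), tip_force = tip_force,
       contact = contact, broken = broken)
}

#' Hand aperture from cable length
#'
#' Affine map from the calibrated closure range
#' `[lmtu_closed_cm, lmtu0_cm]` to \[0, 100\] percent, clamped.
#'
#' @param lmtu cable length (cm), vectorized.
#' @param geom list with `lmtu0_cm` and `lmtu_closed_cm` (see
#'   [default_config()]'s `geometry` block).
#' @return aperture in percent of full opening.
#' @export
aperture_from_lmtu <- function(lmtu, geom = default_config()$geometry) {
  if (geom$lmtu_closed_cm >= geom$lmtu0_cm)
    stop("inverted aperture calibration")
  a <- (lmtu - geom$lmtu_closed_cm) / (geom$lmtu0_cm - geom$lmtu_closed_cm)
  pmin(100, pmax(0, 100 * a))
}
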