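#' Default simulator configuration
#'
#' Returns the full nested configuration used by every module: EMG synthesis
#' and Bayesian decoding, motoneuron pools, muscle, cable geometry, spindle,
#' plant and loop scheduling. All values are plain numbers so the list
#' round-trips through YAML unchanged.
#'
#' The geometry block carries the cable constants of the physical design
#' (initial cable length 39.7 cm, winder radius 0.25 cm, spindle normalization
#' length 23.6 cm). Plant and beam constants are the package's desk-scale
#' calibration of the virtual hardware replacement; they are deliberately
#' exposed here rather than hard-coded.
#'
#' @param ... named overrides merged into the defaults, e.g.
#'   `default_config(loop = list(duration = 2))`. Merging is recursive and
#'   per-key, so partial sub-lists are allowed.
#' @return nested list of configuration blocks.
#' @export
#' @examples
#' cfg <- default_config(object = list(kind = "elastic_beam"))
#' cfg$geometry$lmtu0_cm
default_config <- function(...) {
  cfg <- list(
    emg = list(
      fs = 1000,
      band = c(30, 300)
    ),
    bayes = list(
      grid_n = 100,
      diffusion = 1e-2,   # latent-drive diffusion rate, units^2 per s
      jump = 0.1,         # uniform re-seeding rate, probability mass per s
      sigma_floor = 0.02, # half-Gaussian observation scale at zero drive
      scale_mA = 20       # full-scale alpha command
    ),
    neurons = list(
      n_pools = 6,
      pool_size = 128,
      k = 40,             # current units delivered at full normalized drive
      noise_sigma = 2,    # EPSC Gaussian noise SD (5% of k)
      # recruitment thresholds spread over the ~5-8.5 mA command band seen
      # between the dead zone and full closure
      pool_gains = 2 / seq(5.0, 15.0, length.out = 6),
      izh = list(a = 0.02, b = 0.2, c = -65, d = 8),
      v_cut = 30
    ),
    synapse = list(
      tau_s = 0.005,      # EPSC decay time constant
      gain = 0.002        # current increment per afferent spike
    ),
    muscle = list(
      tau_twitch = 0.03,  # twitch low-pass time constant (s)
      quantal = 2.9e-3,   # activation increment per unit-weight spike
      F0 = 1, F1 = 1.8, Vm = 3,
      Kse = 60, Kpe = 15, # lumped stiffnesses, same units as the K_alpha law
      b_damp = 0.1,
      Fmax = 50,          # tension scale (N)
      lce_opt_cm = 4.5,   # CE optimal length for the force-length curve
      Kse_n_per_cm = 30,  # series-elastic (tendon/cable) stiffness
      b_n_s_per_cm = 0.15 # CE damping for the dynamic force balance
    ),
    geometry = list(
      lmtu0_cm = 39.7,    # initial cable length
      r_cm = 0.25,        # winder radius
      lrest_cm = 23.6,    # MTU resting length used for spindle normalization
      lmtu_closed_cm = 39.7 - 2 * pi * 0.25  # one full winder turn = closure
    ),
    plant = list(
      k_return_n_per_cm = 2.8, # lumped passive extension spring, at the cable
      tau_motor_s = 0.1,       # motor torque-controller lag
      mobility = 9,            # rad/s of winder speed per N of net cable force
      friction_mA = 5,         # static-friction dead zone, alpha equivalent
      friction_n = 1.75,       # kinetic Coulomb friction at the cable (N)
      friction_static_ratio = 1.4, # breakaway/kinetic friction ratio
      tau_vel_s = 0.01,        # winder velocity relaxation
                               # so the dead zone edge sits at ~5 mA
      ratio = 2                # fingertip travel (cm) per cm of cable travel
    ),
    object = list(
      kind = "none",           # none | rigid | elastic_beam
      stiffness_n_per_cm = 8,
      hover_gap_cm = 1,
      breakage_n = 4.4
    ),
    spindle = list(
      gamma_dyn = 0,
      gamma_sta = 0,
      n_afferents = 128,
      encoder = "poisson",     # poisson | threshold
      rate_ceiling = 500
    ),
    loop = list(
      dt_model = 0.001,
      dt_plant = 0.01,
      duration = 1,
      seed = 1,
      ia_gain = 1
    ),
    alpha = list(scale_mA = 20),
    events = list(
      tension_frac = 0.01,   # t1: tension above this fraction of trace max
      length_cm = 0.01,      # t2: |dLmtu| above 0.1 mm
      deform_rate_frac = 0.05, # t4: deformation rate below 5% of its peak
      settle_frac = 0.05,    # t5: force within +-5% of final value...
      settle_hold_s = 0.2    # ...for this long
    )
  )
  modifyList(cfg, list(...))
}

#' Validate a configuration list
#'
#' Checks structural invariants that the simulator relies on: positive rates
#' and stiffnesses, the EMG band inside Nyquist, plant step an integer
#' multiple of the model step, and a recognized object kind.
#'
#' @param cfg configuration list as returned by [default_config()].
#' @return `cfg`, invisibly, or an error describing the first violation.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  with(cfg, {
    if (emg$fs <= 0) stop("emg$fs must be > 0")
    if (!(emg$band[1] > 0 && emg$band[1] < emg$band[2] &&
          emg$band[2] < emg$fs / 2))
      stop("emg$band must satisfy 0 < lo < hi < fs/2 (Nyquist)")
    if (bayes$grid_n < 2) stop("bayes$grid_n must be >= 2")
    if (bayes$diffusion < 0 || bayes$jump < 0)
      stop("bayes rates must be non-negative")
    if (neurons$n_pools < 1 || neurons$pool_size < 1)
      stop("neurons: pool layout must be positive")
    if (neurons$noise_sigma < 0) stop("neurons$noise_sigma must be >= 0")
    if (synapse$tau_s <= 0) stop("synapse$tau_s must be > 0")
    if (muscle$tau_twitch <= 0) stop("muscle$tau_twitch must be > 0")
    if (muscle$Vm == 0) stop("muscle$Vm must be nonzero")
    if (muscle$Kse <= 0 || muscle$Kpe < 0) stop("muscle stiffnesses invalid")
    if (geometry$r_cm <= 0 || geometry$lmtu0_cm <= 0)
      stop("geometry must be positive")
    if (geometry$lmtu_closed_cm >= geometry$lmtu0_cm)
      stop("aperture calibration inverted: lmtu_closed must be < lmtu0")
    if (!object$kind %in% c("none", "rigid", "elastic_beam"))
      stop("unknown object kind: ", object$kind)
    if (object$kind == "elastic_beam" && object$stiffness_n_per_cm <= 0)
      stop("elastic object requires stiffness > 0")
    m <- loop$dt_plant / loop$dt_model
    if (abs(m - round(m)) > 1e-9 || m < 1)
      stop("loop$dt_plant must be an integer multiple of loop$dt_model")
    if (events$tension_frac <= 0 || events$length_cm <= 0 ||
        events$deform_rate_frac <= 0 || events$settle_frac <= 0)
      stop("event thresholds must have nonzero width")
  })
  invisible(cfg)
}

#' Read / write a configuration as YAML
#'
#' @param path file path.
#' @param cfg configuration list.
#' @return `read_config` returns the validated configuration list;
#'   `write_config` returns `path` invisibly.
#' @export
read_config <- function(path) {
  cfg <- modifyList(default_config(), yaml::read_yaml(path))
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
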