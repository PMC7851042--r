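#' Cable geometry of the winder-driven musculotendinous unit
#'
#' @param lmtu0_cm initial cable (MTU) length, cm.
#' @param r_cm winder radius, cm.
#' @param lrest_cm MTU resting length used to normalize the spindle input.
#' @return a `cable_geometry` list.
#' @export
cable_geometry <- function(lmtu0_cm = 39.7, r_cm = 0.25, lrest_cm = 23.6) {
  if (r_cm <= 0 || lmtu0_cm <= 0) stop("geometry must be positive")
  structure(list(lmtu0_cm = lmtu0_cm, r_cm = r_cm, lrest_cm = lrest_cm),
            class = "cable_geometry")
}

#' Musculotendinous length from motor rotation
#'
#' The instantaneous cable length equals the initial length minus the length
#' coiled on the winder: `Lmtu = Lmtu0 - r * delta_theta`. One full rotation
#' with the 0.25 cm winder therefore shortens the cable by 2*pi*0.25 ~
#' 1.57 cm.
#'
#' @param delta_theta accumulated motor rotation (rad), vectorized.
#' @param geom a [cable_geometry()].
#' @return Lmtu (cm).
#' @export
#' @examples
#' lmtu_from_angle(2 * pi, cable_geometry())  # 38.129...
lmtu_from_angle <- function(delta_theta, geom = cable_geometry()) {
  lmtu <- geom$lmtu0_cm - geom$r_cm * delta_theta
  if (any(lmtu <= 0))
    stop("rotation ", max(delta_theta),
         " rad implies non-positive cable length")
  lmtu
}

# coefficient table shared by the stiffness law and its composed form;
# the higher-precision printing is used for both branches
.kalpha_coef <- list(
  lower = c(a1 = -57.761, a0 = 60.241, b1 = 57.405, b0 = -12.276),
  upper = c(a1 = -14.611, a0 = 15.238, b1 = 14.465, b0 = -32.307)
)

#' Activation-adjustable muscle stiffness
#'
#' Piecewise-linear stiffness of the active element viewed as an adjustable
#' spring, inferred from the force-length relationship. The branch is chosen
#' by comparing the normalized MTU length with its initial value (1.0), and
#' the result is clamped at zero because only positive stiffness is
#' physically effective.
#'
#' @param alpha normalized command in \[0, 1\] (mA commands must be divided
#'   by the 20 mA full scale first).
#' @param lmtu MTU length normalized by its initial value.
#' @param lmtu0 normalized initial MTU length (branch boundary), default 1.
#' @return K_alpha, same units as the series/parallel stiffnesses.
#' @export
k_alpha <- function(alpha, lmtu, lmtu0 = 1) {
  if (any(alpha < 0 | alpha > 1))
    stop("alpha must be normalized to [0, 1]; divide mA values by the full scale")
  lower <- lmtu <= lmtu0
  cf_lo <- .kalpha_coef$lower
  cf_hi <- .kalpha_coef$upper
  k <- ifelse(lower,
              (cf_lo["a1"] * alpha + cf_lo["a0"]) * lmtu +
                cf_lo["b1"] * alpha + cf_lo["b0"],
              (cf_hi["a1"] * alpha + cf_hi["a0"]) * lmtu +
                cf_hi["b1"] * alpha + cf_hi["b0"])
  unname(pmax(0, k))
}

#' Contractile-element length estimate
#'
#' Without contact the contractile element tracks the cable: both lengths
#' change by the translational displacement of the cable. During contact the
#' MTU is a series chain of the tendon spring and the (parallel + active)
#' element, and the CE length is the series-spring fraction
#' `Kse / (Kse + Kpe + K_alpha)` of the MTU length.
#'
#' @param lmtu normalized MTU length (> 0).
#' @param alpha normalized command in \[0, 1\].
#' @param params list with `Kse`, `Kpe` (and optionally `kalpha`, a
#'   precomputed stiffness overriding [k_alpha()]).
#' @param contact logical contact flag delivered by the plant.
#' @return normalized CE length.
#' @export
lce_estimate <- function(lmtu, alpha, params = default_config()$muscle,
                         contact = FALSE) {
  if (any(lmtu <= 0)) stop("lmtu must be > 0")
  if (!contact) return(lmtu)
  ka <- if (!is.null(params$kalpha)) params$kalpha else k_alpha(alpha, lmtu)
  den <- params$Kse + params$Kpe + ka
  if (any(den <= 0)) stop("non-positive stiffness denominator")
  params$Kse / den * lmtu
}

#' Contact displacement fraction of the contractile element
#'
#' The series-spring displacement divider `Kse / (Kse + Kpe + K_alpha)`
#' applied to length increments during contact; this is the incremental form
#' of [lce_estimate()] and is what the closed loop uses, so that the CE
#' length is continuous at contact onset.
#'
#' @inheritParams lce_estimate
#' @return fraction in (0, 1\].
#' @export
lce_contact_fraction <- function(alpha, lmtu, params = default_config()$muscle) {
  params$Kse / (params$Kse + params$Kpe + k_alpha(alpha, lmtu))
}

#' Direct composed form of the contact CE length
#'
#' Evaluates the contact CE length with the stiffness law substituted
#' directly into the series-fraction expression (single formula, both
#' branches). Provided to cross-check that the composition of
#' [k_alpha()] into [lce_estimate()] and the expanded form agree
#' identically.
#'
#' @inheritParams lce_estimate
#' @return normalized CE length.
#' @export
lce_direct <- function(lmtu, alpha, params = default_config()$muscle) {
  lower <- lmtu <= 1
  cf <- ifelse(rep(lower, length.out = length(lmtu)), 1, 2)
  out <- numeric(length(lmtu))
  for (i in seq_along(lmtu)) {
    c_ <- if (cf[i] == 1) .kalpha_coef$lower else .kalpha_coef$upper
    ka <- (c_["a1"] * alpha + c_["a0"]) * lmtu[i] + c_["b1"] * alpha + c_["b0"]
    ka <- max(0, ka)
    out[i] <- lmtu[i] * params$Kse / (params$Kse + params$Kpe + ka)
  }
  unname(out)
}
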