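#' Deterministic normalized drive profiles
#'
#' Generates the test-input drive traces used throughout the package:
#' constants, steps, ramps, and the three-speed closure profiles (fast
#' 0.87 s, moderate 3.11 s, slow 6.06 s ramps to full drive).
#'
#' @param kind `"constant"`, `"step"`, `"ramp"` or `"closures"`.
#' @param params list of parameters by kind:
#'   constant: `level`, `duration_s`;
#'   step: `from`, `to`, `at_s`, `duration_s`;
#'   ramp: `from`, `to`, `start_s`, `end_s`, `duration_s`;
#'   closures: `speed` one of `"fast"`, `"moderate"`, `"slow"` (ramp 0 to 1
#'   over 0.87 / 3.11 / 6.06 s), `duration_s`.
#' @param fs sample rate (Hz).
#' @return numeric drive trace in \[0, 1\].
#' @export
make_profile <- function(kind, params = list(), fs = 1000) {
  p <- function(name, default) {
    if (!is.null(params[[name]])) params[[name]] else default
  }
  n_of <- function(dur) max(1L, round(dur * fs))
  t_of <- function(n) seq_len(n) / fs
  out <- switch(
    kind,
    constant = rep(p("level", 0.5), n_of(p("duration_s", 1))),
    step = {
      n <- n_of(p("duration_s", 2)); t <- t_of(n)
      ifelse(t > p("at_s", 1), p("to", 0.5), p("from", 0))
    },
    ramp = {
      n <- n_of(p("duration_s", 2)); t <- t_of(n)
      a <- p("start_s", 0.5); b <- p("end_s", 1.5)
      f <- pmin(1, pmax(0, (t - a) / (b - a)))
      p("from", 0) + f * (p("to", 1) - p("from", 0))
    },
    closures = {
      dur_map <- c(fast = 0.87, moderate = 3.11, slow = 6.06)
      d <- dur_map[[p("speed", "moderate")]]
      n <- n_of(p("duration_s", d + 1)); t <- t_of(n)
      pmin(1, t / d)
    },
    stop("unknown profile kind: ", kind)
  )
  if (any(out < 0 | out > 1)) stop("profile leaves [0, 1]")
  out
}

#' Emit the default experiment configurations
#'
#' Writes (or returns) one validated YAML configuration per scripted
#' experiment: free closure, aperture curve, stiffness grid, and the
#' beam-press protocol with the calibrated beam.
#'
#' @param out_dir optional directory; when given, YAML files are written
#'   there and the paths returned.
#' @return named list of configuration lists, or (with `out_dir`) the
#'   written file paths.
#' @export
default_configs <- function(out_dir = NULL) {
  cfgs <- list(
    free_closure = default_config(),
    aperture_curve = default_config(loop = list(duration = 2)),
    stiffness_grid = default_config(
      object = list(kind = "rigid", hover_gap_cm = 1)),
    beam_press = default_config(
      object = list(kind = "elastic_beam", hover_gap_cm = 1,
                    breakage_n = 4.4),
      loop = list(duration = 1.2))
  )
  lapply(cfgs, validate_config)
  if (is.null(out_dir)) return(cfgs)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(cfgs), function(nm) {
    p <- file.path(out_dir, paste0(nm, ".yaml"))
    write_config(cfgs[[nm]], p)
    p
  }, character(1))
  paths
}
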