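#' Synthesize surface EMG as amplitude-modulated band-limited noise
#'
#' Generates a single-channel surrogate EMG: zero-mean Gaussian noise is
#' band-pass filtered to `band`, normalized to unit RMS, and multiplied
#' sample-by-sample by the normalized drive envelope. A constant drive of
#' `d` therefore yields a trace of RMS approximately `d`.
#'
#' @param drive numeric vector of normalized latent drive in \[0, 1\].
#' @param fs sampling rate (Hz).
#' @param band two-element numeric, pass band `(lo, hi)` in Hz with
#'   `0 < lo < hi < fs/2`.
#' @param seed integer seed; identical seeds give bitwise-identical traces.
#' @return an `emg_trace`: list with `samples`, `fs` and `meta`.
#' @export
#' @examples
#' emg <- synth_emg(rep(0.5, 2000), fs = 1000, seed = 1)
#' sqrt(mean(emg$samples^2))  # about 0.5
synth_emg <- function(drive, fs, band = c(30, 300), seed = 1) {
  if (any(drive < 0 | drive > 1)) stop("drive values must lie in [0, 1]")
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < fs / 2))
    stop("band outside Nyquist: need 0 < lo < hi < fs/2")
  n <- length(drive)
  carrier <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    # spectral band-limiting: zero all Fourier bins outside the pass band
    w <- stats::rnorm(n)
    W <- stats::fft(w)
    f <- c(seq(0, floor(n / 2)), seq(ceiling(n / 2) - 1, 1)) * fs / n
    W[f < band[1] | f > band[2]] <- 0
    x <- Re(stats::fft(W, inverse = TRUE)) / n
    r <- sqrt(mean(x^2))
    if (r > 0) x / r else x
  })
  structure(
    list(samples = drive * carrier, fs = fs,
         meta = list(band = band, seed = seed)),
    class = "emg_trace"
  )
}

#' Initialize the Bayesian decoder state
#'
#' The decoder is a discretized drift–jump–likelihood filter over the latent
#' normalized drive on \[0, 1\]: the posterior diffuses (random-walk prior),
#' a small probability mass is redistributed uniformly every step (allowing
#' the abrupt jumps characteristic of this family of EMG decoders), and the
#' rectified observation enters through a half-Gaussian likelihood whose
#' scale grows with the latent drive.
#'
#' @param grid_n number of grid points on \[0, 1\].
#' @param diffusion drift coefficient (drive-units^2 per second).
#' @param jump uniform re-seeding rate (probability mass per second).
#' @param sigma_floor observation scale at zero drive (keeps the likelihood
#'   proper at the origin).
#' @return a `bayes_filter_state` list.
#' @export
bayes_init <- function(grid_n = 100, diffusion = 1e-2, jump = 0.1,
                       sigma_floor = 0.02) {
  if (grid_n < 2) stop("grid_n must be >= 2")
  grid <- seq(0, 1, length.out = grid_n)
  structure(
    list(grid = grid,
         posterior = rep(1 / grid_n, grid_n),
         diffusion = diffusion,
         jump = jump,
         sigma_floor = sigma_floor),
    class = "bayes_filter_state"
  )
}

#' One Bayesian decoder update
#'
#' Propagates the posterior with forward-Euler diffusion (reflecting
#' boundaries) plus a uniform jump mixture, multiplies by the half-Gaussian
#' likelihood of the rectified observation and renormalizes.
#'
#' @param state a `bayes_filter_state`.
#' @param observation rectified (non-negative) EMG amplitude.
#' @param dt step duration (s).
#' @return list with `state` (updated) and `map` (posterior mode in \[0,1\]).
#' @export
bayes_update <- function(state, observation, dt) {
  if (observation < 0) stop("observation must be rectified (>= 0)")
  if (dt <= 0) stop("dt must be > 0")
  p <- state$posterior
  n <- length(p)
  dx <- state$grid[2] - state$grid[1]
  # diffusion with reflecting boundaries (mass-conserving Laplacian)
  lap <- c(p[2] - p[1], p[-c(1, n)] * -2 + p[-c(n - 1, n)] + p[-c(1, 2)],
           p[n - 1] - p[n])
  r <- state$diffusion * dt / dx^2
  if (r > 0.5) r <- 0.5  # explicit-step stability guard
  p <- p + r * lap
  # uniform jump mixture
  j <- min(1, state$jump * dt)
  p <- (1 - j) * p + j / n
  # half-Gaussian likelihood of the rectified signal
  sigma <- state$grid + state$sigma_floor
  lik <- exp(-observation^2 / (2 * sigma^2)) / sigma
  p <- p * lik
  s <- sum(p)
  if (!is.finite(s) || s <= 0)
    stop("posterior renormalization failed (all-zero mass): ",
         "likelihood model mismatch for observation ", observation)
  p <- p / s
  state$posterior <- p
  list(state = state, map = state$grid[which.max(p)])
}

#' Decode an EMG trace into an alpha motor command
#'
#' Rectifies the trace (absolute value), runs the Bayesian filter sample by
#' sample and scales the posterior mode linearly from \[0, 1\] to
#' \[0, `scale_mA`\] mA.
#'
#' @param emg an `emg_trace` (or plain numeric vector with `fs` given in
#'   `params$fs`).
#' @param params list of decoder parameters; see [default_config()]'s
#'   `bayes` block. `scale_mA` sets the full-scale command.
#' @return an `alpha_command`: list with `values` (mA) and `fs`.
#' @export
decode_alpha <- function(emg, params = default_config()$bayes) {
  if (inherits(emg, "emg_trace")) {
    x <- emg$samples
    fs <- emg$fs
  } else {
    x <- as.numeric(emg)
    fs <- params$fs
    if (is.null(fs)) stop("fs must be supplied for a bare numeric trace")
  }
  if (length(x) == 0) stop("empty EMG trace")
  st <- bayes_init(params$grid_n, params$diffusion, params$jump,
                   params$sigma_floor)
  dt <- 1 / fs
  map <- numeric(length(x))
  obs <- abs(x)
  for (i in seq_along(x)) {
    up <- bayes_update(st, obs[i], dt)
    st <- up$state
    map[i] <- up$map
  }
  structure(list(values = map * params$scale_mA, fs = fs,
                 map = map),
            class = "alpha_command")
}

#' Wrap a precomputed normalized drive as an alpha command
#'
#' Convenience for experiments that issue the command directly (bypassing
#' EMG synthesis and decoding), e.g. the step command of the beam-press
#' protocol.
#'
#' @param values_mA numeric vector of commanded current (mA), in \[0, 20\].
#' @param fs sample rate of the command (Hz).
#' @param scale_mA full-scale command used for normalization.
#' @return an `alpha_command`.
#' @export
alpha_command <- function(values_mA, fs, scale_mA = 20) {
  if (any(values_mA < 0 | values_mA > scale_mA))
    stop("alpha command must lie in [0, ", scale_mA, "] mA")
  structure(list(values = values_mA, fs = fs, map = values_mA / scale_mA),
            class = "alpha_command")
}

#' Read / write single-channel EMG as CSV
#'
#' CSV layout is `time_s,amplitude`, one row per sample.
#'
#' @param emg an `emg_trace`.
#' @param path file path.
#' @return `read_emg_csv` returns an `emg_trace`; `write_emg_csv` returns
#'   `path` invisibly.
#' @export
write_emg_csv <- function(emg, path) {
  d <- data.frame(time_s = seq_along(emg$samples) / emg$fs - 1 / emg$fs,
                  amplitude = emg$samples)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_emg_csv
#' @export
read_emg_csv <- function(path) {
  d <- utils::read.csv(path)
  if (nrow(d) < 2) stop("EMG CSV needs at least two samples")
  fs <- 1 / stats::median(diff(d$time_s))
  structure(list(samples = d$amplitude, fs = fs, meta = list(source = path)),
            class = "emg_trace")
}
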