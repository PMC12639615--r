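#' Simulation parameters for a FRAP recording
#'
#' @param k recovery rate constant (per second, > 0); the true half-time of
#'   recovery is `ln(2)/k`.
#' @param mobile_fraction fraction of the bleached signal that recovers, in
#'   `(0, 1]`.
#' @param n_prebleach number of pre-bleach frames (>= 2).
#' @param n_postbleach number of post-bleach frames (>= 10); the default of
#'   143 gives a 145-frame series including two pre-bleach frames, a
#'   realistic confocal time-series length.
#' @param frame_interval seconds between frames (> 0).
#' @param bleach_depth fraction of the pre-bleach intensity removed by the
#'   bleach pulse, in `(0, 1]`.
#' @param photofade_rate acquisition photofading rate (per second, >= 0),
#'   applied multiplicatively as `exp(-rate * t)` to both the bleach ROI and
#'   the bleach-control trace, so bleach-control normalization can undo it
#'   exactly.
#' @param noise_sd additive Gaussian noise SD in intensity units (>= 0).
#' @param background_level camera/background offset added to all traces (>= 0).
#' @param i_pre pre-bleach plateau intensity (arbitrary units).
#' @return a `frap_sim_params` list.
#' @export
frap_sim_params <- function(k = 0.04,
                            mobile_fraction = 0.85,
                            n_prebleach = 2L,
                            n_postbleach = 143L,
                            frame_interval = 1.0,
                            bleach_depth = 0.7,
                            photofade_rate = 0,
                            noise_sd = 0,
                            background_level = 0,
                            i_pre = 1000) {
  if (k <= 0) abort("`k` must be > 0.")
  if (mobile_fraction <= 0 || mobile_fraction > 1) abort("`mobile_fraction` must be in (0, 1].")
  if (n_prebleach < 2) abort("`n_prebleach` must be >= 2.")
  if (n_postbleach < 10) abort("`n_postbleach` must be >= 10.")
  if (frame_interval <= 0) abort("`frame_interval` must be > 0.")
  if (bleach_depth <= 0 || bleach_depth > 1) abort("`bleach_depth` must be in (0, 1].")
  if (photofade_rate < 0 || noise_sd < 0 || background_level < 0) {
    abort("`photofade_rate`, `noise_sd`, `background_level` must be >= 0.")
  }
  structure(
    list(
      k = k, mobile_fraction = mobile_fraction,
      n_prebleach = as.integer(n_prebleach), n_postbleach = as.integer(n_postbleach),
      frame_interval = frame_interval, bleach_depth = bleach_depth,
      photofade_rate = photofade_rate, noise_sd = noise_sd,
      background_level = background_level, i_pre = i_pre
    ),
    class = "frap_sim_params"
  )
}

#' Generate a synthetic FRAP recording
#'
#' Simulates a photobleaching experiment: a pre-bleach plateau, an
#' instantaneous bleach drop, and single-exponential recovery
#' `I(t) = I_bleach + mobile_fraction * (I_pre - I_bleach) * (1 - exp(-k t))`
#' measured from the bleach frame, then corrupted by photofading (applied to
#' ROI and bleach control alike), a background offset, and additive Gaussian
#' noise. The truth block records `k`, `mobile_fraction`, and the half-time
#' `ln(2)/k`.
#'
#' @param params a [frap_sim_params()].
#' @param seed integer seed; identical seeds give bit-identical recordings.
#' @return a `frap_recording`: list with `data` (tibble: `time_s`, `roi`,
#'   `background`, `control`), `bleach_index` (1-based index of the first
#'   post-bleach frame), `truth`, `seed`.
#' @export
generate_frap_recording <- function(params = frap_sim_params(), seed = 1L) {
  if (!inherits(params, "frap_sim_params")) abort("`params` must come from frap_sim_params().")
  with_seed(seed, {
    n <- params$n_prebleach + params$n_postbleach
    t <- (seq_len(n) - 1) * params$frame_interval
    bleach_index <- params$n_prebleach + 1L
    t_post <- t - t[bleach_index]

    i_pre <- params$i_pre
    i_bleach <- i_pre * (1 - params$bleach_depth)
    ideal <- numeric(n)
    ideal[seq_len(params$n_prebleach)] <- i_pre
    post <- bleach_index:n
    ideal[post] <- i_bleach + params$mobile_fraction * (i_pre - i_bleach) *
      (1 - exp(-params$k * t_post[post]))

    fade <- exp(-params$photofade_rate * t)
    roi <- ideal * fade + params$background_level
    control <- i_pre * fade + params$background_level
    background <- rep(params$background_level, n)
    if (params$noise_sd > 0) {
      roi <- roi + rnorm(n, 0, params$noise_sd)
      control <- control + rnorm(n, 0, params$noise_sd)
      background <- background + rnorm(n, 0, params$noise_sd)
    }
    structure(
      list(
        data = tibble(time_s = t, roi = roi, background = background, control = control),
        bleach_index = bleach_index,
        truth = list(
          k = params$k,
          mobile_fraction = params$mobile_fraction,
          t_half = log(2) / params$k,
          params = params
        ),
        seed = as.integer(seed)
      ),
      class = "frap_recording"
    )
  })
}

#' Construct a FRAP recording from raw traces
#'
#' @param time_s strictly increasing frame times in seconds.
#' @param roi,background,control per-frame mean intensities of the bleach
#'   ROI, a background ROI, and an unbleached bleach-control region.
#' @param bleach_index 1-based index of the first post-bleach frame; when
#'   `NULL` it is detected as the global minimum of the
#'   background-subtracted ROI trace (earliest frame on ties).
#' @return a `frap_recording`.
#' @export
frap_recording <- function(time_s, roi, background, control, bleach_index = NULL) {
  n <- length(time_s)
  if (n < 12) abort("a recording needs at least 12 frames.")
  if (length(roi) != n || length(background) != n || length(control) != n) {
    abort("all traces must have the same length as `time_s`.")
  }
  if (any(diff(time_s) <= 0)) abort("`time_s` must be strictly increasing.")
  if (is.null(bleach_index)) {
    bleach_index <- which.min(roi - background)
  }
  bleach_index <- as.integer(bleach_index)
  if (bleach_index < 2L || bleach_index >= n) {
    abort("`bleach_index` must leave >= 1 pre-bleach and >= 1 post-bleach frame.")
  }
  structure(
    list(
      data = tibble(time_s = time_s, roi = roi, background = background, control = control),
      bleach_index = bleach_index,
      truth = NULL, seed = NA_integer_
    ),
    class = "frap_recording"
  )
}

#' @export
print.frap_recording <- function(x, ...) {
  cat(sprintf(
    "<frap_recording> %d frames, bleach at frame %d (t = %.3g s)%s\n",
    nrow(x$data), x$bleach_index, x$data$time_s[x$bleach_index],
    if (!is.null(x$truth)) sprintf(", truth t_half = %.3g s", x$truth$t_half) else ""
  ))
  invisible(x)
}

#' @method as_tibble frap_recording
#' @export
as_tibble.frap_recording <- function(x, ...) x$data
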