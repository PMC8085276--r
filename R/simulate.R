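#' Scene configuration for the synthetic movie generator
#'
#' Describes a field of view populated with soma-like cells: isotropic
#' Gaussian-profile blobs whose brightness follows calcium-transient
#' kinetics. A transient is a double-exponential event
#' `(1 - exp(-u/rise_tau_s)) * exp(-u/decay_tau_s)`, normalized to unit peak,
#' with onsets drawn from a Poisson process of rate `event_rate_hz` per cell
#' and peak amplitudes drawn uniformly from `amplitude_range` (intensity
#' units). Cells are placed by rejection sampling so their 2-sigma masks do
#' not overlap.
#'
#' @param n_cells number of cells (>= 0)
#' @param cell_radius_px Gaussian sigma of the soma profile, in pixels
#' @param background_level constant background intensity in `[0, 1)`
#' @param soma_brightness resting (baseline) soma intensity above background,
#'   in `(0, 1]`
#' @param event_rate_hz expected transient onsets per cell per second
#' @param rise_tau_s,decay_tau_s transient rise and decay time constants (s)
#' @param amplitude_range length-2 numeric, uniform range of transient peak
#'   amplitudes in intensity units
#' @param seed integer seed controlling cell placement and event times
#' @return a list of class `"scene_config"`
#' @export
scene_config <- function(n_cells = 10, cell_radius_px = 4,
                         background_level = 0.1, soma_brightness = 0.4,
                         event_rate_hz = 0.2, rise_tau_s = 0.05,
                         decay_tau_s = 0.5, amplitude_range = c(0.1, 0.4),
                         seed = 1) {
  check_scalar(n_cells, "n_cells", lower = 0, integer = TRUE)
  check_scalar(cell_radius_px, "cell_radius_px", lower = 1e-6)
  check_scalar(background_level, "background_level", lower = 0, upper = 1 - 1e-9)
  check_scalar(soma_brightness, "soma_brightness", lower = 1e-9, upper = 1)
  check_scalar(event_rate_hz, "event_rate_hz", lower = 0)
  check_scalar(rise_tau_s, "rise_tau_s", lower = 1e-9)
  check_scalar(decay_tau_s, "decay_tau_s", lower = 1e-9)
  if (length(amplitude_range) != 2 || amplitude_range[1] > amplitude_range[2] ||
      amplitude_range[1] < 0 || amplitude_range[2] > 1)
    stop_invalid("amplitude_range must be (lo, hi) within (0, 1]")
  structure(as.list(environment()), class = "scene_config")
}

# unit-peak double-exponential calcium transient kernel sampled at `times`
transient_kernel <- function(times, rise_tau_s, decay_tau_s) {
  k <- ifelse(times >= 0,
              (1 - exp(-times / rise_tau_s)) * exp(-times / decay_tau_s), 0)
  tpk <- rise_tau_s * log1p(decay_tau_s / rise_tau_s)
  peak <- (1 - exp(-tpk / rise_tau_s)) * exp(-tpk / decay_tau_s)
  k / peak
}

place_cells <- function(n_cells, height, width, radius, max_tries = 5000) {
  margin <- 2 * radius + 1
  if (n_cells == 0) return(matrix(numeric(0), ncol = 2))
  centers <- matrix(NA_real_, n_cells, 2)
  placed <- 0
  for (try in seq_len(max_tries)) {
    cand <- c(runif(1, margin, height - margin), runif(1, margin, width - margin))
    if (placed == 0 ||
        min(sqrt(rowSums((centers[seq_len(placed), , drop = FALSE] -
                          matrix(cand, placed, 2, byrow = TRUE))^2))) > 4 * radius) {
      placed <- placed + 1
      centers[placed, ] <- cand
      if (placed == n_cells) return(centers)
    }
  }
  stop_invalid("could not place ", n_cells, " non-overlapping cells in a ",
               height, " x ", width, " field of view")
}

#' Generate a noise-free synthetic two-photon movie
#'
#' Produces a fixed-FOV ground-truth movie: constant background plus, for
#' each cell, a Gaussian-profile blob modulated in time by
#' `soma_brightness + sum of transients`. Intensities are clipped to
#' `[0, 1]`. Also returns each cell's binary mask (profile within 2 sigma)
#' and its exact noiseless ROI-mean fluorescence time course, computed from
#' the returned movie itself so downstream trace comparisons are exact.
#'
#' @param scene a [scene_config()]
#' @param n_frames number of frames (>= 1)
#' @param rate_hz sampling rate in Hz
#' @param height,width frame dimensions in pixels (>= 8)
#' @return a list with elements `movie` (class `"movie"`), `masks`
#'   (`H x W x n_cells` logical array), `traces` (`n_frames x n_cells`
#'   matrix of noiseless ROI means), `activity` (`n_frames x n_cells`
#'   matrix of per-cell brightness time courses above background) and
#'   `centers`
#' @export
generate_ground_truth_movie <- function(scene, n_frames, rate_hz = 40,
                                        height = 500, width = 500) {
  if (!inherits(scene, "scene_config")) stop_invalid("scene must be a scene_config")
  check_scalar(n_frames, "n_frames", lower = 1, integer = TRUE)
  check_scalar(rate_hz, "rate_hz", lower = 1e-9)
  check_scalar(height, "height", lower = 8, integer = TRUE)
  check_scalar(width, "width", lower = 8, integer = TRUE)

  with_seed(scene$seed, {
    centers <- place_cells(scene$n_cells, height, width, scene$cell_radius_px)
    times <- (seq_len(n_frames) - 1) / rate_hz
    duration <- n_frames / rate_hz
    activity <- matrix(0, n_frames, max(scene$n_cells, 1))
    profiles <- vector("list", scene$n_cells)
    masks <- array(FALSE, dim = c(height, width, max(scene$n_cells, 1)))
    yy <- matrix(seq_len(height), height, width)
    xx <- matrix(seq_len(width), height, width, byrow = TRUE)
    for (ci in seq_len(scene$n_cells)) {
      d2 <- (yy - centers[ci, 1])^2 + (xx - centers[ci, 2])^2
      prof <- exp(-d2 / (2 * scene$cell_radius_px^2))
      prof[d2 > (3 * scene$cell_radius_px)^2] <- 0
      profiles[[ci]] <- prof
      masks[, , ci] <- prof >= exp(-2)
      act <- rep(scene$soma_brightness, n_frames)
      n_ev <- rpois(1, scene$event_rate_hz * duration)
      if (n_ev > 0) {
        onsets <- sort(runif(n_ev, 0, duration))
        amps <- runif(n_ev, scene$amplitude_range[1], scene$amplitude_range[2])
        for (k in seq_len(n_ev))
          act <- act + amps[k] *
            transient_kernel(times - onsets[k], scene$rise_tau_s, scene$decay_tau_s)
      }
      activity[, ci] <- act
    }
    frames <- array(scene$background_level, dim = c(height, width, n_frames))
    for (t in seq_len(n_frames)) {
      img <- frames[, , t]
      for (ci in seq_len(scene$n_cells))
        img <- img + profiles[[ci]] * activity[t, ci]
      frames[, , t] <- pmin(img, 1)
    }
    movie <- as_movie(frames, rate_hz = rate_hz)
    traces <- matrix(NA_real_, n_frames, max(scene$n_cells, 1))
    flat <- matrix(frames, height * width, n_frames)
    for (ci in seq_len(scene$n_cells))
      traces[, ci] <- colMeans(flat[as.vector(masks[, , ci]), , drop = FALSE])
    if (scene$n_cells == 0) {
      masks <- array(FALSE, dim = c(height, width, 0))
      traces <- matrix(numeric(0), n_frames, 0)
      activity <- matrix(numeric(0), n_frames, 0)
    }
    list(movie = movie, masks = masks, traces = traces,
         activity = activity, centers = centers)
  })
}
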