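#' Mixed Poisson-Gaussian noise parameters
#'
#' The corruption model is `m = t + ns_p(t) + ns_g`: a signal-dependent shot
#' noise term plus i.i.d. zero-mean Gaussian read noise. Shot noise is
#' parameterized by a photon budget `B` (expected photon count at intensity
#' 1.0) defining `Poisson(B * t) / B`, and `poisson_magnitude` linearly
#' scales the resulting zero-mean deviation:
#' `ns_p(t) = poisson_magnitude * (Poisson(B * t) / B - t)`.
#' Magnitude 1 is physical shot noise at budget `B`; magnitude 0 disables the
#' term exactly. Per-pixel variance is
#' `poisson_magnitude^2 * t / B + gaussian_sd^2` and the corruption is
#' mean-preserving.
#'
#' @param poisson_magnitude dimensionless scale of the shot-noise deviation
#'   (>= 0)
#' @param photon_budget expected photons at intensity 1.0 (> 0)
#' @param gaussian_sd standard deviation of the read noise, intensity units
#'   (>= 0)
#' @param seed optional integer seed; if `NULL` the current RNG stream is used
#' @return a list of class `"noise_params"`
#' @export
noise_params <- function(poisson_magnitude = 1, photon_budget = 1000,
                         gaussian_sd = 0.02, seed = NULL) {
  check_scalar(poisson_magnitude, "poisson_magnitude", lower = 0)
  check_scalar(photon_budget, "photon_budget", lower = .Machine$double.xmin)
  check_scalar(gaussian_sd, "gaussian_sd", lower = 0)
  if (!is.null(seed)) check_scalar(seed, "seed", integer = TRUE)
  structure(list(poisson_magnitude = poisson_magnitude,
                 photon_budget = photon_budget,
                 gaussian_sd = gaussian_sd, seed = seed),
            class = "noise_params")
}

#' Corrupt a frame with mixed Poisson-Gaussian noise
#'
#' Applies `m = t + ns_p(t) + ns_g` pixelwise (see [noise_params()]). The
#' output is deliberately not clipped so that the noise stays exactly
#' additive and mean-preserving; use [clip_unit()] before export. With
#' `poisson_magnitude = 0` and `gaussian_sd = 0` the frame is returned
#' unchanged and the RNG stream is not advanced.
#'
#' @param frame a matrix (or 1-frame movie) with intensities in `[0, 1]`
#' @param params a [noise_params()]
#' @param gaussian_sd optional override of `params$gaussian_sd`, used when a
#'   sequence shares one draw of the read-noise level
#' @return a matrix of the same dimensions
#' @export
corrupt <- function(frame, params, gaussian_sd = NULL) {
  t <- as_frame_matrix(frame)
  if (!inherits(params, "noise_params")) stop_invalid("params must be noise_params")
  if (any(t < 0)) stop_invalid("frame intensities must be non-negative")
  sd_g <- if (is.null(gaussian_sd)) params$gaussian_sd else gaussian_sd
  check_scalar(sd_g, "gaussian_sd", lower = 0)
  with_seed(params$seed, {
    m <- t
    if (params$poisson_magnitude > 0) {
      B <- params$photon_budget
      shot <- matrix(rpois(length(t), B * t) / B, nrow(t), ncol(t))
      m <- m + params$poisson_magnitude * (shot - t)
    }
    if (sd_g > 0)
      m <- m + matrix(rnorm(length(t), 0, sd_g), nrow(t), ncol(t))
    m
  })
}

#' Corrupt every frame of a movie
#'
#' @param movie a `"movie"` with intensities in `[0, 1]`
#' @param params a [noise_params()]
#' @param gaussian_sds optional per-frame vector of read-noise SDs (length
#'   `n_frames`), e.g. one independent draw per frame or per sequence
#' @return a `"movie"` of corrupted (unclipped) frames
#' @export
corrupt_movie <- function(movie, params, gaussian_sds = NULL) {
  if (!inherits(movie, "movie")) stop_invalid("movie must be a movie")
  nt <- n_frames(movie)
  if (!is.null(gaussian_sds) && length(gaussian_sds) != nt)
    stop_invalid("gaussian_sds must have one entry per frame")
  out <- unclass(movie)
  with_seed(params$seed, {
    p <- params
    p$seed <- NULL  # one stream across frames
    for (i in seq_len(nt))
      out[, , i] <- corrupt(movie[, , i], p,
                            gaussian_sd = if (is.null(gaussian_sds)) NULL
                                          else gaussian_sds[i])
    as_movie(out, rate_hz = attr(movie, "rate_hz"))
  })
}

#' Average frames into a reference image
#'
#' Pixel-wise arithmetic mean of a stack of frames of the same field of
#' view; with 100 noisy frames the residual noise shrinks by a factor of 10
#' (the `1/sqrt(N)` law), giving a usable clean reference for supervised
#' training.
#'
#' @param frames a `"movie"`, an `H x W x N` array, or a list of matrices
#' @return the mean frame as a matrix
#' @export
average_reference <- function(frames) {
  if (is.list(frames) && !inherits(frames, "movie")) {
    if (length(frames) == 0) stop_invalid("cannot average an empty frame sequence")
    frames <- as_movie(frames, rate_hz = 1)
  }
  if (inherits(frames, "movie")) frames <- unclass(frames)
  if (is.matrix(frames)) return(frames)
  if (!is.array(frames) || length(dim(frames)) != 3 || dim(frames)[3] < 1)
    stop_invalid("cannot average an empty frame sequence")
  rowMeans(frames, dims = 2)
}
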