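#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)` in dB. Identical images (MSE = 0) give
#' `+Inf`; callers that need a finite cap should apply it themselves.
#'
#' @param reference,test equally sized matrices
#' @param data_range dynamic range of the data (1.0 for unit-normalized)
#' @return PSNR in dB
#' @export
psnr <- function(reference, test, data_range = 1.0) {
  reference <- as_frame_matrix(reference, "reference")
  test <- as_frame_matrix(test, "test")
  if (!identical(dim(reference), dim(test)))
    stop_invalid("reference and test must have identical dimensions")
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

gaussian_kernel_1d <- function(size = 11, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# valid-region separable filtering via banded matrix products
filter_valid <- function(img, g) {
  k <- length(g)
  H <- nrow(img); W <- ncol(img)
  Fv <- matrix(0, H - k + 1, H)
  for (j in seq_len(k)) Fv[cbind(seq_len(H - k + 1), seq_len(H - k + 1) + j - 1)] <- g[j]
  Fh <- matrix(0, W - k + 1, W)
  for (j in seq_len(k)) Fh[cbind(seq_len(W - k + 1), seq_len(W - k + 1) + j - 1)] <- g[j]
  Fv %*% img %*% t(Fh)
}

#' Structural similarity index
#'
#' Single-scale SSIM with an 11 x 11 Gaussian window (sigma = 1.5),
#' stabilizers `K1 = 0.01`, `K2 = 0.03`, and Gaussian-weighted local moments
#' (no sample-covariance correction). The local map is computed on the valid
#' region (a `(window - 1) / 2` border is excluded) and averaged.
#'
#' @inheritParams psnr
#' @param window_size,sigma Gaussian window parameters
#' @param K1,K2 stabilizer constants
#' @return the mean SSIM, a scalar in `[-1, 1]`
#' @export
ssim <- function(reference, test, data_range = 1.0, window_size = 11,
                 sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  x <- as_frame_matrix(reference, "reference")
  y <- as_frame_matrix(test, "test")
  if (!identical(dim(x), dim(y)))
    stop_invalid("reference and test must have identical dimensions")
  if (min(dim(x)) < window_size)
    stop_invalid("images must be at least ", window_size, " pixels per side")
  g <- gaussian_kernel_1d(window_size, sigma)
  mu_x <- filter_valid(x, g); mu_y <- filter_valid(y, g)
  s_xx <- filter_valid(x * x, g) - mu_x^2
  s_yy <- filter_valid(y * y, g) - mu_y^2
  s_xy <- filter_valid(x * y, g) - mu_x * mu_y
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  ssim_map <- ((2 * mu_x * mu_y + C1) * (2 * s_xy + C2)) /
    ((mu_x^2 + mu_y^2 + C1) * (s_xx + s_yy + C2))
  mean(ssim_map)
}

#' Extract an ROI fluorescence trace
#'
#' Averages the pixels inside the ROI mask per frame to obtain `f(t)`, takes
#' the baseline `f0` as the 25th percentile of `f` (linear interpolation
#' between order statistics), and computes `dff = (f - f0) / f0`.
#'
#' @param movie a `"movie"`
#' @param roi_mask a logical (or 0/1) matrix matching the frame dimensions
#'   with at least one `TRUE` pixel
#' @return a list of class `"trace"` with elements `f`, `rate_hz`, `f0`,
#'   `dff`
#' @export
extract_trace <- function(movie, roi_mask) {
  if (!inherits(movie, "movie")) stop_invalid("movie must be a movie")
  d <- dim(movie)
  mask <- roi_mask != 0
  if (!is.matrix(mask) || !identical(dim(mask), d[1:2]))
    stop_invalid("roi_mask must match the frame dimensions")
  if (!any(mask)) stop_invalid("roi_mask is empty")
  flat <- matrix(unclass(movie), d[1] * d[2], d[3])
  f <- colMeans(flat[as.vector(mask), , drop = FALSE])
  f0 <- quantile(f, 0.25, type = 7, names = FALSE)
  if (f0 <= 0)
    stop(errorCondition("baseline f0 is not positive; dF/F is undefined",
                        class = c("caldenoise_degenerate_baseline", "error")))
  structure(list(f = f, rate_hz = attr(movie, "rate_hz"), f0 = f0,
                 dff = (f - f0) / f0),
            class = "trace")
}

#' Transient analysis windows
#'
#' Window lengths are converted to frames via `round(seconds * rate)` with
#' a floor of one frame: at 40 Hz the 75 ms peak window is 3 frames and the
#' 2 s baseline window is 80 frames. The peak window is centered on
#' `peak_index`; the baseline window ends at the frame immediately before
#' the peak window starts.
#'
#' @param peak_index frame index of the transient peak (1-based)
#' @param peak_window_s peak-centered averaging window, seconds
#' @param baseline_window_s baseline window, seconds
#' @return a list of class `"transient_window"`
#' @export
transient_window <- function(peak_index, peak_window_s = 0.075,
                             baseline_window_s = 2.0) {
  check_scalar(peak_index, "peak_index", lower = 1, integer = TRUE)
  check_scalar(peak_window_s, "peak_window_s", lower = 1e-9)
  check_scalar(baseline_window_s, "baseline_window_s", lower = 1e-9)
  structure(list(peak_index = peak_index, peak_window_s = peak_window_s,
                 baseline_window_s = baseline_window_s),
            class = "transient_window")
}

window_frames <- function(seconds, rate_hz) max(1L, as.integer(round(seconds * rate_hz)))

#' Transient signal-to-noise ratio
#'
#' `SNR = (Peak - mean(Baseline)) / SD(Baseline)` on the dF/F trace, where
#' `Peak` is the mean over the peak-centered window and `Baseline` is the
#' window placed immediately before it; SD is the sample standard deviation
#' (denominator N - 1).
#'
#' @param trace a `"trace"` from [extract_trace()]
#' @param window a [transient_window()]
#' @return the transient SNR, a scalar
#' @export
transient_snr <- function(trace, window) {
  if (!inherits(trace, "trace")) stop_invalid("trace must be a trace")
  if (!inherits(window, "transient_window"))
    stop_invalid("window must be a transient_window")
  n <- length(trace$dff)
  wp <- window_frames(window$peak_window_s, trace$rate_hz)
  wb <- window_frames(window$baseline_window_s, trace$rate_hz)
  p0 <- window$peak_index - (wp - 1L) %/% 2L
  peak_idx <- p0:(p0 + wp - 1L)
  base_idx <- (p0 - wb):(p0 - 1L)
  if (min(base_idx) < 1 || max(peak_idx) > n)
    stop_invalid("baseline/peak windows fall outside the trace (need indices ",
                 min(base_idx), "..", max(peak_idx), " in 1..", n, ")")
  base <- trace$dff[base_idx]
  if (sd(base) == 0)
    stop(errorCondition("baseline dF/F has zero variance; SNR is undefined",
                        class = c("caldenoise_degenerate_baseline", "error")))
  (mean(trace$dff[peak_idx]) - mean(base)) / sd(base)
}

#' Locate the dF/F peak of a trace
#'
#' Convenience helper returning the index of the maximum dF/F value,
#' optionally restricted to a frame range.
#'
#' @param trace a `"trace"`
#' @param from,to inclusive search bounds (frame indices)
#' @export
find_peak <- function(trace, from = 1, to = length(trace$dff)) {
  idx <- from:to
  idx[which.max(trace$dff[idx])]
}

#' Per-frame spatial quality of a movie
#'
#' Computes PSNR and SSIM of every test frame against the reference — a
#' movie of equal length or a single fixed-FOV frame broadcast over all
#' test frames — plus their mean and SD.
#'
#' @param reference a `"movie"` matching `test`, or a single frame matrix
#' @param test a `"movie"`
#' @param data_range dynamic range passed to [psnr()] and [ssim()]
#' @return a list of class `"quality_report"`: `per_frame` (data frame
#'   `frame, psnr_db, ssim`) and `summary` (mean and SD of each metric)
#' @export
movie_quality <- function(reference, test, data_range = 1.0) {
  if (!inherits(test, "movie")) stop_invalid("test must be a movie")
  nt <- n_frames(test)
  ref_frame <- function(i) {
    if (inherits(reference, "movie")) {
      if (n_frames(reference) != nt)
        stop_invalid("reference movie must match the test frame count")
      reference[, , i]
    } else as_frame_matrix(reference, "reference")
  }
  per <- data.frame(frame = seq_len(nt), psnr_db = NA_real_, ssim = NA_real_)
  for (i in seq_len(nt)) {
    per$psnr_db[i] <- psnr(ref_frame(i), test[, , i], data_range)
    per$ssim[i] <- ssim(ref_frame(i), test[, , i], data_range)
  }
  structure(list(
    per_frame = per,
    summary = data.frame(metric = c("psnr_db", "ssim"),
                         mean = c(mean(per$psnr_db), mean(per$ssim)),
                         sd = c(sd(per$psnr_db), sd(per$ssim)))),
    class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("quality over %d frames: PSNR %.2f +/- %.2f dB, SSIM %.4f +/- %.4f\n",
              nrow(x$per_frame), x$summary$mean[1], x$summary$sd[1],
              x$summary$mean[2], x$summary$sd[2]))
  invisible(x)
}
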