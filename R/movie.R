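#' Construct a movie
#'
#' A movie is an ordered stack of equally sized grayscale frames with a
#' sampling rate, stored as an `H x W x T` numeric array of class `"movie"`
#' with a `rate_hz` attribute. Frame intensities are normalized fluorescence
#' units; ground-truth (noise-free) movies lie in `[0, 1]`, corrupted movies
#' may exceed that range until explicitly clipped.
#'
#' @param frames an `H x W x T` array, a single `H x W` matrix (one frame),
#'   or a list of equally sized matrices
#' @param rate_hz sampling rate in Hz (> 0)
#' @return an object of class `"movie"`
#' @export
as_movie <- function(frames, rate_hz = 40) {
  check_scalar(rate_hz, "rate_hz", lower = .Machine$double.xmin)
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(frames) == 0) stop_invalid("movie must contain at least one frame")
    if (length(dims) != 1) stop_invalid("all frames must share identical dimensions")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1]], length(frames)))
  }
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1))
  if (!is.array(frames) || length(dim(frames)) != 3)
    stop_invalid("frames must be an H x W x T array")
  if (dim(frames)[3] < 1) stop_invalid("movie must contain at least one frame")
  if (any(!is.finite(frames))) stop_invalid("all intensities must be finite")
  structure(frames, rate_hz = rate_hz, class = "movie")
}

#' @export
print.movie <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("movie: %d x %d pixels, %d frames @ %g Hz, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], attr(x, "rate_hz"), min(x), max(x)))
  invisible(x)
}

#' Number of frames in a movie
#' @param movie a `"movie"` object
#' @export
n_frames <- function(movie) dim(movie)[3]

#' Extract a single frame as a matrix
#' @param movie a `"movie"` object
#' @param i frame index (1-based)
#' @export
get_frame <- function(movie, i) {
  if (i < 1 || i > n_frames(movie)) stop_invalid("frame index out of range")
  movie[, , i, drop = TRUE]
}

#' Subset frames of a movie, keeping rate and class
#' @param movie a `"movie"` object
#' @param idx frame indices
#' @export
subset_frames <- function(movie, idx) {
  if (any(idx < 1 | idx > n_frames(movie))) stop_invalid("frame index out of range")
  as_movie(movie[, , idx, drop = FALSE], rate_hz = attr(movie, "rate_hz"))
}

#' Clip intensities to the unit interval
#'
#' Corruption is additive and deliberately unclipped so its first two moments
#' stay exact; use this before export or display.
#' @param x a movie, frame matrix, or numeric array
#' @export
clip_unit <- function(x) {
  y <- pmin(pmax(x, 0), 1)
  attributes(y) <- attributes(x)
  y
}

as_frame_matrix <- function(x, name = "frame") {
  if (inherits(x, "movie")) {
    if (n_frames(x) != 1) stop_invalid(name, " must be a single frame")
    return(x[, , 1, drop = TRUE])
  }
  if (is.array(x) && length(dim(x)) == 3 && dim(x)[3] == 1)
    return(x[, , 1, drop = TRUE])
  if (!is.matrix(x)) stop_invalid(name, " must be a 2-D matrix")
  x
}
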