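#' Per-frame motion description
#'
#' Generates concrete per-frame displacements for a movie, either rigid
#' (one `(dy, dx)` shift per frame, in pixels) or elastic (a smooth
#' nonuniform displacement field per frame, built by bilinear upsampling of
#' a coarse grid of i.i.d. normal node displacements). Frames are warped by
#' backward bilinear sampling, so zero displacement is an exact identity.
#'
#' @param n_frames number of frames the motion covers
#' @param kind `"rigid"` or `"elastic"`
#' @param max_shift peak displacement amplitude in pixels
#' @param grid number of coarse nodes per axis for elastic fields
#' @param frame_prob probability that a given frame moves at all; values
#'   below 1 produce temporally sparse, spike-like artifacts
#' @param seed integer seed
#' @param shifts optional `n_frames x 2` matrix of explicit rigid `(dy, dx)`
#'   shifts; overrides random generation
#' @param fields optional list (length `n_frames`) of `list(dy=, dx=)`
#'   full-resolution displacement matrices; overrides random generation
#' @return a list of class `"motion_params"`
#' @export
motion_params <- function(n_frames, kind = c("rigid", "elastic"),
                          max_shift = 2, grid = 4, frame_prob = 1, seed = 1,
                          shifts = NULL, fields = NULL) {
  kind <- match.arg(kind)
  check_scalar(n_frames, "n_frames", lower = 1, integer = TRUE)
  check_scalar(max_shift, "max_shift", lower = 0)
  check_scalar(grid, "grid", lower = 2, integer = TRUE)
  check_scalar(frame_prob, "frame_prob", lower = 0, upper = 1)
  if (!is.null(shifts)) {
    if (!is.matrix(shifts) || nrow(shifts) != n_frames || ncol(shifts) != 2)
      stop_invalid("shifts must be an n_frames x 2 matrix")
    kind <- "rigid"
  }
  if (!is.null(fields)) {
    if (length(fields) != n_frames)
      stop_invalid("fields must supply one displacement field per frame")
    kind <- "elastic"
  }
  structure(list(n_frames = n_frames, kind = kind, max_shift = max_shift,
                 grid = grid, frame_prob = frame_prob, seed = seed,
                 shifts = shifts, fields = fields),
            class = "motion_params")
}

# bilinear upsampling of a coarse grid whose nodes span the full frame
upsample_grid <- function(coarse, height, width) {
  g <- nrow(coarse)
  ys <- seq(1, height, length.out = g)
  xs <- seq(1, width, length.out = g)
  rows <- apply(coarse, 2, function(v) approx(ys, v, xout = seq_len(height))$y)
  t(apply(rows, 1, function(v) approx(xs, v, xout = seq_len(width))$y))
}

resolve_motion <- function(motion, height, width) {
  if (!is.null(motion$fields)) {
    for (f in motion$fields)
      if (!identical(dim(f$dy), c(height, width)) ||
          !identical(dim(f$dx), c(height, width)))
        stop_invalid("displacement field dimensions must match the frames")
    return(motion$fields)
  }
  if (!is.null(motion$shifts)) {
    return(lapply(seq_len(motion$n_frames), function(i)
      list(dy = matrix(motion$shifts[i, 1], height, width),
           dx = matrix(motion$shifts[i, 2], height, width))))
  }
  with_seed(motion$seed, {
    moves <- runif(motion$n_frames) <= motion$frame_prob
    zero <- list(dy = matrix(0, height, width), dx = matrix(0, height, width))
    if (motion$kind == "rigid") {
      sh <- matrix(runif(2 * motion$n_frames, -motion$max_shift, motion$max_shift),
                   ncol = 2)
      lapply(seq_len(motion$n_frames), function(i) {
        if (!moves[i]) return(zero)
        list(dy = matrix(sh[i, 1], height, width),
             dx = matrix(sh[i, 2], height, width))
      })
    } else {
      lapply(seq_len(motion$n_frames), function(i) {
        cy <- matrix(rnorm(motion$grid^2, 0, motion$max_shift / 2),
                     motion$grid, motion$grid)
        cx <- matrix(rnorm(motion$grid^2, 0, motion$max_shift / 2),
                     motion$grid, motion$grid)
        if (!moves[i]) return(zero)
        list(dy = pmax(pmin(upsample_grid(cy, height, width), motion$max_shift),
                       -motion$max_shift),
             dx = pmax(pmin(upsample_grid(cx, height, width), motion$max_shift),
                       -motion$max_shift))
      })
    }
  })
}

#' Apply motion artifacts to a movie
#'
#' Warps each frame by its displacement (rigid shift or nonuniform field)
#' using bilinear interpolation; regions sampled from outside the frame are
#' filled with `fill` (typically the background level). Dimensions and frame
#' count are preserved.
#'
#' @param movie a `"movie"`
#' @param motion a [motion_params()] covering `n_frames(movie)` frames
#' @param fill intensity used for out-of-frame samples
#' @return a `"movie"` of warped frames
#' @export
add_motion <- function(movie, motion, fill = 0) {
  if (!inherits(movie, "movie")) stop_invalid("movie must be a movie")
  if (!inherits(motion, "motion_params")) stop_invalid("motion must be motion_params")
  if (motion$n_frames != n_frames(movie))
    stop_invalid("motion covers ", motion$n_frames, " frames but the movie has ",
                 n_frames(movie))
  d <- dim(movie)
  fields <- resolve_motion(motion, d[1], d[2])
  out <- unclass(movie)
  for (i in seq_len(d[3]))
    out[, , i] <- cpp_warp(movie[, , i], fields[[i]]$dy, fields[[i]]$dx, fill)
  as_movie(out, rate_hz = attr(movie, "rate_hz"))
}
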