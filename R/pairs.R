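#' Training pairs
#'
#' A training pair holds a 3-channel input stack (`H x W x 3`, three frames
#' stacked as channels) and a 3-channel target in which one frame is
#' replicated into all three channels. `stage_tag` records whether the pair
#' belongs to supervised pre-training (clean reference target) or to
#' noise-to-noise fine-tuning (fourth noisy frame as target).
#'
#' @param input_stack,target_stack `H x W x 3` arrays
#' @param stage_tag `"supervised"` or `"noise2noise"`
#' @param meta list of provenance fields (source frame indices, drawn
#'   read-noise SD, crop offsets)
#' @return a list of class `"training_pair"`
#' @export
training_pair <- function(input_stack, target_stack,
                          stage_tag = c("supervised", "noise2noise"),
                          meta = list()) {
  stage_tag <- match.arg(stage_tag)
  if (!is.array(input_stack) || length(dim(input_stack)) != 3 ||
      dim(input_stack)[3] != 3)
    stop_invalid("input_stack must be an H x W x 3 array")
  if (!identical(dim(input_stack), dim(target_stack)))
    stop_invalid("input and target must have identical dimensions")
  structure(list(input = input_stack, target = target_stack,
                 stage_tag = stage_tag, meta = meta),
            class = "training_pair")
}

replicate3 <- function(frame) array(frame, dim = c(dim(frame), 3))

#' Build supervised noisy-stack / clean-reference pairs
#'
#' For each pair, one read-noise SD is drawn uniformly from `sd_range` and
#' shared by the pair's three frames; the reference is then corrupted three
#' times independently (same Poisson and Gaussian magnitudes within the
#' sequence) and the three corruptions are stacked as the input. The target
#' is the clean reference replicated into three channels.
#'
#' @param reference a clean reference frame (matrix) with intensities in
#'   `[0, 1]`
#' @param n_pairs number of pairs (>= 1)
#' @param noise a [noise_params()]; its `gaussian_sd` is ignored when
#'   `sd_range` is given
#' @param sd_range length-2 range from which each sequence's read-noise SD
#'   is drawn, or `NULL` to use `noise$gaussian_sd` for every pair
#' @param seed integer seed
#' @return a list of `"training_pair"` objects with `stage_tag`
#'   `"supervised"`
#' @export
make_supervised_pairs <- function(reference, n_pairs, noise,
                                  sd_range = c(0, 0.05), seed = 1) {
  reference <- as_frame_matrix(reference, "reference")
  check_scalar(n_pairs, "n_pairs", lower = 1, integer = TRUE)
  if (!inherits(noise, "noise_params")) stop_invalid("noise must be noise_params")
  if (!is.null(sd_range) &&
      (length(sd_range) != 2 || sd_range[1] > sd_range[2] || sd_range[1] < 0))
    stop_invalid("sd_range must be an increasing non-negative pair")
  p <- noise
  p$seed <- NULL
  with_seed(seed, {
    lapply(seq_len(n_pairs), function(i) {
      sd_i <- if (is.null(sd_range)) noise$gaussian_sd
              else runif(1, sd_range[1], sd_range[2])
      stack <- array(NA_real_, dim = c(dim(reference), 3))
      for (ch in 1:3) stack[, , ch] <- corrupt(reference, p, gaussian_sd = sd_i)
      training_pair(stack, replicate3(reference), "supervised",
                    meta = list(pair_id = i, gaussian_sd = sd_i))
    })
  })
}

#' Build noise-to-noise pairs from four-frame sequences
#'
#' Partitions a movie into non-overlapping windows of four consecutive
#' frames. In each window the first three frames form the input stack and
#' the fourth frame, replicated into three channels, is the target — two
#' independent noisy observations of (nearly) the same underlying signal,
#' requiring no clean data.
#'
#' @param movie a `"movie"` with at least 4 frames
#' @param max_pairs cap on the number of pairs (default: all
#'   `floor(T / 4)` windows)
#' @return a list of `"training_pair"` objects with `stage_tag`
#'   `"noise2noise"`; each pair's `meta$frames` records the four source
#'   frame indices
#' @export
make_n2n_pairs <- function(movie, max_pairs = Inf) {
  if (!inherits(movie, "movie")) stop_invalid("movie must be a movie")
  nt <- n_frames(movie)
  if (nt < 4) stop_invalid("noise-to-noise pairing needs at least 4 frames")
  n_win <- min(nt %/% 4L, max_pairs)
  lapply(seq_len(n_win), function(w) {
    i0 <- (w - 1) * 4L
    training_pair(movie[, , i0 + (1:3), drop = FALSE],
                  replicate3(movie[, , i0 + 4L]),
                  "noise2noise",
                  meta = list(pair_id = w, frames = i0 + (1:4)))
  })
}

#' Extract random aligned patches from training pairs
#'
#' Applies the same random square crop to a pair's input and target,
#' yielding `per_pair` patch pairs per source pair. Channel count and stage
#' tags are preserved; crop offsets are recorded in `meta` and reproducible
#' under the seed.
#'
#' @param pairs list of `"training_pair"` objects
#' @param patch_size side of the square patch (<= frame dimensions)
#' @param per_pair patches per source pair
#' @param seed integer seed
#' @return a list of `"training_pair"` objects of size
#'   `patch_size x patch_size x 3`
#' @export
extract_patches <- function(pairs, patch_size, per_pair = 1, seed = 1) {
  check_scalar(patch_size, "patch_size", lower = 1, integer = TRUE)
  check_scalar(per_pair, "per_pair", lower = 1, integer = TRUE)
  with_seed(seed, {
    out <- list()
    for (p in pairs) {
      d <- dim(p$input)
      if (patch_size > d[1] || patch_size > d[2])
        stop_invalid("patch_size ", patch_size, " exceeds frame size ",
                     d[1], " x ", d[2])
      for (k in seq_len(per_pair)) {
        y0 <- if (d[1] == patch_size) 1L else sample.int(d[1] - patch_size + 1, 1)
        x0 <- if (d[2] == patch_size) 1L else sample.int(d[2] - patch_size + 1, 1)
        meta <- p$meta
        meta$crop <- c(y0, x0)
        out[[length(out) + 1L]] <- training_pair(
          p$input[y0:(y0 + patch_size - 1), x0:(x0 + patch_size - 1), , drop = FALSE],
          p$target[y0:(y0 + patch_size - 1), x0:(x0 + patch_size - 1), , drop = FALSE],
          p$stage_tag, meta)
      }
    }
    out
  })
}

#' Deterministic train/validation split
#'
#' Seeded permutation of pair indices followed by a fixed fractional split,
#' so the same call always yields the same partition.
#'
#' @param pairs list of `"training_pair"` objects
#' @param val_fraction fraction held out for validation
#' @param seed integer seed
#' @return `list(train =, val =)`
#' @export
split_pairs <- function(pairs, val_fraction = 0.1, seed = 1) {
  check_scalar(val_fraction, "val_fraction", lower = 0, upper = 0.9)
  n <- length(pairs)
  if (n < 1) stop_invalid("no pairs to split")
  n_val <- floor(n * val_fraction)
  perm <- with_seed(seed, sample.int(n))
  list(train = pairs[sort(perm[seq_len(n - n_val)])],
       val = if (n_val > 0) pairs[sort(perm[(n - n_val + 1):n])] else list())
}

# stack a list of equally sized pairs into (H, W, 3, N) input/target arrays
pairs_to_arrays <- function(pairs) {
  if (length(pairs) == 0)
    return(list(input = array(0, c(0, 0, 3, 0)), target = array(0, c(0, 0, 3, 0))))
  d <- dim(pairs[[1]]$input)
  inp <- array(NA_real_, dim = c(d, length(pairs)))
  tgt <- array(NA_real_, dim = c(d, length(pairs)))
  for (i in seq_along(pairs)) {
    if (!identical(dim(pairs[[i]]$input), d))
      stop_invalid("all pairs must share identical dimensions")
    inp[, , , i] <- pairs[[i]]$input
    tgt[, , , i] <- pairs[[i]]$target
  }
  list(input = inp, target = tgt)
}

#' Serialize training pairs to a directory
#'
#' Writes each pair as two multi-page TIFFs (`pair_<id>_input.tif`,
#' `pair_<id>_target.tif`, channels as pages) plus a `manifest.csv`
#' recording stage tags, source indices and the read-noise SD used.
#'
#' @param pairs list of `"training_pair"` objects
#' @param dir output directory (created if missing)
#' @export
write_pairs <- function(pairs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- data.frame(pair_id = seq_along(pairs),
                    stage_tag = vapply(pairs, `[[`, "", "stage_tag"),
                    gaussian_sd = vapply(pairs, function(p)
                      if (is.null(p$meta$gaussian_sd)) NA_real_
                      else p$meta$gaussian_sd, 0),
                    source_frames = vapply(pairs, function(p)
                      paste(p$meta$frames, collapse = ";"), ""))
  for (i in seq_along(pairs)) {
    tiff::writeTIFF(lapply(1:3, function(ch) clip_unit(pairs[[i]]$input[, , ch])),
                    file.path(dir, sprintf("pair_%04d_input.tif", i)),
                    bits.per.sample = 16, compression = "none")
    tiff::writeTIFF(lapply(1:3, function(ch) clip_unit(pairs[[i]]$target[, , ch])),
                    file.path(dir, sprintf("pair_%04d_target.tif", i)),
                    bits.per.sample = 16, compression = "none")
  }
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
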