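#' Read a grayscale movie from a multi-page TIFF
#'
#' Accepts single- or multi-page grayscale TIFFs (8/16-bit integer or
#' float). Integer data are mapped linearly to `[0, 1]` by the bit depth
#' (the convention used by [write_movie()]); float data are taken as-is.
#' The sampling rate is not stored in the TIFF and is supplied by the
#' caller (default 40 Hz).
#'
#' @param path path to a TIFF file
#' @param rate_hz sampling rate to attach to the movie
#' @return a `"movie"`
#' @export
read_movie <- function(path, rate_hz = 40) {
  if (!file.exists(path))
    stop(errorCondition(paste0("cannot read movie: file not found: ", path),
                        class = c("caldenoise_format", "error")))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop(errorCondition(
                      paste0("cannot read movie ", path, ": ", conditionMessage(e)),
                      class = c("caldenoise_format", "error"))))
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2, TRUE)))
    stop(errorCondition(paste0("not a grayscale TIFF (multi-channel pages): ", path),
                        class = c("caldenoise_format", "error")))
  as_movie(pages, rate_hz = rate_hz)
}

#' Write a movie as a multi-page grayscale TIFF
#'
#' Intensities are clipped to `[0, 1]` and scaled linearly to the full code
#' range of the chosen bit depth (e.g. `[0, 65535]` at 16 bits);
#' uncompressed output bytes are deterministic for identical input.
#'
#' @param movie a `"movie"`
#' @param path output path
#' @param bit_depth 8, 16, or 32 (32 writes float, lossless for `[0, 1]`)
#' @export
write_movie <- function(movie, path, bit_depth = 16) {
  if (!inherits(movie, "movie")) stop_invalid("movie must be a movie")
  if (!bit_depth %in% c(8, 16, 32)) stop_invalid("bit_depth must be 8, 16, or 32")
  frames <- lapply(seq_len(n_frames(movie)),
                   function(i) clip_unit(movie[, , i]))
  ok <- tryCatch(tiff::writeTIFF(frames, path, bits.per.sample = bit_depth,
                                 compression = "none"),
                 error = function(e) stop(errorCondition(
                   paste0("cannot write movie ", path, ": ", conditionMessage(e)),
                   class = c("caldenoise_io", "error"))))
  invisible(path)
}

#' Read / write an ROI mask
#'
#' Masks are single-page TIFFs; on reading, pixels above `threshold` are
#' `TRUE`.
#'
#' @param path TIFF path
#' @param threshold binarization threshold in `[0, 1]`
#' @return a logical matrix
#' @export
read_mask <- function(path, threshold = 0.5) {
  m <- read_movie(path, rate_hz = 1)
  m[, , 1] > threshold
}

#' @rdname read_mask
#' @param mask a logical (or 0/1) matrix
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)),
                  path, bits.per.sample = 8, compression = "none")
  invisible(path)
}

#' Write fluorescence traces as CSV
#'
#' Long format with columns `frame_index, time_s, cell_id, value`.
#'
#' @param traces an `n_frames x n_cells` matrix
#' @param rate_hz sampling rate used to derive `time_s`
#' @param path output CSV path
#' @export
write_traces <- function(traces, rate_hz, path) {
  nt <- nrow(traces)
  df <- data.frame(
    frame_index = rep(seq_len(nt), ncol(traces)),
    time_s = rep((seq_len(nt) - 1) / rate_hz, ncol(traces)),
    cell_id = rep(seq_len(ncol(traces)), each = nt),
    value = as.vector(traces))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a nested run configuration (YAML)
#'
#' @param path YAML file path
#' @return a nested list
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop(errorCondition(paste0("config not found: ", path),
                        class = c("caldenoise_format", "error")))
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @param config a nested list
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
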