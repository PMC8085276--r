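#' Configuration of the residual spatiotemporal denoising network
#'
#' The network is a plain stack of `depth` same-padded convolutions with
#' 3 x 3 x c kernels and leaky-ReLU activations (no normalization layers):
#' the first layer maps the `channels` input frames to
#' `first_layer_filters` feature maps, the hidden layers carry
#' `hidden_filters` maps, and the last layer (linear, no activation) maps
#' back to `channels` output maps. The network predicts the residual noise
#' of a 3-frame stack; the clean estimate is input minus residual.
#'
#' @param depth number of convolution layers (>= 3)
#' @param first_layer_filters filters in layer 1
#' @param hidden_filters filters in layers `2 .. depth-1`
#' @param kernel_size spatial kernel side; only 3 is implemented
#' @param channels temporal stack depth c (fixed contract: 3)
#' @param lrelu_slope negative slope of the leaky ReLU, in (0, 1)
#' @return a list of class `"model_config"`
#' @export
model_config <- function(depth = 20, first_layer_filters = 128,
                         hidden_filters = 64, kernel_size = 3, channels = 3,
                         lrelu_slope = 0.1) {
  check_scalar(depth, "depth", lower = 3, integer = TRUE)
  check_scalar(first_layer_filters, "first_layer_filters", lower = 1, integer = TRUE)
  check_scalar(hidden_filters, "hidden_filters", lower = 1, integer = TRUE)
  if (kernel_size != 3) stop_invalid("only kernel_size = 3 is implemented")
  if (channels != 3) stop_invalid("the stack depth (channels) is fixed at 3")
  check_scalar(lrelu_slope, "lrelu_slope", lower = 1e-9, upper = 1 - 1e-9)
  structure(as.list(environment()), class = "model_config")
}

# output channel count of each layer
filter_plan <- function(config) {
  c(config$first_layer_filters,
    rep(config$hidden_filters, config$depth - 2), config$channels)
}

#' Build an untrained network
#'
#' Weights use fan-in variance scaling adapted to the leaky ReLU,
#' `sd = sqrt(2 / ((1 + slope^2) * fan_in))`; biases start at zero. The
#' final (residual-head) layer starts at zero so the untrained network
#' predicts a zero residual — the standard residual-branch initialization,
#' which makes early training stable at a small constant learning rate.
#'
#' Each layer's weights are stored as a `(9 * c_in) x c_out` matrix whose
#' row `(r - 1) * c_in + c` holds kernel offset `r` (column-major over the
#' 3 x 3 window) for input channel `c`; see [kernel_weights()].
#'
#' @param config a [model_config()]
#' @param seed integer seed for the weight draw
#' @return a list of class `"denoise_model"` with elements `config`,
#'   `weights`, `biases`, `provenance` (`"untrained"`), `seed`
#' @export
build_model <- function(config = model_config(), seed = 1) {
  if (!inherits(config, "model_config")) stop_invalid("config must be a model_config")
  plan <- filter_plan(config)
  c_in <- c(config$channels, plan[-length(plan)])
  with_seed(seed, {
    weights <- vector("list", config$depth)
    biases <- vector("list", config$depth)
    for (l in seq_len(config$depth)) {
      fan_in <- 9 * c_in[l]
      sdw <- sqrt(2 / ((1 + config$lrelu_slope^2) * fan_in))
      weights[[l]] <- if (l == config$depth)
        matrix(0, fan_in, plan[l])
      else matrix(rnorm(fan_in * plan[l], 0, sdw), fan_in, plan[l])
      biases[[l]] <- rep(0, plan[l])
    }
    structure(list(config = config, weights = weights, biases = biases,
                   provenance = "untrained", seed = seed),
              class = "denoise_model")
  })
}

#' @export
print.denoise_model <- function(x, ...) {
  cat(sprintf("denoise_model: %d layers, filters [%s], %s, %s parameters\n",
              x$config$depth,
              paste(filter_plan(x$config), collapse = ", "),
              x$provenance, format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#' @param model a `"denoise_model"`
#' @export
n_parameters <- function(model) {
  sum(vapply(model$weights, length, 0L)) + sum(vapply(model$biases, length, 0L))
}

#' Convert a 4-D kernel array to the packed weight-matrix layout
#'
#' Utility for constructing layers with hand-specified kernels (e.g. a box
#' filter) in tests and examples. `kernels[ky, kx, c_in, c_out]` follows the
#' cross-correlation convention: the tap at `(ky, kx)` reads the input at
#' offset `(ky - 2, kx - 2)` from the output pixel.
#'
#' @param kernels a `3 x 3 x c_in x c_out` array
#' @return a `(9 * c_in) x c_out` weight matrix
#' @export
kernel_weights <- function(kernels) {
  d <- dim(kernels)
  if (length(d) != 4 || d[1] != 3 || d[2] != 3)
    stop_invalid("kernels must be 3 x 3 x c_in x c_out")
  W <- matrix(NA_real_, 9 * d[3], d[4])
  for (kx in 1:3) for (ky in 1:3) for (ci in seq_len(d[3])) {
    r <- (kx - 1) * 3 + (ky - 1)
    W[r * d[3] + ci, ] <- kernels[ky, kx, ci, ]
  }
  W
}

check_stack <- function(stack, config) {
  if (!is.array(stack) || length(dim(stack)) != 3)
    stop_invalid("stack must be an H x W x 3 array")
  d <- dim(stack)
  if (d[3] != config$channels)
    stop_invalid("stack must have ", config$channels, " channels, got ", d[3])
  if (d[1] < config$kernel_size || d[2] < config$kernel_size)
    stop_invalid("stack must be at least ", config$kernel_size, " pixels per side")
  d
}

#' Predict the residual noise of a 3-frame stack
#'
#' Pure deterministic function of the weights and input; no clipping. The
#' spatial dimensions are preserved by same (zero) padding.
#'
#' @param model a `"denoise_model"`
#' @param stack an `H x W x 3` array (three consecutive frames as channels)
#' @return an `H x W x 3` residual array
#' @export
predict_residual <- function(model, stack) {
  d <- check_stack(stack, model$config)
  res <- cpp_forward(model$weights, model$biases, as.numeric(stack),
                     d[1], d[2], model$config$lrelu_slope)
  array(res, dim = d)
}

#' Denoise a 3-frame stack into one clean frame
#'
#' Subtracts the predicted residual from the stack per channel, averages the
#' three resulting channel estimates into a single frame, and clips to
#' `[0, 1]`.
#'
#' @inheritParams predict_residual
#' @return an `H x W` matrix
#' @export
denoise_stack <- function(model, stack) {
  res <- predict_residual(model, stack)
  clip_unit(rowMeans(stack - res, dims = 2))
}

#' Denoise every frame of a movie
#'
#' For frame `n` the network sees the stack `(n-1, n, n+1)`; at the
#' sequence edges the first/last frame is replicated, so the output has
#' exactly as many frames as the input.
#'
#' @param model a `"denoise_model"`
#' @param movie a `"movie"`
#' @return the denoised `"movie"`
#' @export
denoise_movie <- function(model, movie) {
  if (!inherits(movie, "movie")) stop_invalid("movie must be a movie")
  nt <- n_frames(movie)
  d <- dim(movie)
  prev <- c(1, seq_len(nt - 1))
  nxt <- c(seq_len(nt - 1) + 1, nt)
  stacks <- array(NA_real_, dim = c(d[1], d[2], 3, nt))
  stacks[, , 1, ] <- movie[, , prev]
  stacks[, , 2, ] <- movie[, , seq_len(nt)]
  stacks[, , 3, ] <- movie[, , nxt]
  res <- array(cpp_forward(model$weights, model$biases, as.numeric(stacks),
                           d[1], d[2], model$config$lrelu_slope),
               dim = dim(stacks))
  out <- array(NA_real_, dim = d)
  den <- stacks - res
  for (i in seq_len(nt)) out[, , i] <- rowMeans(den[, , , i], dims = 2)
  as_movie(clip_unit(out), rate_hz = attr(movie, "rate_hz"))
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single archive holding the configuration, weights,
#' provenance tag and training seed; loading reproduces inference
#' bit-exactly.
#'
#' @param model a `"denoise_model"`
#' @param path file path (conventionally `.ckpt.rds`)
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "denoise_model")) stop_invalid("model must be a denoise_model")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_invalid("checkpoint not found: ", path)
  model <- readRDS(path)
  if (!inherits(model, "denoise_model"))
    stop_invalid("file is not a denoise_model checkpoint: ", path)
  model
}
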