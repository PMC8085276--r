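# small reusable builders for unit tests

tiny_model_config <- function(...) {
  model_config(depth = 3, first_layer_filters = 4, hidden_filters = 4, ...)
}

zero_weights <- function(model) {
  for (l in seq_along(model$weights)) {
    model$weights[[l]][] <- 0
    model$biases[[l]][] <- 0
  }
  model
}

random_stack <- function(H = 16, W = 16, seed = 1) {
  set.seed(seed)
  array(runif(H * W * 3), c(H, W, 3))
}

flat_movie <- function(value, H = 16, W = 16, nt = 8, rate = 40) {
  as_movie(array(value, c(H, W, nt)), rate_hz = rate)
}

# direct (slow) zero-padded 3x3 cross-correlation, the conv oracle
conv3_oracle <- function(input, kernels, bias = NULL) {
  d <- dim(input)
  cin <- dim(kernels)[3]; cout <- dim(kernels)[4]
  pad <- array(0, c(d[1] + 2, d[2] + 2, cin))
  pad[2:(d[1] + 1), 2:(d[2] + 1), ] <- input
  out <- array(0, c(d[1], d[2], cout))
  for (co in seq_len(cout)) for (ci in seq_len(cin))
    for (ky in 1:3) for (kx in 1:3)
      out[, , co] <- out[, , co] + kernels[ky, kx, ci, co] *
        pad[(ky - 1) + seq_len(d[1]), (kx - 1) + seq_len(d[2]), ci]
  if (!is.null(bias)) for (co in seq_len(cout)) out[, , co] <- out[, , co] + bias[co]
  out
}

# hand-made trace object for temporal-metric tests
make_trace <- function(dff, rate_hz = 40, f0 = 1) {
  structure(list(f = f0 * (1 + dff), rate_hz = rate_hz, f0 = f0, dff = dff),
            class = "trace")
}
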