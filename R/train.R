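#' Training configuration
#'
#' Hyperparameters for the two-stage training procedure. The learning rate
#' is constant across epochs (no schedule); the optimizer is Adam with the
#' standard moment decays. `epochs_initial` applies to supervised
#' pre-training, `epochs_finetune` to noise-to-noise fine-tuning.
#'
#' @param learning_rate constant Adam step size
#' @param epochs_initial epochs of supervised pre-training
#' @param epochs_finetune epochs of noise-to-noise fine-tuning
#' @param batch_size mini-batch size in patches
#' @param beta1,beta2,eps Adam moment decays and stabilizer
#' @param validation_fraction fraction of pairs held out per stage for the
#'   validation curve and best-checkpoint selection
#' @param seed integer seed controlling the split and batch shuffling
#' @param checkpoint_dir optional directory; when set, each stage writes its
#'   best checkpoint and a `loss_history.csv` there
#' @param verbose print a line per epoch
#' @return a list of class `"train_config"`
#' @export
train_config <- function(learning_rate = 1e-4, epochs_initial = 50,
                         epochs_finetune = 10, batch_size = 32,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         validation_fraction = 0.1, seed = 1,
                         checkpoint_dir = NULL, verbose = FALSE) {
  check_scalar(learning_rate, "learning_rate", lower = .Machine$double.xmin)
  check_scalar(epochs_initial, "epochs_initial", lower = 1, integer = TRUE)
  check_scalar(epochs_finetune, "epochs_finetune", lower = 1, integer = TRUE)
  check_scalar(batch_size, "batch_size", lower = 1, integer = TRUE)
  check_scalar(validation_fraction, "validation_fraction", lower = 0, upper = 0.5)
  structure(as.list(environment()), class = "train_config")
}

#' Residual L2 loss
#'
#' The network is trained to predict the noise, so the desired residual of
#' a pair is `input_stack - target_stack` (per channel) and the loss is the
#' mean squared difference between the predicted and desired residuals over
#' all pixels and channels.
#'
#' @param predicted,input_stack,target_stack `H x W x 3` arrays of matching
#'   shape
#' @return a non-negative scalar
#' @export
residual_loss <- function(predicted, input_stack, target_stack) {
  if (!identical(dim(predicted), dim(input_stack)) ||
      !identical(dim(predicted), dim(target_stack)))
    stop_invalid("predicted, input and target must have identical shapes")
  mean((predicted - (input_stack - target_stack))^2)
}

train_stage <- function(model, pairs, config, stage, epochs) {
  if (!inherits(model, "denoise_model")) stop_invalid("model must be a denoise_model")
  if (!inherits(config, "train_config")) stop_invalid("config must be a train_config")
  if (length(pairs) < 1) stop_invalid("training requires at least one pair")
  split <- split_pairs(pairs, config$validation_fraction, seed = config$seed)
  tr <- pairs_to_arrays(split$train)
  va <- pairs_to_arrays(split$val)
  d <- dim(tr$input)
  n_train <- d[4]
  order <- with_seed(config$seed + 1L,
                     vapply(seq_len(epochs), function(e) sample.int(n_train),
                            integer(n_train)))
  order <- matrix(as.integer(order), nrow = n_train)
  has_val <- length(split$val) > 0
  fit <- cpp_train(model$weights, model$biases,
                   as.numeric(tr$input), as.numeric(tr$target),
                   if (has_val) as.numeric(va$input) else numeric(0),
                   if (has_val) as.numeric(va$target) else numeric(0),
                   order, d[1], d[2], config$batch_size,
                   config$learning_rate, config$beta1, config$beta2,
                   config$eps, model$config$lrelu_slope,
                   track_best = has_val, verbose = config$verbose)
  model$weights <- fit$W
  model$biases <- fit$b
  records <- data.frame(stage = stage, epoch = seq_len(epochs),
                        train_loss = fit$train_loss,
                        val_loss = fit$val_loss)
  if (!is.null(config$checkpoint_dir)) {
    dir.create(config$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    save_model(model, file.path(config$checkpoint_dir,
                                paste0(stage, "_best.ckpt.rds")))
    hist_path <- file.path(config$checkpoint_dir, "loss_history.csv")
    write.csv(if (file.exists(hist_path))
                rbind(read.csv(hist_path), records) else records,
              hist_path, row.names = FALSE)
  }
  list(model = model, records = records, best_epoch = fit$best_epoch)
}

#' Supervised pre-training on synthetic pairs
#'
#' Runs `epochs_initial` epochs of Adam on the residual L2 loss over
#' shuffled mini-batches of supervised pairs, recording per-epoch mean
#' training and validation losses. The returned model carries the weights of
#' the epoch with the lowest validation loss (best checkpoint) and
#' provenance `"initial-trained"`. Fully reproducible given the seeds.
#'
#' @param model an untrained (or compatible) `"denoise_model"`
#' @param pairs supervised training pairs of identical patch size
#' @param config a [train_config()]
#' @return `list(model =, records =)` where `records` is a data frame with
#'   columns `stage, epoch, train_loss, val_loss`
#' @export
train_initial <- function(model, pairs, config = train_config()) {
  out <- train_stage(model, pairs, config, "initial", config$epochs_initial)
  out$model$provenance <- "initial-trained"
  out[c("model", "records")]
}

#' Model-blind noise-to-noise fine-tuning
#'
#' Re-trains the whole network (no layer freezing, fresh optimizer state)
#' on noise-to-noise pairs built from raw four-frame sequences, starting
#' from the supervised weights. Because the targets are themselves noisy,
#' the converged loss is floored near the target-noise variance and should
#' not be expected to fall much below it.
#'
#' @param model a `"denoise_model"` with provenance `"initial-trained"` (or
#'   `"fine-tuned"`, for continued fine-tuning)
#' @param pairs noise-to-noise training pairs
#' @param config a [train_config()]
#' @return `list(model =, records =)` with provenance `"fine-tuned"`
#' @export
finetune <- function(model, pairs, config = train_config()) {
  if (!inherits(model, "denoise_model")) stop_invalid("model must be a denoise_model")
  if (!model$provenance %in% c("initial-trained", "fine-tuned"))
    stop(errorCondition(
      "fine-tuning requires an initially trained model (provenance 'initial-trained')",
      class = c("caldenoise_precondition", "error")))
  out <- train_stage(model, pairs, config, "finetune", config$epochs_finetune)
  out$model$provenance <- "fine-tuned"
  out[c("model", "records")]
}

#' Evaluate a model on a set of pairs without updating weights
#'
#' Deterministic given the weights; returns a single loss record.
#'
#' @param model a `"denoise_model"`
#' @param pairs non-empty list of pairs of identical size
#' @param stage,epoch bookkeeping fields for the record
#' @return a one-row data frame `stage, epoch, train_loss, val_loss` where
#'   `val_loss` holds the evaluated mean residual loss
#' @export
evaluate_epoch <- function(model, pairs, stage = "eval", epoch = NA_integer_) {
  if (length(pairs) < 1) stop_invalid("evaluation requires at least one pair")
  arr <- pairs_to_arrays(pairs)
  d <- dim(arr$input)
  loss <- cpp_dataset_loss(model$weights, model$biases,
                           as.numeric(arr$input), as.numeric(arr$target),
                           d[1], d[2], model$config$lrelu_slope, 16L)
  data.frame(stage = stage, epoch = epoch,
             train_loss = NA_real_, val_loss = loss)
}
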