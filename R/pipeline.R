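#' Default end-to-end run configuration
#'
#' Nested configuration for [run_pipeline()], pre-filled with the package's
#' desk-scale study conditions: a 128 x 128, 40 Hz fixed-FOV movie with 10
#' cells; corruption with shot noise of magnitude 1 (photon budget 1000)
#' and a read-noise SD drawn once per 4-frame sequence from U(0, 0.05); a
#' reference averaged from the first 100 corrupted frames; 400 supervised
#' 32 x 32 patch pairs; the 20-layer network; 15 supervised + 5
#' noise-to-noise epochs of Adam at a constant 1e-4 (batch size 4, chosen
#' so a single-CPU run gets many optimizer updates per unit compute). Every
#' stage derives
#' its own seed from the global `seed`, so a run is fully reproducible.
#'
#' @param seed global integer seed
#' @return a nested list of class `"run_config"`
#' @export
run_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    geometry = list(height = 128, width = 128, n_frames = 480, rate_hz = 40),
    scene = list(n_cells = 10, cell_radius_px = 4, background_level = 0.1,
                 soma_brightness = 0.4, event_rate_hz = 0.2,
                 rise_tau_s = 0.05, decay_tau_s = 0.5,
                 amplitude_range = c(0.1, 0.4)),
    noise = list(poisson_magnitude = 1, photon_budget = 1000,
                 sd_range = c(0, 0.05)),
    dataset = list(reference_frames = 100, n_supervised_sequences = 100,
                   patch_size = 32, patches_per_sequence = 4,
                   n2n_patches_per_pair = 2, heldout_frames = 24),
    model = list(depth = 20, first_layer_filters = 128, hidden_filters = 64,
                 lrelu_slope = 0.1),
    training = list(learning_rate = 1e-4, epochs_initial = 15,
                    epochs_finetune = 5, batch_size = 4,
                    validation_fraction = 0.1),
    evaluation = list(trace_segment_frames = 120)
  ), class = "run_config")
}

derive_seed <- function(seed, k) (as.integer(seed) * 101L + k * 7919L) %% 2000000000L

#' Run the full simulate / train / fine-tune / denoise / evaluate workflow
#'
#' Executes, in order: ground-truth simulation, corruption, reference
#' averaging, supervised patch-pair construction, supervised pre-training,
#' noise-to-noise pairing and fine-tuning, denoising of a held-out frame
#' segment, and spatial plus temporal quality evaluation. When `out_dir` is
#' given, the resolved configuration (YAML), loss history (CSV), per-frame
#' quality (CSV), traces (CSV) and a run summary (JSON) are written next to
#' each other.
#'
#' Frame budget within the simulated movie: the first
#' `dataset$reference_frames` frames build the reference, the last
#' `dataset$heldout_frames` frames are held out for evaluation, and the
#' frames in between supply the non-overlapping 4-frame noise-to-noise
#' windows.
#'
#' @param config a [run_config()]
#' @param out_dir optional output directory
#' @param verbose print stage progress
#' @return a list with elements `model` (fine-tuned), `model_initial` (after
#'   supervised pre-training only), `records` (loss history), `quality_noisy`,
#'   `quality_denoised`, `snr` (per-cell transient SNR, raw vs denoised),
#'   `summary` (flat named list of headline numbers), plus the simulated,
#'   corrupted and held-out movies for downstream analysis
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL, verbose = FALSE) {
  if (!inherits(config, "run_config") && !is.list(config))
    stop_invalid("config must be a run_config")
  cfg <- config
  g <- cfg$geometry
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  say("simulating %d x %d ground truth, %d frames", g$height, g$width, g$n_frames)
  sim <- stage("simulate", {
    sc <- do.call(scene_config, c(cfg$scene, list(seed = derive_seed(cfg$seed, 1L))))
    generate_ground_truth_movie(sc, g$n_frames, g$rate_hz, g$height, g$width)
  })

  say("corrupting movie")
  noisy <- stage("corrupt", {
    np <- noise_params(cfg$noise$poisson_magnitude, cfg$noise$photon_budget,
                       gaussian_sd = 0, seed = derive_seed(cfg$seed, 2L))
    n_win <- ceiling(g$n_frames / 4)
    sds <- with_seed(derive_seed(cfg$seed, 3L),
                     rep(runif(n_win, cfg$noise$sd_range[1], cfg$noise$sd_range[2]),
                         each = 4)[seq_len(g$n_frames)])
    corrupt_movie(sim$movie, np, gaussian_sds = sds)
  })

  say("building reference from %d frames", cfg$dataset$reference_frames)
  reference <- stage("reference", {
    average_reference(subset_frames(noisy, seq_len(cfg$dataset$reference_frames)))
  })

  say("building %d supervised sequences -> %d patches",
      cfg$dataset$n_supervised_sequences,
      cfg$dataset$n_supervised_sequences * cfg$dataset$patches_per_sequence)
  sup_patches <- stage("supervised-pairs", {
    np <- noise_params(cfg$noise$poisson_magnitude, cfg$noise$photon_budget,
                       gaussian_sd = 0)
    sup <- make_supervised_pairs(clip_unit(reference),
                                 cfg$dataset$n_supervised_sequences, np,
                                 sd_range = cfg$noise$sd_range,
                                 seed = derive_seed(cfg$seed, 4L))
    extract_patches(sup, cfg$dataset$patch_size,
                    cfg$dataset$patches_per_sequence,
                    seed = derive_seed(cfg$seed, 5L))
  })

  tc <- train_config(learning_rate = cfg$training$learning_rate,
                     epochs_initial = cfg$training$epochs_initial,
                     epochs_finetune = cfg$training$epochs_finetune,
                     batch_size = cfg$training$batch_size,
                     validation_fraction = cfg$training$validation_fraction,
                     seed = derive_seed(cfg$seed, 6L),
                     checkpoint_dir = if (is.null(out_dir)) NULL
                                      else file.path(out_dir, "checkpoints"),
                     verbose = verbose)

  say("supervised pre-training (%d epochs)", tc$epochs_initial)
  model <- stage("build-model", {
    mc <- model_config(depth = cfg$model$depth,
                       first_layer_filters = cfg$model$first_layer_filters,
                       hidden_filters = cfg$model$hidden_filters,
                       lrelu_slope = cfg$model$lrelu_slope)
    build_model(mc, seed = derive_seed(cfg$seed, 7L))
  })
  init <- stage("train-initial", train_initial(model, sup_patches, tc))

  say("noise-to-noise fine-tuning (%d epochs)", tc$epochs_finetune)
  n2n_range <- (cfg$dataset$reference_frames + 1):
    (g$n_frames - cfg$dataset$heldout_frames)
  fine <- stage("finetune", {
    n2n <- make_n2n_pairs(subset_frames(noisy, n2n_range))
    n2n_patches <- extract_patches(n2n, cfg$dataset$patch_size,
                                   cfg$dataset$n2n_patches_per_pair,
                                   seed = derive_seed(cfg$seed, 8L))
    finetune(init$model, n2n_patches, tc)
  })
  records <- rbind(init$records, fine$records)

  say("denoising held-out frames")
  heldout_idx <- (g$n_frames - cfg$dataset$heldout_frames + 1):g$n_frames
  clean_held <- subset_frames(sim$movie, heldout_idx)
  noisy_held <- subset_frames(noisy, heldout_idx)
  denoised_held <- stage("denoise", denoise_movie(fine$model, noisy_held))

  say("evaluating spatial quality")
  q_noisy <- stage("quality", movie_quality(clean_held, noisy_held))
  q_den <- stage("quality", movie_quality(clean_held, denoised_held))

  say("evaluating traces")
  snr <- stage("traces", {
    seg_len <- min(cfg$evaluation$trace_segment_frames, g$n_frames)
    seg <- (g$n_frames - seg_len + 1):g$n_frames
    noisy_seg <- subset_frames(noisy, seg)
    den_seg <- denoise_movie(fine$model, noisy_seg)
    wb <- window_frames(2, g$rate_hz)
    wp <- window_frames(0.075, g$rate_hz)
    first_ok <- wb + (wp - 1) %/% 2 + 1
    n_cells <- dim(sim$masks)[3]
    out <- data.frame(cell = seq_len(n_cells), snr_raw = NA_real_,
                      snr_denoised = NA_real_)
    for (ci in seq_len(n_cells)) {
      res <- tryCatch({
        tr_raw <- extract_trace(noisy_seg, sim$masks[, , ci])
        tr_den <- extract_trace(den_seg, sim$masks[, , ci])
        pk <- find_peak(tr_den, from = min(first_ok, seg_len), to = seg_len)
        w <- transient_window(pk)
        c(transient_snr(tr_raw, w), transient_snr(tr_den, w))
      }, error = function(e) c(NA_real_, NA_real_))
      out$snr_raw[ci] <- res[1]
      out$snr_denoised[ci] <- res[2]
    }
    out
  })

  summary <- list(
    psnr_noisy_db = q_noisy$summary$mean[1],
    psnr_denoised_db = q_den$summary$mean[1],
    ssim_noisy = q_noisy$summary$mean[2],
    ssim_denoised = q_den$summary$mean[2],
    final_train_loss_initial = init$records$train_loss[nrow(init$records)],
    final_train_loss_finetune = fine$records$train_loss[nrow(fine$records)],
    n_heldout_frames = length(heldout_idx))
  # transient SNR is undefined when no trace admits the baseline window
  if (any(is.finite(snr$snr_raw))) {
    summary$median_snr_raw <- stats::median(snr$snr_raw, na.rm = TRUE)
    summary$median_snr_denoised <- stats::median(snr$snr_denoised, na.rm = TRUE)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_run_config(unclass(cfg), file.path(out_dir, "config_resolved.yaml"))
    write.csv(records, file.path(out_dir, "loss_history.csv"), row.names = FALSE)
    write.csv(cbind(q_noisy$per_frame,
                    psnr_denoised = q_den$per_frame$psnr_db,
                    ssim_denoised = q_den$per_frame$ssim),
              file.path(out_dir, "quality.csv"), row.names = FALSE)
    write.csv(snr, file.path(out_dir, "transient_snr.csv"), row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    write_movie(denoised_held, file.path(out_dir, "denoised_heldout.tif"))
  }

  invisible(list(model = fine$model, model_initial = init$model,
                 records = records, noisy = noisy,
                 quality_noisy = q_noisy, quality_denoised = q_den,
                 snr = snr, summary = summary,
                 heldout = list(clean = clean_held, noisy = noisy_held,
                                denoised = denoised_held),
                 sim = sim, reference = reference))
}
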