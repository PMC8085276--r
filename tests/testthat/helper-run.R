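# the shared desk-scale two-stage training run (simulate -> corrupt ->
# supervised pre-training -> noise-to-noise fine-tuning -> denoise), computed
# once per session and reused by the tests that examine its outputs
desk_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_pipeline(run_config(seed = 1))
    cache
  }
})

# elastic-motion companion experiment: per-frame nonuniform deformation of a
# clean segment, corrupted and denoised with the trained model from desk_run()
motion_run <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    run <- desk_run()
    seg <- subset_frames(run$sim$movie, 201:360)
    # temporally sparse nonuniform deformations: spike-like artifacts
    mot <- motion_params(n_frames(seg), kind = "elastic", max_shift = 2,
                         grid = 4, frame_prob = 0.2, seed = 11)
    moved <- add_motion(seg, mot, fill = 0.1)
    noisy <- corrupt_movie(moved, noise_params(1, 1000, gaussian_sd = 0.02,
                                               seed = 12))
    denoised <- denoise_movie(run$model, noisy)
    cache <<- list(clean = seg, moved = moved, noisy = noisy,
                   denoised = denoised, masks = run$sim$masks,
                   rate_hz = 40)
    cache
  }
})
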