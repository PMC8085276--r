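test_that("supervised pairs replicate the reference and share one noise level", {
  ref <- random_stack(24, 24, seed = 4)[, , 1] * 0.8
  clean_np <- noise_params(poisson_magnitude = 0, gaussian_sd = 0)
  pairs <- make_supervised_pairs(ref, 3, clean_np, sd_range = NULL, seed = 2)
  for (p in pairs) {
    expect_identical(p$stage_tag, "supervised")
    for (ch in 1:3) {
      expect_equal(p$input[, , ch], ref, tolerance = 0)   # identity corruption
      expect_equal(p$target[, , ch], ref, tolerance = 0)  # replicated target
    }
  }
  noisy_np <- noise_params(poisson_magnitude = 1, photon_budget = 1000)
  pairs <- make_supervised_pairs(ref, 5, noisy_np, sd_range = c(0, 0.05), seed = 3)
  sds <- vapply(pairs, function(p) p$meta$gaussian_sd, 0)
  expect_true(all(sds > 0 & sds < 0.05))
  expect_equal(length(unique(sds)), 5L)  # re-drawn per sequence
  for (p in pairs) {
    # channels are three independent corruptions: pairwise distinct
    expect_gt(max(abs(p$input[, , 1] - p$input[, , 2])), 0)
    expect_gt(max(abs(p$input[, , 2] - p$input[, , 3])), 0)
    expect_identical(p$target[, , 1], p$target[, , 2])
    expect_identical(p$target[, , 2], p$target[, , 3])
  }
  expect_error(make_supervised_pairs(ref, 0, noisy_np),
               class = "caldenoise_invalid_argument")
})

test_that("supervised corruption is mean-preserving around the target", {
  ref <- matrix(0.4, 16, 16)
  np <- noise_params(poisson_magnitude = 1, photon_budget = 800)
  pairs <- make_supervised_pairs(ref, 120, np, sd_range = c(0, 0.05), seed = 9)
  grand_mean <- mean(vapply(pairs, function(p) mean(p$input), 0))
  tv <- 0.4 / 800 + 0.05^2 / 3
  expect_lt(abs(grand_mean - 0.4), 4 * sqrt(tv / (120 * 3 * 256)))
})

test_that("noise-to-noise pairing partitions the movie into 4-frame windows", {
  mv <- as_movie(array(seq_len(8 * 8 * 17) / (8 * 8 * 17), c(8, 8, 17)), 40)
  pairs <- make_n2n_pairs(mv)
  expect_length(pairs, 4L)  # floor(17 / 4) non-overlapping windows
  for (w in seq_along(pairs)) {
    p <- pairs[[w]]
    expect_identical(p$stage_tag, "noise2noise")
    expect_identical(p$meta$frames, (w - 1) * 4L + (1:4))
    for (ch in 1:3)
      expect_equal(p$input[, , ch], mv[, , (w - 1) * 4 + ch], tolerance = 0)
    expect_equal(p$target[, , 1], mv[, , (w - 1) * 4 + 4], tolerance = 0)
  }
  # all four source indices are distinct within every window
  expect_true(all(vapply(pairs, function(p) length(unique(p$meta$frames)) == 4L, TRUE)))

  single <- make_n2n_pairs(subset_frames(mv, 1:4))
  expect_length(single, 1L)
  expect_error(make_n2n_pairs(subset_frames(mv, 1:3)),
               class = "caldenoise_invalid_argument")
})

test_that("paper-scale pair counts are reachable", {
  mv <- flat_movie(0.5, 8, 8, nt = 3600)
  expect_length(make_n2n_pairs(mv), 900L)
  ref <- matrix(0.5, 8, 8)
  np <- noise_params(poisson_magnitude = 0, gaussian_sd = 0)
  expect_length(make_supervised_pairs(ref, 1200, np, sd_range = NULL), 1200L)
})

test_that("patch extraction keeps alignment, shapes, and is seeded", {
  ref <- random_stack(32, 40, seed = 6)[, , 1]
  np <- noise_params(poisson_magnitude = 0, gaussian_sd = 0.03)
  pairs <- make_supervised_pairs(ref, 2, np, sd_range = NULL, seed = 5)
  full <- extract_patches(pairs, patch_size = 32, per_pair = 1, seed = 1)
  expect_length(full, 2L)
  expect_equal(dim(full[[1]]$input), c(32L, 32L, 3L))

  pat <- extract_patches(pairs, 16, per_pair = 4, seed = 2)
  expect_length(pat, 8L)
  for (p in pat) {
    expect_equal(dim(p$input), c(16L, 16L, 3L))
    expect_equal(dim(p$target), c(16L, 16L, 3L))
    y0 <- p$meta$crop[1]; x0 <- p$meta$crop[2]
    src <- pairs[[p$meta$pair_id]]
    expect_equal(p$input, src$input[y0:(y0 + 15), x0:(x0 + 15), , drop = FALSE],
                 tolerance = 0)
    expect_equal(p$target, src$target[y0:(y0 + 15), x0:(x0 + 15), , drop = FALSE],
                 tolerance = 0)
  }
  expect_identical(extract_patches(pairs, 16, 4, seed = 2), pat)
  expect_error(extract_patches(pairs, 64, 1), class = "caldenoise_invalid_argument")
})

test_that("the train/validation split is a seeded deterministic partition", {
  ref <- matrix(0.5, 8, 8)
  np <- noise_params(poisson_magnitude = 0, gaussian_sd = 0.01)
  pairs <- make_supervised_pairs(ref, 20, np, seed = 1)
  s1 <- split_pairs(pairs, 0.1, seed = 3)
  s2 <- split_pairs(pairs, 0.1, seed = 3)
  expect_length(s1$train, 18L)
  expect_length(s1$val, 2L)
  expect_identical(vapply(s1$val, function(p) p$meta$pair_id, 0L),
                   vapply(s2$val, function(p) p$meta$pair_id, 0L))
})

test_that("pair serialization writes TIFFs and a manifest", {
  dir <- withr::local_tempdir()
  ref <- random_stack(12, 12, seed = 8)[, , 1]
  np <- noise_params(poisson_magnitude = 0, gaussian_sd = 0.02)
  pairs <- make_supervised_pairs(ref, 2, np, seed = 4)
  man <- write_pairs(pairs, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_length(list.files(dir, pattern = "\\.tif$"), 4L)
  expect_equal(nrow(man), 2L)
  expect_true(all(man$stage_tag == "supervised"))
})
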