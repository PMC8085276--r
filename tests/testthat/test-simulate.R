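test_that("an empty scene produces the constant background image", {
  sc <- scene_config(n_cells = 0, background_level = 0.12, seed = 3)
  out <- generate_ground_truth_movie(sc, n_frames = 5, rate_hz = 40,
                                     height = 32, width = 24)
  expect_equal(dim(out$movie), c(32L, 24L, 5L))
  expect_true(all(out$movie == 0.12))
  expect_equal(dim(out$masks)[3], 0L)
})

test_that("the full-scale field of view and rate are accepted", {
  sc <- scene_config(n_cells = 5, seed = 2)
  out <- generate_ground_truth_movie(sc, n_frames = 2, rate_hz = 40,
                                     height = 500, width = 500)
  expect_equal(attr(out$movie, "rate_hz"), 40)
  expect_equal(dim(out$movie)[1:2], c(500L, 500L))
  expect_true(all(out$movie >= 0 & out$movie <= 1))
})

test_that("returned traces equal ROI means recomputed from the movie", {
  sc <- scene_config(n_cells = 6, event_rate_hz = 1, seed = 5)
  out <- generate_ground_truth_movie(sc, n_frames = 40, rate_hz = 40,
                                     height = 64, width = 64)
  for (ci in seq_len(6)) {
    mask <- out$masks[, , ci]
    recomputed <- vapply(seq_len(40), function(t) {
      fr <- out$movie[, , t]
      mean(fr[mask])
    }, 0)
    expect_lt(max(abs(recomputed - out$traces[, ci])), 1e-9)
  }
})

test_that("transients rise and decay with the configured kinetics", {
  tpk <- 0.05 * log1p(0.5 / 0.05)
  expect_equal(transient_kernel(tpk, 0.05, 0.5), 1, tolerance = 1e-12)  # unit peak
  k <- transient_kernel(seq(0, 3, by = 0.025), 0.05, 0.5)
  expect_lte(max(k), 1)
  expect_equal(k[1], 0)
  pk <- which.max(k)
  expect_true(all(diff(k[pk:length(k)]) <= 0))  # monotone decay after peak
})

test_that("simulation is bit-reproducible under a fixed seed and rejects bad input", {
  sc <- scene_config(n_cells = 3, cell_radius_px = 2, seed = 7)
  a <- generate_ground_truth_movie(sc, 6, 40, 32, 32)
  b <- generate_ground_truth_movie(sc, 6, 40, 32, 32)
  expect_identical(a$movie, b$movie)
  expect_identical(a$traces, b$traces)
  expect_error(generate_ground_truth_movie(sc, 0, 40, 32, 32),
               class = "caldenoise_invalid_argument")
  expect_error(generate_ground_truth_movie(sc, 5, -1, 32, 32),
               class = "caldenoise_invalid_argument")
  expect_error(generate_ground_truth_movie(sc, 5, 40, 4, 32),
               class = "caldenoise_invalid_argument")
})

test_that("corruption with zero magnitudes is the identity", {
  fr <- random_stack(16, 16, seed = 1)[, , 1]
  np <- noise_params(poisson_magnitude = 0, gaussian_sd = 0, seed = 4)
  expect_identical(corrupt(fr, np), fr)
  expect_error(corrupt(fr - 1, np), class = "caldenoise_invalid_argument")
})

test_that("corruption matches the closed-form mean and variance", {
  # constant frame: E[m] = t, Var[m] = mag^2 t / B + sd^2
  n_px <- 100000
  t_val <- 0.5
  fr <- matrix(t_val, 400, 250)
  np <- noise_params(poisson_magnitude = 1, photon_budget = 1000,
                     gaussian_sd = 0.02, seed = 99)
  m <- corrupt(fr, np)
  true_var <- t_val / 1000 + 0.02^2  # 9.0e-4
  se_mean <- sqrt(true_var / n_px)
  expect_lt(abs(mean(m) - t_val), 4 * se_mean)
  se_var <- true_var * sqrt(2 / (n_px - 1))
  expect_lt(abs(var(as.vector(m)) - true_var), 4 * se_var)
})

test_that("variance decomposes across Poisson and Gaussian settings", {
  fr <- matrix(0.3, 320, 320)
  cases <- list(c(mag = 1, sd = 0),      # shot only
                c(mag = 0, sd = 0.04),   # read only
                c(mag = 2, sd = 0.03))   # scaled shot + read
  for (cs in cases) {
    np <- noise_params(cs[["mag"]], 500, cs[["sd"]], seed = 17)
    m <- corrupt(fr, np)
    tv <- cs[["mag"]]^2 * 0.3 / 500 + cs[["sd"]]^2
    expect_lt(abs(mean(m) - 0.3), 4 * sqrt(tv / length(fr)))
    expect_lt(abs(var(as.vector(m)) - tv), 4 * tv * sqrt(2 / (length(fr) - 1)))
  }
})

test_that("frame averaging is exact on identical frames and follows 1/sqrt(N)", {
  fr <- random_stack(32, 32, seed = 2)[, , 1]
  stack100 <- array(fr, c(32, 32, 100))
  expect_equal(average_reference(stack100), fr, tolerance = 1e-12)
  expect_error(average_reference(list()), class = "caldenoise_invalid_argument")

  clean <- matrix(0.5, 128, 128)
  np <- noise_params(poisson_magnitude = 0, gaussian_sd = 0.05, seed = 31)
  mv <- as_movie(array(0.5, c(128, 128, 100)), 40)
  noisy <- corrupt_movie(mv, np)
  for (N in c(1, 10, 100)) {
    ref <- average_reference(unclass(noisy)[, , 1:N, drop = FALSE])
    rms <- sqrt(mean((ref - clean)^2))
    expect_lt(abs(rms - 0.05 / sqrt(N)), 0.3 * 0.05 / sqrt(N))
  }
})

test_that("zero motion is the identity and integer shifts are pixel-exact", {
  sc <- scene_config(n_cells = 3, cell_radius_px = 2, seed = 9)
  mv <- generate_ground_truth_movie(sc, 4, 40, 40, 40)$movie
  still <- motion_params(4, shifts = matrix(0, 4, 2))
  expect_equal(unclass(add_motion(mv, still)), unclass(mv), tolerance = 0)

  sh <- motion_params(4, shifts = matrix(rep(c(3, 0), each = 4), 4, 2))
  moved <- add_motion(mv, sh, fill = -1)
  # content moves down 3 rows; top 3 rows filled
  expect_equal(moved[4:40, , 2], mv[1:37, , 2], tolerance = 1e-12)
  expect_true(all(moved[1:3, , ] == -1))
})

test_that("nonuniform deformation displaces cells off their masks", {
  sc <- scene_config(n_cells = 4, seed = 12)
  out <- generate_ground_truth_movie(sc, 6, 40, 64, 64)
  mot <- motion_params(6, kind = "elastic", max_shift = 3, grid = 4, seed = 13)
  moved <- add_motion(out$movie, mot, fill = out$movie[1, 1, 1])
  mask <- out$masks[, , 1]
  # normalized in-mask mass: warping must change the signal under the mask
  overlap <- vapply(seq_len(6), function(t) {
    a <- out$movie[, , t][mask]; b <- moved[, , t][mask]
    sum(pmin(a, b)) / sum(a)
  }, 0)
  expect_true(any(overlap < 1 - 1e-4))
  expect_error(add_motion(out$movie, motion_params(3, seed = 1)),
               class = "caldenoise_invalid_argument")
})
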