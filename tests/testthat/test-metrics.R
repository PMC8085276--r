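test_that("psnr matches closed forms and a brute-force oracle", {
  x <- random_stack(64, 64, seed = 1)[, , 1]
  expect_identical(psnr(x, x), Inf)
  expect_equal(psnr(x, x + 0.1), 20.0, tolerance = 1e-12)
  y <- random_stack(64, 64, seed = 2)[, , 1]
  brute <- 10 * log10(1 / (sum((x - y)^2) / length(x)))
  expect_lt(abs(psnr(x, y) - brute), 1e-10)
  expect_error(psnr(x, y[1:32, ]), class = "caldenoise_invalid_argument")
  # strictly decreasing in MSE
  expect_gt(psnr(x, x + 0.01), psnr(x, x + 0.02))
})

test_that("ssim satisfies identity and the constant-image closed form", {
  x <- random_stack(32, 32, seed = 3)[, , 1]
  expect_equal(ssim(x, x), 1, tolerance = 1e-12)
  a <- matrix(0.4, 24, 24); b <- matrix(0.5, 24, 24)
  C1 <- 0.01^2
  closed <- (2 * 0.4 * 0.5 + C1) / (0.4^2 + 0.5^2 + C1)
  expect_lt(abs(ssim(a, b) - closed), 1e-9)
  expect_lt(ssim(x, 1 - x), 1)
  expect_error(ssim(x[1:8, 1:8], x[1:8, 1:8]), class = "caldenoise_invalid_argument")
})

test_that("ssim agrees with an independent reference implementation", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  py <- paste(
    "import sys, numpy as np",
    "from skimage.metrics import structural_similarity as ss",
    "x = np.loadtxt(sys.argv[1], delimiter=','); y = np.loadtxt(sys.argv[2], delimiter=',')",
    "print(float(ss(x, y, data_range=1.0, gaussian_weights=True, sigma=1.5,",
    "               use_sample_covariance=False)))",
    sep = "\n")
  script <- withr::local_tempfile(fileext = ".py"); writeLines(py, script)
  fx <- withr::local_tempfile(fileext = ".csv")
  fy <- withr::local_tempfile(fileext = ".csv")
  set.seed(4)
  for (k in 1:5) {
    x <- matrix(runif(48 * 48), 48)
    y <- pmin(pmax(x + rnorm(48 * 48, 0, 0.1), 0), 1)
    write.table(x, fx, sep = ",", row.names = FALSE, col.names = FALSE)
    write.table(y, fy, sep = ",", row.names = FALSE, col.names = FALSE)
    ref <- as.numeric(system2("python", c(script, fx, fy), stdout = TRUE))
    skip_if(length(ref) != 1 || is.na(ref), "reference SSIM unavailable")
    expect_lt(abs(ssim(x, y) - ref), 1e-6)
  }
})

test_that("trace extraction follows the 25th-percentile baseline convention", {
  mv <- flat_movie(0.3, 8, 8, nt = 6)
  mask <- matrix(TRUE, 8, 8)
  tr <- extract_trace(mv, mask)
  expect_equal(tr$f, rep(0.3, 6))
  expect_equal(tr$f0, 0.3)
  expect_equal(tr$dff, rep(0, 6))

  vals <- c(10, 10, 10, 20)
  mv2 <- as_movie(array(rep(vals, each = 16), c(4, 4, 4)), 40)
  tr2 <- extract_trace(mv2, matrix(TRUE, 4, 4))
  expect_equal(tr2$f0, 10)              # linear-interpolation percentile
  expect_equal(tr2$dff, c(0, 0, 0, 1))

  expect_error(extract_trace(mv, matrix(FALSE, 8, 8)),
               class = "caldenoise_invalid_argument")
  expect_error(extract_trace(flat_movie(0, 8, 8, 4), mask),
               class = "caldenoise_degenerate_baseline")
})

test_that("dF/F and transient SNR are invariant to positive scaling of f", {
  sc <- scene_config(n_cells = 2, cell_radius_px = 2, event_rate_hz = 2, seed = 30)
  out <- generate_ground_truth_movie(sc, 200, 40, 32, 32)
  noisy <- corrupt_movie(out$movie, noise_params(0, 1000, 0.01, seed = 31))
  tr <- extract_trace(noisy, out$masks[, , 1])
  scaled <- as_movie(unclass(noisy) * 3.7, 40)
  tr_s <- extract_trace(scaled, out$masks[, , 1])
  expect_equal(tr_s$dff, tr$dff, tolerance = 1e-12)
  pk <- max(find_peak(tr), 82)
  if (pk <= 198) {
    w <- transient_window(pk)
    expect_equal(transient_snr(tr_s, w), transient_snr(tr, w), tolerance = 1e-9)
  }
})

test_that("transient SNR recovers A/sigma and validates its windows", {
  # baseline N(0, 0.1) on frames 1..80, peak plateau 1.0 on frames 81..83
  set.seed(5)
  snrs <- replicate(200, {
    dff <- c(rnorm(80, 0, 0.1), 1, 1, 1)
    transient_snr(make_trace(dff, rate_hz = 40), transient_window(82))
  })
  expect_lt(abs(mean(snrs) - 10), 1.5)  # within 15 % of A / sigma = 10

  # oracle recomputation with explicit 3- and 80-frame windows at 40 Hz
  dff <- c(rnorm(80, 0, 0.1), 0.9, 1.1, 1.0, rnorm(5, 0, 0.1))
  tr <- make_trace(dff)
  base <- dff[1:80]; peak <- dff[81:83]
  expect_equal(transient_snr(tr, transient_window(82)),
               (mean(peak) - mean(base)) / sd(base), tolerance = 1e-12)

  # windows that do not fit raise an invalid-argument error
  expect_error(transient_snr(make_trace(rnorm(82)), transient_window(81)),
               class = "caldenoise_invalid_argument")
  # zero-variance baseline raises a degenerate-baseline error
  expect_error(transient_snr(make_trace(c(rep(0, 80), 1, 1, 1)),
                             transient_window(82)),
               class = "caldenoise_degenerate_baseline")
})

test_that("movie quality reports per-frame metrics with exact summaries", {
  sc <- scene_config(n_cells = 3, cell_radius_px = 2, seed = 33)
  out <- generate_ground_truth_movie(sc, 5, 40, 32, 32)
  noisy <- corrupt_movie(out$movie, noise_params(0, 1000, 0.05, seed = 34))
  rep_same <- movie_quality(out$movie, out$movie)
  expect_true(all(rep_same$per_frame$ssim == 1))
  q <- movie_quality(out$movie, noisy)
  expect_equal(nrow(q$per_frame), 5L)
  expect_equal(q$summary$mean[1], mean(q$per_frame$psnr_db))
  expect_equal(q$summary$sd[2], sd(q$per_frame$ssim))
  # broadcasting a single reference frame over a fixed-FOV movie
  qb <- movie_quality(out$movie[, , 1], noisy)
  expect_equal(nrow(qb$per_frame), 5L)
  expect_error(movie_quality(out$movie[1:16, 1:16, 1], noisy),
               class = "caldenoise_invalid_argument")
})
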