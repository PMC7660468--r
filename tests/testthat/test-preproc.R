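# Registration, repetition averaging and k-space zero-fill.

test_that("phase correlation recovers known sub-pixel shifts", {
  ph <- tiny_phantom(noise = 0)
  ref <- ph$stack$images[[1]]
  for (d in list(c(2, -1), c(0.6, -0.3), c(-1.7, 2.2))) {
    est <- phase_correlation(ref, fourier_shift(ref, d[1], d[2]))
    expect_equal(c(est$dx, est$dy), -d, tolerance = 0.1)
  }
  same <- phase_correlation(ref, ref)
  expect_equal(c(same$dx, same$dy), c(0, 0))
  zero <- phase_correlation(ref, matrix(0, nrow(ref), ncol(ref)))
  expect_equal(zero$peak, 0)
})

test_that("pure-noise pairs fall below the correlation confidence floor", {
  withr::local_seed(2)
  floor_peaks <- replicate(10, {
    a <- matrix(stats::rnorm(64 * 64), 64)
    b <- matrix(stats::rnorm(64 * 64), 64)
    phase_correlation(a, b)$peak
  })
  expect_lt(max(floor_peaks), 0.1)
  ph <- tiny_phantom(noise = 0)
  matched <- phase_correlation(ph$stack$images[[1]],
                               fourier_shift(ph$stack$images[[1]], 1, 1))
  expect_gt(matched$peak, 0.5)
})

test_that("registration restores shift-only corruption", {
  ph <- make_phantom(phantom_spec("late_systole", noise_sigma = 0))
  # shifted copies appended to the pristine originals (reference frame intact)
  withr::local_seed(9)
  n <- length(ph$stack$images)
  shifts <- matrix(stats::rnorm(2 * n, 0, 1), ncol = 2)
  images <- c(ph$stack$images,
              lapply(seq_len(n), function(i) {
                fourier_shift(ph$stack$images[[i]], shifts[i, 1], shifts[i, 2])
              }))
  meta <- dplyr::bind_rows(ph$stack$meta,
                           dplyr::mutate(ph$stack$meta, repetition = 2L))
  meta$index <- seq_len(2 * n)
  st <- new_dwi_stack(images, meta, ph$stack$pixel_spacing)
  reg <- register_stack(st)
  expect_lt(max(abs(reg$shifts$dx[1:n])), 0.02)    # originals untouched
  for (i in seq_len(n)) {
    orig <- ph$stack$images[[i]]
    rel_rms <- sqrt(mean((reg$stack$images[[n + i]] - orig)^2)) /
      sqrt(mean(orig^2))
    expect_lt(rel_rms, 0.01)
  }
  expect_error(register_stack(st, reference = 999), "reference")
})

test_that("repetition averaging groups by b and direction", {
  ph <- tiny_phantom(noise = 0)
  st <- corrupt_stack(ph$stack, n_reps = 8, shift_sigma = 0, noise_sigma = 0)
  expect_equal(length(st$images), 104)
  avg <- average_repetitions(st)
  expect_equal(length(avg$images), 13)
  expect_equal(avg$images[[1]], ph$stack$images[[1]])
  # numeric average of distinct repetitions
  img <- list(matrix(0, 4, 4), matrix(2, 4, 4))
  meta <- tibble::tibble(index = 1:2, b = 0, gx = 0, gy = 0, gz = 0,
                         repetition = 1:2, phase = "p", td = NA_real_)
  expect_equal(average_repetitions(new_dwi_stack(img, meta, 1))$images[[1]],
               matrix(1, 4, 4))
  # unequal group sizes warn
  st2 <- new_dwi_stack(st$images[1:20], st$meta[1:20, ], st$pixel_spacing)
  expect_warning(average_repetitions(st2), "unequal")
})

test_that("averaging reduces Gaussian noise by about sqrt(8)", {
  withr::local_seed(4)
  base <- matrix(0, 48, 48)
  images <- lapply(1:8, function(i) add_noise(base, 0.5, gaussian = TRUE))
  meta <- tibble::tibble(index = 1:8, b = 0, gx = 0, gy = 0, gz = 0,
                         repetition = 1:8, phase = "p", td = NA_real_)
  avg <- average_repetitions(new_dwi_stack(images, meta, 1))
  ratio <- stats::sd(avg$images[[1]]) / 0.5
  expect_equal(ratio, 1 / sqrt(8), tolerance = 0.15)
})

test_that("zero-fill preserves DC, FOV, and the original k-space samples", {
  img <- matrix(1.7, 32, 24)
  up <- zero_fill(img, 2)
  expect_equal(dim(up), c(64, 48))
  expect_equal(max(abs(up - 1.7)), 0, tolerance = 1e-12)
  # single-frequency sinusoid: amplitude preserved on the finer grid
  n <- 32
  x <- outer(sin(2 * pi * 3 * (0:(n - 1)) / n), cos(2 * pi * 2 * (0:(n - 1)) / n))
  up2 <- zero_fill(x, 2)
  fine <- outer(sin(2 * pi * 3 * (0:(2 * n - 1)) / (2 * n)),
                cos(2 * pi * 2 * (0:(2 * n - 1)) / (2 * n)))
  expect_lt(max(abs(up2 - fine)), 1e-10)
  # decimation at aligned grid points returns the input
  rnd <- matrix(stats::rnorm(32 * 24), 32)
  up3 <- zero_fill(rnd, 2)
  expect_lt(max(abs(up3[seq(1, 64, 2), seq(1, 48, 2)] - rnd)), 1e-10)
  expect_equal(mean(up3), mean(rnd), tolerance = 1e-12)
  expect_error(zero_fill(rnd, 1.5), "integer")
  # protocol matrix size: 128x104 doubles to 256x208
  expect_equal(dim(zero_fill(matrix(0, 128, 104), 2)), c(256, 208))
})

test_that("recentring moves the b0 centroid onto the target", {
  ph <- tiny_phantom(noise = 0)
  shifted <- new_dwi_stack(lapply(ph$stack$images, fourier_shift, dx = 2.5, dy = -1.5),
                           ph$stack$meta, ph$stack$pixel_spacing)
  rc <- recenter_stack(shifted)
  g <- cdti_grid(dim(rc$stack$images[[1]]), rc$stack$pixel_spacing)
  b0 <- rc$stack$images[[1]]
  w <- pmax(b0 - 0.2 * max(b0), 0)
  expect_lt(abs(sum(w * g$x) / sum(w)), 0.1)
  expect_lt(abs(sum(w * g$y) / sum(w)), 0.1)
})
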