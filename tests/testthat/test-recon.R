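test_that("hamming window has the analytic endpoint and center values", {
  w <- hamming_2d(128)
  expect_equal(w[1, 1], 0.08^2, tolerance = 1e-12)
  w9 <- hamming_2d(9)
  expect_equal(w9[5, 5], 1)
  expect_equal(w9[1, 5], 0.08)
  expect_error(hamming_2d(1), ">= 2")
})

test_that("centered inverse FFT is unitary up to the 1/N^2 convention", {
  set.seed(4)
  n <- 16
  G <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n)
  img <- ifft2_image(G)
  # Parseval: image power equals k-space power / N^2
  expect_equal(sum(Mod(img)^2), sum(Mod(G)^2) / n^2, tolerance = 1e-12)
  # round trip through the forward transform
  Gf <- qmriseq:::fftshift2(stats::fft(qmriseq:::ifftshift2(img)))
  expect_equal(Gf, G, tolerance = 1e-12)
  # delta at k-space center -> constant-magnitude image
  D <- matrix(0 + 0i, n, n); D[n / 2 + 1, n / 2 + 1] <- 1
  expect_equal(stats::sd(Mod(ifft2_image(D))), 0, tolerance = 1e-14)
})

test_that("sum-of-squares combination has its analytic special cases", {
  set.seed(5)
  im <- matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8)
  expect_equal(sos_combine(list(im)), Mod(im))
  expect_equal(sos_combine(list(im, im)), sqrt(2) * Mod(im),
               tolerance = 1e-12)
  im2 <- matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8)
  expect_equal(sos_combine(list(im, im2)), sos_combine(list(im2, im)))
  # equals sqrt(channels) times the root of the quadratic mean
  chans <- list(im, im2, im + im2)
  qm <- sqrt((Mod(im)^2 + Mod(im2)^2 + Mod(im + im2)^2) / 3)
  expect_equal(sos_combine(chans), sqrt(3) * qm, tolerance = 1e-12)
})

test_that("joint normalization scales to max 1 and preserves ratios", {
  set.seed(6)
  arr <- array(runif(8 * 8 * 3, 0.1, 5), dim = c(8, 8, 3))
  is <- image_set(arr, "slice", 1:3)
  nrm <- normalize_set(is)
  expect_equal(max(nrm$data), 1)
  expect_gte(min(nrm$data), 0)
  expect_equal(nrm$data[1, 1, 1] / nrm$data[5, 3, 2],
               arr[1, 1, 1] / arr[5, 3, 2], tolerance = 1e-12)
  expect_error(normalize_set(image_set(array(0, c(2, 2, 1)), "slice", 1)),
               "no positive")
})

test_that("k-space sorting detects duplicates and gaps and splits echoes", {
  p <- protocol_params(matrix_n = 16, tr = 4.5, te_list = 0.007 * (1:3),
                       echo_spacing = 0.007)
  raw <- simulate_sequence(make_multiecho_tse(p), disk_phantom(16))
  frames <- sort_kspace(raw)
  expect_length(frames, 3)                      # one grid per echo
  expect_equal(vapply(frames, `[[`, numeric(1), "te"), 0.007 * (1:3),
               tolerance = 1e-9)
  # corrupt: drop one readout -> incomplete k-space
  broken <- raw
  keep <- -5
  broken$samples <- broken$samples[, , keep, drop = FALSE]
  broken$meta <- broken$meta[keep, ]
  expect_error(sort_kspace(broken), "missing PE line")
  # corrupt: duplicate PE line
  dup <- raw
  dup$meta$pe_line[6] <- dup$meta$pe_line[9]
  expect_error(sort_kspace(dup), "more than once")
})

test_that("noiseless matched-resolution reconstruction recovers the phantom", {
  n <- 16
  ph <- disk_phantom(n)
  ph$pd[4, 11:13] <- 0
  s <- make_irse(protocol_params(matrix_n = n, tr = 3, te = 0.01, ti = 1.0))
  img <- reconstruct(simulate_sequence(s, ph), apodize = FALSE)
  I <- img$data[, , 1]
  Iref <- ph$pd
  expect_lt(sqrt(mean((I - Iref)^2)) / sqrt(mean(Iref^2)), 0.02)
})

test_that("apodization reduces Gibbs overshoot on an oversampled disk edge", {
  nm <- 32
  ph <- make_grid_phantom(2 * nm, 2 * nm, t1 = 2, t2 = 1.5)
  s <- make_irse(protocol_params(matrix_n = nm, tr = 3, te = 0.01, ti = 1.0))
  raw <- simulate_sequence(s, ph)
  plain <- reconstruct(raw, apodize = FALSE)
  apod <- reconstruct(raw, apodize = TRUE)
  xy <- qmriseq:::voxel_centers(nm, 0.25)
  r <- sqrt(outer(xy$y^2, xy$x^2, `+`))
  mask <- r < 0.92 * (0.9 * 0.25 / 2)
  ov_plain <- gibbs_overshoot(plain$data[, , 1], mask)
  ov_apod <- gibbs_overshoot(apod$data[, , 1], mask)
  expect_gt(ov_plain, 0.02)
  expect_lt(ov_apod, ov_plain)
})
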