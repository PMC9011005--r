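# fixture pair for the frozen reference values: smooth bump plus a fixed
# noise draw, both clipped to [0, 1]
metric_fixture <- function(n = 48) {
  xy <- seq(-1, 1, length.out = n)
  base <- outer(xy, xy, function(a, b) exp(-(a^2 + b^2) * 3)) +
    0.1 * outer(sin(4 * pi * xy), cos(3 * pi * xy))
  base <- (base - min(base)) / (max(base) - min(base))
  set.seed(7)
  test <- pmin(pmax(base + matrix(rnorm(n * n, 0, 0.05), n, n), 0), 1)
  list(ref = base, test = test)
}

test_that("PSNR has its closed-form values and sentinel", {
  x <- matrix(0.4, 16, 16)
  expect_equal(psnr(x, x), 300)                  # capped sentinel
  zero <- matrix(0, 16, 16)
  expect_equal(psnr(zero, zero + 0.1), 20, tolerance = 1e-12)
  f <- metric_fixture()
  # frozen from an independent reference implementation on this fixture
  expect_equal(psnr(f$ref, f$test), 26.0835521412, tolerance = 1e-6)
})

test_that("PSNR decreases monotonically with noise level", {
  set.seed(8)
  ref <- metric_fixture()$ref
  noise <- matrix(rnorm(length(ref)), nrow(ref))
  vals <- vapply(seq(0.01, 0.1, length.out = 10), function(s)
    psnr(ref, ref + s * noise), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("SSIM is 1 at identity, symmetric, bounded, and matches the reference", {
  f <- metric_fixture()
  expect_equal(ssim(f$ref, f$ref), 1, tolerance = 1e-12)
  expect_equal(ssim(f$ref, f$test), ssim(f$test, f$ref), tolerance = 1e-12)
  # frozen from an independent reference implementation on this fixture
  expect_equal(ssim(f$ref, f$test), 0.7576130246, tolerance = 1e-6)
  set.seed(9)
  for (k in 1:5) {
    a <- matrix(runif(32 * 32), 32)
    b <- matrix(runif(32 * 32), 32)
    v <- ssim(a, b)
    expect_gte(v, -1); expect_lte(v, 1)
  }
})

test_that("SSIM decreases monotonically under increasing blur", {
  f <- metric_fixture()
  blur_once <- function(img) {
    k <- matrix(1 / 9, 3, 3)
    n <- nrow(img)
    out <- img
    for (i in 2:(n - 1)) for (j in 2:(n - 1))
      out[i, j] <- sum(img[(i - 1):(i + 1), (j - 1):(j + 1)] * k)
    out
  }
  img <- f$ref
  vals <- numeric(4)
  for (k in 1:4) {
    img <- blur_once(img)
    vals[k] <- ssim(f$ref, img)
  }
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals < 1))
})

test_that("RF power scales quadratically with amplitude and with duty cycle", {
  p <- tiny_irse_params(n = 8)
  s <- make_irse(p)
  rep1 <- rf_power_summary(s)
  expect_gt(rep1$time_averaged_b1sq, 0)
  expect_equal(rep1$reference_mass, 70)
  # doubling every RF amplitude quadruples the averaged power
  s2 <- s
  for (k in seq_along(s2$blocks))
    if (!is.null(s2$blocks[[k]]$rf))
      s2$blocks[[k]]$rf$amp <- 2 * s2$blocks[[k]]$rf$amp
  expect_equal(rf_power_summary(s2)$time_averaged_b1sq,
               4 * rep1$time_averaged_b1sq, tolerance = 1e-12)
  # halving the repetition period (same pulses) doubles the averaged power
  rf <- rf_pulse(pi / 2, "excitation")
  long <- new_sequence(list(seq_block(rf = rf), seq_block(delay = 0.999)))
  short <- new_sequence(list(seq_block(rf = rf), seq_block(delay = 0.499)))
  expect_equal(rf_power_summary(short)$time_averaged_b1sq,
               2 * rf_power_summary(long)$time_averaged_b1sq,
               tolerance = 1e-12)
  expect_equal(rf_power_summary(short)$duty_cycle,
               2 * rf_power_summary(long)$duty_cycle, tolerance = 1e-12)
  # no RF -> zero power
  s0 <- new_sequence(list(seq_block(delay = 1)), meta = list())
  expect_equal(rf_power_summary(s0)$time_averaged_b1sq, 0)
  expect_equal(rf_power_summary(s0)$duty_cycle, 0)
})

test_that("RF energy is additive over concatenated sequences", {
  a <- make_irse(tiny_irse_params(n = 8, ti = 0.1, tr = 1, te = 0.012))
  b <- make_irse(tiny_irse_params(n = 8, ti = 0.3, tr = 2, te = 0.012))
  ab <- new_sequence(c(a$blocks, b$blocks), meta = a$meta)
  ra <- rf_power_summary(a); rb <- rf_power_summary(b)
  rab <- rf_power_summary(ab)
  expect_equal(rab$time_averaged_b1sq * seq_duration(ab),
               ra$time_averaged_b1sq * seq_duration(a) +
                 rb$time_averaged_b1sq * seq_duration(b), tolerance = 1e-9)
})
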