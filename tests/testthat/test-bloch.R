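test_that("hard-pulse rotations follow the stated convention and preserve norm", {
  m0 <- magnetization(0, 1)
  inv <- apply_rf(m0, pi, 0.7)
  expect_equal(Mod(inv$mxy), 0, tolerance = 1e-12)
  expect_equal(inv$mz, -1, tolerance = 1e-12)
  exc <- apply_rf(m0, pi / 2, 0)
  expect_equal(exc$mxy, -1i, tolerance = 1e-12)
  expect_equal(exc$mz, 0, tolerance = 1e-12)
  idt <- apply_rf(magnetization(0.3 + 0.2i, 0.5), 0, 1.1)
  expect_equal(idt$mxy, 0.3 + 0.2i)
  expect_equal(idt$mz, 0.5)
  # norm preservation over random rotations applied to random states
  set.seed(11)
  for (k in 1:50) {
    m <- magnetization(complex(real = rnorm(1), imaginary = rnorm(1)),
                       rnorm(1))
    nrm0 <- Mod(m$mxy)^2 + m$mz^2
    r <- apply_rf(m, runif(1, 0, 2 * pi), runif(1, 0, 2 * pi))
    expect_equal(Mod(r$mxy)^2 + r$mz^2, nrm0, tolerance = 1e-12)
  }
})

test_that("free precession follows the closed-form relaxation solution", {
  m <- magnetization(1 + 0i, -1, 1)
  # T2 half-life
  h <- free_precess(magnetization(1 + 0i, 0), 0.08 * log(2), 1, 0.08)
  expect_equal(Mod(h$mxy), 0.5, tolerance = 1e-12)
  # closed-form longitudinal recovery: 1 - 2*exp(-0.3) after inversion
  r <- free_precess(m, 0.15, 0.5, 0.1)
  expect_equal(r$mz, 1 - 2 * exp(-0.3), tolerance = 1e-9)
  expect_equal(r$mz, -0.48164, tolerance = 1e-4)
  # long-time limit reaches thermal equilibrium
  eq <- free_precess(m, 100, 0.5, 0.1)
  expect_equal(Mod(eq$mxy), 0, tolerance = 1e-12)
  expect_equal(eq$mz, 1, tolerance = 1e-12)
  # precession phase
  ph <- free_precess(magnetization(1 + 0i, 0), 0.01, 1, 1e6, dphi = pi / 2)
  expect_equal(Arg(ph$mxy), -pi / 2, tolerance = 1e-9)
})

test_that("relaxation is contractive and monotone", {
  t1 <- 0.8; t2 <- 0.1
  m <- magnetization(0.6 + 0.3i, -0.5)
  prev_mxy <- Mod(m$mxy); prev_mz <- m$mz
  for (k in 1:20) {
    m <- free_precess(m, 0.05, t1, t2, dphi = 0.3)
    expect_lte(Mod(m$mxy), prev_mxy + 1e-14)
    expect_gte(m$mz, prev_mz - 1e-14)   # approaches m0 from below
    prev_mxy <- Mod(m$mxy); prev_mz <- m$mz
  }
})

test_that("IRSE simulation matches the closed-form steady-state signal", {
  n <- 8
  worst <- 0
  for (t1 in c(0.2, 1.0)) {
    for (ti in c(0.1, 1.0)) {
      t2 <- 0.5 * t1; tr <- 4.5; te <- 0.01
      ph <- single_voxel_phantom(n, t1 = t1, t2 = t2)
      s <- make_irse(protocol_params(matrix_n = n, tr = tr, te = te, ti = ti))
      raw <- simulate_sequence(s, ph)
      meas <- Mod(raw$samples[n / 2 + 1, 1, 1])
      pred <- abs(1 - 2 * exp(-ti / t1) + exp(-tr / t1)) * exp(-te / t2)
      worst <- max(worst, abs(meas - pred))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("the inversion null suppresses the echo at TI = T1 ln 2", {
  t1 <- 0.3
  ph <- single_voxel_phantom(8, t1 = t1, t2 = 0.1)
  s <- make_irse(protocol_params(matrix_n = 8, tr = 10 * t1, te = 0.01,
                                 ti = round(t1 * log(2), 6)))
  raw <- simulate_sequence(s, ph)
  expect_lt(max(Mod(raw$samples)), 1e-3)
})

test_that("simulation is linear in the phantom", {
  n <- 8
  ph1 <- single_voxel_phantom(n, t1 = 0.5, t2 = 0.1, at = c(3, 5))
  ph2 <- single_voxel_phantom(n, t1 = 1.2, t2 = 0.2, at = c(6, 2))
  both <- ph1
  both$pd <- ph1$pd + ph2$pd
  both$t1[ph2$pd > 0] <- 1.2
  both$t2[ph2$pd > 0] <- 0.2
  s <- make_irse(tiny_irse_params(n = n))
  r1 <- simulate_sequence(s, ph1)$samples
  r2 <- simulate_sequence(s, ph2)$samples
  rb <- simulate_sequence(s, both)$samples
  expect_equal(rb, r1 + r2, tolerance = 1e-12)
})

test_that("simulated k-space equals the DFT of the proton-density map", {
  n <- 16
  ph <- disk_phantom(n)
  ph$pd[3:5, 10:12] <- 0                      # break symmetry
  s <- make_irse(protocol_params(matrix_n = n, tr = 3, te = 0.01, ti = 1.0))
  raw <- simulate_sequence(s, ph)
  iso <- to_isochromats(ph)
  kk <- ((0:(n - 1)) - n / 2) / ph$fov
  G_or <- matrix(0 + 0i, n, n)
  for (m in 1:n) for (p in 1:n)
    G_or[m, p] <- sum(iso$pd * exp(-2i * pi * (kk[m] * iso$x + kk[p] * iso$y)))
  G <- sort_kspace(raw)[[1]]$grids[[1]]
  sc <- sum(Mod(G) * Mod(G_or)) / sum(Mod(G_or)^2)
  err <- sqrt(mean(Mod(Mod(G) - sc * Mod(G_or))^2)) /
    sqrt(mean((sc * Mod(G_or))^2))
  expect_lt(err, 0.01)
})

test_that("steady-state preparation adds exactly n_dummy TR and converges", {
  p <- protocol_params(matrix_n = 8, tr = 2.5, te = 0.01, ti = 0.2)
  s1 <- make_irse(p)                          # builders default to 1 dummy
  s0 <- steady_state_prep(s1, 0)
  expect_equal(seq_duration(s0), seq_duration(s1))
  s3 <- steady_state_prep(s1, 2)
  expect_equal(seq_duration(s3) - seq_duration(s1), 2 * p$tr,
               tolerance = 1e-9)
  # with TR >= 5 T1max, signals with and without extra dummies agree
  ph <- single_voxel_phantom(8, t1 = 0.5, t2 = 0.1)
  a <- simulate_sequence(s1, ph)$samples
  b <- simulate_sequence(s3, ph)$samples
  expect_lt(max(Mod(a - b)) / max(Mod(a)), 1e-4)
})

test_that("simulation contract errors are raised", {
  p <- tiny_irse_params(n = 8)
  s <- make_irse(p)
  ph <- disk_phantom(8)
  ph$pd[] <- 0
  expect_warning(simulate_sequence(s, ph), "no isochromats")
  s_noadc <- new_sequence(list(seq_block(delay = 1e-3)), meta = list(ns = 1))
  expect_error(simulate_sequence(s_noadc, disk_phantom(8)), "no ADC")
})
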