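test_that("both fitters invert noiseless model signals to 0.1 percent", {
  tr <- 4.5
  for (t1 in c(0.1, 0.35, 0.8, 2.0)) {
    s <- abs(1 - 2 * exp(-TI_LIST / t1) + exp(-tr / t1))
    f <- fit_t1_voxel(s, TI_LIST, tr)
    expect_true(f$converged)
    expect_lt(abs(f$value / t1 - 1), 1e-3)
  }
  te <- 0.007 * (1:23)
  for (t2 in c(0.02, 0.08, 0.18, 0.3)) {
    f <- fit_t2_voxel(exp(-te / t2), te)
    expect_true(f$converged)
    expect_lt(abs(f$value / t2 - 1), 1e-3)
  }
  # the documented example: T2 = 80 ms from the 23-echo train
  f80 <- fit_t2_voxel(exp(-te / 0.08), te)
  expect_lt(abs(f80$value - 0.08), 0.08 * 1e-3)
})

test_that("degenerate signals return non-converged results, never errors", {
  expect_false(fit_t1_voxel(rep(0, 10), TI_LIST, 4.5)$converged)
  te <- 0.007 * (1:10)
  expect_false(fit_t2_voxel(rep(0, 10), te)$converged)
  cst <- fit_t2_voxel(rep(0.7, 10), te)
  expect_false(cst$converged)
  expect_error(fit_t1_voxel(c(1, 2), c(0.1, 0.2), 4.5), ">= 4")
  expect_error(fit_t2_voxel(c(1, 2, 3), c(0.1, 0.1, 0.2)), "increasing")
})

test_that("fitted values are scale-equivariant and monotone in the truth", {
  te <- 0.007 * (1:23)
  s <- exp(-te / 0.12) + 0.01
  f1 <- fit_t2_voxel(s, te)
  f2 <- fit_t2_voxel(2 * s, te)
  expect_equal(f2$value, f1$value, tolerance = 1e-6)
  expect_equal(f2$a, 2 * f1$a, tolerance = 1e-4)
  tr <- 4.5
  grid <- seq(0.1, 2, length.out = 8)
  fitted <- vapply(grid, function(t1)
    fit_t1_voxel(abs(1 - 2 * exp(-TI_LIST / t1) + exp(-tr / t1)),
                 TI_LIST, tr)$value, numeric(1))
  expect_true(all(diff(fitted) > 0))
})

test_that("map_fit validates the contrast axis, mask, and echo subset", {
  arr <- array(runif(4 * 4 * 10, 0.2, 1), dim = c(4, 4, 10))
  im_ti <- image_set(arr, "TI", TI_LIST, tr = 4.5)
  expect_error(map_fit(im_ti, "t2"), "axis mismatch")
  expect_error(map_fit(im_ti, "t1", mask = matrix(FALSE, 4, 4)), "empty")
  te23 <- 0.007 * (1:23)
  arr2 <- array(rep(exp(-te23 / 0.1), each = 16), dim = c(4, 4, 23))
  im_te <- image_set(arr2, "TE", te23)
  pm <- map_fit(im_te, "t2", echo_subset = 5:23)
  expect_equal(length(pm$axis_values), 19)
  expect_equal(pm$map[2, 2], 0.1, tolerance = 1e-3)
  expect_error(map_fit(im_te, "t1"), "axis mismatch")
})

test_that("ROI statistics honor convergence, locality, and single voxels", {
  map <- matrix(NA_real_, 6, 6)
  conv <- matrix(FALSE, 6, 6)
  map[2, 2] <- 0.5; conv[2, 2] <- TRUE
  map[5, 5] <- 0.5; conv[5, 5] <- TRUE
  map[5, 2] <- 9.9                       # not converged; must be ignored
  pmap <- structure(list(map = map, converged = conv, kind = "t1",
                         mask = conv), class = "qmri_parmap")
  one <- matrix(FALSE, 6, 6); one[2, 2] <- TRUE
  other <- matrix(FALSE, 6, 6); other[5, 5] <- TRUE
  both <- one | other
  bad <- matrix(FALSE, 6, 6); bad[5, 2] <- TRUE
  st <- roi_stats(pmap, list(one, other, both, bad))
  expect_equal(st$mean[1], 0.5)
  expect_equal(st$sd[1], 0)
  expect_equal(st$mean[1], st$mean[2])   # disjoint ROIs, identical values
  expect_equal(st$n[3], 2)
  expect_equal(st$n[4], 0)               # unconverged voxel excluded
})

test_that("interior sphere ROIs erode by one voxel", {
  lay <- default_sphere_layout("t2_plane")
  rois <- sphere_rois(lay, 32, 0.25, erode = 1)
  rois0 <- sphere_rois(lay, 32, 0.25, erode = 0)
  expect_length(rois, 10)
  for (k in 1:10) expect_true(all(rois0[[k]][rois[[k]]]))
  expect_true(sum(rois[[1]]) < sum(rois0[[1]]))
})
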