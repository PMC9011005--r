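test_that("banded phase-encode order covers k-space once and centers correctly", {
  po <- tse_pe_order(8, 4, center_echo = 2)
  expect_equal(dim(po$table), c(4, 2))
  expect_setequal(as.vector(po$table), 0:7)
  # center line (index 4) lives in the band acquired at echo 2
  expect_true(4 %in% po$table[2, ])
  # arbitrary sizes: flattened table is a permutation
  for (etl in c(1, 2, 8)) {
    po <- tse_pe_order(32, etl, center_echo = min(2, etl))
    expect_setequal(as.vector(po$table), 0:31)
  }
  expect_error(tse_pe_order(10, 4), "divisible|TRUE")
})

test_that("randomized slice order is a reproducible uniform permutation", {
  expect_equal(random_slice_order(1, 5)$order, 0L)
  a <- random_slice_order(11, 3)$order
  b <- random_slice_order(11, 3)$order
  expect_identical(a, b)
  expect_setequal(a, 0:10)
  # Monte-Carlo uniformity: first slot frequency ~ 1/11 within 3 sigma
  firsts <- vapply(1:10000, function(s) random_slice_order(11, s)$order[1],
                   integer(1))
  p <- 1 / 11
  bound <- 3 * sqrt(p * (1 - p) / 10000)
  for (sl in 0:10)
    expect_lt(abs(mean(firsts == sl) - p), bound + 1e-12)
})

test_that("TSE echo-train structure matches matrix_n / etl excitations", {
  p <- protocol_params(matrix_n = 32, tr = 3, te = 0.05, etl = 4,
                       center_echo = 2)
  s <- make_tse(p)
  ann <- qmriseq:::annotate_readouts(s)
  ro <- ann$readouts
  expect_equal(length(unique(ro$t_exc)), 8)        # 32 / 4 excitations
  expect_true(all(table(ro$t_exc) == 4))           # 4 echoes each
  expect_setequal(ro$pe_line, 0:31)                # full coverage
  # the full-size protocol's table implies 64 excitations of 4 echoes
  po <- tse_pe_order(256, 4, 2)
  expect_equal(po$n_excitations, 64)
  expect_setequal(as.vector(po$table), 0:255)
  expect_error(make_tse(protocol_params(matrix_n = 30, etl = 4)),
               "divisible")
})

test_that("etl = 1 TSE degenerates to IRSE timing without the inversion", {
  pt <- protocol_params(matrix_n = 8, tr = 2, te = 0.012, etl = 1)
  st <- make_tse(pt)
  pi_ <- tiny_irse_params(n = 8, ti = 0.15, tr = 2, te = 0.012)
  si <- make_irse(pi_)
  rt <- timing_report(st); ri <- timing_report(si)
  expect_equal(rt$measured_te, ri$measured_te, tolerance = 1e-9)
  expect_equal(rt$measured_tr, ri$measured_tr, tolerance = 1e-9)
  expect_true(is.na(rt$measured_ti))
})

test_that("multi-echo TSE acquires one line at all echoes", {
  te_list <- 0.007 * (1:23)
  p <- protocol_params(matrix_n = 32, tr = 4.5, te_list = te_list,
                       echo_spacing = 0.007)
  s <- make_multiecho_tse(p)
  ann <- qmriseq:::annotate_readouts(s)
  ro <- ann$readouts
  expect_equal(nrow(ro), 32 * 23)
  expect_true(all(table(ro$t_exc) == 23))
  # within one excitation, every echo sees the same PE line
  one <- ro[ro$t_exc == ro$t_exc[1], ]
  expect_equal(length(unique(one$pe_line)), 1)
  rep <- timing_report(s)
  expect_equal(max(rep$echo_times), 0.161, tolerance = 1e-9)
  expect_equal(rep$echo_spacing, 0.007, tolerance = 1e-9)
  # degenerate single-echo case
  p1 <- protocol_params(matrix_n = 8, tr = 2, te_list = 0.012,
                        echo_spacing = 0.012)
  expect_equal(timing_report(make_multiecho_tse(p1))$echoes_per_excitation, 1)
  expect_error(make_multiecho_tse(
    protocol_params(matrix_n = 8, tr = 2, te_list = c(0.007, 0.02),
                    echo_spacing = 0.007)), "arithmetic")
})

test_that("the T1 protocol yields one IRSE per TI with increasing measured TI", {
  p <- protocol_params(matrix_n = 8, tr = 4.5, te = 0.010,
                       ti_list = TI_LIST)
  seqs <- make_t1_protocol(p)
  expect_length(seqs, 10)
  tis <- vapply(seqs, function(s) timing_report(s)$measured_ti, numeric(1))
  expect_equal(tis, TI_LIST, tolerance = 1e-9)
  expect_true(all(diff(tis) > 0))
  expect_length(make_t1_protocol(
    protocol_params(matrix_n = 8, tr = 4.5, te = 0.01, ti_list = 0.05)), 1)
})

test_that("infeasible timing is rejected with the violated interval named", {
  expect_error(make_irse(tiny_irse_params(ti = 2.5, tr = 2)), "infeasible")
  expect_error(make_irse(protocol_params(matrix_n = 256, n_slices = 11,
                                         tr = 1.5, te = 0.012, ti = 0.15)),
               "TR")
})

test_that("every preset reproduces its nominal timing within one raster tick", {
  tick <- 1e-6
  cases <- list(
    list(name = "irse_acr", scale = 8, te = 0.012, ti = 0.150, tr = 2.0),
    list(name = "tse_acr", scale = 8, te = 0.050, ti = NA, tr = 3.0),
    list(name = "irse_sim", scale = 1, te = 0.010, ti = 0.200, tr = 4.5),
    list(name = "tse_sim", scale = 1, te = 0.010, ti = NA, tr = 4.5))
  for (cs in cases) {
    pr <- qmri_preset(cs$name, scale = cs$scale)
    s <- make_preset_sequence(pr)
    rep <- timing_report(s)
    expect_lt(abs(rep$measured_te - cs$te), tick + 1e-12)
    expect_lt(abs(rep$measured_tr - cs$tr), tick + 1e-12)
    if (!is.na(cs$ti)) expect_lt(abs(rep$measured_ti - cs$ti), tick + 1e-12)
  }
})
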