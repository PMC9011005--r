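# Protocol generators: qualitative IRSE and TSE, 10-TI T1-mapping IRSE,
# and the 23-echo multi-echo TSE for T2 mapping.
#
# Timing layout of one spin-echo train (times relative to the excitation
# center, ESP = echo spacing):
#   [inversion] -- TI -- excitation -- readout-prephaser -- delay --
#   { refocusing at (2k-1)*ESP/2 -- PE blip -- delay -- readout with the
#     echo-center sample at k*ESP -- PE rewind -- delay } for k = 1..ETL
# The frequency-encode prephaser is placed between excitation and the first
# refocusing pulse (its accumulated k is sign-flipped by the pulse); phase
# encoding uses a blip after each refocusing pulse and a rewind after each
# readout so that every echo sees exactly its own PE area.  Slices are
# played sequentially within each TR in the randomized slice order; TR is
# padded with a trailing delay.

#' Protocol parameter set
#'
#' Validates and bundles the parameters shared by all sequence builders.
#'
#' @param fov field of view in meters.
#' @param matrix_n matrix size N (square matrix, N x N).
#' @param n_slices number of slices.
#' @param slice_thickness slice thickness in meters.
#' @param tr,te,ti repetition/echo/inversion times in seconds (`ti`
#'   optional).
#' @param flip_excitation,flip_refocus flip angles in radians.
#' @param etl echo train length (echoes per excitation).
#' @param echo_spacing echo spacing in seconds (defaults to
#'   `te / center_echo` for multi-line TSE, `te` otherwise).
#' @param center_echo echo index acquiring the k-space-center band in
#'   qualitative TSE (default 2, placing the nominal TE at the center
#'   band).
#' @param ti_list inversion times for T1 mapping (strictly increasing).
#' @param te_list echo times for multi-echo T2 mapping (arithmetic
#'   progression with step `echo_spacing`).
#' @param slice_order_seed seed for the randomized slice order.
#' @param n_dummy steady-state preparation cycles without ADC.
#' @param dwell ADC dwell time in seconds.
#' @param rf_duration RF pulse duration in seconds.
#' @param rf_shape `"block"` or `"sinc"` RF envelope.
#' @return a list of class `protocol_params`.
#' @export
protocol_params <- function(fov = 0.25, matrix_n = 128, n_slices = 1,
                            slice_thickness = 0.005, tr = 4.5, te = 0.01,
                            ti = NULL,
                            flip_excitation = pi / 2, flip_refocus = pi,
                            etl = 1, echo_spacing = NULL, center_echo = 2,
                            ti_list = NULL, te_list = NULL,
                            slice_order_seed = 0, n_dummy = 1,
                            dwell = 1e-5, rf_duration = 1e-3,
                            rf_shape = "block") {
  stopifnot(matrix_n > 0, etl >= 1, n_slices >= 1, fov > 0, tr > 0)
  if (is.null(echo_spacing))
    echo_spacing <- if (etl > 1 && is.null(te_list)) te / center_echo else te
  if (!is.null(ti_list)) {
    if (any(diff(ti_list) <= 0)) stop("ti_list must be strictly increasing")
  }
  if (!is.null(te_list) && length(te_list) > 1) {
    d <- diff(te_list)
    if (any(abs(d - echo_spacing) > 1e-9))
      stop("te_list must be an arithmetic progression with step echo_spacing")
  }
  structure(list(
    fov = fov, matrix_n = as.integer(matrix_n),
    n_slices = as.integer(n_slices), slice_thickness = slice_thickness,
    tr = tr, te = te, ti = ti,
    flip_excitation = flip_excitation, flip_refocus = flip_refocus,
    etl = as.integer(etl), echo_spacing = echo_spacing,
    center_echo = as.integer(center_echo),
    ti_list = ti_list, te_list = te_list,
    slice_order_seed = slice_order_seed, n_dummy = as.integer(n_dummy),
    dwell = dwell, rf_duration = rf_duration, rf_shape = rf_shape
  ), class = "protocol_params")
}

#' Randomized slice excitation order
#'
#' Uniformly random permutation of slices `0..n_slices-1`, deterministic
#' given the seed; the global RNG state is left untouched.
#'
#' @param n_slices number of slices.
#' @param seed integer seed.
#' @return a list of class `slice_order` with `order` (0-based permutation)
#'   and `seed`.
#' @export
random_slice_order <- function(n_slices, seed = 0) {
  stopifnot(n_slices >= 1)
  perm <- with_seed(seed, sample.int(n_slices)) - 1L
  structure(list(order = perm, seed = seed), class = "slice_order")
}

#' Multi-echo (banded) phase-encode order for TSE
#'
#' Splits the `matrix_n` PE lines into `etl` contiguous bands of
#' `matrix_n/etl` lines.  The band containing the k-space center line
#' (0-based index `matrix_n/2`) is acquired at echo `center_echo`; the
#' remaining bands are assigned to the remaining echoes by cyclic rotation,
#' preserving band order.  Every line is covered exactly once.
#'
#' @param matrix_n matrix size (divisible by `etl`).
#' @param etl echo train length.
#' @param center_echo 1-based echo acquiring the center band.
#' @return a list of class `pe_order` with `table` (etl x n_excitations
#'   matrix of 0-based PE lines), `n_echoes`, `n_excitations`.
#' @export
tse_pe_order <- function(matrix_n, etl, center_echo = 2) {
  stopifnot(matrix_n %% etl == 0, center_echo >= 1, center_echo <= etl)
  npb <- matrix_n / etl                       # lines per band
  band_of_center <- floor((matrix_n / 2) / npb)      # 0-based band index
  # echo e (1-based) acquires band (band_of_center + e - center_echo) mod etl
  bands <- (band_of_center + seq_len(etl) - center_echo) %% etl
  tab <- matrix(0L, nrow = etl, ncol = npb)
  for (e in seq_len(etl))
    tab[e, ] <- as.integer(bands[e] * npb + seq_len(npb) - 1L)
  structure(list(table = tab, n_echoes = etl, n_excitations = npb),
            class = "pe_order")
}

# --- internal geometry -----------------------------------------------------

se_geometry <- function(p) {
  n <- p$matrix_n
  dwell <- p$dwell
  rise <- 1e-4
  pad_pre <- 5e-5
  pad_post <- pad_pre + dwell           # readout symmetric about the echo
  flat <- pad_pre + n * dwell + pad_post
  gx <- 1 / (p$fov * dwell)
  t_ec <- rise + pad_pre + (n / 2 + 0.5) * dwell  # block start -> echo center
  a_half <- gx * (rise / 2 + pad_pre + (n / 2 + 0.5) * dwell)
  list(dwell = dwell, rise = rise, pad_pre = pad_pre, flat = flat,
       gx = gx, t_ec = t_ec, a_half = a_half,
       ro_dur = rise + flat + rise,
       d_pre = 5e-4, pre_rise = 1e-4, pre_flat = 3e-4,
       d_blip = 3e-4, blip_rise = 1.5e-4)
}

chk_delay <- function(d, what) {
  if (d < -1e-12)
    stop(sprintf("infeasible timing: %s (shortfall %.3f ms)", what, -d * 1e3))
  quantize_time(max(d, 0), RASTER_RF)
}

# blocks of one spin-echo train for one slice
# pe_lines: 0-based PE line per echo; esp: echo spacing (s)
se_segment <- function(p, g, slice, pe_lines, esp, adc_on,
                       with_inversion = FALSE) {
  d_rf <- p$rf_duration
  freq <- freq_for_slice(slice, p$n_slices)
  n <- p$matrix_n
  blocks <- list()
  add <- function(b) blocks[[length(blocks) + 1L]] <<- b

  if (with_inversion) {
    add(seq_block(rf = rf_pulse(pi, "inversion", d_rf, freq = freq,
                                shape = p$rf_shape)))
    add(seq_block(delay = chk_delay(p$ti - d_rf, "TI shorter than RF spacing")))
  }
  add(seq_block(rf = rf_pulse(p$flip_excitation, "excitation", d_rf,
                              phase = 0, freq = freq, shape = p$rf_shape)))
  add(seq_block(gx = trap_for_area("x", g$a_half, g$pre_rise, g$pre_flat)))
  add(seq_block(delay = chk_delay(esp / 2 - d_rf - g$d_pre,
                                  "echo spacing/2 vs excitation-refocus gap")))
  n_echo <- length(pe_lines)
  for (k in seq_len(n_echo)) {
    add(seq_block(rf = rf_pulse(p$flip_refocus, "refocusing", d_rf,
                                phase = pi / 2, freq = freq,
                                shape = p$rf_shape)))
    a_pe <- (pe_lines[k] - n / 2) / p$fov
    add(seq_block(gy = trap_for_area("y", a_pe, g$blip_rise, 0)))
    add(seq_block(delay = chk_delay(esp / 2 - d_rf / 2 - g$d_blip - g$t_ec,
                                    "echo spacing/2 vs readout half-window")))
    ro <- grad_trap("x", g$gx, g$rise, g$flat, g$rise)
    adc <- if (adc_on)
      adc_event(n, g$dwell, delay = g$rise + g$pad_pre, freq = freq,
                echo_index = k)
    add(seq_block(gx = ro, adc = adc))
    add(seq_block(gy = trap_for_area("y", -a_pe, g$blip_rise, 0)))
    if (k < n_echo)
      add(seq_block(delay = chk_delay(
        esp / 2 - (g$ro_dur - g$t_ec) - g$d_blip - d_rf / 2,
        "inter-echo gap")))
  }
  blocks
}

seg_duration <- function(blocks) sum(vapply(blocks, `[[`, numeric(1), "duration"))

# assemble full sequence: one TR cycle = all slices' segments + fill delay
build_cycles <- function(p, g, pe_for_cycle, esp, with_inversion, name) {
  so <- random_slice_order(p$n_slices, p$slice_order_seed)
  n_cycles <- length(pe_for_cycle)
  blocks <- list()
  seg_dur <- NULL
  for (cyc in seq_len(p$n_dummy + n_cycles)) {
    is_dummy <- cyc <= p$n_dummy
    pe_lines <- pe_for_cycle[[if (is_dummy) 1L else cyc - p$n_dummy]]
    for (sl in so$order) {
      seg <- se_segment(p, g, sl, pe_lines, esp, adc_on = !is_dummy,
                        with_inversion = with_inversion)
      if (is.null(seg_dur)) seg_dur <- seg_duration(seg)
      blocks <- c(blocks, seg)
    }
    fill <- p$tr - p$n_slices * seg_dur
    if (fill < -1e-12)
      stop(sprintf(paste0("infeasible timing: %d slice segments of %.3f ms ",
                          "exceed TR = %.3f ms"),
                   p$n_slices, seg_dur * 1e3, p$tr * 1e3))
    blocks[[length(blocks) + 1L]] <- seq_block(delay = quantize_time(fill, RASTER_RF))
  }
  meta <- list(name = name, fov = p$fov, n = p$matrix_n, ns = p$n_slices,
               thk = p$slice_thickness, tr = p$tr, te = p$te, ti = p$ti,
               params = p, slice_order = so)
  new_sequence(blocks, meta)
}

# --- builders --------------------------------------------------------------

#' Build an inversion-recovery spin-echo (IRSE) sequence
#'
#' Per TR and slice: 180 degree inversion, delay to TI, 90 degree
#' excitation, refocusing pulse at TE/2 and a readout whose echo-center
#' sample falls at TE.  One PE line per excitation, acquired in sequential
#' line order; slices are interleaved within each TR in the randomized
#' slice order.  Residual transverse magnetization is spoiled by the
#' simulator contract at each excitation/inversion.
#'
#' @param params a [protocol_params()] with `ti` set and `etl = 1`.
#' @return a `pulseq_seq`.
#' @export
make_irse <- function(params) {
  p <- params
  if (is.null(p$ti)) stop("IRSE requires an inversion time (ti)")
  if (p$etl != 1) stop("IRSE uses etl = 1")
  if (p$ti + p$te >= p$tr)
    stop(sprintf("infeasible timing: TI + TE = %.1f ms does not fit in TR = %.1f ms",
                 (p$ti + p$te) * 1e3, p$tr * 1e3))
  g <- se_geometry(p)
  pe_for_cycle <- lapply(seq_len(p$matrix_n) - 1L, function(l) l)
  build_cycles(p, g, pe_for_cycle, esp = p$te, with_inversion = TRUE,
               name = sprintf("irse_TI%.0fms", p$ti * 1e3))
}

#' Build a turbo spin-echo (TSE) sequence
#'
#' One excitation followed by `etl` refocusing pulses; echo `k` of
#' excitation `j` acquires PE line `pe_order$table[k, j]` from the banded
#' phase-encode order, so `matrix_n / etl` excitations cover k-space once.
#' With `etl = 1` this degenerates to a conventional spin echo (identical
#' timing to [make_irse()] without the inversion block).
#'
#' @param params a [protocol_params()]; `matrix_n` must be divisible by
#'   `etl`.
#' @return a `pulseq_seq`.
#' @export
make_tse <- function(params) {
  p <- params
  if (p$matrix_n %% p$etl != 0)
    stop("matrix_n must be divisible by etl")
  po <- tse_pe_order(p$matrix_n, p$etl, min(p$center_echo, p$etl))
  g <- se_geometry(p)
  esp <- p$echo_spacing
  pe_for_cycle <- lapply(seq_len(po$n_excitations), function(j) po$table[, j])
  out <- build_cycles(p, g, pe_for_cycle, esp = esp, with_inversion = FALSE,
                      name = sprintf("tse_TR%.0fms_TE%.0fms_%decho",
                                     p$tr * 1e3, p$te * 1e3, p$etl))
  out$meta$pe_order <- po
  out
}

#' Build a multi-echo TSE sequence for T2 mapping
#'
#' Every excitation acquires a single PE line at all `length(te_list)`
#' echoes, so each echo index yields a complete k-space at its own TE;
#' `matrix_n` excitations cover k-space once per echo.
#'
#' @param params a [protocol_params()] with `te_list` an arithmetic
#'   progression starting at `echo_spacing`.
#' @return a `pulseq_seq`.
#' @export
make_multiecho_tse <- function(params) {
  p <- params
  if (is.null(p$te_list)) stop("multi-echo TSE requires te_list")
  esp <- p$echo_spacing
  if (abs(p$te_list[1] - esp) > 1e-9)
    stop("te_list must start at echo_spacing (echo k occurs at k*echo_spacing)")
  if (length(p$te_list) > 1 && any(abs(diff(p$te_list) - esp) > 1e-9))
    stop("te_list must be an arithmetic progression with step echo_spacing")
  n_echo <- length(p$te_list)
  p$te <- p$te_list[1]
  g <- se_geometry(p)
  pe_for_cycle <- lapply(seq_len(p$matrix_n) - 1L,
                         function(l) rep(l, n_echo))
  out <- build_cycles(p, g, pe_for_cycle, esp = esp, with_inversion = FALSE,
                      name = sprintf("tse_multiecho_%dte", n_echo))
  out$meta$te_list <- p$te_list
  out
}

#' Build the multi-TI IRSE protocol for T1 mapping
#'
#' One IRSE sequence per inversion time, identical except for the
#' inversion delay; list order follows `ti_list`.
#'
#' @param params a [protocol_params()] with nonempty `ti_list`.
#' @return a list of `pulseq_seq`, one per TI.
#' @export
make_t1_protocol <- function(params) {
  p <- params
  if (is.null(p$ti_list) || !length(p$ti_list))
    stop("T1 protocol requires a nonempty ti_list")
  lapply(p$ti_list, function(ti) {
    pi_ <- p; pi_$ti <- ti
    tryCatch(make_irse(pi_), error = function(e)
      stop(sprintf("TI = %.0f ms: %s", ti * 1e3, conditionMessage(e))))
  })
}
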