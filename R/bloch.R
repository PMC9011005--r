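# Isochromat Bloch simulator.
#
# Evolution model: relaxation and gradient-induced precession are applied
# as exact piecewise closed-form updates between events (gradient phase is
# integrated analytically over trapezoid segments, no time stepping); RF
# pulses act instantaneously at the pulse center (hard-pulse
# approximation), with relaxation running through the full pulse duration.
# Excitation and inversion pulses are true rotations preceded by ideal
# spoiling (residual transverse magnetization of all slices is zeroed,
# standing in for crusher gradients at TR boundaries).  Refocusing pulses
# are applied as ideal phase-reversal operators: mxy -> exp(2i*phase) *
# Conj(mxy) with mz unchanged.  Together these choices make the
# inversion-recovery steady state exactly
#   S = A * (1 - 2*exp(-TI/T1) + exp(-TR/T1)) * exp(-TE/T2),
# the signal model the parameter mapping fits.

#' Magnetization state
#'
#' @param mxy complex transverse magnetization (rotating frame).
#' @param mz real longitudinal magnetization.
#' @param m0 equilibrium magnetization.
#' @return a list of class `magnetization`; vectors are accepted for
#'   ensemble states.
#' @export
magnetization <- function(mxy = 0 + 0i, mz = 1, m0 = 1) {
  structure(list(mxy = as.complex(mxy), mz = as.numeric(mz),
                 m0 = as.numeric(m0)), class = "magnetization")
}

#' Instantaneous RF rotation
#'
#' Rotates the magnetization by `flip` about the transverse axis at angle
#' `phase`; with `phase = 0` (rotation about +x) a flip of pi/2 maps +z to
#' -y, i.e. `mxy = -1i`.  The rotation preserves the magnetization norm.
#'
#' @param m a [magnetization()] (fields may be vectors).
#' @param flip flip angle in radians.
#' @param phase rotation-axis angle in radians.
#' @return the rotated `magnetization`.
#' @export
apply_rf <- function(m, flip, phase = 0) {
  c2 <- cos(flip / 2)^2
  s2 <- sin(flip / 2)^2
  sa <- sin(flip)
  e1 <- exp(1i * phase)
  mxy <- m$mxy * c2 + e1^2 * Conj(m$mxy) * s2 - 1i * e1 * m$mz * sa
  mz <- m$mz * cos(flip) + Im(m$mxy * Conj(e1)) * sa
  magnetization(mxy, mz, m$m0)
}

# ideal refocusing: transverse phase reversal about the axis at `phase`,
# longitudinal magnetization untouched (see module header)
apply_refocus <- function(m, phase = pi / 2) {
  m$mxy <- exp(2i * phase) * Conj(m$mxy)
  m
}

#' Free precession and relaxation
#'
#' Closed-form relaxation over `dt` with accumulated precession angle
#' `dphi` (radians): `mxy' = mxy * exp(-dt/t2) * exp(-1i*dphi)` and
#' `mz' = m0 + (mz - m0) * exp(-dt/t1)`.  For an isochromat at position
#' `r` under a gradient `g` (Hz/m), `dphi = 2*pi*g*r*dt`.
#'
#' @param m a [magnetization()].
#' @param dt interval in seconds (>= 0).
#' @param t1,t2 relaxation times in seconds (> 0).
#' @param dphi accumulated precession angle in radians.
#' @return the evolved `magnetization`.
#' @export
free_precess <- function(m, dt, t1, t2, dphi = 0) {
  stopifnot(dt >= 0, all(t1 > 0), all(t2 > 0))
  magnetization(m$mxy * exp(-dt / t2 - 1i * dphi),
                m$m0 + (m$mz - m$m0) * exp(-dt / t1),
                m$m0)
}

#' Simulate a sequence on a phantom
#'
#' Executes the event timeline against every isochromat of the phantom and
#' returns raw k-space in the `(samples, channels, readouts)` layout with
#' per-readout metadata (slice, PE line, echo index, echo time).  Slices
#' are ideal: every slice excites an independent copy of the 2D phantom,
#' selected by the RF/ADC frequency offset.
#'
#' @param seq a `pulseq_seq` containing at least one ADC event.
#' @param phantom a `qmri_phantom`.
#' @param sensitivities optional list of complex coil-sensitivity matrices
#'   (same size as the phantom maps); default is a single uniform channel.
#' @param seed unused at present (the simulator is deterministic); kept so
#'   stochastic extensions do not change the signature.
#' @return an object of class `raw_kspace` with elements `samples`
#'   (complex array samples x channels x readouts), `meta` (data.frame),
#'   `dwell`, `matrix_n`, `fov`, `seq_meta`.
#' @export
simulate_sequence <- function(seq, phantom, sensitivities = NULL, seed = 0) {
  stopifnot(inherits(seq, "pulseq_seq"), inherits(phantom, "qmri_phantom"))
  iso <- to_isochromats(phantom)
  if (nrow(iso) == 0) {
    warning("phantom has no isochromats; signal will be empty")
  }
  ann <- annotate_readouts(seq)
  if (is.null(ann$readouts))
    stop("sequence contains no ADC event; nothing to simulate")
  ro_meta <- ann$readouts
  ns <- if (!is.null(seq$meta$ns)) seq$meta$ns else 1L

  n_iso <- nrow(iso)
  x <- iso$x; y <- iso$y; pd <- iso$pd
  r1 <- 1 / iso$t1; r2 <- 1 / iso$t2

  sens <- if (is.null(sensitivities)) {
    list(rep(1 + 0i, n_iso))
  } else {
    lapply(sensitivities, function(s) {
      as.complex(s[cbind(iso$row, iso$col)])
    })
  }
  n_ch <- length(sens)

  # state: one column per slice
  mxy <- matrix(0 + 0i, n_iso, ns)
  mz <- matrix(1, n_iso, ns)

  evolve <- function(dt, ix, iy) {
    if (dt <= 0 && ix == 0 && iy == 0) return()
    decay <- exp(-dt * r2 - 2i * pi * (x * ix + y * iy))
    mxy <<- mxy * decay
    e1 <- exp(-dt * r1)
    mz <<- 1 + (mz - 1) * e1
  }

  n_ro <- nrow(ro_meta)
  first_adc <- ro_meta$block[1]
  samples_list <- vector("list", n_ro)
  ro_i <- 0L
  t_abs <- 0

  for (bi in seq_along(seq$blocks)) {
    b <- seq$blocks[[bi]]
    if (!is.null(b$rf)) {
      rf <- b$rf
      tc <- rf$delay + rf$center
      evolve(tc, trap_integral(b$gx, 0, tc), trap_integral(b$gy, 0, tc))
      sl <- slice_from_freq(rf$freq, ns) + 1L
      if (rf$use == "refocusing") {
        mxy[, sl] <- exp(2i * rf$phase) * Conj(mxy[, sl])
      } else {
        mxy[] <- 0 + 0i                       # ideal spoiling
        flip <- rf_flip(rf)
        st <- apply_rf(magnetization(mxy[, sl], mz[, sl]), flip, rf$phase)
        mxy[, sl] <- st$mxy
        mz[, sl] <- st$mz
      }
      evolve(b$duration - tc,
             trap_integral(b$gx, tc, b$duration),
             trap_integral(b$gy, tc, b$duration))
    } else if (!is.null(b$adc)) {
      adc <- b$adc
      ro_i <- ro_i + 1L
      sl <- slice_from_freq(adc$freq, ns) + 1L
      ts <- adc_sample_times(adc)
      # analytic evolution from block start to each sample time
      ix <- vapply(ts, function(t) trap_integral(b$gx, 0, t), numeric(1))
      iy <- vapply(ts, function(t) trap_integral(b$gy, 0, t), numeric(1))
      decay <- exp(outer(-r2, ts) -
                   2i * pi * (outer(x, ix) + outer(y, iy)))
      sig <- matrix(0 + 0i, adc$num, n_ch)
      for (ch in seq_len(n_ch)) {
        w <- pd * sens[[ch]] * mxy[, sl]
        sig[, ch] <- colSums(w * decay)
      }
      samples_list[[ro_i]] <- sig
      evolve(b$duration,
             trap_integral(b$gx, 0, b$duration),
             trap_integral(b$gy, 0, b$duration))
    } else {
      evolve(b$duration,
             trap_integral(b$gx, 0, b$duration),
             trap_integral(b$gy, 0, b$duration))
    }
    t_abs <- t_abs + b$duration
  }

  nsamp <- nrow(samples_list[[1]])
  samples <- array(0 + 0i, dim = c(nsamp, n_ch, n_ro))
  for (k in seq_len(n_ro)) samples[, , k] <- samples_list[[k]]

  structure(list(
    samples = samples,
    meta = ro_meta[c("slice", "echo", "pe_line", "t_center", "t_since_exc")],
    dwell = seq$blocks[[first_adc]]$adc$dwell,
    matrix_n = seq$meta$n,
    fov = seq$meta$fov,
    seq_meta = seq$meta[c("name", "tr", "te", "ti", "ns")]
  ), class = "raw_kspace")
}

#' @export
print.raw_kspace <- function(x, ...) {
  d <- dim(x$samples)
  cat("<raw_kspace>", d[1], "samples x", d[2], "channels x", d[3],
      "readouts\n")
  cat("  slices:", length(unique(x$meta$slice)),
      " echoes:", max(x$meta$echo), "\n")
  invisible(x)
}

#' Prepend steady-state preparation cycles
#'
#' Rebuilds the sequence with `n_dummy` leading excitation cycles whose
#' ADC events are disabled; the duration grows by exactly `n_dummy * TR`.
#' Requires a sequence produced by one of the protocol builders (which
#' store their parameters in the sequence metadata).
#'
#' @param seq a builder-generated `pulseq_seq`.
#' @param n_dummy number of preparation cycles (>= 0).
#' @return a `pulseq_seq`.
#' @export
steady_state_prep <- function(seq, n_dummy) {
  stopifnot(n_dummy >= 0)
  p <- seq$meta$params
  if (is.null(p))
    stop("steady_state_prep needs a builder-generated sequence ",
         "(metadata carries no protocol parameters)")
  p$n_dummy <- p$n_dummy + as.integer(n_dummy)
  if (!is.null(p$te_list)) return(make_multiecho_tse(p))
  if (!is.null(p$ti)) return(make_irse(p))
  make_tse(p)
}
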