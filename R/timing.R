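# Event-timeline audit: everything here is measured from the block list,
# never copied from sequence metadata.

# Per-readout annotation shared by the timing auditor, the simulator and
# k-space sorting.  Tracks, per slice, the last excitation time and echo
# counter; tracks the k-space position (kx, ky) accumulated from gradient
# areas, reset at each excitation and sign-flipped at each refocusing pulse
# (phase reversal of the transverse magnetization negates accumulated
# spatial phase).
annotate_readouts <- function(seq) {
  ns <- if (!is.null(seq$meta$ns)) seq$meta$ns else 1L
  n  <- seq$meta$n
  fov <- seq$meta$fov
  t0 <- 0
  kx <- 0; ky <- 0
  last_exc <- rep(NA_real_, ns)
  echo_ct  <- rep(0L, ns)
  active <- NA_integer_
  rf_log <- list()
  ro_log <- list()
  for (bi in seq_along(seq$blocks)) {
    b <- seq$blocks[[bi]]
    if (!is.null(b$rf)) {
      rf <- b$rf
      tc <- t0 + rf$delay + rf$center
      sl <- slice_from_freq(rf$freq, ns)
      if (rf$use == "refocusing") {
        # gradient area accumulated before the pulse center, then negated
        kx <- -(kx + trap_integral(b$gx, 0, rf$delay + rf$center))
        ky <- -(ky + trap_integral(b$gy, 0, rf$delay + rf$center))
        kx <- kx + trap_integral(b$gx, rf$delay + rf$center, b$duration)
        ky <- ky + trap_integral(b$gy, rf$delay + rf$center, b$duration)
      } else {
        kx <- 0; ky <- 0
        if (rf$use == "excitation") {
          last_exc[sl + 1L] <- tc
          echo_ct[sl + 1L] <- 0L
          active <- sl
        }
      }
      rf_log[[length(rf_log) + 1L]] <-
        data.frame(t = tc, use = rf$use, slice = sl, flip = rf_flip(rf))
    } else {
      kx <- kx + trap_integral(b$gx, 0, b$duration)
      ky <- ky + trap_integral(b$gy, 0, b$duration)
    }
    if (!is.null(b$adc)) {
      adc <- b$adc
      sl <- slice_from_freq(adc$freq, ns)
      echo_ct[sl + 1L] <- echo_ct[sl + 1L] + 1L
      t_ec <- t0 + adc_echo_time(adc)
      ky_ec <- ky + trap_integral(b$gy, 0, adc_echo_time(adc))
      pe <- if (!is.null(n)) as.integer(round(ky_ec * fov + n / 2)) else NA_integer_
      ro_log[[length(ro_log) + 1L]] <- data.frame(
        block = bi, slice = sl, echo = echo_ct[sl + 1L],
        pe_line = pe, t_center = t_ec,
        t_since_exc = t_ec - last_exc[sl + 1L],
        t_exc = last_exc[sl + 1L])
    }
    t0 <- t0 + b$duration
  }
  list(rf = if (length(rf_log)) do.call(rbind, rf_log) else NULL,
       readouts = if (length(ro_log)) do.call(rbind, ro_log) else NULL,
       duration = t0)
}

#' Audit sequence timing from the event timeline
#'
#' Measures TE, TI, TR, echo spacing and echo count directly from the block
#' list.  TE is the interval from an excitation center to the echo center
#' (the k-space-center ADC sample); for multi-line echo trains it is the
#' echo at which the central k-space line is acquired (the effective TE).
#' TI is inversion center to the next excitation center of the same slice;
#' TR is the interval between successive excitations of the same slice.
#'
#' @param seq a `pulseq_seq` with at least one excitation and one ADC.
#' @return a list of class `timing_report` with elements `measured_te`,
#'   `measured_ti`, `measured_tr`, `echo_spacing`, `echo_times`,
#'   `echoes_per_excitation`, `n_slices_seen`, `total_duration`.
#' @export
timing_report <- function(seq) {
  ann <- annotate_readouts(seq)
  rf <- ann$rf
  if (is.null(rf) || !any(rf$use == "excitation"))
    stop("timing audit: sequence contains no excitation pulse")
  if (is.null(ann$readouts))
    stop("timing audit: sequence contains no ADC event")
  ro <- ann$readouts

  # TR: successive excitations of the same slice
  exc <- rf[rf$use == "excitation", ]
  tr_meas <- NA_real_
  for (sl in unique(exc$slice)) {
    tt <- exc$t[exc$slice == sl]
    if (length(tt) >= 2) { tr_meas <- diff(tt)[1]; break }
  }

  # TI: inversion center -> next excitation center, same slice
  ti_meas <- NA_real_
  inv <- rf[rf$use == "inversion", ]
  if (nrow(inv) > 0) {
    t_inv <- inv$t[1]; sl <- inv$slice[1]
    nxt <- exc$t[exc$slice == sl & exc$t > t_inv]
    if (length(nxt)) ti_meas <- nxt[1] - t_inv
  }

  # first excitation train that carries readouts
  first <- ro[ro$t_exc == min(ro$t_exc), , drop = FALSE]
  echo_times <- first$t_since_exc[order(first$echo)]
  esp <- if (length(echo_times) >= 2) diff(echo_times)[1] else NA_real_

  # effective TE: echo at which the central line is acquired
  n <- seq$meta$n
  te_meas <- echo_times[1]
  if (!is.null(n) && !any(is.na(ro$pe_line))) {
    ctr <- ro[ro$pe_line == n / 2, , drop = FALSE]
    if (nrow(ctr) > 0) {
      ec <- sort(unique(ctr$echo))
      if (length(ec) == 1) {
        one <- first$t_since_exc[first$echo == ec]
        te_meas <- if (length(one)) one else
          ctr$t_since_exc[ctr$echo == ec][1]
      }
      # central line at every echo (multi-echo): keep first-echo TE
    }
  }

  structure(list(
    measured_te = te_meas,
    measured_ti = ti_meas,
    measured_tr = tr_meas,
    echo_spacing = esp,
    echo_times = echo_times,
    echoes_per_excitation = max(ro$echo),
    n_slices_seen = length(unique(ro$slice)),
    total_duration = ann$duration
  ), class = "timing_report")
}

#' @export
print.timing_report <- function(x, ...) {
  ms <- function(v) if (is.na(v)) "NA" else sprintf("%.3f ms", v * 1e3)
  cat("<timing_report>\n")
  cat("  TE:", ms(x$measured_te), " TI:", ms(x$measured_ti),
      " TR:", ms(x$measured_tr), "\n")
  cat("  echoes/excitation:", x$echoes_per_excitation,
      " spacing:", ms(x$echo_spacing), "\n")
  cat("  slices seen:", x$n_slices_seen,
      " total duration:", sprintf("%.3f s", x$total_duration), "\n")
  invisible(x)
}
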