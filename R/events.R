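#' @title Pulse-sequence event model
#' @description
#' Sequences are ordered lists of blocks; each block holds at most one RF
#' event, one trapezoidal gradient per axis, one ADC window, and a pure
#' delay.  Units follow the Pulseq convention: RF amplitudes in Hz,
#' gradients in Hz/m, all times in seconds in the object model.  RF and ADC
#' events live on a 1 microsecond raster, gradients on a 10 microsecond
#' raster.
#' @name event-model
NULL

RASTER_RF   <- 1e-6
RASTER_GRAD <- 1e-5

RF_USES <- c("excitation", "refocusing", "inversion")

#' Create an RF pulse event
#'
#' The envelope is stored as a normalized shape sampled on the RF raster
#' together with a peak amplitude in Hz.  The flip angle is
#' `2*pi * amp * sum(shape) * raster`, i.e. 2*pi times the time integral of
#' the envelope.  Supported shapes are a constant (block) pulse and an
#' apodized sinc; both are symmetric, so the pulse center sits at half the
#' duration.
#'
#' @param flip flip angle in radians.
#' @param use one of `"excitation"`, `"refocusing"`, `"inversion"`.
#' @param duration pulse duration in seconds (multiple of the RF raster).
#' @param phase RF phase offset in radians.
#' @param freq frequency offset in Hz (used to tag the excited slice).
#' @param shape `"block"` or `"sinc"`.
#' @param tbw time-bandwidth product for the sinc shape.
#' @return an object of class `rf_event`.
#' @export
rf_pulse <- function(flip, use, duration = 1e-3, phase = 0, freq = 0,
                     shape = c("block", "sinc"), tbw = 4) {
  shape <- match.arg(shape)
  use <- match.arg(use, RF_USES)
  stopifnot(duration > 0, is.finite(flip))
  if (!on_raster(duration, RASTER_RF))
    stop("RF duration must be a multiple of the RF raster (1 us)")
  n <- round(duration / RASTER_RF)
  env <- switch(shape,
    block = rep(1, n),
    sinc = {
      t <- (seq_len(n) - 0.5) / n - 0.5        # [-0.5, 0.5)
      x <- tbw * t
      s <- ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x))
      w <- 0.54 + 0.46 * cos(2 * pi * t)       # Hamming apodization
      s * w
    })
  env <- env / max(abs(env))
  # peak amplitude from the signed envelope integral
  amp <- flip / (2 * pi * sum(env) * RASTER_RF)
  structure(list(
    type = "rf", amp = amp, shape = env, shape_name = shape,
    duration = n * RASTER_RF, delay = 0, freq = freq, phase = phase,
    center = n * RASTER_RF / 2, use = use
  ), class = "rf_event")
}

rf_flip <- function(rf) 2 * pi * rf$amp * sum(rf$shape) * RASTER_RF

#' Create a trapezoidal gradient event
#'
#' @param axis `"x"`, `"y"`, or `"z"`.
#' @param amplitude plateau amplitude in Hz/m.
#' @param rise,flat,fall segment durations in seconds (gradient raster).
#' @param delay delay from block start in seconds.
#' @return an object of class `grad_event`; its `area` (Hz s/m) is
#'   `amplitude * (flat + rise/2 + fall/2)`.
#' @export
grad_trap <- function(axis, amplitude, rise, flat, fall, delay = 0) {
  axis <- match.arg(axis, c("x", "y", "z"))
  stopifnot(rise >= 0, fall >= 0, flat >= 0, delay >= 0)
  for (t in c(rise, flat, fall, delay))
    if (!on_raster(t, RASTER_GRAD))
      stop("gradient segment times must be multiples of the gradient raster (10 us)")
  structure(list(
    type = "trap", axis = axis, amp = amplitude,
    rise = rise, flat = flat, fall = fall, delay = delay,
    duration = delay + rise + flat + fall
  ), class = "grad_event")
}

# plateau amplitude for a requested area with fixed ramp/flat timing
trap_for_area <- function(axis, area, rise, flat, fall = rise, delay = 0) {
  amp <- area / (flat + rise / 2 + fall / 2)
  grad_trap(axis, amp, rise, flat, fall, delay)
}

grad_area <- function(g) g$amp * (g$flat + g$rise / 2 + g$fall / 2)

# integral of the trapezoid waveform from block time ta to tb (Hz s/m)
trap_integral <- function(g, ta, tb) {
  if (is.null(g)) return(0)
  # cumulative integral at time t from block start
  cum <- function(t) {
    t <- t - g$delay
    if (t <= 0) return(0)
    a <- 0
    tr <- min(t, g$rise)
    if (g$rise > 0) a <- a + g$amp * tr^2 / (2 * g$rise) else a <- a
    if (t <= g$rise) return(a)
    tf <- min(t - g$rise, g$flat)
    a <- a + g$amp * tf
    if (t <= g$rise + g$flat) return(a)
    td <- min(t - g$rise - g$flat, g$fall)
    if (g$fall > 0) a <- a + g$amp * (td - td^2 / (2 * g$fall))
    a
  }
  cum(tb) - cum(ta)
}

#' Create an ADC (readout) event
#'
#' Samples are taken at the centers of `num` consecutive dwell intervals
#' starting `delay` seconds into the block.  The echo-center sample is the
#' one with 0-based index `num/2` (the k-space center sample).
#'
#' @param num number of samples.
#' @param dwell dwell time in seconds.
#' @param delay delay from block start in seconds.
#' @param freq,phase receiver frequency (Hz) and phase (rad) offsets.
#' @param echo_index 1-based echo number within the excitation train.
#' @return an object of class `adc_event`.
#' @export
adc_event <- function(num, dwell, delay = 0, freq = 0, phase = 0,
                      echo_index = 1L) {
  stopifnot(num >= 1, dwell > 0, delay >= 0, echo_index >= 1)
  structure(list(
    type = "adc", num = as.integer(num), dwell = dwell, delay = delay,
    freq = freq, phase = phase, echo_index = as.integer(echo_index),
    duration = delay + num * dwell
  ), class = "adc_event")
}

# block-relative time of the echo-center sample (0-based index num/2)
adc_echo_time <- function(adc) {
  adc$delay + (floor(adc$num / 2) + 0.5) * adc$dwell
}

adc_sample_times <- function(adc) {
  adc$delay + (seq_len(adc$num) - 0.5) * adc$dwell
}

#' Assemble a sequence block
#'
#' A block holds at most one RF event, one gradient per axis, one ADC and a
#' pure delay; its duration is the maximum event end time (or the explicit
#' delay, whichever is longer).
#'
#' @param rf,gx,gy,gz,adc optional events.
#' @param delay pure delay in seconds.
#' @return an object of class `seq_block`.
#' @export
seq_block <- function(rf = NULL, gx = NULL, gy = NULL, gz = NULL,
                      adc = NULL, delay = 0) {
  evs <- list(rf = rf, gx = gx, gy = gy, gz = gz, adc = adc)
  dur <- delay
  for (e in evs) if (!is.null(e)) dur <- max(dur, e$duration)
  structure(list(rf = rf, gx = gx, gy = gy, gz = gz, adc = adc,
                 delay = delay, duration = dur),
            class = "seq_block")
}

#' Assemble a sequence from blocks
#'
#' @param blocks list of [seq_block()] objects.
#' @param meta named list of nominal metadata: `name`, `fov` (m), `n`
#'   (matrix size), `ns` (slices), `thk` (m), `tr`, `te`, `ti` (seconds;
#'   `ti` optional), plus builder bookkeeping.
#' @return an object of class `pulseq_seq`.
#' @export
new_sequence <- function(blocks, meta = list()) {
  stopifnot(length(blocks) >= 1)
  structure(list(blocks = blocks, meta = meta,
                 raster_rf = RASTER_RF, raster_grad = RASTER_GRAD),
            class = "pulseq_seq")
}

#' Total duration of a sequence
#'
#' @param seq a `pulseq_seq`.
#' @return duration in seconds (exact sum of block durations).
#' @export
seq_duration <- function(seq) {
  sum(vapply(seq$blocks, function(b) b$duration, numeric(1)))
}

#' @export
print.pulseq_seq <- function(x, ...) {
  m <- x$meta
  cat("<pulseq_seq>", if (!is.null(m$name)) m$name else "", "\n")
  cat("  blocks:", length(x$blocks),
      " duration:", format(seq_duration(x), digits = 6), "s\n")
  if (!is.null(m$n))
    cat("  matrix:", m$n, " slices:", m$ns,
        " FOV:", m$fov, "m\n")
  tims <- c(TR = m$tr, TE = m$te, TI = m$ti)
  tims <- tims[!vapply(tims, is.null, logical(1))]
  if (length(tims))
    cat("  nominal:", paste(names(tims), unlist(tims), sep = "=",
                            collapse = "  "), "(s)\n")
  invisible(x)
}

# slice index (0-based) from an RF/ADC frequency offset; slices are tagged
# with freq = (slice - (ns-1)/2) * SLICE_FREQ_STEP
SLICE_FREQ_STEP <- 1000
slice_from_freq <- function(freq, ns) {
  as.integer(round(freq / SLICE_FREQ_STEP + (ns - 1) / 2))
}
freq_for_slice <- function(slice, ns) {
  (slice - (ns - 1) / 2) * SLICE_FREQ_STEP
}
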