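# Image-quality metrics (PSNR, SSIM on [0,1]-normalized images) and a
# relative RF-power monitor.

#' Peak signal-to-noise ratio
#'
#' `10*log10(R^2 / MSE)` with data range `R = 1` for jointly normalized
#' images.  Identical images are reported with the capped sentinel
#' `max_db`.
#'
#' @param reference,test congruent numeric images in [0, 1].
#' @param data_range dynamic range R (default 1).
#' @param max_db sentinel cap in dB for (near-)identical images.
#' @return PSNR in dB.
#' @export
psnr <- function(reference, test, data_range = 1, max_db = 300) {
  stopifnot(all(dim(reference) == dim(test)))
  mse <- mean((reference - test)^2)
  if (mse <= data_range^2 * 10^(-max_db / 10)) return(max_db)
  10 * log10(data_range^2 / mse)
}

# separable Gaussian filter with reflected edges (matches
# scipy.ndimage.gaussian_filter defaults used by the reference SSIM)
gaussian_filter2 <- function(img, sigma = 1.5, truncate = 3.5) {
  r <- as.integer(truncate * sigma + 0.5)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  n1 <- nrow(img); n2 <- ncol(img)
  refl <- function(n) c(seq(r, 1), seq_len(n), seq(n, n - r + 1))
  pad <- img[refl(n1), refl(n2)]
  # convolve rows then columns
  out <- apply(pad, 2, function(col) stats::filter(col, k, sides = 2))
  out <- t(apply(out, 1, function(row) stats::filter(row, k, sides = 2)))
  out[r + seq_len(n1), r + seq_len(n2)]
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM with an 11-point Gaussian window (sigma = 1.5),
#' constants `C1 = (0.01 R)^2`, `C2 = (0.03 R)^2`, weighted covariances
#' (no sample-covariance correction), and the border of half a window
#' width excluded from the mean - the standard configuration of the
#' original SSIM publication.
#'
#' @param reference,test congruent numeric images in [0, 1].
#' @param data_range dynamic range R (default 1).
#' @param sigma Gaussian window standard deviation in voxels.
#' @return SSIM in [-1, 1]; 1 for identical images.
#' @export
ssim <- function(reference, test, data_range = 1, sigma = 1.5) {
  stopifnot(all(dim(reference) == dim(test)))
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  f <- function(m) gaussian_filter2(m, sigma)
  ux <- f(reference); uy <- f(test)
  vx <- f(reference^2) - ux^2
  vy <- f(test^2) - uy^2
  vxy <- f(reference * test) - ux * uy
  s <- ((2 * ux * uy + c1) * (2 * vxy + c2)) /
    ((ux^2 + uy^2 + c1) * (vx + vy + c2))
  r <- as.integer(3.5 * sigma + 0.5)
  n1 <- nrow(s); n2 <- ncol(s)
  mean(s[(r + 1):(n1 - r), (r + 1):(n2 - r)])
}

#' Relative RF power summary of a sequence
#'
#' Time-averaged squared RF amplitude, `mean(|b1(t)|^2)` over the full
#' sequence duration, in Hz^2 (relative units - no electromagnetic body
#' model, so no W/kg claim), plus the RF duty cycle and the bookkeeping
#' reference mass.
#'
#' @param seq a `pulseq_seq` with positive duration.
#' @param mass reference subject mass in kg (recorded, default 70).
#' @return a list of class `rf_power_report` with `time_averaged_b1sq`
#'   (Hz^2), `rf_energy` (Hz^2 s), `duty_cycle`, `reference_mass`.
#' @export
rf_power_summary <- function(seq, mass = 70) {
  stopifnot(inherits(seq, "pulseq_seq"))
  dur <- seq_duration(seq)
  if (dur <= 0) stop("sequence has no duration")
  energy <- 0
  on_time <- 0
  for (b in seq$blocks) {
    if (is.null(b$rf)) next
    rf <- b$rf
    energy <- energy + rf$amp^2 * sum(Mod(rf$shape)^2) * RASTER_RF
    on_time <- on_time + rf$duration
  }
  structure(list(time_averaged_b1sq = energy / dur,
                 rf_energy = energy,
                 duty_cycle = on_time / dur,
                 reference_mass = mass,
                 duration = dur),
            class = "rf_power_report")
}

#' @export
print.rf_power_report <- function(x, ...) {
  cat("<rf_power_report>\n")
  cat(sprintf("  time-averaged |B1|^2: %.4g Hz^2 (relative units)\n",
              x$time_averaged_b1sq))
  cat(sprintf("  RF duty cycle: %.4f; reference mass: %g kg\n",
              x$duty_cycle, x$reference_mass))
  invisible(x)
}
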