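# Voxel-wise T1/T2 mapping from multi-contrast image sets.
#
# Signal models (magnitude data; A = signal scaling, B = signal offset):
#   inversion recovery:  S(TI) = | A*(1 - 2*exp(-TI/T1) + exp(-TR/T1)) + B |
#   spin-echo decay:     S(TE) =   A*exp(-TE/T2) + B
# Fits use bounded Levenberg-Marquardt least squares with deterministic
# initializers (no random restarts): T1 from the signal-null location
# TI_min / ln 2, T2 from a log-linear regression of the offset-corrected
# decay.

t1_signal <- function(ti, t1, a, b, tr) {
  a * (1 - 2 * exp(-ti / t1) + exp(-tr / t1)) + b
}

t2_signal <- function(te, t2, a, b) {
  a * exp(-te / t2) + b
}

fit_result <- function(value, a, b, residual_rms, converged) {
  list(value = value, a = a, b = b, residual_rms = residual_rms,
       converged = converged)
}

fail_fit <- function() fit_result(NA_real_, NA_real_, NA_real_, NA_real_, FALSE)

#' Fit the inversion-recovery T1 model to one voxel
#'
#' Fits `|A*(1 - 2*exp(-TI/T1) + exp(-TR/T1)) + B|` to magnitude signals
#' (the absolute value accommodates the polarity lost in magnitude
#' reconstruction).  T1 is bounded to [1 ms, 10 s] and initialized from
#' the signal minimum: for TR much larger than T1 the magnitude null sits
#' at `TI = T1*ln 2`.
#'
#' @param signal non-negative magnitudes, one per TI.
#' @param ti_list inversion times in seconds, strictly increasing,
#'   length >= 4.
#' @param tr repetition time in seconds.
#' @return a fit result list: `value` (T1, seconds), `a`, `b`,
#'   `residual_rms`, `converged`.  Never throws on non-convergence.
#' @export
fit_t1_voxel <- function(signal, ti_list, tr) {
  if (length(signal) != length(ti_list) || length(signal) < 4)
    stop("need >= 4 TI points matching the signal length")
  if (any(diff(ti_list) <= 0)) stop("ti_list must be strictly increasing")
  smax <- max(signal)
  if (!is.finite(smax) || smax <= 0) return(fail_fit())
  lower <- c(1e-3, 0, -Inf)
  upper <- c(10, Inf, Inf)
  res_fn <- function(p)
    abs(t1_signal(ti_list, p[1], p[2], p[3], tr)) - signal
  # The magnitude model has narrow local minima when the signal null falls
  # between sampled TIs.  Global initialization: restore candidate signal
  # polarities (first k points negated, k = 0..n), solve the then-linear
  # (A, B) least squares on a dense log-spaced T1 grid, and polish the best
  # candidate with one bounded Levenberg-Marquardt fit of the magnitude
  # model.
  n <- length(signal)
  grid <- exp(seq(log(lower[1]), log(upper[1]), length.out = 150))
  G <- 1 - 2 * exp(-outer(ti_list, 1 / grid)) +
    matrix(exp(-tr / grid), n, length(grid), byrow = TRUE)
  S1 <- colSums(G); S2 <- colSums(G^2)
  syy <- sum(signal^2)
  best <- c(rss = Inf, t1 = NA, a = NA, b = NA)
  for (k in 0:n) {
    signed <- signal * c(rep(-1, k), rep(1, n - k))
    sy <- sum(signed)
    sgy <- colSums(G * signed)
    den <- n * S2 - S1^2
    a <- (n * sgy - S1 * sy) / den
    b <- (sy - a * S1) / n
    rss <- pmax(syy - 2 * a * sgy - 2 * b * sy + a^2 * S2 +
                  2 * a * b * S1 + n * b^2, 0)
    # exclude nearly-constant model columns (collinear with the offset),
    # where the normal equations cancel catastrophically
    rss[a < 0 | !is.finite(rss) | den <= 1e-9 * n * S2] <- Inf
    i <- which.min(rss)
    if (rss[i] < best["rss"])
      best <- c(rss = rss[i], t1 = grid[i], a = a[i], b = b[i])
  }
  if (!is.finite(best["rss"])) return(fail_fit())
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(t1 = best[["t1"]], a = best[["a"]],
                               b = best[["b"]]),
                       lower = lower, upper = upper, fn = res_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ftol = 1e-10, ptol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail_fit())
  # keep the polish only if it did not leave the global basin (compare
  # magnitude-model costs; the grid cost is for the signed model)
  p <- fit$par
  p0 <- c(t1 = best[["t1"]], a = best[["a"]], b = best[["b"]])
  if (sum(res_fn(p)^2) > sum(res_fn(p0)^2)) p <- p0
  ok <- is.finite(p[1]) && p[1] > lower[1] * 1.001 && p[1] < upper[1] * 0.999
  fit_result(unname(p[1]), unname(p[2]), unname(p[3]),
             sqrt(mean(res_fn(p)^2)), ok)
}

#' Fit the exponential T2 decay model to one voxel
#'
#' Fits `A*exp(-TE/T2) + B`; T2 is initialized from a log-linear
#' regression of the offset-corrected signal and bounded to [1 ms, 10 s].
#' A constant (non-decaying) signal yields `converged = FALSE`.
#'
#' @param signal non-negative magnitudes, one per TE.
#' @param te_list echo times in seconds, strictly increasing, length >= 3.
#' @return a fit result list as in [fit_t1_voxel()], `value` being T2.
#' @export
fit_t2_voxel <- function(signal, te_list) {
  if (length(signal) != length(te_list) || length(signal) < 3)
    stop("need >= 3 TE points matching the signal length")
  if (any(diff(te_list) <= 0)) stop("te_list must be strictly increasing")
  smax <- max(signal)
  if (!is.finite(smax) || smax <= 0) return(fail_fit())
  lower <- c(1e-3, 0, -Inf)
  upper <- c(10, Inf, Inf)
  s0 <- signal - min(signal)
  use <- s0 > 0.02 * max(s0)
  t2_0 <- 0.05
  a0 <- smax
  if (sum(use) >= 2) {
    co <- stats::coef(stats::lm(log(s0[use]) ~ te_list[use]))
    if (is.finite(co[2]) && co[2] < 0) {
      t2_0 <- min(max(-1 / co[2], lower[1]), upper[1])
      a0 <- exp(co[1])
    }
  }
  par0 <- c(t2 = t2_0, a = a0, b = min(signal))
  res_fn <- function(p) t2_signal(te_list, p[1], p[2], p[3]) - signal
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                       fn = res_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ftol = 1e-10, ptol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail_fit())
  p <- fit$par
  ok <- fit$info %in% 1:4 && is.finite(p[1]) && p[1] > lower[1] * 1.001 &&
    p[1] < upper[1] * 0.999 && p[2] > 0
  fit_result(unname(p[1]), unname(p[2]), unname(p[3]),
             sqrt(mean(res_fn(p)^2)), ok)
}

#' Voxel-wise parameter mapping over an image set
#'
#' Applies [fit_t1_voxel()] or [fit_t2_voxel()] to every voxel inside the
#' mask.  The image-set contrast axis must match the requested map kind
#' (`"TI"` for T1, `"TE"` for T2).  `echo_subset` restricts the contrasts
#' used, e.g. `5:23` to fit only the later echoes of a 23-echo
#' acquisition.
#'
#' @param images an `image_set` with a TI or TE contrast axis.
#' @param kind `"t1"` or `"t2"`.
#' @param mask logical matrix of voxels to fit; default: voxels whose
#'   maximum signal across contrasts exceeds 10 percent of the global
#'   maximum (a programmatic stand-in for a drawn phantom ROI).
#' @param echo_subset optional integer indices of contrasts to use.
#' @param tr repetition time in seconds (T1 fits; defaults to the value
#'   recorded in the image set).
#' @return an object of class `qmri_parmap` with matrices `map` (seconds),
#'   `a`, `b`, `residual_rms`, logical `converged`, plus `kind`, `mask`,
#'   `axis_values`.
#' @export
map_fit <- function(images, kind = c("t1", "t2"), mask = NULL,
                    echo_subset = NULL, tr = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(images, "image_set"))
  want <- if (kind == "t1") "TI" else "TE"
  if (!identical(images$axis_kind, want))
    stop(sprintf("contrast axis mismatch: %s mapping needs a %s axis, got %s",
                 kind, want, images$axis_kind))
  ax <- images$axis_values
  dat <- images$data
  if (!is.null(echo_subset)) {
    ax <- ax[echo_subset]
    dat <- dat[, , echo_subset, drop = FALSE]
  }
  if (is.null(tr)) tr <- images$tr
  if (kind == "t1" && is.null(tr))
    stop("T1 mapping requires tr")
  n1 <- dim(dat)[1]; n2 <- dim(dat)[2]
  if (is.null(mask)) {
    peak <- apply(dat, c(1, 2), max)
    mask <- peak > 0.1 * max(peak)
  }
  if (!any(mask)) stop("mask is empty")
  map <- a <- b <- res <- matrix(NA_real_, n1, n2)
  conv <- matrix(FALSE, n1, n2)
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    sig <- dat[i, j, ]
    f <- if (kind == "t1") fit_t1_voxel(sig, ax, tr)
         else fit_t2_voxel(sig, ax)
    map[i, j] <- f$value; a[i, j] <- f$a; b[i, j] <- f$b
    res[i, j] <- f$residual_rms; conv[i, j] <- f$converged
  }
  structure(list(map = map, a = a, b = b, residual_rms = res,
                 converged = conv, kind = kind, mask = mask,
                 axis_values = ax, fov = images$fov),
            class = "qmri_parmap")
}

#' @export
print.qmri_parmap <- function(x, ...) {
  cat("<qmri_parmap>", toupper(x$kind), "map;",
      sum(x$mask), "voxels fitted,", sum(x$converged), "converged\n")
  invisible(x)
}

#' Interior sphere ROIs from a layout
#'
#' One mask per sphere, eroded by `erode` voxels (voxel centers within
#' `radius - erode * voxel_size` of the sphere center) so that only
#' interior voxels enter the ROI statistics.
#'
#' @param layout a [sphere_layout()].
#' @param n grid size the masks are rasterized on.
#' @param fov field of view in meters.
#' @param erode erosion in voxels (default 1).
#' @return list of logical `n x n` matrices.
#' @export
sphere_rois <- function(layout, n, fov, erode = 1) {
  xy <- voxel_centers(n, fov)
  X <- matrix(xy$x, n, n, byrow = TRUE)
  Y <- matrix(xy$y, n, n)
  vox <- fov / n
  lapply(seq_along(layout$radii), function(s) {
    r <- layout$radii[s] - erode * vox
    ((X - layout$centers[s, 1])^2 + (Y - layout$centers[s, 2])^2) <= r^2
  })
}

#' Per-ROI statistics of a parameter map
#'
#' Mean, standard deviation, median and count of the fitted values over
#' converged voxels in each ROI.
#'
#' @param pmap a `qmri_parmap`.
#' @param rois list of logical masks (e.g. from [sphere_rois()]).
#' @return data.frame with columns `roi`, `n`, `mean`, `sd`, `median`.
#' @export
roi_stats <- function(pmap, rois) {
  stopifnot(inherits(pmap, "qmri_parmap"))
  out <- lapply(seq_along(rois), function(k) {
    m <- rois[[k]] & pmap$converged
    v <- pmap$map[m]
    data.frame(roi = k, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else
                 if (length(v) == 1) 0 else NA_real_,
               median = if (length(v)) stats::median(v) else NA_real_)
  })
  do.call(rbind, out)
}
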