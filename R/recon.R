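# Cartesian reconstruction: acquisition-order correction, optional Hamming
# apodization, centered 2D inverse FFT, sum-of-squares channel combination,
# joint [0,1] normalization.

#' Sort raw readouts into complete k-space grids
#'
#' Groups readouts by slice and echo and fills one `matrix_n x matrix_n`
#' grid per channel and frame, correcting the phase-encode acquisition
#' order using the per-readout metadata.  If every echo of a slice covers
#' all PE lines (multi-echo acquisition), each echo becomes its own frame;
#' otherwise the echoes of a slice are parts of one image (banded TSE) and
#' are merged.
#'
#' @param raw a `raw_kspace`.
#' @return a list of frames, each a list with `slice`, `echo` (NA when
#'   echoes are merged), `te` (echo time of the frame, seconds), and
#'   `grids` (list of complex matrices, one per channel; readout sample
#'   index in rows, PE line in columns).
#' @export
sort_kspace <- function(raw) {
  stopifnot(inherits(raw, "raw_kspace"))
  n <- raw$matrix_n
  meta <- raw$meta
  n_ch <- dim(raw$samples)[2]
  frames <- list()
  for (sl in sort(unique(meta$slice))) {
    sub <- which(meta$slice == sl)
    echoes <- sort(unique(meta$echo[sub]))
    # multi-echo acquisitions re-acquire PE lines at several echoes (one
    # k-space per echo); banded TSE splits disjoint line sets across the
    # echoes of one k-space
    pairs <- unique(data.frame(echo = meta$echo[sub],
                               pe = meta$pe_line[sub]))
    split_echoes <- length(echoes) > 1 && anyDuplicated(pairs$pe) > 0
    groups <- if (split_echoes) {
      lapply(echoes, function(e) sub[meta$echo[sub] == e])
    } else {
      list(sub)
    }
    for (g in groups) {
      lines <- meta$pe_line[g]
      dup <- lines[duplicated(lines)]
      if (length(dup))
        stop("k-space integrity error: PE line(s) ",
             paste(unique(dup), collapse = ", "), " acquired more than once")
      missing <- setdiff(0:(n - 1), lines)
      if (length(missing))
        stop("incomplete k-space: missing PE line(s) ",
             paste(missing, collapse = ", "))
      grids <- vector("list", n_ch)
      for (ch in seq_len(n_ch)) {
        G <- matrix(0 + 0i, n, n)
        G[, lines + 1L] <- raw$samples[, ch, g]
        grids[[ch]] <- G
      }
      ech <- unique(meta$echo[g])
      frames[[length(frames) + 1L]] <- list(
        slice = sl,
        echo = if (length(ech) == 1) ech else NA_integer_,
        te = stats::median(meta$t_since_exc[g]),
        grids = grids)
    }
  }
  frames
}

#' 2D Hamming apodization window
#'
#' Outer product of two n-point Hamming windows
#' `w(k) = 0.54 - 0.46*cos(2*pi*k/(n-1))`, multiplied onto k-space before
#' the inverse FFT to suppress Gibbs ringing.
#'
#' @param n window size (>= 2).
#' @return an `n x n` matrix with value 1 at the center and 0.08 at the
#'   edges.
#' @export
hamming_2d <- function(n) {
  stopifnot(n >= 2)
  w <- as.numeric(signal::hamming(n))
  outer(w, w)
}

#' Centered 2D inverse FFT
#'
#' K-space center at the grid center (index `n/2 + 1` for even n, 0-based
#' `n/2`), image DC at the image center; scaled by `1/(n*n)` so that image
#' power equals k-space power divided by `n^2`.
#'
#' @param grid complex k-space matrix.
#' @return complex image matrix of the same size.
#' @export
ifft2_image <- function(grid) {
  fftshift2(stats::fft(ifftshift2(grid), inverse = TRUE)) / length(grid)
}

# k-space grid -> magnitude-convention complex image aligned with the
# phantom's [row, col] voxel array.  Compensates the half-voxel offset of
# the coordinate convention (voxel centers at half-integer positions) with
# linear phase ramps before the IFFT, then remaps axes: readout samples
# encode x (phantom columns), PE lines encode y (phantom rows, y up).
grid_to_image <- function(grid) {
  n <- nrow(grid)
  u <- seq_len(n) - 1 - n / 2
  ramp_m <- exp(1i * pi * u / n)    # readout axis, half-voxel in x
  ramp_p <- exp(1i * pi * u / n)    # PE axis, half-voxel in y
  img <- ifft2_image(grid * outer(ramp_m, ramp_p))
  # rows of img index x -> phantom columns; columns index y ascending ->
  # phantom rows counted upward: transpose and flip rows
  out <- t(img)
  out[c(seq(n, 1)), , drop = FALSE]
}

#' Sum-of-squares channel combination
#'
#' @param images list of complex or numeric images (one per channel) with
#'   congruent dimensions.
#' @return magnitude image: voxel-wise square root of the summed squared
#'   channel magnitudes.
#' @export
sos_combine <- function(images) {
  stopifnot(length(images) >= 1)
  acc <- Mod(images[[1]])^2
  for (im in images[-1]) {
    stopifnot(all(dim(im) == dim(images[[1]])))
    acc <- acc + Mod(im)^2
  }
  sqrt(acc)
}

#' Create an image set
#'
#' @param data numeric array `x-by-y-by-frames` (frames are slices or
#'   contrasts).
#' @param axis_kind `"slice"`, `"TI"`, or `"TE"`.
#' @param axis_values coordinate of each frame (slice index or seconds).
#' @param fov field of view in meters.
#' @param tr repetition time carried for downstream fitting.
#' @param normalized whether joint [0,1] normalization has been applied.
#' @return an object of class `image_set`.
#' @export
image_set <- function(data, axis_kind, axis_values, fov = NULL, tr = NULL,
                      normalized = FALSE) {
  if (length(dim(data)) == 2) data <- array(data, dim = c(dim(data), 1))
  stopifnot(length(axis_values) == dim(data)[3])
  structure(list(data = data, axis_kind = axis_kind,
                 axis_values = axis_values, fov = fov, tr = tr,
                 normalized = normalized), class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<image_set>", d[1], "x", d[2], "x", d[3], "frames; axis",
      x$axis_kind, if (x$normalized) "(normalized)" else "", "\n")
  invisible(x)
}

#' Joint [0,1] normalization of an image set
#'
#' Divides every image by the single global maximum across all slices or
#' contrasts, preserving inter-contrast ratios (required by the parameter
#' mapping).
#'
#' @param images an `image_set`.
#' @return the normalized `image_set` (global max exactly 1).
#' @export
normalize_set <- function(images) {
  stopifnot(inherits(images, "image_set"))
  mx <- max(images$data)
  if (!is.finite(mx) || mx <= 0)
    stop("cannot normalize: image set has no positive values")
  images$data <- images$data / mx
  images$normalized <- TRUE
  images
}

#' Reconstruct images from raw k-space
#'
#' Full chain: [sort_kspace()] (acquisition-order correction), optional
#' [hamming_2d()] apodization, centered inverse FFT per channel,
#' [sos_combine()], and joint [normalize_set()].  A list of `raw_kspace`
#' objects (e.g. the per-TI acquisitions of the T1 protocol) is
#' reconstructed into a single jointly-normalized set ordered as given.
#'
#' @param raw a `raw_kspace` or list of them.
#' @param apodize multiply each k-space with the Hamming window before the
#'   IFFT (the quantitative-mapping default; qualitative reconstructions
#'   typically disable it).
#' @param normalize apply the joint [0,1] normalization (default); set
#'   FALSE to keep images in absolute signal units, e.g. for noise
#'   calibration.
#' @return an `image_set` of magnitude images.
#' @export
reconstruct <- function(raw, apodize = TRUE, normalize = TRUE) {
  raws <- if (inherits(raw, "raw_kspace")) list(raw) else raw
  stopifnot(all(vapply(raws, inherits, logical(1), "raw_kspace")))
  n <- raws[[1]]$matrix_n
  win <- if (apodize) hamming_2d(n)
  imgs <- list()
  axis_vals <- numeric(0)
  axis_kind <- NULL
  for (rw in raws) {
    frames <- sort_kspace(rw)
    for (fr in frames) {
      ch_imgs <- lapply(fr$grids, function(G) {
        if (apodize) G <- G * win
        grid_to_image(G)
      })
      imgs[[length(imgs) + 1L]] <- sos_combine(ch_imgs)
    }
    if (length(raws) > 1) {
      if (length(frames) != 1)
        stop("multi-acquisition reconstruction expects one frame per raw object")
      axis_kind <- "TI"
      axis_vals <- c(axis_vals, rw$seq_meta$ti)
    } else {
      slices <- vapply(frames, function(f) as.numeric(f$slice), numeric(1))
      if (length(frames) == length(unique(slices))) {
        axis_kind <- "slice"          # one frame per slice (or single frame)
        axis_vals <- slices
      } else {
        axis_kind <- "TE"             # echo-sorted multi-contrast frames
        axis_vals <- vapply(frames, `[[`, numeric(1), "te")
      }
    }
  }
  arr <- array(0, dim = c(n, n, length(imgs)))
  for (k in seq_along(imgs)) arr[, , k] <- imgs[[k]]
  out <- image_set(arr, axis_kind, axis_vals,
                   fov = raws[[1]]$fov, tr = raws[[1]]$seq_meta$tr)
  if (normalize) normalize_set(out) else out
}

#' Gibbs edge-overshoot metric
#'
#' Quantifies ringing adjacent to a sharp edge: the maximum image value
#' over a mask of near-edge interior voxels divided by the median over the
#' same mask, minus one.  Used to verify that apodization reduces Gibbs
#' overshoot.
#'
#' @param img magnitude image.
#' @param mask logical matrix of interior voxels near the edge.
#' @return non-negative overshoot fraction.
#' @export
gibbs_overshoot <- function(img, mask) {
  v <- img[mask]
  max(v) / stats::median(v) - 1
}
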