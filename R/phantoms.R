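# Numerical phantoms: a resolution grid phantom and NIST-style T1/T2
# sphere planes, plus isochromat expansion and complex noise injection.
#
# Coordinate convention: maps are [row, col] arrays with voxel (1,1) at the
# top-left corner; column j maps to x = -FOV/2 + (j - 1/2) * FOV/n (x to
# the right) and row i to y = +FOV/2 - (i - 1/2) * FOV/n (y up).

#' Construct a phantom from parameter maps
#'
#' @param pd,t1,t2 equal-sized matrices: proton density (dimensionless,
#'   >= 0), T1 and T2 in seconds.  Wherever `pd > 0`, `t2 <= t1` is
#'   enforced.
#' @param fov field of view in meters.
#' @return an object of class `qmri_phantom`.
#' @export
new_phantom <- function(pd, t1, t2, fov) {
  stopifnot(all(dim(pd) == dim(t1)), all(dim(pd) == dim(t2)), fov > 0)
  if (any(pd < 0)) stop("proton density must be non-negative")
  sup <- pd > 0
  if (any(t2[sup] > t1[sup] + 1e-12))
    stop("phantom invariant violated: t2 > t1 on the support")
  structure(list(pd = pd, t1 = t1, t2 = t2, fov = fov,
                 n = nrow(pd)), class = "qmri_phantom")
}

#' @export
print.qmri_phantom <- function(x, ...) {
  cat("<qmri_phantom>", x$n, "x", ncol(x$pd), " FOV", x$fov, "m;",
      sum(x$pd > 0), "voxels with signal\n")
  invisible(x)
}

#' Resolution grid phantom
#'
#' A uniform disk (T1/T2 homogeneous) crossed by zero-proton-density grid
#' lines with the given period, emulating a resolution-target phantom.
#' All proton-density values are 0 or 1.
#'
#' @param n grid size (n x n voxels).
#' @param period grid-line period in voxels (`period = n` gives a plain
#'   disk with no interior lines).
#' @param t1,t2 relaxation times of the disk material in seconds.
#' @param fov field of view in meters.
#' @param radius disk radius as a fraction of FOV/2.
#' @return a `qmri_phantom`.
#' @export
make_grid_phantom <- function(n, period, t1 = 0.5, t2 = 0.1, fov = 0.25,
                              radius = 0.9) {
  stopifnot(n >= period, period >= 2)
  xy <- voxel_centers(n, fov)
  r2 <- outer(xy$y^2, xy$x^2, `+`)
  pd <- matrix(0, n, n)
  pd[r2 <= (radius * fov / 2)^2] <- 1
  line <- (seq_len(n) %% period) == (period %/% 2)
  if (period < n) {
    pd[line, ] <- 0
    pd[, line] <- 0
  }
  new_phantom(pd, matrix(t1, n, n), matrix(t2, n, n), fov)
}

#' Sphere layout for NIST-style T1/T2 planes
#'
#' @param centers two-column matrix of sphere centers (meters).
#' @param radii sphere radii (meters).
#' @param t1,t2 per-sphere relaxation times (seconds).
#' @param pd per-sphere proton density.
#' @param disk_radius radius of the enclosing phantom disk (meters).
#' @param disk_t1,disk_t2,disk_pd background disk properties.
#' @return a list of class `sphere_layout`.  Spheres must be pairwise
#'   disjoint and inside the enclosing disk.
#' @export
sphere_layout <- function(centers, radii, t1, t2, pd = 1,
                          disk_radius, disk_t1 = 3, disk_t2 = 1,
                          disk_pd = 1) {
  k <- nrow(centers)
  stopifnot(length(radii) == k, length(t1) == k, length(t2) == k)
  pd <- rep_len(pd, k)
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      d <- sqrt(sum((centers[i, ] - centers[j, ])^2))
      if (d < radii[i] + radii[j])
        stop(sprintf("sphere layout invalid: spheres %d and %d overlap", i, j))
    }
  }
  rr <- sqrt(rowSums(centers^2)) + radii
  if (any(rr > disk_radius + 1e-12))
    stop("sphere layout invalid: sphere outside the enclosing disk")
  structure(list(centers = centers, radii = radii, t1 = t1, t2 = t2,
                 pd = pd, disk_radius = disk_radius, disk_t1 = disk_t1,
                 disk_t2 = disk_t2, disk_pd = disk_pd),
            class = "sphere_layout")
}

#' Default synthetic sphere layouts for the T1 and T2 planes
#'
#' Ten spheres on a ring inside a water-like disk.  These layouts are
#' synthetic stand-ins for the physical calibration plates: the T1 plane
#' spans 0.05-2.0 s (bracketing the protocol's TI range 50-3000 ms), the
#' T2 plane spans 0.02-0.3 s (bracketing the TE range 7-161 ms), both
#' log-spaced.
#'
#' @param kind `"t1_plane"` or `"t2_plane"`.
#' @param fov field of view in meters the layout is scaled to.
#' @return a [sphere_layout()].
#' @export
default_sphere_layout <- function(kind = c("t1_plane", "t2_plane"),
                                  fov = 0.25) {
  kind <- match.arg(kind)
  h <- fov / 2
  k <- 10
  ang <- 2 * pi * (seq_len(k) - 1) / k + pi / 2
  ring <- 0.55 * h
  centers <- cbind(ring * cos(ang), ring * sin(ang))
  radii <- rep(0.16 * h, k)
  if (kind == "t1_plane") {
    t1 <- exp(seq(log(0.05), log(2.0), length.out = k))
    t2 <- pmin(0.5 * t1, 0.3)
  } else {
    t2 <- exp(seq(log(0.02), log(0.3), length.out = k))
    t1 <- pmax(3 * t2, 0.2)
  }
  sphere_layout(centers, radii, t1, t2, pd = 1, disk_radius = 0.9 * h)
}

#' Rasterize a sphere-plane phantom
#'
#' @param kind `"t1_plane"` or `"t2_plane"` (selects the default layout).
#' @param layout a [sphere_layout()]; default [default_sphere_layout()].
#' @param n grid size (n x n).
#' @param fov field of view in meters.
#' @return a `qmri_phantom`; a voxel carries the parameters of the sphere
#'   containing its center, else of the background disk, else `pd = 0`.
#' @export
make_plane_phantom <- function(kind = c("t1_plane", "t2_plane"),
                               layout = NULL, n = 128, fov = 0.25) {
  kind <- match.arg(kind)
  stopifnot(n >= 32)
  if (is.null(layout)) layout <- default_sphere_layout(kind, fov)
  xy <- voxel_centers(n, fov)
  X <- matrix(xy$x, n, n, byrow = TRUE)
  Y <- matrix(xy$y, n, n)
  pd <- matrix(0, n, n); t1 <- matrix(1, n, n); t2 <- matrix(1, n, n)
  disk <- (X^2 + Y^2) <= layout$disk_radius^2
  pd[disk] <- layout$disk_pd
  t1[disk] <- layout$disk_t1
  t2[disk] <- layout$disk_t2
  for (s in seq_along(layout$radii)) {
    m <- ((X - layout$centers[s, 1])^2 + (Y - layout$centers[s, 2])^2) <=
      layout$radii[s]^2
    pd[m] <- layout$pd[s]
    t1[m] <- layout$t1[s]
    t2[m] <- layout$t2[s]
  }
  ph <- new_phantom(pd, t1, t2, fov)
  ph$layout <- layout
  ph$kind <- kind
  ph
}

voxel_centers <- function(n, fov) {
  d <- fov / n
  list(x = -fov / 2 + (seq_len(n) - 0.5) * d,     # by column
       y = fov / 2 - (seq_len(n) - 0.5) * d)      # by row
}

#' Expand a phantom into isochromats
#'
#' One isochromat per voxel with nonzero proton density, located at the
#' voxel center's physical coordinates.
#'
#' @param ph a `qmri_phantom`.
#' @return a data.frame with columns `x`, `y` (meters), `pd`, `t1`, `t2`,
#'   and the source voxel indices `row`, `col`.
#' @export
to_isochromats <- function(ph) {
  idx <- which(ph$pd > 0, arr.ind = TRUE)
  xy <- voxel_centers(ph$n, ph$fov)
  data.frame(
    x = xy$x[idx[, "col"]],
    y = xy$y[idx[, "row"]],
    pd = ph$pd[idx],
    t1 = ph$t1[idx],
    t2 = ph$t2[idx],
    row = idx[, "row"],
    col = idx[, "col"]
  )
}

#' Add complex Gaussian noise to raw k-space
#'
#' I.i.d. Gaussian noise with standard deviation `sigma` per real and
#' imaginary component is added to every sample; deterministic given the
#' seed, and the global RNG state is left untouched.
#'
#' @param raw a `raw_kspace`.
#' @param sigma noise standard deviation in signal units (>= 0).
#' @param seed integer seed.
#' @return the noisy `raw_kspace`.
#' @export
add_noise <- function(raw, sigma, seed = 0) {
  stopifnot(inherits(raw, "raw_kspace"), sigma >= 0)
  if (sigma == 0) return(raw)
  n <- length(raw$samples)
  noise <- with_seed(seed, complex(real = stats::rnorm(n, 0, sigma),
                                   imaginary = stats::rnorm(n, 0, sigma)))
  raw$samples <- raw$samples + array(noise, dim = dim(raw$samples))
  raw$noise_sigma <- sigma
  raw
}
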