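# Preset loading and end-to-end experiment orchestration.

#' List bundled protocol presets
#'
#' @return character vector of preset names.
#' @export
list_presets <- function() {
  dir <- system.file("extdata", "presets", package = "qmriseq")
  sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
}

#' Load a protocol preset
#'
#' Presets carry the acquisition parameters of the four validation
#' protocols (qualitative IRSE/TSE, 10-TI T1 mapping, 23-echo T2 mapping)
#' and the two low-resolution simulation protocols.  `scale` divides the
#' matrix size (and the phantom resolution downstream) while leaving
#' TR/TE/TI untouched, for desk-scale runs.
#'
#' @param name preset name (see [list_presets()]).
#' @param scale integer matrix downscaling factor.
#' @return a list of class `qmri_preset` with `name`, `builder`,
#'   `phantom_kind`, `params` (a [protocol_params()]).
#' @export
qmri_preset <- function(name, scale = 1) {
  dir <- system.file("extdata", "presets", package = "qmriseq")
  path <- file.path(dir, paste0(name, ".yaml"))
  if (!file.exists(path))
    stop("unknown preset '", name, "'; available: ",
         paste(list_presets(), collapse = ", "))
  y <- yaml::read_yaml(path)
  n <- y$matrix_n / scale
  if (n != round(n)) stop("scale must divide the matrix size")
  etl <- if (!is.null(y$etl)) y$etl else 1
  te_list <- if (!is.null(y$n_echoes))
    y$echo_spacing * seq_len(y$n_echoes)
  p <- protocol_params(
    fov = y$fov, matrix_n = n, n_slices = y$n_slices,
    slice_thickness = y$slice_thickness,
    tr = y$tr, te = if (!is.null(y$te)) y$te else y$echo_spacing,
    ti = y$ti, etl = etl,
    echo_spacing = y$echo_spacing,
    center_echo = if (!is.null(y$center_echo)) y$center_echo else 2,
    ti_list = unlist(y$ti_list), te_list = te_list)
  structure(list(name = y$name, builder = y$builder,
                 phantom_kind = y$phantom, params = p, scale = scale),
            class = "qmri_preset")
}

#' Build the sequence(s) of a preset
#'
#' @param preset a [qmri_preset()].
#' @return a `pulseq_seq`, or a list of them for the multi-TI T1 protocol.
#' @export
make_preset_sequence <- function(preset) {
  stopifnot(inherits(preset, "qmri_preset"))
  switch(preset$builder,
    irse = make_irse(preset$params),
    tse = make_tse(preset$params),
    multiecho = make_multiecho_tse(preset$params),
    t1map = make_t1_protocol(preset$params),
    stop("unknown builder: ", preset$builder))
}

#' Build the phantom of a preset
#'
#' @param preset a [qmri_preset()].
#' @param n grid size; defaults to the preset's (scaled) matrix size.
#' @return a `qmri_phantom`.
#' @export
make_preset_phantom <- function(preset, n = NULL) {
  if (is.null(n)) n <- preset$params$matrix_n
  fov <- preset$params$fov
  switch(preset$phantom_kind,
    grid = make_grid_phantom(n, max(n / 8, 2), fov = fov),
    t1_plane = make_plane_phantom("t1_plane", n = n, fov = fov),
    t2_plane = make_plane_phantom("t2_plane", n = n, fov = fov),
    stop("unknown phantom kind: ", preset$phantom_kind))
}

#' Run a full simulated experiment
#'
#' End-to-end pipeline for one preset: build the sequence(s), write the
#' `.seq` files, simulate the phantom acquisition, optionally add complex
#' noise at a prescribed SNR, reconstruct, and - for the quantitative
#' presets - fit the parameter map and tabulate per-sphere ROI statistics.
#' A JSON summary (timing report, RF power, ROI table, provenance) is
#' written to `outdir` along with the `.seq` files and RDS bundles.
#'
#' @param preset_name preset name (see [list_presets()]).
#' @param scale matrix downscaling factor (desk runs: 4-8).
#' @param snr complex-noise SNR, defined as peak k-space magnitude over
#'   per-component noise sigma; `Inf` for noiseless.
#' @param seed noise seed.
#' @param outdir output directory (created); `NULL` for no file output.
#' @param apodize Hamming apodization before the IFFT; default TRUE for
#'   the quantitative mapping presets, FALSE otherwise.
#' @return invisibly, a list with `sequences`, `raw`, `images`, `map`
#'   (or NULL), `roi_table` (or NULL), `timing`, `rf_power`, `summary`.
#' @export
run_experiment <- function(preset_name, scale = 4, snr = Inf, seed = 1,
                           outdir = NULL, apodize = NULL) {
  t_start <- Sys.time()
  preset <- qmri_preset(preset_name, scale)
  quantitative <- preset$builder %in% c("t1map", "multiecho")
  if (is.null(apodize)) apodize <- quantitative
  seqs <- make_preset_sequence(preset)
  seq_list <- if (inherits(seqs, "pulseq_seq")) list(seqs) else seqs
  phantom <- make_preset_phantom(preset)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(seq_list))
      write_seq(seq_list[[i]],
                file.path(outdir, sprintf("%s_%02d.seq", preset$name, i)))
  }

  raw <- lapply(seq_list, simulate_sequence, phantom = phantom)
  if (is.finite(snr)) {
    sigma <- noise_sigma_for_snr(raw, snr)
    raw <- lapply(seq_along(raw), function(i)
      add_noise(raw[[i]], sigma, seed + i - 1))
  }
  images <- reconstruct(if (length(raw) == 1) raw[[1]] else raw,
                        apodize = apodize)

  pmap <- NULL; roi_tab <- NULL
  if (preset$builder == "t1map") {
    pmap <- map_fit(images, "t1", tr = preset$params$tr)
  } else if (preset$builder == "multiecho") {
    n_e <- length(preset$params$te_list)
    pmap <- map_fit(images, "t2",
                    echo_subset = if (n_e >= 6) 5:n_e else seq_len(n_e))
  }
  if (!is.null(pmap) && !is.null(phantom$layout)) {
    rois <- sphere_rois(phantom$layout, phantom$n, phantom$fov)
    roi_tab <- roi_stats(pmap, rois)
    truth <- if (pmap$kind == "t1") phantom$layout$t1 else phantom$layout$t2
    roi_tab$truth <- truth
    roi_tab$rel_err_median <- roi_tab$median / truth - 1
  }

  timing <- timing_report(seq_list[[1]])
  power <- rf_power_summary(seq_list[[1]])
  summary <- list(
    preset = preset$name, scale = scale, snr = snr, seed = seed,
    matrix_n = preset$params$matrix_n,
    n_frames = dim(images$data)[3],
    axis_kind = images$axis_kind,
    timing = list(te_ms = timing$measured_te * 1e3,
                  ti_ms = timing$measured_ti * 1e3,
                  tr_ms = timing$measured_tr * 1e3,
                  echoes_per_excitation = timing$echoes_per_excitation),
    rf = list(time_averaged_b1sq = power$time_averaged_b1sq,
              duty_cycle = power$duty_cycle),
    roi = roi_tab,
    wall_time_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))

  if (!is.null(outdir)) {
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
    saveRDS(list(raw = raw, images = images, map = pmap),
            file.path(outdir, paste0(preset$name, "_bundle.rds")))
    if (requireNamespace("png", quietly = TRUE))
      write_montage(images, file.path(outdir, paste0(preset$name,
                                                     "_montage.png")))
  }
  invisible(list(sequences = seq_list, phantom = phantom, raw = raw,
                 images = images, map = pmap, roi_table = roi_tab,
                 timing = timing, rf_power = power, summary = summary))
}

#' K-space noise sigma for a prescribed image-domain SNR
#'
#' SNR is defined voxel-wise: the peak magnitude of the noiseless
#' (unapodized, unnormalized) reconstruction divided by the per-voxel
#' image-noise standard deviation.  For an N x N Cartesian reconstruction,
#' complex k-space noise of standard deviation `sigma` per component
#' produces image noise `sigma / N` per component, so the k-space sigma
#' realizing the requested SNR is `N * peak / SNR`.
#'
#' @param raw a `raw_kspace` or list of them (noiseless).
#' @param snr requested peak-signal-to-noise ratio.
#' @return k-space noise standard deviation per real/imaginary component.
#' @export
noise_sigma_for_snr <- function(raw, snr) {
  stopifnot(snr > 0)
  raws <- if (inherits(raw, "raw_kspace")) list(raw) else raw
  clean <- reconstruct(if (length(raws) == 1) raws[[1]] else raws,
                       apodize = FALSE, normalize = FALSE)
  peak <- max(clean$data)
  raws[[1]]$matrix_n * peak / snr
}

# grayscale montage of an image set (requires the png package)
write_montage <- function(images, path, ncol = NULL) {
  d <- dim(images$data)
  nf <- d[3]
  if (is.null(ncol)) ncol <- ceiling(sqrt(nf))
  nrow_ <- ceiling(nf / ncol)
  M <- matrix(0, nrow_ * d[1], ncol * d[2])
  for (k in seq_len(nf)) {
    i <- (k - 1) %/% ncol
    j <- (k - 1) %% ncol
    M[i * d[1] + seq_len(d[1]), j * d[2] + seq_len(d[2])] <- images$data[, , k]
  }
  png::writePNG(pmin(pmax(M / max(M), 0), 1), path)
  invisible(path)
}
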