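# Reader/writer for a Pulseq text-format dialect (1.2.1 section layout).
#
# Sections: [VERSION], [DEFINITIONS], [BLOCKS], [RF], [TRAP], [ADC],
# [DELAYS], [SHAPES].  Times are written in microseconds (ADC dwell in
# nanoseconds), RF amplitudes in Hz, gradients in Hz/m, per the format's
# field conventions.  Two columns carried over from later Pulseq revisions
# are kept: the RF table ends with a `use` code (1 excitation,
# 2 refocusing, 3 inversion) and the TRAP table has a trailing delay
# column.  Shapes are written uncompressed; the reader also accepts
# Pulseq run-length-compressed (derivative-encoded) shapes.

RF_USE_CODE <- c(excitation = 1L, refocusing = 2L, inversion = 3L)

#' Write a sequence to a Pulseq-dialect `.seq` text file
#'
#' @param seq a `pulseq_seq`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @seealso [read_seq()]; `write_seq` then `read_seq` then `write_seq`
#'   reproduces the first file byte for byte.
#' @export
write_seq <- function(seq, path) {
  stopifnot(inherits(seq, "pulseq_seq"))
  # event tables keyed by a canonical signature, ids in encounter order
  rf_tab <- list();  rf_key <- character()
  tr_tab <- list();  tr_key <- character()
  ad_tab <- list();  ad_key <- character()
  dl_tab <- numeric(); dl_key <- character()
  sh_tab <- list();  sh_key <- character()

  shape_id <- function(samples) {
    key <- paste(fmt_num(samples), collapse = ",")
    i <- match(key, sh_key)
    if (is.na(i)) {
      sh_tab[[length(sh_tab) + 1L]] <<- samples
      sh_key[length(sh_key) + 1L] <<- key
      i <- length(sh_tab)
    }
    i
  }

  blocks <- matrix(0L, nrow = length(seq$blocks), ncol = 7)
  for (bi in seq_along(seq$blocks)) {
    b <- seq$blocks[[bi]]
    # raster audit
    bad <- !on_raster(b$duration, RASTER_RF)
    if (!is.null(b$rf)) bad <- bad || !on_raster(b$rf$duration, RASTER_RF)
    for (g in list(b$gx, b$gy, b$gz))
      if (!is.null(g)) bad <- bad ||
          !all(vapply(c(g$rise, g$flat, g$fall, g$delay),
                      on_raster, logical(1), raster = RASTER_GRAD))
    if (bad)
      stop(sprintf("write_seq: block %d violates raster quantization", bi))

    row <- integer(7); row[1] <- bi
    if (b$delay > 0) {
      key <- fmt_num(round(b$delay * 1e6))
      i <- match(key, dl_key)
      if (is.na(i)) {
        dl_tab[length(dl_tab) + 1L] <- round(b$delay * 1e6)
        dl_key[length(dl_key) + 1L] <- key
        i <- length(dl_tab)
      }
      row[2] <- i
    }
    if (!is.null(b$rf)) {
      rf <- b$rf
      mag_id <- shape_id(rf$shape)
      vals <- c(fmt_num(c(rf$amp, mag_id, 0, round(rf$delay * 1e6),
                          rf$freq, rf$phase)), RF_USE_CODE[[rf$use]])
      key <- paste(vals, collapse = " ")
      i <- match(key, rf_key)
      if (is.na(i)) {
        rf_tab[[length(rf_tab) + 1L]] <- key
        rf_key[length(rf_key) + 1L] <- key
        i <- length(rf_tab)
      }
      row[3] <- i
    }
    gcols <- c(x = 4L, y = 5L, z = 6L)
    for (g in list(b$gx, b$gy, b$gz)) {
      if (is.null(g)) next
      vals <- fmt_num(c(g$amp, round(g$rise * 1e6), round(g$flat * 1e6),
                        round(g$fall * 1e6), round(g$delay * 1e6)))
      key <- paste(vals, collapse = " ")
      i <- match(key, tr_key)
      if (is.na(i)) {
        tr_tab[[length(tr_tab) + 1L]] <- key
        tr_key[length(tr_key) + 1L] <- key
        i <- length(tr_tab)
      }
      row[gcols[[g$axis]]] <- i
    }
    if (!is.null(b$adc)) {
      a <- b$adc
      vals <- fmt_num(c(a$num, round(a$dwell * 1e9), round(a$delay * 1e6),
                        a$freq, a$phase))
      key <- paste(vals, collapse = " ")
      i <- match(key, ad_key)
      if (is.na(i)) {
        ad_tab[[length(ad_tab) + 1L]] <- key
        ad_key[length(ad_key) + 1L] <- key
        i <- length(ad_tab)
      }
      row[7] <- i
    }
    blocks[bi, ] <- row
  }

  out <- c("# Pulseq sequence file", "# Created with qmriseq", "",
           "[VERSION]", "major 1", "minor 2", "revision 1", "")

  m <- seq$meta
  defs <- list(FOV = m$fov, Name = m$name, Ns = m$ns, Nx = m$n, Ny = m$n,
               TE = m$te, TI = m$ti, TR = m$tr, Thk = m$thk)
  defs <- defs[!vapply(defs, is.null, logical(1))]
  if (length(defs)) {
    out <- c(out, "[DEFINITIONS]")
    for (k in sort(names(defs))) {
      v <- defs[[k]]
      out <- c(out, paste(k, if (is.character(v)) v else fmt_num(v)))
    }
    out <- c(out, "")
  }

  out <- c(out, "[BLOCKS]",
           apply(blocks, 1, function(r) paste(r, collapse = " ")), "")
  if (length(rf_tab))
    out <- c(out, "[RF]",
             paste(seq_along(rf_tab), unlist(rf_tab)), "")
  if (length(tr_tab))
    out <- c(out, "[TRAP]",
             paste(seq_along(tr_tab), unlist(tr_tab)), "")
  if (length(ad_tab))
    out <- c(out, "[ADC]",
             paste(seq_along(ad_tab), unlist(ad_tab)), "")
  if (length(dl_tab))
    out <- c(out, "[DELAYS]",
             paste(seq_along(dl_tab), fmt_num(dl_tab)), "")
  if (length(sh_tab)) {
    out <- c(out, "[SHAPES]", "")
    for (i in seq_along(sh_tab)) {
      out <- c(out, paste("shape_id", i),
               paste("num_samples", length(sh_tab[[i]])),
               fmt_num(sh_tab[[i]]), "")
    }
  }
  con <- file(path, open = "wb")   # LF endings on every platform
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}

# Decode a Pulseq run-length-compressed shape: stored values are the sample
# derivative; two consecutive equal stored values are followed by a count of
# additional repetitions beyond the pair.
decompress_shape <- function(vals, num_samples) {
  deriv <- numeric(0)
  i <- 1
  prev <- NA_real_
  while (i <= length(vals)) {
    v <- vals[i]
    if (!is.na(prev) && v == prev) {
      if (i + 1 > length(vals))
        stop("corrupt compressed shape: repeat pair without a count")
      count <- vals[i + 1]
      deriv <- c(deriv, rep(v, count + 1))
      i <- i + 2
      prev <- NA_real_
    } else {
      deriv <- c(deriv, v)
      prev <- v
      i <- i + 1
    }
  }
  out <- cumsum(deriv)
  if (length(out) != num_samples)
    stop("corrupt compressed shape: expected ", num_samples,
         " samples, got ", length(out))
  out
}

#' Read a Pulseq-dialect `.seq` text file
#'
#' Accepts version 1.2.x and 1.3.x headers and both uncompressed and
#' run-length-compressed shapes.  Echo indices are reassigned by counting
#' ADC events since the last excitation pulse.
#'
#' @param path file path.
#' @return a `pulseq_seq`.
#' @export
read_seq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  known <- c("VERSION", "DEFINITIONS", "BLOCKS", "RF", "TRAP", "ADC",
             "DELAYS", "SHAPES")
  sec <- NA_character_
  chunks <- stats::setNames(vector("list", length(known)), known)
  chunk_ln <- stats::setNames(vector("list", length(known)), known)
  for (ln in seq_along(lines)) {
    s <- trimws(lines[ln])
    if (s == "" || startsWith(s, "#")) next
    if (startsWith(s, "[")) {
      name <- gsub("\\[|\\]", "", s)
      if (!name %in% known)
        stop(sprintf("parse error at line %d: unknown section [%s]", ln, name))
      sec <- name
      next
    }
    if (is.na(sec))
      stop(sprintf("parse error at line %d: content before any section", ln))
    chunks[[sec]] <- c(chunks[[sec]], s)
    chunk_ln[[sec]] <- c(chunk_ln[[sec]], ln)
  }

  # version
  ver <- chunks$VERSION
  if (is.null(ver)) stop("missing [VERSION] section")
  kv <- do.call(rbind, strsplit(ver, "\\s+"))
  vmaj <- as.integer(kv[kv[, 1] == "major", 2])
  vmin <- as.integer(kv[kv[, 1] == "minor", 2])
  if (length(vmaj) != 1 || vmaj != 1 || !(vmin %in% c(2L, 3L)))
    stop(sprintf("unsupported Pulseq version %s.%s (supported: 1.2, 1.3)",
                 vmaj, vmin))

  meta <- list()
  if (!is.null(chunks$DEFINITIONS)) {
    for (s in chunks$DEFINITIONS) {
      p <- strsplit(s, "\\s+")[[1]]
      key <- p[1]; val <- paste(p[-1], collapse = " ")
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (is.na(num)) val else num
    }
  }
  meta <- list(name = meta$Name, fov = meta$FOV, n = meta$Nx,
               ns = meta$Ns, thk = meta$Thk,
               tr = meta$TR, te = meta$TE, ti = meta$TI)
  meta <- meta[!vapply(meta, is.null, logical(1))]

  parse_rows <- function(sec_name) {
    rows <- chunks[[sec_name]]
    if (is.null(rows)) return(NULL)
    do.call(rbind, lapply(rows, function(s) as.numeric(strsplit(s, "\\s+")[[1]])))
  }

  # shapes
  shapes <- list()
  sh <- chunks$SHAPES
  if (!is.null(sh)) {
    i <- 1
    while (i <= length(sh)) {
      p <- strsplit(sh[i], "\\s+")[[1]]
      if (p[1] != "shape_id") stop("malformed [SHAPES] section near: ", sh[i])
      id <- as.integer(p[2])
      p2 <- strsplit(sh[i + 1], "\\s+")[[1]]
      if (p2[1] != "num_samples") stop("malformed shape ", id)
      nsamp <- as.integer(p2[2])
      j <- i + 2
      vals <- numeric(0)
      while (j <= length(sh) &&
             !startsWith(sh[j], "shape_id")) {
        vals <- c(vals, as.numeric(sh[j])); j <- j + 1
      }
      shapes[[id]] <- if (length(vals) == nsamp) vals else
        decompress_shape(vals, nsamp)
      i <- j
    }
  }

  rf_rows <- parse_rows("RF")
  tr_rows <- parse_rows("TRAP")
  ad_rows <- parse_rows("ADC")
  dl_rows <- parse_rows("DELAYS")
  bl_rows <- parse_rows("BLOCKS")
  if (is.null(bl_rows)) stop("missing [BLOCKS] section")

  get_rf <- function(id) {
    r <- rf_rows[rf_rows[, 1] == id, ]
    shape <- shapes[[r[3]]]
    use <- names(RF_USE_CODE)[match(r[8], RF_USE_CODE)]
    n <- length(shape)
    structure(list(
      type = "rf", amp = r[2], shape = shape,
      shape_name = if (all(shape == 1)) "block" else "sinc",
      duration = n * RASTER_RF, delay = r[5] * 1e-6,
      freq = r[6], phase = r[7], center = n * RASTER_RF / 2, use = use
    ), class = "rf_event")
  }
  get_trap <- function(id, axis) {
    r <- tr_rows[tr_rows[, 1] == id, ]
    grad_trap(axis, r[2], r[3] * 1e-6, r[4] * 1e-6, r[5] * 1e-6, r[6] * 1e-6)
  }
  get_adc <- function(id) {
    r <- ad_rows[ad_rows[, 1] == id, ]
    adc_event(r[2], r[3] * 1e-9, r[4] * 1e-6, r[5], r[6])
  }

  blocks <- vector("list", nrow(bl_rows))
  for (k in seq_len(nrow(bl_rows))) {
    r <- bl_rows[k, ]
    blocks[[k]] <- seq_block(
      rf = if (r[3] > 0) get_rf(r[3]) else NULL,
      gx = if (r[4] > 0) get_trap(r[4], "x") else NULL,
      gy = if (r[5] > 0) get_trap(r[5], "y") else NULL,
      gz = if (r[6] > 0) get_trap(r[6], "z") else NULL,
      adc = if (r[7] > 0) get_adc(r[7]) else NULL,
      delay = if (r[2] > 0) dl_rows[dl_rows[, 1] == r[2], 2] * 1e-6 else 0)
  }

  out <- new_sequence(blocks, meta)
  # reassign echo indices by counting ADCs since the last excitation
  ct <- 0L
  for (k in seq_along(out$blocks)) {
    b <- out$blocks[[k]]
    if (!is.null(b$rf) && b$rf$use == "excitation") ct <- 0L
    if (!is.null(b$adc)) {
      ct <- ct + 1L
      out$blocks[[k]]$adc$echo_index <- ct
    }
  }
  out
}
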