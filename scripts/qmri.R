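#!/usr/bin/env Rscript
# Thin command-line front end over the qmriseq package.
#
#   Rscript scripts/qmri.R seqgen  --preset <name> [--scale k] --out <dir>
#   Rscript scripts/qmri.R run     --preset <name> [--scale k] [--snr x]
#                                  [--seed n] --out <dir> [--no-apodize]
#   Rscript scripts/qmri.R timing  --seq <file.seq>
#   Rscript scripts/qmri.R rfpower --seq <file.seq>
#   Rscript scripts/qmri.R metrics --ref <ref.csv> --test <test.csv>
#
# seqgen writes the preset's .seq file(s) plus a JSON timing report; run
# executes the full simulate/reconstruct/map pipeline; metrics compares two
# [0,1]-normalized images stored as headerless CSV matrices.

suppressMessages(library(qmriseq))

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1) stop("usage: qmri.R <seqgen|run|timing|rfpower|metrics> ...")
cmd <- argv[1]
args <- argv[-1]
get_opt <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i)) return(default)
  args[i + 1]
}
has_flag <- function(flag) flag %in% args

if (cmd == "seqgen") {
  preset <- qmri_preset(get_opt("--preset"),
                        scale = as.numeric(get_opt("--scale", "1")))
  out <- get_opt("--out", ".")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seqs <- make_preset_sequence(preset)
  if (inherits(seqs, "pulseq_seq")) seqs <- list(seqs)
  reports <- lapply(seq_along(seqs), function(i) {
    f <- file.path(out, sprintf("%s_%02d.seq", preset$name, i))
    write_seq(seqs[[i]], f)
    rep <- timing_report(seqs[[i]])
    cat("wrote", f, "\n")
    list(file = basename(f), te_ms = rep$measured_te * 1e3,
         ti_ms = rep$measured_ti * 1e3, tr_ms = rep$measured_tr * 1e3,
         echoes = rep$echoes_per_excitation)
  })
  jsonlite::write_json(reports, file.path(out, "timing_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
} else if (cmd == "run") {
  res <- run_experiment(get_opt("--preset"),
                        scale = as.numeric(get_opt("--scale", "4")),
                        snr = as.numeric(get_opt("--snr", "Inf")),
                        seed = as.integer(get_opt("--seed", "1")),
                        outdir = get_opt("--out", "qmri_out"),
                        apodize = if (has_flag("--no-apodize")) FALSE else NULL)
  cat("frames:", res$summary$n_frames, "axis:", res$summary$axis_kind, "\n")
  if (!is.null(res$roi_table)) print(res$roi_table)
} else if (cmd == "timing") {
  print(timing_report(read_seq(get_opt("--seq"))))
} else if (cmd == "rfpower") {
  print(rf_power_summary(read_seq(get_opt("--seq"))))
} else if (cmd == "metrics") {
  ref <- as.matrix(read.csv(get_opt("--ref"), header = FALSE))
  tst <- as.matrix(read.csv(get_opt("--test"), header = FALSE))
  out <- list(psnr_db = psnr(ref, tst), ssim = ssim(ref, tst))
  cat(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA), "\n")
} else {
  stop("unknown subcommand: ", cmd)
}
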