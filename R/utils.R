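# internal numeric helpers shared across modules

# round-half-up quantization onto a raster grid (seconds)
quantize_time <- function(t, raster) {
  floor(t / raster + 0.5) * raster
}

# TRUE if t lies on the raster grid within floating slack
on_raster <- function(t, raster, tol = 1e-9) {
  abs(t - quantize_time(t, raster)) <= tol
}

# centered FFT index shifts (even and odd n)
fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  i1 <- c(seq(floor(n1 / 2) + 1, n1), seq_len(floor(n1 / 2)))
  i2 <- c(seq(floor(n2 / 2) + 1, n2), seq_len(floor(n2 / 2)))
  m[i1, i2, drop = FALSE]
}

ifftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  i1 <- c(seq(ceiling(n1 / 2) + 1, n1), seq_len(ceiling(n1 / 2)))
  i2 <- c(seq(ceiling(n2 / 2) + 1, n2), seq_len(ceiling(n2 / 2)))
  m[i1, i2, drop = FALSE]
}

# run expr with a private RNG stream; global .Random.seed restored afterwards
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

fmt_num <- function(x) {
  vapply(x, function(v) sprintf("%.9g", v), character(1))
}
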