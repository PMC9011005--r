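# shared fixtures: tiny phantoms and parameter sets built in code

single_voxel_phantom <- function(n = 8, t1 = 0.5, t2 = 0.1, fov = 0.25,
                                 at = c(n / 2, n / 2)) {
  pd <- matrix(0, n, n)
  pd[at[1], at[2]] <- 1
  new_phantom(pd, matrix(t1, n, n), matrix(t2, n, n), fov)
}

disk_phantom <- function(n = 16, t1 = 2, t2 = 1.5) {
  make_grid_phantom(n, n, t1 = t1, t2 = t2)
}

tiny_irse_params <- function(n = 8, ti = 0.15, tr = 2, te = 0.012, ...) {
  protocol_params(matrix_n = n, tr = tr, te = te, ti = ti, etl = 1, ...)
}

# TI list printed in the protocol table
TI_LIST <- c(0.050, 0.075, 0.100, 0.125, 0.150, 0.250,
             1.000, 1.500, 2.000, 3.000)
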