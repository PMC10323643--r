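# Independent oracles and phantom builders used across the suite.

# Circuit impedance by admittance composition: each parallel block summed as
# conductances, independently of the package's closed-form block expressions.
oracle_circuit_impedance <- function(omega, p) {
  p <- unclass(p)
  y_cpa <- p[["Q"]] * (1i * omega)^p[["n"]]
  z_interface <- 1 / (1 / p[["R_ct"]] + y_cpa)
  z_ecm <- 1 / (1 / p[["R_ECM"]] + 1i * omega * p[["C_ECM"]])
  z_cell <- 1 / (1 / p[["R_seal"]] + 1 / p[["R_cell"]] +
                   1i * omega * p[["C_cell"]])
  z_interface + p[["R_ccm"]] + z_ecm + z_cell
}

# Brute-force lattice opening of the pore phase by a disk of diameter d:
# a placement at pixel p is valid iff every in-image pixel within Euclidean
# distance d/2 of p is pore; the opening is the union of all valid disks.
oracle_open_fraction <- function(pore, d) {
  r <- d / 2
  nr <- nrow(pore); nc <- ncol(pore)
  covered <- matrix(FALSE, nr, nc)
  off <- expand.grid(dy = -floor(r):floor(r), dx = -floor(r):floor(r))
  off <- off[sqrt(off$dy^2 + off$dx^2) <= r, ]
  for (py in 1:nr) for (px in 1:nc) {
    ys <- py + off$dy; xs <- px + off$dx
    inside <- ys >= 1 & ys <= nr & xs >= 1 & xs <= nc
    if (all(pore[cbind(ys[inside], xs[inside])])) {
      covered[cbind(ys[inside], xs[inside])] <- TRUE
    }
  }
  sum(covered & pore) / sum(pore)
}

# Fibril-everywhere mask with a grid of disjoint circular pores of diameter D.
disk_pore_phantom <- function(D, n_per_side = 4) {
  S <- 2 * D * n_per_side
  m <- matrix(TRUE, S, S)
  idx <- seq_len(S)
  cs <- seq(D, S - D, by = 2 * D)
  for (cy in cs) for (cx in cs) {
    dist2 <- outer((idx - cy)^2, (idx - cx)^2, "+")
    m[dist2 <= (D / 2)^2] <- FALSE
  }
  m
}

make_spectrum_pair <- function(factor = 1, params = default_circuit_params()) {
  f <- default_frequency_grid()
  z <- circuit_impedance(2 * pi * f, params)
  list(z0 = impedance_spectrum(f, z, time_min = 0),
       zt = impedance_spectrum(f, factor * z, time_min = 30))
}

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}
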