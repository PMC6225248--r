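# Builders shared across test files. Everything is generated in code;
# no stored fixtures.

# decomposition exposing only the terms the LIE family needs, for a chosen
# ligand role ("PP" or "Abeta")
make_lie_decomp <- function(int_es = 0, sol_es_c = 0, sol_es_u = 0,
                            int_vdw = 0, sol_vdw_c = 0, sol_vdw_u = 0,
                            gas_es_c = 0, gas_es_u = 0,
                            role = "PP", sigma = 0) {
  rolec <- paste0(role, "_complex")
  energy_decomposition(tibble::tibble(
    moiety = c("complex", rolec, role, "complex", rolec, role, rolec, role),
    term = c("int_es", "sol_es", "sol_es", "int_vdw", "sol_vdw", "sol_vdw",
             "gas_es", "gas_es"),
    mean = c(int_es, sol_es_c, sol_es_u, int_vdw, sol_vdw_c, sol_vdw_u,
             gas_es_c, gas_es_u),
    sigma = sigma))
}

# decomposition with simple bundle deltas: des lands in int_es, dvdw in
# int_vdw, all other terms zero
delta_decomp <- function(des, dvdw, role = "PP", sigma = 0) {
  make_lie_decomp(int_es = des, int_vdw = dvdw, role = role, sigma = sigma)
}

# a small random polymer-ish conformer for i/o round trips
random_conformer <- function(n_res = 4, seed = 1, chain = "A") {
  set.seed(seed)
  atoms <- c("N", "CA", "C", "O")
  df <- tibble::tibble(
    atom = rep(atoms, n_res),
    resname = rep(sample(c("ALA", "GLY", "LEU", "GLU", "LYS"), n_res,
                         replace = TRUE), each = 4),
    resid = rep(seq_len(n_res), each = 4),
    chain = chain,
    x = round(stats::runif(4 * n_res, 0, 5), 3),
    y = round(stats::runif(4 * n_res, 0, 5), 3),
    z = round(stats::runif(4 * n_res, 0, 5), 3))
  conformer(df)
}

# ensemble of noisy copies of a base conformer, optionally structurally
# scrambled (so groups are > cutoff apart even after superposition)
noisy_ensemble <- function(base, n, noise = 0.01, seed = 1, scramble = FALSE) {
  frames <- lapply(seq_len(n), function(i) {
    set.seed(seed + i)
    c2 <- base
    if (scramble) c2$z <- c2$z + 1.5 * sin(seq_len(nrow(c2)))
    c2$x <- c2$x + stats::rnorm(nrow(c2), 0, noise)
    c2$y <- c2$y + stats::rnorm(nrow(c2), 0, noise)
    c2$z <- c2$z + stats::rnorm(nrow(c2), 0, noise)
    c2
  })
  frames
}

# independent RMSD oracle: exhaustive search over a rotation grid refined
# by Nelder-Mead, no Kabsch algebra shared with the implementation
grid_rmsd_oracle <- function(P, Q, n_coarse = 16) {
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  rot <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
    Rz %*% Ry %*% Rx
  }
  f <- function(a) sqrt(mean(rowSums((P0 - Q0 %*% t(rot(a)))^2)))
  g <- seq(0, 2 * pi, length.out = n_coarse + 1)[-1]
  best <- c(0, 0, 0); bv <- f(best)
  for (a1 in g) for (a2 in g[g <= pi]) for (a3 in g) {
    v <- f(c(a1, a2, a3))
    if (v < bv) { bv <- v; best <- c(a1, a2, a3) }
  }
  opt <- stats::optim(best, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}
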