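# Shared fixtures, built in code once per test run.

ics_tab <- ideal_ic_table()

# Gauss-Legendre nodes/weights on [a, b] via the Golub-Welsch eigenvalue
# method; used as the quadrature oracle for orthonormality checks.
gauss_legendre <- function(n, a = -1, b = 1) {
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(x = (b - a) / 2 * x + (a + b) / 2, w = (b - a) / 2 * w)
}

# A rigid motion applied to an atom table.
transform_atoms <- function(atoms, R, t = c(0, 0, 0)) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1] + t[1]
  atoms$y <- xyz[, 2] + t[2]
  atoms$z <- xyz[, 3] + t[3]
  atoms
}

# Encode one residue's own conformation about its CA.
encode_residue <- function(atoms, config, channel_set = config$channel_set) {
  ca <- as.numeric(atoms[atoms$atom_name == "CA", c("x", "y", "z")][1, ])
  cl <- channelize(atoms, ca, channel_set)
  encode(cl, config)
}

# A minimal untrained model wrapper around freshly initialized parameters.
fresh_model <- function(net_cfg, enc_cfg) {
  list(params = chipacker:::net_init(net_cfg, encoding_multiplicities(enc_cfg)),
       config = net_cfg, encoding_config = enc_cfg,
       type_levels = chipacker:::AA3)
}
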