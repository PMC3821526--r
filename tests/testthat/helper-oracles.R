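# Independent oracles and shared fixtures.  The oracles deliberately use a
# different formulation from the package code paths they check.

# O(N^2) double-loop pair count (checks build_spring_network)
oracle_spring_count <- function(xyz, cutoff) {
  n <- nrow(xyz)
  cnt <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= cutoff) cnt <- cnt + 1L
    }
  }
  cnt
}

# Hessian via the B-matrix outer-product formulation H = sum_s k_s b_s b_s^T
# (the package assembles 3x3 blocks instead)
oracle_hessian <- function(xyz, springs) {
  n <- nrow(xyz)
  H <- matrix(0, 3L * n, 3L * n)
  for (s in seq_len(nrow(springs))) {
    i <- springs$i[s]
    j <- springs$j[s]
    r <- xyz[j, ] - xyz[i, ]
    rhat <- r / sqrt(sum(r^2))
    b <- numeric(3L * n)
    b[(3L * i - 2L):(3L * i)] <- -rhat
    b[(3L * j - 2L):(3L * j)] <- rhat
    H <- H + springs$k[s] * tcrossprod(b)
  }
  H
}

rot_z_oracle <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3L, 3L)
}

file_bytes <- function(path) readBin(path, "raw", file.info(path)$size)

# Test-side PDB ATOM formatter, independent of write_pdb()
atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                      altloc = " ", record = "ATOM  ") {
  sprintf("%s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          record, serial, paste0(" ", name), altloc, resname, chain, resno,
          x, y, z)
}

# The default synthetic hexamer with its unbound and bound mode sets,
# computed once per session (several files use it).
.hex_cache <- new.env(parent = emptyenv())
hex_fixture <- function() {
  if (is.null(.hex_cache$val)) {
    spec <- oligomer_spec()
    cg <- make_cn_oligomer(spec)
    net <- build_spring_network(cg)
    netb <- add_bridge_springs(net, cg,
                               bridge_spec(donor_resno = spec$donor_index,
                                           acceptor_resno = spec$acceptor_index))
    mu <- compute_modes(build_hessian(net))
    mb <- compute_modes(build_hessian(netb))
    .hex_cache$val <- list(spec = spec, cg = cg, net = net, netb = netb,
                           mu = mu, mb = mb)
  }
  .hex_cache$val
}

connexin_fixture_path <- function() {
  system.file("extdata", "connexins_synthetic.fasta", package = "carbanm",
              mustWork = TRUE)
}
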