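# Shared fixtures: all inputs are generated in code, no files shipped.

# A correctly column-aligned PDB ATOM/HETATM line.
pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     occ = 1, alt = " ", element = NULL, record = "ATOM",
                     insert = " ") {
  if (is.null(element)) element <- toupper(substr(gsub("[^A-Za-z]", "", name), 1, 1))
  # atom names of <4 chars start in column 14 by convention
  name_fmt <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_fmt, alt, resname, chain, resno, insert,
          x, y, z, occ, 0, element)
}

# Single-strand RNA-like chain: `atoms_per_res` heavy atoms per residue laid
# out on a gentle helix; residue 1 lacks the phosphate when drop_5p_P.
chain_pdb <- function(n_res = 8, drop_5p_P = TRUE) {
  atom_names <- c("P", "OP1", "O5'", "C5'", "C4'", "C3'", "O3'", "C1'", "C2", "N1")
  lines <- character(0)
  serial <- 0L
  for (t in seq_len(n_res)) {
    names_t <- if (t == 1 && drop_5p_P) setdiff(atom_names, c("P", "OP1")) else atom_names
    for (a in seq_along(names_t)) {
      serial <- serial + 1L
      phi <- 0.6 * t + 0.15 * a
      lines <- c(lines, pdb_line(serial, names_t[a], "G", "A", t,
                                 6 * cos(phi) + 0.3 * a, 6 * sin(phi), 2.8 * t + 0.2 * a))
    }
  }
  c(lines, "END")
}

# Count of heavy atoms the chain_pdb fixture emits.
chain_pdb_n_atoms <- function(n_res = 8, drop_5p_P = TRUE) {
  10L * n_res - if (drop_5p_P) 2L else 0L
}

# Bare bead structure from a coordinate matrix (bypasses PDB parsing).
make_beads <- function(xyz, role = "ATOM:X", chain = "A") {
  xyz <- as.matrix(xyz)
  df <- data.frame(chain = chain, resid = as.character(seq_len(nrow(xyz))),
                   role = role, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   stringsAsFactors = FALSE)
  attr(df, "scheme") <- bead_scheme("AA")
  class(df) <- c("bead_structure", "data.frame")
  df
}

dofi <- function(i) as.vector(rbind(3 * i - 2, 3 * i - 1, 3 * i))

# A connected random network: cloud in a box with a cutoff covering the
# whole box diagonal scaled down, retried until exactly 6 zero modes.
connected_network <- function(n, seed, cutoff_frac = 0.9, box = 12) {
  cloud <- random_cloud(n, box = box, min_separation = 1.5, seed = seed)
  build_network(cloud, cutoff = cutoff_frac * box * sqrt(3))
}

# Explicit pairwise harmonic energy of a network at bead coordinates X.
network_energy <- function(network, X) {
  sp <- network$springs
  dx <- X[sp$i, , drop = FALSE] - X[sp$j, , drop = FALSE]
  d <- sqrt(rowSums(dx^2))
  0.5 * sum(sp$k * (d - sp$d)^2)
}

# Central finite-difference Hessian of network_energy (independent oracle).
fd_hessian <- function(network, h = 1e-4) {
  X0 <- bead_coords(network$structure)
  n_dof <- 3 * nrow(X0)
  as_X <- function(v) matrix(v, ncol = 3, byrow = TRUE)
  x0 <- as.vector(t(X0))
  H <- matrix(0, n_dof, n_dof)
  for (p in seq_len(n_dof)) {
    for (q in p:n_dof) {
      if (p == q) {
        xp <- x0; xp[p] <- xp[p] + h
        xm <- x0; xm[p] <- xm[p] - h
        H[p, p] <- (network_energy(network, as_X(xp)) -
                      2 * network_energy(network, as_X(x0)) +
                      network_energy(network, as_X(xm))) / h^2
      } else {
        xpp <- x0; xpp[c(p, q)] <- xpp[c(p, q)] + h
        xmm <- x0; xmm[c(p, q)] <- xmm[c(p, q)] - h
        xpm <- x0; xpm[p] <- xpm[p] + h; xpm[q] <- xpm[q] - h
        xmp <- x0; xmp[p] <- xmp[p] - h; xmp[q] <- xmp[q] + h
        H[p, q] <- H[q, p] <-
          (network_energy(network, as_X(xpp)) + network_energy(network, as_X(xmm)) -
             network_energy(network, as_X(xpm)) - network_energy(network, as_X(xmp))) /
          (4 * h^2)
      }
    }
  }
  H
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}
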