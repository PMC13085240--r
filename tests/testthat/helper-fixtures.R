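# In-code fixture builders shared by the unit tests.

# A lone water: O bonded to two hydrogens, one frame.
water_system <- function() {
  atoms <- atom_table(serial = 1:3, name = c("OH2", "H1", "H2"),
                      element = c("O", "H", "H"), resname = "HOH",
                      resid = 1L, segid = "WAT")
  bonds <- bond_graph(rbind(c(0L, 1L), c(0L, 2L)), 3L)
  frames <- list(RS = rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
  assemble_system(atoms, bonds, frames)
}

# A PDB file with a single water, written to a temp path.
water_pdb <- function() {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "ATOM      2  H1  HOH A   1       0.960   0.000   0.000  1.00  0.00           H",
    "ATOM      3  H2  HOH A   1      -0.240   0.930   0.000  1.00  0.00           H",
    "END"), path)
  path
}

# Chain of carbons all named CX (every bond cutable under the cx_rules
# table below), with per-atom coordinates on the x axis.
cx_chain <- function(n, bonds_extra = NULL) {
  atoms <- atom_table(serial = seq_len(n), name = rep("CX", n),
                      element = "C", resname = "LIG", resid = 1L)
  edges <- cbind(0:(n - 2), 1:(n - 1))
  if (!is.null(bonds_extra)) edges <- rbind(edges, bonds_extra)
  frames <- list(RS = cbind(1.5 * (seq_len(n) - 1), 0, 0))
  assemble_system(atoms, bond_graph(edges, n), frames)
}

cx_rules <- function() cut_rules("CX", "CX")

# A star: atoms A1, A2, A3 around X and Y (A1-X, A2-X, X-Y, A3-Y), all
# carbons named CX. Seeding {A1, A2, A3} exercises two-pass shared-MM
# merging (X first, then Y).
cx_two_pass <- function() {
  n <- 5L  # A1=0, A2=1, X=2, Y=3, A3=4
  atoms <- atom_table(serial = 1:n, name = rep("CX", n), element = "C",
                      resname = "LIG", resid = 1L)
  edges <- rbind(c(0L, 2L), c(1L, 2L), c(2L, 3L), c(3L, 4L))
  frames <- list(RS = cbind(seq_len(n), 0, 0))
  assemble_system(atoms, bond_graph(edges, n), frames)
}

# Default small test topology (deterministic).
test_topology <- function(seed = 7, ...) {
  make_topology(topology_recipe(seed = seed, ...))
}

# A tiny 2-basis Hamiltonian with no two-electron term and orthonormal
# basis; analytic ground-state energy -3 for 2 electrons.
h2_analytic <- function() {
  model_hamiltonian(diag(2), matrix(c(-1, -0.5, -0.5, -1), 2, 2),
                    array(0, c(2, 2, 2, 2)), c(1L, 2L), 2L)
}

# Two non-interacting fragments (block-diagonal in every operator):
# atoms 1..2 and 3..4, one basis function each, 2 electrons per fragment.
block_fragments <- function() {
  S <- diag(4)
  S[1, 2] <- S[2, 1] <- 0.3
  S[3, 4] <- S[4, 3] <- 0.3
  h <- matrix(0, 4, 4)
  h[1:2, 1:2] <- matrix(c(-2, -0.8, -0.8, -1.6), 2, 2)
  h[3:4, 3:4] <- matrix(c(-1.9, -0.7, -0.7, -1.5), 2, 2)
  eri <- array(0, c(4, 4, 4, 4))
  for (blk in list(1:2, 3:4)) {
    for (mu in blk) for (nu in blk) for (la in blk) for (si in blk) {
      eri[mu, nu, la, si] <- 0.2 * S[mu, nu] * S[la, si]
    }
  }
  model_hamiltonian(S, h, eri, c(1L, 2L, 3L, 4L), 4L)
}

# Perturbed copy of a Hamiltonian: shifts the one-electron diagonal on the
# given atoms (a reaction-like local change giving a relative energy).
perturb_hamiltonian <- function(H, eps, atoms) {
  h <- H$core_h
  mu <- which(H$atom_of_basis %in% atoms)
  diag(h)[mu] <- diag(h)[mu] + eps
  model_hamiltonian(H$overlap, h, H$two_electron, H$atom_of_basis,
                    H$n_electrons, H$constant_energy)
}
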