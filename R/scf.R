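# Restricted closed-shell SCF on toy model Hamiltonians.
#
# The model is a Hartree-Fock-like functional with a tunable fraction of
# exact exchange,
#   E[D] = E0 + Tr(D h) + 1/2 Tr(D J[D]) - cx/4 Tr(D K[D]),
# so a "high-level" (cx = 1.0) vs "low-level" (cx = 0.25) pair mimics the
# hybrid-vs-GGA accuracy gap that drives projection-based embedding,
# without any real DFT machinery. Densities carry the occupation factor 2;
# all solutions are closed-shell aufbau.

#' Define a model Hamiltonian
#'
#' @param overlap symmetric positive-definite AO overlap matrix S.
#' @param core_h symmetric one-electron matrix h.
#' @param two_electron 4-index array `(mu nu | lambda sigma)` with 8-fold
#'   permutational symmetry.
#' @param atom_of_basis integer vector mapping each basis function to a
#'   1-based atom index.
#' @param n_electrons even electron count, at most `2 * n_basis`.
#' @param constant_energy additive constant (e.g. a nuclear-repulsion-like
#'   term), default 0.
#' @return An object of class `model_hamiltonian`.
#' @export
model_hamiltonian <- function(overlap, core_h, two_electron, atom_of_basis,
                              n_electrons, constant_energy = 0) {
  n <- nrow(overlap)
  stopifnot(ncol(overlap) == n, all(dim(core_h) == n),
            all(dim(two_electron) == n))
  abort_if(max(abs(overlap - t(overlap))) > 1e-10,
           "model_hamiltonian(): overlap not symmetric")
  abort_if(min(eigen(overlap, symmetric = TRUE,
                     only.values = TRUE)$values) <= 0,
           "model_hamiltonian(): overlap not positive definite")
  abort_if(max(abs(core_h - t(core_h))) > 1e-10,
           "model_hamiltonian(): core_h not symmetric")
  abort_if(length(atom_of_basis) != n,
           "model_hamiltonian(): atom_of_basis length %d != n_basis %d",
           length(atom_of_basis), n)
  abort_if(n_electrons %% 2 != 0 || n_electrons > 2 * n || n_electrons <= 0,
           "model_hamiltonian(): need an even electron count in (0, %d]",
           2 * n)
  # spot-check the 8-fold symmetry on the full (small) tensor
  abort_if(max(abs(two_electron - aperm(two_electron, c(2, 1, 3, 4)))) > 1e-10 ||
             max(abs(two_electron - aperm(two_electron, c(3, 4, 1, 2)))) > 1e-10 ||
             max(abs(two_electron - aperm(two_electron, c(1, 2, 4, 3)))) > 1e-10,
           "model_hamiltonian(): two-electron tensor lacks 8-fold symmetry")
  structure(list(n_basis = n, overlap = overlap, core_h = core_h,
                 two_electron = two_electron,
                 atom_of_basis = as.integer(atom_of_basis),
                 n_atoms = max(atom_of_basis),
                 n_electrons = as.integer(n_electrons),
                 constant_energy = constant_energy),
            class = "model_hamiltonian")
}

#' Define an energy-functional level
#'
#' High- and low-level models differ only in their exact-exchange fraction.
#'
#' @param label `"HL"` or `"LL"` (free-form, informational).
#' @param exchange_fraction fraction of exact exchange in `[0, 1]`.
#' @return A `level_spec` list.
#' @export
level_spec <- function(label, exchange_fraction) {
  abort_if(exchange_fraction < 0 || exchange_fraction > 1,
           "level_spec(): exchange_fraction must be in [0,1]")
  structure(list(label = label, exchange_fraction = exchange_fraction),
            class = "level_spec")
}

# Coulomb and exchange contractions of the two-electron tensor.
coulomb_matrix <- function(H, D) {
  n <- H$n_basis
  matrix(matrix(H$two_electron, n * n, n * n) %*% as.vector(D), n, n)
}

exchange_matrix <- function(H, D) {
  n <- H$n_basis
  t4 <- aperm(H$two_electron, c(1, 3, 2, 4))  # [mu,nu,la,si] <- (mu la|nu si)
  matrix(matrix(t4, n * n, n * n) %*% as.vector(D), n, n)
}

#' Energy of a density at a given level
#'
#' `E = E0 + Tr(D h) + 1/2 Tr(D J[D]) - cx/4 Tr(D K[D])`.
#'
#' @param H a `model_hamiltonian`.
#' @param level a [level_spec()].
#' @param D density matrix (with occupation factor 2).
#' @return The energy (toy units).
#' @export
level_energy <- function(H, level, D) {
  abort_if(!all(dim(D) == H$n_basis),
           "level_energy(): density is %dx%d, basis is %d",
           nrow(D), ncol(D), H$n_basis)
  J <- coulomb_matrix(H, D)
  K <- exchange_matrix(H, D)
  H$constant_energy + sum(D * H$core_h) + 0.5 * sum(D * J) -
    level$exchange_fraction * 0.25 * sum(D * K)
}

#' Fock matrix of a density at a given level
#'
#' `F = h + J[D] - cx/2 K[D]`, the derivative of [level_energy()] with
#' respect to the density.
#'
#' @inheritParams level_energy
#' @return The Fock matrix.
#' @export
fock_matrix <- function(H, level, D) {
  H$core_h + coulomb_matrix(H, D) -
    0.5 * level$exchange_fraction * exchange_matrix(H, D)
}

# Symmetric inverse square root of the overlap.
inv_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(e$values), nrow = length(e$values)) %*%
    t(e$vectors)
}

# Generalized symmetric eigenproblem F C = S C eps via S^{-1/2}.
gen_eigen <- function(F_mat, X) {
  Fo <- t(X) %*% F_mat %*% X
  Fo <- (Fo + t(Fo)) / 2
  e <- eigen(Fo, symmetric = TRUE)
  ord <- order(e$values)
  list(values = e$values[ord],
       vectors = X %*% e$vectors[, ord, drop = FALSE])
}

#' Solve the closed-shell SCF equations
#'
#' Deterministic initial guess from the core Hamiltonian, optimal-damping
#' iterations (line-searched Roothaan steps with guaranteed energy
#' descent), aufbau occupation, convergence on the commutator norm
#' `max |F D S - S D F| <= tol` of the idempotent aufbau candidate.
#'
#' @param H a `model_hamiltonian`.
#' @param level a [level_spec()].
#' @param tol convergence tolerance on the commutator (default 1e-8).
#' @param max_iter maximum iterations (default 6000; near-degenerate cases approach the fixed point slowly).
#' @return List with `density` (D), `coefficients` (all MOs, columns; the
#'   occupied block spans `density` exactly), `mo_energies` (Ritz values
#'   of the converged Fock), `n_occ`, `energy`, `n_iter`, `residual`.
#' @export
scf_solve <- function(H, level, tol = 1e-8, max_iter = 6000L) {
  S <- H$overlap
  X <- inv_sqrt(S)
  nocc <- H$n_electrons %/% 2L
  eg <- gen_eigen(H$core_h, X)
  D <- 2 * tcrossprod(eg$vectors[, seq_len(nocc), drop = FALSE])
  .scf_iterate(H, level, D, S, X, nocc, tol, max_iter)
}

# Core SCF loop: optimal-damping (line-searched Roothaan) iterations.
# Each step diagonalizes the Fock of the current (possibly mixed) density,
# forms the aufbau candidate, and mixes with the line-search-optimal
# weight, which guarantees monotone energy descent. Convergence is tested
# on the idempotent aufbau candidate against its own Fock, so the returned
# density is idempotent and its occupied orbitals span it exactly.
.scf_iterate <- function(H, level, D, S, X, nocc, tol, max_iter) {
  residual <- Inf
  for (it in seq_len(max_iter)) {
    F_mix <- fock_matrix(H, level, D)
    eg <- gen_eigen(F_mix, X)
    C_occ <- eg$vectors[, seq_len(nocc), drop = FALSE]
    D_au <- 2 * tcrossprod(C_occ)
    F_au <- fock_matrix(H, level, D_au)
    err <- F_au %*% D_au %*% S - S %*% D_au %*% F_au
    residual <- max(abs(err))
    if (residual <= tol) {
      ritz <- vapply(seq_len(ncol(eg$vectors)), function(k)
        as.numeric(t(eg$vectors[, k]) %*% F_au %*% eg$vectors[, k]),
        numeric(1))
      return(list(density = D_au,
                  coefficients = eg$vectors,
                  mo_energies = ritz,
                  eig_final = eg,
                  n_occ = nocc,
                  energy = level_energy(H, level, D_au),
                  n_iter = it, residual = residual))
    }
    # the energy is exactly quadratic along the segment D + l (D_au - D),
    # so the optimal-damping weight has a closed form:
    # E(l) = E(D) + l Tr(delta F[D]) + l^2/2 Tr(delta G[delta])
    delta <- D_au - D
    slope <- sum(delta * F_mix)
    curv <- sum(delta * (fock_matrix(H, level, delta) - H$core_h))
    lam <- if (curv > 0) max(min(-slope / curv, 1), 1e-3) else 1
    D <- D + lam * delta
  }
  stop(sprintf("scf_solve(): no convergence in %d iterations (residual %.3e)",
               max_iter, residual), call. = FALSE)
}

#' Mulliken populations of molecular orbitals
#'
#' Gross population of each MO on each atom,
#' `Q_A(i) = sum_{mu in A} C_mu_i (S C)_mu_i`; columns sum to 1 for
#' S-normalized MOs.
#'
#' @param H a `model_hamiltonian`.
#' @param C coefficient matrix (basis x MO).
#' @return Matrix `n_atoms x n_mo` of populations.
#' @export
mulliken_populations <- function(H, C) {
  SC <- H$overlap %*% C
  contrib <- C * SC                  # per-basis-function contribution
  # rows indexed by atom id even when an atom carries no basis function
  # (possible after AO truncation)
  pops <- matrix(0, H$n_atoms, ncol(C))
  grouped <- rowsum(contrib, H$atom_of_basis)
  pops[as.integer(rownames(grouped)), ] <- grouped
  pops
}

# Pipek-Mezey objective: sum over MOs of squared per-atom populations.
pm_objective <- function(H, C) sum(mulliken_populations(H, C)^2)

#' Localize occupied orbitals (Pipek-Mezey)
#'
#' Rotates the occupied block to maximize the sum of squared per-atom
#' Mulliken populations via 2x2 Jacobi sweeps; the occupied density is
#' unchanged by construction.
#'
#' @param H a `model_hamiltonian`.
#' @param C_occ occupied coefficient matrix (basis x n_occ).
#' @param max_sweeps maximum Jacobi sweeps (default 200).
#' @param tol stop when a full sweep improves the objective by less than
#'   this (default 1e-10).
#' @return The localized coefficient matrix.
#' @export
localize_orbitals <- function(H, C_occ, max_sweeps = 200L, tol = 1e-10) {
  nmo <- ncol(C_occ)
  if (nmo < 2L) return(C_occ)
  C <- C_occ
  S <- H$overlap
  atom <- H$atom_of_basis
  atoms <- sort(unique(atom))
  obj_prev <- pm_objective(H, C)
  for (sweep in seq_len(max_sweeps)) {
    for (s in seq_len(nmo - 1L)) {
      for (t in (s + 1L):nmo) {
        SC_s <- S %*% C[, s]; SC_t <- S %*% C[, t]
        Ast <- 0; Bst <- 0
        for (A in atoms) {
          mu <- atom == A
          Qss <- sum(C[mu, s] * SC_s[mu])
          Qtt <- sum(C[mu, t] * SC_t[mu])
          Qst <- 0.5 * sum(C[mu, s] * SC_t[mu] + C[mu, t] * SC_s[mu])
          Ast <- Ast + Qst^2 - 0.25 * (Qss - Qtt)^2
          Bst <- Bst + Qst * (Qss - Qtt)
        }
        if (sqrt(Ast^2 + Bst^2) < 1e-14) next
        gamma <- 0.25 * atan2(Bst, -Ast)
        cs <- cos(gamma); sn <- sin(gamma)
        new_s <- cs * C[, s] + sn * C[, t]
        new_t <- -sn * C[, s] + cs * C[, t]
        C[, s] <- new_s; C[, t] <- new_t
      }
    }
    obj <- pm_objective(H, C)
    if (obj - obj_prev < tol) break
    obj_prev <- obj
  }
  C
}

#' Select active MOs by Mulliken population on active atoms
#'
#' Localized occupied MOs whose summed Mulliken population on the active
#' atoms reaches the threshold are assigned to the active subsystem.
#'
#' @param H a `model_hamiltonian`.
#' @param C_loc localized occupied coefficients.
#' @param active_atoms 1-based atom indices of the active subsystem.
#' @param threshold population threshold, default 0.3.
#' @return Integer vector of selected MO column indices.
#' @export
select_active_mos <- function(H, C_loc, active_atoms, threshold = 0.3) {
  pops <- mulliken_populations(H, C_loc)
  act <- colSums(pops[active_atoms, , drop = FALSE])
  sel <- which(act >= threshold)
  abort_if(length(sel) == 0L,
           paste0("select_active_mos(): no MO reaches population %.2f on the",
                  " active atoms; enlarge the active set"), threshold)
  sel
}
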