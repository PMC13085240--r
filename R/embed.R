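# Huzinaga projection-based QM-in-QM embedding, AO truncation, and the
# subtractive ONIOM comparator.
#
# Workflow: solve the low level (LL) for the whole system, localize the
# occupied orbitals, pick active MOs by Mulliken population on the active
# atoms, freeze the remaining (environment) orbitals, and re-optimize the
# active orbitals at the high level (HL) under the Huzinaga projection
# operator -1/2 (F D_B S + S D_B F), which shifts the frozen environment
# orbitals out of the occupied window and keeps the active solution
# S-orthogonal to them. The total energy carries a first-order correction
# in the active-density difference.

#' Embedded SCF with a frozen environment (Huzinaga projection)
#'
#' Re-optimizes the active orbitals at the HL while the environment density
#' `D_B` (from the frozen LL environment MOs) is held fixed. The effective
#' operator is `F_HL[D_A + D_B] - 1/2 (F D_B S + S D_B F)`. Occupation is
#' aufbau over eigenvectors with negligible environment character, so the
#' converged active density satisfies `Tr(D_A S D_B S) ~ 0`.
#'
#' @param H a `model_hamiltonian` (full system).
#' @param hl_level HL [level_spec()].
#' @param C_active initial active orbitals (columns, S-orthonormal), e.g.
#'   the selected localized LL MOs.
#' @param D_env frozen environment density (matrix; 0 matrix for an empty
#'   environment).
#' @param tol commutator convergence tolerance (default 1e-8).
#' @param max_iter maximum iterations (default 6000; near-degenerate cases approach the fixed point slowly).
#' @return List with `density` (the re-optimized active density),
#'   `coefficients`, `n_occ`, `n_iter`, `residual`, `env_overlap`
#'   (`Tr(D_A S D_B S)`), `electron_count` (`Tr(D_A S)`).
#' @export
huzinaga_scf <- function(H, hl_level, C_active, D_env,
                         tol = 1e-8, max_iter = 6000L) {
  S <- H$overlap
  X <- inv_sqrt(S)
  n_act <- ncol(C_active)
  D_A <- 2 * tcrossprod(C_active)
  residual <- Inf
  huz <- function(D_tot) {
    F_mat <- fock_matrix(H, hl_level, D_tot)
    FDS <- F_mat %*% D_env %*% S
    list(eff = F_mat - 0.5 * (FDS + t(FDS)), plain = F_mat)
  }
  # aufbau candidate over the non-environment eigenvectors of F_eff
  candidate <- function(F_eff) {
    eg <- gen_eigen(F_eff, X)
    env_char <- vapply(seq_len(ncol(eg$vectors)), function(k) {
      c_k <- eg$vectors[, k]
      0.5 * as.numeric(t(c_k) %*% S %*% D_env %*% S %*% c_k)
    }, numeric(1))
    keep <- which(env_char < 0.5)
    abort_if(length(keep) < n_act,
             "huzinaga_scf(): fewer than %d non-environment eigenvectors",
             n_act)
    eg$vectors[, keep[seq_len(n_act)], drop = FALSE]
  }
  for (it in seq_len(max_iter)) {
    F_mix <- huz(D_A + D_env)
    C_au <- candidate(F_mix$eff)
    D_au <- 2 * tcrossprod(C_au)
    F_au <- huz(D_au + D_env)$eff
    err <- F_au %*% D_au %*% S - S %*% D_au %*% F_au
    residual <- max(abs(err))
    if (residual <= tol) {
      return(list(density = D_au,
                  coefficients = C_au,
                  n_occ = n_act,
                  n_iter = it, residual = residual,
                  env_overlap = sum((D_au %*% S) * t(D_env %*% S)),
                  electron_count = sum(D_au * S)))
    }
    # optimal-damping step with the closed-form quadratic line search
    # (the environment density is constant along the segment)
    delta <- D_au - D_A
    slope <- sum(delta * F_mix$plain)
    curv <- sum(delta * (fock_matrix(H, hl_level, delta) - H$core_h))
    lam <- if (curv > 0) max(min(-slope / curv, 1), 1e-3) else 1
    D_A <- D_A + lam * delta
  }
  stop(sprintf(
    "huzinaga_scf(): no convergence in %d iterations (residual %.3e)",
    max_iter, residual), call. = FALSE)
}

#' Embedding energy with first-order correction
#'
#' `E = E_LL[D] - E_LL[D_A] + E_HL[D_A~] + Tr{(D_A~ - D_A) V_emb}` with the
#' embedding potential realized as `V_emb = F_LL[D] - F_LL[D_A]` (the
#' derivative of the LL-minus-HL energy difference with respect to the
#' active density; the realization is configurable via `v_emb`).
#'
#' @param H a `model_hamiltonian`.
#' @param ll_level,hl_level [level_spec()] objects.
#' @param D full-system LL density.
#' @param D_A active-subsystem LL density (from the selected localized MOs).
#' @param D_tilde_A HL-embedded active density from [huzinaga_scf()].
#' @param v_emb optional explicit embedding-potential matrix overriding the
#'   default realization.
#' @return An object of class `embedding_result` with `E_total` and a
#'   `terms` list (`E_LL_full`, `E_LL_active`, `E_HL_active`,
#'   `first_order_correction`).
#' @export
embedding_energy <- function(H, ll_level, hl_level, D, D_A, D_tilde_A,
                             v_emb = NULL) {
  abort_if(!all(dim(D) == H$n_basis) || !all(dim(D_A) == H$n_basis) ||
             !all(dim(D_tilde_A) == H$n_basis),
           "embedding_energy(): density dimension mismatch")
  if (is.null(v_emb)) {
    v_emb <- fock_matrix(H, ll_level, D) - fock_matrix(H, ll_level, D_A)
  }
  terms <- list(
    E_LL_full = level_energy(H, ll_level, D),
    E_LL_active = level_energy(H, ll_level, D_A),
    E_HL_active = level_energy(H, hl_level, D_tilde_A),
    first_order_correction = sum((D_tilde_A - D_A) * v_emb))
  E <- terms$E_LL_full - terms$E_LL_active + terms$E_HL_active +
    terms$first_order_correction
  structure(list(E_total = E, terms = terms), class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf(paste0("embedding_result: E_total = %.10f\n",
                     "  E_LL[full] = %.10f  E_LL[active] = %.10f\n",
                     "  E_HL[active~] = %.10f  1st-order corr = %.3e\n"),
              x$E_total, x$terms$E_LL_full, x$terms$E_LL_active,
              x$terms$E_HL_active, x$terms$first_order_correction))
  invisible(x)
}

#' AO basis truncation for the embedded high-level problem
#'
#' Retains the basis functions whose Mulliken-type contribution
#' `|C_mu_i (S C)_mu_i|` to any active MO exceeds `tau_ao`, plus every
#' function centered on an active atom, and restricts the Hamiltonian to
#' the retained set. Environment quantities (densities) are projected by
#' plain restriction to the retained rows/columns.
#'
#' @param H a `model_hamiltonian`.
#' @param C_loc localized occupied coefficients (full basis).
#' @param active_mos active MO column indices.
#' @param active_atoms 1-based active atom indices.
#' @param tau_ao truncation threshold (default 1e-4; 0 keeps everything).
#' @return List with `H` (reduced `model_hamiltonian`, original atom ids
#'   preserved), `keep` (retained basis indices in the full basis).
#' @export
less_ao_truncate <- function(H, C_loc, active_mos, active_atoms,
                             tau_ao = 1e-4) {
  SC <- H$overlap %*% C_loc
  contrib <- abs(C_loc * SC)[, active_mos, drop = FALSE]
  important <- apply(contrib, 1, max) > tau_ao
  on_active <- H$atom_of_basis %in% active_atoms
  keep <- which(important | on_active)
  abort_if(length(keep) == 0L, "less_ao_truncate(): empty retained set")
  Hr <- model_hamiltonian(
    overlap = H$overlap[keep, keep, drop = FALSE],
    core_h = H$core_h[keep, keep, drop = FALSE],
    two_electron = H$two_electron[keep, keep, keep, keep, drop = FALSE],
    atom_of_basis = H$atom_of_basis[keep],
    n_electrons = min(H$n_electrons, 2L * length(keep)),
    constant_energy = H$constant_energy)
  Hr$n_atoms <- H$n_atoms
  list(H = Hr, keep = keep)
}

#' Full Huzinaga embedding pipeline on a model Hamiltonian
#'
#' LL SCF on the whole system, Pipek-Mezey localization, Mulliken
#' active-MO selection, frozen-environment HL SCF, and the corrected
#' embedding energy — optionally with AO truncation of the HL subproblem.
#'
#' @param H a `model_hamiltonian`.
#' @param active_atoms 1-based active atom indices.
#' @param hl_level,ll_level [level_spec()] objects (defaults: exchange
#'   fractions 1.0 and 0.25).
#' @param mo_threshold Mulliken active-MO selection threshold (default 0.3).
#' @param tau_ao AO truncation threshold; `NULL` disables truncation.
#' @return List with `result` (an `embedding_result`), `diagnostics`
#'   (environment overlap, electron count, active MO indices, retained
#'   basis set), and the intermediate densities `D`, `D_A`, `D_tilde_A`
#'   (full-basis, `D_tilde_A` zero-padded when truncated).
#' @export
huzinaga_embed <- function(H, active_atoms,
                           hl_level = level_spec("HL", 1.0),
                           ll_level = level_spec("LL", 0.25),
                           mo_threshold = 0.3, tau_ao = NULL) {
  ll <- scf_solve(H, ll_level)
  C_occ <- ll$coefficients[, seq_len(ll$n_occ), drop = FALSE]
  C_loc <- localize_orbitals(H, C_occ)
  act <- select_active_mos(H, C_loc, active_atoms, mo_threshold)
  env <- setdiff(seq_len(ll$n_occ), act)
  C_act <- C_loc[, act, drop = FALSE]
  D_A <- 2 * tcrossprod(C_act)
  D_env <- if (length(env)) 2 * tcrossprod(C_loc[, env, drop = FALSE])
           else matrix(0, H$n_basis, H$n_basis)
  keep <- seq_len(H$n_basis)
  if (!is.null(tau_ao)) {
    tr <- less_ao_truncate(H, C_loc, act, active_atoms, tau_ao)
    keep <- tr$keep
    Hr <- tr$H
  } else {
    Hr <- H
  }
  if (length(keep) < H$n_basis) {
    # re-orthonormalize the restricted active orbitals in the reduced metric
    C0 <- C_act[keep, , drop = FALSE]
    M <- t(C0) %*% Hr$overlap %*% C0
    C0 <- C0 %*% inv_sqrt(M)
    # the plainly restricted environment density is no longer idempotent;
    # purify it so the frozen-environment projection stays exact in the
    # reduced basis
    D_env_r <- .purify_density(Hr$overlap, D_env[keep, keep, drop = FALSE])
    # environment electrons dropped from the reduced basis still act on
    # the active block through their (long-range) mean-field potential;
    # fold that residual potential into the reduced one-electron term so
    # the reduced embedded operator matches the restriction of the full
    # one. The reduced Hamiltonian used for the *energy* stays plain.
    G_env_full <- (fock_matrix(H, hl_level, D_env) -
                     H$core_h)[keep, keep, drop = FALSE]
    G_env_red <- fock_matrix(Hr, hl_level, D_env_r) - Hr$core_h
    Hr_scf <- Hr
    Hr_scf$core_h <- Hr$core_h + G_env_full - G_env_red
    emb <- huzinaga_scf(Hr_scf, hl_level, C0, D_env_r)
    D_tilde_full <- matrix(0, H$n_basis, H$n_basis)
    D_tilde_full[keep, keep] <- emb$density
    v_emb <- fock_matrix(H, ll_level, ll$density) -
      fock_matrix(H, ll_level, D_A)
    res <- structure(list(
      E_total = NA_real_,
      terms = list(E_LL_full = level_energy(H, ll_level, ll$density),
                   E_LL_active = level_energy(H, ll_level, D_A),
                   E_HL_active = level_energy(Hr, hl_level, emb$density),
                   first_order_correction = sum(
                     (emb$density - D_A[keep, keep]) *
                       v_emb[keep, keep]))),
      class = "embedding_result")
    res$E_total <- res$terms$E_LL_full - res$terms$E_LL_active +
      res$terms$E_HL_active + res$terms$first_order_correction
  } else if (length(env) == 0L) {
    # degenerate partition: an empty environment makes the embedded
    # problem the plain full-system HL problem; solve it with the same
    # deterministic initialization as any other full SCF
    hl_res <- scf_solve(H, hl_level)
    emb <- list(density = hl_res$density, n_iter = hl_res$n_iter,
                env_overlap = 0,
                electron_count = sum(hl_res$density * H$overlap))
    D_tilde_full <- emb$density
    res <- embedding_energy(H, ll_level, hl_level, ll$density, D_A,
                            emb$density)
  } else {
    emb <- huzinaga_scf(Hr, hl_level, C_act, D_env)
    D_tilde_full <- emb$density
    res <- embedding_energy(H, ll_level, hl_level, ll$density, D_A,
                            emb$density)
  }
  list(result = res,
       diagnostics = list(active_mos = act,
                          n_env_mos = length(env),
                          env_overlap = emb$env_overlap,
                          electron_count = emb$electron_count,
                          expected_electrons = 2 * length(act),
                          retained_basis = keep,
                          scf_iterations = c(ll = ll$n_iter,
                                             embedded = emb$n_iter)),
       D = ll$density, D_A = D_A, D_tilde_A = D_tilde_full)
}

# Nearest idempotent density (occupation factor 2) in the metric S: keep
# the round(Tr(D S)/2) natural orbitals with the largest occupations. A
# projected environment with (near-)zero trace purifies to the zero
# density rather than a phantom occupied orbital.
.purify_density <- function(S, D) {
  n_occ <- round(sum(D * S) / 2)
  if (n_occ < 1L) return(matrix(0, nrow(S), ncol(S)))
  Xh <- inv_sqrt(S)
  Sh <- solve(Xh)                       # S^{1/2}
  e <- eigen((Sh %*% D %*% Sh) / 2, symmetric = TRUE)
  C <- Xh %*% e$vectors[, seq_len(n_occ), drop = FALSE]
  2 * tcrossprod(C)
}

# --------------------------------------------------------------- ONIOM --

#' Subtractive ONIOM combination
#'
#' `E = E_LL(full) - E_LL(active, capped) + E_HL(active, capped)`, with
#' both capped-subsystem energies computed on the identical capped model.
#' With HL = LL the combination collapses to `E_LL(full)` exactly.
#'
#' @param e_ll_full LL energy of the full system.
#' @param e_ll_active_capped LL energy of the capped active subsystem.
#' @param e_hl_active_capped HL energy of the same capped subsystem.
#' @return The ONIOM total energy.
#' @export
oniom_energy <- function(e_ll_full, e_ll_active_capped, e_hl_active_capped) {
  e_ll_full - e_ll_active_capped + e_hl_active_capped
}

#' Capped active subsystem of a model Hamiltonian
#'
#' Restricts the Hamiltonian to the basis functions of the active atoms
#' and, for every severed strong one-electron coupling between an active
#' and an environment atom, appends one cap basis function (the toy
#' analogue of a hydrogen link atom) carrying a diagonal attraction
#' `cap_strength` and the severed function's couplings to the active block.
#' The electron count is `2 * n_active_mos`; when `n_active_mos` is `NULL`
#' it is derived from a localization-based assignment of the full-system LL
#' MOs (majority population threshold 0.5).
#'
#' @param H a `model_hamiltonian`.
#' @param active_atoms 1-based active atom indices.
#' @param cap_strength diagonal one-electron term of each cap function
#'   (default -0.5; 0 gives inert caps).
#' @param n_active_mos electron bookkeeping override (pairs).
#' @param coupling_threshold minimum `|h|` between basis functions for a
#'   severed coupling to receive a cap (default 0.05).
#' @param ll_level level used for the localization-based electron count.
#' @return A `model_hamiltonian` for the capped subsystem; attribute
#'   `"n_caps"` records the number of cap functions.
#' @export
capped_subsystem <- function(H, active_atoms, cap_strength = -0.5,
                             n_active_mos = NULL, coupling_threshold = 0.05,
                             ll_level = level_spec("LL", 0.25)) {
  in_active <- H$atom_of_basis %in% active_atoms
  keep <- which(in_active)
  abort_if(length(keep) == 0L, "capped_subsystem(): no active basis functions")
  # severed strong couplings: (active fn, env fn) pairs above threshold,
  # one cap per severed env function
  sever <- which(abs(H$core_h) > coupling_threshold &
                   outer(in_active, !in_active, `&`), arr.ind = TRUE)
  cap_src <- sort(unique(sever[, 2]))
  if (is.null(n_active_mos)) {
    ll <- scf_solve(H, ll_level)
    C_loc <- localize_orbitals(
      H, ll$coefficients[, seq_len(ll$n_occ), drop = FALSE])
    pops <- mulliken_populations(H, C_loc)
    n_active_mos <- sum(colSums(pops[active_atoms, , drop = FALSE]) >= 0.5)
    abort_if(n_active_mos == 0L,
             "capped_subsystem(): no MO assigns to the active atoms")
  }
  nk <- length(keep); nc <- length(cap_src); nn <- nk + nc
  S <- diag(1, nn); h <- matrix(0, nn, nn)
  S[seq_len(nk), seq_len(nk)] <- H$overlap[keep, keep]
  h[seq_len(nk), seq_len(nk)] <- H$core_h[keep, keep]
  eri <- array(0, rep(nn, 4))
  eri[seq_len(nk), seq_len(nk), seq_len(nk), seq_len(nk)] <-
    H$two_electron[keep, keep, keep, keep]
  for (c_i in seq_along(cap_src)) {
    col <- nk + c_i
    src <- cap_src[c_i]
    S[col, seq_len(nk)] <- H$overlap[src, keep]
    S[seq_len(nk), col] <- H$overlap[keep, src]
    h[col, seq_len(nk)] <- H$core_h[src, keep]
    h[seq_len(nk), col] <- H$core_h[keep, src]
    h[col, col] <- cap_strength
  }
  # caps inherit diagonal unit overlap; keep S positive definite by scaling
  # cap couplings down if needed
  scale <- 1
  while (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 1e-6 &&
         scale > 1e-3) {
    scale <- scale / 2
    for (c_i in seq_along(cap_src)) {
      col <- nk + c_i
      S[col, seq_len(nk)] <- scale * H$overlap[cap_src[c_i], keep]
      S[seq_len(nk), col] <- scale * H$overlap[keep, cap_src[c_i]]
    }
  }
  Hc <- model_hamiltonian(S, h, eri,
                          atom_of_basis = c(H$atom_of_basis[keep],
                                            rep(max(H$atom_of_basis) + 1L, nc)),
                          n_electrons = 2L * as.integer(n_active_mos),
                          constant_energy = H$constant_energy)
  attr(Hc, "n_caps") <- nc
  attr(Hc, "n_active_mos") <- as.integer(n_active_mos)
  Hc
}

#' ONIOM comparator pipeline
#'
#' Builds the capped active subsystem and combines the three SCF energies
#' subtractively.
#'
#' @inheritParams capped_subsystem
#' @param hl_level,ll_level [level_spec()] objects.
#' @return List with `energy`, the three component energies, and the
#'   capped Hamiltonian.
#' @export
oniom_embed <- function(H, active_atoms,
                        hl_level = level_spec("HL", 1.0),
                        ll_level = level_spec("LL", 0.25),
                        cap_strength = -0.5, n_active_mos = NULL) {
  full_is_active <- setequal(unique(H$atom_of_basis), active_atoms)
  Hc <- if (full_is_active) H else
    capped_subsystem(H, active_atoms, cap_strength, n_active_mos,
                     ll_level = ll_level)
  e_ll_full <- scf_solve(H, ll_level)$energy
  e_ll_cap <- scf_solve(Hc, ll_level)$energy
  e_hl_cap <- scf_solve(Hc, hl_level)$energy
  list(energy = oniom_energy(e_ll_full, e_ll_cap, e_hl_cap),
       e_ll_full = e_ll_full, e_ll_active_capped = e_ll_cap,
       e_hl_active_capped = e_hl_cap, capped = Hc)
}
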