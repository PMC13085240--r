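# Toy-scale electronic structure: SCF, localization, active-MO selection,
# frozen-environment embedding, AO truncation, and the ONIOM comparator.

LL <- level_spec("LL", 0.25)
HL <- level_spec("HL", 1.0)

test_that("level_energy reduces to the constant at zero density", {
  H <- make_hamiltonian(hamiltonian_recipe(seed = 2))
  D0 <- matrix(0, H$n_basis, H$n_basis)
  expect_equal(level_energy(H, LL, D0), H$constant_energy)
  expect_error(level_energy(H, LL, matrix(0, 2, 2)), "density is")
})

test_that("the 2-basis one-electron model has the analytic ground energy", {
  H <- h2_analytic()
  s <- scf_solve(H, HL)
  expect_equal(s$energy, -3.0, tolerance = 1e-10)
  expect_equal(level_energy(H, HL, s$density), -3.0, tolerance = 1e-10)
})

test_that("full-exchange energies match the element-wise textbook formula", {
  H <- make_hamiltonian(hamiltonian_recipe(n_atoms = 2, basis_per_atom = 2,
                                           seed = 6))
  s <- scf_solve(H, HL)
  expect_equal(level_energy(H, HL, s$density),
               oracle_level_energy(H, 1.0, s$density), tolerance = 1e-10)
  expect_equal(level_energy(H, LL, s$density),
               oracle_level_energy(H, 0.25, s$density), tolerance = 1e-10)
})

test_that("without two-electron terms the MOs are the (h, S) eigenpairs", {
  H <- make_hamiltonian(hamiltonian_recipe(n_atoms = 3, seed = 4))
  H0 <- model_hamiltonian(H$overlap, H$core_h,
                          array(0, rep(H$n_basis, 4)),
                          H$atom_of_basis, H$n_electrons)
  s <- scf_solve(H0, HL)
  ref <- sort(Re(eigen(solve(H0$overlap, H0$core_h))$values))
  expect_equal(s$mo_energies, ref, tolerance = 1e-7)
})

test_that("SCF energies agree with a direct-minimization oracle", {
  for (sd in c(2, 6)) {
    H <- make_hamiltonian(hamiltonian_recipe(n_atoms = 3, basis_per_atom = 2,
                                             seed = sd))
    s <- scf_solve(H, LL)
    expect_equal(s$energy, oracle_scf_energy(H, 0.25), tolerance = 1e-7)
  }
})

test_that("SCF solutions satisfy trace and idempotency invariants", {
  for (sd in 1:10) {
    H <- make_hamiltonian(hamiltonian_recipe(n_atoms = 4, seed = sd))
    s <- scf_solve(H, LL)
    D <- s$density; S <- H$overlap
    expect_lt(abs(sum(D * S) - H$n_electrons), 1e-8)
    expect_lt(max(abs(D %*% S %*% D - 2 * D)), 1e-7)
    expect_lte(s$residual, 1e-8)
  }
})

test_that("localization preserves the density and increases the objective", {
  H <- make_hamiltonian(hamiltonian_recipe(n_atoms = 4, seed = 3))
  s <- scf_solve(H, LL)
  C_occ <- s$coefficients[, seq_len(s$n_occ), drop = FALSE]
  C_loc <- localize_orbitals(H, C_occ)
  expect_lt(max(abs(2 * tcrossprod(C_loc) - s$density)), 1e-10)
  expect_gte(pm_objective(H, C_loc), pm_objective(H, C_occ) - 1e-12)
})

test_that("localized MOs of non-interacting fragments live on one fragment", {
  H <- block_fragments()
  s <- scf_solve(H, LL)
  C_loc <- localize_orbitals(H, s$coefficients[, seq_len(s$n_occ),
                                               drop = FALSE])
  pops <- mulliken_populations(H, C_loc)
  frag <- rbind(colSums(pops[1:2, , drop = FALSE]),
                colSums(pops[3:4, , drop = FALSE]))
  expect_true(all(apply(frag, 2, max) >= 0.99))
})

test_that("active MOs are selected by Mulliken population threshold", {
  H <- block_fragments()
  s <- scf_solve(H, LL)
  C_loc <- localize_orbitals(H, s$coefficients[, seq_len(s$n_occ),
                                               drop = FALSE])
  expect_length(select_active_mos(H, C_loc, 1:4), s$n_occ)
  frag1 <- select_active_mos(H, C_loc, 1:2)
  expect_length(frag1, 1L)
  pops <- mulliken_populations(H, C_loc)
  expect_gte(colSums(pops[1:2, , drop = FALSE])[frag1], 0.99)
  expect_error(select_active_mos(H, C_loc, 1:2, threshold = 1.5),
               "enlarge")
})

test_that("self-embedding (HL = LL) reproduces the full LL energy", {
  for (sd in 1:20) {
    H <- make_hamiltonian(hamiltonian_recipe(n_atoms = 4 + sd %% 3,
                                             seed = sd))
    e_ll <- scf_solve(H, LL)$energy
    emb <- huzinaga_embed(H, 1:2, hl_level = LL)
    expect_lt(abs(emb$result$E_total - e_ll), 1e-8)
  }
})

test_that("whole-system active space reproduces the full HL energy", {
  for (sd in 1:10) {
    H <- make_hamiltonian(hamiltonian_recipe(n_atoms = 4, seed = sd))
    e_hl <- scf_solve(H, HL)$energy
    emb <- huzinaga_embed(H, seq_len(H$n_atoms))
    expect_lt(abs(emb$result$E_total - e_hl), 1e-8)
  }
})

test_that("embedded solutions conserve electrons and stay orthogonal to the environment", {
  for (sd in 1:20) {
    H <- make_hamiltonian(hamiltonian_recipe(n_atoms = 5, seed = sd))
    emb <- huzinaga_embed(H, 1:2)
    expect_lt(abs(emb$diagnostics$electron_count -
                    emb$diagnostics$expected_electrons), 1e-8)
    expect_lt(abs(emb$diagnostics$env_overlap), 1e-8)
  }
})

test_that("the first-order correction moves the energy toward full HL", {
  # statistical assertion over a fixed seed set: the corrected energy is
  # closer to the full-HL reference than the uncorrected sum on average
  err_corr <- c(); err_raw <- c()
  for (sd in 1:20) {
    H <- make_hamiltonian(hamiltonian_recipe(n_atoms = 5, seed = 100 + sd))
    e_hl <- scf_solve(H, HL)$energy
    emb <- huzinaga_embed(H, 1:2)
    t <- emb$result$terms
    raw <- t$E_LL_full - t$E_LL_active + t$E_HL_active
    err_corr <- c(err_corr, abs(emb$result$E_total - e_hl))
    err_raw <- c(err_raw, abs(raw - e_hl))
  }
  expect_lt(mean(err_corr), mean(err_raw))
})

test_that("embedding energy decomposition collapses in the degenerate cases", {
  H <- make_hamiltonian(hamiltonian_recipe(seed = 12))
  s <- scf_solve(H, LL)
  D <- s$density
  res <- embedding_energy(H, LL, LL, D, D, D)
  expect_equal(res$E_total, level_energy(H, LL, D), tolerance = 1e-12)
  expect_equal(res$terms$first_order_correction, 0, tolerance = 1e-12)
  expect_error(embedding_energy(H, LL, HL, D, D, matrix(0, 2, 2)),
               "dimension mismatch")
})

test_that("AO truncation at tau 0 retains the full basis and energy", {
  H <- make_hamiltonian(hamiltonian_recipe(n_atoms = 5, seed = 9))
  full <- huzinaga_embed(H, 1:2)
  tr0 <- huzinaga_embed(H, 1:2, tau_ao = 0)
  expect_equal(length(tr0$diagnostics$retained_basis), H$n_basis)
  expect_equal(tr0$result$E_total, full$result$E_total, tolerance = 1e-12)
})

test_that("block fixtures truncate to exactly the active fragment", {
  H <- block_fragments()
  s <- scf_solve(H, LL)
  C_loc <- localize_orbitals(H, s$coefficients[, seq_len(s$n_occ),
                                               drop = FALSE])
  act <- select_active_mos(H, C_loc, 1:2)
  tr <- less_ao_truncate(H, C_loc, act, 1:2, tau_ao = 1e-4)
  expect_equal(tr$keep, 1:2)
  expect_error(less_ao_truncate(H, C_loc * 0, act, integer(0), 10),
               "empty retained set")
})

test_that("truncated relative energies converge to the untruncated ones", {
  devs4 <- c(); devs6 <- c()
  for (sd in 1:5) {
    H1 <- make_hamiltonian(hamiltonian_recipe(n_atoms = 6,
                                              coupling_decay = 0.1,
                                              seed = sd))
    H2 <- perturb_hamiltonian(H1, 0.05, 1:2)
    rel <- function(tau) {
      huzinaga_embed(H2, 1:2, tau_ao = tau)$result$E_total -
        huzinaga_embed(H1, 1:2, tau_ao = tau)$result$E_total
    }
    r_ref <- rel(NULL)
    devs4 <- c(devs4, abs(rel(1e-4) - r_ref))
    devs6 <- c(devs6, abs(rel(0) - r_ref))
  }
  expect_lt(max(devs4), 1e-3)
  expect_equal(max(devs6), 0)
})

test_that("the subtractive combination collapses for equal levels", {
  expect_equal(oniom_energy(-10, -4, -4), -10)
  for (sd in 1:5) {
    H <- make_hamiltonian(hamiltonian_recipe(n_atoms = 4, seed = sd))
    o <- oniom_embed(H, 1:2, hl_level = LL, ll_level = LL)
    expect_equal(o$energy, scf_solve(H, LL)$energy, tolerance = 1e-12)
    o_full <- oniom_embed(H, 1:4)
    expect_equal(o_full$energy, scf_solve(H, HL)$energy, tolerance = 1e-10)
  }
})

test_that("capped subsystems restrict the Hamiltonian and count electrons", {
  # non-interacting fragments: no severed coupling, pure restriction
  H <- block_fragments()
  Hc <- capped_subsystem(H, 1:2)
  expect_equal(attr(Hc, "n_caps"), 0L)
  expect_equal(Hc$n_basis, 2L)
  expect_equal(Hc$overlap, H$overlap[1:2, 1:2])
  # electron count equals twice the localization-assigned active MO count
  expect_equal(Hc$n_electrons, 2L * attr(Hc, "n_active_mos"))
  # a coupled chain gains cap functions for severed strong couplings
  H2 <- make_hamiltonian(hamiltonian_recipe(n_atoms = 4, seed = 3))
  Hc2 <- capped_subsystem(H2, 1:2, coupling_threshold = 0.01)
  expect_gt(attr(Hc2, "n_caps"), 0L)
  expect_equal(Hc2$n_basis,
               sum(H2$atom_of_basis %in% 1:2) + attr(Hc2, "n_caps"))
  # inert caps at zero strength still enter the basis
  Hc3 <- capped_subsystem(H2, 1:2, cap_strength = 0,
                          coupling_threshold = 0.01)
  expect_equal(attr(Hc3, "n_caps"), attr(Hc2, "n_caps"))
})

test_that("model Hamiltonians round-trip through JSON", {
  H <- make_hamiltonian(hamiltonian_recipe(n_atoms = 3, seed = 11))
  path <- tempfile(fileext = ".json")
  write_hamiltonian_json(H, path)
  back <- read_hamiltonian_json(path)
  expect_equal(back$overlap, H$overlap, tolerance = 1e-12)
  expect_equal(back$two_electron, H$two_electron, tolerance = 1e-12)
  expect_equal(back$n_electrons, H$n_electrons)
})
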