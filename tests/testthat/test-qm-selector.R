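# The selection pipeline is checked stage by stage against hand-traceable
# fixtures and, end to end, against the independent brute-force oracle in
# helper-oracle.R.

test_that("radial_core at radius 0 closes over bonded hydrogens", {
  sys <- water_system()
  spec <- selection_spec(core = 1, radius = 0, frames = "RS")
  expect_equal(radial_core(sys, spec), 0:2)
})

test_that("radial seeding takes the union over requested frames", {
  atoms <- atom_table(serial = 1:2, name = c("C1", "C2"), element = "C")
  g <- bond_graph(NULL, 2L)
  sys <- assemble_system(atoms, g, list(
    RS = rbind(c(0, 0, 0), c(3.5, 0, 0)),
    TS1 = rbind(c(0, 0, 0), c(2.5, 0, 0))))
  both <- radial_core(sys, selection_spec(1, 3.0, c("RS", "TS1")))
  rs_only <- radial_core(sys, selection_spec(1, 3.0, "RS"))
  expect_true(1L %in% both)
  expect_false(1L %in% rs_only)
})

test_that("radial_core matches the all-pairs distance oracle", {
  tp <- test_topology(seed = 11)
  core_serial <- tp$system$atoms$serial[tp$system$atoms$name == "MG"][1]
  spec <- selection_spec(core_serial, 4.0, c("RS", "TS1"))
  expect_equal(radial_core(tp$system, spec),
               oracle_radial(tp$system, resolve_atoms(tp$system, core_serial),
                             4.0, c("RS", "TS1")))
})

test_that("topological extension absorbs whole components without rules", {
  sys <- cx_chain(6)
  # empty rule table: everything absorbed, no events
  r <- topological_extension(sys, 2L, cut_rules("ZZ", "ZZ"))
  expect_equal(r$atoms, 0:5)
  expect_equal(nrow(r$cut_events), 0L)
  # seed = whole component is already closed
  r2 <- topological_extension(sys, 0:5, cx_rules())
  expect_equal(r2$atoms, 0:5)
  expect_equal(nrow(r2$cut_events), 0L)
})

test_that("extension halts at cutable bonds and records the events", {
  sys <- cx_chain(6)
  r <- topological_extension(sys, 2L, cx_rules())
  expect_equal(r$atoms, 2L)
  expect_equal(r$cut_events$mm_atom, c(1L, 3L))
})

test_that("ring bonds are never cut", {
  # 4-ring plus a tail: ring bonds are not cutable even though the name
  # pair matches, so the ring is absorbed; the tail bond is cut
  sys <- cx_chain(5, bonds_extra = rbind(c(0L, 3L)))  # 0-1-2-3-0 ring, 3-4 tail
  r <- topological_extension(sys, 0L, cx_rules())
  expect_equal(r$atoms, 0:3)
  expect_equal(r$cut_events$qm_atom, 3L)
  expect_equal(r$cut_events$mm_atom, 4L)
})

test_that("shared-MM-atom cut events are merged by absorption", {
  # A1=0, A2=1 both bonded to X=2; X bonded to a tail atom 3
  atoms <- atom_table(serial = 1:4, name = rep("CX", 4), element = "C")
  g <- bond_graph(rbind(c(0L, 2L), c(1L, 2L), c(2L, 3L)), 4L)
  sys <- assemble_system(atoms, g, list(RS = cbind(1:4, 0, 0)))
  r <- topological_extension(sys, c(0L, 1L), cx_rules())
  expect_equal(sort(r$cut_events$mm_atom), c(2L, 2L))
  m <- merge_shared_mm_links(sys, r, cx_rules())
  expect_true(2L %in% m$atoms)
  expect_equal(m$cut_events$mm_atom, 3L)
  expect_equal(anyDuplicated(m$cut_events$mm_atom), 0L)
})

test_that("merging iterates when absorption exposes a new shared MM atom", {
  sys <- cx_two_pass()
  r <- topological_extension(sys, c(0L, 1L, 4L), cx_rules())
  m <- merge_shared_mm_links(sys, r, cx_rules())
  expect_equal(m$atoms, 0:4)
  expect_equal(nrow(m$cut_events), 0L)
  expect_equal(m$merged, c(2L, 3L))
})

test_that("merging leaves all-distinct MM atoms unchanged", {
  sys <- cx_chain(5)
  r <- topological_extension(sys, 2L, cx_rules())
  m <- merge_shared_mm_links(sys, r, cx_rules())
  expect_equal(m$atoms, r$atoms)
  expect_equal(m$cut_events, r$cut_events)
})

test_that("detached aliphatic islands are pruned by carbon count", {
  el_island <- function(names, elements) {
    n <- 3L + length(names)
    atoms <- atom_table(serial = seq_len(n),
                        name = c(rep("CX", 3), names),
                        element = c(rep("C", 3), elements))
    # core chain 0-1-2; island atoms bonded among themselves only
    edges <- rbind(c(0L, 1L), c(1L, 2L))
    if (length(names) > 1) {
      edges <- rbind(edges, cbind(3L:(n - 2L), 4L:(n - 1L)))
    }
    sys <- assemble_system(atoms, bond_graph(edges, n),
                           list(RS = cbind(seq_len(n), 0, 0)))
    region <- list(atoms = 0:(n - 1L),
                   cut_events = data.frame(qm_atom = integer(0),
                                           mm_atom = integer(0),
                                           rule = character(0)))
    prune_small_fragments(sys, region, core_atoms = 0L)
  }
  # ethyl-like island (2 C + H's): pruned
  pruned <- el_island(c("C1", "C2", "H1", "H2"), c("C", "C", "H", "H"))
  expect_equal(pruned$atoms, 0:2)
  # propyl (3 C): retained
  kept <- el_island(c("C1", "C2", "C3"), c("C", "C", "C"))
  expect_length(kept$atoms, 6L)
  # island containing an oxygen: retained (not aliphatic)
  oxy <- el_island(c("C1", "O1"), c("C", "O"))
  expect_length(oxy$atoms, 5L)
})

test_that("pruning the core component itself is an error", {
  atoms <- atom_table(serial = 1:2, name = c("C1", "C2"), element = "C")
  sys <- assemble_system(atoms, bond_graph(rbind(c(0L, 1L)), 2L),
                         list(RS = cbind(1:2, 0, 0)))
  region <- list(atoms = 0:1, cut_events = data.frame(
    qm_atom = integer(0), mm_atom = integer(0), rule = character(0)))
  expect_error(prune_small_fragments(sys, region, core_atoms = 0L),
               "core component")
})

test_that("link atoms sit on the cut bond at the fixed distance", {
  atoms <- atom_table(serial = 1:2, name = c("C1", "C2"), element = "C")
  sys <- assemble_system(atoms, bond_graph(rbind(c(0L, 1L)), 2L),
                         list(RS = rbind(c(0, 0, 0), c(2, 0, 0)),
                              TS1 = rbind(c(1, 1, 1), c(1, 1, 3))))
  region <- list(cut_events = data.frame(qm_atom = 0L, mm_atom = 1L,
                                         rule = "x"))
  l1 <- place_link_atoms(sys, region, "RS")
  expect_equal(unlist(l1[1, c("x", "y", "z")], use.names = FALSE),
               c(1.09, 0, 0))
  l2 <- place_link_atoms(sys, region, "TS1")
  expect_equal(unlist(l2[1, c("x", "y", "z")], use.names = FALSE),
               c(1, 1, 2.09))
  # coincident coordinates error
  sys2 <- assemble_system(atoms, bond_graph(rbind(c(0L, 1L)), 2L),
                          list(RS = rbind(c(0, 0, 0), c(0, 0, 0))))
  expect_error(place_link_atoms(sys2, region, "RS"), "coincident")
})

test_that("formal charge sums templates, with charge-center tie-breaking", {
  # ASP sidechain group + LYS sidechain group fully selected: charges cancel
  tp <- test_topology(seed = 1, n_residues = 10, charged_fraction = 0.4)
  sys <- tp$system
  a <- sys$atoms
  asp_res <- unique(a$resid[a$resname == "ASP"])
  lys_res <- unique(a$resid[a$resname == "LYS"])
  stopifnot(length(asp_res) > 0, length(lys_res) > 0)
  sel <- a$index[(a$resid == asp_res[1] | a$resid == lys_res[1]) &
                   a$segid == "PROT"]
  expect_equal(region_formal_charge(sys, sel), 0L)

  # partial ASP with the carboxylate carbon inside counts, with a warning
  asp_rows <- a[a$resid == asp_res[1] & a$segid == "PROT", ]
  partial <- asp_rows$index[asp_rows$name %in% c("CG", "OD1")]
  expect_warning(fc <- region_formal_charge(sys, partial), "partially")
  expect_equal(fc, -1L)
  # partial ASP without the charge center does not count
  partial2 <- asp_rows$index[asp_rows$name %in% c("OD1", "OD2")]
  expect_warning(fc2 <- region_formal_charge(sys, partial2), "partially")
  expect_equal(fc2, 0L)
})

test_that("metal-ion and nucleotide templates combine additively", {
  atoms <- atom_table(
    serial = 1:4,
    name = c("MG", "PG", "O1G", "O2G"),
    element = c("Mg", "P", "O", "O"),
    resname = c("MG", "GTP", "GTP", "GTP"),
    resid = c(1L, 2L, 2L, 2L))
  sys <- assemble_system(atoms, bond_graph(rbind(c(1L, 2L), c(1L, 3L)), 4L),
                         list(RS = cbind(1:4, 0, 0)))
  # GTP template group includes PA/PB atoms not present here; the present
  # group atoms (PG, O1G, O2G) are all selected -> counts
  expect_equal(region_formal_charge(sys, 0:3), -2L)
})

test_that("select_region equals the composed brute-force oracle", {
  for (seed in c(3, 11, 27)) {
    tp <- test_topology(seed = seed)
    sys <- tp$system
    core_serial <- sys$atoms$serial[sys$atoms$name == "MG"][1]
    spec <- selection_spec(core_serial, 3.5, c("RS", "TS1"))
    reg <- suppressWarnings(select_region(sys, spec))
    want <- oracle_select(sys, resolve_atoms(sys, core_serial), 3.5,
                          c("RS", "TS1"), spec$cut_rules)
    expect_equal(reg$atom_indices, want)
  }
})

test_that("regions grow monotonically with radius and frame set", {
  tp <- test_topology(seed = 5)
  sys <- tp$system
  core_serial <- sys$atoms$serial[sys$atoms$name == "MG"][1]
  r3 <- suppressWarnings(select_region(sys, selection_spec(core_serial, 3, "RS")))
  r5 <- suppressWarnings(select_region(sys, selection_spec(core_serial, 5, "RS")))
  expect_true(all(r3$atom_indices %in% r5$atom_indices))
  multi <- suppressWarnings(select_region(
    sys, selection_spec(core_serial, 3, c("RS", "TS1", "INT", "TS2", "PS"))))
  expect_true(all(r3$atom_indices %in% multi$atom_indices))
})

test_that("nested series are non-decreasing and bounded by the component", {
  tp <- test_topology(seed = 5)
  sys <- tp$system
  core_serial <- sys$atoms$serial[sys$atoms$name == "MG"][1]
  spec <- selection_spec(core_serial, 3, "RS")
  series <- suppressWarnings(nested_series(sys, spec, c(3, 5, 7)))
  sizes <- vapply(series, function(r) length(r$atom_indices), 1L)
  expect_true(all(diff(sizes) >= 0))
  single <- suppressWarnings(nested_series(sys, spec, 5))
  expect_equal(single[[1]]$atom_indices,
               suppressWarnings(select_region(
                 sys, selection_spec(core_serial, 5, "RS")))$atom_indices)
  expect_error(nested_series(sys, spec, c(5, 3)), "strictly increasing")
  # a huge radius returns every atom of the system
  big <- suppressWarnings(nested_series(sys, spec, c(0, 1e6)))
  expect_equal(big[[2]]$atom_indices, sys$atoms$index)
})

test_that("exclusion variants recompute cuts, merges, and pruning", {
  tp <- test_topology(seed = 13)
  sys <- tp$system
  core_serial <- sys$atoms$serial[sys$atoms$name == "MG"][1]
  reg <- suppressWarnings(select_region(sys, selection_spec(core_serial, 5,
                                                            "RS")))
  # excluding nothing is the identity
  expect_equal(exclusion_variant(sys, reg, integer(0))$atom_indices,
               reg$atom_indices)
  # excluding a selected whole water shrinks by exactly that water
  a <- sys$atoms
  wat_res <- unique(a$resid[a$resname == "HOH" &
                              a$index %in% reg$atom_indices])
  wat_res <- Filter(function(rr)
    all(a$index[a$resid == rr & a$segid == "WAT"] %in% reg$atom_indices),
    wat_res)
  stopifnot(length(wat_res) > 0)
  wat <- a$index[a$resid == wat_res[1] & a$segid == "WAT"]
  ex <- suppressWarnings(exclusion_variant(sys, reg, wat))
  expect_equal(ex$atom_indices, setdiff(reg$atom_indices, wat))
  expect_equal(ex$cut_events, reg$cut_events)
  # excluding a core atom errors
  expect_error(exclusion_variant(sys, reg, reg$core_indices[1]),
               "core atom")
})

test_that("excluding a bonded moiety creates a forced boundary cut", {
  sys <- cx_chain(5)
  spec <- selection_spec(1, 1e3, "RS", cut_rules = cut_rules("ZZ", "ZZ"))
  reg <- select_region(sys, spec)
  expect_equal(reg$atom_indices, 0:4)
  ex <- exclusion_variant(sys, reg, 4L)
  expect_equal(ex$atom_indices, 0:3)
  expect_equal(ex$cut_events$mm_atom, 4L)
})

test_that("identical inputs give byte-identical provenance", {
  tp1 <- test_topology(seed = 9)
  tp2 <- test_topology(seed = 9)
  core <- tp1$system$atoms$serial[tp1$system$atoms$name == "MG"][1]
  r1 <- suppressWarnings(select_region(tp1$system,
                                       selection_spec(core, 4, "RS")))
  r2 <- suppressWarnings(select_region(tp2$system,
                                       selection_spec(core, 4, "RS")))
  expect_identical(r1$provenance, r2$provenance)
  expect_identical(r1$atom_indices, r2$atom_indices)
})

test_that("selection reports are written with serials, links, and charge", {
  tp <- test_topology(seed = 3)
  sys <- tp$system
  core <- sys$atoms$serial[sys$atoms$name == "MG"][1]
  reg <- suppressWarnings(select_region(sys, selection_spec(core, 4, "RS")))
  prefix <- tempfile()
  paths <- write_region_report(sys, reg, prefix)
  serials <- as.integer(readLines(paste0(prefix, "_atoms.txt")))
  expect_equal(serials, index_to_serial(sys, reg$atom_indices))
  rep <- jsonlite::fromJSON(paste0(prefix, "_report.json"))
  expect_equal(rep$n_atoms, length(reg$atom_indices))
  expect_equal(rep$formal_charge, reg$formal_charge)
})
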