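# Topologically extended distance-based QM-region selection.
#
# Pipeline: radial seeding around declared core atoms (union over requested
# frames, hydrogens completed afterwards) -> iterative extension along
# covalent bonds until every boundary bond is cutable -> merging of cut
# events that share an MM-side atom (absorbing the shared atom shrinks the
# number of link atoms) -> pruning of small aliphatic fragments detached
# from the core -> formal-charge accounting from residue templates.
# Every stage appends to a provenance log; the whole pipeline is
# deterministic for fixed inputs (ties broken by ascending internal index).

#' Specify a QM-region selection
#'
#' @param core core atoms: a numeric vector of 1-based file serials, or a
#'   character vector of `"SEGID:RESID:NAME"` identifiers. The core focuses
#'   the selection on where the reaction happens and can be a single atom.
#' @param radius seeding radius in angstrom (heavy-atom distances).
#' @param frames character vector of frame labels to consider; atoms within
#'   the radius in *any* requested frame are seeded (union semantics, suited
#'   to geometry changes along a preliminary reaction path).
#' @param cut_rules a [cut_rules()] table; default [default_cut_rules()].
#' @param prune_max_carbons detached aliphatic fragments with up to this
#'   many carbons are dropped from the selection (default 2).
#' @param merge_shared_mm whether to absorb MM atoms shared by two cut
#'   events (default `TRUE`).
#' @param d_link link-atom (hydrogen) placement distance in angstrom along
#'   the cut bond, default 1.09 (a standard C-H bond length).
#' @return An object of class `selection_spec`.
#' @export
selection_spec <- function(core, radius, frames,
                           cut_rules = default_cut_rules(),
                           prune_max_carbons = 2L,
                           merge_shared_mm = TRUE,
                           d_link = 1.09) {
  abort_if(length(core) == 0L, "selection_spec(): core_atoms must be non-empty")
  abort_if(!is.numeric(radius) || radius < 0,
           "selection_spec(): radius must be >= 0")
  abort_if(length(frames) == 0L, "selection_spec(): frames must be non-empty")
  structure(list(core = core, radius = radius, frames = as.character(frames),
                 cut_rules = cut_rules,
                 prune_max_carbons = as.integer(prune_max_carbons),
                 merge_shared_mm = isTRUE(merge_shared_mm),
                 d_link = d_link),
            class = "selection_spec")
}

#' Resolve core-atom identifiers to internal indices
#'
#' @param system a `molecular_system`.
#' @param core numeric serials or `"SEGID:RESID:NAME"` strings.
#' @return Sorted integer vector of 0-based internal indices.
#' @export
resolve_atoms <- function(system, core) {
  a <- system$atoms
  idx <- if (is.numeric(core)) {
    m <- match(as.integer(core), a$serial)
    abort_if(anyNA(m), "resolve_atoms(): unknown serial %d",
             as.integer(core)[is.na(m)][1])
    a$index[m]
  } else {
    vapply(as.character(core), function(s) {
      p <- strsplit(s, ":", fixed = TRUE)[[1]]
      abort_if(length(p) != 3L,
               "resolve_atoms(): expected 'SEGID:RESID:NAME', got '%s'", s)
      hit <- which(a$segid == p[1] & a$resid == as.integer(p[2]) &
                     a$name == p[3])
      abort_if(length(hit) == 0L, "resolve_atoms(): no atom matches '%s'", s)
      abort_if(length(hit) > 1L, "resolve_atoms(): '%s' is ambiguous", s)
      a$index[hit]
    }, integer(1), USE.NAMES = FALSE)
  }
  sort(unique(idx))
}

#' Radial core seeding
#'
#' Selects every heavy atom within `spec$radius` of any core atom in any of
#' the requested frames (union over frames), then completes hydrogens: every
#' hydrogen bonded to a selected heavy atom is added and, symmetrically, the
#' heavy atom bonded to any selected hydrogen. Hydrogens never seed through
#' the distance criterion itself.
#'
#' @param system a `molecular_system`.
#' @param spec a `selection_spec`.
#' @return Sorted integer vector of 0-based indices.
#' @export
radial_core <- function(system, spec) {
  core <- resolve_atoms(system, spec$core)
  missing_frames <- setdiff(spec$frames, names(system$frames))
  abort_if(length(missing_frames) > 0L, "radial_core(): no frame '%s'",
           missing_frames[1])
  heavy <- which(!system$atoms$is_hydrogen) - 1L
  sel <- core
  for (fl in spec$frames) {
    xyz <- system$frames[[fl]]
    cx <- xyz[core + 1L, , drop = FALSE]
    for (h in heavy) {
      d2 <- min(colSums((t(cx) - xyz[h + 1L, ])^2))
      if (d2 <= spec$radius^2) sel <- c(sel, h)
    }
  }
  sel <- sort(unique(sel))
  .complete_hydrogens(system, sel)
}

# Fixpoint of the hydrogen-completion rules.
.complete_hydrogens <- function(system, sel) {
  is_h <- system$atoms$is_hydrogen
  repeat {
    added <- integer(0)
    for (i in sel) {
      nb <- neighbors_of(system$bonds, i)
      if (is_h[i + 1L]) {
        added <- c(added, nb[!is_h[nb + 1L] & !(nb %in% sel)])
      } else {
        added <- c(added, nb[is_h[nb + 1L] & !(nb %in% sel)])
      }
    }
    if (length(added) == 0L) return(sel)
    sel <- sort(unique(c(sel, added)))
  }
}

#' Iterative topological extension with cut rules
#'
#' Grows a seed set along covalent bonds: a boundary bond (inside, outside)
#' is crossed unless it matches a cut rule. Growth continues until no
#' non-cutable boundary bond remains; the surviving cutable boundary bonds
#' become the cut events.
#'
#' @param system a `molecular_system`.
#' @param seed_set integer vector of 0-based seed indices (non-empty).
#' @param rules a `cut_rules` table.
#' @param forbidden optional set of indices the extension must never enter;
#'   boundary bonds into it are always recorded as cut events (used by
#'   [exclusion_variant()]).
#' @return A list with `atoms` (sorted indices) and `cut_events`
#'   (`data.frame` with columns `qm_atom`, `mm_atom`, `rule`).
#' @export
topological_extension <- function(system, seed_set, rules,
                                  forbidden = integer(0)) {
  abort_if(length(seed_set) == 0L, "topological_extension(): empty seed set")
  ctx <- cutability_context(system)
  inside <- rep(FALSE, n_atoms(system))
  inside[seed_set + 1L] <- TRUE
  frontier <- sort(unique(seed_set))
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (i in frontier) {
      for (j in neighbors_of(system$bonds, i)) {
        if (inside[j + 1L] || j %in% forbidden) next
        if (is.na(match_cut_rule(system, i, j, rules, ctx))) {
          inside[j + 1L] <- TRUE
          nxt <- c(nxt, j)
        }
      }
    }
    frontier <- sort(unique(nxt))
  }
  atoms <- which(inside) - 1L
  list(atoms = atoms,
       cut_events = .boundary_events(system, atoms, rules, ctx, forbidden))
}

# All boundary bonds of a closed region, with their matched rules. After
# closure every boundary bond either matches a rule or leads into the
# forbidden set (a forced exclusion cut).
.boundary_events <- function(system, atoms, rules, ctx, forbidden = integer(0)) {
  inside <- rep(FALSE, n_atoms(system))
  inside[atoms + 1L] <- TRUE
  qm <- integer(0); mm <- integer(0); rule <- character(0)
  for (i in atoms) {
    for (j in neighbors_of(system$bonds, i)) {
      if (inside[j + 1L]) next
      r <- match_cut_rule(system, i, j, rules, ctx)
      if (is.na(r)) {
        abort_if(!(j %in% forbidden),
                 "internal error: non-cutable boundary bond %d-%d survived closure",
                 i, j)
        r <- "excluded-moiety"
      }
      qm <- c(qm, i); mm <- c(mm, j); rule <- c(rule, r)
    }
  }
  ev <- data.frame(qm_atom = qm, mm_atom = mm, rule = rule,
                   stringsAsFactors = FALSE)
  ev[order(ev$qm_atom, ev$mm_atom), , drop = FALSE]
}

#' Merge cut events sharing an MM-side atom
#'
#' If two cutting events have the same MM-side atom, placing two link atoms
#' on top of each other would be unphysical; the shared atom is absorbed
#' into the region instead and the extension re-runs, decreasing the number
#' of cut bonds. Iterates until no MM atom appears in two events.
#'
#' @param system a `molecular_system`.
#' @param region a list with `atoms` and `cut_events` (as returned by
#'   [topological_extension()]).
#' @param rules a `cut_rules` table.
#' @param forbidden indices that may never be absorbed.
#' @return Updated region list, plus a `merged` integer vector of absorbed
#'   atoms.
#' @export
merge_shared_mm_links <- function(system, region, rules,
                                  forbidden = integer(0)) {
  merged <- integer(0)
  repeat {
    mm <- region$cut_events$mm_atom
    shared <- sort(unique(mm[duplicated(mm)]))
    shared <- setdiff(shared, forbidden)
    if (length(shared) == 0L) break
    absorb <- shared[1]
    merged <- c(merged, absorb)
    region <- topological_extension(system, c(region$atoms, absorb), rules,
                                    forbidden = forbidden)
  }
  region$merged <- merged
  region
}

#' Prune detached small aliphatic fragments
#'
#' Connected components of the selection's induced subgraph that (a) do not
#' contain any core atom, (b) consist solely of carbon atoms plus their
#' hydrogens, and (c) have at most `max_carbons` carbons, are removed
#' together with their cut events. Pruning runs before link-atom placement,
#' so generated link hydrogens are never counted.
#'
#' @param system a `molecular_system`.
#' @param region region list with `atoms` and `cut_events`.
#' @param core_atoms 0-based indices of the selection's core atoms.
#' @param max_carbons prune threshold (default 2).
#' @return Updated region list with a `pruned` field listing removed atoms.
#' @export
prune_small_fragments <- function(system, region, core_atoms,
                                  max_carbons = 2L) {
  comp <- .induced_components(system, region$atoms)
  el <- system$atoms$element
  core_comps <- unique(comp[match(core_atoms, region$atoms)])
  core_comps <- core_comps[!is.na(core_comps)]
  drop <- integer(0)
  for (cid in unique(comp)) {
    members <- region$atoms[comp == cid]
    heavies <- members[el[members + 1L] != "H"]
    aliphatic <- length(heavies) > 0L && all(el[heavies + 1L] == "C") &&
      length(heavies) <= max_carbons
    if (!aliphatic) next
    abort_if(cid %in% core_comps,
             paste0("prune_small_fragments(): the core component itself is a ",
                    "<=%d-carbon aliphatic fragment; degenerate selection"),
             max_carbons)
    drop <- c(drop, members)
  }
  if (length(drop)) {
    region$atoms <- setdiff(region$atoms, drop)
    keep <- !(region$cut_events$qm_atom %in% drop)
    region$cut_events <- region$cut_events[keep, , drop = FALSE]
  }
  region$pruned <- sort(drop)
  region
}

# Component ids over the induced subgraph of `atoms` (parallel to `atoms`).
.induced_components <- function(system, atoms) {
  pos <- integer(n_atoms(system)); pos[atoms + 1L] <- seq_along(atoms)
  comp <- integer(length(atoms))
  cid <- 0L
  for (s in seq_along(atoms)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    stack <- s
    while (length(stack)) {
      k <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[k] != 0L) next
      comp[k] <- cid
      nb <- pos[neighbors_of(system$bonds, atoms[k]) + 1L]
      nb <- nb[nb != 0L]
      stack <- c(stack, nb[comp[nb] == 0L])
    }
  }
  comp
}

#' Place hydrogen link atoms for a frame
#'
#' For each cut event, a hydrogen is placed on the segment from the QM atom
#' toward the MM atom at a fixed distance (`d_link`).
#'
#' @param system a `molecular_system`.
#' @param region a `qm_region` (or any list with a `cut_events` field).
#' @param frame_label which frame's coordinates to use.
#' @param d_link placement distance in angstrom (default 1.09).
#' @return A `data.frame` with columns `qm_atom`, `mm_atom`, `x`, `y`, `z`.
#' @export
place_link_atoms <- function(system, region, frame_label, d_link = 1.09) {
  abort_if(!frame_label %in% names(system$frames),
           "place_link_atoms(): no frame '%s'", frame_label)
  xyz <- system$frames[[frame_label]]
  ev <- region$cut_events
  out <- matrix(NA_real_, nrow(ev), 3)
  for (k in seq_len(nrow(ev))) {
    q <- xyz[ev$qm_atom[k] + 1L, ]
    m <- xyz[ev$mm_atom[k] + 1L, ]
    v <- m - q
    nv <- sqrt(sum(v^2))
    abort_if(nv < 1e-8,
             "place_link_atoms(): coincident QM/MM coordinates for bond %d-%d",
             ev$qm_atom[k], ev$mm_atom[k])
    out[k, ] <- q + d_link * v / nv
  }
  data.frame(qm_atom = ev$qm_atom, mm_atom = ev$mm_atom,
             x = out[, 1], y = out[, 2], z = out[, 3])
}

#' Formal charge of a selection from residue templates
#'
#' Sums the template charges of charged groups wholly inside the region. A
#' partially selected charged group raises a warning and counts only if its
#' designated charge-center atom is selected. Per-residue overrides (keyed
#' `"SEGID:RESID"`) take precedence over the residue-name templates.
#'
#' @param system a `molecular_system`.
#' @param atom_indices 0-based indices of the selection.
#' @return Integer total formal charge.
#' @export
region_formal_charge <- function(system, atom_indices) {
  a <- system$atoms
  total <- 0L
  sel <- rep(FALSE, n_atoms(system)); sel[atom_indices + 1L] <- TRUE
  res_keys <- unique(paste(a$segid, a$resid, sep = ":"))
  for (key in res_keys) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    rows <- which(a$segid == parts[1] & a$resid == as.integer(parts[2]))
    resname <- a$resname[rows[1]]
    tpl <- system$charge_overrides[[key]] %||%
      system$charge_templates[[resname]]
    if (is.null(tpl)) next
    group_names <- tpl$group_atoms %||% character(0)
    grows <- if (length(group_names)) rows[a$name[rows] %in% group_names]
             else rows
    if (length(grows) == 0L) next
    inside <- sel[grows]
    if (all(inside)) {
      total <- total + as.integer(tpl$charge)
    } else if (any(inside)) {
      center_row <- rows[a$name[rows] == (tpl$center %||% a$name[grows[1]])]
      counts <- length(center_row) > 0L && any(sel[center_row])
      warning(sprintf(
        "charged group %s (%s) only partially selected; %s",
        key, resname,
        if (counts) "counted (charge center inside)" else
          "not counted (charge center outside)"), call. = FALSE)
      if (counts) total <- total + as.integer(tpl$charge)
    }
  }
  total
}

#' Select a QM region
#'
#' Runs the full pipeline: [radial_core()] seeding, [topological_extension()],
#' [merge_shared_mm_links()], [prune_small_fragments()], and
#' [region_formal_charge()], keeping an ordered provenance log.
#'
#' @param system a `molecular_system`.
#' @param spec a [selection_spec()].
#' @return An object of class `qm_region` with fields `atom_indices`
#'   (sorted 0-based), `cut_events`, `formal_charge`, `core_indices`,
#'   `provenance`, and `spec`.
#' @export
select_region <- function(system, spec) {
  stopifnot(inherits(spec, "selection_spec"))
  core <- resolve_atoms(system, spec$core)
  log <- character(0)
  seed <- radial_core(system, spec)
  log <- c(log, sprintf("radial_core: radius %.3f A over frames [%s] -> %d atoms",
                        spec$radius, paste(spec$frames, collapse = ","),
                        length(seed)))
  region <- topological_extension(system, seed, spec$cut_rules)
  log <- c(log, sprintf("topological_extension: -> %d atoms, %d cut events",
                        length(region$atoms), nrow(region$cut_events)))
  if (spec$merge_shared_mm) {
    region <- merge_shared_mm_links(system, region, spec$cut_rules)
    log <- c(log, sprintf("merge_shared_mm_links: absorbed [%s] -> %d atoms, %d cut events",
                          paste(region$merged, collapse = ","),
                          length(region$atoms), nrow(region$cut_events)))
  }
  region <- prune_small_fragments(system, region, core,
                                  spec$prune_max_carbons)
  log <- c(log, sprintf("prune_small_fragments: removed [%s] -> %d atoms",
                        paste(region$pruned, collapse = ","),
                        length(region$atoms)))
  fc <- region_formal_charge(system, region$atoms)
  log <- c(log, sprintf("formal_charge: %+d", fc))
  structure(list(atom_indices = sort(region$atoms),
                 cut_events = region$cut_events,
                 formal_charge = fc,
                 core_indices = core,
                 provenance = log,
                 spec = spec),
            class = "qm_region")
}

#' @export
print.qm_region <- function(x, ...) {
  cat(sprintf("qm_region: %d atoms, %d cut events, formal charge %+d\n",
              length(x$atom_indices), nrow(x$cut_events), x$formal_charge))
  invisible(x)
}

#' Nested series of QM regions over increasing radii
#'
#' One region per radius with otherwise identical settings; used for QM-size
#' convergence studies of reaction profiles.
#'
#' @param system a `molecular_system`.
#' @param spec a `selection_spec` (its radius field is overridden).
#' @param radii strictly increasing numeric radii (angstrom).
#' @return List of `qm_region` objects (sizes non-decreasing).
#' @export
nested_series <- function(system, spec, radii) {
  abort_if(length(radii) == 0L || any(diff(radii) <= 0),
           "nested_series(): radii must be strictly increasing")
  lapply(radii, function(r) {
    s <- spec; s$radius <- r
    select_region(system, s)
  })
}

#' Exclusion variant of a region
#'
#' Removes a moiety from an existing selection and re-finalizes the region:
#' boundary cut events are recomputed (bonds into the excluded moiety are
#' cut regardless of the rule table), shared-MM-link merging re-runs, and
#' fragments are re-pruned. Used for residue exclusion scans that probe
#' which edge moieties the relative energies are sensitive to.
#'
#' @param system a `molecular_system`.
#' @param region a `qm_region`.
#' @param moiety_atoms 0-based indices to exclude; must be inside the
#'   region and must not contain a core atom.
#' @return A new `qm_region`.
#' @export
exclusion_variant <- function(system, region, moiety_atoms) {
  moiety_atoms <- sort(unique(as.integer(moiety_atoms)))
  if (length(moiety_atoms) == 0L) return(region)
  abort_if(!all(moiety_atoms %in% region$atom_indices),
           "exclusion_variant(): moiety atom %d is not in the region",
           setdiff(moiety_atoms, region$atom_indices)[1])
  abort_if(any(moiety_atoms %in% region$core_indices),
           "exclusion_variant(): moiety contains core atom %d",
           intersect(moiety_atoms, region$core_indices)[1])
  spec <- region$spec
  seed <- setdiff(region$atom_indices, moiety_atoms)
  r <- topological_extension(system, seed, spec$cut_rules,
                             forbidden = moiety_atoms)
  if (spec$merge_shared_mm) {
    r <- merge_shared_mm_links(system, r, spec$cut_rules,
                               forbidden = moiety_atoms)
  }
  r <- prune_small_fragments(system, r, region$core_indices,
                             spec$prune_max_carbons)
  fc <- region_formal_charge(system, r$atoms)
  structure(list(atom_indices = sort(r$atoms),
                 cut_events = r$cut_events,
                 formal_charge = fc,
                 core_indices = region$core_indices,
                 provenance = c(region$provenance,
                                sprintf("exclusion_variant: removed [%s] -> %d atoms",
                                        paste(moiety_atoms, collapse = ","),
                                        length(r$atoms))),
                 spec = spec),
            class = "qm_region")
}

#' Write a selection report
#'
#' Writes the QM atom list as 1-based serials (plain text, one per line), a
#' link-atom PDB per frame, and a JSON report with counts, cut events,
#' formal charge and the provenance log.
#'
#' @param system a `molecular_system`.
#' @param region a `qm_region`.
#' @param prefix output path prefix.
#' @return Invisibly, the written file paths.
#' @export
write_region_report <- function(system, region, prefix) {
  paths <- character(0)
  list_path <- paste0(prefix, "_atoms.txt")
  writeLines(as.character(index_to_serial(system, region$atom_indices)),
             list_path)
  paths <- c(paths, list_path)
  for (fl in region$spec$frames) {
    links <- place_link_atoms(system, region, fl, region$spec$d_link)
    p <- paste0(prefix, "_links_", fl, ".pdb")
    if (nrow(links)) {
      # a link-only PDB: write just the placed hydrogens
      bio3d::write.pdb(file = p, xyz = as.numeric(t(as.matrix(
        links[, c("x", "y", "z")]))),
        eleno = seq_len(nrow(links)), elety = rep("HL", nrow(links)),
        resid = rep("LNK", nrow(links)), resno = seq_len(nrow(links)),
        elesy = rep("H", nrow(links)))
    } else {
      writeLines("END", p)
    }
    paths <- c(paths, p)
  }
  report <- list(
    n_atoms = length(region$atom_indices),
    serials = index_to_serial(system, region$atom_indices),
    n_cut_events = nrow(region$cut_events),
    cut_events = lapply(seq_len(nrow(region$cut_events)), function(k) list(
      qm_serial = index_to_serial(system, region$cut_events$qm_atom[k]),
      mm_serial = index_to_serial(system, region$cut_events$mm_atom[k]),
      rule = region$cut_events$rule[k])),
    formal_charge = region$formal_charge,
    provenance = region$provenance)
  jp <- paste0(prefix, "_report.json")
  jsonlite::write_json(report, jp, auto_unbox = TRUE, digits = 8)
  invisible(c(paths, jp))
}
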