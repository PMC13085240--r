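# Core data model: atoms, bond graph, coordinate frames, assembled system.
#
# Internal atom indexing is 0-based and contiguous; all file I/O speaks the
# source file's 1-based serials. Conversion happens only in the explicit
# helpers serial_to_index() / index_to_serial().

#' Build an atom table
#'
#' Canonical per-atom record used throughout the package. `index` is the
#' contiguous 0-based internal index; `serial` is the (unique) 1-based serial
#' from the source file.
#'
#' @param serial integer vector of file serials.
#' @param name atom names (e.g. `"CA"`, `"OD1"`).
#' @param element element symbols; if `NA`, inferred from the atom name via
#'   [guess_element()].
#' @param resname residue names.
#' @param resid integer residue identifiers.
#' @param segid segment identifiers (default `"MAIN"`).
#' @param charge optional partial charges (elementary charge units).
#' @return A `data.frame` with columns `index`, `serial`, `name`, `element`,
#'   `resname`, `resid`, `segid`, `charge`, `is_hydrogen`.
#' @export
atom_table <- function(serial, name, element = NA_character_,
                       resname = "UNK", resid = 1L, segid = "MAIN",
                       charge = NA_real_) {
  n <- length(serial)
  serial <- as.integer(serial)
  abort_if(anyDuplicated(serial) > 0L,
           "atom_table(): duplicate serial %d",
           serial[duplicated(serial)][1])
  name <- as.character(name)
  element <- rep_len(as.character(element), n)
  missing_el <- is.na(element) | !nzchar(element)
  if (any(missing_el)) element[missing_el] <- guess_element(name[missing_el])
  atoms <- data.frame(
    index = seq_len(n) - 1L,
    serial = serial,
    name = name,
    element = element,
    resname = rep_len(as.character(resname), n),
    resid = rep_len(as.integer(resid), n),
    segid = rep_len(as.character(segid), n),
    charge = rep_len(as.numeric(charge), n),
    is_hydrogen = element == "H",
    stringsAsFactors = FALSE
  )
  atoms
}

# Element-from-name heuristic used when no element column is available
# (PSF topologies carry atom types, not elements). Two-letter elements are
# recognized before the single-letter fallback on the first alphabetic
# character.
.element_prefixes <- c(
  "CL" = "Cl", "BR" = "Br", "MG" = "Mg", "ZN" = "Zn", "FE" = "Fe",
  "NA" = "Na", "CA2" = "Ca", "MN" = "Mn", "CU" = "Cu", "K" = "K"
)

#' Infer an element symbol from an atom name
#'
#' Strips leading digits, checks a table of common two-letter elements
#' (Cl, Br, Mg, Zn, Fe, Na, Mn, Cu), then falls back to the first letter.
#' Note `"CA"` is taken as a protein alpha-carbon, not calcium; calcium ions
#' must carry an explicit element.
#'
#' @param name character vector of atom names.
#' @return Character vector of element symbols.
#' @export
guess_element <- function(name) {
  vapply(name, function(nm) {
    up <- toupper(gsub("^[0-9']+", "", nm))
    for (pref in names(.element_prefixes)) {
      if (up == pref) return(.element_prefixes[[pref]])
    }
    first <- substr(gsub("[^A-Z]", "", up), 1, 1)
    abort_if(!nzchar(first), "cannot infer element from atom name '%s'", nm)
    first
  }, character(1), USE.NAMES = FALSE)
}

#' Build an undirected bond graph
#'
#' @param edges two-column integer matrix of 0-based internal index pairs
#'   (or an empty/`NULL` value for no bonds).
#' @param n_atoms number of atoms the graph spans.
#' @return An object of class `bond_graph` with fields `edges` (canonical
#'   `i < j` ordering, deduplicated, row-sorted) and `adjacency` (list of
#'   sorted 0-based neighbour vectors, one per atom).
#' @export
bond_graph <- function(edges, n_atoms) {
  n_atoms <- as.integer(n_atoms)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2)
  }
  edges <- matrix(as.integer(edges), ncol = 2)
  abort_if(any(edges < 0L | edges >= n_atoms),
           "bond_graph(): bond endpoint out of range [0, %d)", n_atoms)
  abort_if(any(edges[, 1] == edges[, 2]), "bond_graph(): self-edge rejected")
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- unique(edges)
  if (nrow(edges) > 1L) edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  adjacency <- vector("list", n_atoms)
  for (k in seq_len(n_atoms)) adjacency[[k]] <- integer(0)
  if (nrow(edges) > 0L) {
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      adjacency[[i + 1L]] <- c(adjacency[[i + 1L]], j)
      adjacency[[j + 1L]] <- c(adjacency[[j + 1L]], i)
    }
    adjacency <- lapply(adjacency, sort)
  }
  structure(list(edges = edges, adjacency = adjacency, n_atoms = n_atoms),
            class = "bond_graph")
}

#' Neighbours of an atom in a bond graph
#' @param graph a `bond_graph`.
#' @param index 0-based internal atom index.
#' @return Sorted integer vector of 0-based neighbour indices.
#' @export
neighbors_of <- function(graph, index) {
  graph$adjacency[[as.integer(index) + 1L]]
}

# Connected component membership, 1-based component ids per atom.
graph_components <- function(graph) {
  if (nrow(graph$edges) == 0L) return(seq_len(graph$n_atoms))
  g <- igraph::make_empty_graph(n = graph$n_atoms, directed = FALSE)
  g <- igraph::add_edges(g, t(graph$edges + 1L))
  igraph::components(g)$membership
}

# Edges that are part of some cycle (i.e. not bridges). Returns a logical
# vector over rows of graph$edges. Used by the cut rules: ring bonds are
# never cutable.
edges_in_rings <- function(graph) {
  ne <- nrow(graph$edges)
  if (ne == 0L) return(logical(0))
  g <- igraph::make_empty_graph(n = graph$n_atoms, directed = FALSE)
  g <- igraph::add_edges(g, t(graph$edges + 1L))
  br <- igraph::bridges(g)
  res <- rep(TRUE, ne)
  res[as.integer(br)] <- FALSE
  res
}

#' Assemble a validated molecular system
#'
#' Binds atoms, bonds, one or more coordinate frames (stationary points
#' along a reaction path, e.g. RS, TS1, INT, TS2, PS), and formal-charge
#' templates into the container every other module consumes.
#'
#' @param atoms an atom table from [atom_table()].
#' @param bonds a [bond_graph()] over the same atoms.
#' @param frames named list of `n_atoms x 3` coordinate matrices (angstrom);
#'   names are the frame labels and must be unique.
#' @param charge_templates residue formal-charge templates, default
#'   [default_charge_templates()].
#' @param charge_overrides optional named list of per-residue overrides,
#'   keyed `"SEGID:RESID"`, each an integer formal charge.
#' @return An object of class `molecular_system`.
#' @export
assemble_system <- function(atoms, bonds, frames,
                            charge_templates = default_charge_templates(),
                            charge_overrides = list()) {
  n <- nrow(atoms)
  stopifnot(inherits(bonds, "bond_graph"))
  abort_if(bonds$n_atoms != n,
           "assemble_system(): bond graph spans %d atoms, system has %d",
           bonds$n_atoms, n)
  abort_if(is.null(names(frames)) || any(!nzchar(names(frames))),
           "assemble_system(): frames must be a named list")
  abort_if(anyDuplicated(names(frames)) > 0L,
           "assemble_system(): duplicate frame label '%s'",
           names(frames)[duplicated(names(frames))][1])
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    abort_if(nrow(f) != n || ncol(f) != 3L,
             "assemble_system(): frame must be %d x 3, got %d x %d",
             n, nrow(f), ncol(f))
    storage.mode(f) <- "double"
    dimnames(f) <- NULL
    f
  })
  structure(list(atoms = atoms, bonds = bonds, frames = frames,
                 charge_templates = charge_templates,
                 charge_overrides = charge_overrides),
            class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  cat(sprintf("molecular_system: %d atoms, %d bonds, %d frame(s) [%s]\n",
              nrow(x$atoms), nrow(x$bonds$edges), length(x$frames),
              paste(names(x$frames), collapse = ", ")))
  invisible(x)
}

#' Number of atoms in a system
#' @param system a `molecular_system`.
#' @return Integer atom count.
#' @export
n_atoms <- function(system) nrow(system$atoms)

#' Map file serials to internal 0-based indices
#' @param system a `molecular_system`.
#' @param serial integer vector of 1-based serials.
#' @return Integer vector of 0-based internal indices.
#' @export
serial_to_index <- function(system, serial) {
  m <- match(as.integer(serial), system$atoms$serial)
  abort_if(anyNA(m), "unknown atom serial %d",
           as.integer(serial)[is.na(m)][1])
  system$atoms$index[m]
}

#' Map internal 0-based indices to file serials
#' @param system a `molecular_system`.
#' @param index integer vector of 0-based internal indices.
#' @return Integer vector of 1-based serials.
#' @export
index_to_serial <- function(system, index) {
  system$atoms$serial[as.integer(index) + 1L]
}

#' Default residue formal-charge templates
#'
#' Formal charges of a QM selection are accounted through residue templates
#' rather than derived from the electronic structure: each charged residue
#' template names its integer charge, the atoms that constitute the charged
#' group, and a single designated charge-center atom that decides the
#' accounting when a group is only partially selected. The table covers the
#' standard charged amino acids plus the nucleotide/metal species of a
#' GTPase active site (GTP(4-), GDP(3-), Mg(2+)); it is an ordinary named
#' list the caller can extend or override.
#'
#' @return Named list; each entry has fields `charge` (integer),
#'   `group_atoms` (character vector of atom names, empty meaning the whole
#'   residue), and `center` (charge-center atom name).
#' @export
default_charge_templates <- function() {
  list(
    ASP = list(charge = -1L, group_atoms = c("CG", "OD1", "OD2"),
               center = "CG"),
    GLU = list(charge = -1L, group_atoms = c("CD", "OE1", "OE2"),
               center = "CD"),
    LYS = list(charge = +1L, group_atoms = c("NZ", "HZ1", "HZ2", "HZ3"),
               center = "NZ"),
    ARG = list(charge = +1L, group_atoms = c("CZ", "NE", "NH1", "NH2"),
               center = "CZ"),
    GTP = list(charge = -4L,
               group_atoms = c("PA", "PB", "PG",
                               "O1A", "O2A", "O3A", "O1B", "O2B", "O3B",
                               "O1G", "O2G", "O3G"),
               center = "PG"),
    GDP = list(charge = -3L,
               group_atoms = c("PA", "PB",
                               "O1A", "O2A", "O3A", "O1B", "O2B", "O3B"),
               center = "PB"),
    MG  = list(charge = +2L, group_atoms = "MG", center = "MG")
  )
}
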