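# File I/O: PDB coordinates (via bio3d), PSF bond lists, and a native JSON
# topology that round-trips the full molecular_system.

#' Read atoms and coordinates from a PDB file
#'
#' Reads `ATOM`/`HETATM` records in file order, preserving serials, and
#' returns coordinates in angstrom. Element symbols come from the PDB
#' element column when present, otherwise from atom-name heuristics
#' ([guess_element()]). A file with no atom records yields an empty table
#' rather than an error.
#'
#' @param path path to a PDB file.
#' @return A list with `atoms` (see [atom_table()]) and `coords`
#'   (`n x 3` matrix, angstrom).
#' @export
read_pdb <- function(path) {
  abort_if(!file.exists(path), "read_pdb(): no such file '%s'", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) {
    return(list(atoms = atom_table(integer(0), character(0)),
                coords = matrix(numeric(0), ncol = 3)))
  }
  # validate fixed-width records before handing the file to the parser,
  # so malformed lines are reported by line number
  serials <- integer(0)
  for (ln in which(rec)) {
    l <- lines[ln]
    abort_if(nchar(l) < 54,
             "read_pdb(): malformed record at line %d (too short)", ln)
    xyz <- suppressWarnings(as.numeric(c(substr(l, 31, 38),
                                         substr(l, 39, 46),
                                         substr(l, 47, 54))))
    abort_if(anyNA(xyz),
             "read_pdb(): malformed coordinates at line %d", ln)
    s <- suppressWarnings(as.integer(substr(l, 7, 11)))
    abort_if(!is.na(s) && s %in% serials,
             "read_pdb(): duplicate serial %d at line %d", s, ln)
    serials <- c(serials, s)
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  element <- a$elesy
  element[is.na(element) | !nzchar(trimws(element))] <- NA_character_
  element <- ifelse(is.na(element), NA_character_, .normalize_element(element))
  segid <- a$segid
  segid[is.na(segid) | !nzchar(segid)] <- ifelse(
    is.na(a$chain[is.na(segid) | !nzchar(segid)]) |
      !nzchar(a$chain[is.na(segid) | !nzchar(segid)]),
    "MAIN", a$chain[is.na(segid) | !nzchar(segid)])
  atoms <- atom_table(serial = a$eleno, name = trimws(a$elety),
                      element = element, resname = trimws(a$resid),
                      resid = a$resno, segid = segid,
                      charge = NA_real_)
  list(atoms = atoms, coords = cbind(a$x, a$y, a$z))
}

.normalize_element <- function(el) {
  el <- trimws(el)
  paste0(toupper(substr(el, 1, 1)), tolower(substring(el, 2)))
}

#' Write one frame of a system as a PDB file
#'
#' @param system a `molecular_system`.
#' @param frame_label which frame to write.
#' @param path output path.
#' @param extra optional list of additional atoms to append, each a list
#'   with `name`, `element`, `resname`, `resid`, `xyz` (used for link-atom
#'   output).
#' @return Invisibly, the path.
#' @export
write_frame_pdb <- function(system, frame_label, path, extra = NULL) {
  abort_if(!frame_label %in% names(system$frames),
           "write_frame_pdb(): no frame '%s'", frame_label)
  a <- system$atoms
  xyz <- system$frames[[frame_label]]
  serial <- a$serial; name <- a$name; resname <- a$resname
  resid <- a$resid; element <- a$element
  if (length(extra)) {
    nx <- length(extra)
    serial <- c(serial, max(serial, 0L) + seq_len(nx))
    name <- c(name, vapply(extra, `[[`, "", "name"))
    resname <- c(resname, vapply(extra, `[[`, "", "resname"))
    resid <- c(resid, vapply(extra, function(e) as.integer(e$resid), 1L))
    element <- c(element, vapply(extra, `[[`, "", "element"))
    xyz <- rbind(xyz, do.call(rbind, lapply(extra, `[[`, "xyz")))
  }
  bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)), eleno = serial,
                   elety = name, resid = resname, resno = resid,
                   elesy = element)
  invisible(path)
}

#' Read a bond list into a bond graph
#'
#' Accepts either a PSF file (the `!NBOND` section) or a JSON file holding
#' an array of `[serial, serial]` pairs (optionally wrapped as
#' `{"bonds": [...]}`). Serials are resolved against `atoms`.
#'
#' @param path path to the bond file.
#' @param atoms atom table the serials refer to.
#' @return A [bond_graph()] over internal 0-based indices.
#' @export
read_bonds <- function(path, atoms) {
  abort_if(!file.exists(path), "read_bonds(): no such file '%s'", path)
  txt <- readLines(path, warn = FALSE)
  pairs <- if (any(grepl("!NBOND", txt, fixed = TRUE))) {
    .parse_psf_bonds(txt)
  } else {
    parsed <- jsonlite::fromJSON(paste(txt, collapse = "\n"),
                                 simplifyMatrix = TRUE)
    if (is.list(parsed) && !is.null(parsed$bonds)) parsed <- parsed$bonds
    if (length(parsed) == 0L) matrix(integer(0), ncol = 2) else
      matrix(as.integer(parsed), ncol = 2)
  }
  if (nrow(pairs) == 0L) return(bond_graph(NULL, nrow(atoms)))
  idx <- match(as.integer(pairs), atoms$serial)
  abort_if(anyNA(idx), "read_bonds(): bond references unknown serial %d",
           as.integer(pairs)[is.na(idx)][1])
  bond_graph(matrix(atoms$index[idx], ncol = 2), nrow(atoms))
}

.parse_psf_bonds <- function(txt) {
  at <- grep("!NBOND", txt, fixed = TRUE)[1]
  n_bonds <- as.integer(strsplit(trimws(txt[at]), "\\s+")[[1]][1])
  abort_if(is.na(n_bonds), "read_bonds(): malformed !NBOND header")
  ints <- integer(0)
  ln <- at + 1L
  while (length(ints) < 2L * n_bonds && ln <= length(txt)) {
    tok <- strsplit(trimws(txt[ln]), "\\s+")[[1]]
    tok <- tok[nzchar(tok)]
    if (length(tok)) ints <- c(ints, as.integer(tok))
    ln <- ln + 1L
  }
  abort_if(length(ints) < 2L * n_bonds,
           "read_bonds(): !NBOND promises %d bonds, found %d indices",
           n_bonds, length(ints))
  matrix(ints[seq_len(2L * n_bonds)], ncol = 2, byrow = TRUE)
}

#' Write a molecular system as a native JSON topology
#'
#' The native format stores atoms (with 1-based serials), bonds as serial
#' pairs, all frames, and the formal-charge configuration, and round-trips
#' exactly (integers bitwise, coordinates to 1e-6 angstrom).
#'
#' @param system a `molecular_system`.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_topology_json <- function(system, path) {
  a <- system$atoms
  obj <- list(
    atoms = lapply(seq_len(nrow(a)), function(k) list(
      serial = a$serial[k], name = a$name[k], element = a$element[k],
      resname = a$resname[k], resid = a$resid[k], segid = a$segid[k],
      charge = if (is.na(a$charge[k])) NULL else a$charge[k]
    )),
    bonds = if (nrow(system$bonds$edges)) {
      lapply(seq_len(nrow(system$bonds$edges)), function(k)
        index_to_serial(system, system$bonds$edges[k, ]))
    } else list(),
    frames = lapply(system$frames, function(f)
      lapply(seq_len(nrow(f)), function(k) unname(f[k, ]))),
    formal_charges = lapply(system$charge_templates, function(t) list(
      charge = t$charge, group_atoms = as.list(t$group_atoms),
      center = t$center)),
    charge_overrides = system$charge_overrides
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 8, null = "null")
  invisible(path)
}

#' Read a native JSON topology into a molecular system
#'
#' @param path path written by [write_topology_json()].
#' @return A `molecular_system`.
#' @export
read_topology_json <- function(path) {
  abort_if(!file.exists(path), "read_topology_json(): no such file '%s'", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  atoms <- atom_table(
    serial = vapply(obj$atoms, function(x) as.integer(x$serial), 1L),
    name = vapply(obj$atoms, function(x) as.character(x$name), ""),
    element = vapply(obj$atoms, function(x) as.character(x$element), ""),
    resname = vapply(obj$atoms, function(x) as.character(x$resname), ""),
    resid = vapply(obj$atoms, function(x) as.integer(x$resid), 1L),
    segid = vapply(obj$atoms, function(x) as.character(x$segid), ""),
    charge = vapply(obj$atoms, function(x)
      if (is.null(x$charge)) NA_real_ else as.numeric(x$charge), 1)
  )
  serial_pairs <- if (length(obj$bonds)) {
    matrix(vapply(obj$bonds, function(b) as.integer(unlist(b)),
                  integer(2)), ncol = 2, byrow = TRUE)
  } else matrix(integer(0), ncol = 2)
  idx <- matrix(match(serial_pairs, atoms$serial), ncol = 2)
  abort_if(anyNA(idx), "read_topology_json(): bond references unknown serial")
  bonds <- bond_graph(matrix(atoms$index[idx], ncol = 2), nrow(atoms))
  frames <- lapply(obj$frames, function(f)
    matrix(vapply(f, function(r) as.numeric(unlist(r)), numeric(3)),
           ncol = 3, byrow = TRUE))
  templates <- lapply(obj$formal_charges, function(t) list(
    charge = as.integer(t$charge),
    group_atoms = as.character(unlist(t$group_atoms)),
    center = as.character(t$center)))
  assemble_system(atoms, bonds, frames,
                  charge_templates = templates,
                  charge_overrides = obj$charge_overrides %||% list())
}
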