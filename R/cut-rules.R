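# Cut rules: which covalent bonds the QM/MM boundary may sever.
#
# Cuts are restricted to apolar single carbon-carbon bonds. The rule table
# lists allowed atom-name pairs; on top of that, three hard constraints are
# enforced at match time regardless of the table: both atoms must be carbon,
# neither may be a hydrogen, and the bond must not belong to a ring (ring
# membership is computed from the bond graph, as bonds that are not bridges).
# Bond orders are not modelled; "single bond" status is implied by the
# name-pair table.

#' Construct a cut-rule table
#'
#' @param qm_name,mm_name character vectors of atom-name pairs; matching is
#'   direction-agnostic (both orientations are tried).
#' @param resname optional residue-name context; `NA` matches any residue.
#' @param description human-readable rule labels.
#' @return A `data.frame` of class `cut_rules`.
#' @export
cut_rules <- function(qm_name, mm_name, resname = NA_character_,
                      description = NULL) {
  abort_if(any(!nzchar(qm_name)) || any(!nzchar(mm_name)),
           "cut_rules(): empty atom-name pattern")
  n <- length(qm_name)
  if (is.null(description)) description <- paste0(qm_name, "-", mm_name)
  structure(data.frame(qm_name = qm_name, mm_name = mm_name,
                       resname = rep_len(resname, n),
                       description = rep_len(description, n),
                       stringsAsFactors = FALSE),
            class = c("cut_rules", "data.frame"))
}

#' Default cut-rule table for standard amino-acid sidechains
#'
#' A conservative table of aliphatic C-C bonds along standard sidechains:
#' the Calpha-Cbeta bond and the successive sidechain carbon-carbon bonds
#' (Cbeta-Cgamma, Cgamma-Cdelta, Cdelta-Cepsilon, including the branched
#' Cgamma1/Cgamma2 and Cdelta1/Cdelta2 variants). Backbone amide C-N bonds,
#' bonds to non-carbon heavy atoms, and ring bonds are never cutable; the
#' first is guaranteed by omission from this table, the latter two by the
#' hard constraints applied at match time.
#'
#' @return A `cut_rules` table.
#' @export
default_cut_rules <- function() {
  cut_rules(
    qm_name = c("CA", "CB", "CB", "CB", "CG", "CG", "CG", "CG1", "CD"),
    mm_name = c("CB", "CG", "CG1", "CG2", "CD", "CD1", "CD2", "CD1", "CE")
  )
}

# Precompute, for one system, everything bond-cutability needs: a logical
# per-edge "in a ring" flag keyed by canonical edge id.
cutability_context <- function(system) {
  edges <- system$bonds$edges
  ring <- edges_in_rings(system$bonds)
  n <- n_atoms(system)
  key <- edges[, 1] * n + edges[, 2]
  list(n = n, ring_keys = key[ring])
}

edge_key <- function(i, j, n) pmin(i, j) * n + pmax(i, j)

#' Test whether a bond may be cut
#'
#' @param system a `molecular_system`.
#' @param i,j 0-based internal indices of the bonded atoms (QM side, MM
#'   side; matching tries both orientations).
#' @param rules a `cut_rules` table.
#' @param ctx optional precomputed context from inside the selector; callers
#'   can ignore it.
#' @return The matched rule description (character) or `NA` if not cutable.
#' @export
match_cut_rule <- function(system, i, j, rules, ctx = NULL) {
  a <- system$atoms
  ii <- i + 1L; jj <- j + 1L
  if (a$element[ii] != "C" || a$element[jj] != "C") return(NA_character_)
  if (is.null(ctx)) ctx <- cutability_context(system)
  if (edge_key(i, j, ctx$n) %in% ctx$ring_keys) return(NA_character_)
  for (k in seq_len(nrow(rules))) {
    r <- rules[k, ]
    fwd <- a$name[ii] == r$qm_name && a$name[jj] == r$mm_name
    rev <- a$name[ii] == r$mm_name && a$name[jj] == r$qm_name
    if (!(fwd || rev)) next
    if (!is.na(r$resname) &&
        !(a$resname[ii] == r$resname || a$resname[jj] == r$resname)) next
    return(r$description)
  }
  NA_character_
}
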