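# Composite energy assembly for reaction profiles: complete-basis-set (CBS)
# extrapolation, local-approximation-free (LAF) threshold extrapolation with
# uncertainty, coupled-cluster corrections at reduced QM size, and QM-size
# convergence reports.

#' Two-point CBS extrapolation of correlation energies
#'
#' Inverse-cubic model `E(X) = E_CBS + A * X^-3` solved from energies at
#' consecutive basis cardinal numbers X and X+1:
#' `E_CBS = ((X+1)^3 E_{X+1} - X^3 E_X) / ((X+1)^3 - X^3)`.
#'
#' @param e_x,e_x1 correlation energies at cardinals X and X+1.
#' @param x the smaller cardinal number (>= 2).
#' @return Extrapolated CBS correlation energy.
#' @export
cbs_extrapolate_corr <- function(e_x, e_x1, x) {
  abort_if(x < 2, "cbs_extrapolate_corr(): cardinal number must be >= 2")
  ((x + 1)^3 * e_x1 - x^3 * e_x) / ((x + 1)^3 - x^3)
}

#' Two-point CBS extrapolation of Hartree-Fock energies
#'
#' Exponential model `E(X) = E_CBS + A * exp(-alpha X)` solved from two
#' consecutive cardinals: `E_CBS = E_{X+1} + (E_{X+1} - E_X)/(exp(alpha)-1)`.
#'
#' @param e_x,e_x1 HF energies at cardinals X and X+1.
#' @param x the smaller cardinal number (>= 2).
#' @param alpha exponential decay constant (default 1.63).
#' @return Extrapolated CBS HF energy.
#' @export
cbs_extrapolate_hf <- function(e_x, e_x1, x, alpha = 1.63) {
  abort_if(x < 2, "cbs_extrapolate_hf(): cardinal number must be >= 2")
  abort_if(alpha <= 0, "cbs_extrapolate_hf(): alpha must be > 0")
  e_x1 + (e_x1 - e_x) / (exp(alpha) - 1)
}

#' LAF extrapolation from Normal/Tight local-correlation thresholds
#'
#' Estimates the local-approximation-free limit from energies computed at
#' the Normal and Tight threshold sets. The extrapolant is
#' `E_Tight + coeff * (E_Tight - E_Normal)` and the residual threshold error
#' is reported as the half-width `|coeff * (E_Tight - E_Normal)|` (with the
#' default `coeff = 0.5`, the familiar `+/- 0.5 (E_T - E_N)` band).
#'
#' @param e_normal,e_tight energies at Normal and Tight thresholds (same
#'   state and basis).
#' @param coeff extrapolation coefficient (default 0.5, configurable).
#' @return An [uncertain()] value.
#' @examples
#' laf_extrapolate(0, -0.2)   # -0.3 +/- 0.1
#' @export
laf_extrapolate <- function(e_normal, e_tight, coeff = 0.5) {
  d <- coeff * (e_tight - e_normal)
  uncertain(e_tight + d, abs(d))
}

#' Reference composite energy from CBS and threshold pieces
#'
#' Assembles the reference composite
#' `E = E_Normal^CBS + E_{N-T}^X - E_Normal^X`: a Normal-threshold CBS value
#' corrected by the threshold extrapolation evaluated in the finite basis X.
#' When the Tight and Normal results coincide (`E_{N-T}^X = E_Normal^X`) the
#' composite reduces to the plain Normal CBS value.
#'
#' @param e_normal_cbs Normal-threshold CBS-extrapolated energy.
#' @param e_nt_x threshold-extrapolated (N-T) energy at finite cardinal X.
#' @param e_normal_x Normal-threshold energy at the same cardinal X.
#' @return Composite reference energy.
#' @export
lno_composite_reference <- function(e_normal_cbs, e_nt_x, e_normal_x) {
  e_normal_cbs + e_nt_x - e_normal_x
}

# ---------------------------------------------------------------- tables --

.known_units <- c("hartree" = 1, "kcal/mol" = NA)

#' Construct/validate an energy table
#'
#' Long-format table keyed by (state, method, basis, lno threshold, QM
#' size). Energies are stored in hartree.
#'
#' @param df data.frame with columns `state`, `method`, `basis` (character:
#'   a cardinal number or `"CBS(X,X+1)"`), `lno` (`Normal`, `Tight`, `N-T`,
#'   or `na`), `qm_size` (integer), `energy` (hartree).
#' @return The validated data.frame of class `energy_table`.
#' @export
energy_table <- function(df) {
  need <- c("state", "method", "basis", "lno", "qm_size", "energy")
  miss <- setdiff(need, names(df))
  abort_if(length(miss) > 0L, "energy_table(): missing column(s) %s",
           paste(miss, collapse = ", "))
  abort_if(any(!is.finite(df$energy)), "energy_table(): non-finite energy")
  bad_lno <- setdiff(unique(df$lno), c("Normal", "Tight", "N-T", "na"))
  abort_if(length(bad_lno) > 0L, "energy_table(): unknown lno level '%s'",
           bad_lno[1])
  key <- do.call(paste, c(df[c("state", "method", "basis", "lno", "qm_size")],
                          sep = "\r"))
  abort_if(anyDuplicated(key) > 0L, "energy_table(): duplicate key '%s'",
           gsub("\r", "/", key[duplicated(key)][1]))
  df$qm_size <- as.integer(df$qm_size)
  class(df) <- c("energy_table", "data.frame")
  df
}

#' Read an energy table from CSV
#'
#' Expects the header `state,method,basis,lno,qm_size,energy,unit`; the
#' `unit` column must be `hartree` or `kcal/mol` (anything else errors
#' rather than being silently assumed). Values are converted to hartree.
#'
#' @param path CSV path.
#' @return An [energy_table()].
#' @export
read_energy_table <- function(path) {
  abort_if(!file.exists(path), "read_energy_table(): no such file '%s'", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  abort_if(!"unit" %in% names(df), "read_energy_table(): missing unit column")
  bad <- setdiff(unique(df$unit), names(.known_units))
  abort_if(length(bad) > 0L, "read_energy_table(): unknown unit '%s'", bad[1])
  df$energy <- ifelse(df$unit == "kcal/mol", from_kcal(df$energy), df$energy)
  df$unit <- NULL
  energy_table(df)
}

#' Look up energies for a set of states
#'
#' @param table an `energy_table`.
#' @param states states to retrieve, in order.
#' @param method,basis,lno,qm_size key selectors (scalar each; `NULL` means
#'   the column must be unique after the other selectors apply).
#' @return Named numeric vector of energies (hartree) in state order.
#' @export
lookup_energies <- function(table, states, method = NULL, basis = NULL,
                            lno = NULL, qm_size = NULL) {
  sub <- table
  for (col in c("method", "basis", "lno", "qm_size")) {
    val <- switch(col, method = method, basis = basis, lno = lno,
                  qm_size = qm_size)
    if (!is.null(val)) sub <- sub[sub[[col]] == val, , drop = FALSE]
  }
  e <- numeric(length(states))
  missing <- character(0)
  for (k in seq_along(states)) {
    rows <- which(sub$state == states[k])
    if (length(rows) == 0L) {
      missing <- c(missing, states[k])
    } else {
      abort_if(length(rows) > 1L,
               "lookup_energies(): key for state '%s' is ambiguous (%d rows)",
               states[k], length(rows))
      e[k] <- sub$energy[rows]
    }
  }
  abort_if(length(missing) > 0L, "lookup_energies(): missing state(s): %s",
           paste(missing, collapse = ", "))
  stats::setNames(e, states)
}

# ------------------------------------------------------------- profiles --

#' Define a reaction path
#'
#' @param states ordered stationary-point labels (e.g.
#'   `c("RS","TS1","INT","TS2","PS")`).
#' @param reference reference state for relative energies (default the
#'   first state).
#' @return A list of class `path_spec`.
#' @export
path_spec <- function(states, reference = states[1]) {
  abort_if(!reference %in% states,
           "path_spec(): reference '%s' not among states", reference)
  structure(list(states = states, reference = reference),
            class = "path_spec")
}

#' Relative energy profile over a reaction path
#'
#' Converts absolute energies to kcal/mol relative to the reference state
#' and derives the standard tracked quantities: the two barriers (TS1-RS,
#' TS2-RS), their difference (TS1-TS2, which discriminates the
#' rate-determining step), and the reaction energy (PS-RS) — each only when
#' the involved states are on the path.
#'
#' @param table an `energy_table`.
#' @param path a [path_spec()].
#' @param ... key selectors passed to [lookup_energies()].
#' @return List with `profile` (named kcal/mol relative energies) and
#'   `quantities` (named kcal/mol derived quantities).
#' @export
relative_profile <- function(table, path, ...) {
  stopifnot(inherits(path, "path_spec"))
  e <- lookup_energies(table, path$states, ...)
  rel <- to_kcal(e - e[[path$reference]])
  list(profile = rel, quantities = profile_quantities(rel, path$reference))
}

#' Derived tracked quantities of a relative profile
#'
#' @param rel named numeric vector of relative energies (kcal/mol).
#' @param reference reference state name.
#' @return Named numeric vector (subset of `TS1-RS`, `TS2-RS`, `TS1-TS2`,
#'   `PS-RS` for which the states are present).
#' @export
profile_quantities <- function(rel, reference = "RS") {
  q <- numeric(0)
  has <- function(s) s %in% names(rel)
  if (has("TS1")) q["TS1-RS"] <- rel[["TS1"]] - rel[[reference]]
  if (has("TS2")) q["TS2-RS"] <- rel[["TS2"]] - rel[[reference]]
  if (has("TS1") && has("TS2")) q["TS1-TS2"] <- rel[["TS1"]] - rel[["TS2"]]
  if (has("PS")) q["PS-RS"] <- rel[["PS"]] - rel[[reference]]
  q
}

#' Coupled-cluster correction at reduced QM size
#'
#' The difference between a coupled-cluster relative energy and the
#' corresponding DFT relative energy, both evaluated at the same (reduced)
#' QM size. Because this correction converges faster with QM size than the
#' relative energies themselves, it can be computed on a smaller region and
#' transferred to a larger-region DFT profile.
#'
#' @param de_cc_small CC relative energy at the small QM size (kcal/mol).
#' @param de_dft_small DFT relative energy at the same QM size (kcal/mol).
#' @param qm_size_cc,qm_size_dft optional QM sizes of the two inputs; if
#'   both given they must match.
#' @return The correction (kcal/mol).
#' @examples
#' cc_correction(4.13, 3.15)  # 0.98
#' @export
cc_correction <- function(de_cc_small, de_dft_small,
                          qm_size_cc = NULL, qm_size_dft = NULL) {
  if (!is.null(qm_size_cc) && !is.null(qm_size_dft)) {
    abort_if(qm_size_cc != qm_size_dft,
             "cc_correction(): QM sizes differ (%d vs %d)",
             qm_size_cc, qm_size_dft)
  }
  de_cc_small - de_dft_small
}

#' Assemble the composite free-energy estimate
#'
#' `dG = dE_DFT_E + ddE_CC - TdS`: the electronic relative energy at the
#' production DFT level, an optional coupled-cluster correction, and an
#' externally supplied entropic term (0 for electronic-only profiles).
#'
#' @param de_dft_e DFT relative energy (kcal/mol).
#' @param dde_cc coupled-cluster correction (kcal/mol, default 0).
#' @param tds entropic contribution T*dS (kcal/mol, default 0).
#' @return Composite estimate (kcal/mol).
#' @examples
#' composite_assemble(3.65, 0.98)  # 4.63
#' @export
composite_assemble <- function(de_dft_e, dde_cc = 0, tds = 0) {
  de_dft_e + dde_cc - tds
}

#' Mean absolute error of a profile against a reference profile
#'
#' @param profile,reference named numeric vectors of relative energies over
#'   the same state set (kcal/mol).
#' @param exclude states excluded from the mean (default the reference
#'   state `"RS"`, which is identically zero in both).
#' @return Mean absolute deviation (kcal/mol).
#' @export
mae_vs_reference <- function(profile, reference, exclude = "RS") {
  abort_if(!setequal(names(profile), names(reference)),
           "mae_vs_reference(): state sets differ (%s vs %s)",
           paste(names(profile), collapse = ","),
           paste(names(reference), collapse = ","))
  states <- setdiff(names(profile), exclude)
  mean(abs(profile[states] - reference[states]))
}

#' QM-size convergence report
#'
#' For each tracked quantity, finds the smallest QM size from which the
#' quantity stays within `tol_kcal` of its value at the largest size (taken
#' as the asymptote) for that size *and all larger ones*, and flags
#' non-monotonic approach (absolute deviations that increase with size).
#'
#' @param series data.frame with a `qm_size` column and one numeric column
#'   per tracked quantity (kcal/mol), one row per size.
#' @param tol_kcal convergence tolerance (default 1 kcal/mol).
#' @return A list per quantity with `converged_size` (the largest size
#'   always qualifies, so this is well defined), `deviations` (named by
#'   size), and `monotonic`.
#' @export
convergence_report <- function(series, tol_kcal = 1) {
  abort_if(!"qm_size" %in% names(series),
           "convergence_report(): series needs a qm_size column")
  abort_if(nrow(series) < 2L,
           "convergence_report(): need at least two QM sizes")
  series <- series[order(series$qm_size), , drop = FALSE]
  sizes <- series$qm_size
  quantities <- setdiff(names(series), "qm_size")
  out <- list()
  for (q in quantities) {
    v <- series[[q]]
    dev <- abs(v - v[length(v)])
    within <- dev <= tol_kcal
    # smallest size such that it and every larger size are within tol
    ok_from <- rev(cumprod(rev(within))) == 1
    converged_size <- sizes[which(ok_from)[1]]
    out[[q]] <- list(converged_size = converged_size,
                     deviations = stats::setNames(dev, sizes),
                     monotonic = all(diff(dev) <= 1e-12))
  }
  structure(out, class = "convergence_report", tol_kcal = tol_kcal)
}
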