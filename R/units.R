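#' Hartree to kcal/mol conversion factor
#'
#' All energies are carried internally in hartree; reports and reaction
#' profiles use kcal/mol, the customary unit for barrier heights.
#'
#' @format A length-one numeric, 627.5094740631 kcal/mol per hartree.
#' @export
HARTREE_TO_KCAL <- 627.5094740631

#' Convert hartree to kcal/mol
#'
#' @param e_hartree numeric vector of energies in hartree.
#' @return Energies in kcal/mol.
#' @examples
#' to_kcal(1)      # 627.5094740631
#' to_kcal(0.03)   # a typical barrier, 18.83 kcal/mol
#' @export
to_kcal <- function(e_hartree) {
  stopifnot(is.numeric(e_hartree))
  e_hartree * HARTREE_TO_KCAL
}

#' Convert kcal/mol to hartree
#' @param e_kcal numeric vector of energies in kcal/mol.
#' @return Energies in hartree.
#' @export
from_kcal <- function(e_kcal) {
  stopifnot(is.numeric(e_kcal))
  e_kcal / HARTREE_TO_KCAL
}

#' Value with an uncertainty half-width
#'
#' A number together with a symmetric uncertainty band, used for
#' local-approximation-free extrapolants whose residual threshold error is
#' reported as a +/- half-width.
#'
#' @param value numeric value.
#' @param halfwidth non-negative half-width, same units as `value`.
#' @return An object of class `uncertain` with fields `value`, `halfwidth`.
#' @examples
#' uncertain(-0.3, 0.1)
#' @export
uncertain <- function(value, halfwidth = 0) {
  stopifnot(is.numeric(value), length(value) == 1L,
            is.numeric(halfwidth), length(halfwidth) == 1L)
  abort_if(halfwidth < 0, "uncertain(): halfwidth must be >= 0, got %g",
           halfwidth)
  structure(list(value = value, halfwidth = halfwidth), class = "uncertain")
}

#' @export
print.uncertain <- function(x, ...) {
  cat(sprintf("%g +/- %g\n", x$value, x$halfwidth))
  invisible(x)
}

as_uncertain <- function(x) {
  if (inherits(x, "uncertain")) return(x)
  stopifnot(is.numeric(x), length(x) == 1L)
  uncertain(x, 0)
}

#' Propagate uncertain values through a linear combination
#'
#' Computes `sum(coeffs[i] * values[i])` where each value may carry an
#' uncertainty half-width. Values combine linearly; half-widths combine in
#' quadrature under a declared independence assumption, or by plain summation
#' of absolute contributions in `"worst_case"` mode.
#'
#' @param values list of `uncertain` objects or plain numbers.
#' @param coeffs numeric coefficients, recycled to the length of `values`
#'   (default all 1).
#' @param mode `"quadrature"` (independent errors) or `"worst_case"`.
#' @return An `uncertain` object.
#' @examples
#' propagate(list(uncertain(0, 3), uncertain(0, 4)))        # 0 +/- 5
#' propagate(list(uncertain(1, 2)), coeffs = -3)            # -3 +/- 6
#' @export
propagate <- function(values, coeffs = 1,
                      mode = c("quadrature", "worst_case")) {
  mode <- match.arg(mode)
  values <- lapply(values, as_uncertain)
  coeffs <- rep_len(coeffs, length(values))
  v <- sum(vapply(values, `[[`, numeric(1), "value") * coeffs)
  hw <- vapply(values, `[[`, numeric(1), "halfwidth") * abs(coeffs)
  h <- if (mode == "quadrature") sqrt(sum(hw^2)) else sum(hw)
  uncertain(v, h)
}
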