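# Conformer records and ensemble containers.

HARTREE_TO_KJ <- 2625.4996
R_GAS_KJ <- 8.314462618e-3  # kJ mol^-1 K^-1

#' Create a conformer record
#'
#' A conformer record bundles one candidate geometry with its identity,
#' electronic energy and, when available, the per-atom isotropic shieldings
#' from a GIAO calculation. Atom order is significant: shieldings are aligned
#' to it, and all conformers of one molecule are assumed to share it.
#'
#' @param id Character label for the conformer.
#' @param elements Character vector of element symbols, one per atom.
#' @param coords Numeric matrix of Cartesian coordinates in Angstrom, one row
#'   per atom, three columns.
#' @param energy Electronic energy, or `NULL` when unknown.
#' @param shieldings Numeric vector of isotropic shieldings in ppm aligned to
#'   the atom order, or `NULL`.
#' @param energy_unit Unit of `energy`: `"hartree"` (converted to kJ/mol on
#'   construction, the package-internal unit) or `"kJ/mol"`.
#' @return An object of class `conformer`, a list with fields `id`,
#'   `elements`, `coords`, `energy` (kJ/mol) and `shieldings`.
#' @export
conformer_record <- function(id, elements, coords, energy = NULL,
                             shieldings = NULL,
                             energy_unit = c("hartree", "kJ/mol")) {
  energy_unit <- match.arg(energy_unit)
  elements <- as.character(elements)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L)
    stop("coords must have three columns (x, y, z)")
  if (nrow(coords) != length(elements))
    stop("conformer '", id, "': coords has ", nrow(coords),
         " rows but elements has ", length(elements), " entries")
  if (any(!is.finite(coords)))
    stop("conformer '", id, "': non-finite coordinate")
  if (!is.null(energy)) {
    energy <- as.numeric(energy)
    if (length(energy) != 1L || !is.finite(energy))
      stop("conformer '", id, "': energy must be a single finite number")
    if (energy_unit == "hartree") energy <- energy * HARTREE_TO_KJ
  }
  if (!is.null(shieldings)) {
    shieldings <- as.numeric(shieldings)
    if (length(shieldings) != length(elements))
      stop("conformer '", id, "': ", length(shieldings),
           " shieldings for ", length(elements), " atoms")
  }
  structure(list(id = as.character(id), elements = elements, coords = coords,
                 energy = energy, shieldings = shieldings),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat("<conformer> ", x$id, ": ", length(x$elements), " atoms", sep = "")
  if (!is.null(x$energy)) cat(sprintf(", E = %.3f kJ/mol", x$energy))
  if (!is.null(x$shieldings)) cat(", shieldings present")
  cat("\n")
  invisible(x)
}

is_hydrogen <- function(elements) toupper(elements) %in% c("H", "D", "T")

ensemble_ids <- function(ensemble) vapply(ensemble, `[[`, character(1), "id")

ensemble_energies <- function(ensemble) {
  vapply(ensemble, function(cf)
    if (is.null(cf$energy)) NA_real_ else cf$energy, numeric(1))
}

check_ensemble <- function(ensemble) {
  if (!is.list(ensemble) || length(ensemble) == 0L)
    stop("ensemble must be a non-empty list of conformer records")
  ok <- vapply(ensemble, inherits, logical(1), "conformer")
  if (!all(ok))
    stop("ensemble elements ", paste(which(!ok), collapse = ", "),
         " are not conformer records")
  invisible(ensemble)
}
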