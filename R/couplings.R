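# Ensemble-averaged 3JHH coupling comparison. Calculated couplings are
# consumed as input (computed externally at the QM level); no Karplus-type
# fallback is provided.

#' Mixture-averaged coupling constants
#'
#' Population-weighted mean per proton pair, `J_mix = sum_k x_k J_k`.
#'
#' @param table A [coupling_table()].
#' @param x Molar-fraction composition over the table's conformer columns
#'   (or over `representatives` when given).
#' @param representatives Optional character vector of conformer ids
#'   selecting and ordering the columns `x` refers to.
#' @return Named numeric vector of mixture couplings in Hz, one per pair.
#' @export
mixture_couplings <- function(table, x, representatives = NULL) {
  stopifnot(inherits(table, "coupling_table"))
  J <- table$j_calc
  if (!is.null(representatives)) {
    miss <- setdiff(representatives, colnames(J))
    if (length(miss))
      stop("coupling table lacks conformer(s): ",
           paste(miss, collapse = ", "))
    J <- J[, representatives, drop = FALSE]
  }
  check_composition(x, ncol(J))
  stats::setNames(drop(J %*% x), table$pair_label)
}

#' Root-mean-square deviation of couplings
#'
#' `sqrt(mean((J_mix - J_exp)^2))` over the measured pairs.
#'
#' @param j_mix Calculated (possibly mixture-averaged) couplings in Hz.
#' @param j_exp Experimental couplings in Hz, same length.
#' @return RMSD in Hz.
#' @export
j_rmsd <- function(j_mix, j_exp) {
  if (length(j_mix) == 0L) stop("j_rmsd of an empty vector")
  if (length(j_mix) != length(j_exp)) stop("length mismatch")
  sqrt(mean((j_mix - j_exp)^2))
}

#' Coupling RMSD over a molar-fraction grid
#'
#' Evaluates [j_rmsd()] for every composition of the simplex grid and
#' reports the minimising composition — the coupling-based counterpart of
#' the mixture DP4+ scan, usable as an independent conformational
#' restraint.
#'
#' @param table A [coupling_table()] carrying `j_exp`.
#' @param step Grid step, default 0.1.
#' @param representatives Optional conformer ids selecting/ordering the
#'   mixture components (default: all table columns).
#' @return Data frame with fraction columns and `j_rmsd` (Hz); the best row
#'   index is attached as attribute `argmin` (vector when tied).
#' @export
j_rmsd_scan <- function(table, step = 0.1, representatives = NULL) {
  stopifnot(inherits(table, "coupling_table"))
  J <- table$j_calc
  if (!is.null(representatives)) {
    miss <- setdiff(representatives, colnames(J))
    if (length(miss))
      stop("coupling table lacks conformer(s): ",
           paste(miss, collapse = ", "))
    J <- J[, representatives, drop = FALSE]
  }
  grid <- simplex_grid(ncol(J), step)
  mix <- J %*% t(grid)  # pairs x compositions
  dev <- sqrt(colMeans((mix - table$j_exp)^2))
  out <- data.frame(grid, j_rmsd = dev, row.names = NULL)
  names(out)[seq_len(ncol(J))] <- colnames(J)
  attr(out, "argmin") <- which(dev == min(dev))
  out
}
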