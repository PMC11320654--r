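# Rigid-body superposition RMSD, conformer pre-filtering, hierarchical
# clustering of an ensemble, and dihedral diagnostics. Atom order is assumed
# consistent across conformers of the same molecule (true for conformational
# searches); no symmetry-equivalent-atom renumbering is attempted.

# optimal proper rotation mapping centred P onto centred Q (rows = atoms)
kabsch_rotation <- function(P, Q) {
  S <- crossprod(P, Q)
  sv <- svd(S)
  d <- sign(det(sv$u) * det(sv$v))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' RMSD after optimal rigid superposition (Kabsch)
#'
#' Least-squares rigid-body alignment: both selections are centred, the
#' optimal proper rotation is obtained from the SVD of the covariance
#' matrix (reflections excluded), and the root-mean-square deviation of the
#' superposed atoms is returned.
#'
#' @param a,b [conformer_record()]s of the same molecule.
#' @param selection Integer vector of atom indices used for the
#'   superposition, applied to both conformers. Default `NULL` selects the
#'   heavy (non-hydrogen) atoms.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(a, b, selection = NULL) {
  stopifnot(inherits(a, "conformer"), inherits(b, "conformer"))
  if (is.null(selection)) {
    if (length(a$elements) != length(b$elements))
      stop("conformers have different atom counts; supply a selection")
    selection <- which(!is_hydrogen(a$elements))
  }
  selection <- as.integer(selection)
  if (length(selection) < 3L)
    stop("superposition needs at least 3 atoms")
  if (any(selection < 1L) || any(selection > nrow(a$coords)) ||
      any(selection > nrow(b$coords)))
    stop("selection indexes atoms absent from a conformer")
  if (any(a$elements[selection] != b$elements[selection]))
    warning("paired atoms differ in element between '", a$id, "' and '",
            b$id, "'")
  P <- a$coords[selection, , drop = FALSE]
  Q <- b$coords[selection, , drop = FALSE]
  P <- sweep(P, 2L, colMeans(P))
  Q <- sweep(Q, 2L, colMeans(Q))
  A <- kabsch_rotation(P, Q)
  sqrt(mean(rowSums((P %*% A - Q)^2)))
}

#' Pairwise RMSD matrix of an ensemble
#'
#' @param ensemble List of [conformer_record()]s.
#' @inheritParams kabsch_rmsd
#' @return Symmetric matrix of RMSDs in Angstrom with zero diagonal,
#'   conformer ids as dimnames.
#' @export
rmsd_matrix <- function(ensemble, selection = NULL) {
  check_ensemble(ensemble)
  n <- length(ensemble)
  ids <- ensemble_ids(ensemble)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1L)
    for (i in seq_len(n - 1L))
      for (j in (i + 1L):n)
        m[i, j] <- m[j, i] <- kabsch_rmsd(ensemble[[i]], ensemble[[j]],
                                          selection = selection)
  m
}

#' Pre-filter a conformer ensemble by energy window and RMSD redundancy
#'
#' Drops conformers whose energy exceeds the minimum by more than
#' `energy_window`, then scans the survivors in ascending energy and drops
#' any conformer lying within `rmsd_cutoff` (heavy-atom Kabsch RMSD) of an
#' already-kept one — near-duplicates would only replicate each other's
#' chemical shifts. The scan order makes the result independent of input
#' ordering.
#'
#' @param ensemble List of [conformer_record()]s, all with energies.
#' @param energy_window Energy threshold above the minimum, kJ/mol
#'   (default 12).
#' @param rmsd_cutoff Redundancy cutoff in Angstrom (default 1).
#' @param selection Atom selection for the RMSD, as in [kabsch_rmsd()].
#' @return The kept conformers, in ascending energy order.
#' @export
prefilter_conformers <- function(ensemble, energy_window = 12,
                                 rmsd_cutoff = 1, selection = NULL) {
  check_ensemble(ensemble)
  e <- ensemble_energies(ensemble)
  if (anyNA(e))
    stop("conformer(s) without energy: ",
         paste(ensemble_ids(ensemble)[is.na(e)], collapse = ", "))
  ord <- order(e)
  ensemble <- ensemble[ord]
  e <- e[ord]
  within <- e - e[1] <= energy_window + 1e-9
  ensemble <- ensemble[within]
  kept <- list()
  for (cf in ensemble) {
    redundant <- any(vapply(kept, function(kc)
      kabsch_rmsd(kc, cf, selection = selection) < rmsd_cutoff,
      logical(1)))
    if (!redundant) kept[[length(kept) + 1L]] <- cf
  }
  kept
}

#' Cluster a conformer ensemble by pairwise RMSD
#'
#' Agglomerative hierarchical clustering on the pairwise Kabsch RMSD
#' matrix, with the tree cut at `merge_distance`. Complete linkage is the
#' default: every pair inside a cluster is then within the merge distance,
#' giving geometrically homogeneous clusters. The representative of each
#' cluster is its lowest-energy member (first by id when energies are
#' absent).
#'
#' @param ensemble List of [conformer_record()]s.
#' @param merge_distance Tree cut height in Angstrom (default 0.25).
#' @param selection Atom selection for the RMSD, as in [kabsch_rmsd()].
#' @param linkage `"complete"` (default), `"average"` or `"single"`.
#' @return An object of class `cluster_result`: list with `labels` (named
#'   integer cluster per conformer), `rmsd_matrix`, `merge_distance`,
#'   `representatives` (conformer id per cluster) and `linkage`.
#' @export
cluster_conformers <- function(ensemble, merge_distance = 0.25,
                               selection = NULL,
                               linkage = c("complete", "average",
                                           "single")) {
  check_ensemble(ensemble)
  linkage <- match.arg(linkage)
  ids <- ensemble_ids(ensemble)
  m <- rmsd_matrix(ensemble, selection = selection)
  if (length(ensemble) == 1L) {
    labels <- stats::setNames(1L, ids)
  } else {
    hc <- stats::hclust(stats::as.dist(m), method = linkage)
    labels <- stats::cutree(hc, h = merge_distance)
    names(labels) <- ids
  }
  e <- ensemble_energies(ensemble)
  reps <- vapply(sort(unique(labels)), function(cl) {
    member <- which(labels == cl)
    if (all(is.na(e[member]))) ids[member[order(ids[member])[1]]]
    else ids[member[which.min(e[member])]]
  }, character(1))
  structure(list(labels = labels, rmsd_matrix = m,
                 merge_distance = merge_distance,
                 representatives = unname(reps), linkage = linkage),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  k <- length(x$representatives)
  cat("Conformer clustering: ", length(x$labels), " conformers in ", k,
      " cluster(s) at merge distance ", x$merge_distance, " A (",
      x$linkage, " linkage)\n", sep = "")
  for (cl in seq_len(k)) {
    member <- names(x$labels)[x$labels == cl]
    cat("  cluster ", cl, " [rep ", x$representatives[cl], "]: ",
        paste(member, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Signed dihedral angle
#'
#' Torsion i-j-k-l by the IUPAC convention: 0 degrees for the cis (eclipsed)
#' arrangement, sign from the right-hand rule about the j-k bond, range
#' (-180, 180].
#'
#' @param conformer A [conformer_record()].
#' @param i,j,k,l Four distinct 1-based atom indices.
#' @return Angle in degrees.
#' @export
dihedral <- function(conformer, i, j, k, l) {
  idx <- c(i, j, k, l)
  if (anyDuplicated(idx)) stop("dihedral atoms must be distinct")
  if (any(idx < 1L) || any(idx > nrow(conformer$coords)))
    stop("atom index out of range")
  r <- conformer$coords
  b1 <- r[j, ] - r[i, ]
  b2 <- r[k, ] - r[j, ]
  b3 <- r[l, ] - r[k, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop("three consecutive atoms are collinear; dihedral undefined")
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  if (ang == 0) ang <- 0  # normalise -0
  ang
}
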