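# Readers and writers for XYZ ensembles, quantum-chemistry logs and
# delimited experimental tables. All files are plain UTF-8 text with a
# decimal point; atom indices are 1-based everywhere on disk and converted
# exactly once, here, at the I/O boundary.

#' Read a multi-structure XYZ file
#'
#' Parses a file of concatenated XYZ blocks (atom-count line, comment line,
#' then one `element x y z` line per atom). The comment line may carry
#' `id=<label>` and `energy=<Hartree>` tokens; absent an id, conformers are
#' labelled `conf-<k>` by block position. Blank lines between blocks and
#' trailing whitespace are ignored.
#'
#' @param path Path to the XYZ file.
#' @return A list of [conformer_record()] objects, in file order.
#' @export
read_xyz_ensemble <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[ \t\r]+$", "", lines)
  out <- list()
  i <- 1L
  k <- 0L
  n_lines <- length(lines)
  while (i <= n_lines) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    k <- k + 1L
    n_atoms <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n_atoms) || n_atoms < 1L)
      stop("XYZ parse error in block ", k, " at line ", i,
           ": expected an atom count, got '", lines[i], "'")
    if (i + 1L + n_atoms > n_lines)
      stop("XYZ parse error in block ", k, " at line ", i,
           ": block declares ", n_atoms, " atoms but the file ends early")
    comment <- lines[i + 1L]
    atom_lines <- lines[(i + 2L):(i + 1L + n_atoms)]
    if (any(!nzchar(trimws(atom_lines))))
      stop("XYZ parse error in block ", k, ": blank line inside atom list")
    toks <- strsplit(trimws(atom_lines), "[ \t]+")
    bad <- which(vapply(toks, length, integer(1)) < 4L)
    if (length(bad))
      stop("XYZ parse error in block ", k, " at line ", i + 1L + bad[1],
           ": expected 'element x y z'")
    elements <- vapply(toks, `[[`, character(1), 1L)
    coords <- t(vapply(toks, function(tk) {
      v <- suppressWarnings(as.numeric(tk[2:4]))
      v
    }, numeric(3)))
    if (any(!is.finite(coords))) {
      bad <- which(apply(!is.finite(coords), 1L, any))[1]
      stop("XYZ parse error in block ", k, " at line ", i + 1L + bad,
           ": non-numeric coordinate")
    }
    id <- xyz_comment_field(comment, "id")
    if (is.na(id)) id <- paste0("conf-", k)
    energy <- xyz_comment_field(comment, "energy")
    energy <- if (is.na(energy)) NULL else as.numeric(energy)
    out[[k]] <- conformer_record(id, elements, coords, energy = energy,
                                 energy_unit = "hartree")
    i <- i + 2L + n_atoms
  }
  out
}

xyz_comment_field <- function(comment, key) {
  m <- regmatches(comment,
                  regexpr(paste0(key, "=[^ \t]+"), comment))
  if (length(m) == 0L) return(NA_character_)
  sub(paste0("^", key, "="), "", m[1])
}

#' Write an ensemble to a multi-structure XYZ file
#'
#' Inverse of [read_xyz_ensemble()]: coordinates are printed at ten decimal
#' places, and each comment line records the conformer id and, when present,
#' the energy (converted back to Hartree).
#'
#' @param ensemble List of [conformer_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz_ensemble <- function(ensemble, path) {
  check_ensemble(ensemble)
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in ensemble) {
    writeLines(as.character(length(cf$elements)), con)
    comment <- paste0("id=", cf$id)
    if (!is.null(cf$energy))
      comment <- paste0(comment,
                        sprintf(" energy=%.10f", cf$energy / HARTREE_TO_KJ))
    writeLines(comment, con)
    writeLines(sprintf("%-3s %15.10f %15.10f %15.10f", cf$elements,
                       cf$coords[, 1], cf$coords[, 2], cf$coords[, 3]), con)
  }
  invisible(path)
}

# atomic number -> symbol, enough for organic molecules and common
# heteroatoms in Gaussian orientation blocks
ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe")

#' Parse a Gaussian-style quantum-chemistry log
#'
#' Extracts the last printed geometry (from a `Standard orientation` or
#' `Input orientation` block), the last SCF energy (`SCF Done:` line,
#' Hartree) and, when the log contains a GIAO job, the per-atom
#' `Isotropic =` shieldings. When a log holds an optimization followed by an
#' NMR single point, last-value-wins yields the NMR-step quantities. The
#' parser does not distinguish gas-phase from continuum-solvent (PCM) jobs;
#' users must know which parameter set their shieldings call for.
#'
#' @param path Path to the log file.
#' @param id Conformer label; defaults to the file name without extension.
#' @return A [conformer_record()] with energy in kJ/mol.
#' @export
parse_qm_log <- function(path, id = NULL) {
  if (is.null(id))
    id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)

  scf <- grep("SCF Done:", lines, value = TRUE)
  if (length(scf) == 0L)
    stop("no 'SCF Done' energy found in ", path)
  energy <- as.numeric(sub(".*=\\s*(-?[0-9.]+([DdEe][+-][0-9]+)?).*", "\\1",
                           scf[length(scf)]))
  if (!is.finite(energy))
    stop("could not parse SCF energy from '", scf[length(scf)], "'")

  orient <- grep("(Standard|Input) orientation:", lines)
  if (length(orient) == 0L)
    stop("no geometry (orientation block) found in ", path)
  start <- orient[length(orient)] + 5L  # skip header and ruler lines
  end <- start
  while (end <= length(lines) && !grepl("^\\s*-{5,}", lines[end]))
    end <- end + 1L
  rows <- strsplit(trimws(lines[start:(end - 1L)]), "\\s+")
  atnum <- vapply(rows, function(r) as.integer(r[2]), integer(1))
  coords <- t(vapply(rows, function(r) {
    as.numeric(r[(length(r) - 2L):length(r)])
  }, numeric(3)))
  if (any(is.na(atnum)) || any(!is.finite(coords)))
    stop("malformed orientation block in ", path)
  elements <- ELEMENT_SYMBOLS[atnum]

  iso <- grep("Isotropic\\s*=", lines, value = TRUE)
  shieldings <- NULL
  if (length(iso) > 0L) {
    shieldings <- as.numeric(sub(".*Isotropic\\s*=\\s*(-?[0-9.]+).*", "\\1",
                                 iso))
    if (any(!is.finite(shieldings)))
      stop("could not parse an 'Isotropic =' shielding in ", path)
    if (length(shieldings) != length(elements))
      stop(path, ": ", length(shieldings), " isotropic shieldings for ",
           length(elements), " atoms")
  }
  conformer_record(id, elements, coords, energy = energy,
                   shieldings = shieldings, energy_unit = "hartree")
}

#' Read an experimental shift-assignment table
#'
#' The CSV must have columns `site_label`, `nucleus` (`H1` or `C13`),
#' `delta_exp` (ppm) and `atom_indices` (1-based indices, semicolon-separated
#' when several atoms are experimentally isochronous, e.g. a methyl group).
#'
#' @param path Path to the CSV file.
#' @return A `shift_table` data frame with a list column `atom_indices`.
#' @export
read_shift_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("site_label", "nucleus", "delta_exp", "atom_indices")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("shift table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  idx <- lapply(strsplit(df$atom_indices, ";"), function(s)
    suppressWarnings(as.integer(trimws(s))))
  shift_table(site_label = trimws(df$site_label),
              nucleus = trimws(df$nucleus),
              delta_exp = suppressWarnings(as.numeric(df$delta_exp)),
              atom_indices = idx)
}

#' Construct and validate a shift-assignment table
#'
#' @param site_label Character vector of unique site labels.
#' @param nucleus `"H1"` or `"C13"` per site.
#' @param delta_exp Experimental shift in ppm per site (`NA` allowed; such
#'   sites are dropped symmetrically from all candidates during scoring).
#' @param atom_indices List of integer vectors of 1-based atom indices.
#' @return A data frame of class `shift_table`.
#' @export
shift_table <- function(site_label, nucleus, delta_exp, atom_indices) {
  if (!is.list(atom_indices)) atom_indices <- as.list(atom_indices)
  n <- length(site_label)
  stopifnot(length(nucleus) == n, length(delta_exp) == n,
            length(atom_indices) == n)
  bad <- character(0)
  dup <- unique(site_label[duplicated(site_label)])
  if (length(dup))
    bad <- c(bad, paste0("duplicate site_label: ",
                         paste(dup, collapse = ", ")))
  wrong_nuc <- site_label[!nucleus %in% c("H1", "C13")]
  if (length(wrong_nuc))
    bad <- c(bad, paste0("unknown nucleus code at site(s): ",
                         paste(wrong_nuc, collapse = ", ")))
  for (i in seq_len(n)) {
    ai <- atom_indices[[i]]
    if (length(ai) == 0L || anyNA(ai) || any(ai <= 0L))
      bad <- c(bad, paste0("invalid atom_indices at site ", site_label[i]))
    else if (anyDuplicated(ai))
      bad <- c(bad, paste0("repeated atom index at site ", site_label[i]))
  }
  if (length(bad))
    stop("shift table validation failed:\n  ",
         paste(bad, collapse = "\n  "))
  df <- data.frame(site_label = as.character(site_label),
                   nucleus = as.character(nucleus),
                   delta_exp = as.numeric(delta_exp),
                   stringsAsFactors = FALSE)
  df$atom_indices <- lapply(atom_indices, as.integer)
  class(df) <- c("shift_table", "data.frame")
  df
}

#' Check a shift table against a conformer's atoms
#'
#' Verifies that every referenced atom exists and that its element matches
#' the row's nucleus (H for H1, C for C13).
#'
#' @param table A `shift_table`.
#' @param conformer A [conformer_record()].
#' @return `TRUE` invisibly; errors list the offending sites.
#' @export
validate_assignments <- function(table, conformer) {
  bad <- character(0)
  want <- c(H1 = "H", C13 = "C")
  for (i in seq_len(nrow(table))) {
    ai <- table$atom_indices[[i]]
    if (any(ai > length(conformer$elements))) {
      bad <- c(bad, paste0(table$site_label[i], " references absent atom(s) ",
                           paste(ai[ai > length(conformer$elements)],
                                 collapse = ",")))
      next
    }
    el <- toupper(conformer$elements[ai])
    if (any(el != want[[table$nucleus[i]]]))
      bad <- c(bad, paste0(table$site_label[i], " (", table$nucleus[i],
                           ") maps to element(s) ",
                           paste(unique(el), collapse = ",")))
  }
  if (length(bad))
    stop("assignment check failed for conformer '", conformer$id, "':\n  ",
         paste(bad, collapse = "\n  "))
  invisible(TRUE)
}

#' Read a coupling-constant table
#'
#' The CSV must have columns `pair_label`, `j_exp` (Hz), then one column of
#' calculated 3JHH values (Hz) per conformer id.
#'
#' @param path Path to the CSV file.
#' @return A `coupling_table`: list with `pair_label`, `j_exp` and the
#'   matrix `j_calc` (pairs x conformers, conformer ids as column names).
#' @export
read_coupling_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("pair_label", "j_exp")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("coupling table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  ids <- setdiff(names(df), need)
  if (length(ids) == 0L)
    stop("coupling table ", path, " has no per-conformer columns")
  j_calc <- as.matrix(df[, ids, drop = FALSE])
  storage.mode(j_calc) <- "double"
  coupling_table(df$pair_label, as.numeric(df$j_exp), j_calc)
}

#' Construct a coupling table
#'
#' @param pair_label Character labels of the coupled proton pairs.
#' @param j_exp Experimental 3JHH in Hz.
#' @param j_calc Numeric matrix (pairs x conformers) of calculated 3JHH in
#'   Hz, with conformer ids as column names.
#' @return A list of class `coupling_table`.
#' @export
coupling_table <- function(pair_label, j_exp, j_calc) {
  j_calc <- as.matrix(j_calc)
  stopifnot(length(pair_label) == length(j_exp),
            nrow(j_calc) == length(j_exp))
  if (is.null(colnames(j_calc)))
    stop("j_calc must carry conformer ids as column names")
  if (any(!is.finite(j_exp)) || any(!is.finite(j_calc)))
    stop("coupling table contains non-finite Hz values")
  structure(list(pair_label = as.character(pair_label),
                 j_exp = as.numeric(j_exp), j_calc = j_calc),
            class = "coupling_table")
}

#' Attach shieldings from a plain CSV
#'
#' For users of quantum-chemistry codes without Gaussian-style logs: a CSV
#' with columns `conformer_id`, `atom_index` (1-based), `shielding` (ppm)
#' supplies the isotropic shieldings directly.
#'
#' @param ensemble List of [conformer_record()] objects.
#' @param path Path to the CSV file.
#' @return The ensemble with `shieldings` filled in.
#' @export
attach_shieldings_csv <- function(ensemble, path) {
  check_ensemble(ensemble)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("conformer_id", "atom_index", "shielding")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("shielding table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  ids <- ensemble_ids(ensemble)
  unknown <- setdiff(unique(df$conformer_id), ids)
  if (length(unknown))
    stop("shielding table references unknown conformer(s): ",
         paste(unknown, collapse = ", "))
  for (k in seq_along(ensemble)) {
    sub <- df[df$conformer_id == ids[k], , drop = FALSE]
    if (nrow(sub) == 0L) next
    n_atoms <- length(ensemble[[k]]$elements)
    if (any(sub$atom_index < 1L | sub$atom_index > n_atoms))
      stop("shielding table: atom index out of range for conformer ", ids[k])
    s <- rep(NA_real_, n_atoms)
    s[sub$atom_index] <- sub$shielding
    ensemble[[k]]$shieldings <- s
  }
  ensemble
}
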