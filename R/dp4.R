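# DP4+ core: shift referencing, linear scaling, error statistics and the
# Student-t probability over an arbitrary set of candidate shift sets.
#
# For a candidate c and nucleus N, unscaled shifts are delta_calc = sigma_ref
# - sigma (sigma = equivalent-atom-averaged isotropic shielding). Scaled
# shifts remove systematic slope/offset error by OLS of delta_calc on
# delta_exp per candidate and nucleus. Each selected channel (nucleus x
# {scaled, unscaled}) contributes log t-density terms; candidate
# probabilities are the softmax of summed log-likelihoods under a uniform
# prior.

DP4_KINDS <- c("scaled", "unscaled")
DP4_NUCLEI <- c("H1", "C13")

#' DP4+ t-distribution parameters
#'
#' Holds, for each nucleus (`H1`, `C13`) and error kind (`scaled`,
#' `unscaled`), the location `mu`, scale `sigma` and degrees of freedom `nu`
#' of the Student-t error model, plus the reference shielding `sigma_ref`
#' (TMS computed at the shift-calculation level) used to convert shieldings
#' to shifts. These are configuration, not constants: they depend on the
#' level of theory and on whether the GIAO job used a continuum solvent
#' model, and should match published parameter tables for the level in use.
#'
#' @param H1,C13 Lists with entries `scaled` and `unscaled`, each a numeric
#'   vector or list with `mu`, `sigma`, `nu`, plus `sigma_ref` (ppm).
#' @return An object of class `dp4_params`.
#' @seealso [read_dp4_params()] for the YAML representation.
#' @export
#' @examples
#' p <- dp4_params(
#'   H1 = list(scaled = c(mu = 0, sigma = 0.185, nu = 14.18),
#'             unscaled = c(mu = 0, sigma = 0.185, nu = 14.18),
#'             sigma_ref = 31.85),
#'   C13 = list(scaled = c(mu = 0, sigma = 2.306, nu = 11.38),
#'              unscaled = c(mu = 0, sigma = 2.306, nu = 11.38),
#'              sigma_ref = 186.52))
dp4_params <- function(H1, C13) {
  p <- list(H1 = H1, C13 = C13)
  for (nuc in DP4_NUCLEI) {
    cell <- p[[nuc]]
    if (is.null(cell$sigma_ref) || !is.finite(as.numeric(cell$sigma_ref)))
      stop("dp4_params: missing sigma_ref for ", nuc)
    cell$sigma_ref <- as.numeric(cell$sigma_ref)
    for (kind in DP4_KINDS) {
      v <- cell[[kind]]
      if (is.null(v))
        stop("dp4_params: missing ", kind, " parameters for ", nuc)
      v <- unlist(v)[c("mu", "sigma", "nu")]
      if (anyNA(v))
        stop("dp4_params: ", nuc, " ", kind,
             " must provide mu, sigma and nu")
      if (v[["sigma"]] <= 0 || v[["nu"]] <= 0)
        stop("dp4_params: sigma and nu must be positive (", nuc, " ",
             kind, ")")
      cell[[kind]] <- v
    }
    p[[nuc]] <- cell
  }
  structure(p, class = "dp4_params")
}

#' @export
print.dp4_params <- function(x, ...) {
  cat("<dp4_params>\n")
  for (nuc in DP4_NUCLEI) {
    cat(sprintf("  %-3s sigma_ref = %8.4f ppm\n", nuc, x[[nuc]]$sigma_ref))
    for (kind in DP4_KINDS)
      cat(sprintf("      %-8s mu = %7.4f  sigma = %7.4f  nu = %7.2f\n",
                  kind, x[[nuc]][[kind]][["mu"]],
                  x[[nuc]][[kind]][["sigma"]], x[[nuc]][[kind]][["nu"]]))
  }
  invisible(x)
}

#' Read DP4+ parameters from a YAML file
#'
#' The document maps each nucleus to `{scaled: {mu, sigma, nu}, unscaled:
#' {mu, sigma, nu}, sigma_ref}`, optionally nested under named parameter
#' sets (for example `pcm` and `gas`, since continuum-solvent and gas-phase
#' GIAO jobs call for different error statistics and reference shieldings).
#'
#' @param path Path to the YAML file. The default is the file shipped with
#'   the package.
#' @param set Name of the parameter set to select when the document holds
#'   several; ignored otherwise.
#' @return A [dp4_params()] object.
#' @export
read_dp4_params <- function(path = system.file("extdata", "dp4_params.yaml",
                                               package = "confshift"),
                            set = "pcm") {
  doc <- yaml::read_yaml(path)
  if (!all(DP4_NUCLEI %in% names(doc))) {
    if (!set %in% names(doc))
      stop("parameter set '", set, "' not found in ", path,
           " (available: ", paste(names(doc), collapse = ", "), ")")
    doc <- doc[[set]]
  }
  dp4_params(H1 = doc$H1, C13 = doc$C13)
}

#' Write DP4+ parameters to YAML
#'
#' @param params A [dp4_params()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dp4_params <- function(params, path) {
  stopifnot(inherits(params, "dp4_params"))
  doc <- lapply(unclass(params), function(cell) {
    list(scaled = as.list(cell$scaled), unscaled = as.list(cell$unscaled),
         sigma_ref = cell$sigma_ref)
  })
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Student-t error density
#'
#' Density of the DP4+ error model: a Student-t with `nu` degrees of
#' freedom, location `mu` and scale `sigma`, evaluated at `error`.
#'
#' @param error Shift error in ppm (vectorised).
#' @param mu Location in ppm.
#' @param sigma Scale in ppm, positive.
#' @param nu Degrees of freedom, positive.
#' @param log Return the log density?
#' @return Density in 1/ppm (or its log).
#' @export
t_density <- function(error, mu, sigma, nu, log = FALSE) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  if (!is.finite(nu) || nu <= 0) stop("nu must be positive")
  if (log) stats::dt((error - mu) / sigma, df = nu, log = TRUE) - log(sigma)
  else stats::dt((error - mu) / sigma, df = nu) / sigma
}

#' Per-site calculated shifts for one conformer
#'
#' Converts a conformer's shieldings to per-site calculated shifts: for each
#' site, the arithmetic mean over its experimentally isochronous atoms of
#' `sigma_ref - shielding`.
#'
#' @param conformer A [conformer_record()] with shieldings.
#' @param table A [shift_table()].
#' @param params A [dp4_params()] supplying `sigma_ref` per nucleus.
#' @return Numeric vector of calculated shifts in ppm, ordered as the table.
#' @export
candidate_site_shifts <- function(conformer, table, params) {
  s <- site_shieldings(conformer, table)
  ref <- vapply(table$nucleus, function(nuc) params[[nuc]]$sigma_ref,
                numeric(1))
  unname(ref - s)
}

# per-site equivalent-atom-averaged shieldings, ordered as the table
site_shieldings <- function(conformer, table) {
  if (is.null(conformer$shieldings))
    stop("conformer '", conformer$id, "' has no shieldings")
  n_atoms <- length(conformer$shieldings)
  vapply(seq_len(nrow(table)), function(i) {
    ai <- table$atom_indices[[i]]
    if (any(ai > n_atoms))
      stop("site ", table$site_label[i], ": atom index ",
           paste(ai[ai > n_atoms], collapse = ","),
           " absent from conformer '", conformer$id, "'")
    v <- conformer$shieldings[ai]
    if (anyNA(v))
      stop("site ", table$site_label[i],
           ": missing shielding for conformer '", conformer$id, "'")
    mean(v)
  }, numeric(1))
}

#' Linear scaling of calculated against experimental shifts
#'
#' Ordinary least squares of `delta_calc = m * delta_exp + b`; scaled shifts
#' are `(delta_calc - b) / m`, removing the systematic slope/offset error of
#' the level of theory. Computed per candidate and per nucleus.
#'
#' @param delta_calc Calculated shifts in ppm.
#' @param delta_exp Experimental shifts in ppm, same length.
#' @return An object of class `scaling_fit`: list with slope `m`, intercept
#'   `b` (ppm) and `scaled` shifts (ppm).
#' @export
fit_scaling <- function(delta_calc, delta_exp) {
  n <- length(delta_exp)
  if (length(delta_calc) != n)
    stop("delta_calc and delta_exp must have equal length")
  if (n < 2L)
    stop("scaling needs at least 2 sites; use the unscaled channel only")
  if (stats::var(delta_exp) == 0)
    stop("degenerate regression (no variance in experimental shifts); ",
         "use the unscaled channel only")
  fit <- stats::.lm.fit(cbind(1, delta_exp), delta_calc)
  b <- fit$coefficients[1]
  m <- fit$coefficients[2]
  if (!is.finite(m) || m == 0)
    stop("degenerate regression (zero slope); use the unscaled channel only")
  structure(list(m = unname(m), b = unname(b),
                 scaled = unname((delta_calc - b) / m)),
            class = "scaling_fit")
}

#' Corrected mean absolute error
#'
#' CMAE: mean of `|delta_scaled - delta_exp|` over the assigned sites.
#'
#' @param delta_scaled Scaled calculated shifts in ppm.
#' @param delta_exp Experimental shifts in ppm, same length.
#' @return CMAE in ppm.
#' @export
cmae <- function(delta_scaled, delta_exp) {
  if (length(delta_scaled) == 0L) stop("cmae of an empty vector")
  if (length(delta_scaled) != length(delta_exp))
    stop("length mismatch")
  mean(abs(delta_scaled - delta_exp))
}

#' Corrected maximum error
#'
#' CMaxErr: maximum of `|delta_scaled - delta_exp|` over the assigned sites.
#'
#' @inheritParams cmae
#' @return CMaxErr in ppm.
#' @export
cmaxerr <- function(delta_scaled, delta_exp) {
  if (length(delta_scaled) == 0L) stop("cmaxerr of an empty vector")
  if (length(delta_scaled) != length(delta_exp))
    stop("length mismatch")
  max(abs(delta_scaled - delta_exp))
}

# --- scoring engine ---------------------------------------------------------

# calc: sites x candidates matrix of calculated shifts for ONE nucleus;
# returns list(loglik = candidates vector, errors = sites x candidates,
# scaling = list of scaling_fit or NULL)
score_channel <- function(calc, delta_exp, pars, scaled) {
  if (scaled) {
    fits <- lapply(seq_len(ncol(calc)), function(j)
      fit_scaling(calc[, j], delta_exp))
    err <- vapply(fits, function(f) f$scaled - delta_exp,
                  numeric(nrow(calc)))
    err <- matrix(err, nrow = nrow(calc))
  } else {
    fits <- NULL
    err <- calc - delta_exp
  }
  ll <- colSums(t_density(err, pars[["mu"]], pars[["sigma"]], pars[["nu"]],
                          log = TRUE))
  list(loglik = ll, errors = err, scaling = fits)
}

softmax <- function(loglik) {
  z <- exp(loglik - max(loglik))
  z / sum(z)
}

# build sites x candidates calc-shift matrix from an ensemble or a list of
# per-site shift vectors
candidate_matrix <- function(candidates, table, params) {
  if (all(vapply(candidates, inherits, logical(1), "conformer"))) {
    m <- vapply(candidates, candidate_site_shifts, numeric(nrow(table)),
                table = table, params = params)
    ids <- ensemble_ids(candidates)
  } else {
    n <- nrow(table)
    len <- vapply(candidates, length, integer(1))
    if (any(len != n))
      stop("candidate shift vectors must cover all ", n, " sites")
    m <- vapply(candidates, as.numeric, numeric(n))
    ids <- names(candidates)
    if (is.null(ids)) ids <- paste0("cand-", seq_along(candidates))
  }
  m <- matrix(m, nrow = nrow(table))
  colnames(m) <- ids
  m
}

#' DP4+ probabilities over candidate conformations
#'
#' The central fit: scores every candidate's calculated shifts against the
#' experimental assignments with the Student-t error model, in up to four
#' channels (nucleus x scaled/unscaled), and returns normalised DP4+
#' probabilities under a uniform prior. Candidate ranking uses shift
#' agreement alone; energies play no role here.
#'
#' @param candidates Either a list of [conformer_record()]s with shieldings,
#'   or a named list of per-site calculated shift vectors ordered as the
#'   table.
#' @param table A [shift_table()]. Sites with `NA` experimental shift are
#'   dropped from all candidates symmetrically.
#' @param params A [dp4_params()].
#' @param channels Nuclei to use, subset of `c("H1", "C13")`.
#' @param kinds Error kinds to use, subset of `c("scaled", "unscaled")`.
#' @return An object of class `dp4_fit` with components `ids`, `loglik`
#'   (candidates x channel cells), `prob` (candidates x reported channels:
#'   each cell, `H1`, `C13`, `scaled`, `unscaled`, `combined`), `errors`
#'   (CMAE/CMaxErr per candidate and nucleus), `scaling`, and the inputs.
#'   Methods: `print`, `summary`, `coef` (combined probabilities),
#'   `residuals`, `plot`.
#' @export
#' @examples
#' study <- generate_study(seed = 1, n_conformers = 3,
#'                         ground_truth = c(1, 0, 0))
#' fit <- dp4_fit(study$ensemble, study$shift_table, study$params)
#' coef(fit)
dp4_fit <- function(candidates, table, params,
                    channels = c("H1", "C13"),
                    kinds = c("scaled", "unscaled")) {
  stopifnot(inherits(table, "shift_table"), inherits(params, "dp4_params"))
  channels <- match.arg(channels, DP4_NUCLEI, several.ok = TRUE)
  kinds <- match.arg(kinds, DP4_KINDS, several.ok = TRUE)
  if (length(candidates) == 0L) stop("no candidates supplied")

  calc <- candidate_matrix(candidates, table, params)
  keep <- !is.na(table$delta_exp)
  if (!all(keep)) {
    message("dropping ", sum(!keep),
            " site(s) with missing experimental shift")
    table <- table[keep, , drop = FALSE]
    class(table) <- c("shift_table", "data.frame")
    calc <- calc[keep, , drop = FALSE]
  }
  ids <- colnames(calc)
  if (anyDuplicated(ids))
    stop("candidate ids must be unique")
  n_cand <- ncol(calc)

  cells <- as.vector(outer(channels, kinds, paste, sep = "."))
  loglik <- matrix(0, n_cand, length(cells),
                   dimnames = list(ids, cells))
  scaling <- list()
  err_rows <- list()
  for (nuc in channels) {
    in_nuc <- table$nucleus == nuc
    if (!any(in_nuc)) {
      loglik[, paste(nuc, kinds, sep = ".")] <- 0
      next
    }
    sub_calc <- calc[in_nuc, , drop = FALSE]
    d_exp <- table$delta_exp[in_nuc]
    for (kind in kinds) {
      sc <- score_channel(sub_calc, d_exp, params[[nuc]][[kind]],
                          scaled = kind == "scaled")
      loglik[, paste(nuc, kind, sep = ".")] <- sc$loglik
    }
    # CMAE/CMaxErr are defined on scaled shifts; computed whether or not
    # the scaled likelihood channel is selected
    sm <- tryCatch(score_channel(sub_calc, d_exp,
                                 params[[nuc]][["scaled"]], scaled = TRUE),
                   error = function(e) NULL)
    if (!is.null(sm)) {
      scaling[[nuc]] <- sm$scaling
      names(scaling[[nuc]]) <- ids
      err_rows[[nuc]] <- data.frame(
        candidate = ids, nucleus = nuc,
        cmae = apply(abs(sm$errors), 2L, mean),
        cmaxerr = apply(abs(sm$errors), 2L, max),
        n_sites = sum(in_nuc), stringsAsFactors = FALSE)
    }
  }
  errors <- if (length(err_rows))
    do.call(rbind, c(err_rows, list(make.row.names = FALSE)))
  else NULL

  prob <- dp4_channel_probs(loglik, channels, kinds)
  if (n_cand == 1L)
    message("single candidate: all probabilities are 1 by construction")

  structure(list(ids = ids, loglik = loglik, prob = prob, errors = errors,
                 scaling = scaling, calc = calc, table = table,
                 params = params, channels = channels, kinds = kinds,
                 call = match.call()),
            class = "dp4_fit")
}

# aggregate cell log-likelihoods into reported probability channels
dp4_channel_probs <- function(loglik, channels, kinds) {
  cells <- colnames(loglik)
  groups <- list()
  for (cl in cells) groups[[cl]] <- cl
  for (nuc in channels)
    groups[[nuc]] <- grep(paste0("^", nuc, "\\."), cells, value = TRUE)
  for (kind in kinds)
    groups[[kind]] <- grep(paste0("\\.", kind, "$"), cells, value = TRUE)
  groups[["combined"]] <- cells
  prob <- vapply(groups, function(g)
    softmax(rowSums(loglik[, g, drop = FALSE])),
    numeric(nrow(loglik)))
  prob <- matrix(prob, nrow = nrow(loglik),
                 dimnames = list(rownames(loglik), names(groups)))
  prob
}

#' @export
print.dp4_fit <- function(x, ...) {
  p <- x$prob[, "combined"]
  top <- which(p == max(p))
  cat("DP4+ fit over ", length(x$ids), " candidate(s), ",
      nrow(x$table), " sites (",
      paste(x$channels, collapse = "+"), "; ",
      paste(x$kinds, collapse = "+"), ")\n", sep = "")
  cat("Top candidate", if (length(top) > 1) "s (tied)" else "", ": ",
      paste(x$ids[top], collapse = ", "),
      sprintf(" (combined probability %.2f%%)\n", 100 * p[top[1]]),
      sep = "")
  invisible(x)
}

#' @export
summary.dp4_fit <- function(object, ...) {
  p <- object$prob
  tab <- data.frame(candidate = object$ids,
                    round(100 * p[, intersect(
                      c("H1", "C13", "scaled", "unscaled", "combined"),
                      colnames(p)), drop = FALSE], 2),
                    stringsAsFactors = FALSE, row.names = NULL)
  comb <- p[, "combined"]
  res <- list(probabilities = tab, errors = object$errors,
              top = object$ids[comb == max(comb)],
              channels = object$channels, kinds = object$kinds)
  class(res) <- "summary.dp4_fit"
  res
}

#' @export
print.summary.dp4_fit <- function(x, ...) {
  cat("DP4+ probabilities (%):\n")
  print(x$probabilities, row.names = FALSE)
  cat("\nError statistics (scaled shifts, ppm):\n")
  ex <- x$errors
  ex$cmae <- round(ex$cmae, 3)
  ex$cmaxerr <- round(ex$cmaxerr, 3)
  print(ex, row.names = FALSE)
  cat("\nTop candidate(s): ", paste(x$top, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
coef.dp4_fit <- function(object, channel = "combined", ...) {
  stats::setNames(object$prob[, channel], object$ids)
}

#' @export
residuals.dp4_fit <- function(object, candidate = NULL,
                              kind = c("scaled", "unscaled"), ...) {
  kind <- match.arg(kind)
  if (is.null(candidate)) {
    p <- object$prob[, "combined"]
    candidate <- object$ids[which.max(p)]
  }
  j <- match(candidate, object$ids)
  if (is.na(j)) stop("unknown candidate '", candidate, "'")
  out <- numeric(nrow(object$table))
  for (nuc in object$channels) {
    in_nuc <- object$table$nucleus == nuc
    if (!any(in_nuc)) next
    d_exp <- object$table$delta_exp[in_nuc]
    d_calc <- object$calc[in_nuc, j]
    if (kind == "scaled")
      d_calc <- object$scaling[[nuc]][[candidate]]$scaled
    out[in_nuc] <- d_calc - d_exp
  }
  stats::setNames(out, object$table$site_label)
}

#' @export
plot.dp4_fit <- function(x, channel = "combined", ...) {
  p <- 100 * x$prob[, channel]
  graphics::barplot(p, names.arg = x$ids, las = 2,
                    ylab = sprintf("DP4+ probability (%%), %s channel",
                                   channel),
                    col = "steelblue", ...)
  invisible(x)
}

#' Per-candidate error summary
#'
#' CMAE and CMaxErr (scaled shifts) per candidate and nucleus, as a data
#' frame — the table the corrected-error comparison of candidate
#' conformations is read from.
#'
#' @param fit A [dp4_fit()] object.
#' @return Data frame with columns `candidate`, `nucleus`, `cmae`,
#'   `cmaxerr`, `n_sites`.
#' @export
error_summary <- function(fit) {
  stopifnot(inherits(fit, "dp4_fit"))
  fit$errors
}
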