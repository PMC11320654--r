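# Boltzmann populations, molar-fraction simplex grids, mixture-averaged
# shifts and the mixture DP4+ scan with ternary aggregation.

#' Boltzmann populations from conformer energies
#'
#' Equilibrium fractions proportional to `exp(-(E_k - E_min) / (R T))`,
#' with R = 8.314462618 J mol^-1 K^-1. Invariant under a uniform energy
#' shift; referencing to the minimum keeps the exponentials in range.
#'
#' @param energies Numeric vector of energies in kJ/mol, or a list of
#'   [conformer_record()]s (their energies are used, names their ids).
#' @param temperature Temperature in K, default 298.15.
#' @return Named numeric vector of weights summing to 1.
#' @export
boltzmann_weights <- function(energies, temperature = 298.15) {
  if (is.list(energies)) {
    check_ensemble(energies)
    e <- ensemble_energies(energies)
    names(e) <- ensemble_ids(energies)
    energies <- e
  }
  if (length(energies) == 0L) stop("no energies supplied")
  if (any(!is.finite(energies)))
    stop("non-finite energy at position(s) ",
         paste(which(!is.finite(energies)), collapse = ", "))
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive")
  w <- exp(-(energies - min(energies)) / (R_GAS_KJ * temperature))
  w / sum(w)
}

#' Enumerate molar-fraction compositions on a simplex grid
#'
#' All `k`-component molar-fraction vectors whose coordinates are
#' non-negative integer multiples of `step` and sum to 1, including the
#' vertices (pure conformers). The number of compositions is the
#' stars-and-bars count `choose(1/step + k - 1, k - 1)`.
#'
#' @param k Number of mixture components.
#' @param step Grid step; `1/step` must be a positive integer.
#' @return Numeric matrix with `k` columns, one composition per row, in
#'   lexicographically decreasing order of fractions.
#' @export
simplex_grid <- function(k, step) {
  if (k < 1L) stop("k must be at least 1")
  n <- 1 / step
  if (!is.finite(n) || abs(n - round(n)) > 1e-9 || n < 1)
    stop("1/step must be a positive integer (got step = ", step, ")")
  n <- as.integer(round(n))
  counts <- integer_compositions(n, as.integer(k))
  grid <- counts * step
  # snap away float dust so rows sum to 1 exactly at double precision
  grid <- round(grid, 12)
  colnames(grid) <- paste0("x", seq_len(k))
  grid
}

# all k-tuples of non-negative integers summing to n, first coordinate
# descending (recursive enumeration)
integer_compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1L, 1L))
  parts <- lapply(n:0, function(first) {
    rest <- integer_compositions(n - first, k - 1L)
    cbind(first, rest, deparse.level = 0)
  })
  do.call(rbind, parts)
}

check_composition <- function(x, k = NULL) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("composition must be a finite numeric vector")
  if (any(x < -1e-12 | x > 1 + 1e-12))
    stop("molar fractions must lie in [0, 1]")
  if (abs(sum(x) - 1) > 1e-9)
    stop("molar fractions must sum to 1 (got ", format(sum(x)), ")")
  if (!is.null(k) && length(x) != k)
    stop("composition has ", length(x), " components, expected ", k)
  invisible(x)
}

#' Mixture-averaged site values
#'
#' Population-weighted arithmetic mean per site, `v_i = sum_k x_k v_ik`.
#' Averaging is done in shielding space; the downstream shielding-to-shift
#' conversion is affine, so the order of averaging and referencing is
#' immaterial.
#'
#' @param values Numeric matrix, sites x representatives.
#' @param x Molar-fraction composition, one entry per representative.
#' @return Numeric vector of mixture-averaged values per site.
#' @export
mixture_shifts <- function(values, x) {
  values <- as.matrix(values)
  check_composition(x, ncol(values))
  drop(values %*% x)
}

# sites x representatives matrix of equivalent-atom-averaged shieldings
representative_shieldings <- function(representatives, table) {
  check_ensemble(representatives)
  m <- vapply(representatives, site_shieldings, numeric(nrow(table)),
              table = table)
  m <- matrix(m, nrow = nrow(table),
              dimnames = list(table$site_label,
                              ensemble_ids(representatives)))
  m
}

#' Mixture DP4+ scan over a molar-fraction grid
#'
#' Treats every composition of the simplex grid as one DP4+ candidate: the
#' representatives' shieldings are mixture-averaged, converted to shifts,
#' scaled per composition, and scored with the Student-t model; the
#' probabilities are normalised over the entire grid (uniform prior over
#' compositions). CMAE and CMaxErr per nucleus are computed for every
#' composition along the way.
#'
#' @param representatives List of [conformer_record()]s with shieldings, one
#'   per conformational cluster.
#' @param table A [shift_table()].
#' @param params A [dp4_params()].
#' @param step Grid step for [simplex_grid()], default 0.1.
#' @param channels,kinds As in [dp4_fit()].
#' @return An object of class `mixture_fit`: list with `grid` (compositions
#'   x components), `step`, `ids` (representative ids), `loglik`, `prob`
#'   (per-composition probabilities by channel, column `combined` is the
#'   headline one), and `errors` (per-composition CMAE/CMaxErr per nucleus).
#'   Methods: `print`, `summary`, `coef` (argmax composition), `plot`
#'   (ternary heat map).
#' @export
#' @examples
#' study <- generate_study(seed = 7, n_conformers = 3, n_sites_h = 10,
#'                         n_sites_c = 10, ground_truth = c(0.6, 0.3, 0.1))
#' fit <- mixture_fit(study$ensemble, study$shift_table, study$params,
#'                    step = 0.1)
#' coef(fit)
mixture_fit <- function(representatives, table, params, step = 0.1,
                        channels = c("H1", "C13"),
                        kinds = c("scaled", "unscaled")) {
  stopifnot(inherits(table, "shift_table"), inherits(params, "dp4_params"))
  channels <- match.arg(channels, DP4_NUCLEI, several.ok = TRUE)
  kinds <- match.arg(kinds, DP4_KINDS, several.ok = TRUE)
  if (length(representatives) < 1L)
    stop("at least one representative is required")

  keep <- !is.na(table$delta_exp)
  if (!all(keep)) {
    message("dropping ", sum(!keep),
            " site(s) with missing experimental shift")
    table <- table[keep, , drop = FALSE]
    class(table) <- c("shift_table", "data.frame")
  }
  ids <- ensemble_ids(representatives)
  shield <- representative_shieldings(representatives, table)
  grid <- simplex_grid(length(representatives), step)
  rownames(grid) <- apply(grid, 1L, compose_label)

  # sites x compositions mixture shieldings, then shifts
  mix_shield <- shield %*% t(grid)
  ref <- vapply(table$nucleus, function(nuc) params[[nuc]]$sigma_ref,
                numeric(1))
  mix_calc <- ref - mix_shield

  cells <- as.vector(outer(channels, kinds, paste, sep = "."))
  loglik <- matrix(0, nrow(grid), length(cells),
                   dimnames = list(rownames(grid), cells))
  err_cols <- list()
  for (nuc in channels) {
    in_nuc <- table$nucleus == nuc
    if (!any(in_nuc)) next
    sub_calc <- mix_calc[in_nuc, , drop = FALSE]
    d_exp <- table$delta_exp[in_nuc]
    for (kind in kinds) {
      sc <- score_channel(sub_calc, d_exp, params[[nuc]][[kind]],
                          scaled = kind == "scaled")
      loglik[, paste(nuc, kind, sep = ".")] <- sc$loglik
    }
    sm <- tryCatch(score_channel(sub_calc, d_exp,
                                 params[[nuc]][["scaled"]], scaled = TRUE),
                   error = function(e) NULL)
    if (!is.null(sm)) {
      err_cols[[paste0("cmae_", nuc)]] <- apply(abs(sm$errors), 2L, mean)
      err_cols[[paste0("cmaxerr_", nuc)]] <- apply(abs(sm$errors), 2L, max)
    }
  }
  errors <- if (length(err_cols))
    data.frame(composition = rownames(grid), err_cols,
               stringsAsFactors = FALSE, row.names = NULL)
  else NULL

  prob <- dp4_channel_probs(loglik, channels, kinds)
  structure(list(grid = grid, step = step, ids = ids, loglik = loglik,
                 prob = prob, errors = errors, table = table,
                 params = params, channels = channels, kinds = kinds,
                 call = match.call()),
            class = "mixture_fit")
}

compose_label <- function(x) paste(format(x, trim = TRUE), collapse = ":")

#' @export
print.mixture_fit <- function(x, ...) {
  p <- x$prob[, "combined"]
  top <- which(p == max(p))
  cat("Mixture DP4+ scan: ", length(x$ids), " representatives (",
      paste(x$ids, collapse = ", "), "), step ", x$step, ", ",
      nrow(x$grid), " compositions\n", sep = "")
  cat("Most probable composition",
      if (length(top) > 1) "s (tied)" else "", ":\n", sep = "")
  for (t in top)
    cat("  ", rownames(x$grid)[t],
        sprintf("  (probability %.1f%%)\n", 100 * p[t]))
  invisible(x)
}

#' @export
summary.mixture_fit <- function(object, n_top = 5L, ...) {
  p <- object$prob[, "combined"]
  ord <- order(p, decreasing = TRUE)
  top <- utils::head(ord, n_top)
  tab <- data.frame(object$grid[top, , drop = FALSE],
                    probability = round(100 * p[top], 2),
                    row.names = NULL)
  names(tab)[seq_along(object$ids)] <- object$ids
  best_err <- NULL
  if (!is.null(object$errors)) {
    best_err <- lapply(grep("^cmae_", names(object$errors), value = TRUE),
                       function(cl) {
                         j <- which.min(object$errors[[cl]])
                         data.frame(statistic = cl,
                                    composition =
                                      object$errors$composition[j],
                                    value = object$errors[[cl]][j])
                       })
    best_err <- do.call(rbind, best_err)
  }
  res <- list(top = tab, best_errors = best_err, step = object$step,
              n_grid = nrow(object$grid))
  class(res) <- "summary.mixture_fit"
  res
}

#' @export
print.summary.mixture_fit <- function(x, ...) {
  cat("Top compositions (DP4+ probability, %):\n")
  print(x$top, row.names = FALSE)
  if (!is.null(x$best_errors)) {
    cat("\nBest scaled errors over the grid (ppm):\n")
    be <- x$best_errors
    be$value <- round(be$value, 4)
    print(be, row.names = FALSE)
  }
  cat("\nGrid: ", x$n_grid, " compositions at step ", x$step, "\n",
      sep = "")
  invisible(x)
}

#' @export
coef.mixture_fit <- function(object, ...) {
  p <- object$prob[, "combined"]
  top <- which(p == max(p))
  est <- object$grid[top, , drop = FALSE]
  colnames(est) <- object$ids
  if (length(top) == 1L) drop(est) else est
}

#' Probability mass of a composition band
#'
#' Sums grid probabilities over the compositions a predicate selects — for
#' example a band of molar-ratio combinations between two compositions.
#'
#' @param fit A [mixture_fit()] object.
#' @param predicate Function taking one composition (numeric vector) and
#'   returning `TRUE`/`FALSE`.
#' @param channel Probability channel, default `"combined"`.
#' @return Scalar probability in `[0, 1]`.
#' @export
band_probability <- function(fit, predicate, channel = "combined") {
  stopifnot(inherits(fit, "mixture_fit"))
  sel <- apply(fit$grid, 1L, function(x) isTRUE(predicate(x)))
  sum(fit$prob[sel, channel])
}

#' Per-composition error scan
#'
#' CMAE and CMaxErr per nucleus for every grid composition, with the
#' scaling ("corrected" step) refitted per composition — the table from
#' which the best-fitting mixture by corrected errors is read.
#'
#' @inheritParams mixture_fit
#' @return Data frame: one row per composition, fraction columns, then
#'   `cmae_*` / `cmaxerr_*` per nucleus.
#' @export
mixture_error_scan <- function(representatives, table, params, step = 0.1,
                               channels = c("H1", "C13")) {
  fit <- mixture_fit(representatives, table, params, step = step,
                     channels = channels)
  cbind(as.data.frame(fit$grid), fit$errors[, -1, drop = FALSE])
}

#' Aggregate a mixture grid onto three ternary axes
#'
#' Partitions the mixture components into three groups, sums fractions
#' within each group and probabilities over compositions mapping to the
#' same aggregated triple — the reduction used to display a 4-component
#' grid on a ternary diagram, with minor components summed on one axis.
#'
#' @param fit A [mixture_fit()] object.
#' @param groups List of three integer vectors partitioning
#'   `seq_along(fit$ids)`.
#' @param labels Axis labels; default derived from grouped ids.
#' @return A data frame of class `ternary_grid` with columns `a`, `b`, `c`
#'   (aggregated fractions) and `probability`; axis labels as attribute
#'   `labels`. Total probability is preserved.
#' @export
aggregate_ternary <- function(fit, groups = NULL, labels = NULL) {
  stopifnot(inherits(fit, "mixture_fit"))
  k <- length(fit$ids)
  if (is.null(groups)) {
    if (k == 3L) groups <- list(1L, 2L, 3L)
    else if (k > 3L) groups <- list(1L, 2L, 3:k)
    else stop("ternary aggregation needs at least 3 components")
  }
  if (length(groups) != 3L)
    stop("groups must partition the components into exactly 3 groups")
  flat <- sort(unlist(groups))
  if (!identical(as.integer(flat), seq_len(k)))
    stop("groups must cover every component exactly once")
  if (is.null(labels))
    labels <- vapply(groups, function(g)
      paste(fit$ids[g], collapse = "+"), character(1))
  tri <- vapply(groups, function(g)
    rowSums(fit$grid[, g, drop = FALSE]), numeric(nrow(fit$grid)))
  tri <- round(matrix(tri, ncol = 3L), 12)
  key <- apply(tri, 1L, paste, collapse = "|")
  p <- fit$prob[, "combined"]
  agg <- rowsum(p, key)
  first <- !duplicated(key)
  out <- data.frame(a = tri[first, 1], b = tri[first, 2], c = tri[first, 3],
                    probability = agg[match(key[first], rownames(agg)), 1],
                    row.names = NULL)
  out <- out[order(-out$a, -out$b), ]
  rownames(out) <- NULL
  attr(out, "labels") <- labels
  class(out) <- c("ternary_grid", "data.frame")
  out
}

#' @export
plot.mixture_fit <- function(x, groups = NULL, ...) {
  tg <- aggregate_ternary(x, groups = groups)
  plot(tg, ...)
  invisible(x)
}

#' @export
plot.ternary_grid <- function(x, cex = 1.6, main = "Mixture DP4+ scan",
                              ...) {
  labels <- attr(x, "labels")
  # ternary -> planar: A bottom-left, B bottom-right, C top
  px <- x$b + 0.5 * x$c
  py <- sqrt(3) / 2 * x$c
  pal <- grDevices::colorRampPalette(c("#2c7bb6", "#ffffbf", "#d7191c"))(64)
  rel <- x$probability / max(x$probability)
  cols <- pal[pmax(1L, ceiling(rel * 64))]
  graphics::plot.new()
  graphics::plot.window(xlim = c(-0.12, 1.12), ylim = c(-0.12, 1.0),
                        asp = 1)
  graphics::polygon(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2), border = "grey40")
  graphics::points(px, py, pch = 21, bg = cols, col = "grey30", cex = cex)
  graphics::text(c(-0.05, 1.05, 0.5), c(-0.05, -0.05, sqrt(3) / 2 + 0.06),
                 labels, cex = 0.9)
  graphics::title(main = main)
  invisible(x)
}

#' Write a mixture grid to CSV
#'
#' One row per composition: molar fractions, log-likelihood and
#' probability; consumable by ternary-plotting tools.
#'
#' @param fit A [mixture_fit()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mixture_csv <- function(fit, path) {
  stopifnot(inherits(fit, "mixture_fit"))
  df <- data.frame(fit$grid,
                   log_likelihood = rowSums(fit$loglik),
                   probability = fit$prob[, "combined"], row.names = NULL)
  names(df)[seq_along(fit$ids)] <- fit$ids
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
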