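# End-to-end analyses behind the command-line entry point: single-conformer
# selection (prefilter -> DP4+ -> errors -> Boltzmann) and mixture analysis
# (cluster -> representatives -> grid scan -> couplings). Outputs are
# written only after all computation succeeds, so an aborted stage leaves
# no partial report behind.

#' Build and validate an analysis configuration
#'
#' @param ensemble Path to a multi-structure XYZ file, or a list of
#'   [conformer_record()]s.
#' @param shifts Path to a shift-table CSV, or a [shift_table()].
#' @param params Path to a DP4+ parameter YAML, or a [dp4_params()].
#' @param couplings Optional path to a coupling CSV, or a
#'   [coupling_table()].
#' @param shieldings Optional path to a shielding CSV (see
#'   [attach_shieldings_csv()]).
#' @param channels Nuclei to use.
#' @param kinds Error kinds to use.
#' @param step Mixture grid step.
#' @param merge_distance Cluster merge distance in Angstrom.
#' @param energy_window Prefilter energy window in kJ/mol.
#' @param rmsd_cutoff Prefilter redundancy cutoff in Angstrom.
#' @param temperature Temperature in K for Boltzmann populations.
#' @param param_set Named parameter set inside the YAML (e.g. `"pcm"`,
#'   `"gas"`).
#' @param out_dir Optional output directory for CSV/JSON reports.
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(ensemble, shifts, params = NULL,
                            couplings = NULL, shieldings = NULL,
                            channels = c("H1", "C13"),
                            kinds = c("scaled", "unscaled"),
                            step = 0.1, merge_distance = 0.25,
                            energy_window = 12, rmsd_cutoff = 1,
                            temperature = 298.15, param_set = "pcm",
                            out_dir = NULL) {
  for (nm in c("ensemble", "shifts", "params", "couplings", "shieldings")) {
    v <- get(nm)
    if (is.character(v) && !file.exists(v))
      stop("config error: ", nm, " path does not exist: ", v)
  }
  if (abs(1 / step - round(1 / step)) > 1e-9)
    stop("config error: 1/step must be an integer")
  structure(list(ensemble = ensemble, shifts = shifts, params = params,
                 couplings = couplings, shieldings = shieldings,
                 channels = channels, kinds = kinds, step = step,
                 merge_distance = merge_distance,
                 energy_window = energy_window, rmsd_cutoff = rmsd_cutoff,
                 temperature = temperature, param_set = param_set,
                 out_dir = out_dir),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file whose keys are the arguments of
#'   [analysis_config()]; relative paths resolve against the file's
#'   directory.
#' @param ... Overrides applied after reading.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path, ...) {
  doc <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (nm in c("ensemble", "shifts", "params", "couplings", "shieldings"))
    if (!is.null(doc[[nm]]) && !grepl("^/", doc[[nm]]))
      doc[[nm]] <- file.path(base, doc[[nm]])
  over <- list(...)
  doc[names(over)] <- over
  do.call(analysis_config, doc)
}

load_config_inputs <- function(config) {
  stage("load", {
    ensemble <- if (is.character(config$ensemble))
      read_xyz_ensemble(config$ensemble) else config$ensemble
    check_ensemble(ensemble)
    if (!is.null(config$shieldings) && is.character(config$shieldings))
      ensemble <- attach_shieldings_csv(ensemble, config$shieldings)
    shifts <- if (is.character(config$shifts))
      read_shift_table(config$shifts) else config$shifts
    params <- config$params
    if (is.null(params)) params <- read_dp4_params(set = config$param_set)
    else if (is.character(params))
      params <- read_dp4_params(params, set = config$param_set)
    couplings <- config$couplings
    if (!is.null(couplings) && is.character(couplings))
      couplings <- read_coupling_table(couplings)
    validate_assignments(shifts, ensemble[[1]])
    message("load: ", length(ensemble), " conformers, ", nrow(shifts),
            " assigned sites")
    list(ensemble = ensemble, shifts = shifts, params = params,
         couplings = couplings)
  })
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the single-conformation analysis
#'
#' The workflow for molecules expected to populate one conformation:
#' energy-window/RMSD pre-filtering, per-conformer DP4+ probabilities in
#' all channels, CMAE/CMaxErr summaries, and Boltzmann populations for
#' comparison with the shift-based ranking.
#'
#' @param config An [analysis_config()] (or arguments for it, via `...`).
#' @param ... Used to build a config when `config` is missing.
#' @return An object of class `analysis_report`: list with `dp4` (a
#'   [dp4_fit()]), `errors`, `boltzmann`, `kept_ids`, and a `provenance`
#'   block (config echo, package version, timestamp). When
#'   `config$out_dir` is set, CSV/JSON reports are written there.
#' @export
run_conformer_analysis <- function(config, ...) {
  if (missing(config)) config <- analysis_config(...)
  stopifnot(inherits(config, "analysis_config"))
  inputs <- load_config_inputs(config)
  ensemble <- inputs$ensemble

  energies <- ensemble_energies(ensemble)
  if (!anyNA(energies)) {
    ensemble <- stage("prefilter", prefilter_conformers(
      ensemble, energy_window = config$energy_window,
      rmsd_cutoff = config$rmsd_cutoff))
    message("prefilter: kept ", length(ensemble), " of ",
            length(inputs$ensemble), " conformers")
  } else message("prefilter: skipped (not all conformers have energies)")

  fit <- stage("dp4", dp4_fit(ensemble, inputs$shifts, inputs$params,
                              channels = config$channels,
                              kinds = config$kinds))
  boltz <- NULL
  if (!anyNA(ensemble_energies(ensemble)))
    boltz <- stage("boltzmann",
                   boltzmann_weights(ensemble,
                                     temperature = config$temperature))
  report <- structure(
    list(dp4 = fit, errors = fit$errors, boltzmann = boltz,
         kept_ids = ensemble_ids(ensemble),
         provenance = provenance_block(config)),
    class = "analysis_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Run the mixture (conformational-equilibrium) analysis
#'
#' The workflow for molecules in fast conformational exchange: cluster the
#' ensemble, take one representative per cluster, scan all molar-fraction
#' combinations of the representatives on a simplex grid with the DP4+
#' metric, tabulate per-composition errors, and (when couplings are
#' supplied) scan the coupling RMSD over the same grid.
#'
#' @inheritParams run_conformer_analysis
#' @return An `analysis_report` with `clusters` (a [cluster_conformers()]
#'   result), `mixture` (a [mixture_fit()]), `error_scan`, optional
#'   `j_scan`, and `provenance`.
#' @export
run_mixture_analysis <- function(config, ...) {
  if (missing(config)) config <- analysis_config(...)
  stopifnot(inherits(config, "analysis_config"))
  inputs <- load_config_inputs(config)
  ensemble <- inputs$ensemble

  clusters <- stage("cluster", cluster_conformers(
    ensemble, merge_distance = config$merge_distance))
  reps <- ensemble[match(clusters$representatives,
                         ensemble_ids(ensemble))]
  message("cluster: ", length(ensemble), " conformers -> ",
          length(reps), " representatives (",
          paste(clusters$representatives, collapse = ", "), ")")
  if (length(reps) < 2L)
    message("mixture scan over a single representative is trivially the ",
            "pure conformer")

  fit <- stage("mixture", mixture_fit(reps, inputs$shifts, inputs$params,
                                      step = config$step,
                                      channels = config$channels,
                                      kinds = config$kinds))
  message("mixture: ", nrow(fit$grid), " compositions at step ",
          config$step)
  j_scan <- NULL
  if (!is.null(inputs$couplings))
    j_scan <- stage("jrmsd", j_rmsd_scan(
      inputs$couplings, step = config$step,
      representatives = intersect(colnames(inputs$couplings$j_calc),
                                  clusters$representatives)))
  report <- structure(
    list(clusters = clusters, mixture = fit,
         error_scan = cbind(as.data.frame(fit$grid),
                            fit$errors[, -1, drop = FALSE]),
         j_scan = j_scan, provenance = provenance_block(config)),
    class = "analysis_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

provenance_block <- function(config) {
  cfg <- unclass(config)
  cfg <- cfg[vapply(cfg, function(v)
    is.character(v) || is.numeric(v) || is.null(v), logical(1))]
  list(config = cfg,
       package = "confshift",
       version = as.character(utils::packageVersion("confshift")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== confshift analysis report ==\n")
  if (!is.null(x$dp4)) {
    print(x$dp4)
    if (!is.null(x$boltzmann)) {
      top <- which.max(x$boltzmann)
      cat(sprintf("Boltzmann: top population %s (%.2f%%)\n",
                  names(x$boltzmann)[top], 100 * x$boltzmann[top]))
    }
  }
  if (!is.null(x$mixture)) {
    print(x$clusters)
    print(x$mixture)
    if (!is.null(x$j_scan)) {
      am <- attr(x$j_scan, "argmin")[1]
      cat(sprintf("Coupling scan: best J-RMSD %.3f Hz at %s\n",
                  x$j_scan$j_rmsd[am],
                  paste(format(unlist(
                    x$j_scan[am, seq_len(ncol(x$j_scan) - 1L)]),
                    trim = TRUE), collapse = ":")))
    }
  }
  invisible(x)
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$dp4)) {
    p <- report$dp4$prob
    utils::write.csv(data.frame(candidate = report$dp4$ids, p,
                                row.names = NULL),
                     file.path(dir, "dp4_probabilities.csv"),
                     row.names = FALSE)
    utils::write.csv(report$errors, file.path(dir, "error_summary.csv"),
                     row.names = FALSE)
    if (!is.null(report$boltzmann))
      utils::write.csv(data.frame(candidate = names(report$boltzmann),
                                  population = unname(report$boltzmann)),
                       file.path(dir, "boltzmann.csv"), row.names = FALSE)
  }
  if (!is.null(report$mixture)) {
    write_mixture_csv(report$mixture, file.path(dir, "mixture_grid.csv"))
    utils::write.csv(report$error_scan, file.path(dir, "error_scan.csv"),
                     row.names = FALSE)
    if (length(report$mixture$ids) >= 3L) {
      tg <- aggregate_ternary(report$mixture)
      utils::write.csv(as.data.frame(tg), file.path(dir, "ternary.csv"),
                       row.names = FALSE)
    }
    if (!is.null(report$j_scan))
      utils::write.csv(report$j_scan, file.path(dir, "j_rmsd_scan.csv"),
                       row.names = FALSE)
    utils::write.csv(data.frame(conformer = names(report$clusters$labels),
                                cluster = unname(report$clusters$labels)),
                     file.path(dir, "clusters.csv"), row.names = FALSE)
  }
  jsonlite::write_json(report$provenance,
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
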