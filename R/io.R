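#' Run configuration
#'
#' Settings shared by the command-line entry points: model variant (the
#' three comparator variants of the dynamic-IKr analysis), cycle lengths,
#' dose grid, beat counts, solver tolerances and seed.
#'
#' @param variant \code{"optimized-dynamic"} (calibrated conductances +
#'   dynamic IKr binding), \code{"dynamic-unoptimized"} (dynamic binding on
#'   the uncalibrated conductance set) or \code{"optimized-static-IC50"}
#'   (calibrated conductances, IKr as static Hill pore block).
#' @param cl_set cycle lengths (ms).
#' @param doses concentration multiples of Cmax.
#' @param n_beats steady-state beats per condition.
#' @param rtol,atol solver tolerances.
#' @param seed random seed (optimizer only; simulations are deterministic).
#' @return List of class \code{"run_config"}.
#' @export
run_config <- function(variant = c("optimized-dynamic",
                                   "dynamic-unoptimized",
                                   "optimized-static-IC50"),
                       cl_set = 2000, doses = standard_dose_grid(),
                       n_beats = 1000, rtol = 1e-6, atol = 1e-6, seed = 1) {
  variant <- match.arg(variant)
  num <- c(cl_set, doses, n_beats, rtol, atol)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all numeric settings must be positive", call. = FALSE)
  structure(list(variant = variant, cl_set = cl_set, doses = doses,
                 n_beats = n_beats, rtol = rtol, atol = atol, seed = seed),
            class = "run_config")
}

#' Read a run configuration from a YAML or key:value file
#'
#' @param path file path; fields as in [run_config()] (missing fields take
#'   the defaults).
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  cfg <- if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::read_yaml(path)
  } else {
    # minimal fallback: "key: value" lines, comma-separated vectors
    ln <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
    kv <- strsplit(ln, ":\\s*")
    stats::setNames(lapply(kv, function(p) {
      v <- strsplit(p[2], ",\\s*")[[1]]
      n <- suppressWarnings(as.numeric(v))
      if (anyNA(n)) v else n
    }), vapply(kv, `[[`, "", 1))
  }
  do.call(run_config, cfg[intersect(names(cfg),
                                    names(formals(run_config)))])
}

## short config fingerprint for output-file headers
.config_hash <- function(config) {
  s <- paste(vapply(config, function(x) paste(format(x), collapse = ","),
                    ""), collapse = ";")
  if (requireNamespace("digest", quietly = TRUE))
    return(substr(digest::digest(s, algo = "sha1"), 1, 12))
  # tiny fallback checksum
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 0xffffffff)
}

#' Write a results table with a provenance header
#'
#' CSV preceded by comment lines (\code{#}) carrying the package version,
#' the config hash and the seed, so every output file is traceable to its
#' run settings.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param config a [run_config()] (or any list) hashed into the header.
#' @return \code{path}, invisibly.
#' @export
write_result_csv <- function(df, path, config = run_config()) {
  hdr <- c(sprintf("# package: cipaord %s",
                   as.character(utils::packageVersion("cipaord"))),
           sprintf("# config_hash: %s", .config_hash(config)),
           sprintf("# seed: %s", format(config$seed)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a results table written by [write_result_csv()]
#'
#' @param path file path.
#' @return Data frame (header comment lines are attached as attribute
#'   \code{"provenance"}).
#' @export
read_result_csv <- function(path) {
  ln <- readLines(path)
  hdr <- ln[startsWith(ln, "#")]
  df <- utils::read.csv(text = ln[!startsWith(ln, "#")],
                        stringsAsFactors = FALSE)
  attr(df, "provenance") <- hdr
  df
}

## baseline parameters + drug-application mode for a config variant
.variant_setup <- function(config) {
  switch(config$variant,
         "optimized-dynamic" = list(params = ord_params(),
                                    static_ikr = FALSE),
         "dynamic-unoptimized" = list(
           params = ord_params(scaling = scaling_original()),
           static_ikr = FALSE),
         "optimized-static-IC50" = list(params = ord_params(),
                                        static_ikr = TRUE))
}

#' Simulation entry point
#'
#' Runs the control and every (drug, dose, CL) condition of the config and
#' writes one metric-panel CSV per cycle length.  EAD/alternans exclusions
#' are logged and flagged in the output.
#'
#' @param config a [run_config()].
#' @param drugs named list of [drug_profile()]s (empty list gives
#'   control-only output).
#' @param out_dir output directory (created if missing).
#' @param quiet suppress progress messages.
#' @return Invisible list of written file paths.
#' @export
cmd_simulate <- function(config, drugs, out_dir = ".", quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vs <- .variant_setup(config)
  paths <- character()
  for (cl in config$cl_set) {
    tab <- metric_panel_table(drugs, doses = config$doses, cl = cl,
                              n_beats = config$n_beats, params = vs$params,
                              static_ikr = vs$static_ikr, quiet = quiet)
    if (any(!tab$valid) && !quiet)
      message("excluded (EAD/alternans): ",
              paste(sprintf("%s@%gx", tab$drug[!tab$valid],
                            tab$conc_multiple[!tab$valid]), collapse = ", "))
    p <- file.path(out_dir, sprintf("metrics_cl%d.csv", as.integer(cl)))
    write_result_csv(tab, p, config)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Classification entry point
#'
#' Builds training-error and leave-one-out tables over a metric/dose grid
#' from a metric-panel CSV.
#'
#' @param metrics_csv path written by [cmd_simulate()].
#' @param drugs named list of [drug_profile()]s carrying risk categories.
#' @param metric_names metric columns to score.
#' @param doses dose grid to score (intersected with the panel's doses).
#' @param out_dir output directory.
#' @param config a [run_config()] for output headers.
#' @return Invisible list with the two tables.
#' @export
cmd_classify <- function(metrics_csv, drugs, metric_names = "qNet",
                         doses = NULL, out_dir = ".",
                         config = run_config()) {
  tab <- substitute_invalid_doses(read_result_csv(metrics_csv))
  if (is.null(doses))
    doses <- setdiff(sort(unique(tab$conc_multiple)), 0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- expand.grid(metric = metric_names, dose = doses,
                      stringsAsFactors = FALSE)
  score <- function(fun) {
    err <- mapply(function(mc, ds) {
      d <- risk_dataset_from_panel(tab, drugs, metric = mc, dose = ds)
      fun(d)$error
    }, grid$metric, grid$dose)
    cbind(grid, error = err)
  }
  train <- score(risk_training_error)
  loo <- score(risk_loo_error)
  write_result_csv(train, file.path(out_dir, "training_error.csv"), config)
  write_result_csv(loo, file.path(out_dir, "loo_error.csv"), config)
  invisible(list(training = train, loo = loo))
}

#' Robustness entry point
#'
#' Computes the IKr-reduction threshold table and the metric/threshold
#' correlation table for a drug panel.
#'
#' @param config a [run_config()].
#' @param drugs named list of [drug_profile()]s.
#' @param metrics_csv optional metric CSV (from [cmd_simulate()], same CL)
#'   to correlate against; skipped when \code{NULL}.
#' @param out_dir output directory.
#' @param precision threshold search precision (percent).
#' @param quiet suppress progress messages.
#' @return Invisible list with \code{thresholds} and (optionally)
#'   \code{correlations}.
#' @export
cmd_threshold <- function(config, drugs, metrics_csv = NULL, out_dir = ".",
                          precision = 0.01, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vs <- .variant_setup(config)
  cl <- config$cl_set[1]
  th <- threshold_table(drugs, config$doses, cl = cl, params = vs$params,
                        precision = precision,
                        n_steady_beats = config$n_beats, quiet = quiet)
  write_result_csv(th, file.path(out_dir, "thresholds.csv"), config)
  out <- list(thresholds = th)
  if (!is.null(metrics_csv)) {
    tab <- read_result_csv(metrics_csv)
    cor_tab <- threshold_correlation_table(tab, th)
    write_result_csv(cor_tab, file.path(out_dir, "correlations.csv"),
                     config)
    out$correlations <- cor_tab
  }
  invisible(out)
}

#' Calibration entry point
#'
#' Runs [optimize_conductances()] against a target CSV and writes the
#' per-generation log and the best scaler set.
#'
#' @param targets_csv calibration target CSV
#'   (see [read_calibration_targets()]).
#' @param out_dir output directory.
#' @param config an [optimizer_config()].
#' @param n_beats beats per objective evaluation.
#' @param quiet suppress progress messages.
#' @return Invisible [optimize_conductances()] result.
#' @export
cmd_calibrate <- function(targets_csv, out_dir = ".",
                          config = optimizer_config(), n_beats = 200,
                          quiet = TRUE) {
  targets <- read_calibration_targets(targets_csv)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- optimize_conductances(targets, config, n_beats = n_beats,
                               quiet = quiet)
  log_df <- data.frame(generation = seq_along(res$trace) - 1,
                       min_cost = res$trace)
  hdr_cfg <- run_config(seed = config$seed)
  write_result_csv(log_df, file.path(out_dir, "calibration_log.csv"),
                   hdr_cfg)
  best <- data.frame(channel = names(res$scaling),
                     scaler = as.numeric(res$scaling))
  write_result_csv(best, file.path(out_dir, "calibrated_scalers.csv"),
                   hdr_cfg)
  invisible(res)
}
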