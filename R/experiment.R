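#' Run configuration
#'
#' A flat list of the knobs of a full benchmarking run: simulation
#' parameters, MICL scheme, model list and cross-validation settings.
#' Serializes to a plain `key = value` text file, so a run can be
#' reproduced from the resolved copy written next to its outputs.
#'
#' @param n_cows,seed,partition_noise_sd_kg Simulation settings (see
#'   [sim_params()]).
#' @param scheme_lo,scheme_hi,scheme_width MICL scheme (see
#'   [micl_scheme()]).
#' @param methods Model ids to benchmark.
#' @param n_folds,n_reps Cross-validation settings.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(n_cows = 3000L, seed = 1L,
                       partition_noise_sd_kg = sim_params()$partition_noise_sd_kg,
                       scheme_lo = 9, scheme_hi = 15, scheme_width = 0.5,
                       methods = c("M0", "M1", "M2A", "M2B", "M3A", "M3B",
                                   "M4", "M5", "M6A", "M6B", "M7A", "M7B"),
                       n_folds = 10L, n_reps = 30L) {
  structure(list(
    n_cows = as.integer(n_cows), seed = as.integer(seed),
    partition_noise_sd_kg = partition_noise_sd_kg,
    scheme_lo = scheme_lo, scheme_hi = scheme_hi, scheme_width = scheme_width,
    methods = methods, n_folds = as.integer(n_folds),
    n_reps = as.integer(n_reps)
  ), class = "run_config")
}

#' @rdname run_config
#' @param path File path of a `key = value` config file; `methods` is a
#'   comma-separated list.
#' @export
read_run_config <- function(path) {
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  args <- list()
  for (i in seq_along(keys)) {
    v <- vals[i]
    args[[keys[i]]] <- if (keys[i] == "methods") {
      trimws(strsplit(v, ",")[[1]])
    } else {
      as.numeric(v)
    }
  }
  do.call(run_config, args[names(args) %in% names(formals(run_config))])
}

#' @rdname run_config
#' @param config A `run_config` object.
#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    paste(k, "=", if (k == "methods") paste(v, collapse = ",") else
      format(v, digits = 17))
  }, "")
  tmp <- paste0(path, ".tmp", Sys.getpid())
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full simulation-and-benchmark experiment
#'
#' Simulates (or loads) a herd, fits every requested model on the full
#' herd, writes their correction-factor tables and coefficient estimates,
#' runs the repeated cross-validation benchmark, and writes the report and
#' factor-versus-midpoint curve data. A resolved copy of the configuration
#' is written next to the outputs; the same configuration and seed
#' reproduce identical files.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @param records Optional pre-loaded milking records; when given, the
#'   simulation step is skipped and `n_cows`/`seed` only govern the
#'   cross-validation fold randomization.
#' @return Invisibly, a list with the output paths, the benchmark `report`
#'   data frame and the full-herd `fits`.
#' @export
run_full_experiment <- function(config = run_config(), out_dir, records = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  scheme <- micl_scheme(config$scheme_lo, config$scheme_hi, config$scheme_width)
  if (is.null(records)) {
    records <- simulate_herd(sim_params(
      n_cows = config$n_cows, seed = config$seed,
      partition_noise_sd_kg = config$partition_noise_sd_kg))
  } else {
    records <- as_milking_records(records)
  }
  paths <- list(
    config = file.path(out_dir, "config.txt"),
    records = file.path(out_dir, "records.csv"),
    factors = file.path(out_dir, "factor_tables.csv"),
    models = file.path(out_dir, "models.txt"),
    report = file.path(out_dir, "report.csv"),
    curves = file.path(out_dir, "factor_curves.csv")
  )
  stage <- "configuration"
  on.exit({
    # a failed stage leaves no partial outputs behind
    for (p in paths) if (file.exists(p)) unlink(p)
  })
  write_run_config(config, paths$config)
  stage <- "simulation"
  write_milking_records(records, paths$records)
  stage <- "model fitting"
  fits <- tryCatch(
    lapply(stats::setNames(config$methods, config$methods), function(m) {
      fit_daily_yield(records, m, scheme = scheme)
    }),
    error = function(e) stop("stage '", stage, "' failed: ",
                             conditionMessage(e), call. = FALSE))
  tables <- Filter(Negate(is.null), lapply(fits, `[[`, "table"))
  if (length(tables)) {
    # harmonize optional columns (only the exponential tables carry rho)
    all_cols <- unique(unlist(lapply(tables, names)))
    all_tab <- do.call(rbind, lapply(tables, function(tb) {
      tb <- as.data.frame(tb)
      for (nm in setdiff(all_cols, names(tb))) tb[[nm]] <- NA_real_
      tb[all_cols]
    }))
    atomic_write_csv(all_tab, paths$factors)
    curves <- all_tab[, c("model_id", "kind", "session", "midpoint_h", "factor")]
    atomic_write_csv(curves[order(curves$model_id, curves$session,
                                  curves$midpoint_h), ], paths$curves)
  }
  cf_fits <- Filter(function(f) !is.null(coef(f)), fits)
  if (length(cf_fits)) {
    lines <- unlist(lapply(cf_fits, function(f) {
      cf <- coef(f)
      cf <- cf[!is.na(cf)]
      c(paste0("[", f$method, "]"),
        sprintf("%s = %.17g", names(cf), cf))
    }))
    writeLines(lines, paths$models)
  }
  stage <- "cross-validation"
  preds <- tryCatch(
    crossvalidate(records, methods = config$methods, scheme = scheme,
                  n_folds = config$n_folds, n_reps = config$n_reps,
                  seed = config$seed),
    error = function(e) stop("stage '", stage, "' failed: ",
                             conditionMessage(e), call. = FALSE))
  report <- eval_report(preds)
  report_rounded <- report
  num <- vapply(report_rounded, is.numeric, TRUE)
  report_rounded[num] <- round(report_rounded[num], 3)
  atomic_write_csv(report_rounded, paths$report)
  on.exit()  # success: keep outputs
  invisible(list(paths = paths, report = report, fits = fits, preds = preds))
}
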