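# File interchange: spectrum CSV (wide, polar), fit-results CSV, feature
# CSV with a JSON sidecar. All floats written with full precision.

#' Write / read cohort measurements as CSV
#'
#' One row per fruit x day: metadata columns then `zmod_*` (Ohm) and
#' `phase_*` (degrees). The frequency grid goes to a JSON companion file
#' `<path>.freq.json` so the CSV stays rectangular.
#'
#' @param meas a `bis_measurements` table.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(meas, path) {
  stopifnot(inherits(meas, "bis_measurements"))
  df <- as.data.frame(meas)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 15, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(freq_hz = attr(meas, "freq")),
                       paste0(path, ".freq.json"), digits = NA)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @param path CSV path written by [write_spectra_csv()].
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".freq.json"), simplifyVector = TRUE)
  attr(df, "freq") <- as.numeric(side$freq_hz)
  class(df) <- c("bis_measurements", "data.frame")
  df
}

#' Write fit results as CSV
#'
#' Schema: `sample_id, day, r_e, q_e, alpha_e, r_ex, r_i, q_m, alpha_m,
#' chi_square, converged`.
#'
#' @param fits an `ecfit_batch` or its `as.data.frame()`.
#' @param path CSV path.
#' @export
write_fits_csv <- function(fits, path) {
  df <- if (inherits(fits, "ecfit_batch")) as.data.frame(fits) else fits
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 15, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a feature table as CSV plus JSON sidecar
#'
#' The CSV holds instance id, label and features; the sidecar
#' (`<path>.meta.json`) records the dataset kind, feature order and any
#' normalisation statistics.
#'
#' @param table a [feature_table].
#' @param path CSV path.
#' @param stats optional normalisation statistics to record.
#' @param seed optional seed to record.
#' @export
write_feature_csv <- function(table, path, stats = NULL, seed = NULL) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(instance = rownames(table$x), storage = table$y,
                   table$x, check.names = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 15, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(kind = table$kind, features = colnames(table$x), seed = seed)
  if (!is.null(stats)) {
    meta$normalization <- list(mean = as.list(stats$mean),
                               sd = as.list(stats$sd))
  }
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full pipeline from a configuration
#'
#' simulate -> fit -> assemble (six datasets) -> benchmark -> report.
#' Configuration is a YAML file or a nested list with optional sections
#' `design` (`n_per_group`), `cohort` (any [cohort_params()] argument),
#' `fit` (`starts`, `topology`, `chi_sq_gate`, `enabled`), `bench`
#' (`families`, `repeats`, `folds`, `train_frac`, `paper_mode`). Every
#' stage seed derives from the single master seed. Outputs (spectrum CSV,
#' fit CSV, six feature CSVs, benchmark CSV/JSON, run manifest) are written
#' under `outdir`.
#'
#' @param config YAML path or list; `NULL` for defaults.
#' @param seed master seed.
#' @param outdir output directory (created if missing); `NULL` skips all
#'   file output.
#' @return list with `cohort`, `fits`, `datasets`, `benchmark`, `manifest`.
#' @export
run_pipeline <- function(config = NULL, seed = 1L, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- config %||% list()
  design <- do.call(study_design, config$design %||% list())
  params <- do.call(cohort_params, config$cohort %||% list())
  fit_cfg <- config$fit %||% list()
  bench_cfg <- config$bench %||% list()
  fit_enabled <- fit_cfg$enabled %||% TRUE

  cohort <- simulate_cohort(seed = seed, design = design, params = params)

  fits <- NULL
  ec_table <- NULL
  if (fit_enabled) {
    fits <- fit_ec_batch(cohort$measurements,
                         starts = fit_cfg$starts %||% 8L,
                         topology = fit_cfg$topology %||% "parallel_electrode",
                         chi_sq_gate = fit_cfg$chi_sq_gate %||% 3e-4,
                         seed = derive_seed(seed, "fit_batch"))
    ec_table <- as.data.frame(fits)
  }
  kinds <- if (fit_enabled) dataset_kinds else
    c("bio-raw", "bio-delta", "bio-delta-diam")
  datasets <- lapply(kinds, function(k) {
    assemble_dataset(cohort, k, ec_table = ec_table)
  })
  names(datasets) <- kinds

  benchmark <- run_benchmark(
    datasets,
    families = bench_cfg$families %||% bis_model_families(),
    seed = derive_seed(seed, "bench"),
    repeats = bench_cfg$repeats %||% 5L,
    folds = bench_cfg$folds %||% 10L,
    train_frac = bench_cfg$train_frac %||% 0.8,
    paper_mode = isTRUE(bench_cfg$paper_mode))

  manifest <- list(
    seed = seed,
    stage_seeds = list(fit = derive_seed(seed, "fit_batch"),
                       bench = derive_seed(seed, "bench")),
    design = list(n_per_group = design$n_per_group, days = design$days,
                  n_freq = length(design$freq)),
    counts = list(samples = nrow(cohort$samples),
                  spectra = nrow(cohort$measurements),
                  instances = nrow(datasets[[1]]$x)),
    fold_signature = benchmark$fold_signature,
    timestamp = format(Sys.time(), tz = "UTC"))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_spectra_csv(cohort$measurements, file.path(outdir, "spectra.csv"))
    if (!is.null(ec_table)) {
      write_fits_csv(ec_table, file.path(outdir, "ec_fits.csv"))
    }
    for (k in names(datasets)) {
      write_feature_csv(datasets[[k]],
                        file.path(outdir, paste0("features_", k, ".csv")),
                        seed = seed)
    }
    utils::write.csv(benchmark$results,
                     file.path(outdir, "benchmark.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(results = benchmark$results,
           accuracies = lapply(benchmark$cv, function(ds)
             lapply(ds, `[[`, "accuracies")),
           p_values = benchmark$p_values,
           settings = benchmark$settings),
      file.path(outdir, "benchmark.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(cohort = cohort, fits = fits, datasets = datasets,
       benchmark = benchmark, manifest = manifest)
}
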