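#' Write the tidy DSE time-series TSV
#'
#' Columns, fixed in name and order: `index`, `abscissa`, `component`,
#' `scope`, `value`; one row per defined series element (E only at the two
#' edges). Indexing is 1-based: pair index t refers to scans (t, t+1).
#'
#' @param dse a `dse_series`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dse_series_tsv <- function(dse, path) {
  utils::write.table(as.data.frame(dse), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

inference_tsv_columns <- c("t", "t_plus_1", "dvars", "sqrt_dvar", "dvar",
                           "pct_dvar", "delta_pct_dvar", "rel_dvars",
                           "x_stat", "p_value", "z_score",
                           "flag_statistical", "flag_practical")

write_inference_tsv <- function(result, path) {
  df <- as.data.frame(result)
  df$t_plus_1 <- df$t + 1L
  utils::write.table(df[, inference_tsv_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a run or experiment configuration (YAML or JSON)
#'
#' YAML files require the `yaml` package; JSON is read with jsonlite.
#'
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Run the full DVARS / DSE quality-control pipeline on one dataset
#'
#' End to end: read the input (4D NIfTI or a delimited voxels-by-time text
#' matrix), center/scale it, compute the DSE time series and variance
#' images, the DSE table, the DVARS chi-squared inference with robust null
#' moments, and write the report bundle into `output_dir`:
#' \itemize{
#'   \item `dse_series.tsv` — tidy time series (12 series);
#'   \item `dse_table.tsv` / `.json` / `.txt` — the DSE summary table;
#'   \item `inference.tsv` — one row per scan pair with all standardized
#'     variants, p, Z, and flags;
#'   \item `flagged_pairs.tsv` — (t, t+1) pairs passing Bonferroni, with the
#'     practical-significance flag;
#'   \item `null_model.json` — mu0, sigma0^2, nu, nu/I, estimator settings;
#'   \item `provenance.json` — package version, configuration, input MD5;
#'   \item `A_var.nii` / `D_var.nii` / `S_var.nii` — variance maps in the
#'     input grid (NIfTI input only);
#'   \item `dse_plot.pdf` — optional DSE plot with flagged stripes.
#' }
#' The run is deterministic: identical inputs give identical outputs. On
#' error, files already written by this run are removed.
#'
#' @param input path to a 4D NIfTI file or to a delimited text matrix
#'   (voxels in rows), or a numeric matrix / `dse_raw` object.
#' @param output_dir directory for the report bundle (created if needed).
#' @param mask optional 3D NIfTI mask path (NIfTI input only).
#' @param scale_mode,target see [scale_center()].
#' @param mu0_method,var_method,d see [estimate_null_model()].
#' @param alpha,delta_threshold,sided see [dvars_inference()].
#' @param write_images write the A/D/S maps (NIfTI input only).
#' @param plot also write `dse_plot.pdf`.
#' @return invisibly, a list with `scaled`, `dse`, `table`, `images`,
#'   `inference`, `null`, and `files` (paths written).
#' @export
run_qc <- function(input, output_dir, mask = NULL,
                   scale_mode = "median", target = 100,
                   mu0_method = "median_dvars2", var_method = "hiqr",
                   d = 1 / 3, alpha = 0.05, delta_threshold = 5,
                   sided = "one", write_images = TRUE, plot = FALSE) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(writer, file) {
    p <- file.path(output_dir, file)
    writer(p)
    written <<- c(written, p)
    p
  }
  input_md5 <- NULL
  tryCatch({
    if (is.character(input)) {
      input_md5 <- unname(tools::md5sum(input))
      raw <- if (grepl("\\.nii(\\.gz)?$", input, ignore.case = TRUE)) {
        read_nifti_4d(input, mask)
      } else {
        as.matrix(utils::read.table(input, header = FALSE))
      }
    } else raw <- input

    scaled <- scale_center(raw, scale_mode = scale_mode, target = target)
    dse <- compute_dse_timeseries(scaled)
    imgs <- compute_dse_images(scaled)
    tab <- dse_table(dse)
    inf <- dvars_inference(dse, data = scaled, mu0_method = mu0_method,
                           var_method = var_method, d = d, alpha = alpha,
                           delta_threshold = delta_threshold, sided = sided)
    null <- attr(inf, "null")

    emit(function(p) write_dse_series_tsv(dse, p), "dse_series.tsv")
    emit(function(p) write_dse_table(tab, p, "tsv"), "dse_table.tsv")
    emit(function(p) write_dse_table(tab, p, "json"), "dse_table.json")
    emit(function(p) write_dse_table(tab, p, "txt"), "dse_table.txt")
    emit(function(p) write_inference_tsv(inf, p), "inference.tsv")
    emit(function(p) utils::write.table(attr(inf, "flagged_pairs"), p,
                                        sep = "\t", quote = FALSE,
                                        row.names = FALSE),
         "flagged_pairs.tsv")
    emit(function(p) jsonlite::write_json(list(
      mu0 = null$mu0, sigma0_sq = null$sigma0_sq, nu = null$nu,
      nu_over_I = null$nu / dse$I, mu0_method = null$mu0_method,
      var_method = null$var_method, d = null$d, alpha = alpha,
      delta_threshold = delta_threshold, sided = sided),
      p, auto_unbox = TRUE, digits = NA), "null_model.json")
    emit(function(p) jsonlite::write_json(list(
      package = "dseqc",
      version = as.character(utils::packageVersion("dseqc")),
      input = if (is.character(input)) input else "<in-memory matrix>",
      input_md5 = input_md5, mask = mask,
      config = list(scale_mode = scale_mode, target = target,
                    mu0_method = mu0_method, var_method = var_method, d = d,
                    alpha = alpha, delta_threshold = delta_threshold,
                    sided = sided),
      I = dse$I, T = dse$T,
      excluded_voxels = nrow(scaled$excluded)),
      p, auto_unbox = TRUE, digits = NA), "provenance.json")

    if (write_images && !is.null(scaled$geometry)) {
      geom <- scaled$geometry
      geom$mask_idx <- geom$mask_idx[scaled$retained]
      emit(function(p) write_nifti(imgs$A_img, p, geometry = geom), "A_var.nii")
      emit(function(p) write_nifti(imgs$D_img, p, geometry = geom), "D_var.nii")
      emit(function(p) write_nifti(imgs$S_img, p, geometry = geom), "S_var.nii")
    }
    if (plot) {
      emit(function(p) {
        grDevices::pdf(p, width = 9, height = 5)
        on.exit(grDevices::dev.off())
        plot(dse, inference = inf)
      }, "dse_plot.pdf")
    }
    invisible(list(scaled = scaled, dse = dse, table = tab, images = imgs,
                   inference = inf, null = null, files = written))
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
}

#' Run simulation experiments from a configuration
#'
#' Drives the bias, validity and power experiments from a config list (or
#' YAML/JSON file; see [read_run_config()]) with top-level keys naming the
#' experiments to run (`bias`, `validity`, `power`), each holding the
#' arguments of the corresponding `run_*_experiment()` function, plus
#' optional `seed` and `output_dir`. Results are written as TSV (and the
#' validity classification as JSON); seeds are logged in the provenance
#' file.
#'
#' @param config named list or path to a YAML/JSON file.
#' @param output_dir output directory, overriding the config's.
#' @return invisibly, list of experiment results.
#' @export
run_experiments <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  output_dir <- output_dir %||% config$output_dir %||% "."
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  known <- intersect(names(config), c("bias", "validity", "power"))
  if (!length(known)) stop("invalid grid: config names no experiment (bias/validity/power)")
  results <- list()
  if (!is.null(config$bias)) {
    args <- config$bias
    args$seed <- args$seed %||% seed
    if (!is.null(args$scenarios))
      args$scenarios <- lapply(args$scenarios, unlist)
    results$bias <- do.call(run_bias_experiment, args)
    utils::write.table(results$bias, file.path(output_dir, "bias.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(config$validity)) {
    args <- config$validity
    spec_args <- args$spec %||% list()
    args$spec <- do.call(simulation_spec, spec_args)
    args$seed <- args$seed %||% seed
    res <- do.call(run_validity_experiment, args)
    results$validity <- res
    summary <- do.call(rbind, lapply(names(res), function(nm) {
      data.frame(setting = nm, alpha = res[[nm]]$rates$alpha,
                 rate = res[[nm]]$rates$rate, se = res[[nm]]$rates$se,
                 ks_stat = res[[nm]]$ks_stat,
                 classification = res[[nm]]$classification)
    }))
    utils::write.table(summary, file.path(output_dir, "validity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      lapply(res, function(r) list(classification = r$classification,
                                   ks_stat = r$ks_stat)),
      file.path(output_dir, "validity.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(config$power)) {
    args <- config$power
    args$seed <- args$seed %||% seed
    results$power <- do.call(run_power_experiment, args)
    utils::write.table(results$power, file.path(output_dir, "power.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(list(
    package = "dseqc",
    version = as.character(utils::packageVersion("dseqc")),
    seed = seed, experiments = known, scaled_settings = TRUE),
    file.path(output_dir, "experiments_provenance.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(results)
}
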