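## ---- report writing ----

## em-dash convention for absent regions in the flat TSV tables
fmt_cell <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x)) "—"
  else format(x, digits = 10, trim = TRUE, scientific = FALSE)
}

#' Write melt-analysis report files
#'
#' Writes a machine-readable JSON report plus a flat TSV table mirroring the
#' layout of the midpoint/thermodynamics summary tables: columns T_m1..T_m3,
#' T_onset, T_I1, T_I2, per-region dH/dS, and the totals. Regions absent from
#' the fit are emitted as JSON null / em-dash cells. The JSON report records
#' the software version, input digest, seed and the full configuration, and
#' flags every reporting convention (Celsius-axis regression, onset
#' construction, T_ref rule) so they cannot be mistaken for measured
#' quantities.
#'
#' @param fit A [melt_fit()] result.
#' @param dir Output directory (created if needed).
#' @param label Sample label; defaults to the signal's metadata label.
#' @param input_digest Optional MD5 of the input file.
#' @param seed Optional integer seed recorded in the report.
#' @return Named character vector with paths \code{report} and
#'   \code{tables}, invisibly.
#' @export
write_results <- function(fit, dir = ".", label = NULL, input_digest = NA,
                          seed = NA) {
  stopifnot(inherits(fit, "melt_fit"))
  if (!length(fit$sigmoids) || !length(fit$regions))
    stopf("empty segmentation result: nothing to write",
          class = "mabtherm_validation_error")
  if (is.null(label))
    label <- if (!is.null(fit$signal) && !is.null(fit$signal$meta))
      fit$signal$meta$label else "sample"
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  pad <- function(x, n) { length(x) <- n; x }
  T_m <- pad(fit$T_m, 3L); T_I <- pad(fit$T_I, 2L)
  reg <- lapply(fit$regions, function(r)
    list(index = r$index, T_m = r$T_m, dH_kJ_mol = r$dH_paper,
         dS_J_K_mol = r$dS, dH_vH_kJ_mol = r$dH_vH,
         se = as.list(r$se), n = r$n))
  report <- list(
    software = list(package = "mabtherm",
                    version = as.character(utils::packageVersion("mabtherm"))),
    input_digest = input_digest, seed = seed,
    config = unclass(fit$control),
    conventions = list(
      dH_reporting = "intercept of the dG-vs-T(degC) regression at 0 degC; dH_vH = T_m(K) x dS reported alongside",
      T_onset = "tangent/threshold construction; a reporting convention, not an instrument reading",
      T_ref = fit$totals$T_ref_rule),
    mode = fit$mode, n = fit$n,
    shape = if (is.null(fit$shape)) NULL else
      list(kind = fit$shape$kind, rmse = fit$shape$rmse,
           candidates = as.list(attr(fit$shape, "candidate_rmse"))),
    T_m = as.list(T_m), T_I = as.list(T_I), T_onset = fit$T_onset,
    regions = reg,
    totals = list(dH_total = fit$totals$dH_total,
                  dS_total = fit$totals$dS_total,
                  dG_total = fit$totals$dG_total,
                  T_ref = fit$totals$T_ref,
                  se = as.list(fit$totals$se)))
  report_path <- file.path(dir, paste0(label, ".report.json"))
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)

  getr <- function(i, fld) if (i <= length(fit$regions)) fit$regions[[i]][[fld]] else NA
  row <- c(label = label,
           stats::setNames(vapply(1:3, function(i) fmt_cell(T_m[i]), ""),
                           paste0("T_m", 1:3)),
           T_onset = fmt_cell(fit$T_onset),
           stats::setNames(vapply(1:2, function(i) fmt_cell(T_I[i]), ""),
                           paste0("T_I", 1:2)),
           stats::setNames(unlist(lapply(1:3, function(i)
             c(fmt_cell(getr(i, "dH_paper")), fmt_cell(getr(i, "dS"))))),
             as.vector(rbind(paste0("dH", 1:3), paste0("dS", 1:3)))),
           dH_total = fmt_cell(fit$totals$dH_total),
           dS_total = fmt_cell(fit$totals$dS_total),
           dG_total = fmt_cell(fit$totals$dG_total))
  tables_path <- file.path(dir, paste0(label, ".tables.tsv"))
  utils::write.table(t(as.matrix(row)), tables_path, sep = "\t",
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(c(report = report_path, tables = tables_path))
}

## ---- pipeline configuration ----

.pipeline_keys <- c("preprocess", "segmentation", "thermo", "sample", "seed")

#' Read and validate a pipeline configuration file
#'
#' YAML with top-level keys \code{preprocess} (see [preprocess_config()]),
#' \code{segmentation} and \code{thermo} (see [melt_control()]),
#' \code{sample} (see [sample_meta()]) and \code{seed}. Unknown keys are
#' rejected.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return A list with elements \code{preprocess} (a
#'   \code{preprocess_config}), \code{control} (a \code{melt_control}),
#'   \code{sample} (a \code{sample_meta} or NULL) and \code{seed}.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), .pipeline_keys)
  if (length(unknown))
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "),
          class = "mabtherm_config_error")
  pp <- do.call(preprocess_config, cfg$preprocess %||% list())
  ctrl_args <- c(cfg$segmentation %||% list(), cfg$thermo %||% list())
  known <- names(formals(melt_control))
  bad <- setdiff(names(ctrl_args), known)
  if (length(bad))
    stopf("unknown segmentation/thermo key(s): %s", paste(bad, collapse = ", "),
          class = "mabtherm_config_error")
  ctrl <- do.call(melt_control, ctrl_args)
  samp <- if (!is.null(cfg$sample)) do.call(sample_meta, cfg$sample) else NULL
  list(preprocess = pp, control = ctrl, sample = samp, seed = cfg$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- end-to-end drivers ----

#' Analyse a melt data file end to end
#'
#' Reads a CD melt file (full temperature x wavelength matrix, or a
#' two-column single-wavelength series), preprocesses matrix input
#' (zeroing, Savitzky-Golay smoothing, MRE conversion when metadata is
#' available), fits the melt-curve model and writes the report files.
#'
#' @param input Path to the input CSV/TSV.
#' @param config Path to a YAML pipeline configuration, or a list (see
#'   [read_pipeline_config()]), or NULL for defaults.
#' @param output_dir Directory for the report files.
#' @param label Sample label for the report file names.
#' @param units Units of the stored input values.
#' @return The [melt_fit()] object, invisibly; report paths in
#'   \code{attr(, "paths")}.
#' @export
analyze_melt <- function(input, config = NULL, output_dir = dirname(input),
                         label = NULL, units = c("MRE", "millidegrees")) {
  units <- match.arg(units)
  cfg <- read_pipeline_config(config %||% list())
  header <- strsplit(readLines(input, n = 1L), "[\t,]")[[1]]
  is_matrix <- length(header) > 2L &&
    !anyNA(suppressWarnings(as.numeric(header[-1L])))
  if (is_matrix) {
    ser <- read_melt_csv(input, units = if (units == "MRE") "MRE" else "millidegrees",
                         meta = cfg$sample)
    ser <- preprocess_cd(ser, cfg$preprocess)
    sig <- extract_wavelength(ser, 218)
  } else {
    sig <- read_melt_signal_csv(input, units = units, meta = cfg$sample)
  }
  fit <- melt_fit(sig, control = cfg$control)
  message(sprintf("mabtherm: %d region(s); conventions: Celsius-axis dH/dS, T_onset %s, T_ref %s",
                  length(fit$sigmoids), cfg$control$onset_mode,
                  fit$totals$T_ref_rule))
  if (is.null(label)) label <- tools::file_path_sans_ext(basename(input))
  paths <- write_results(fit, output_dir, label = label,
                         input_digest = unname(tools::md5sum(input)),
                         seed = cfg$seed %||% NA)
  attr(fit, "paths") <- paths
  invisible(fit)
}

#' Simulate a melt fixture to disk
#'
#' Writes a single-wavelength melt CSV (\code{temperature_C, signal}) plus a
#' ground-truth JSON sidecar recording the generating specification and the
#' seed. The same seed reproduces identical files.
#'
#' @param spec A [melt_spec()] or a [melt_preset()] name.
#' @param seed Integer seed (overrides the spec's).
#' @param out Output CSV path; the sidecar is \code{<out>.truth.json}.
#' @return Named character vector of the written paths, invisibly.
#' @export
simulate_melt <- function(spec = "f1il-like", seed = 42,
                          out = "melt_sim.csv") {
  if (is.character(spec)) spec <- melt_preset(spec, seed = seed)
  stopifnot(inherits(spec, "melt_spec"))
  if (!is.null(seed)) spec$seed <- seed
  sig <- generate_cd_signal(spec)
  df <- data.frame(temperature_C = sig$temperatures, signal = sig$y)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   out, row.names = FALSE, quote = FALSE)
  truth <- attr(sig, "truth")
  sidecar <- paste0(out, ".truth.json")
  jsonlite::write_json(
    list(seed = spec$seed, noise_sd = spec$noise_sd,
         baseline_low = spec$baseline_low, baseline_high = spec$baseline_high,
         transitions = lapply(spec$transitions, unclass),
         f_true = truth$f_true),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(data = out, truth = sidecar))
}

#' Simulate a BLI fixture to disk
#'
#' Writes a sensorgram CSV (\code{time_s, response_nm, phase}) plus a
#' ground-truth JSON sidecar.
#'
#' @param params Kinetic constants (see [generate_sensorgram()]).
#' @param C Analyte concentration, M.
#' @param model \code{"one_to_two"} or \code{"one_to_one"}.
#' @param noise_sd Noise SD, nm.
#' @param seed Integer seed.
#' @param out Output CSV path.
#' @param ... Passed to [generate_sensorgram()].
#' @return Named character vector of the written paths, invisibly.
#' @export
simulate_bli <- function(params, C, model = "one_to_two", noise_sd = 0,
                         seed = 42, out = "bli_sim.csv", ...) {
  sg <- generate_sensorgram(params, C, model = model, noise_sd = noise_sd,
                            seed = seed, ...)
  df <- data.frame(time_s = sg$t, response_nm = sg$R, phase = sg$phase)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   out, row.names = FALSE, quote = FALSE)
  sidecar <- paste0(out, ".truth.json")
  jsonlite::write_json(c(attr(sg, "truth")[c("params", "C", "model",
                                             "model_form", "noise_sd")],
                         list(seed = seed)),
                       sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(data = out, truth = sidecar))
}

#' Read a sensorgram CSV
#'
#' Expects columns \code{time_s, response_nm, phase}.
#'
#' @param path File path.
#' @param C Analyte concentration, M; alternatively supply
#'   \code{conc_mgml} and \code{mw}.
#' @param conc_mgml,mw Mass concentration (mg/mL) and molar mass (g/mol)
#'   used when \code{C} is missing.
#' @return A [sensorgram()].
#' @export
read_sensorgram_csv <- function(path, C = NULL, conc_mgml = 0.96,
                                mw = 146000) {
  if (!file.exists(path))
    stopf("file '%s' does not exist", path, class = "mabtherm_io_error")
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!nrow(df) || ncol(df) < 3L)
    stopf("'%s': expected columns time_s, response_nm, phase", path,
          class = "mabtherm_parse_error")
  if (is.null(C)) C <- mass_to_molar(conc_mgml, mw)
  sensorgram(as.numeric(df[[1L]]), as.numeric(df[[2L]]),
             trimws(as.character(df[[3L]])), C)
}

#' Fit a sensorgram file under both binding models
#'
#' Reads a sensorgram CSV, fits both the 1:1 and 1:2 models, and (optionally)
#' writes a JSON report including both models' parameters and RMSE so the
#' model comparison is explicit. When the 1:2 fit improves RMSE by less than
#' 5% over the 1:1 fit the report flags likely over-parameterisation.
#'
#' @inheritParams read_sensorgram_csv
#' @param out Optional JSON report path.
#' @return A list with elements \code{one_to_one}, \code{one_to_two} (both
#'   [bli_fit()] objects) and \code{report} (the report list).
#' @export
fit_bli_file <- function(path, C = NULL, conc_mgml = 0.96, mw = 146000,
                         out = NULL) {
  sg <- read_sensorgram_csv(path, C = C, conc_mgml = conc_mgml, mw = mw)
  f1 <- bli_fit(sg, "one_to_one")
  f2 <- bli_fit(sg, "one_to_two")
  report <- list(
    input = path, C = sg$C,
    one_to_one = c(f1$params, list(KD = f1$KD, rmse = f1$rmse,
                                   converged = f1$converged)),
    one_to_two = c(f2$params, list(KD = f2$KD, rmse = f2$rmse,
                                   converged = f2$converged)),
    preferred = if (f2$rmse < 0.95 * f1$rmse) "one_to_two" else "one_to_one",
    overparameterised = f2$rmse >= 0.95 * f1$rmse)
  if (!is.null(out))
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  list(one_to_one = f1, one_to_two = f2, report = report)
}
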