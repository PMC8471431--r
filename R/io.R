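#' Write a baseband record as CSV plus JSON sidecar
#'
#' The waveform goes to `<patient_id>.csv` with columns `time_s`,
#' `amplitude` (full double precision); acquisition metadata (`patient_id`,
#' `fs_hz`, `flow_mL_min`, and the radar parameters used, when supplied) go
#' to `<patient_id>.json`. Sidecar fields round-trip bit-exactly.
#'
#' @param x A `baseband_signal`.
#' @param dir Output directory (created if missing).
#' @param radar A `radar_params` to record in the sidecar, or `NULL`.
#' @return Invisibly, the two file paths.
#' @export
write_baseband <- function(x, dir, radar = NULL) {
  stopifnot(inherits(x, "baseband_signal"), !is.na(x$patient_id))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  csv <- file.path(dir, paste0(x$patient_id, ".csv"))
  json <- file.path(dir, paste0(x$patient_id, ".json"))
  df <- data.frame(time_s = x$t, amplitude = x$b)
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   csv, row.names = FALSE, quote = FALSE)
  side <- list(patient_id = x$patient_id, fs_hz = x$fs,
               flow_mL_min = x$flow_mL_min)
  if (!is.null(radar)) side$radar <- unclass(radar)
  jsonlite::write_json(side, json, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(csv = csv, json = json))
}

#' Read a baseband record written by [write_baseband()]
#'
#' @param path Path to the `.csv` waveform file (the `.json` sidecar is
#'   looked up next to it) or to the `.json` sidecar.
#' @return A `baseband_signal` with attribute `radar` when the sidecar
#'   recorded the radar parameters.
#' @export
read_baseband <- function(path) {
  base <- sub("\\.(csv|json)$", "", path)
  csv <- paste0(base, ".csv"); json <- paste0(base, ".json")
  if (!file.exists(csv)) stop("waveform file not found: ", csv)
  if (!file.exists(json)) stop("sidecar file not found: ", json)
  df <- utils::read.csv(csv)
  if (!all(c("time_s", "amplitude") %in% names(df)))
    stop("malformed waveform CSV (need columns time_s, amplitude): ", csv)
  tt <- suppressWarnings(as.numeric(df$time_s))
  bb <- suppressWarnings(as.numeric(df$amplitude))
  if (anyNA(tt) || anyNA(bb)) {
    bad <- which(is.na(tt) | is.na(bb))[1]
    stop("malformed waveform row in ", csv, " at data line ", bad)
  }
  df <- data.frame(time_s = tt, amplitude = bb)
  side <- jsonlite::read_json(json)
  x <- baseband_signal(df$time_s, df$amplitude, as.numeric(side$fs_hz),
                       side$patient_id,
                       ifelse(is.null(side$flow_mL_min), NA_real_,
                              as.numeric(side$flow_mL_min)))
  if (!is.null(side$radar)) attr(x, "radar") <- side$radar
  x
}

#' Write / read the cohort manifest
#'
#' @param manifest Manifest data.frame (see [simulate_cohort()]).
#' @param path CSV path.
#' @return `write_manifest`: the path, invisibly. `read_manifest`: the
#'   data.frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(format(manifest, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) utils::read.csv(path)

#' Write / read the harmonic-ratio feature table
#'
#' @param features Feature table from [feature_table()].
#' @param path CSV path.
#' @return `write_features`: the path, invisibly. `read_features`: the
#'   data.frame (schema-checked).
#' @export
write_features <- function(features, path) {
  utils::write.csv(format(features, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path)
  needed <- c("patient_id", "flow_mL_min", "f0_hz", paste0("P", 1:6),
              hr_feature_names())
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("feature table schema mismatch; missing columns: ",
         paste(missing, collapse = ", "))
  df
}

#' Write a per-cutoff metrics report as JSON
#'
#' @param report One element of `threshold_sweep(...)$reports`.
#' @param path JSON path.
#' @return The path, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  out <- list(cutoff = report$cutoff,
              confusion = list(tp = report$confusion$tp,
                               fn = report$confusion$fn,
                               fp = report$confusion$fp,
                               tn = report$confusion$tn),
              sensitivity_pct = report$sensitivity_pct,
              specificity_pct = report$specificity_pct,
              accuracy_pct = report$accuracy_pct,
              ppv_pct = report$ppv_pct, auc = report$auc,
              seed = report$seed, k = report$k)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Simulate a cohort to disk
#'
#' Pipeline front end: generates a synthetic cohort and writes one
#' CSV+JSON waveform pair per patient plus `manifest.csv` and a
#' `run_metadata.json` (seed, n, package version).
#'
#' @param out_dir Output directory.
#' @param n Number of patients.
#' @param seed Integer seed.
#' @param pp,tp,p Simulation parameter objects.
#' @return Invisibly, the cohort object.
#' @export
cli_simulate <- function(out_dir, n = 45, seed = 1, pp = physio_params(),
                         tp = turbulence_params(), p = radar_params()) {
  if (n < 1) stop("n must be a positive count")
  cohort <- simulate_cohort(cohort_spec(n_patients = n, seed = seed),
                            pp = pp, tp = tp, p = p)
  for (r in cohort$records) write_baseband(r, out_dir, radar = p)
  write_manifest(cohort$manifest, file.path(out_dir, "manifest.csv"))
  jsonlite::write_json(
    list(seed = seed, n_patients = n,
         package_version = as.character(utils::packageVersion("vwmflow"))),
    file.path(out_dir, "run_metadata.json"), auto_unbox = TRUE)
  invisible(cohort)
}

#' Extract features from a directory of waveform records
#'
#' @param waveform_dir Directory of CSV+JSON record pairs.
#' @param out_csv Optional path for the feature table CSV.
#' @param fspec Band-pass specification, or `NULL` to skip conditioning.
#' @return The feature table (with `rejections` attribute); rejected
#'   records are reported via `message()`.
#' @export
cli_features <- function(waveform_dir, out_csv = NULL,
                         fspec = filter_spec()) {
  files <- sort(list.files(waveform_dir, pattern = "\\.csv$",
                           full.names = TRUE))
  files <- files[basename(files) != "manifest.csv"]
  if (!length(files)) stop("no waveform CSV files in ", waveform_dir)
  records <- lapply(files, read_baseband)
  feats <- feature_table(records, fspec = fspec)
  rej <- attr(feats, "rejections")
  if (nrow(rej))
    message("rejected ", nrow(rej), " record(s): ",
            paste(rej$patient_id, "-", rej$reason, collapse = "; "))
  if (!is.null(out_csv)) write_features(feats, out_csv)
  feats
}

#' Screen and classify a feature table across cutoffs
#'
#' Produces the screening report (one CSV per cutoff), a metrics JSON per
#' cutoff, a decision-value table CSV, and ROC points CSV. A cutoff that
#' leaves one class empty is reported as an error entry while the other
#' cutoffs are still produced.
#'
#' @param features Feature table (data.frame or path to its CSV).
#' @param out_dir Output directory.
#' @param cutoffs Detection cutoffs (mL/min).
#' @param k Cross-validation folds.
#' @param seed Integer seed.
#' @return Invisibly, the `threshold_sweep` object.
#' @export
cli_evaluate <- function(features, out_dir, cutoffs = c(600, 750), k = 10,
                         seed = 1) {
  if (is.character(features)) features <- read_features(features)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  sweep <- threshold_sweep(features, cutoffs = cutoffs, k = k, seed = seed)
  for (co in names(sweep$reports)) {
    rep <- sweep$reports[[co]]
    if (!is.null(rep$error)) {
      message("cutoff ", co, " mL/min failed: ", rep$error)
      next
    }
    scr <- screen_features(features, cutoff = rep$cutoff)
    utils::write.csv(scr, file.path(out_dir,
                                    paste0("screening_", co, ".csv")),
                     row.names = FALSE)
    write_metrics_json(rep, file.path(out_dir,
                                      paste0("metrics_", co, ".json")))
    utils::write.csv(data.frame(patient_id = rep$patient_id,
                                decision_value = rep$decision_values,
                                flow_mL_min = features$flow_mL_min),
                     file.path(out_dir, paste0("decision_values_", co,
                                               ".csv")),
                     row.names = FALSE)
    cohort <- label_cohort(features, cutoff = rep$cutoff)
    roc <- roc_analysis(cohort$label,
                        rep$decision_values)
    utils::write.csv(roc$curve, file.path(out_dir,
                                          paste0("roc_", co, ".csv")),
                     row.names = FALSE)
  }
  invisible(sweep)
}
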