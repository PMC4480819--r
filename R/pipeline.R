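#' Pipeline run configuration
#'
#' @param activity_gbq Administered Y-90 activity in GBq (>= 0).
#' @param threshold_maa,threshold_sc Fractional thresholds in (0, 1),
#'   default 0.10 each.
#' @param maa_scale Scale for the MAA subtraction (default 1).
#' @param prior_dose_gy Prior mean liver dose in Gy (default 0).
#' @param seed Optional integer seed echoed into outputs.
#' @param output_dir Directory for artifacts (created if missing).
#' @return A list of class `run_config`.
#' @export
run_config <- function(activity_gbq, threshold_maa = 0.10, threshold_sc = 0.10,
                       maa_scale = 1, prior_dose_gy = 0, seed = NULL,
                       output_dir = ".") {
  if (activity_gbq < 0) stop("`activity_gbq` must be non-negative")
  for (th in c(threshold_maa, threshold_sc))
    if (th <= 0 || th >= 1) stop("thresholds must lie in (0, 1)")
  if (prior_dose_gy < 0) stop("`prior_dose_gy` must be non-negative")
  structure(list(activity_gbq = activity_gbq,
                 threshold_maa = threshold_maa, threshold_sc = threshold_sc,
                 maa_scale = maa_scale, prior_dose_gy = prior_dose_gy,
                 seed = seed, output_dir = output_dir),
            class = "run_config")
}

#' End-to-end segmentation and dosimetry run
#'
#' Orchestrates the full chain on a co-registered TcMAA/TcSC pair: dual-tracer
#' segmentation, compartment volumes, MIRD dose report, and the
#' dose-threshold planning recommendation. Writes the label volume as NIfTI
#' plus JSON volume and dose reports (doses serialized to 0.1 Gy) and a plain
#' log echoing the configuration. Inputs may be [spect_volume()] objects or
#' NIfTI paths.
#'
#' @param config A [run_config()].
#' @param maa,sc TcMAA and TcSC volumes or NIfTI file paths.
#' @return The [dose_report()] (with the recommendation attached as
#'   `$recommendation`), invisibly.
#' @export
run_pipeline <- function(config, maa, sc) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(maa)) maa <- read_spect_nifti(maa, "TcMAA")
  if (is.character(sc)) sc <- read_spect_nifti(sc, "TcSC")
  check_coregistered(maa, sc)

  seg <- segment_dual_tracer(maa, sc,
                             threshold_maa = config$threshold_maa,
                             threshold_sc = config$threshold_sc,
                             maa_scale = config$maa_scale)
  report <- dose_report(seg$labels, maa, config$activity_gbq)
  rec <- planning_recommendation(report, config$prior_dose_gy)
  report$recommendation <- rec

  out <- config$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  write_labels_nifti(seg$labels, file.path(out, "compartment_labels.nii.gz"))
  write_report_json(volume_report_list(seg$volumes),
                    file.path(out, "volume_report.json"))
  write_report_json(dose_report_list(report, config),
                    file.path(out, "dose_report.json"))
  writeLines(c("dualspect pipeline run",
               sprintf("version: %s", as.character(utils::packageVersion("dualspect"))),
               sprintf("activity_gbq: %.6g", config$activity_gbq),
               sprintf("threshold_maa: %.6g", config$threshold_maa),
               sprintf("threshold_sc: %.6g", config$threshold_sc),
               sprintf("maa_scale: %.6g", config$maa_scale),
               sprintf("prior_dose_gy: %.6g", config$prior_dose_gy),
               sprintf("seed: %s", if (is.null(config$seed)) "none" else config$seed)),
             file.path(out, "run_log.txt"))
  invisible(report)
}

# Stable JSON serialization: fixed field order, fixed precision, so identical
# inputs give byte-identical files.
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(6), pretty = TRUE)
  invisible(path)
}

volume_report_list <- function(v) {
  list(units = "mL",
       V_T = round(v$V_T, 2), V_FL_IR = round(v$V_FL_IR, 2),
       V_FL_UN = round(v$V_FL_UN, 2), V_FL_TOT = round(v$V_FL_TOT, 2),
       V_NULL = round(v$V_NULL, 2), V_TOTAL_LIVER = round(v$V_TOTAL_LIVER, 2),
       fractional_volumes = as.list(round(v$fractional_volumes, 4)))
}

dose_report_list <- function(report, config = NULL) {
  out <- list(
    units = list(dose = "Gy", activity = "GBq", volume = "mL"),
    administered_activity_gbq = report$administered_activity_gbq,
    D_T = round(report$D_T, 1),
    D_FL_IR = round(report$D_FL_IR, 1),
    D_FL_TOT = round(report$D_FL_TOT, 1),
    D_FL_UN = round(report$D_FL_UN, 1),
    ratio_T_FL = if (is.na(report$ratio_T_FL)) NULL else round(report$ratio_T_FL, 3),
    activity_fractions = as.list(round(report$activity_fractions, 4)),
    volumes = volume_report_list(report$volumes))
  if (!is.null(report$recommendation)) out$recommendation <- report$recommendation
  if (!is.null(config))
    out$config <- list(threshold_maa = config$threshold_maa,
                       threshold_sc = config$threshold_sc,
                       maa_scale = config$maa_scale,
                       prior_dose_gy = config$prior_dose_gy)
  out
}
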