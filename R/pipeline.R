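# Orchestration: reproduce the four-field irradiation study end-to-end on
# synthetic data - beam model, synthetic readouts, processing, dose and LET
# calibration, quenching correction - and emit the summary statistics.

#' Default study configuration
#'
#' The four proton fields of the study design: a 230 MeV dose-calibration
#' field read at 2 cm PMMA with doses 0.1-1.1 Gy; a 70 MeV single energy
#' layer (positions from 1 cm PMMA to just proximal of the Bragg peak); and
#' two SOBPs (73-112 MeV, 4 cm plateau; 120-177 MeV, 8.5 cm plateau) with
#' positions from the entrance region to near the distal edge, 1 Gy at the
#' plateaus. Deep positions are capped just proximal of each beam's distal
#' edge so every package sees proton fluence.
#'
#' @param seed Study RNG seed.
#' @return A plain (YAML-serializable) nested list.
#' @export
default_study_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    truth = list(),  # truth_model() defaults
    fields = list(
      list(name = "d1", energy_min = 230, energy_max = 230,
           depths_pmma = 2.0, plateau_dose = 1.0,
           cal_doses = c(0.1, 0.3, 0.5, 0.7, 0.9, 1.1)),
      list(name = "f1", energy_min = 70, energy_max = 70,
           depths_pmma = seq(1.0, 3.45, length.out = 6),
           plateau_dose = 1.0),
      list(name = "f2", energy_min = 73, energy_max = 112,
           energy_spacing = 1, sobp_width = 4.0,
           depths_pmma = seq(2.0, 8.0, length.out = 9),
           plateau_dose = 1.0),
      list(name = "f3", energy_min = 120, energy_max = 177,
           energy_spacing = 1, sobp_width = 8.5,
           depths_pmma = seq(5.0, 17.9, length.out = 9),
           plateau_dose = 1.0)
    )
  )
}

#' Read / write a study configuration as YAML
#'
#' @param path YAML file path.
#' @param config A configuration list.
#' @return The configuration list (`read_study_config`) or the path.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$seed), length(cfg$fields) >= 1L)
  cfg
}

#' @rdname read_study_config
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# materialize proton_field objects from the config, sharing one table
build_study_fields <- function(config, table = stopping_power_table()) {
  lapply(config$fields, function(f) {
    spacing <- if (is.null(f$energy_spacing)) 1 else f$energy_spacing
    energies <- if (f$energy_min == f$energy_max) f$energy_min else
      seq(f$energy_min, f$energy_max, by = spacing)
    proton_field(
      name = f$name, energies = energies,
      depths_pmma = f$depths_pmma,
      sobp_width = f$sobp_width,
      plateau_dose = if (is.null(f$plateau_dose)) 1 else f$plateau_dose,
      cal_doses = f$cal_doses,
      table = table
    )
  })
}

build_truth <- function(config) {
  do.call(truth_model, config$truth)
}

# package-level aggregate of a detector-table column
aggregate_by_package <- function(det, column) {
  ids <- unique(det$package_id)
  out <- lapply(ids, function(pid) {
    pm <- package_aggregate(det[[column]][det$package_id == pid])
    data.frame(package_id = pid, mean = pm$mean, sd = pm$sd, sem = pm$sem,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

sem_weights <- function(sem) {
  if (all(is.finite(sem)) && all(sem > 0)) sem else NULL
}

#' Run the complete synthetic study
#'
#' Executes the full measurement chain: beam-model dose and f-LET at every
#' OSLD position, synthetic pulsed readouts, band separation and reference
#' correction, dose calibration from the 230 MeV series, LET calibration
#' from all packages (package-SEM weighted), per-detector LET and quenched
#' dose estimates, the relative-efficiency curve from the SOBP-plateau
#' packages (single-energy-layer points omitted, as their Bragg-peak
#' positioning is misalignment-sensitive), and quenching-corrected doses.
#' Fully deterministic for a given seed.
#'
#' @param config Configuration list, see [default_study_config()].
#' @param noise Poisson counting noise on (`TRUE`) or off.
#' @param cv Inter-detector sensitivity CV (default: the truth model's).
#' @param use_reference Use reference-corrected UV/blue ratios for the LET
#'   chain (`TRUE`, the standard procedure) or raw ratios (`FALSE`,
#'   fitted with the saturating-exponential form).
#' @return An object of class `"study_report"`: list with `packages`
#'   (per-package records), `detectors` (per-detector results), `spreads`,
#'   `summary`, and the fitted `dose_fit`, `let_fit`, `efficiency`.
#' @export
run_full_study <- function(config = default_study_config(), noise = TRUE,
                           cv = NULL, use_reference = TRUE) {
  table <- stopping_power_table()
  truth <- build_truth(config)
  if (is.null(cv)) cv <- truth$cv
  fields <- build_study_fields(config, table)
  dataset <- generate_study(fields, truth, seed = config$seed, noise = noise,
                            cv = cv)
  det <- merge(process_dataset(dataset), dataset$packages,
               by = "package_id", sort = FALSE)
  det <- det[order(det$package_id, det$detector_id), ]

  # package membership flags
  meta <- dataset$packages
  meta$is_cal <- meta$field == fields[[1L]]$name &
    !is.null(fields[[1L]]$cal_doses)
  meta$is_plateau <- FALSE
  for (f in fields) {
    if (is.null(f$sobp_width)) next
    lo <- (f$distal - f$sobp_width) / f$rsp
    meta$is_plateau <- meta$is_plateau |
      (meta$field == f$name & meta$depth_pmma >= lo)
  }

  # dose calibration from the calibration series (blue S/S_R vs dose)
  cal_ids <- meta$package_id[meta$is_cal]
  agg_sb <- aggregate_by_package(det, "sb_over_ref")
  cal_rows <- agg_sb[match(cal_ids, agg_sb$package_id), ]
  cal_doses <- meta$true_dose[match(cal_ids, meta$package_id)]
  dose_fit <- calibrate_dose(cal_rows$mean, cal_doses,
                             sem_weights(cal_rows$sem))

  # LET calibration from all packages
  ratio_col <- if (use_reference) "ratio_corrected" else "ratio_raw"
  agg_ratio <- aggregate_by_package(det, ratio_col)
  agg_ratio <- agg_ratio[match(meta$package_id, agg_ratio$package_id), ]
  let_fit <- calibrate_let(agg_ratio$mean, meta$true_let,
                           sem_weights(agg_ratio$sem),
                           corrected = use_reference)

  # per-detector estimates
  det$ratio_used <- det[[ratio_col]]
  det$let_est <- vapply(det$ratio_used, function(r) {
    tryCatch(estimate_let(let_fit, r), error = function(e) NA_real_)
  }, numeric(1))
  det$dose_quenched <- vapply(det$sb_over_ref, function(s) {
    tryCatch(estimate_quenched_dose(dose_fit, s), error = function(e) NA_real_)
  }, numeric(1))

  # efficiency curve from SOBP-plateau packages plus the calibration point
  cal_ratio <- mean(det$ratio_corrected[det$package_id %in% cal_ids])
  pl_ids <- meta$package_id[meta$is_plateau]
  agg_dq <- aggregate_by_package(det, "dose_quenched")
  agg_rc <- aggregate_by_package(det, "ratio_corrected")
  pl_dq <- agg_dq$mean[match(pl_ids, agg_dq$package_id)]
  pl_rc <- agg_rc$mean[match(pl_ids, agg_rc$package_id)]
  pl_dose <- meta$true_dose[match(pl_ids, meta$package_id)]
  efficiency <- build_efficiency(pl_dq, pl_dose, pl_rc, cal_ratio)

  det$eta <- efficiency_at(efficiency, det$ratio_corrected)
  det$dose_corrected <- det$dose_quenched / det$eta

  # per-package records
  records <- meta
  for (col in c("let_est", "dose_quenched", "dose_corrected", "eta",
                "ratio_used")) {
    agg <- aggregate_by_package(det, col)
    agg <- agg[match(meta$package_id, agg$package_id), ]
    records[[paste0(col, "_mean")]] <- agg$mean
    records[[paste0(col, "_sd")]] <- agg$sd
    records[[paste0(col, "_sem")]] <- agg$sem
  }
  records$let_sem <- vapply(seq_len(nrow(records)), function(i) {
    tryCatch(
      propagate_let_uncertainty(let_fit, records$ratio_used_mean[i],
                                agg_ratio$sem[i]),
      error = function(e) NA_real_
    )
  }, numeric(1))
  records$let_dev_pct <- 100 *
    (records$let_est_mean - records$true_let) / records$true_let
  records$dose_dev <- records$dose_corrected_mean - records$true_dose

  spreads <- spread_report(det)
  summary <- recompute_summary(records)

  structure(
    list(
      packages = records, detectors = det, spreads = spreads,
      summary = summary, dose_fit = dose_fit, let_fit = let_fit,
      efficiency = efficiency, config = config
    ),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<study_report> %d packages; mean |LET deviation| %.2f%% ",
      "(mixed doses), %.2f%% (1 Gy plateaus)\n"
    ),
    nrow(x$packages), x$summary$mean_abs_let_dev_pct,
    x$summary$mean_abs_let_dev_pct_equal_dose
  ))
  invisible(x)
}

#' Recompute the summary statistics from the per-package records
#'
#' The summary is a pure function of the records table: mean absolute LET
#' deviation over packages with true f-LET in the calibrated 0.6-6.5
#' keV/um range (mixed doses), the same for the equal-dose (1 Gy SOBP
#' plateau) subset, and the plateau dose-recovery statistics.
#'
#' @param records The `packages` element of a [run_full_study()] report.
#' @return List of summary statistics.
#' @export
recompute_summary <- function(records) {
  in_range <- is.finite(records$let_est_mean) &
    records$true_let >= 0.6 & records$true_let <= 6.5
  equal <- in_range & records$is_plateau
  pl <- records$is_plateau
  list(
    n_packages = nrow(records),
    mean_abs_let_dev_pct = mean(abs(records$let_dev_pct[in_range])),
    mean_abs_let_dev_pct_equal_dose = mean(abs(records$let_dev_pct[equal])),
    n_mixed = sum(in_range), n_equal_dose = sum(equal),
    plateau_dose_dev_over_sd = mean(
      abs(records$dose_dev[pl]) / records$dose_corrected_sd[pl]
    ),
    max_plateau_dose_dev_over_sd = max(
      abs(records$dose_dev[pl]) / records$dose_corrected_sd[pl]
    )
  )
}

#' Detector-spread report
#'
#' Pooled deviation-from-package-mean spreads (sample SD) of the raw and
#' reference-corrected quantities: the per-band integrals S, the corrected
#' S/S_R, and the raw and corrected UV/blue ratios.
#'
#' @param det Per-detector results (the `detectors` element of a report, or
#'   a [process_dataset()] table).
#' @return Named list of spread sigmas (fractions).
#' @export
spread_report <- function(det) {
  if (length(unique(det$package_id)) < 10L) {
    stop("spread report needs at least 10 packages")
  }
  sp <- function(col) deviation_spread(det[[col]], det$package_id)$sigma
  list(
    sigma_s_blue = sp("s_blue"),
    sigma_s_uv = sp("s_uv"),
    sigma_sb_over_ref = sp("sb_over_ref"),
    sigma_suv_over_ref = sp("suv_over_ref"),
    sigma_ratio_raw = sp("ratio_raw"),
    sigma_ratio_corrected = sp("ratio_corrected")
  )
}

#' Export a study report
#'
#' Writes the per-package and per-detector tables as CSV, the summary and
#' spreads as JSON, and the calibration fits as JSON, with deterministic
#' ordering; re-exporting an identical report reproduces identical files.
#'
#' @param report A [run_full_study()] report.
#' @param dir Output directory (created if missing).
#' @return Vector of written paths, invisibly.
#' @export
export_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
    message("created output directory ", dir)
  }
  paths <- c(
    packages = file.path(dir, "packages.csv"),
    detectors = file.path(dir, "detectors.csv"),
    summary = file.path(dir, "summary.json"),
    dose_fit = file.path(dir, "dose_calibration.json"),
    let_fit = file.path(dir, "let_calibration.json")
  )
  utils::write.csv(report$packages, paths[["packages"]], row.names = FALSE)
  utils::write.csv(report$detectors, paths[["detectors"]], row.names = FALSE)
  jsonlite::write_json(
    list(summary = report$summary, spreads = report$spreads),
    paths[["summary"]], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  write_calibration(report$dose_fit, paths[["dose_fit"]],
                    created_from = "dose calibration series")
  write_calibration(report$let_fit, paths[["let_fit"]],
                    created_from = "LET calibration, all packages")
  invisible(paths)
}
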