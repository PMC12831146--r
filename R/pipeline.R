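#' Default pipeline configuration
#'
#' A single declarative configuration covering every tunable of the
#' simulate/quantify/stats pipeline: scan geometry, Phansalkar constants
#' (23.4-um radius), large-vessel masking, the 250-um ring width, the
#' 0.1-mm^2 VFD grid unit, the scene and cohort generators, and the model
#' formula sets (univariable screen set and one multivariable model over
#' age, AXL, SE, CT, global CCFD%, PSV area and VFD).
#'
#' @param seed Integer seed recorded in the config and used by `simulate`.
#' @return A nested list; write it with [yaml::write_yaml()] and load a
#'   user-edited copy with [load_config()].
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    geometry = list(scan_mm = 6, raster_px = 1024L),
    phansalkar = list(radius_um = 23.4, k = 0.25, r = 0.5, p = 2, q = 10),
    masking = list(dilation_um = 50, opening_um = 10),
    ring_width_um = 250,
    vfd_unit_area_mm2 = 0.1,
    scene = list(deficit_fraction_target = 0.18,
                 attenuation_amplitude = 0.3,
                 n_psv = 3L, noise_sd = 0.02),
    cohort = list(n_subjects = 31L, p_both_eyes = 0.68,
                  psv_per_eye_mean = 2.3, confound_axl_ccfd = 0.47,
                  sd_subject = 4, sd_eye = 2.5, sd_resid = 5),
    stats = list(
      response = "fd_psv",
      univariable = c("age_y", "axl_mm", "se_d", "ct_um",
                      "global_ccfd_pct", "area_mm2", "vfd_mm"),
      multivariable = c("age_y", "axl_mm", "se_d", "ct_um",
                        "global_ccfd_pct", "area_mm2", "vfd_mm"),
      power_term = "axl_mm")
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and fills any missing keys from [default_config()];
#' unknown predictor names in the stats section are rejected.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @param seed Optional seed override.
#' @return A configuration list.
#' @export
load_config <- function(path = NULL, seed = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  schema <- c("age_y", "axl_mm", "se_d", "ct_um", "ct_axl",
              "global_ccfd_pct", "area_mm2", "vfd_mm", "fd_psv", "fd_250")
  bad <- setdiff(c(cfg$stats$univariable, cfg$stats$multivariable,
                   cfg$stats$response), schema)
  if (length(bad)) {
    stop("unknown cohort columns in stats config: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(cfg, f)
  unname(tools::md5sum(f))
}

#' Simulate a scene + cohort fixture bundle
#'
#' Writes a complete, self-describing fixture bundle: 16-bit TIFF flow /
#' structure / superficial images, PNG truth and PSV label masks, the
#' simulated cohort CSV, and a JSON manifest recording the seed, geometry,
#' truth parameters and config hash.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_simulate <- function(config = default_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sp <- scene_params(
    raster_px = config$geometry$raster_px,
    scan_mm = config$geometry$scan_mm,
    deficit_fraction_target = config$scene$deficit_fraction_target,
    attenuation_amplitude = config$scene$attenuation_amplitude,
    n_psv = config$scene$n_psv,
    noise_sd = config$scene$noise_sd,
    seed = config$seed)
  scene <- generate_cc_scene(sp)
  write_enface(scene$flow, file.path(out_dir, "flow.tif"))
  write_enface(scene$structure, file.path(out_dir, "structure.tif"))
  write_enface(scene$superficial, file.path(out_dir, "superficial.tif"))
  write_mask(scene$truth_deficit, file.path(out_dir, "truth_deficit.png"))
  write_mask(scene$vessel_truth, file.path(out_dir, "vessel_truth.png"))
  png::writePNG(scene$psv_labels / 255, file.path(out_dir, "psv_labels.png"))

  cp <- cohort_params(
    n_subjects = config$cohort$n_subjects,
    p_both_eyes = config$cohort$p_both_eyes,
    psv_per_eye_mean = config$cohort$psv_per_eye_mean,
    sd_subject = config$cohort$sd_subject,
    sd_eye = config$cohort$sd_eye,
    sd_resid = config$cohort$sd_resid,
    confound_axl_ccfd = config$cohort$confound_axl_ccfd,
    seed = config$seed)
  cohort <- generate_cohort(cp)
  write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)

  manifest <- list(
    scene_id = sprintf("scene-%08d", config$seed),
    seed = config$seed,
    config_hash = config_hash(config),
    geometry = list(scan_mm = sp$scan_mm, raster_px = sp$raster_px),
    fovea_xy = scene$fovea_xy,
    truth = list(deficit_fraction_target = sp$deficit_fraction_target,
                 realized_deficit_fraction = mean(scene$truth_deficit$pixels),
                 attenuation_amplitude = sp$attenuation_amplitude,
                 n_psv = length(scene$psv_rois)),
    files = list(flow = "flow.tif", structure = "structure.tif",
                 superficial = "superficial.tif",
                 truth_deficit = "truth_deficit.png",
                 vessel_truth = "vessel_truth.png",
                 psv_labels = "psv_labels.png", cohort = "cohort.csv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Quantify a scene bundle into per-PSV records
#'
#' Runs the full quantification chain on a simulated (or equivalently
#' structured real) bundle: inverse-structure compensation, Phansalkar
#' binarization, large-vessel exclusion, global CCFD%, and per-PSV FDPSV /
#' FD250 / area / VFD / X-Y offsets. Deterministic for fixed inputs.
#'
#' @param config Configuration list.
#' @param scene_dir Directory written by [run_simulate()].
#' @param out_csv Output CSV path (default `psv_records.csv` in
#'   `scene_dir`).
#' @return Data frame of PSV records (also written to `out_csv`).
#' @export
run_quantify <- function(config = default_config(), scene_dir,
                         out_csv = file.path(scene_dir, "psv_records.csv")) {
  man_path <- file.path(scene_dir, "manifest.json")
  if (!file.exists(man_path)) stop("manifest.json not found in ", scene_dir,
                                   call. = FALSE)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  pitch <- 1000 * man$geometry$scan_mm / man$geometry$raster_px
  need <- c("flow", "structure", "superficial", "psv_labels")
  for (nm in need) {
    if (!file.exists(file.path(scene_dir, man$files[[nm]]))) {
      stop("bundle is missing the ", nm, " file (", man$files[[nm]], ")",
           call. = FALSE)
    }
  }
  flow <- load_enface(file.path(scene_dir, man$files$flow), pitch, "flow")
  structure_img <- load_enface(file.path(scene_dir, man$files$structure),
                               pitch, "structure")
  superficial <- load_enface(file.path(scene_dir, man$files$superficial),
                             pitch, "superficial")
  rois <- load_psv_labels(file.path(scene_dir, man$files$psv_labels), flow)

  pp <- phansalkar_params(radius_um = config$phansalkar$radius_um,
                          k = config$phansalkar$k, r = config$phansalkar$r,
                          p = config$phansalkar$p, q = config$phansalkar$q)
  comp <- compensate(flow, structure_img)
  deficit <- phansalkar_binarize(comp, pp)
  excl <- vessel_exclusion_mask(superficial,
                                dilation_um = config$masking$dilation_um,
                                opening_um = config$masking$opening_um)
  global_fd <- fd_percent(deficit, excl)
  geom <- scan_geometry(man$geometry$scan_mm, man$geometry$raster_px)
  fovea <- as.numeric(man$fovea_xy)

  rows <- lapply(seq_along(rois), function(k) {
    m <- fd_psv_metrics(deficit, excl, rois[[k]], geom = geom,
                        ring_width_um = config$ring_width_um)
    v <- vfd(rois[[k]], fovea_xy = fovea, geom = geom,
             unit_area_mm2 = config$vfd_unit_area_mm2)
    data.frame(psv_id = k,
               fd_psv = m$fd_psv, fd_250 = m$fd_250,
               area_mm2 = psv_area(rois[[k]], geom),
               vfd_mm = v$vfd_mm, x_off_mm = v$x_off_mm,
               y_off_mm = v$y_off_mm,
               global_ccfd_pct = global_fd$ccfd_percent)
  })
  records <- if (length(rows)) do.call(rbind, rows) else
    data.frame(psv_id = integer(), fd_psv = numeric(), fd_250 = numeric(),
               area_mm2 = numeric(), vfd_mm = numeric(),
               x_off_mm = numeric(), y_off_mm = numeric(),
               global_ccfd_pct = numeric())
  # provenance
  records$scene_id <- rep(man$scene_id, nrow(records))
  records$seed <- rep(man$seed, nrow(records))
  records$config_hash <- rep(config_hash(config), nrow(records))
  write.csv(records, out_csv, row.names = FALSE)
  records
}

#' Statistical stage over a cohort table
#'
#' Mirrors the screening-then-modelling structure of a PSV flow-deficit
#' analysis: Spearman screen of every candidate predictor, one univariable
#' nested mixed model per predictor, one multivariable model over the full
#' set, VIFs for the multivariable predictors, residual/Q-Q diagnostic
#' plots, and an optional post hoc power estimate for one term. Outputs are
#' written as CSV/JSON/PNG into `out_dir`.
#'
#' @param config Configuration list.
#' @param cohort Cohort data frame or CSV path.
#' @param out_dir Output directory.
#' @return List with `spearman`, `univariable` (list of [fit_mixed]
#'   results), `multivariable`, `vif`, `power`.
#' @export
run_stats <- function(config = default_config(), cohort, out_dir) {
  if (is.character(cohort)) cohort <- read.csv(cohort)
  needed <- unique(c("subject_id", "eye_id", config$stats$response,
                     config$stats$univariable, config$stats$multivariable))
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  resp <- config$stats$response

  sp_tab <- spearman_screen(cohort, resp, config$stats$univariable)
  write.csv(sp_tab, file.path(out_dir, "spearman.csv"), row.names = FALSE)

  uni <- lapply(config$stats$univariable, function(pr) {
    fit_mixed(cohort, resp, pr)
  })
  names(uni) <- config$stats$univariable
  uni_tab <- do.call(rbind, lapply(names(uni), function(pr) {
    tt <- uni[[pr]]$terms
    tt <- tt[tt$term == pr, , drop = FALSE]
    tt$predictor <- pr
    tt
  }))
  write.csv(uni_tab, file.path(out_dir, "univariable.csv"),
            row.names = FALSE)

  multi <- fit_mixed(cohort, resp, config$stats$multivariable)
  write.csv(multi$terms, file.path(out_dir, "multivariable.csv"),
            row.names = FALSE)
  vif_tab <- vif(cohort, config$stats$multivariable)
  write.csv(vif_tab, file.path(out_dir, "vif.csv"), row.names = FALSE)

  # assumption diagnostics (inspected, not auto-judged)
  png(file.path(out_dir, "diagnostics.png"), width = 900, height = 450)
  par(mfrow = c(1, 2))
  plot(fitted(multi$fit), residuals(multi$fit),
       xlab = "fitted", ylab = "residual", main = "Residuals vs fitted")
  abline(h = 0, lty = 2)
  stats::qqnorm(residuals(multi$fit), main = "Residual Q-Q")
  stats::qqline(residuals(multi$fit))
  dev.off()

  power <- NULL
  pt_term <- config$stats$power_term
  if (!is.null(pt_term) && pt_term %in% multi$terms$term) {
    i <- match(pt_term, multi$terms$term)
    power <- posthoc_power(multi$terms$estimate[i], multi$terms$se[i],
                           n_eff = multi$n_subjects,
                           k = length(config$stats$multivariable))
  }
  summary_json <- list(
    n_obs = multi$n_obs, n_eyes = multi$n_eyes,
    n_subjects = multi$n_subjects, r2 = multi$r2,
    singular = multi$singular,
    var_subject = multi$var_subject, var_eye = multi$var_eye,
    var_resid = multi$var_resid,
    power_term = pt_term, power = power,
    config_hash = config_hash(config))
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(spearman = sp_tab, univariable = uni, multivariable = multi,
       vif = vif_tab, power = power)
}

#' Run the full pipeline: simulate, quantify, model
#'
#' @param config Configuration list.
#' @param out_dir Output root; scene bundle under `scene/`, statistical
#'   report under `stats/`.
#' @return List with `manifest`, `records`, `stats`.
#' @export
run_all <- function(config = default_config(), out_dir) {
  scene_dir <- file.path(out_dir, "scene")
  manifest <- run_simulate(config, scene_dir)
  records <- run_quantify(config, scene_dir)
  stats_res <- run_stats(config, file.path(scene_dir, "cohort.csv"),
                         file.path(out_dir, "stats"))
  list(manifest = manifest, records = records, stats = stats_res)
}
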