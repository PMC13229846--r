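## End-to-end pipeline.
##
## simulate (or ingest) -> calibrate per light condition -> extract ROI
## colours -> convert to Lab/LCh -> quantify pigments from the wet-lab
## table -> filter -> fit models -> report tables.  Every stage reads its
## inputs from, and persists its outputs to, plain CSV/JSON files under the
## configured output directory, so any stage can be re-run independently
## and reproducibly from the persisted intermediates.

#' Default pipeline configuration
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Mandatory seed; drives the synthetic study and the
#'   cross-validation segmentation.
#' @param mode `"synthetic"` (default; the study is generated) or `"real"`
#'   (images, ROIs and wet-lab tables are read from `paths`).
#' @param paths For real mode: list with `images` (directory of
#'   `<cultivar>_<condition>.png`), `rois` (directory of
#'   `<cultivar>.json`), `wetlab` (CSV), optional `hplc` (CSV of individual
#'   carotenoid contents).
#' @param n_replicates,pixel_noise_sd Passed to [study_design()] in
#'   synthetic mode.
#' @param illuminant Illuminant name for the Lab conversion.
#' @param calibration_method Passed to [fit_calibration()].
#' @param margin_fraction Chip margin for [measure_chips()].
#' @param pigments_all_conditions Pigments modelled under every light
#'   condition (default the two total contents).
#' @param pigments_default_condition Pigments modelled under the default
#'   condition only (the HPLC individual carotenoids).
#' @param default_condition Default light condition label (default
#'   `"WF0"`).
#' @param n_segments,ncomp Cross-validation segments and PLS components.
#' @param write_images Write rendered PNGs in synthetic mode (default
#'   `FALSE`; tables are always written).
#' @return Configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed, mode = c("synthetic", "real"),
                            paths = list(),
                            n_replicates = 6L, pixel_noise_sd = 1.5,
                            illuminant = "D65_10",
                            calibration_method = "quadratic_cross_band",
                            margin_fraction = 0.2,
                            pigments_all_conditions = c("tcc", "tac"),
                            pigments_default_condition =
                              c("lutein", "alpha_carotene", "beta_carotene",
                                "lycopene"),
                            default_condition = "WF0",
                            n_segments = 10L, ncomp = 5L,
                            write_images = FALSE) {
  if (missing(seed)) stop("a seed is mandatory")
  mode <- match.arg(mode)
  if (mode == "real") {
    for (p in c("images", "rois", "wetlab"))
      if (is.null(paths[[p]]) || !file.exists(paths[[p]]))
        stop("real mode requires an existing '", p, "' path")
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), mode = mode,
                 paths = paths, n_replicates = n_replicates,
                 pixel_noise_sd = pixel_noise_sd, illuminant = illuminant,
                 calibration_method = calibration_method,
                 margin_fraction = margin_fraction,
                 pigments_all_conditions = pigments_all_conditions,
                 pigments_default_condition = pigments_default_condition,
                 default_condition = default_condition,
                 n_segments = n_segments, ncomp = ncomp,
                 write_images = write_images),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the fields of [pipeline_config()].
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(pipeline_config, obj)
}

.logger <- function(out_dir) {
  log_path <- file.path(out_dir, "pipeline.log")
  function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", sprintf(...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
  }
}

# -- stage: obtain images + wet-lab table ------------------------------------

.pipeline_study <- function(config) {
  if (config$mode == "synthetic") {
    design <- study_design(seed = config$seed,
                           n_replicates = config$n_replicates,
                           pixel_noise_sd = config$pixel_noise_sd)
    generate_study(design, render_images = TRUE)
  } else {
    .ingest_real_study(config)
  }
}

.ingest_real_study <- function(config) {
  img_files <- list.files(config$paths$images, pattern = "\\.png$",
                          full.names = TRUE)
  if (length(img_files) == 0L) stop("no PNG images found under ",
                                    config$paths$images)
  images <- list()
  for (f in img_files) {
    key <- sub("\\.png$", "", basename(f))
    parts <- strsplit(key, "_")[[1]]
    cultivar <- parts[1]
    condition <- paste(parts[-1], collapse = "_")
    roi_path <- file.path(config$paths$rois, paste0(cultivar, ".json"))
    if (!file.exists(roi_path))
      stop("missing ROI file for sample '", cultivar, "': ", roi_path)
    px <- png::readPNG(f) * 255
    images[[key]] <- structure(
      list(pixels = px, roi_polygons = read_rois(roi_path),
           checker_layout = checker_layout(8, 6, 16, 4),
           checker_reference = colorchecker_srgb(),
           cultivar = cultivar, light_condition = condition, truth = NULL),
      class = "synthetic_image")
  }
  wetlab <- utils::read.csv(config$paths$wetlab)
  truth <- if (!is.null(config$paths$hplc))
    utils::read.csv(config$paths$hplc) else NULL
  structure(list(images = images, truth = truth, wetlab = wetlab,
                 design = NULL), class = "carot_study")
}

# -- stage: calibrate + extract + convert ------------------------------------

.stage_colour <- function(study, config, log) {
  illum <- illuminant(config$illuminant)
  cal_rows <- list(); sample_rows <- list()
  for (key in names(study$images)) {
    img <- study$images[[key]]
    chips <- measure_chips(img, img$checker_layout, img$checker_reference,
                           margin_fraction = config$margin_fraction)
    cal <- fit_calibration(chips, method = config$calibration_method,
                           illum = illum,
                           light_condition = img$light_condition)
    cal_rows[[key]] <- data.frame(image = key,
                                  light_condition = img$light_condition,
                                  mean_delta = cal$mean_delta)
    cal_img <- apply_calibration(cal, img$pixels)
    shape <- dim(cal_img)[1:2]
    for (roi_name in names(img$roi_polygons)) {
      mask <- rasterise_polygon(img$roi_polygons[[roi_name]], shape)
      meas <- roi_colour(cal_img, mask)
      lab <- srgb_to_lab(meas$mean_rgb, illum)
      lch <- lab_to_lch(lab)
      replicate <- as.integer(sub(".*_r", "", roi_name))
      sample_rows[[paste(key, roi_name)]] <- data.frame(
        cultivar = img$cultivar, replicate = replicate,
        light_condition = img$light_condition,
        R = meas$mean_rgb[1], G = meas$mean_rgb[2], B = meas$mean_rgb[3],
        sd_R = meas$sd_rgb[1], sd_G = meas$sd_rgb[2], sd_B = meas$sd_rgb[3],
        n_pixels = meas$n_pixels,
        L_star = lab[1], a_star = lab[2], b_star = lab[3],
        C_star = lch[2], h_deg = lch[3])
    }
  }
  calib <- do.call(rbind, cal_rows)
  per_cond <- tapply(calib$mean_delta, calib$light_condition, mean)
  for (cn in names(per_cond))
    log("calibration %s: mean delta E = %.3f", cn, per_cond[[cn]])
  samples <- do.call(rbind, sample_rows)
  rownames(samples) <- NULL
  list(samples = samples, calibration = calib)
}

# -- stage: quantify pigments from the wet-lab table -------------------------

.stage_quantify <- function(study, samples, config, log) {
  wl <- study$wetlab
  assay <- if (!is.null(study$design)) study$design$assay
           else study_design(seed = 1)$assay
  tcc <- lichtenthaler_tcc(wl$A662, wl$A645, wl$A470,
                           extract_volume_mL = assay$tcc_volume_mL,
                           sample_mass_g = assay$tcc_mass_g,
                           moisture_fraction = wl$moisture_fraction,
                           path_length_cm = assay$path_length_cm)
  contents <- data.frame(cultivar = wl$cultivar, replicate = wl$replicate,
                         tcc = tcc$tcc_mg_per_100g_fw, tac = NA_real_)
  has_tac <- !is.na(wl$A520_pH1)
  if (any(has_tac)) {
    tac <- ph_differential_tac(wl$A520_pH1[has_tac], wl$A700_pH1[has_tac],
                               wl$A520_pH45[has_tac], wl$A700_pH45[has_tac],
                               DF = assay$DF, MW = assay$MW, EF = assay$EF,
                               extract_volume_mL = assay$tac_volume_mL,
                               sample_mass_g = assay$tac_mass_g,
                               moisture_fraction =
                                 wl$moisture_fraction[has_tac],
                               path_length_cm = assay$path_length_cm)
    contents$tac[has_tac] <- tac$tac_mg_per_100g_fw
  }
  # individual carotenoid contents come from the HPLC table when provided
  if (!is.null(study$truth)) {
    hplc_cols <- intersect(c("lutein", "lycopene", "alpha_carotene",
                             "beta_carotene"), names(study$truth))
    hplc <- unique(study$truth[, c("cultivar", "replicate", hplc_cols)])
    contents <- merge(contents, hplc, by = c("cultivar", "replicate"),
                      all.x = TRUE, sort = FALSE)
  }
  log("quantified %d samples (%d with anthocyanin assay)",
      nrow(contents), sum(has_tac))
  merge(samples, contents, by = c("cultivar", "replicate"), sort = FALSE)
}

# -- stage: filter + model ---------------------------------------------------

.stage_model <- function(contents, config, log, models_dir) {
  grid <- rbind(
    expand.grid(pigment = config$pigments_all_conditions,
                light_condition = unique(contents$light_condition),
                stringsAsFactors = FALSE),
    expand.grid(pigment = config$pigments_default_condition,
                light_condition = config$default_condition,
                stringsAsFactors = FALSE))
  report_rows <- list(); removed_all <- list()
  for (i in seq_len(nrow(grid))) {
    pig <- grid$pigment[i]; cond <- grid$light_condition[i]
    rows <- contents[contents$light_condition == cond, , drop = FALSE]
    flt <- apply_content_filters(rows, pig)
    if (nrow(flt$removed) > 0) {
      removed <- flt$removed[, c("cultivar", "replicate", "light_condition",
                                 "reason")]
      removed$pigment <- pig
      removed_all[[length(removed_all) + 1L]] <- removed
    }
    kept <- flt$kept
    n <- nrow(kept)
    if (n < max(config$n_segments, config$ncomp + 2L)) {
      log("model %s / %s skipped: only %d usable samples", pig, cond, n)
      report_rows[[length(report_rows) + 1L]] <- data.frame(
        pigment = pig, light_condition = cond, model_type = "pls",
        n = n, r2 = NA_real_, rmse_cal = NA_real_, rmse_cal_pct = NA_real_,
        rmsep = NA_real_, rmsep_pct = NA_real_)
      next
    }
    X <- as.matrix(kept[, .predictor_names])
    y <- kept[[pig]]
    fit <- fit_pls(X, y, ncomp = config$ncomp)
    cv <- cross_validate(X, y,
                         model_spec = list(type = "pls",
                                           ncomp = config$ncomp),
                         n_segments = config$n_segments,
                         seed = config$seed + i)
    report_rows[[length(report_rows) + 1L]] <- data.frame(
      pigment = pig, light_condition = cond, model_type = "pls", n = n,
      r2 = fit$r2_ss, rmse_cal = fit$rmse_cal,
      rmse_cal_pct = fit$rmse_cal_pct,
      rmsep = cv$rmsep, rmsep_pct = cv$rmsep_pct)
    jsonlite::write_json(
      list(pigment = pig, light_condition = cond, n = n,
           ncomp = fit$ncomp,
           coefficients = as.list(fit$coefficients_original_scale),
           r2 = fit$r2_ss, rmse_cal = fit$rmse_cal, rmsep = cv$rmsep,
           cv_seed = cv$seed),
      file.path(models_dir, paste0(pig, "_", cond, ".json")),
      auto_unbox = TRUE, digits = NA)
    log("model %s / %s: n = %d, R2 = %.3f, RMSEP = %.3f (%.1f%%)",
        pig, cond, n, fit$r2_ss, cv$rmsep, cv$rmsep_pct)
  }
  list(reports = do.call(rbind, report_rows),
       removed = if (length(removed_all)) do.call(rbind, removed_all)
                 else data.frame())
}

#' Run the full image-to-model pipeline
#'
#' Executes the requested stages in order, persisting each stage's outputs
#' as plain CSV/JSON under `config$out_dir`: `truth.csv` / `wetlab.csv`
#' (synthetic inputs), `calibration_summary.csv`, `samples.csv` (per-disk
#' calibrated colours), `contents.csv` (colours merged with pigment
#' contents), `models/*.json`, `reports/` (long CSV and markdown), a
#' `filtered.csv` audit of removed rows with reason codes, a run
#' `manifest.json` and `pipeline.log`.  Later stages read the persisted
#' outputs of earlier ones, so e.g. `stages = "model"` re-fits models from
#' an existing `contents.csv` and yields byte-identical reports for the
#' same seed.
#'
#' @param config A [pipeline_config()] (or path to its YAML form).
#' @param stages Subset of `c("simulate", "colour", "quantify", "model",
#'   "report")`, in pipeline order.
#' @return Invisibly, a list with the key tables (`samples`, `contents`,
#'   `reports`, `calibration`, `removed`).
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "colour", "quantify",
                                    "model", "report")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "models"), showWarnings = FALSE)
  dir.create(file.path(out, "reports"), showWarnings = FALSE)
  log <- .logger(out)
  log("pipeline start: mode = %s, seed = %d, stages = %s", config$mode,
      config$seed, paste(stages, collapse = ","))
  study <- NULL
  need_study <- any(c("simulate", "colour", "quantify") %in% stages)
  if (need_study) {
    study <- .pipeline_study(config)
    if ("simulate" %in% stages) {
      utils::write.csv(study$truth, file.path(out, "truth.csv"),
                       row.names = FALSE)
      utils::write.csv(study$wetlab, file.path(out, "wetlab.csv"),
                       row.names = FALSE)
      if (config$write_images && config$mode == "synthetic")
        write_study(study, file.path(out, "study"))
      log("study ready: %d truth rows, %d wet-lab rows",
          nrow(study$truth), nrow(study$wetlab))
    }
  }
  samples <- calibration <- contents <- reports <- removed <- NULL
  if ("colour" %in% stages) {
    res <- .stage_colour(study, config, log)
    samples <- res$samples; calibration <- res$calibration
    utils::write.csv(samples, file.path(out, "samples.csv"),
                     row.names = FALSE)
    utils::write.csv(calibration, file.path(out, "calibration_summary.csv"),
                     row.names = FALSE)
  }
  if ("quantify" %in% stages) {
    if (is.null(samples))
      samples <- utils::read.csv(file.path(out, "samples.csv"))
    contents <- .stage_quantify(study, samples, config, log)
    utils::write.csv(contents, file.path(out, "contents.csv"),
                     row.names = FALSE)
  }
  if ("model" %in% stages) {
    # always model from the persisted table so that re-running this stage
    # alone reproduces the full run byte for byte (CSV round-trip included)
    contents <- utils::read.csv(file.path(out, "contents.csv"))
    res <- .stage_model(contents, config, log, file.path(out, "models"))
    reports <- res$reports; removed <- res$removed
    utils::write.csv(reports, file.path(out, "model_reports.csv"),
                     row.names = FALSE)
    utils::write.csv(removed, file.path(out, "filtered.csv"),
                     row.names = FALSE)
  }
  if ("report" %in% stages) {
    if (is.null(reports))
      reports <- utils::read.csv(file.path(out, "model_reports.csv"))
    tables <- build_report_tables(reports)
    utils::write.csv(tables$long, file.path(out, "reports",
                                            "report_long.csv"),
                     row.names = FALSE)
    write_report_markdown(tables, file.path(out, "reports", "report.md"))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("carotlab")),
    seed = config$seed, mode = config$mode, stages = stages,
    n_samples = if (!is.null(samples)) nrow(samples) else NA,
    n_contents = if (!is.null(contents)) nrow(contents) else NA,
    n_models = if (!is.null(reports)) sum(!is.na(reports$r2)) else NA,
    n_filtered = if (!is.null(removed)) nrow(removed) else NA,
    calibration_mean_delta = if (!is.null(calibration))
      mean(calibration$mean_delta) else NA)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log("pipeline done")
  invisible(list(samples = samples, contents = contents, reports = reports,
                 calibration = calibration, removed = removed,
                 manifest = manifest))
}

#' Per-cultivar descriptive statistics of pigment contents
#'
#' Mean, sample SD (n - 1 denominator, the convention of descriptive
#' "mean +/- SD" tables), minimum and maximum per cultivar and pigment.
#'
#' @param records Data frame with `cultivar` and pigment content columns.
#' @param pigments Pigment columns to summarise (default: those present).
#' @return Long data frame: `cultivar`, `pigment`, `n`, `mean`, `sd`,
#'   `min`, `max`.
#' @export
summarise_contents <- function(records,
                               pigments = intersect(pigment_names(),
                                                    names(records))) {
  rows <- list()
  for (pig in pigments) {
    for (cu in unique(records$cultivar)) {
      v <- records[[pig]][records$cultivar == cu]
      v <- v[!is.na(v)]
      if (length(v) == 0L) next
      rows[[paste(pig, cu)]] <- data.frame(
        cultivar = cu, pigment = pig, n = length(v), mean = mean(v),
        sd = if (length(v) > 1) stats::sd(v) else 0,
        min = min(v), max = max(v))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
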