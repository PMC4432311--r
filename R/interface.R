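#' Run configuration
#'
#' Bundles every tunable of the pipeline with its default.  Defaults mirror
#' the reference instrument and analysis constants: 552 nm center
#' wavelength, 0.75 NA collection, Eq-variant "A" of the moment
#' combination, 10-px stromal band, Henyey-Greenstein fit over (2, 45]
#' degrees in 90 bins, mean per-patient aggregation, decision threshold
#' g = 0.938, histogram bin 0.01, PSA strata at 6 / 10 / 20 ng/ml.
#' Configs serialize as JSON ([write_config()] / [read_config()]); every
#' run writes its resolved config into the output manifest.
#'
#' @param ... overrides of the defaults (unknown names are rejected).
#' @return a `run_config` (named list).
#' @export
run_config <- function(...) {
  defaults <- list(
    wavelength_nm = 552, na = 0.75, pixel_size_um = 0.05,
    variant = "A", band_width_px = 10,
    fit_theta_min = 2, fit_theta_max = 45, fit_n_bins = 90,
    aggregation = "mean", threshold_g = 0.938, bin_width = 0.01,
    strata = c(6, 10, 20),
    n_recurrent = 92, n_nonrecurrent = 89, n_unscorable = 20,
    n_boot = 0, seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0)
    stop_parameter(sprintf("unknown config field(s): %s",
                           paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, over)
  for (nm in c("wavelength_nm", "na", "pixel_size_um", "band_width_px",
               "fit_theta_max", "fit_n_bins", "threshold_g", "bin_width"))
    check_number(cfg[[nm]], nm, lower = 0, strict_lower = TRUE)
  check_number(cfg$fit_theta_min, "fit_theta_min", lower = 0)
  check_number(cfg$seed, "seed")
  if (!cfg$variant %in% c("A", "B"))
    stop_parameter('`variant` must be "A" or "B"')
  if (!cfg$aggregation %in% c("mean", "median"))
    stop_parameter('`aggregation` must be "mean" or "median"')
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  if (!inherits(config, "run_config"))
    stop_parameter("`config` must be a run_config")
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("config file not found: %s", path))
  vals <- jsonlite::fromJSON(path)
  do.call(run_config, vals)
}

.manifest <- function(out_dir, config, extra = list()) {
  m <- c(list(package = "qpianiso",
              version = as.character(utils::packageVersion("qpianiso")),
              config = unclass(config),
              seed = config$seed),
         extra)
  jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.ensure_dir <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop_io(sprintf("cannot create output directory %s", out_dir))
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ file.create(probe, showWarnings = FALSE) },
                 error = function(e) FALSE)
  if (!isTRUE(ok)) stop_io(sprintf("output directory not writable: %s", out_dir))
  unlink(probe)
  invisible(out_dir)
}

#' Simulate synthetic data to disk
#'
#' Emits the synthetic cohort (CSVs) and/or synthetic tissue cores (float
#' TIFF phase map + 8-bit mask TIFFs per stromal ROI), each with a manifest
#' recording package version, resolved config and seed.  Reruns with the
#' same config are byte-identical.
#'
#' @param config a [run_config()].
#' @param out_dir writable output directory.
#' @param what any of `"cohort"`, `"cores"`.
#' @param n_cores number of synthetic cores when `"cores"` is requested.
#' @param core_args extra arguments passed to [gen_core_image()].
#' @return invisible list of written paths.
#' @export
cli_simulate <- function(config = run_config(), out_dir,
                         what = c("cohort"), n_cores = 1,
                         core_args = list()) {
  .ensure_dir(out_dir)
  written <- list()
  if ("cohort" %in% what) {
    spec <- cohort_spec(n_recurrent = config$n_recurrent,
                        n_nonrecurrent = config$n_nonrecurrent,
                        n_unscorable = config$n_unscorable,
                        seed = config$seed)
    cohort <- gen_cohort(spec)
    written$cohort <- write_cohort_csv(cohort, out_dir)
  }
  if ("cores" %in% what) {
    for (i in seq_len(n_cores)) {
      args <- utils::modifyList(
        list(texture = texture_spec(pixel_size = config$pixel_size_um,
                                    seed = derive_seed(config$seed, i)),
             band_width = config$band_width_px,
             seed = derive_seed(config$seed, paste0("core", i))),
        core_args)
      core <- do.call(gen_core_image, args)
      stem <- file.path(out_dir, sprintf("core_%02d", i))
      write_phase_tiff(core$image, paste0(stem, "_phase.tif"))
      for (k in seq_along(core$stromal_rois))
        write_mask_tiff(core$stromal_rois[[k]],
                        sprintf("%s_stroma_%02d.tif", stem, k))
      written[[sprintf("core_%02d", i)]] <- paste0(stem, "_phase.tif")
    }
  }
  .manifest(out_dir, config, list(outputs = names(written)))
  invisible(written)
}

#' Compute anisotropy for an image and a set of masks
#'
#' One scattering result per mask, serialized as JSON records
#' `{roi_id, g, grad_term, var_term, sigma_g, variant, n_pixels}`.  A
#' background mask adds propagated uncertainty; `oracle = TRUE` adds the
#' Henyey-Greenstein fit g and R-squared per ROI.  Per-ROI failures (e.g.
#' an empty mask) become error entries in the JSON instead of aborting the
#' whole run; the function then signals via the `n_failed` attribute and
#' the CLI exits nonzero.
#'
#' @param image_path float-TIFF phase map.
#' @param mask_paths character vector of mask TIFFs.
#' @param config a [run_config()].
#' @param out_path output JSON path (optional).
#' @param background_path optional background (no-tissue) mask TIFF.
#' @param oracle add the far-field Henyey-Greenstein fit per ROI.
#' @return list of per-ROI records (invisible when `out_path` given).
#' @export
cli_anisotropy <- function(image_path, mask_paths, config = run_config(),
                           out_path = NULL, background_path = NULL,
                           oracle = FALSE) {
  img <- read_phase_tiff(image_path, pixel_size = config$pixel_size_um,
                         wavelength = config$wavelength_nm)
  noise <- NULL
  if (!is.null(background_path)) {
    bg <- read_mask_tiff(background_path)
    noise <- background_noise(img, bg, variant = config$variant)
  }
  results <- lapply(seq_along(mask_paths), function(i) {
    roi_id <- sub("\\.tiff?$", "", basename(mask_paths[i]))
    tryCatch({
      roi <- read_mask_tiff(mask_paths[i])
      res <- withCallingHandlers(
        anisotropy_from_phase(img, roi, variant = config$variant),
        warning = function(w) invokeRestart("muffleWarning"))
      if (!is.null(noise)) res <- g_uncertainty(res, noise)
      rec <- list(roi_id = roi_id, g = res$g, grad_term = res$grad_term,
                  var_term = res$var_term, sigma_g = res$sigma_g,
                  variant = res$variant, n_pixels = res$n_pixels,
                  out_of_range = res$out_of_range)
      if (oracle) {
        hg <- anisotropy_from_oracle(
          img, roi, n_bins = config$fit_n_bins,
          theta_max = config$fit_theta_max, na = config$na,
          fit_range = c(config$fit_theta_min, config$fit_theta_max))
        rec$g_hg <- hg$g_fit
        rec$r_squared_hg <- hg$r_squared
      }
      rec
    }, qpianiso_error = function(e) {
      list(roi_id = roi_id, error = conditionMessage(e),
           error_class = class(e)[1])
    })
  })
  n_failed <- sum(vapply(results, function(r) !is.null(r$error), logical(1)))
  attr(results, "n_failed") <- n_failed
  if (!is.null(out_path)) {
    jsonlite::write_json(lapply(results, function(r) r), out_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(results))
  }
  results
}

#' Cohort-level report
#'
#' Recomputes the whole patient-level analysis from the cohort CSVs and
#' writes the summary layer: per-group histogram table (fixed bin width),
#' Welch test, ROC AUC with sensitivity/specificity at the configured
#' threshold, Pearson correlation of g with pre-surgical PSA, the
#' PSA-stratified AUC table (anisotropy vs CAPRA-S), and the CAPRA-S AUC
#' with the count of excluded (unscorable) patients.  Tables land as CSVs
#' plus one `summary.json`; histogram figures are written as PNG when a
#' bitmap device is available.
#'
#' @param patients_csv,rois_csv cohort CSV paths (see [cohort-io]).
#' @param config a [run_config()].
#' @param out_dir writable output directory.
#' @return invisible list with all computed tables and statistics.
#' @export
cli_cohort_report <- function(patients_csv, rois_csv,
                              config = run_config(), out_dir) {
  .ensure_dir(out_dir)
  cohort <- read_cohort_csv(patients_csv, rois_csv)
  patients <- cohort$patients
  if (length(unique(patients$group)) < 2L)
    stop_stat("cohort contains a single class: group comparison impossible")
  ## per-patient aggregate from the ROI table
  agg <- tapply(cohort$rois$g,
                factor(cohort$rois$patient_id, levels = patients$patient_id),
                function(v) aggregate_patient_g(v, config$aggregation))
  patients$g_agg <- as.numeric(agg)
  if (anyNA(patients$g_agg))
    stop_data("some patients have no ROI g values")
  is_rec <- patients$group == "recurrent"

  hist_tab <- do.call(rbind, lapply(split(patients, patients$group),
    function(p) {
      h <- g_histogram(p$g_agg, config$bin_width)
      if (nrow(h) > 0) h$group <- p$group[1]
      h
    }))
  rownames(hist_tab) <- NULL

  welch <- welch_t_test(patients$g_agg[is_rec], patients$g_agg[!is_rec])
  roc <- roc_auc(is_rec, patients$g_agg, n_boot = config$n_boot,
                 seed = config$seed)
  ss <- sens_spec_at_threshold(is_rec, patients$g_agg, config$threshold_g)

  has_psa <- !is.na(patients$psa_ng_ml)
  r_psa <- if (sum(has_psa) >= 3)
    pearson_r(patients$g_agg[has_psa], patients$psa_ng_ml[has_psa]) else
      NA_real_

  score_one <- function(i) {
    tryCatch(capra_s_score(patients$psa_ng_ml[i],
                           patients$gleason_primary[i],
                           patients$gleason_secondary[i],
                           patients$margins[i], patients$svi[i],
                           patients$ece[i], patients$lni[i])$total,
             qpianiso_error_unscorable = function(e) NA_real_)
  }
  patients$capra_s <- vapply(seq_len(nrow(patients)), score_one, numeric(1))
  n_excluded <- sum(is.na(patients$capra_s))
  scorable <- !is.na(patients$capra_s)
  roc_capra <- if (length(unique(is_rec[scorable])) == 2L)
    roc_auc(is_rec[scorable], patients$capra_s[scorable],
            direction = "higher_score_positive", n_boot = config$n_boot,
            seed = config$seed) else NULL
  patients$g_mean <- patients$g_agg
  strata_tab <- psa_stratified_comparison(patients, config$strata)

  group_stats <- do.call(rbind, lapply(split(patients, patients$group),
    function(p) data.frame(group = p$group[1], n = nrow(p),
                           mean_g = mean(p$g_agg), sd_g = stats::sd(p$g_agg),
                           median_g = stats::median(p$g_agg))))
  rownames(group_stats) <- NULL

  utils::write.csv(hist_tab, file.path(out_dir, "histogram.csv"),
                   row.names = FALSE)
  utils::write.csv(strata_tab, file.path(out_dir, "psa_strata_auc.csv"),
                   row.names = FALSE)
  utils::write.csv(group_stats, file.path(out_dir, "group_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(patients, file.path(out_dir, "patients_scored.csv"),
                   row.names = FALSE)
  summary <- list(
    n_patients = nrow(patients),
    group_stats = group_stats,
    welch = welch,
    auc_g = roc$auc, auc_g_ci = c(roc$ci_lower, roc$ci_upper),
    threshold_g = config$threshold_g,
    sensitivity = ss$sensitivity, specificity = ss$specificity,
    pearson_r_psa_g = r_psa,
    auc_capra = if (is.null(roc_capra)) NA else roc_capra$auc,
    capra_excluded = n_excluded)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .manifest(out_dir, config,
            list(inputs = c(patients_csv, rois_csv)))

  if (capabilities("png")) {
    tryCatch({
      grDevices::png(file.path(out_dir, "histogram.png"), 800, 500)
      on.exit(grDevices::dev.off(), add = TRUE)
      brks <- seq(floor(min(patients$g_agg) / config$bin_width),
                  ceiling(max(patients$g_agg) / config$bin_width)) *
        config$bin_width
      h1 <- graphics::hist(patients$g_agg[is_rec], breaks = brks,
                           plot = FALSE)
      h2 <- graphics::hist(patients$g_agg[!is_rec], breaks = brks,
                           plot = FALSE)
      graphics::plot(h1, col = grDevices::rgb(0.8, 0.2, 0.2, 0.5),
                     xlab = "anisotropy g", main = "per-patient g by group")
      graphics::plot(h2, col = grDevices::rgb(0.2, 0.2, 0.8, 0.5),
                     add = TRUE)
    }, error = function(e) NULL)
  }
  invisible(c(summary, list(histogram = hist_tab, strata = strata_tab,
                            patients = patients)))
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `anisotropy`, `oracle` and
#' `cohort-report` (see `inst/cli/qpianiso.R` for the Rscript wrapper).
#' Exit codes: 0 success, 2 parameter/data error, 3 statistical error,
#' 4 I/O error.
#'
#' @param args character vector of CLI arguments (default: the command
#'   line).
#' @return integer exit code (invisibly); the Rscript wrapper quits with
#'   it.
#' @export
qpi_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: qpianiso <subcommand> [options]",
    "  simulate      --out DIR [--config FILE] [--seed N] [--cores N] [--cohort-only]",
    "  anisotropy    --image FILE --masks F1,F2,... --out FILE",
    "                [--background FILE] [--oracle] [--config FILE]",
    "  oracle        --image FILE --mask FILE [--config FILE]",
    "  cohort-report --patients FILE --rois FILE --out DIR [--config FILE]",
    "                [--threshold-g X] [--wavelength-nm X] [--seed N]",
    sep = "\n")
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  sub <- args[1]; rest <- args[-1]
  opt <- list(); flagset <- character(0)
  i <- 1L
  while (i <= length(rest)) {
    a <- rest[i]
    if (a %in% c("--oracle", "--cohort-only")) {
      flagset <- c(flagset, sub("^--", "", a)); i <- i + 1L
    } else if (startsWith(a, "--")) {
      if (i == length(rest)) { message("missing value for ", a); return(invisible(2L)) }
      opt[[sub("^--", "", a)]] <- rest[i + 1L]; i <- i + 2L
    } else { message("unexpected argument ", a); return(invisible(2L)) }
  }
  load_cfg <- function() {
    cfg <- if (!is.null(opt$config)) read_config(opt$config) else run_config()
    if (!is.null(opt$seed)) cfg$seed <- as.numeric(opt$seed)
    if (!is.null(opt$`threshold-g`)) cfg$threshold_g <- as.numeric(opt$`threshold-g`)
    if (!is.null(opt$`wavelength-nm`)) cfg$wavelength_nm <- as.numeric(opt$`wavelength-nm`)
    cfg
  }
  code <- tryCatch({
    switch(sub,
      simulate = {
        cfg <- load_cfg()
        what <- if ("cohort-only" %in% flagset) "cohort" else
          c("cohort", if (!is.null(opt$cores)) "cores")
        cli_simulate(cfg, out_dir = opt$out, what = what,
                     n_cores = as.integer(opt$cores %||% 1))
        0L
      },
      anisotropy = {
        cfg <- load_cfg()
        res <- cli_anisotropy(opt$image,
                              strsplit(opt$masks, ",")[[1]],
                              config = cfg, out_path = opt$out,
                              background_path = opt$background,
                              oracle = "oracle" %in% flagset)
        if (attr(res, "n_failed") > 0) 2L else 0L
      },
      oracle = {
        cfg <- load_cfg()
        img <- read_phase_tiff(opt$image, pixel_size = cfg$pixel_size_um,
                               wavelength = cfg$wavelength_nm)
        roi <- read_mask_tiff(opt$mask)
        fit <- anisotropy_from_oracle(
          img, roi, n_bins = cfg$fit_n_bins, theta_max = cfg$fit_theta_max,
          na = cfg$na, fit_range = c(cfg$fit_theta_min, cfg$fit_theta_max))
        cat(jsonlite::toJSON(list(g_hg = fit$g_fit,
                                  r_squared = fit$r_squared),
                             auto_unbox = TRUE, digits = NA), "\n")
        0L
      },
      `cohort-report` = {
        cfg <- load_cfg()
        cli_cohort_report(opt$patients, opt$rois, config = cfg,
                          out_dir = opt$out)
        0L
      },
      { message("unknown subcommand: ", sub); message(usage); 1L })
  },
  qpianiso_error_stat = function(e) { message("statistical error: ", conditionMessage(e)); 3L },
  qpianiso_error_io = function(e) { message("I/O error: ", conditionMessage(e)); 4L },
  qpianiso_error = function(e) { message("error: ", conditionMessage(e)); 2L })
  invisible(code)
}
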