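test_that("run_config validates and serializes", {
  cfg <- run_config()
  expect_equal(cfg$wavelength_nm, 552)
  expect_equal(cfg$na, 0.75)
  expect_equal(cfg$threshold_g, 0.938)
  expect_equal(cfg$strata, c(6, 10, 20))
  expect_parameter_error(run_config(nonsense = 1))
  expect_parameter_error(run_config(variant = "C"))
  expect_parameter_error(run_config(wavelength_nm = -1))

  tf <- tempfile(fileext = ".json")
  write_config(run_config(threshold_g = 0.93, seed = 4), tf)
  back <- read_config(tf)
  expect_equal(back$threshold_g, 0.93)
  expect_equal(back$seed, 4)
  unlink(tf)
})

test_that("cli_simulate writes a reproducible cohort with manifest", {
  cfg <- run_config(n_recurrent = 10, n_nonrecurrent = 9, n_unscorable = 2,
                    seed = 11)
  d1 <- tempfile("sim1"); d2 <- tempfile("sim2")
  cli_simulate(cfg, d1, what = "cohort")
  cli_simulate(cfg, d2, what = "cohort")
  expect_identical(readLines(file.path(d1, "patients.csv")),
                   readLines(file.path(d2, "patients.csv")))
  expect_identical(readLines(file.path(d1, "rois.csv")),
                   readLines(file.path(d2, "rois.csv")))
  man <- jsonlite::fromJSON(file.path(d1, "manifest.json"))
  expect_equal(man$seed, 11)
  expect_equal(man$config$n_recurrent, 10)
  # cohort-only mode emits no TIFFs
  expect_length(list.files(d1, pattern = "\\.tif$"), 0)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("default simulated cohort has the reference group sizes 92/89", {
  d <- tempfile("simdef")
  cli_simulate(run_config(), d, what = "cohort")
  pats <- read.csv(file.path(d, "patients.csv"))
  expect_equal(sum(pats$group == "recurrent"), 92L)
  expect_equal(sum(pats$group == "non-recurrent"), 89L)
  unlink(d, recursive = TRUE)
})

test_that("cli_anisotropy: per-ROI records, reruns identical, empty mask fails per-ROI", {
  d <- tempfile("core")
  dir.create(d)
  core <- gen_core_image(n_glands = 2, canvas = c(520, 520),
                         gland_radius_px = 60, band_width = 8,
                         texture = texture_spec(sigma_phi = 0.3,
                                                corr_len = 0.5),
                         seed = 3)
  imgp <- file.path(d, "phase.tif")
  write_phase_tiff(core$image, imgp)
  mps <- character(2)
  for (k in 1:2) {
    mps[k] <- file.path(d, sprintf("roi%d.tif", k))
    write_mask_tiff(core$stromal_rois[[k]], mps[k])
  }
  out1 <- file.path(d, "res1.json"); out2 <- file.path(d, "res2.json")
  cli_anisotropy(imgp, mps, out_path = out1)
  cli_anisotropy(imgp, mps, out_path = out2)
  expect_identical(readLines(out1), readLines(out2))
  res <- jsonlite::fromJSON(out1, simplifyVector = FALSE)
  expect_length(res, 2)
  expect_true(all(vapply(res, function(r)
    all(c("roi_id", "g", "grad_term", "var_term", "variant",
          "n_pixels") %in% names(r)), logical(1))))
  direct <- anisotropy_from_phase(core$image, core$stromal_rois[[1]])
  expect_equal(res[[1]]$g, direct$g, tolerance = 1e-5)  # float TIFF storage

  # empty mask -> error entry, not an abort
  emp <- file.path(d, "empty.tif")
  write_mask_tiff(roi_mask(matrix(FALSE, 520, 520)), emp)
  res2 <- cli_anisotropy(imgp, c(mps[1], emp))
  expect_equal(attr(res2, "n_failed"), 1L)
  expect_null(res2[[1]]$error)
  expect_match(res2[[2]]$error, "empty")
  unlink(d, recursive = TRUE)
})

test_that("cli_anisotropy --oracle adds an HG fit per ROI", {
  d <- tempfile("coreo"); dir.create(d)
  img <- gen_scattering_texture(0.94, shape = c(256, 256), seed = 8)
  imgp <- file.path(d, "phase.tif")
  write_phase_tiff(img, imgp)
  mp <- file.path(d, "m.tif")
  write_mask_tiff(roi_mask(matrix(TRUE, 256, 256)), mp)
  res <- cli_anisotropy(imgp, mp, oracle = TRUE)
  expect_true(is.numeric(res[[1]]$g_hg))
  expect_true(res[[1]]$r_squared_hg > 0.5)
  unlink(d, recursive = TRUE)
})

test_that("cli_cohort_report emits all summary tables and honors exclusions", {
  cfg <- run_config(n_recurrent = 40, n_nonrecurrent = 40,
                    n_unscorable = 20, seed = 13)
  d <- tempfile("rep")
  cli_simulate(cfg, d, what = "cohort")
  out <- tempfile("repout")
  rep <- cli_cohort_report(file.path(d, "patients.csv"),
                           file.path(d, "rois.csv"), cfg, out)
  for (f in c("histogram.csv", "psa_strata_auc.csv", "group_stats.csv",
              "patients_scored.csv", "summary.json", "manifest.json"))
    expect_true(file.exists(file.path(out, f)))
  smry <- jsonlite::fromJSON(file.path(out, "summary.json"))
  expect_equal(smry$capra_excluded, 20L)
  expect_true(smry$auc_g > 0.5)      # g separates the groups
  expect_true(is.numeric(smry$welch$p))
  hist_tab <- read.csv(file.path(out, "histogram.csv"))
  expect_equal(sum(hist_tab$count), 80L)

  # threshold override changes sens/spec but never the AUC
  cfg2 <- run_config(n_recurrent = 40, n_nonrecurrent = 40,
                     n_unscorable = 20, seed = 13, threshold_g = 0.9)
  out2 <- tempfile("repout2")
  rep2 <- cli_cohort_report(file.path(d, "patients.csv"),
                            file.path(d, "rois.csv"), cfg2, out2)
  expect_equal(rep2$auc_g, rep$auc_g)
  expect_false(isTRUE(all.equal(rep2$sensitivity, rep$sensitivity)))
  unlink(c(d, out, out2), recursive = TRUE)
})

test_that("qpi_main dispatches and returns distinct exit codes", {
  expect_equal(qpi_main(character(0)), 1L)
  expect_equal(qpi_main("frobnicate"), 1L)
  # I/O failure -> 4
  expect_equal(suppressMessages(
    qpi_main(c("cohort-report", "--patients", tempfile(), "--rois",
               tempfile(), "--out", tempfile()))), 4L)
  # simulate runs end to end
  d <- tempfile("cliS")
  expect_equal(suppressMessages(
    qpi_main(c("simulate", "--out", d, "--seed", "3", "--cohort-only"))), 0L)
  expect_true(file.exists(file.path(d, "patients.csv")))
  unlink(d, recursive = TRUE)
})
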