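#' Cohort specification for synthetic matched patient groups
#'
#' Describes the synthetic analogue of a matched recurrent / non-recurrent
#' prostatectomy cohort.  Group-level anisotropy targets default to the
#' reference group summaries (recurrent mean 0.911, sd 0.039, median 0.921;
#' non-recurrent 0.935, 0.031, 0.945), group sizes default to 92 / 89, and
#' each patient carries 12-16 per-ROI g values.
#'
#' @param n_recurrent,n_nonrecurrent group sizes (>= 0).
#' @param g_recurrent,g_nonrecurrent named numeric `c(mean=, sd=, median=)`
#'   targets for the patient-level g distribution of each group.
#' @param rois_per_patient integer range `c(lo, hi)` of regions per patient,
#'   within \[1, 32\].
#' @param roi_sd within-patient sd of per-ROI g about the patient mean.
#' @param psa_meanlog,psa_sdlog log-normal parameters of pre-surgical PSA
#'   (ng/ml), shared by both groups (PSA is independent of g here).
#' @param n_unscorable number of patients given one missing CAPRA-S field.
#' @param seed RNG seed.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_recurrent = 92, n_nonrecurrent = 89,
                        g_recurrent = c(mean = 0.911, sd = 0.039,
                                        median = 0.921),
                        g_nonrecurrent = c(mean = 0.935, sd = 0.031,
                                           median = 0.945),
                        rois_per_patient = c(12, 16), roi_sd = 0.01,
                        psa_meanlog = log(8), psa_sdlog = 0.8,
                        n_unscorable = 20, seed = 1) {
  check_number(n_recurrent, "n_recurrent", lower = 0)
  check_number(n_nonrecurrent, "n_nonrecurrent", lower = 0)
  for (nm in c("g_recurrent", "g_nonrecurrent")) {
    tg <- get(nm)
    if (!is.numeric(tg) || !all(c("mean", "sd", "median") %in% names(tg)))
      stop_parameter(sprintf("`%s` must be named c(mean=, sd=, median=)", nm))
    if (tg[["sd"]] <= 0)
      stop_parameter(sprintf("`%s['sd']` must be > 0", nm))
  }
  if (length(rois_per_patient) != 2L || rois_per_patient[1] < 1 ||
      rois_per_patient[2] > 32 || rois_per_patient[1] > rois_per_patient[2])
    stop_parameter("`rois_per_patient` must be c(lo, hi) within [1, 32]")
  check_number(roi_sd, "roi_sd", lower = 0)
  check_number(n_unscorable, "n_unscorable", lower = 0)
  check_number(seed, "seed")
  structure(list(n_recurrent = as.integer(n_recurrent),
                 n_nonrecurrent = as.integer(n_nonrecurrent),
                 g_recurrent = g_recurrent, g_nonrecurrent = g_nonrecurrent,
                 rois_per_patient = as.integer(rois_per_patient),
                 roi_sd = roi_sd, psa_meanlog = psa_meanlog,
                 psa_sdlog = psa_sdlog,
                 n_unscorable = as.integer(n_unscorable), seed = seed),
            class = "cohort_spec")
}

is_cohort_spec <- function(x) inherits(x, "cohort_spec")

#' Calibrate the skewed g-distribution family to (mean, sd, median)
#'
#' The patient-level g distribution is a reflected gamma,
#' `g = location - Gamma(shape, scale)` (left-skewed, long tail toward low
#' g) or its mirror image for right skew — a three-parameter
#' location/scale/shape family whose mean, sd and median can be matched
#' exactly: the shape solves `(median - mean)/sd = (shape - q50(shape)) /
#' sqrt(shape)` on the decreasing branch, then scale and location follow in
#' closed form.  Targets whose skew offset exceeds what the family supports
#' (|median - mean|/sd beyond about 0.40) raise a calibration error.
#'
#' @param mean,sd,median the three targets; `sd > 0`.
#' @return list `(family, location, scale, shape, sign)` consumed by
#'   [rg_skew()].
#' @export
calibrate_g_family <- function(mean, sd, median) {
  check_number(mean, "mean"); check_number(median, "median")
  check_number(sd, "sd", lower = 0, strict_lower = TRUE)
  delta <- (median - mean) / sd
  if (abs(delta) < 1e-8)
    return(list(family = "normal", location = mean, scale = sd,
                shape = Inf, sign = 1))
  h <- function(k) (k - stats::qgamma(0.5, k)) / sqrt(k)
  ## h rises from 0 (k -> 0) to ~0.40 near k ~ 0.25, then decreases;
  ## calibrate on the decreasing branch (larger shape = milder skew)
  k_mode <- stats::optimize(h, c(1e-3, 5), maximum = TRUE)
  if (abs(delta) > h(k_mode$maximum))
    stop_parameter(sprintf(
      "infeasible targets: |median - mean|/sd = %.3f exceeds the %.3f the family supports",
      abs(delta), h(k_mode$maximum)))
  if (abs(delta) < h(1e6))   # negligible skew: a normal matches all three
    return(list(family = "normal", location = mean, scale = sd,
                shape = Inf, sign = 1))
  k <- stats::uniroot(function(k) h(k) - abs(delta),
                      lower = k_mode$maximum, upper = 1e6, tol = 1e-12)$root
  scale <- sd / sqrt(k)
  sgn <- if (delta > 0) -1 else 1   # median > mean: reflect (left skew)
  location <- mean - sgn * k * scale
  list(family = "gamma", location = location, scale = scale, shape = k,
       sign = sgn)
}

#' Draw from the calibrated skewed g family
#'
#' @param n number of draws.
#' @param fam a calibration from [calibrate_g_family()].
#' @return numeric vector (not yet clipped to (0, 1)).
#' @export
rg_skew <- function(n, fam) {
  if (identical(fam$family, "normal"))
    return(stats::rnorm(n, fam$location, fam$scale))
  fam$location + fam$sign * stats::rgamma(n, shape = fam$shape,
                                          scale = fam$scale)
}

.clip01 <- function(x) pmin(pmax(x, 1e-6), 1 - 1e-6)

#' Generate a synthetic matched cohort
#'
#' Draws per-patient anisotropy from the group-calibrated skew family
#' (see [calibrate_g_family()]), attaches 12-16 per-ROI g values (patient
#' mean plus small within-patient noise, clipped to (0, 1)), and fills in
#' matched clinical covariates: recurrent patients are pair-matched to
#' non-recurrent partners on age, race, Gleason patterns and pTNM stage
#' (excess patients in either group stay unmatched).  Pre-surgical PSA is
#' log-normal and independent of g.  `n_unscorable` patients have one
#' CAPRA-S field blanked (PSA, ECE or LNI) to emulate missing clinical data.
#'
#' Deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return a `qpi_cohort`: list of data frames `patients` (one row per
#'   patient: patient_id, pair_id, group, age, race, gleason_primary,
#'   gleason_secondary, ptnm, psa_ng_ml, margins, svi, ece, lni, g_mean,
#'   n_rois) and `rois` (long format: patient_id, roi_id, g).
#' @export
gen_cohort <- function(spec) {
  if (!is_cohort_spec(spec)) stop_parameter("`spec` must be a cohort_spec")
  n_r <- spec$n_recurrent; n_n <- spec$n_nonrecurrent
  n <- n_r + n_n
  empty_pat <- data.frame(
    patient_id = character(0), pair_id = character(0), group = character(0),
    age = integer(0), race = character(0), gleason_primary = integer(0),
    gleason_secondary = integer(0), ptnm = character(0),
    psa_ng_ml = numeric(0), margins = logical(0), svi = logical(0),
    ece = logical(0), lni = logical(0), g_mean = numeric(0),
    n_rois = integer(0), stringsAsFactors = FALSE)
  if (n == 0)
    return(structure(list(patients = empty_pat,
                          rois = data.frame(patient_id = character(0),
                                            roi_id = integer(0),
                                            g = numeric(0))),
                     class = "qpi_cohort"))
  fam_r <- calibrate_g_family(spec$g_recurrent[["mean"]],
                              spec$g_recurrent[["sd"]],
                              spec$g_recurrent[["median"]])
  fam_n <- calibrate_g_family(spec$g_nonrecurrent[["mean"]],
                              spec$g_nonrecurrent[["sd"]],
                              spec$g_nonrecurrent[["median"]])
  with_seed(spec$seed, {
    n_pairs <- min(n_r, n_n)
    group <- c(rep("recurrent", n_r), rep("non-recurrent", n_n))
    pair_of <- function(i, grp) {
      k <- if (grp == "recurrent") i else i - n_r
      if (k <= n_pairs) sprintf("pair_%03d", k) else NA_character_
    }
    ## matched covariates are drawn once per pair, reused for both members
    pair_age <- sample(48:75, max(n_r, n_n), replace = TRUE)
    pair_race <- sample(c("white", "black", "other"), max(n_r, n_n),
                        replace = TRUE, prob = c(0.7, 0.22, 0.08))
    gl_levels <- list(c(3, 3), c(3, 4), c(4, 3), c(4, 4), c(4, 5), c(5, 4))
    pair_gl <- sample(seq_along(gl_levels), max(n_r, n_n), replace = TRUE,
                      prob = c(0.18, 0.34, 0.22, 0.14, 0.08, 0.04))
    pair_stage <- sample(c("pT2a", "pT2b", "pT2c", "pT3a", "pT3b"),
                         max(n_r, n_n), replace = TRUE,
                         prob = c(0.15, 0.2, 0.3, 0.25, 0.1))
    idx_in_group <- c(seq_len(n_r), seq_len(n_n))
    age <- pair_age[idx_in_group]
    race <- pair_race[idx_in_group]
    gl <- pair_gl[idx_in_group]
    stage <- pair_stage[idx_in_group]
    g_pat <- .clip01(c(rg_skew(n_r, fam_r), rg_skew(n_n, fam_n)))
    psa <- exp(stats::rnorm(n, spec$psa_meanlog, spec$psa_sdlog))
    margins <- stats::runif(n) < ifelse(group == "recurrent", 0.45, 0.3)
    svi <- stats::runif(n) < ifelse(group == "recurrent", 0.25, 0.15)
    ece <- stats::runif(n) < ifelse(group == "recurrent", 0.4, 0.3)
    lni <- stats::runif(n) < 0.05
    n_rois <- sample(spec$rois_per_patient[1]:spec$rois_per_patient[2], n,
                     replace = TRUE)
    patients <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      pair_id = vapply(seq_len(n), function(i) pair_of(i, group[i]),
                       character(1)),
      group = group, age = age, race = race,
      gleason_primary = vapply(gl, function(k) gl_levels[[k]][1], numeric(1)),
      gleason_secondary = vapply(gl, function(k) gl_levels[[k]][2],
                                 numeric(1)),
      ptnm = stage, psa_ng_ml = psa, margins = margins, svi = svi,
      ece = ece, lni = lni, g_mean = NA_real_, n_rois = n_rois,
      stringsAsFactors = FALSE)
    ## blank one CAPRA-S field for exactly n_unscorable patients
    n_miss <- min(spec$n_unscorable, n)
    if (n_miss > 0) {
      miss_idx <- sample(n, n_miss)
      which_field <- sample(c("psa_ng_ml", "ece", "lni"), n_miss,
                            replace = TRUE)
      for (j in seq_len(n_miss))
        patients[[which_field[j]]][miss_idx[j]] <- NA
    }
    rois <- data.frame(
      patient_id = rep(patients$patient_id, n_rois),
      roi_id = unlist(lapply(n_rois, seq_len)),
      g = .clip01(rep(g_pat, n_rois) +
                    stats::rnorm(sum(n_rois), 0, spec$roi_sd)),
      stringsAsFactors = FALSE)
    patients$g_mean <- as.numeric(
      tapply(rois$g, factor(rois$patient_id, levels = patients$patient_id),
             mean))
    structure(list(patients = patients, rois = rois), class = "qpi_cohort")
  })
}

#' @export
print.qpi_cohort <- function(x, ...) {
  tab <- table(x$patients$group)
  cat(sprintf("<qpi_cohort> %d patients (%s), %d ROIs\n",
              nrow(x$patients),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              nrow(x$rois)))
  invisible(x)
}

#' Synthetic post-surgical PSA series
#'
#' Piecewise-exponential PSA trajectories (ng/ml, time-ordered) consistent
#' with the biochemical-recurrence rule: non-recurrent series stay at a low
#' noisy nadir, capped strictly below 0.2 ng/ml so no clause of the rule can
#' fire; recurrent series rise exponentially from the nadir and are
#' guaranteed to exceed 0.4 ng/ml.  Deterministic given `seed`.
#'
#' @param group `"recurrent"` or `"non-recurrent"`.
#' @param n_tests number of post-surgical tests, at least 5.
#' @param seed RNG seed.
#' @return numeric vector of PSA values in time order.
#' @export
gen_psa_series <- function(group = c("recurrent", "non-recurrent"),
                           n_tests = 8, seed = 1) {
  group <- match.arg(group)
  check_number(n_tests, "n_tests")
  if (n_tests < 5)
    stop_parameter(sprintf("`n_tests` must be >= 5 (got %g)", n_tests))
  n_tests <- as.integer(n_tests)
  with_seed(seed, {
    nadir <- stats::runif(1, 0.02, 0.08)
    jitter <- exp(stats::rnorm(n_tests, 0, 0.1))
    if (group == "non-recurrent") {
      pmin(nadir * jitter, 0.15)
    } else {
      rate <- log(0.6 / nadir) / (n_tests - 1)   # reach ~0.6 by the last test
      v <- nadir * exp(rate * (0:(n_tests - 1))) * jitter
      v[n_tests] <- max(v[n_tests], 0.45)        # guarantee the > 0.4 clause
      v
    }
  })
}
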