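#' Aggregate per-ROI anisotropy to one value per patient
#'
#' The analysis unit for histograms and ROC curves is the patient; each
#' patient contributes 12-16 stromal regions.  Default aggregation is the
#' arithmetic mean; the median is available.
#'
#' @param roi_g_values numeric vector of per-ROI g values (>= 1 value).
#' @param method `"mean"` (default) or `"median"`.
#' @return scalar g.
#' @export
aggregate_patient_g <- function(roi_g_values, method = c("mean", "median")) {
  method <- match.arg(method)
  if (!is.numeric(roi_g_values) || length(roi_g_values) < 1L ||
      !all(is.finite(roi_g_values)))
    stop_data("`roi_g_values` must hold at least one finite value")
  if (method == "mean") mean(roi_g_values) else stats::median(roi_g_values)
}

#' Histogram of anisotropy values with fixed bin width
#'
#' Half-open bins `[k*w, (k+1)*w)` anchored at zero; counts sum to the
#' number of values.
#'
#' @param values numeric vector of g values in (0, 1).
#' @param bin_width bin width (default 0.01).
#' @return data frame `bin_left`, `bin_right`, `count` (empty for empty
#'   input).
#' @export
g_histogram <- function(values, bin_width = 0.01) {
  check_number(bin_width, "bin_width", lower = 0, strict_lower = TRUE)
  if (length(values) == 0)
    return(data.frame(bin_left = numeric(0), bin_right = numeric(0),
                      count = integer(0)))
  if (!is.numeric(values) || !all(is.finite(values)) ||
      any(values <= 0 | values >= 1))
    stop_data("`values` must be finite and strictly inside (0, 1)")
  k <- floor(values / bin_width)
  ks <- min(k):max(k)
  count <- as.integer(table(factor(k, levels = ks)))
  data.frame(bin_left = ks * bin_width, bin_right = (ks + 1) * bin_width,
             count = count)
}

#' Welch two-sample t-test from group summaries
#'
#' Welch statistic with Welch-Satterthwaite degrees of freedom and two-sided
#' p-value, computed from (mean, sd, n) per group — usable directly on
#' published summary rows.  [welch_t_test()] is the raw-sample front end; it
#' computes the summaries and calls this, so the two paths agree exactly.
#'
#' @param m1,s1,n1 mean, sd (> 0), size (>= 2) of group 1.
#' @param m2,s2,n2 likewise for group 2.
#' @return list `t`, `df`, `p` (two-sided).
#' @export
welch_t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  check_number(m1, "m1"); check_number(m2, "m2")
  check_number(s1, "s1", lower = 0, strict_lower = TRUE)
  check_number(s2, "s2", lower = 0, strict_lower = TRUE)
  check_number(n1, "n1", lower = 2); check_number(n2, "n2", lower = 2)
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' @rdname welch_t_from_summary
#' @param x,y raw samples (length >= 2 each, positive variance).
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop_data("both samples need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_data("zero-variance sample: Welch test undefined")
  welch_t_from_summary(mean(x), stats::sd(x), length(x),
                       mean(y), stats::sd(y), length(y))
}

.check_two_class <- function(is_pos) {
  if (!any(is_pos) || all(is_pos))
    stop_stat("both classes must be present")
}

.as_positive <- function(labels, positive = "recurrent") {
  if (is.logical(labels)) return(labels)
  if (anyNA(labels)) stop_data("labels must not contain NA")
  labels == positive
}

#' ROC area under the curve for an anisotropy-style score
#'
#' Rank (Mann-Whitney) AUC estimator with midrank tie handling.  The
#' `direction` flag encodes that a *lower* g scores toward the positive
#' (recurrent) class; pass `"higher_score_positive"` for risk scores that
#' increase with risk (e.g. CAPRA-S).  An optional seeded percentile
#' bootstrap (resampling patients) yields a confidence interval.
#'
#' @param labels logical (TRUE = positive) or character vector; character
#'   labels are compared against `positive`.
#' @param scores numeric scores, same length.
#' @param direction `"lower_score_positive"` (default) or
#'   `"higher_score_positive"`.
#' @param positive label counted as the positive class (default
#'   `"recurrent"`).
#' @param n_boot bootstrap replicates for the CI (0 = none).
#' @param conf confidence level (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @return an `roc_result`: `auc`, `n_pos`, `n_neg`, `direction`, and
#'   `ci_lower`/`ci_upper` when bootstrapped.
#' @export
roc_auc <- function(labels, scores,
                    direction = c("lower_score_positive",
                                  "higher_score_positive"),
                    positive = "recurrent", n_boot = 0, conf = 0.95,
                    seed = 1) {
  direction <- match.arg(direction)
  is_pos <- .as_positive(labels, positive)
  if (length(is_pos) != length(scores))
    stop_data("labels and scores must have equal length")
  if (anyNA(scores) || !all(is.finite(scores)))
    stop_data("scores must be finite")
  .check_two_class(is_pos)
  s <- if (direction == "lower_score_positive") -scores else scores
  auc_of <- function(is_pos, s) {
    n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
    r <- rank(s)  # midranks
    (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  auc <- auc_of(is_pos, s)
  out <- list(auc = auc, n_pos = sum(is_pos), n_neg = sum(!is_pos),
              direction = direction, ci_lower = NA_real_,
              ci_upper = NA_real_)
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        repeat {
          i <- sample(length(s), replace = TRUE)
          if (any(is_pos[i]) && !all(is_pos[i]))
            return(auc_of(is_pos[i], s[i]))
        }
      }, numeric(1))
    })
    alpha <- (1 - conf) / 2
    qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE)
    out$ci_lower <- qs[1]; out$ci_upper <- qs[2]
  }
  structure(out, class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (%d pos / %d neg, %s)%s\n",
              x$auc, x$n_pos, x$n_neg, x$direction,
              if (is.na(x$ci_lower)) "" else
                sprintf(", CI [%.3f, %.3f]", x$ci_lower, x$ci_upper)))
  invisible(x)
}

#' Sensitivity and specificity at a g threshold
#'
#' Predicts recurrence when `g < threshold` (strict: a value exactly at the
#' threshold is predicted non-recurrent).  Sensitivity is the fraction of
#' positive (recurrent) patients below the threshold; specificity the
#' fraction of negatives at or above it.
#'
#' @inheritParams roc_auc
#' @param g_values per-patient anisotropy values.
#' @param threshold decision cut-off (default 0.938).
#' @return list `sensitivity`, `specificity`, `threshold`.
#' @export
sens_spec_at_threshold <- function(labels, g_values, threshold = 0.938,
                                   positive = "recurrent") {
  is_pos <- .as_positive(labels, positive)
  if (length(is_pos) != length(g_values))
    stop_data("labels and g_values must have equal length")
  .check_two_class(is_pos)
  pred_pos <- g_values < threshold
  list(sensitivity = mean(pred_pos[is_pos]),
       specificity = mean(!pred_pos[!is_pos]),
       threshold = threshold)
}

#' Youden-optimal g threshold
#'
#' Exhaustive search over candidate cut points (midpoints between
#' consecutive sorted unique g values, plus one candidate below the minimum
#' and one above the maximum) for the threshold maximizing Youden's J =
#' sensitivity + specificity - 1 under the strict `g < t` rule; ties break
#' toward the higher threshold.  Candidates are data-relative, so shifting
#' every g by a constant shifts the threshold by the same constant.
#'
#' @inheritParams sens_spec_at_threshold
#' @return scalar threshold.
#' @export
youden_threshold <- function(labels, g_values, positive = "recurrent") {
  is_pos <- .as_positive(labels, positive)
  .check_two_class(is_pos)
  u <- sort(unique(g_values))
  gap <- if (length(u) > 1) min(diff(u)) / 2 else 0.5
  cand <- c(u[1] - gap, (u[-1] + u[-length(u)]) / 2, u[length(u)] + gap)
  j <- vapply(cand, function(t) {
    ss <- sens_spec_at_threshold(is_pos, g_values, t)
    ss$sensitivity + ss$specificity - 1
  }, numeric(1))
  max(cand[j >= max(j) - 1e-12])   # tie-break: highest threshold
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors, equal length >= 3, finite, each with
#'   positive variance.
#' @return scalar correlation.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_data("x and y must have equal length")
  if (length(x) < 3L) stop_data("at least 3 pairs are required")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_data("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_stat("zero variance: correlation undefined")
  stats::cor(x, y)
}

#' CAPRA-S point table
#'
#' The component points of the post-surgical CAPRA-S risk score (total
#' 0-12).  Shipped as an editable CSV
#' (`system.file("extdata", "capra_s_points.csv", package = "qpianiso")`) so
#' the table can be corrected without code changes; this loader parses that
#' CSV (or a user-supplied one with the same `item,points` layout).
#'
#' @param path optional path to an alternative points CSV.
#' @return named list of component points.
#' @export
capra_s_points <- function(path = NULL) {
  path <- path %||% system.file("extdata", "capra_s_points.csv",
                                package = "qpianiso")
  if (!nzchar(path) || !file.exists(path))
    stop_io("CAPRA-S points table not found")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("item", "points") %in% names(tab)))
    stop_io("points table must have columns `item`, `points`")
  as.list(stats::setNames(tab$points, tab$item))
}

#' CAPRA-S post-surgical risk score
#'
#' Component sum (total 0-12): pre-surgical PSA in ng/ml (<= 6: 0, (6, 10]:
#' 1, (10, 20]: 2, > 20: 3); pathologic Gleason (sum <= 6: 0, 3+4: 1, 4+3:
#' 2, sum 8-10: 3; a Gleason-7 with primary pattern >= 4 counts as 4+3);
#' positive surgical margins +2; seminal vesicle invasion +2;
#' extracapsular extension +1; lymph node invasion +1.  Any missing field
#' makes the patient unscorable — an error naming the missing fields, never
#' a silent partial score.
#'
#' @param psa_ng_ml pre-surgical PSA, ng/ml (> 0).
#' @param gleason_primary,gleason_secondary pathologic Gleason patterns,
#'   1-5.
#' @param margins_positive,svi,ece,lni logical flags (surgical margins,
#'   seminal vesicle invasion, extracapsular extension, lymph node
#'   invasion).
#' @param points a table from [capra_s_points()].
#' @return list `total` (0-12) and `components` (named breakdown).
#' @export
capra_s_score <- function(psa_ng_ml, gleason_primary, gleason_secondary,
                          margins_positive, svi, ece, lni,
                          points = capra_s_points()) {
  vals <- list(psa_ng_ml = psa_ng_ml, gleason_primary = gleason_primary,
               gleason_secondary = gleason_secondary,
               margins_positive = margins_positive, svi = svi, ece = ece,
               lni = lni)
  miss <- names(vals)[vapply(vals, function(v)
    is.null(v) || length(v) != 1L || is.na(v), logical(1))]
  if (length(miss) > 0)
    stop_unscorable(sprintf("unscorable: missing field(s) %s",
                            paste(miss, collapse = ", ")),
                    missing_fields = miss)
  check_number(psa_ng_ml, "psa_ng_ml", lower = 0, strict_lower = TRUE)
  check_number(gleason_primary, "gleason_primary", lower = 1, upper = 5)
  check_number(gleason_secondary, "gleason_secondary", lower = 1, upper = 5)
  for (nm in c("margins_positive", "svi", "ece", "lni"))
    if (!is_flag(vals[[nm]]))
      stop_parameter(sprintf("`%s` must be TRUE or FALSE", nm))
  psa_pts <- if (psa_ng_ml <= 6) points$psa_le6 else
    if (psa_ng_ml <= 10) points$psa_6_10 else
      if (psa_ng_ml <= 20) points$psa_10_20 else points$psa_gt20
  gsum <- gleason_primary + gleason_secondary
  gl_pts <- if (gsum >= 8) points$gleason_8_10 else
    if (gsum == 7 && gleason_primary >= 4) points$gleason_43 else
      if (gsum == 7) points$gleason_34 else points$gleason_le33
  comp <- c(psa = psa_pts, gleason = gl_pts,
            margins = if (margins_positive) points$margins else 0,
            svi = if (svi) points$svi else 0,
            ece = if (ece) points$ece else 0,
            lni = if (lni) points$lni else 0)
  list(total = sum(comp), components = comp)
}

#' Biochemical recurrence rule for a PSA series
#'
#' A time-ordered post-surgical PSA series indicates recurrence when any
#' value exceeds 0.4 ng/ml, or when some value above 0.2 ng/ml is followed
#' by at least two later measurements forming a strictly increasing run
#' above it (values at indices i < j < k with `v[i] > 0.2` and
#' `v[i] < v[j] < v[k]`; the run need not be consecutive).
#'
#' @param psa_series numeric vector of PSA values, ng/ml, in time order
#'   (>= 1 value, none negative).
#' @param threshold_single single-value threshold (default 0.4).
#' @param threshold_rise rising-run threshold (default 0.2).
#' @return logical: recurrence detected.
#' @export
classify_recurrence <- function(psa_series, threshold_single = 0.4,
                                threshold_rise = 0.2) {
  if (!is.numeric(psa_series) || length(psa_series) < 1L ||
      anyNA(psa_series))
    stop_data("`psa_series` must hold at least one PSA value")
  if (any(psa_series < 0))
    stop_data("negative PSA value in series")
  if (any(psa_series > threshold_single)) return(TRUE)
  n <- length(psa_series)
  if (n < 3L) return(FALSE)
  for (i in seq_len(n - 2L)) {
    v <- psa_series[i]
    if (v <= threshold_rise) next
    later <- psa_series[(i + 1L):n]
    best <- Inf   # smallest later value already exceeding v
    for (w in later) {
      if (w > best) return(TRUE)
      if (w > v) best <- min(best, w)
    }
  }
  FALSE
}

#' PSA-stratified comparison of anisotropy and CAPRA-S
#'
#' Splits patients into the PSA ranges used by the CAPRA-S score — (0, 6],
#' (6, 10], (10, 20], (20, Inf) ng/ml, so PSA = 6.0 falls in the first
#' stratum and 6.01 in the second — and computes within each stratum the
#' AUC of anisotropy (lower g = positive) and of CAPRA-S (higher score =
#' positive).  Strata containing a single class (or no patients) report NA
#' AUCs.  Patients without PSA are excluded; patients unscorable for
#' CAPRA-S are excluded from the CAPRA-S AUC only.
#'
#' @param patients data frame with columns `group`, `psa_ng_ml`, a g column
#'   (`g_mean`) and a `capra_s` column (NA where unscorable).
#' @param strata inner stratum boundaries, ng/ml (default `c(6, 10, 20)`).
#' @param positive positive-class label.
#' @return data frame: `stratum`, `psa_lo`, `psa_hi`, `n_rec`, `n_nonrec`,
#'   `auc_g`, `auc_capra`.
#' @export
psa_stratified_comparison <- function(patients, strata = c(6, 10, 20),
                                      positive = "recurrent") {
  for (col in c("group", "psa_ng_ml", "g_mean", "capra_s"))
    if (!col %in% names(patients))
      stop_data(sprintf("`patients` must have column `%s`", col))
  if (any(strata <= 0) || is.unsorted(strata, strictly = TRUE))
    stop_parameter("`strata` must be strictly increasing positive bounds")
  edges <- c(0, strata, Inf)
  keep <- !is.na(patients$psa_ng_ml)
  p <- patients[keep, , drop = FALSE]
  bin <- findInterval(p$psa_ng_ml, edges, left.open = TRUE)
  out <- data.frame(
    stratum = character(0), psa_lo = numeric(0), psa_hi = numeric(0),
    n_rec = integer(0), n_nonrec = integer(0), auc_g = numeric(0),
    auc_capra = numeric(0), stringsAsFactors = FALSE)
  for (s in seq_len(length(edges) - 1L)) {
    ps <- p[bin == s, , drop = FALSE]
    is_pos <- ps$group == positive
    auc_g <- auc_c <- NA_real_
    if (nrow(ps) > 0 && any(is_pos) && !all(is_pos)) {
      auc_g <- roc_auc(is_pos, ps$g_mean,
                       direction = "lower_score_positive")$auc
      sc <- !is.na(ps$capra_s)
      if (any(is_pos[sc]) && !all(is_pos[sc]))
        auc_c <- roc_auc(is_pos[sc], ps$capra_s[sc],
                         direction = "higher_score_positive")$auc
    }
    out <- rbind(out, data.frame(
      stratum = sprintf("(%g, %g]", edges[s], edges[s + 1L]),
      psa_lo = edges[s], psa_hi = edges[s + 1L],
      n_rec = sum(is_pos), n_nonrec = sum(!is_pos),
      auc_g = auc_g, auc_capra = auc_c, stringsAsFactors = FALSE))
  }
  out
}
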